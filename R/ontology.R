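#' Construct a syndrome ontology
#'
#' The knowledge base behind relation refinement: a set of named syndrome
#' classes plus three axiom families.
#' \describe{
#'   \item{equivalence}{unordered pairs of names denoting the same syndrome
#'     concept (same class extension);}
#'   \item{subclass}{(child, parent) is-a edges: the child syndrome inherits
#'     the symptoms associated with its superclass;}
#'   \item{subsume}{(whole, part) edges: a compound syndrome captures the
#'     union of all symptoms of its part syndromes.}
#' }
#' Edge endpoints are added to `classes` automatically. The subclass graph
#' must be acyclic and subsume must be irreflexive.
#'
#' @param classes Character vector of syndrome names.
#' @param equivalence Data frame with columns `a`, `b` (unordered pairs).
#' @param subclass Data frame with columns `child`, `parent`.
#' @param subsume Data frame with columns `whole`, `part`.
#' @return An object of class `syndrome_ontology`.
#' @export
syndrome_ontology <- function(classes = character(),
                              equivalence = NULL,
                              subclass = NULL,
                              subsume = NULL) {
  as_pairs <- function(df, cols) {
    if (is.null(df) || nrow(as.data.frame(df)) == 0L) {
      out <- tibble::tibble(x = character(), y = character())
      names(out) <- cols
      return(out)
    }
    df <- tibble::as_tibble(df)
    names(df)[1:2] <- cols
    dplyr::distinct(df[, cols])
  }
  equivalence <- as_pairs(equivalence, c("a", "b"))
  subclass <- as_pairs(subclass, c("child", "parent"))
  subsume <- as_pairs(subsume, c("whole", "part"))
  if (any(subsume$whole == subsume$part)) {
    rlang::abort("`subsume` must be irreflexive (a syndrome cannot subsume itself).",
      class = "tcmdx_invalid_ontology"
    )
  }
  if (any(equivalence$a == equivalence$b)) {
    equivalence <- equivalence[equivalence$a != equivalence$b, ]
  }
  classes <- sort(unique(c(
    as.character(classes),
    equivalence$a, equivalence$b,
    subclass$child, subclass$parent,
    subsume$whole, subsume$part
  )))
  ont <- structure(
    list(
      classes = classes,
      equivalence = equivalence,
      subclass = subclass,
      subsume = subsume
    ),
    class = "syndrome_ontology"
  )
  check_subclass_acyclic(ont)
  ont
}

# DFS three-colour cycle check on the child -> parent graph.
check_subclass_acyclic <- function(ont) {
  adj <- split(ont$subclass$parent, ont$subclass$child)
  state <- new.env(parent = emptyenv())
  visit <- function(node) {
    s <- state[[node]]
    if (identical(s, "done")) {
      return(invisible(NULL))
    }
    if (identical(s, "active")) {
      rlang::abort(sprintf("Subclass graph contains a cycle through %s.", dQuote(node)),
        class = "tcmdx_invalid_ontology"
      )
    }
    state[[node]] <- "active"
    for (p in adj[[node]]) visit(p)
    state[[node]] <- "done"
    invisible(NULL)
  }
  for (node in unique(ont$subclass$child)) visit(node)
  invisible(ont)
}

#' @export
print.syndrome_ontology <- function(x, ...) {
  s <- ontology_stats(x)
  cat(sprintf(
    "<syndrome_ontology> %d classes | %d subclass | %d equivalent | %d subsume axioms\n",
    s$classes, s$subclass_axioms, s$equivalent_axioms, s$subsume_axioms
  ))
  invisible(x)
}

# Strip a URI down to its local name: fragment after '#', else last path
# segment when the string looks like a URL; plain names pass through.
local_name <- function(x) {
  x <- trimws(x)
  frag <- sub("^.*#", "", x)
  ifelse(
    grepl("#", x),
    frag,
    ifelse(grepl("^[a-zA-Z][a-zA-Z0-9+.-]*://", x), sub("^.*/", "", x), x)
  )
}

# Attribute lookup by local name, ignoring any namespace prefix.
attr_local <- function(node, name) {
  a <- xml2::xml_attrs(node)
  hit <- sub("^.*:", "", names(a)) == name
  if (!any(hit)) {
    return(NA_character_)
  }
  unname(a[hit][1L])
}

parse_owl_ontology <- function(path) {
  doc <- xml2::read_xml(path)
  class_nodes <- xml2::xml_find_all(doc, ".//*[local-name() = 'Class']")
  classes <- character()
  eq <- list()
  sub <- list()
  subsume <- list()
  for (node in class_nodes) {
    about <- attr_local(node, "about")
    if (is.na(about)) about <- attr_local(node, "ID")
    if (is.na(about)) next
    this <- local_name(about)
    classes <- c(classes, this)
    for (child in xml2::xml_children(node)) {
      tag <- xml2::xml_name(child)
      if (tag == "equivalentClass") {
        res <- attr_local(child, "resource")
        if (!is.na(res)) {
          eq[[length(eq) + 1L]] <- c(this, local_name(res))
          next
        }
        restr <- xml2::xml_find_first(child, ".//*[local-name() = 'Restriction']")
        if (inherits(restr, "xml_node")) {
          on_prop <- xml2::xml_find_first(restr, ".//*[local-name() = 'onProperty']")
          some <- xml2::xml_find_first(restr, ".//*[local-name() = 'someValuesFrom']")
          prop <- if (inherits(on_prop, "xml_node")) local_name(attr_local(on_prop, "resource")) else NA
          if (identical(tolower(prop), "subsume") && inherits(some, "xml_node")) {
            part <- attr_local(some, "resource")
            if (!is.na(part)) {
              subsume[[length(subsume) + 1L]] <- c(this, local_name(part))
            }
          } else {
            rlang::warn(sprintf(
              "Skipping restriction on unknown property %s for class %s.",
              dQuote(as.character(prop)), dQuote(this)
            ))
          }
        }
      } else if (tag == "subClassOf") {
        res <- attr_local(child, "resource")
        if (!is.na(res)) sub[[length(sub) + 1L]] <- c(this, local_name(res))
      }
    }
  }
  to_df <- function(lst, cols) {
    if (!length(lst)) {
      return(NULL)
    }
    m <- do.call(rbind, lst)
    stats::setNames(tibble::tibble(x = m[, 1], y = m[, 2]), cols)
  }
  syndrome_ontology(
    classes = classes,
    equivalence = to_df(eq, c("a", "b")),
    subclass = to_df(sub, c("child", "parent")),
    subsume = to_df(subsume, c("whole", "part"))
  )
}

parse_tsv_ontology <- function(path) {
  df <- readr::read_tsv(
    path,
    col_names = c("subject", "predicate", "object"),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (nrow(df) == 0L) {
    return(syndrome_ontology())
  }
  known <- c("class", "equivalent", "is_a", "subsume")
  bad <- setdiff(unique(df$predicate), known)
  if (length(bad)) {
    rlang::warn(sprintf(
      "Skipping %d triple(s) with unknown predicate(s): %s.",
      sum(df$predicate %in% bad), paste(bad, collapse = ", ")
    ))
    df <- df[df$predicate %in% known, ]
  }
  pick <- function(p) df[df$predicate == p, c("subject", "object")]
  syndrome_ontology(
    classes = df$subject[df$predicate == "class"],
    equivalence = stats::setNames(pick("equivalent"), c("a", "b")),
    subclass = stats::setNames(pick("is_a"), c("child", "parent")),
    subsume = stats::setNames(pick("subsume"), c("whole", "part"))
  )
}

#' Load a syndrome ontology from OWL/RDF-XML or the triple TSV dialect
#'
#' Two formats are accepted and auto-detected. (1) OWL in RDF/XML using the
#' common idioms: `owl:Class` declarations, `owl:equivalentClass` between
#' named classes, `owl:equivalentClass` wrapping an `owl:Restriction` on a
#' property locally named `subsume` with `owl:someValuesFrom` a named class
#' (read as a whole/part subsume edge), and `rdfs:subClassOf` between named
#' classes. Restrictions on other properties are skipped with a warning.
#' (2) A header-less 3-column TSV of triples `subject  predicate  object`
#' with predicates `class` (object ignored), `equivalent`, `is_a`,
#' `subsume`.
#'
#' @param path Path to the ontology document.
#' @return A [syndrome_ontology()] object.
#' @export
read_ontology <- function(path) {
  head_txt <- readr::read_file(path)
  if (grepl("^\\s*<", head_txt)) {
    parse_owl_ontology(path)
  } else {
    parse_tsv_ontology(path)
  }
}

#' Write a syndrome ontology in the triple TSV dialect
#'
#' Inverse of the TSV reader: emits one `class` triple per named class (with
#' `"."` as placeholder object) followed by `equivalent`, `is_a` and
#' `subsume` triples. A write/read round trip preserves all four axiom sets
#' exactly.
#'
#' @param ont A [syndrome_ontology()].
#' @param path Output path.
#' @return `ont`, invisibly.
#' @export
write_ontology <- function(ont, path) {
  df <- dplyr::bind_rows(
    tibble::tibble(subject = ont$classes, predicate = "class", object = "."),
    tibble::tibble(
      subject = ont$equivalence$a, predicate = "equivalent",
      object = ont$equivalence$b
    ),
    tibble::tibble(
      subject = ont$subclass$child, predicate = "is_a",
      object = ont$subclass$parent
    ),
    tibble::tibble(
      subject = ont$subsume$whole, predicate = "subsume",
      object = ont$subsume$part
    )
  )
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(ont)
}

#' Equivalence class of a syndrome name
#'
#' Reflexive-symmetric-transitive closure of the equivalence axioms
#' containing `name`. Unknown names yield the singleton `{name}`.
#'
#' @param ont A [syndrome_ontology()].
#' @param name Syndrome name.
#' @return Character vector of equivalent names (including `name`).
#' @export
equivalence_set <- function(ont, name) {
  seen <- name
  frontier <- name
  while (length(frontier)) {
    nxt <- unique(c(
      ont$equivalence$b[ont$equivalence$a %in% frontier],
      ont$equivalence$a[ont$equivalence$b %in% frontier]
    ))
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  sort(unique(seen))
}

#' Ancestor syndromes under the is-a hierarchy
#'
#' Transitive closure upward over subclass edges, excluding `name` itself.
#'
#' @inheritParams equivalence_set
#' @return Character vector of (strict) ancestors; empty for roots and
#'   unknown names.
#' @export
syndrome_ancestors <- function(ont, name) {
  seen <- character()
  frontier <- name
  while (length(frontier)) {
    parents <- unique(ont$subclass$parent[ont$subclass$child %in% frontier])
    frontier <- setdiff(parents, c(seen, name))
    seen <- c(seen, frontier)
  }
  sort(unique(seen))
}

#' Direct parts of a compound (subsuming) syndrome
#'
#' @inheritParams equivalence_set
#' @return Character vector of the syndromes directly subsumed by `name`
#'   (no transitive closure).
#' @export
subsumed_parts <- function(ont, name) {
  sort(unique(ont$subsume$part[ont$subsume$whole == name]))
}

#' Compound syndromes that subsume a given syndrome
#'
#' Inverse of [subsumed_parts()].
#'
#' @inheritParams equivalence_set
#' @return Character vector of wholes whose parts include `name`.
#' @export
subsumers_of <- function(ont, name) {
  sort(unique(ont$subsume$whole[ont$subsume$part == name]))
}

#' Effective symptom set of a syndrome under ontology closure
#'
#' Unions three sources: (a) the mapping-table symptoms of every member of
#' the name's equivalence class; (b) the table symptoms of every is-a
#' ancestor (the subclass inherits its superclass's symptoms); and (c),
#' recursively, the effective symptoms of every subsumed part (the compound
#' captures all symptoms of its parts). Subsume recursion is cycle-checked.
#'
#' @param table A `mapping_table` tibble (see [build_mapping_table()]).
#' @param ont A [syndrome_ontology()].
#' @param name Syndrome name.
#' @param kind Entry kind looked up in the table (default `"syndrome"`).
#' @param merge_equivalents If `TRUE`, subclass and subsume edges of
#'   equivalent names are treated as edges of `name` too (default `FALSE`:
#'   equivalence contributes symptoms only).
#' @return Sorted character vector of symptoms.
#' @export
effective_symptoms <- function(table, ont, name, kind = "syndrome",
                               merge_equivalents = FALSE) {
  rec <- function(nm, stack) {
    if (nm %in% stack) {
      rlang::abort(sprintf("Subsume cycle detected through %s.", dQuote(nm)),
        class = "tcmdx_invalid_ontology"
      )
    }
    eq <- equivalence_set(ont, nm)
    anchors <- if (merge_equivalents) eq else nm
    anc <- unique(unlist(lapply(anchors, function(a) syndrome_ancestors(ont, a))))
    direct <- unlist(lapply(
      unique(c(eq, anc)),
      function(n) table_symptoms(table, n, kind = kind)
    ))
    parts <- unique(unlist(lapply(anchors, function(a) subsumed_parts(ont, a))))
    c(direct, unlist(lapply(parts, rec, stack = c(stack, nm))))
  }
  sort(unique(as.character(rec(name, character()))))
}

#' Axiom counts of a syndrome ontology
#'
#' Raw counts as parsed (not closures). Only named classes are counted;
#' anonymous restriction classes introduced by the OWL subsume idiom are not.
#'
#' @param ont A [syndrome_ontology()].
#' @return A one-row tibble with columns `classes`, `subclass_axioms`,
#'   `equivalent_axioms`, `subsume_axioms`.
#' @export
ontology_stats <- function(ont) {
  tibble::tibble(
    classes = length(ont$classes),
    subclass_axioms = nrow(ont$subclass),
    equivalent_axioms = nrow(ont$equivalence),
    subsume_axioms = nrow(ont$subsume)
  )
}
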