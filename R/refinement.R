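#' Set relation between an input symptom set and a candidate entry
#'
#' Compares the input set S with a candidate syndrome's symptom set T under
#' exact normalized equality (by default) and classifies the relation into
#' one of five mutually exclusive kinds driving refinement:
#' \describe{
#'   \item{equal}{S = T: the candidate (or an equivalent) is a perfect
#'     answer;}
#'   \item{input_superset}{T is a proper subset of S: the input covers more;
#'     compound syndromes that subsume the candidate come into play;}
#'   \item{input_subset}{S is a proper subset of T: a smaller set may fit
#'     better; superclasses are considered;}
#'   \item{partial}{the sets overlap with Jaccard index at or above
#'     `overlap_threshold`: the unmatched part is recalculated for combined
#'     syndromes;}
#'   \item{disjoint}{anything else.}
#' }
#'
#' @param input Non-empty character vector S of normalized input symptoms.
#' @param candidate Non-empty character vector T: the candidate's symptoms.
#' @param overlap_threshold Jaccard threshold for `partial` (default 0.3).
#' @param fuzzy If `TRUE`, a symptom counts as matched when its best fuzzy
#'   weight against the other set reaches `fuzzy_cutoff`, instead of exact
#'   equality (default `FALSE`: crisp set algebra).
#' @param fuzzy_cutoff Weight cutoff for fuzzy membership (default 0.8).
#' @return A length-1 character: one of `"equal"`, `"input_superset"`,
#'   `"input_subset"`, `"partial"`, `"disjoint"`.
#' @export
match_relation <- function(input, candidate, overlap_threshold = 0.3,
                           fuzzy = FALSE, fuzzy_cutoff = 0.8) {
  if (length(input) == 0L || length(candidate) == 0L) {
    rlang::abort("`input` and `candidate` must both be non-empty.",
      class = "tcmdx_invalid_input"
    )
  }
  if (overlap_threshold <= 0 || overlap_threshold > 1) {
    rlang::abort("`overlap_threshold` must lie in (0, 1].")
  }
  S <- unique(input)
  T <- unique(candidate)
  fuzzy_member <- function(x, set) {
    vapply(
      x,
      function(q) best_weight(q, set)$weight >= fuzzy_cutoff,
      logical(1)
    )
  }
  in_T <- if (fuzzy) fuzzy_member(S, T) else S %in% T
  in_S <- if (fuzzy) fuzzy_member(T, S) else T %in% S
  if (all(in_T) && all(in_S)) {
    return("equal")
  }
  if (all(in_S)) {
    return("input_superset")
  }
  if (all(in_T)) {
    return("input_subset")
  }
  n_matched <- sum(in_T)
  jaccard <- n_matched / (length(S) + length(T) - sum(in_S))
  if (n_matched > 0L && jaccard >= overlap_threshold) "partial" else "disjoint"
}

#' Greedy decomposition of a partially matched input into combined syndromes
#'
#' When the input only overlaps a single candidate, it often reflects
#' several syndromes occurring together with one disease. This greedy cover
#' repeatedly ranks the syndrome entries against the remaining input,
#' accepts the top candidate, removes the symptoms it matches, and recurses
#' on the remainder. The loop stops when the remainder shrinks below
#' `min_remainder`, the best score does not exceed `min_score`, or
#' `max_components` components have been accepted.
#'
#' @param input Non-empty character vector of normalized input symptoms.
#' @param table A `mapping_table` tibble.
#' @param ont Optional [syndrome_ontology()]; when supplied, matching and
#'   scoring use each candidate's [effective_symptoms()] closure.
#' @param min_remainder Stop when fewer input symptoms remain (default 1,
#'   i.e. run until the remainder is empty).
#' @param min_score Accept a component only while the best similarity is
#'   strictly above this (default 0).
#' @param max_components Cap on accepted components (default 4).
#' @return A tibble with one row per accepted component: `component` (rank
#'   order), `name`, `sim`, `exact_count`, `matched` (list of input symptoms
#'   the component accounts for). Attributes: `residual` (input symptoms no
#'   component matched) and `exhausted` (`TRUE` when no candidate ever
#'   scored above `min_score`).
#' @export
decompose_partial <- function(input, table, ont = NULL,
                              min_remainder = 1L, min_score = 0,
                              max_components = 4L) {
  if (length(input) == 0L) {
    rlang::abort("`input` must be non-empty.", class = "tcmdx_invalid_input")
  }
  remainder <- unique(input)
  used <- character()
  comps <- list()
  while (length(remainder) >= min_remainder && length(comps) < max_components) {
    pool <- table[table$kind == "syndrome" & !(table$name %in% used), ]
    if (nrow(pool) == 0L) break
    if (!is.null(ont)) {
      pool$symptoms <- purrr::map(
        pool$name, function(nm) effective_symptoms(table, ont, nm)
      )
      pool <- pool[lengths(pool$symptoms) > 0L, ]
      if (nrow(pool) == 0L) break
    }
    ranked <- rank_candidates(pool, remainder, kind = "syndrome")
    best <- ranked[1L, ]
    if (best$sim <= min_score) break
    matched <- intersect(remainder, best$symptoms[[1L]])
    if (length(matched) == 0L) break
    comps[[length(comps) + 1L]] <- tibble::tibble(
      component = length(comps) + 1L,
      name = best$name,
      sim = best$sim,
      exact_count = best$exact_count,
      matched = list(matched)
    )
    used <- c(used, best$name)
    remainder <- setdiff(remainder, matched)
  }
  out <- if (length(comps)) {
    purrr::list_rbind(comps)
  } else {
    tibble::tibble(
      component = integer(), name = character(), sim = numeric(),
      exact_count = integer(), matched = list()
    )
  }
  attr(out, "residual") <- remainder
  attr(out, "exhausted") <- length(comps) == 0L
  out
}

#' Refine an initial candidate syndrome through the ontology
#'
#' Applies the refinement strategy selected by the set relation between the
#' input and the candidate's symptoms: `equal` adds the candidate's
#' equivalents; `input_superset` adds the compound syndromes that subsume
#' it; `input_subset` adds its is-a superclasses; `partial` delegates to
#' [decompose_partial()] and adds the resulting components; `disjoint`
#' leaves the candidate unchanged with a warning. All refined candidates are
#' re-scored with [set_similarity()] against their ontology-expanded
#' [effective_symptoms()], and the result is re-ranked. The initial
#' candidate is always retained, so refinement never returns an empty set.
#'
#' @param input Non-empty character vector of normalized input symptoms.
#' @param candidate Initial candidate syndrome name (present in the table or
#'   the ontology).
#' @param table A `mapping_table` tibble.
#' @param ont A [syndrome_ontology()].
#' @param relation Optional relation kind; computed with [match_relation()]
#'   from the candidate's table symptoms when `NULL`.
#' @param overlap_threshold Passed to [match_relation()].
#' @param ... Passed to [decompose_partial()] for the `partial` strategy.
#' @return A tibble of refined candidates in rank order with columns `name`,
#'   `provenance` (`self`, `equivalent`, `subsumer`, `superclass` or
#'   `decomposition`), `sim`, `exact_count`, `weight_sum`, `list_size`.
#'   Attribute `relation` records the strategy applied.
#' @export
refine <- function(input, candidate, table, ont, relation = NULL,
                   overlap_threshold = 0.3, ...) {
  if (is.null(relation)) {
    T <- table_symptoms(table, candidate, kind = "syndrome")
    if (length(T) == 0L) T <- effective_symptoms(table, ont, candidate)
    relation <- if (length(T)) {
      match_relation(input, T, overlap_threshold = overlap_threshold)
    } else {
      "disjoint"
    }
  }
  relation <- match.arg(
    relation,
    c("equal", "input_superset", "input_subset", "partial", "disjoint")
  )
  cand <- tibble::tibble(name = candidate, provenance = "self")
  extra <- switch(relation,
    equal = tibble::tibble(
      name = setdiff(equivalence_set(ont, candidate), candidate),
      provenance = "equivalent"
    ),
    input_superset = tibble::tibble(
      name = subsumers_of(ont, candidate),
      provenance = "subsumer"
    ),
    input_subset = tibble::tibble(
      name = syndrome_ancestors(ont, candidate),
      provenance = "superclass"
    ),
    partial = {
      comps <- decompose_partial(input, table, ont = ont, ...)
      tibble::tibble(
        name = setdiff(comps$name, candidate),
        provenance = "decomposition"
      )
    },
    disjoint = {
      rlang::warn(sprintf(
        "Input is disjoint from candidate %s; no refinement applied.",
        dQuote(candidate)
      ))
      tibble::tibble(name = character(), provenance = character())
    }
  )
  cand <- dplyr::distinct(
    dplyr::bind_rows(cand, extra),
    .data$name, .keep_all = TRUE
  )
  scores <- purrr::map(cand$name, function(nm) {
    eff <- effective_symptoms(table, ont, nm)
    if (length(eff) == 0L) {
      tibble::tibble(
        sim = 0, exact_count = 0L, weight_sum = 0, list_size = 0L
      )
    } else {
      set_similarity(input, eff)
    }
  }) |>
    purrr::list_rbind()
  out <- dplyr::arrange(
    dplyr::bind_cols(cand, scores),
    dplyr::desc(.data$sim), dplyr::desc(.data$exact_count), .data$name
  )
  attr(out, "relation") <- relation
  out
}
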