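#' Assemble a diagnostic model from cases and an ontology
#'
#' Builds the mapping table from a clinical case table and pairs it with a
#' syndrome ontology and configuration into a single model bundle used by
#' [diagnose()]. Either input may be given as a path (read with
#' [read_cases()] / [read_ontology()]) or as an already-parsed object. A
#' missing ontology degrades gracefully: refinement becomes the identity.
#'
#' @param cases A `tcm_cases` tibble or a path to a delimited case file.
#' @param ontology A [syndrome_ontology()], a path to an ontology document,
#'   or `NULL` (empty ontology, with a warning).
#' @param config A [threshold_config()] for the extraction step.
#' @param overlap_threshold Jaccard threshold for the `partial` relation.
#' @param epsilon Smoothing for [set_similarity()] (default 0).
#' @return An object of class `tcm_model`: a list with elements `table`,
#'   `ontology` and `config`.
#' @export
build_model <- function(cases, ontology = NULL, config = threshold_config(),
                        overlap_threshold = 0.3, epsilon = 0) {
  if (is.character(cases)) cases <- read_cases(cases)
  if (is.character(ontology)) ontology <- read_ontology(ontology)
  if (is.null(ontology)) {
    rlang::warn("No ontology supplied; refinement will be the identity.")
    ontology <- syndrome_ontology()
  }
  structure(
    list(
      table = build_mapping_table(cases, config),
      ontology = ontology,
      config = list(
        threshold = config,
        overlap_threshold = overlap_threshold,
        epsilon = epsilon
      )
    ),
    class = "tcm_model"
  )
}

#' Save / load a diagnostic model directory
#'
#' The bundle is written as three plain-text files: `table.json` (the
#' mapping table), `ontology.tsv` (triple dialect) and `config.yaml`.
#' `load_model()` restores a model that diagnoses identically.
#'
#' @param model A `tcm_model`.
#' @param dir Directory to write to / read from (created if needed).
#' @return `save_model()` returns `model` invisibly; `load_model()` returns
#'   a `tcm_model`.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mapping_table(model$table, file.path(dir, "table.json"))
  write_ontology(model$ontology, file.path(dir, "ontology.tsv"))
  yaml::write_yaml(
    list(
      t_fraction = model$config$threshold$t_fraction,
      t_min = model$config$threshold$t_min,
      fallback_relax = model$config$threshold$fallback_relax,
      small_cutoff = model$config$threshold$small_cutoff,
      overlap_threshold = model$config$overlap_threshold,
      epsilon = model$config$epsilon
    ),
    file.path(dir, "config.yaml")
  )
  invisible(model)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  structure(
    list(
      table = read_mapping_table(file.path(dir, "table.json")),
      ontology = read_ontology(file.path(dir, "ontology.tsv")),
      config = list(
        threshold = threshold_config(
          t_fraction = cfg$t_fraction, t_min = cfg$t_min,
          fallback_relax = cfg$fallback_relax, small_cutoff = cfg$small_cutoff
        ),
        overlap_threshold = cfg$overlap_threshold,
        epsilon = cfg$epsilon
      )
    ),
    class = "tcm_model"
  )
}

#' @export
print.tcm_model <- function(x, ...) {
  cat("<tcm_model>\n")
  print(x$table)
  print(x$ontology)
  invisible(x)
}

#' Diagnose a free-text symptom list
#'
#' End-to-end fuzzy diagnosis: the raw symptoms are normalized; disease and
#' syndrome entries are ranked independently by fuzzy set similarity; the
#' top syndrome's set relation to the input is classified; the candidate is
#' refined through the ontology ([refine()]) and the refined candidates,
#' re-scored against their effective symptom sets, form the final syndrome
#' ranking (followed by the remaining initial candidates in their original
#' order). The result combines one disease with one or more syndromes.
#'
#' With an empty ontology the refinement step is the identity and the
#' syndrome ranking equals the raw [rank_candidates()] order.
#'
#' @param model A `tcm_model` from [build_model()].
#' @param symptoms Character vector of raw symptom descriptions (>= 1 must
#'   survive normalization).
#' @param refine_top How many top syndrome candidates to refine (default 1).
#' @param verbose If `TRUE`, print a structured trace of scores, relation
#'   kind and refinement provenance (default `FALSE`).
#' @return An object of class `tcm_diagnosis`: a list with elements
#'   `disease` (ranked tibble), `syndromes` (ranked tibble with
#'   `provenance`), `relation`, `trace` (the [refine()] output), `residual`
#'   (input symptoms not matched exactly by the top syndrome's effective
#'   set) and `input` (the normalized query).
#' @export
diagnose <- function(model, symptoms, refine_top = 1L, verbose = FALSE) {
  if (!inherits(model, "tcm_model")) {
    rlang::abort("`model` must be a `tcm_model` (see `build_model()`).",
      class = "tcmdx_missing_model"
    )
  }
  input <- normalize_symptom_set(symptoms)
  if (length(input) == 0L) {
    rlang::abort("No valid symptom in the query after normalization.",
      class = "tcmdx_empty_query"
    )
  }
  if (nrow(model$table) == 0L) {
    rlang::abort("The model's mapping table is empty.",
      class = "tcmdx_missing_model"
    )
  }
  eps <- model$config$epsilon %||% 0
  diseases <- if (any(model$table$kind == "disease")) {
    rank_candidates(model$table, input, kind = "disease", epsilon = eps)
  } else {
    tibble::tibble()
  }
  initial <- rank_candidates(model$table, input, kind = "syndrome", epsilon = eps)

  empty_ont <- length(model$ontology$classes) == 0L
  refine_top <- min(refine_top, nrow(initial))
  traces <- list()
  refined <- list()
  if (!empty_ont) {
    for (i in seq_len(refine_top)) {
      cand <- initial$name[i]
      rel <- match_relation(
        input, initial$symptoms[[i]],
        overlap_threshold = model$config$overlap_threshold %||% 0.3
      )
      tr <- refine(input, cand, model$table, model$ontology, relation = rel)
      traces[[cand]] <- tr
      refined[[cand]] <- tr
    }
  }
  if (length(refined)) {
    ref <- dplyr::distinct(purrr::list_rbind(refined), .data$name, .keep_all = TRUE)
    rest <- initial[!(initial$name %in% ref$name), c("name", "sim", "exact_count", "weight_sum", "list_size")]
    if (nrow(rest)) rest$provenance <- "initial"
    syndromes <- dplyr::bind_rows(
      dplyr::arrange(
        ref, dplyr::desc(.data$sim), dplyr::desc(.data$exact_count), .data$name
      ),
      rest
    )
    relation <- attr(traces[[1L]], "relation")
  } else {
    syndromes <- initial[, c("name", "sim", "exact_count", "weight_sum", "list_size")]
    syndromes$provenance <- "initial"
    relation <- NA_character_
  }
  top_name <- syndromes$name[1L]
  top_eff <- if (empty_ont) {
    table_symptoms(model$table, top_name)
  } else {
    effective_symptoms(model$table, model$ontology, top_name)
  }
  residual <- setdiff(input, top_eff)

  out <- structure(
    list(
      disease = diseases,
      syndromes = syndromes,
      relation = relation,
      trace = traces,
      residual = residual,
      input = input
    ),
    class = "tcm_diagnosis"
  )
  if (verbose) print(out)
  out
}

#' @export
print.tcm_diagnosis <- function(x, ...) {
  cat("<tcm_diagnosis>\n")
  cat("  input:   ", paste(x$input, collapse = ", "), "\n", sep = "")
  if (nrow(x$disease)) {
    cat(sprintf(
      "  disease:  %s (sim %.3f)\n", x$disease$name[1], x$disease$sim[1]
    ))
  }
  top <- utils::head(x$syndromes, 3L)
  for (i in seq_len(nrow(top))) {
    cat(sprintf(
      "  syndrome: %s (sim %.3f, %s)\n",
      top$name[i], top$sim[i], top$provenance[i] %||% "initial"
    ))
  }
  if (!is.na(x$relation)) cat("  relation: ", x$relation, "\n", sep = "")
  if (length(x$residual)) {
    cat("  residual: ", paste(x$residual, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Tidy a diagnosis into one row per ranked candidate
#'
#' @param x A `tcm_diagnosis`.
#' @param ... Unused.
#' @return A tibble with columns `kind`, `rank`, `name`, `sim`,
#'   `exact_count`, `provenance`.
#' @method tidy tcm_diagnosis
#' @export
tidy.tcm_diagnosis <- function(x, ...) {
  dis <- if (nrow(x$disease)) {
    tibble::tibble(
      kind = "disease", rank = seq_len(nrow(x$disease)),
      name = x$disease$name, sim = x$disease$sim,
      exact_count = x$disease$exact_count, provenance = "initial"
    )
  } else {
    NULL
  }
  syn <- tibble::tibble(
    kind = "syndrome", rank = seq_len(nrow(x$syndromes)),
    name = x$syndromes$name, sim = x$syndromes$sim,
    exact_count = x$syndromes$exact_count,
    provenance = x$syndromes$provenance %||% "initial"
  )
  dplyr::bind_rows(dis, syn)
}

#' One-row summary of a diagnosis
#'
#' @param x A `tcm_diagnosis`.
#' @param ... Unused.
#' @return A one-row tibble: top disease and syndrome with their scores, the
#'   set relation that drove refinement, and the residual symptom count.
#' @method glance tcm_diagnosis
#' @export
glance.tcm_diagnosis <- function(x, ...) {
  tibble::tibble(
    disease = if (nrow(x$disease)) x$disease$name[1] else NA_character_,
    disease_sim = if (nrow(x$disease)) x$disease$sim[1] else NA_real_,
    syndrome = x$syndromes$name[1],
    syndrome_sim = x$syndromes$sim[1],
    relation = x$relation,
    n_input = length(x$input),
    n_residual = length(x$residual)
  )
}

#' Plot the ranked candidates of a diagnosis
#'
#' @param object A `tcm_diagnosis`.
#' @param top Number of candidates per kind to show (default 5).
#' @param ... Unused.
#' @return A ggplot bar chart of similarity scores, facetted by kind.
#' @method autoplot tcm_diagnosis
#' @export
autoplot.tcm_diagnosis <- function(object, top = 5L, ...) {
  df <- dplyr::slice_head(
    dplyr::group_by(tidy(object), .data$kind),
    n = top
  )
  ggplot2::ggplot(
    df,
    ggplot2::aes(.data$sim, stats::reorder(.data$name, .data$sim),
      fill = .data$provenance
    )
  ) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~kind, scales = "free_y") +
    ggplot2::labs(
      x = "similarity", y = NULL,
      title = "Ranked diagnostic candidates"
    ) +
    ggplot2::theme_minimal()
}
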