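#' Threshold configuration for mapping extraction
#'
#' Controls how the extraction threshold t is derived from the number of
#' contributing cases k: `t = min(k, max(t_min, ceiling(t_fraction * k)))`.
#' With `t_fraction = 1` the extraction is the strict intersection of all
#' case symptom sets; lower fractions keep symptoms present in at least that
#' share of cases, which tolerates noisy or incomplete records.
#'
#' @param t_fraction Fraction in (0, 1] of the k sets a symptom must appear
#'   in (default 1: full intersection).
#' @param t_min Integer lower bound on t (default 1).
#' @param fallback_relax If `TRUE` (default) and the thresholded intersection
#'   of a group is empty, t is decremented until the result is non-empty or
#'   t reaches 1.
#' @param small_cutoff Sets shorter than this all-round are intersected with a
#'   plain linear counting merge instead of galloping search (default 16);
#'   doubling search only pays off on long sorted sets.
#' @return An object of class `threshold_config`.
#' @export
threshold_config <- function(t_fraction = 1, t_min = 1L, fallback_relax = TRUE,
                             small_cutoff = 16L) {
  if (!is.numeric(t_fraction) || length(t_fraction) != 1L ||
      t_fraction <= 0 || t_fraction > 1) {
    rlang::abort("`t_fraction` must be a single number in (0, 1].")
  }
  if (!is.numeric(t_min) || length(t_min) != 1L || t_min < 1) {
    rlang::abort("`t_min` must be an integer >= 1.")
  }
  structure(
    list(
      t_fraction = as.numeric(t_fraction),
      t_min = as.integer(t_min),
      fallback_relax = isTRUE(fallback_relax),
      small_cutoff = as.integer(small_cutoff)
    ),
    class = "threshold_config"
  )
}

#' Derive the extraction threshold t for a group of k cases
#'
#' @param k Number of contributing case symptom sets (k >= 1).
#' @param config A [threshold_config()].
#' @return Integer t with 1 <= t <= k.
#' @export
choose_threshold <- function(k, config = threshold_config()) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 1)
  min(as.integer(k), max(config$t_min, as.integer(ceiling(config$t_fraction * k))))
}

# Galloping (doubling then binary) search: first index j >= lo with
# vec[j] >= target, or length(vec) + 1 when none. vec is a sorted int vector.
gallop_search <- function(vec, lo, target) {
  n <- length(vec)
  if (lo > n || vec[lo] >= target) {
    return(lo)
  }
  step <- 1L
  prev <- lo
  while (prev + step <= n && vec[prev + step] < target) {
    prev <- prev + step
    step <- step * 2L
  }
  hi <- min(n, prev + step)
  if (vec[hi] < target) {
    return(n + 1L)
  }
  lo2 <- prev + 1L
  while (lo2 < hi) {
    mid <- (lo2 + hi) %/% 2L
    if (vec[mid] < target) lo2 <- mid + 1L else hi <- mid
  }
  lo2
}

# t-threshold intersection over strictly increasing integer vectors, in the
# adaptive style: each round the eliminator e is the t-th smallest current
# head, so every element below e lives in at most t - 1 sets and whole runs
# of such elements are skipped by galloping. Returns the sorted elements
# present in >= t of the vectors.
adaptive_t_threshold_codes <- function(codes, t) {
  k <- length(codes)
  n <- lengths(codes)
  pos <- rep(1L, k)
  out <- integer(0)
  repeat {
    active <- which(pos <= n)
    if (length(active) < t) break
    heads <- vapply(active, function(i) codes[[i]][pos[i]], integer(1))
    e <- sort(heads, partial = t)[t]
    occ <- 0L
    for (i in active) {
      j <- gallop_search(codes[[i]], pos[i], e)
      if (j <= n[i] && codes[[i]][j] == e) {
        occ <- occ + 1L
        pos[i] <- j + 1L
      } else {
        pos[i] <- j
      }
    }
    if (occ >= t) out <- c(out, e)
  }
  out
}

# Linear counting merge used when every set is short: tabulate occurrences of
# each code and keep those reaching t.
counting_t_threshold_codes <- function(codes, t, n_vocab) {
  counts <- tabulate(unlist(codes, use.names = FALSE), nbins = n_vocab)
  which(counts >= t)
}

# Map symptom sets onto integer ranks over their sorted union. Each returned
# code vector is strictly increasing iff the corresponding input was sorted.
encode_sets <- function(sets) {
  sets <- lapply(sets, as.character)
  vocab <- sort(unique(unlist(sets, use.names = FALSE)))
  list(vocab = vocab, codes = lapply(sets, match, table = vocab))
}

#' t-threshold intersection of symptom sets
#'
#' Returns exactly the symptoms that occur in at least `t` of the `k` input
#' sets, in sorted order. `t = k` is the ordinary intersection; `t = 1` is
#' the union. Duplicate elements within a set count once. The computation
#' uses an adaptive scheme over the sorted sets (galloping search with the
#' t-th smallest head as eliminator), falling back to a linear counting merge
#' when every set is shorter than the configured small-set cutoff.
#'
#' @param sets List of k character vectors (symptom sets), k >= 1.
#' @param t Integer threshold with 1 <= t <= k.
#' @param small_cutoff Cutoff below which the linear merge is used
#'   (default 16).
#' @return Sorted character vector of symptoms present in >= t sets.
#' @examples
#' threshold_intersect(
#'   list(c("heat", "dizzy", "redface"), c("heat", "dizzy", "sore throat")),
#'   t = 2
#' )
#' @export
threshold_intersect <- function(sets, t, small_cutoff = 16L) {
  if (!is.list(sets) || length(sets) < 1L) {
    rlang::abort("`sets` must be a non-empty list of symptom sets.")
  }
  k <- length(sets)
  if (!is.numeric(t) || length(t) != 1L || t < 1 || t > k) {
    rlang::abort(sprintf(
      "Invalid threshold: t = %s must satisfy 1 <= t <= k = %d.",
      format(t), k
    ), class = "tcmdx_invalid_threshold")
  }
  t <- as.integer(t)
  enc <- encode_sets(lapply(sets, function(s) sort(unique(as.character(s)))))
  if (length(enc$vocab) == 0L) {
    return(character())
  }
  hits <- if (max(lengths(enc$codes)) <= small_cutoff) {
    counting_t_threshold_codes(enc$codes, t, length(enc$vocab))
  } else {
    adaptive_t_threshold_codes(enc$codes, t)
  }
  enc$vocab[hits]
}

#' Adaptive intersection of sorted symptom sequences
#'
#' Intersects k strictly increasing symptom sequences in parallel, cycling
#' through the sets with galloping (doubling then binary) searches so that
#' runs of elements that cannot be in the result are skipped. Equivalent to
#' [threshold_intersect()] with `t = k`, but the inputs must already be
#' strictly increasing; unsorted input is a contract violation and signals an
#' error. For uniformly short sets the doubling search is skipped in favour
#' of a plain merge.
#'
#' @param sets List of k strictly increasing character vectors.
#' @param small_cutoff Cutoff below which a plain merge is used (default 16).
#' @return Sorted character vector: the intersection of the k sequences.
#' @export
adaptive_sorted_intersect <- function(sets, small_cutoff = 16L) {
  if (!is.list(sets) || length(sets) < 1L) {
    rlang::abort("`sets` must be a non-empty list of sorted symptom sequences.")
  }
  enc <- encode_sets(sets)
  unsorted <- vapply(
    enc$codes,
    function(cd) length(cd) > 1L && any(diff(cd) <= 0L),
    logical(1)
  )
  if (any(unsorted)) {
    rlang::abort(sprintf(
      "Input sequence(s) %s are not strictly increasing.",
      paste(utils::head(which(unsorted), 5L), collapse = ", ")
    ), class = "tcmdx_unsorted_input")
  }
  if (length(enc$vocab) == 0L) {
    return(character())
  }
  k <- length(sets)
  hits <- if (max(lengths(enc$codes)) <= small_cutoff) {
    sort(Reduce(intersect, enc$codes))
  } else {
    adaptive_t_threshold_codes(enc$codes, k)
  }
  enc$vocab[hits]
}

#' Build the diagnostic library (mapping table) from clinical cases
#'
#' Groups cases by syndrome name and, independently, by disease name, and for
#' each group of k case symptom sets extracts the minimum associated symptom
#' set by t-threshold intersection with `t = choose_threshold(k, config)`.
#' If the result is empty and `config$fallback_relax` is set, t is relaxed
#' downwards until the result is non-empty or t reaches 1. The result is the
#' diagnostic library of entries `D ~ S`: each disease or syndrome mapped to
#' its most strongly supported symptom set.
#'
#' @param cases A `tcm_cases` tibble (see [as_cases()]).
#' @param config A [threshold_config()].
#' @return A tibble of class `mapping_table` with columns `kind`
#'   (`"disease"` or `"syndrome"`), `name`, `symptoms` (list of sorted
#'   character vectors), `support` (number of contributing cases k) and
#'   `threshold` (the t actually used).
#' @examples
#' cases <- as_cases(data.frame(
#'   disease = "Heat", syndrome = "Heat",
#'   symptoms = c("heat,dizzy,redface", "heat,dizzy,sore throat")
#' ))
#' build_mapping_table(cases)
#' @export
build_mapping_table <- function(cases, config = threshold_config()) {
  if (!is.data.frame(cases) || nrow(cases) == 0L) {
    rlang::abort("`cases` must be a non-empty clinical case table.")
  }
  extract_kind <- function(kind) {
    groups <- split(cases$symptoms, cases[[if (kind == "disease") "disease" else "syndrome"]])
    purrr::imap(groups, function(sets, nm) {
      k <- length(sets)
      t <- choose_threshold(k, config)
      res <- threshold_intersect(sets, t, small_cutoff = config$small_cutoff)
      while (length(res) == 0L && config$fallback_relax && t > 1L) {
        t <- t - 1L
        res <- threshold_intersect(sets, t, small_cutoff = config$small_cutoff)
      }
      tibble::tibble(
        kind = kind, name = nm, symptoms = list(res),
        support = k, threshold = t
      )
    }) |>
      purrr::list_rbind()
  }
  out <- dplyr::bind_rows(extract_kind("disease"), extract_kind("syndrome"))
  class(out) <- c("mapping_table", class(out))
  out
}

# Look up the (sorted) symptom set of one entry; character(0) when absent.
table_symptoms <- function(table, name, kind = "syndrome") {
  hit <- table$kind == kind & table$name == name
  if (!any(hit)) {
    return(character())
  }
  table$symptoms[[which(hit)[1L]]]
}

#' Serialize a mapping table to JSON
#'
#' @param table A `mapping_table` tibble.
#' @param path Output path for the JSON file.
#' @return `table`, invisibly.
#' @export
write_mapping_table <- function(table, path) {
  entries <- purrr::pmap(
    table[c("kind", "name", "symptoms", "support", "threshold")],
    function(kind, name, symptoms, support, threshold) {
      list(
        kind = kind, name = name, symptoms = as.list(symptoms),
        support = support, threshold = threshold
      )
    }
  )
  jsonlite::write_json(entries, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(table)
}

#' Read a mapping table from JSON
#'
#' @param path Path to a JSON file written by [write_mapping_table()].
#' @return A `mapping_table` tibble.
#' @export
read_mapping_table <- function(path) {
  entries <- jsonlite::read_json(path)
  out <- purrr::map(entries, function(e) {
    tibble::tibble(
      kind = e$kind, name = e$name,
      symptoms = list(as.character(unlist(e$symptoms))),
      support = as.integer(e$support),
      threshold = as.integer(e$threshold %||% NA_integer_)
    )
  }) |>
    purrr::list_rbind()
  if (nrow(out) == 0L) {
    out <- tibble::tibble(
      kind = character(), name = character(), symptoms = list(),
      support = integer(), threshold = integer()
    )
  }
  class(out) <- c("mapping_table", class(out))
  out
}

#' Export a mapping table as two-column TSV
#'
#' Writes one row per entry: `disease:Name` or `syndrome:Name` in the first
#' column and the comma-joined symptom set in the second.
#'
#' @inheritParams write_mapping_table
#' @export
write_mapping_tsv <- function(table, path) {
  df <- tibble::tibble(
    entity = paste0(table$kind, ":", table$name),
    symptoms = purrr::map_chr(table$symptoms, paste, collapse = ",")
  )
  readr::write_tsv(df, path, progress = FALSE)
  invisible(table)
}

#' @export
print.mapping_table <- function(x, ...) {
  cat(sprintf(
    "<mapping_table> %d entries (%d disease, %d syndrome); mean symptom-set size %.2f\n",
    nrow(x), sum(x$kind == "disease"), sum(x$kind == "syndrome"),
    if (nrow(x)) mean(lengths(x$symptoms)) else NA_real_
  ))
  NextMethod()
}

#' Plot the entry-size distribution of a mapping table
#'
#' @param object A `mapping_table` tibble.
#' @param ... Unused.
#' @return A ggplot object: symptom-set sizes of the library entries by kind.
#' @method autoplot mapping_table
#' @export
autoplot.mapping_table <- function(object, ...) {
  df <- tibble::tibble(kind = object$kind, size = lengths(object$symptoms))
  ggplot2::ggplot(df, ggplot2::aes(.data$size, fill = .data$kind)) +
    ggplot2::geom_bar(position = "dodge") +
    ggplot2::labs(
      x = "symptoms per library entry", y = "entries",
      title = "Diagnostic library entry sizes"
    ) +
    ggplot2::theme_minimal()
}
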