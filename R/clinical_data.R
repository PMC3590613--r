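#' Normalize symptom labels
#'
#' Canonicalizes free-text symptom descriptions so that equal symptoms compare
#' equal as set elements: leading/trailing whitespace is trimmed, internal runs
#' of whitespace are collapsed to a single space, and the label is case-folded
#' to lower case. No stemming or translation is attempted; matching elsewhere
#' in the package operates on these raw normalized strings.
#'
#' @param x Character vector of raw symptom descriptions.
#' @return Character vector of normalized symptom labels, same length as `x`.
#' @examples
#' normalize_symptom(c("  Dizzy ", "sore   throat"))
#' @export
normalize_symptom <- function(x) {
  if (!is.character(x)) {
    rlang::abort("`x` must be a character vector of symptom descriptions.")
  }
  out <- stringr::str_squish(stringr::str_to_lower(x))
  if (any(!nzchar(out) | is.na(out))) {
    bad <- which(!nzchar(out) | is.na(out))
    rlang::abort(sprintf(
      "Symptom label empty after normalization at position(s) %s.",
      paste(utils::head(bad, 5L), collapse = ", ")
    ), class = "tcmdx_invalid_symptom")
  }
  out
}

# Normalize a raw symptom vector, silently dropping entries that normalize to
# empty, and de-duplicating while preserving first occurrence.
normalize_symptom_set <- function(x) {
  x <- x[!is.na(x)]
  out <- stringr::str_squish(stringr::str_to_lower(x))
  unique(out[nzchar(out)])
}

#' Coerce a data frame to a validated clinical case table
#'
#' A clinical case table has one row per case with columns `disease`,
#' `syndrome` and `symptoms`. On input, `symptoms` may be a character column
#' holding an internally delimited list (e.g. `"heat,dizzy,redface"`) or a
#' list-column of character vectors. Symptoms are normalized with
#' [normalize_symptom()] and de-duplicated preserving first occurrence. Rows
#' whose symptom list is empty after normalization are dropped with a warning;
#' the number dropped is recorded in the `n_skipped` attribute. Rows with
#' identical (disease, syndrome, symptoms) are kept as separate cases:
#' repeated observations strengthen intersection support downstream.
#'
#' @param x A data frame with columns `disease`, `syndrome`, `symptoms`.
#' @param symptom_sep Delimiter separating symptoms inside the `symptoms`
#'   cell (default `","`; `";"` and `"|"` are common alternatives).
#' @return A tibble of class `tcm_cases` with columns `disease` (chr),
#'   `syndrome` (chr) and `symptoms` (list of character vectors).
#' @examples
#' as_cases(data.frame(
#'   disease = "Heat", syndrome = "Heat",
#'   symptoms = "heat,dizzy,redface"
#' ))
#' @export
as_cases <- function(x, symptom_sep = ",") {
  stopifnot(is.data.frame(x))
  missing <- setdiff(c("disease", "syndrome", "symptoms"), names(x))
  if (length(missing)) {
    rlang::abort(sprintf(
      "Case table is missing column(s): %s.", paste(missing, collapse = ", ")
    ), class = "tcmdx_missing_column")
  }
  x <- tibble::as_tibble(x)
  if (is.list(x$symptoms)) {
    sym <- purrr::map(x$symptoms, normalize_symptom_set)
  } else {
    sym <- purrr::map(
      stringr::str_split(as.character(x$symptoms), stringr::fixed(symptom_sep)),
      normalize_symptom_set
    )
  }
  bad_name <- !nzchar(trimws(x$disease)) | !nzchar(trimws(x$syndrome)) |
    is.na(x$disease) | is.na(x$syndrome)
  if (any(bad_name)) {
    rlang::abort(sprintf(
      "Empty disease or syndrome name on row(s) %s.",
      paste(utils::head(which(bad_name), 5L), collapse = ", ")
    ), class = "tcmdx_missing_column")
  }
  empty <- lengths(sym) == 0L
  if (any(empty)) {
    rlang::warn(sprintf(
      "Dropped %d case(s) with empty symptom list after normalization.",
      sum(empty)
    ))
  }
  out <- tibble::tibble(
    disease = trimws(as.character(x$disease))[!empty],
    syndrome = trimws(as.character(x$syndrome))[!empty],
    symptoms = sym[!empty]
  )
  attr(out, "n_skipped") <- sum(empty)
  class(out) <- c("tcm_cases", class(out))
  out
}

#' Read a three-column clinical case table from delimited text
#'
#' Reads a delimited file with header `disease,syndrome,symptoms`, where the
#' `symptoms` cell is itself an internally delimited symptom list, and
#' validates/normalizes it with [as_cases()].
#'
#' @param path Path to the delimited file.
#' @param delim Field delimiter of the file (default `","`).
#' @param symptom_sep Delimiter inside the symptoms cell (default `","`).
#'   When both delimiters are `","` the symptoms cell must be quoted, as
#'   [write_cases()] does.
#' @return A `tcm_cases` tibble (see [as_cases()]).
#' @export
read_cases <- function(path, delim = ",", symptom_sep = ",") {
  df <- readr::read_delim(
    path,
    delim = delim,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  if (nrow(df) == 0L && !all(c("disease", "syndrome", "symptoms") %in% names(df))) {
    return(as_cases(tibble::tibble(
      disease = character(), syndrome = character(), symptoms = character()
    )))
  }
  as_cases(df, symptom_sep = symptom_sep)
}

#' Write a clinical case table to delimited text
#'
#' Inverse of [read_cases()]: symptom lists are collapsed with `symptom_sep`.
#' A read/write/read round trip is the identity on normalized case tables.
#'
#' @param cases A `tcm_cases` tibble.
#' @param path Output path.
#' @inheritParams read_cases
#' @return `cases`, invisibly.
#' @export
write_cases <- function(cases, path, delim = ",", symptom_sep = ",") {
  df <- tibble::tibble(
    disease = cases$disease,
    syndrome = cases$syndrome,
    symptoms = purrr::map_chr(cases$symptoms, paste, collapse = symptom_sep)
  )
  readr::write_delim(df, path, delim = delim, quote = "needed", progress = FALSE)
  invisible(cases)
}

#' Case-length distribution of a clinical case table
#'
#' Counts cases by the number of symptoms they record. In curated TCM case
#' collections the distribution is long-tailed, with lengths roughly in
#' 1--32.
#'
#' @param cases A `tcm_cases` tibble.
#' @return A tibble with columns `length` (symptom count) and `n` (number of
#'   cases of that length); `sum(n)` equals `nrow(cases)`.
#' @export
case_lengths <- function(cases) {
  if (nrow(cases) == 0L) {
    return(tibble::tibble(length = integer(), n = integer()))
  }
  dplyr::count(
    tibble::tibble(length = lengths(cases$symptoms)),
    .data$length, name = "n"
  )
}

#' @export
print.tcm_cases <- function(x, ...) {
  cat(sprintf(
    "<tcm_cases> %d case(s), %d disease(s), %d syndrome(s)\n",
    nrow(x), dplyr::n_distinct(x$disease), dplyr::n_distinct(x$syndrome)
  ))
  NextMethod()
}

#' Plot the case-length histogram of a clinical case table
#'
#' @param object A `tcm_cases` tibble.
#' @param ... Unused.
#' @return A ggplot object: number of clinical cases by symptom-list length.
#' @method autoplot tcm_cases
#' @export
autoplot.tcm_cases <- function(object, ...) {
  ggplot2::ggplot(case_lengths(object), ggplot2::aes(.data$length, .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "symptoms per case", y = "number of cases",
      title = "Clinical cases by length"
    ) +
    ggplot2::theme_minimal()
}
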