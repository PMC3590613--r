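#' Longest common subsequence length of two strings
#'
#' Classic dynamic programme over the character sequences of the two labels
#' (spaces included). The LCS underlies the fuzzy word weight used to match
#' lay symptom descriptions against library terminology letter by letter.
#'
#' @param a,b Character scalars.
#' @return Integer length of the longest common subsequence.
#' @examples
#' lcs_length("ABCBDAB", "BDCABA") # 4
#' @export
lcs_length <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) == 1L, length(b) == 1L)
  x <- utf8ToInt(a)
  y <- utf8ToInt(b)
  na <- length(x)
  nb <- length(y)
  if (na == 0L || nb == 0L) {
    return(0L)
  }
  prev <- integer(nb + 1L)
  for (i in seq_len(na)) {
    cur <- integer(nb + 1L)
    xi <- x[i]
    for (j in seq_len(nb)) {
      cur[j + 1L] <- if (xi == y[j]) {
        prev[j] + 1L
      } else {
        max(cur[j], prev[j + 1L])
      }
    }
    prev <- cur
  }
  prev[nb + 1L]
}

#' Fuzzy word weight between two symptom labels
#'
#' `weight = lcs_length(a, b) / max(nchar(a), nchar(b))`: the ratio of the
#' matched character subsequence over the longer of the two labels. A weight
#' of 1 is an exact match; 0 means no common characters.
#'
#' @param a,b Character scalars; at least one must be non-empty.
#' @return A one-row tibble with columns `lcs_len`, `weight` (in \[0, 1\])
#'   and `is_exact` (`weight == 1`).
#' @examples
#' word_weight("abc", "abcd") # weight 0.75
#' @export
word_weight <- function(a, b) {
  if (!nzchar(a) && !nzchar(b)) {
    rlang::abort("Word weight is undefined for two empty strings.",
      class = "tcmdx_undefined_weight"
    )
  }
  l <- lcs_length(a, b)
  w <- l / max(nchar(a), nchar(b))
  tibble::tibble(lcs_len = l, weight = w, is_exact = w == 1)
}

#' Best fuzzy match of a query symptom against a symptom list
#'
#' Maximum [word_weight()] of `query` over the candidate labels; ties are
#' broken by earliest list position.
#'
#' @param query A normalized symptom label.
#' @param labels Non-empty character vector of candidate labels.
#' @return A one-row tibble with columns `label` (the matched candidate),
#'   `lcs_len`, `weight`, `is_exact`.
#' @export
best_weight <- function(query, labels) {
  if (length(labels) == 0L) {
    rlang::abort("`labels` must be non-empty.", class = "tcmdx_invalid_input")
  }
  weights <- vapply(
    labels,
    function(l) lcs_length(query, l) / max(nchar(query), nchar(l)),
    numeric(1),
    USE.NAMES = FALSE
  )
  i <- which.max(weights)
  tibble::tibble(
    label = labels[i],
    lcs_len = lcs_length(query, labels[i]),
    weight = weights[i],
    is_exact = weights[i] == 1
  )
}

#' Fuzzy set similarity between an input symptom list and a library entry
#'
#' Each input symptom is paired with its best fuzzy match in the candidate
#' list; `exact_count` counts pairs with weight 1, `weight_sum` sums all the
#' weights, and the similarity is
#' `sim = exact_count * weight_sum / list_size`, with `list_size` the size
#' of the candidate entry's symptom list. The score is a ranking value, not
#' a probability: for an input identical to an entry of m distinct symptoms
#' it equals m, and it is 0 whenever no exact match exists, regardless of
#' partial weights.
#'
#' @param input Non-empty character vector of normalized input symptoms.
#' @param list_set Non-empty character vector: the candidate entry's
#'   symptoms.
#' @param epsilon Additive smoothing added to `exact_count` before the
#'   multiplication (default 0: the literal formula). A small positive value
#'   lets purely partial matches rank instead of scoring 0.
#' @return A one-row tibble with columns `sim`, `exact_count`, `weight_sum`,
#'   `list_size`.
#' @examples
#' set_similarity(c("heat", "dizzy"), c("heat", "dizzy")) # sim = 2
#' @export
set_similarity <- function(input, list_set, epsilon = 0) {
  if (length(input) == 0L || length(list_set) == 0L) {
    rlang::abort("`input` and `list_set` must both be non-empty.",
      class = "tcmdx_invalid_input"
    )
  }
  weights <- vapply(
    input,
    function(q) {
      max(vapply(
        list_set,
        function(l) lcs_length(q, l) / max(nchar(q), nchar(l)),
        numeric(1)
      ))
    },
    numeric(1),
    USE.NAMES = FALSE
  )
  exact <- sum(weights == 1)
  wsum <- sum(weights)
  n <- length(list_set)
  tibble::tibble(
    sim = (exact + epsilon) * wsum / n,
    exact_count = as.integer(exact),
    weight_sum = wsum,
    list_size = as.integer(n)
  )
}

#' Rank library entries against an input symptom list
#'
#' Scores every mapping-table entry of the requested kind with
#' [set_similarity()] and sorts by similarity (descending), then exact-match
#' count (descending), then entity name (ascending) so that ranking is
#' deterministic.
#'
#' @param table A `mapping_table` tibble.
#' @param input Non-empty character vector of normalized input symptoms.
#' @param kind `"syndrome"` or `"disease"`.
#' @param epsilon Passed to [set_similarity()].
#' @return The entries of `table` of that kind, with score columns `sim`,
#'   `exact_count`, `weight_sum`, `list_size` appended, in rank order.
#' @export
rank_candidates <- function(table, input, kind = c("syndrome", "disease"),
                            epsilon = 0) {
  kind <- match.arg(kind)
  sub <- table[table$kind == kind & lengths(table$symptoms) > 0L, ]
  if (nrow(sub) == 0L) {
    rlang::abort(sprintf("No %s entries in the mapping table.", kind),
      class = "tcmdx_no_candidates"
    )
  }
  scores <- purrr::map(sub$symptoms, set_similarity, input = input, epsilon = epsilon) |>
    purrr::list_rbind()
  dplyr::arrange(
    dplyr::bind_cols(tibble::as_tibble(sub), scores),
    dplyr::desc(.data$sim), dplyr::desc(.data$exact_count), .data$name
  )
}
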