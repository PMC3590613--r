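#' Plant a synthetic ground truth: syndrome signatures plus ontology
#'
#' Generates the hidden structure a curated clinical-case collection would
#' carry: one symptom signature per base syndrome (sampled without
#' replacement from a synthetic vocabulary `sym0001`, `sym0002`, ...),
#' compound syndromes whose signature is the union of two parts (linked by
#' subsume axioms), equivalence aliases, and is-a chains where the child's
#' signature extends the parent's. The seed fully determines the output.
#'
#' @param n_syndromes Number of base syndromes (default 30).
#' @param n_diseases Number of diseases the syndromes are spread over
#'   (default 5, as in curated TCM collections dominated by few disease
#'   categories).
#' @param vocab_size Size of the symptom vocabulary (default 300).
#' @param signature_size Symptoms per base signature (default 6, near the
#'   mean case length of curated collections).
#' @param p_equiv Probability a syndrome gets an equivalent alias
#'   (default 0.1).
#' @param p_subsume Expected fraction of compound syndromes relative to base
#'   syndromes (default 0.1).
#' @param subclass_depth Length of planted is-a chains (default 2: one
#'   child level below a parent; 1 disables chains).
#' @param seed Integer seed (default 1).
#' @return An object of class `synthetic_truth`: a list with `signatures`
#'   (named list of character vectors), `disease_map` (named character:
#'   syndrome -> disease), `ontology` (a [syndrome_ontology()]),
#'   `base_syndromes` (names whose signatures were sampled directly) and
#'   `params`.
#' @export
generate_truth <- function(n_syndromes = 30L, n_diseases = 5L,
                           vocab_size = 300L, signature_size = 6L,
                           p_equiv = 0.1, p_subsume = 0.1,
                           subclass_depth = 2L, seed = 1L) {
  if (signature_size > vocab_size || n_syndromes < 1L || n_diseases < 1L) {
    rlang::abort("Infeasible generator configuration.",
      class = "tcmdx_invalid_config"
    )
  }
  withr::with_seed(as.integer(seed), {
    vocab <- sprintf("sym%04d", seq_len(vocab_size))
    base <- sprintf("syndrome %02d", seq_len(n_syndromes))
    signatures <- stats::setNames(
      lapply(base, function(i) sort(sample(vocab, signature_size))),
      base
    )
    equivalence <- NULL
    subsume <- NULL
    subclass <- NULL

    # equivalence aliases
    alias_of <- base[stats::runif(n_syndromes) < p_equiv]
    if (length(alias_of)) {
      equivalence <- tibble::tibble(
        a = paste(alias_of, "alias"), b = alias_of
      )
    }

    # compound syndromes: union-of-parts signatures plus subsume axioms
    n_compound <- stats::rbinom(1L, n_syndromes, p_subsume)
    if (n_compound > 0L && n_syndromes >= 2L) {
      for (i in seq_len(n_compound)) {
        parts <- sample(base, 2L)
        nm <- paste(parts, collapse = " with ")
        if (nm %in% names(signatures)) next
        signatures[[nm]] <- sort(union(
          signatures[[parts[1]]], signatures[[parts[2]]]
        ))
        subsume <- dplyr::bind_rows(
          subsume, tibble::tibble(whole = nm, part = parts)
        )
      }
    }

    # is-a chains: child signature extends the parent's
    if (subclass_depth > 1L) {
      parents <- sample(base, max(1L, n_syndromes %/% 10L))
      for (p in parents) {
        parent <- p
        for (d in seq_len(subclass_depth - 1L)) {
          child <- paste(p, "variant", d)
          extra <- sample(setdiff(vocab, signatures[[parent]]), 2L)
          signatures[[child]] <- sort(union(signatures[[parent]], extra))
          subclass <- dplyr::bind_rows(
            subclass, tibble::tibble(child = child, parent = parent)
          )
          parent <- child
        }
      }
    }

    diseases <- sprintf("disease %d", seq_len(n_diseases))
    disease_map <- stats::setNames(
      sample(diseases, length(signatures), replace = TRUE),
      names(signatures)
    )

    structure(
      list(
        signatures = signatures,
        disease_map = disease_map,
        ontology = syndrome_ontology(
          classes = names(signatures),
          equivalence = equivalence,
          subclass = subclass,
          subsume = subsume
        ),
        base_syndromes = base,
        params = list(
          n_syndromes = n_syndromes, n_diseases = n_diseases,
          vocab_size = vocab_size, signature_size = signature_size,
          p_equiv = p_equiv, p_subsume = p_subsume,
          subclass_depth = subclass_depth, seed = as.integer(seed)
        )
      ),
      class = "synthetic_truth"
    )
  })
}

#' Simulate clinical cases from a planted truth
#'
#' Each case starts from its syndrome's planted signature, drops each
#' signature symptom independently with probability `p_drop` (at least one
#' is always kept), appends a Poisson-distributed number of noise symptoms
#' drawn from the rest of the vocabulary, and clamps the total length to
#' `length_range` (curated TCM cases run from 1 to 32 symptoms). The
#' disease column follows the truth's syndrome-to-disease map.
#'
#' @param truth A `synthetic_truth` from [generate_truth()].
#' @param cases_per_syndrome Cases generated per syndrome (default 20).
#' @param p_drop Per-symptom dropout probability (default 0.05).
#' @param extra_mean Mean of the Poisson noise-symptom count (default 3).
#' @param length_range Length clamp, default `c(1L, 32L)`.
#' @param seed Integer seed (default 1).
#' @return A `tcm_cases` tibble.
#' @export
generate_cases <- function(truth, cases_per_syndrome = 20L, p_drop = 0.05,
                           extra_mean = 3, length_range = c(1L, 32L),
                           seed = 1L) {
  stopifnot(p_drop >= 0, p_drop <= 1, extra_mean >= 0)
  vocab <- sprintf("sym%04d", seq_len(truth$params$vocab_size))
  withr::with_seed(as.integer(seed), {
    rows <- purrr::imap(truth$signatures, function(sig, nm) {
      purrr::map(seq_len(cases_per_syndrome), function(i) {
        keep <- sig[stats::runif(length(sig)) >= p_drop]
        if (length(keep) == 0L) keep <- sample(sig, 1L)
        n_extra <- stats::rpois(1L, extra_mean)
        extras <- if (n_extra > 0L) {
          sample(setdiff(vocab, keep), min(n_extra, length(vocab) - length(keep)))
        } else {
          character()
        }
        sym <- c(keep, extras)
        if (length(sym) > length_range[2L]) {
          sym <- sym[seq_len(length_range[2L])]
        }
        tibble::tibble(
          disease = unname(truth$disease_map[[nm]]),
          syndrome = nm,
          symptoms = list(sym)
        )
      }) |>
        purrr::list_rbind()
    }) |>
      purrr::list_rbind()
  })
  as_cases(rows)
}

#' Signature-recovery metrics of an extracted mapping table
#'
#' Compares each planted syndrome signature with the symptom set the
#' extraction recovered for that syndrome: `exact_fraction` is the share of
#' syndromes whose mapping entry equals the signature exactly, and
#' `mean_jaccard` averages the Jaccard index over all syndromes (a syndrome
#' absent from the table counts as 0).
#'
#' @param table A `mapping_table` built from cases generated under `truth`.
#' @param truth The `synthetic_truth` the cases came from.
#' @return A one-row tibble with columns `exact_fraction`, `mean_jaccard`
#'   and `n_syndromes`; the per-syndrome comparison is attached as the
#'   `detail` attribute (tibble with `name`, `exact`, `jaccard`,
#'   `n_recovered`, `n_signature`).
#' @export
evaluate_recovery <- function(table, truth) {
  detail <- purrr::imap(truth$signatures, function(sig, nm) {
    got <- table_symptoms(table, nm, kind = "syndrome")
    inter <- length(intersect(sig, got))
    uni <- length(union(sig, got))
    tibble::tibble(
      name = nm,
      exact = setequal(sig, got),
      jaccard = if (uni == 0L) 0 else inter / uni,
      n_recovered = length(got),
      n_signature = length(sig)
    )
  }) |>
    purrr::list_rbind()
  out <- tibble::tibble(
    exact_fraction = mean(detail$exact),
    mean_jaccard = mean(detail$jaccard),
    n_syndromes = nrow(detail)
  )
  attr(out, "detail") <- detail
  out
}

#' Write near-duplicate (misspelled) variants of symptom labels
#'
#' Produces edit-distance 1--2 corruptions (character drop, swap, or
#' substitution) of given labels, for exercising the LCS weight path with
#' non-exact matches.
#'
#' @param labels Character vector of normalized labels (nchar >= 2).
#' @param seed Integer seed (default 1).
#' @return A tibble with columns `label` and `variant`.
#' @export
misspell_variants <- function(labels, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    variant <- vapply(labels, function(l) {
      ch <- strsplit(l, "")[[1L]]
      op <- sample(c("drop", "swap", "subst"), 1L)
      i <- sample(length(ch), 1L)
      if (op == "drop" && length(ch) > 1L) {
        ch <- ch[-i]
      } else if (op == "swap" && length(ch) > 1L) {
        j <- if (i == length(ch)) i - 1L else i + 1L
        tmp <- ch[i]
        ch[i] <- ch[j]
        ch[j] <- tmp
      } else {
        ch[i] <- sample(letters, 1L)
      }
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
    tibble::tibble(label = labels, variant = variant)
  })
}

#' Write a full synthetic study to disk
#'
#' Convenience wrapper: generates a truth and its cases, then writes
#' `cases.csv`, `ontology.tsv` and `truth.json` into `dir`.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed used for both truth and cases.
#' @param ... Passed to [generate_truth()].
#' @return Invisibly, a list with `truth` and `cases`.
#' @export
simulate_study <- function(dir, seed = 1L, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- generate_truth(seed = seed, ...)
  cases <- generate_cases(truth, seed = seed)
  write_cases(cases, file.path(dir, "cases.csv"))
  write_ontology(truth$ontology, file.path(dir, "ontology.tsv"))
  jsonlite::write_json(
    list(
      signatures = truth$signatures,
      disease_map = as.list(truth$disease_map),
      params = truth$params
    ),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(list(truth = truth, cases = cases))
}
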