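test_that("planted truth is deterministic and respects degenerate configs", {
  t1 <- generate_truth(seed = 11L)
  t2 <- generate_truth(seed = 11L)
  expect_identical(t1$signatures, t2$signatures)
  expect_identical(t1$disease_map, t2$disease_map)
  expect_identical(t1$ontology, t2$ontology)

  flat <- generate_truth(
    p_subsume = 0, p_equiv = 0, subclass_depth = 1L, seed = 3L
  )
  expect_identical(nrow(flat$ontology$subsume), 0L)
  expect_identical(nrow(flat$ontology$equivalence), 0L)
  expect_identical(nrow(flat$ontology$subclass), 0L)
  expect_identical(length(flat$signatures), 30L)

  expect_error(
    generate_truth(signature_size = 10L, vocab_size = 5L),
    class = "tcmdx_invalid_config"
  )
})

test_that("compound signatures are the union of their parts", {
  truth <- generate_truth(p_subsume = 0.5, seed = 21L)
  expect_gt(nrow(truth$ontology$subsume), 0L)
  for (w in unique(truth$ontology$subsume$whole)) {
    parts <- subsumed_parts(truth$ontology, w)
    expect_identical(
      truth$signatures[[w]],
      sort(Reduce(union, truth$signatures[parts]))
    )
  }
  # subclass children extend their parent's signature
  for (i in seq_len(nrow(truth$ontology$subclass))) {
    child <- truth$ontology$subclass$child[i]
    parent <- truth$ontology$subclass$parent[i]
    expect_true(all(truth$signatures[[parent]] %in% truth$signatures[[child]]))
  }
})

test_that("simulated cases reproduce signatures in the noiseless limit", {
  truth <- generate_truth(n_syndromes = 8L, seed = 5L)
  cases <- generate_cases(truth, cases_per_syndrome = 3L, p_drop = 0, extra_mean = 0, seed = 5L)
  expect_identical(nrow(cases), 3L * length(truth$signatures))
  for (i in seq_len(nrow(cases))) {
    expect_setequal(cases$symptoms[[i]], truth$signatures[[cases$syndrome[i]]])
  }
  # determinism: byte-identical case tables under a fixed seed
  again <- generate_cases(truth, cases_per_syndrome = 3L, p_drop = 0, extra_mean = 0, seed = 5L)
  expect_identical(cases, again)
})

test_that("case lengths stay inside the clamp range under heavy noise", {
  truth <- generate_truth(n_syndromes = 6L, seed = 13L)
  cases <- generate_cases(truth,
    cases_per_syndrome = 10L, p_drop = 0.2, extra_mean = 40, seed = 13L
  )
  len <- lengths(cases$symptoms)
  expect_true(all(len >= 1L & len <= 32L))
})

test_that("strict intersection of noisy cases stays inside the signature", {
  truth <- generate_truth(n_syndromes = 10L, p_subsume = 0, p_equiv = 0,
                          subclass_depth = 1L, seed = 17L)
  cases <- generate_cases(truth,
    cases_per_syndrome = 20L, p_drop = 0.1, extra_mean = 3, seed = 17L
  )
  for (nm in names(truth$signatures)[1:5]) {
    sets <- cases$symptoms[cases$syndrome == nm]
    strict <- threshold_intersect(sets, length(sets))
    expect_true(all(strict %in% truth$signatures[[nm]]))
  }
})

test_that("recovery metrics hit the closed-form limits", {
  truth <- generate_truth(n_syndromes = 10L, seed = 29L)
  cases <- generate_cases(truth, cases_per_syndrome = 5L, p_drop = 0, extra_mean = 0, seed = 29L)
  table <- build_mapping_table(cases)
  rec <- evaluate_recovery(table, truth)
  expect_identical(rec$exact_fraction, 1)
  expect_identical(rec$mean_jaccard, 1)

  empty_table <- build_mapping_table(heat_cases())
  rec0 <- evaluate_recovery(empty_table, truth)
  expect_identical(rec0$exact_fraction, 0)
  expect_identical(rec0$mean_jaccard, 0)
  detail <- attr(rec0, "detail")
  expect_identical(nrow(detail), length(truth$signatures))
})

test_that("recovery does not improve when dropout worsens", {
  grid <- c(0, 0.2, 0.45)
  mean_exact <- vapply(grid, function(p_drop) {
    mean(vapply(1:3, function(s) {
      truth <- generate_truth(
        n_syndromes = 12L, p_subsume = 0, p_equiv = 0,
        subclass_depth = 1L, seed = s
      )
      cases <- generate_cases(truth,
        cases_per_syndrome = 12L, p_drop = p_drop, extra_mean = 3, seed = s
      )
      table <- build_mapping_table(cases, threshold_config(0.6))
      evaluate_recovery(table, truth)$exact_fraction
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_exact) <= 0.05))
})

test_that("misspelled variants stay close under the LCS weight", {
  v <- misspell_variants(c("headache", "night sweats", "palpitations"), seed = 2L)
  expect_identical(nrow(v), 3L)
  for (i in seq_len(nrow(v))) {
    w <- word_weight(v$label[i], v$variant[i])$weight
    expect_gte(w, 0.6)
    expect_lte(w, 1)
  }
})

test_that("a simulated study writes a loadable model directory", {
  dir <- withr::local_tempdir()
  out <- simulate_study(dir, seed = 7L, n_syndromes = 6L)
  expect_true(all(file.exists(file.path(
    dir, c("cases.csv", "ontology.tsv", "truth.json")
  ))))
  cases <- read_cases(file.path(dir, "cases.csv"))
  expect_identical(nrow(cases), nrow(out$cases))
  ont <- read_ontology(file.path(dir, "ontology.tsv"))
  expect_identical(ont$classes, out$truth$ontology$classes)
})
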