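test_that("threshold arithmetic clamps as documented", {
  expect_identical(choose_threshold(2, threshold_config(1.0, 1L)), 2L)
  expect_identical(choose_threshold(10, threshold_config(0.6, 2L)), 6L)
  expect_identical(choose_threshold(1, threshold_config(0.2, 1L)), 1L)
  expect_identical(choose_threshold(5, threshold_config(0.1, 3L)), 3L)
  expect_error(threshold_config(t_fraction = 0))
  expect_error(threshold_config(t_fraction = 1.2))
})

test_that("t-threshold intersection matches the worked example and edge cases", {
  sets <- list(c("heat", "dizzy", "redface"), c("heat", "dizzy", "sore throat"))
  expect_identical(threshold_intersect(sets, 2), c("dizzy", "heat"))
  # t = 1 is the union
  expect_identical(
    threshold_intersect(sets, 1),
    sort(unique(unlist(sets)))
  )
  expect_error(threshold_intersect(sets, 0), class = "tcmdx_invalid_threshold")
  expect_error(threshold_intersect(sets, 3), class = "tcmdx_invalid_threshold")
  expect_identical(threshold_intersect(list(character()), 1), character())
})

test_that("t-threshold intersection equals the counting oracle on random instances", {
  set.seed(101)
  for (trial in 1:40) {
    k <- sample(2:20, 1L)
    sets <- random_sets(k)
    for (t in unique(c(1L, sample.int(k, min(k, 4L)), k))) {
      expect_identical(threshold_intersect(sets, t), oracle_threshold(sets, t))
      # force the galloping path too
      expect_identical(
        threshold_intersect(sets, t, small_cutoff = 0L),
        oracle_threshold(sets, t)
      )
    }
  }
  # the specific instance family: 50 sets over a 40-symbol alphabet, t = 25
  sets <- random_sets(50L, alphabet_size = 40L, max_len = 40L)
  expect_identical(threshold_intersect(sets, 25), oracle_threshold(sets, 25))
})

test_that("t-threshold intersection is anti-monotone in t and certified", {
  set.seed(202)
  for (trial in 1:10) {
    k <- sample(3:12, 1L)
    sets <- random_sets(k, alphabet_size = 30L)
    prev <- threshold_intersect(sets, 1)
    for (t in 2:k) {
      cur <- threshold_intersect(sets, t)
      expect_true(all(cur %in% prev))
      # certification: every output element really occurs in >= t sets
      occ <- vapply(
        cur,
        function(e) sum(vapply(sets, function(s) e %in% s, logical(1))),
        numeric(1)
      )
      expect_true(all(occ >= t))
      prev <- cur
    }
  }
})

test_that("adaptive sorted intersection matches naive pairwise intersection", {
  # identical sets: idempotence
  s <- sort(c("heat", "dizzy", "redface"))
  expect_identical(adaptive_sorted_intersect(list(s, s, s)), s)
  # disjoint sets
  expect_identical(
    adaptive_sorted_intersect(list(c("a", "b"), c("c", "d"))),
    character()
  )
  expect_error(
    adaptive_sorted_intersect(list(c("b", "a"))),
    class = "tcmdx_unsorted_input"
  )
  set.seed(303)
  for (trial in 1:20) {
    k <- sample(2:8, 1L)
    sets <- lapply(random_sets(k, alphabet_size = 60L, max_len = 50L),
                   function(s) sort(unique(s)))
    expect_identical(adaptive_sorted_intersect(sets), oracle_pairwise(sets))
    expect_identical(
      adaptive_sorted_intersect(sets, small_cutoff = 0L),
      oracle_pairwise(sets)
    )
  }
})

test_that("mapping extraction recovers the Heat entry and handles k = 1", {
  table <- build_mapping_table(heat_cases())
  expect_s3_class(table, "mapping_table")
  heat_syndrome <- table[table$kind == "syndrome" & table$name == "Heat", ]
  expect_identical(heat_syndrome$symptoms[[1]], c("dizzy", "heat"))
  expect_identical(heat_syndrome$support, 2L)
  heat_disease <- table[table$kind == "disease" & table$name == "Heat", ]
  expect_identical(heat_disease$symptoms[[1]], c("dizzy", "heat"))

  single <- as_cases(data.frame(
    disease = "d", syndrome = "q", symptoms = "x,y"
  ))
  t1 <- build_mapping_table(single)
  expect_identical(
    t1$symptoms[t1$kind == "syndrome"][[1]],
    c("x", "y")
  )
  expect_error(build_mapping_table(heat_cases()[0, ]))
})

test_that("empty strict intersections relax the threshold when allowed", {
  cases <- as_cases(data.frame(
    disease = "d", syndrome = "q",
    symptoms = c("a,b", "b,c", "c,d")
  ))
  relaxed <- build_mapping_table(cases, threshold_config(1.0, fallback_relax = TRUE))
  q <- relaxed[relaxed$kind == "syndrome", ]
  # strict intersection of the three sets is empty; t relaxes to 2
  expect_identical(q$symptoms[[1]], c("b", "c"))
  expect_identical(q$threshold, 2L)

  strict <- build_mapping_table(cases, threshold_config(1.0, fallback_relax = FALSE))
  expect_identical(strict$symptoms[strict$kind == "syndrome"][[1]], character())
})

test_that("extraction is deterministic and serializes through JSON and TSV", {
  table <- build_mapping_table(heat_cases())
  expect_identical(table, build_mapping_table(heat_cases()))

  json <- withr::local_tempfile(fileext = ".json")
  write_mapping_table(table, json)
  again <- read_mapping_table(json)
  expect_identical(again$name, table$name)
  expect_identical(again$symptoms, table$symptoms)
  expect_identical(again$support, table$support)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_mapping_tsv(table, tsv)
  lines <- readLines(tsv)
  expect_identical(lines[1], "entity\tsymptoms")
  expect_length(lines, nrow(table) + 1L)
})
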