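sample_owl <- function() {
  read_ontology(system.file("extdata", "synont-sample.owl", package = "tcmdx"))
}

test_that("the OWL idioms parse into the expected axioms", {
  ont <- sample_owl()
  expect_setequal(
    equivalence_set(ont, "Deficient cold syndrome"),
    c("Deficient cold syndrome", "Cold syndrome", "Yang deficient syndrome")
  )
  expect_identical(
    subsumed_parts(ont, "Qi stagnation and blood stasis"),
    c("Blood stasis syndrome", "Qi stagnation syndrome")
  )
  expect_identical(
    subsumers_of(ont, "Qi stagnation syndrome"),
    "Qi stagnation and blood stasis"
  )
  expect_identical(
    syndrome_ancestors(ont, "Qi stagnation and blood stasis"),
    "Excess syndrome"
  )
  s <- ontology_stats(ont)
  expect_identical(s$subsume_axioms, 2L)
  expect_identical(s$subclass_axioms, 1L)
  expect_identical(s$equivalent_axioms, 2L)
})

test_that("empty documents and unknown predicates are handled", {
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), empty)
  ont <- read_ontology(empty)
  expect_identical(unlist(ontology_stats(ont)), c(
    classes = 0L, subclass_axioms = 0L,
    equivalent_axioms = 0L, subsume_axioms = 0L
  ))

  weird <- withr::local_tempfile(fileext = ".tsv")
  writeLines("a\tcauses\tb\na\tis_a\tb", weird)
  expect_warning(ont2 <- read_ontology(weird), "unknown predicate")
  expect_identical(nrow(ont2$subclass), 1L)

  owl_restr <- withr::local_tempfile(fileext = ".owl")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
    '         xmlns:owl="http://www.w3.org/2002/07/owl#">',
    '  <owl:Class rdf:about="a">',
    "    <owl:equivalentClass>",
    "      <owl:Restriction>",
    '        <owl:onProperty rdf:resource="causes"/>',
    '        <owl:someValuesFrom rdf:resource="b"/>',
    "      </owl:Restriction>",
    "    </owl:equivalentClass>",
    "  </owl:Class>",
    "</rdf:RDF>"
  ), owl_restr)
  expect_warning(ont3 <- read_ontology(owl_restr), "unknown property")
  expect_identical(nrow(ont3$subsume), 0L)
})

test_that("invalid ontologies are rejected", {
  expect_error(
    syndrome_ontology(subclass = data.frame(
      child = c("a", "b", "c"), parent = c("b", "c", "a")
    )),
    class = "tcmdx_invalid_ontology"
  )
  expect_error(
    syndrome_ontology(subsume = data.frame(whole = "a", part = "a")),
    class = "tcmdx_invalid_ontology"
  )
})

test_that("triple-dialect write/load round trip preserves all axiom sets", {
  ont <- syndrome_ontology(
    classes = c("lonely"),
    equivalence = data.frame(a = "a", b = "b"),
    subclass = data.frame(child = c("c", "d"), parent = c("d", "e")),
    subsume = data.frame(whole = "w", part = c("c", "a"))
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ontology(ont, path)
  again <- read_ontology(path)
  expect_identical(again$classes, ont$classes)
  expect_identical(again$equivalence, ont$equivalence)
  expect_identical(again$subclass, ont$subclass)
  expect_identical(again$subsume, ont$subsume)
})

test_that("equivalence closure is a partition (reflexive, symmetric, transitive)", {
  ont <- syndrome_ontology(equivalence = data.frame(
    a = c("a", "b", "x"), b = c("b", "c", "y")
  ))
  expect_setequal(equivalence_set(ont, "a"), c("a", "b", "c"))
  expect_identical(equivalence_set(ont, "unknown"), "unknown")
  for (nm in ont$classes) {
    for (other in equivalence_set(ont, nm)) {
      expect_true(nm %in% equivalence_set(ont, other))
    }
  }
})

test_that("ancestors equal BFS reachability on random DAGs and are transitive", {
  set.seed(404)
  for (trial in 1:5) {
    nodes <- sprintf("n%02d", 1:30)
    # edges only from lower to higher index: acyclic by construction
    from <- sample(nodes[1:29], 40L, replace = TRUE)
    to <- vapply(from, function(f) {
      i <- match(f, nodes)
      sample(nodes[(i + 1):30], 1L)
    }, character(1), USE.NAMES = FALSE)
    ont <- syndrome_ontology(subclass = data.frame(child = from, parent = to))
    for (nm in sample(nodes, 6L)) {
      expect_identical(
        syndrome_ancestors(ont, nm),
        oracle_reachable(from, to, nm)
      )
    }
    # transitivity
    a <- sample(nodes, 1L)
    for (b in syndrome_ancestors(ont, a)) {
      expect_true(all(syndrome_ancestors(ont, b) %in% syndrome_ancestors(ont, a)))
    }
  }
  expect_identical(syndrome_ancestors(sample_owl(), "Excess syndrome"), character())
})

test_that("effective symptoms union equivalents, ancestors and parts", {
  table <- build_mapping_table(as_cases(data.frame(
    disease = "d",
    syndrome = c("b", "c", "parent", "child", "iso"),
    symptoms = c("x", "y", "u", "v", "p,q")
  )))
  ont <- syndrome_ontology(
    subsume = data.frame(whole = "a", part = c("b", "c")),
    subclass = data.frame(child = "child", parent = "parent")
  )
  # whole captures the union of its parts, with no table entry of its own
  expect_identical(effective_symptoms(table, ont, "a"), c("x", "y"))
  # subclass inherits superclass symptoms
  expect_identical(effective_symptoms(table, ont, "child"), c("u", "v"))
  # isolated node: just its own entry
  expect_identical(effective_symptoms(table, ont, "iso"), c("p", "q"))
  # equivalence contributes symptoms
  ont2 <- syndrome_ontology(equivalence = data.frame(a = "iso", b = "b"))
  expect_identical(effective_symptoms(table, ont2, "iso"), c("p", "q", "x"))
})

test_that("effective symptoms are monotone and contain every part's closure", {
  table <- build_mapping_table(as_cases(data.frame(
    disease = "d",
    syndrome = c("b", "c", "e"),
    symptoms = c("x1,x2", "y1", "z1,z2,z3")
  )))
  ont <- syndrome_ontology(subsume = data.frame(whole = "a", part = c("b", "c")))
  before <- effective_symptoms(table, ont, "a")
  # adding a subsume edge never shrinks an effective set
  ont_more <- syndrome_ontology(subsume = data.frame(
    whole = c("a", "a", "b"), part = c("b", "c", "e")
  ))
  after <- effective_symptoms(table, ont_more, "a")
  expect_true(all(before %in% after))
  # whole's closure contains each part's closure
  for (p in subsumed_parts(ont_more, "a")) {
    expect_true(all(effective_symptoms(table, ont_more, p) %in% after))
  }
  # recursive subsume: a -> b -> e
  expect_true(all(c("z1", "z2", "z3") %in% after))
  # subsume cycles are detected during traversal
  ont_cyc <- syndrome_ontology(subsume = data.frame(
    whole = c("a", "b"), part = c("b", "a")
  ))
  expect_error(
    effective_symptoms(table, ont_cyc, "a"),
    class = "tcmdx_invalid_ontology"
  )
})
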