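# Independent oracles and small builders shared across the test files.

# Brute-force occurrence counting: element kept iff it occurs in >= t sets.
oracle_threshold <- function(sets, t) {
  elems <- unique(unlist(lapply(sets, unique), use.names = FALSE))
  if (!length(elems)) return(character())
  counts <- vapply(
    elems,
    function(e) sum(vapply(sets, function(s) e %in% s, logical(1))),
    numeric(1)
  )
  sort(elems[counts >= t])
}

# Fold of pairwise set intersection.
oracle_pairwise <- function(sets) {
  sort(Reduce(intersect, lapply(sets, unique)))
}

# Exponential-enumeration LCS: try all index subsets of the shorter string,
# longest first, and keep the first that is a subsequence of the longer.
oracle_lcs <- function(a, b) {
  if (nchar(a) > nchar(b)) {
    tmp <- a; a <- b; b <- tmp
  }
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  n <- length(ca)
  if (n == 0L) return(0L)
  is_subseq <- function(sub, seq) {
    j <- 1L
    for (s in seq) {
      if (j <= length(sub) && s == sub[j]) j <- j + 1L
    }
    j > length(sub)
  }
  for (len in n:1) {
    for (idx in utils::combn(n, len, simplify = FALSE)) {
      if (is_subseq(ca[idx], cb)) return(len)
    }
  }
  0L
}

# Random symptom-set instances over a bounded alphabet.
random_sets <- function(k, alphabet_size = 50L, max_len = 40L) {
  alphabet <- sprintf("s%03d", seq_len(alphabet_size))
  lapply(seq_len(k), function(i) {
    sample(alphabet, sample.int(min(max_len, alphabet_size), 1L))
  })
}

# BFS reachability, used as the ancestors oracle on random DAGs.
oracle_reachable <- function(edges_from, edges_to, start) {
  seen <- character()
  frontier <- start
  while (length(frontier)) {
    nxt <- unique(edges_to[edges_from %in% frontier])
    frontier <- setdiff(nxt, c(seen, start))
    seen <- c(seen, frontier)
  }
  sort(seen)
}

# The worked two-row Heat table used throughout.
heat_cases <- function() {
  as_cases(data.frame(
    disease = c("Heat", "Heat"),
    syndrome = c("Heat", "Heat"),
    symptoms = c("heat,dizzy,redface", "heat,dizzy,sore throat")
  ))
}

# A toy model with a compound syndrome subsuming two parts: table entries
# carry only the parts, the ontology carries the whole.
compound_model <- function(with_ontology = TRUE) {
  cases <- as_cases(data.frame(
    disease = rep("wind illness", 2L),
    syndrome = c("wind cold", "damp heat"),
    symptoms = c("chills,stiff neck,floating pulse", "thirst,yellow fur,rapid pulse")
  ))
  ont <- if (with_ontology) {
    syndrome_ontology(
      subsume = data.frame(
        whole = "wind cold with damp heat",
        part = c("wind cold", "damp heat")
      )
    )
  } else {
    syndrome_ontology()
  }
  build_model(cases, ont)
}
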