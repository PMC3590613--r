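---
title: "Ontology-assisted syndrome differentiation with tcmdx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ontology-assisted syndrome differentiation with tcmdx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcmdx)
```

## The problem

In Traditional Chinese Medicine (TCM), therapy is decided mainly by the
*syndrome* (pattern of disharmony) a patient presents, diagnosed alongside a
macroscopic *disease* category. A diagnosis is therefore a combined answer
`D = C ⊕ Q`: a disease `C` plus one or more syndromes `Q`, inferred from an
observed symptom set `S = {s1, …, sm}`. Curated clinical case collections
record exactly this as three columns — disease, syndrome, symptom list — one
row per case. `tcmdx` turns such a table into a diagnostic library, refines
candidate syndromes through a small syndrome ontology, and answers free-text
symptom queries by fuzzy ranking.

The pipeline has four stages, each exposed as ordinary functions on tibbles:

1. **Extraction** (`build_mapping_table()`): for every disease and every
   syndrome, reduce its k case symptom sets to a *minimum associated symptom
   set* by t-threshold intersection.
2. **Ontology** (`read_ontology()`, `effective_symptoms()`): equivalence,
   inheritance (is-a) and subsume (compound-of-parts) axioms expand each
   syndrome's symptom set.
3. **Fuzzy matching** (`set_similarity()`, `rank_candidates()`): score a
   user's symptom list against library entries with an LCS-based weight.
4. **Refinement** (`match_relation()`, `refine()`, `diagnose()`): classify
   the set relation between query and top candidate and rectify the answer
   with the ontology.

## Minimum symptom-set extraction

Writing each case as `C ⊕ Q = S(s1, …, sp)`, the same syndrome recurs across
many cases, and the frequency with which a symptom co-occurs with it measures
the strength of their connection. The extraction therefore keeps, for a group
of k case sets, the symptoms present in at least t of them — the
*t-threshold intersection*; `t = k` is the ordinary intersection and `t = 1`
the union. The two-row worked example:

```{r heat}
cases <- read_cases(system.file("extdata", "heat-cases.csv", package = "tcmdx"))
build_mapping_table(cases)
```

Both rows list *heat* and *dizzy*; *redface* and *sore throat* each appear
once, so the entry for Heat is `{dizzy, heat}`.

`threshold_intersect()` is implemented in the adaptive style for sorted
inputs: all k sets are intersected in parallel, and each round the
*eliminator* is the t-th smallest of the current heads. Every element below
the eliminator can occur in at most t − 1 sets, so each set skips forward to
the eliminator with a galloping (doubling-then-binary) search — time
proportional to the shortest certificate of the output rather than to the
total input size. Two numerical choices matter:

* **Small-set cutoff** (`small_cutoff`, default 16): when every set is
  short, doubling search is pure overhead and a linear counting merge is
  used instead. Clinical cases average well under 16 symptoms, so the merge
  is the common path; the galloping path takes over for long sets.
* **Threshold rule**: `t = min(k, max(t_min, ceiling(t_fraction * k)))`.
  The default `t_fraction = 1` reproduces the strict-intersection reading of
  the worked example; with noisy records a fraction around 0.6 is a
  practical operating point. If the thresholded result is empty,
  `fallback_relax = TRUE` decrements t until it is not (or t = 1): an empty
  library entry is never useful, and the relaxation is recorded in the
  `threshold` column.

Sets are compared after mapping symptoms to integer ranks over the sorted
union of the group, which makes the order used by the galloping search
independent of the session locale. Outputs are always sorted
lexicographically, so extraction is deterministic given the same input.

## The syndrome ontology

Syndromes are not independent names: the same concept carries several names
(equivalence), syndromes sit in a categorical is-a hierarchy (a subclass
inherits its superclass's symptoms), and compound syndromes such as
*Qi stagnation and blood stasis* capture the union of their parts' symptoms
(subsume). `read_ontology()` accepts OWL/RDF-XML using the standard idioms —
`owl:equivalentClass` between named classes, `rdfs:subClassOf`, and
`owl:equivalentClass` wrapping an `owl:Restriction` on a property locally
named `subsume` with `owl:someValuesFrom` — or a 3-column TSV triple dialect
(`subject predicate object`, predicates `class`/`equivalent`/`is_a`/
`subsume`) that is convenient for fixtures and round-trips exactly.

```{r owl}
ont <- read_ontology(system.file("extdata", "synont-sample.owl", package = "tcmdx"))
ontology_stats(ont)
equivalence_set(ont, "Deficient cold syndrome")
subsumed_parts(ont, "Qi stagnation and blood stasis")
```

`effective_symptoms()` is the closure used for re-scoring: the union of the
table symptoms of the name's equivalence class, of its is-a ancestors, and —
recursively — the effective symptoms of its subsumed parts. Design choices
where the semantics were genuinely open:

* Equivalence contributes *symptoms* but not the equivalents' subclass or
  subsume edges; `merge_equivalents = TRUE` turns edge sharing on. Axiom
  propagation across equivalence has no single standard reading, so the
  conservative behaviour is the default.
* Subsume composes recursively (a part may itself be a compound), with
  explicit cycle detection; the union semantics makes recursion natural.
* `ontology_stats()` counts named classes only: the anonymous restriction
  classes that the OWL subsume idiom introduces are syntactic scaffolding.
* The subsume property is matched by local name in any namespace, since
  published files vary in their namespace URIs.
* The subclass graph is validated acyclic at construction; subsume cycles
  are caught during traversal.

## Fuzzy matching

User queries are lay descriptions; the library holds technical terms. With
no semantic matcher assumed, similarity is plain text match letter by
letter: for two labels `a`, `b`,

```
weight(a, b) = length(lcs(a, b)) / max(length(a), length(b))
```

where `lcs` is the longest common subsequence (dynamic programming over the
characters of the normalized label, spaces included). Each input symptom is
paired with its best match in the candidate entry (ties to the earliest
position), and

```
sim(input, list) = num(weight = 1) × Σ weight / list_size
```

with `list_size` the *candidate entry's* size. Two consequences are worth
stating plainly: the score is a ranking value, not a probability — an input
identical to an m-symptom entry scores m — and with no exact match at all
the similarity is 0 regardless of partial weights, because the exact-match
count multiplies the weight sum. The formula is implemented literally;
`epsilon > 0` in `set_similarity()` optionally adds smoothing
(`(exact + ε) × …`) for applications that want partial-only matches to
rank, and is off by default. The prose definition of `list_size` is
ambiguous between the input's size and the candidate's; the candidate's
size is used here, which penalizes large entries that the input covers only
partly, and the alternative only rescales scores within a fixed input so
the ranking of equally-sized entries is unchanged.

```{r fuzzy}
word_weight("abc", "abcd")
set_similarity(c("heat", "dizzy"), c("heat", "dizzy", "redface"))
```

## Relation refinement and diagnosis

`diagnose()` ranks disease entries and syndrome entries independently, then
rectifies the top syndrome through the ontology according to the set
relation between the query S and the candidate's set T:

| relation | strategy |
|---|---|
| `S = T` (equal) | the candidate and its equivalents are perfect answers |
| `S ⊃ T` (input_superset) | consider compounds that subsume the candidate |
| `S ⊂ T` (input_subset) | consider the candidate's superclasses |
| `S ∩ T` (partial) | greedily decompose S into combined syndromes |
| disjoint | keep the candidate, warn |

The partial case applies when the overlap's Jaccard index reaches
`overlap_threshold`; no canonical value exists for this cutoff, and the
default 0.3 admits overlaps down to a third of the union while keeping
near-disjoint pairs out. Set relations are computed under crisp normalized
equality by default — fuzzy weights decide *ranking*, not set algebra — with
an optional fuzzy-membership mode (`fuzzy = TRUE`, weight ≥ 0.8 counts as
matched). Decomposition is a greedy cover (rank, take the best, remove its
matched symptoms, recurse) capped at `max_components = 4`, reflecting that
a patient rarely presents more than a few concurrent syndromes; it is not
an exhaustive set cover, which would be exponential and rarely differ on
real inputs. Refined candidates are re-scored against their
`effective_symptoms()` closure — the ontology-expanded set — and the initial
candidate is always retained, so refinement never loses the raw answer.
Disease ranking is not re-run after syndrome refinement.

```{r diagnose}
model <- build_model(
  as_cases(data.frame(
    disease = "wind illness",
    syndrome = c("wind cold", "damp heat"),
    symptoms = c("chills,stiff neck,floating pulse", "thirst,yellow fur,rapid pulse")
  )),
  syndrome_ontology(subsume = data.frame(
    whole = "wind cold with damp heat", part = c("wind cold", "damp heat")
  ))
)
diagnose(model, c(
  "chills", "stiff neck", "floating pulse",
  "thirst", "yellow fur", "rapid pulse"
))
```

The compound syndrome is not a library entry at all — no case mentions it —
yet it ranks first because the input is the union of its parts' symptom
sets and the subsume axiom assembles that union. With an empty ontology,
`diagnose()` reduces exactly to `rank_candidates()`: the ontology is a
strict add-on, which makes ablation comparisons trivial.

## What the synthetic generator emulates — and what it does not

Real case collections of this kind are not redistributable, so the package
ships a seeded generator with planted ground truth. `generate_truth()`
plants one symptom signature per syndrome (default 30 syndromes of 6
symptoms from a 300-token vocabulary, matching the scale of mean case
lengths around 6–8 in curated collections, scaled down from hundreds of
syndromes to keep test runs fast), assigns syndromes to 5 diseases, and
optionally plants equivalence aliases, is-a chains whose child signatures
extend the parent's, and compound syndromes whose signature is the union of
two parts. `generate_cases()` emits cases per syndrome by dropping each
signature symptom with probability `p_drop` (default 0.05) and appending
Poisson(`extra_mean = 3`) noise symptoms, clamped to the 1–32 length range
observed in real collections; the Poisson noise reproduces a long-tailed
length distribution without claiming a fitted model.
`evaluate_recovery()` then scores extraction: with
20 cases per syndrome, `p_drop = 0.05`, 3 noise symptoms on average and
`t_fraction = 0.6`, exact signature recovery is essentially perfect, and
the suite requires ≥ 90% on each of three seeds.

What the generator does *not* emulate: correlated symptoms, vocabulary
misspellings within case tables (near-duplicate labels are exercised
separately via `misspell_variants()`), multi-syndrome rows, or realistic
TCM terminology — symptoms are synthetic tokens `sym0001…`. Passing
recovery tests therefore show that the extraction machinery is correct
under the planted model, not that any particular accuracy carries over to a
real clinical database.

## Degenerate inputs and edge behaviour

* Symptom labels that normalize to empty are dropped at parse time with a
  warning (errors for a whole-query loss in `diagnose()`).
* `threshold_intersect()` rejects t outside `[1, k]`;
  `adaptive_sorted_intersect()` rejects inputs that are not strictly
  increasing rather than silently sorting them.
* A group whose strict intersection is empty keeps a non-empty entry via
  threshold relaxation (see above) unless `fallback_relax = FALSE`.
* An absent ontology degrades every ontology-dependent step to the
  identity; an unknown syndrome name has equivalence class `{name}`, no
  ancestors and no parts.
* All rankings break ties by exact-match count, then name, so outputs are
  reproducible across sessions and platforms.

## Reproducing the headline numbers

`scripts/acceptance.R` in the source repository recomputes every quantity
discussed here from scratch — the worked Heat example, the ontology listing
groups, oracle agreement of the intersection and LCS routines (counting and
enumeration oracles re-derived in the script), the similarity closed form,
synthetic recovery at the study conditions above, and the
compound-promotion contrast with and without the ontology — and writes them
to JSON. Problem sizes are chosen to keep the full run near ten seconds:
200 random intersection instances (k ≤ 20, alphabet ≤ 50), 500 LCS pairs of
length ≤ 8, and 3 × 30 synthetic syndromes.

## Known limitations

* Matching is character-level LCS only; no semantic or embedding matching,
  and no modelling of symptom intensity ("a little pain").
* The literal similarity formula scores 0 without an exact match; the
  epsilon smoothing exists precisely because lay queries may contain only
  near-miss spellings.
* Only the top-ranked syndrome is refined by default (`refine_top`
  raises it); disease ranking is never ontology-refined because the
  ontology models syndromes only.
* OWL support covers the idioms above, not full OWL-DL (no property
  chains, cardinality or disjointness axioms).
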