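---
title: "Evaluating design patterns for compound anatomy–pathology ontologies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating design patterns for compound anatomy–pathology ontologies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontocombine)
```

## The problem

Necropsy findings are coded as pairs: an anatomy class for the site and a
pathology class for the lesion. Analyses that operate over a single
ontology — over-representation tests, semantic similarity — cannot see the
pair structure. `ontocombine` precomposes the observed pairs into compound
classes under four alternative design patterns and provides the quantitative
machinery to judge, on a given dataset, whether (and which) compounding
helps. The external yardstick is a biological fact about inbred mice: mice
of the same strain share a lesion spectrum, so any method that measures
phenotypic similarity well should find same-strain mice more similar than
cross-strain mice.

## Patterns and the structural classifier

Each compound class pairs an anatomy class A with a pathology class P.
MAP/MAPT read "an A bearing lesion P" and use the anatomy taxonomy as
backbone; PAM/PAMT read "a P affecting A" and use the pathology taxonomy
(an adenoma affecting the lung is still an adenoma). The T variants
additionally route the anatomy side of subsumption through transitive
`part_of`, so a lesion in the left ventricle also counts for the heart.

We do not run a DL reasoner. For this fragment — a named class conjoined
with a single existential restriction, a transitive `part_of` role, and the
top-level contextualization axioms — subsumption between compound classes
factors exactly into per-side ancestor tests:

* (A₂, P₂) subsumes (A₁, P₁) iff A₂ ∈ anc(A₁) and P₂ ∈ anc(P₁),

with anc on the anatomy side taken over `is_a` (MAP/PAM) or `is_a ∪ part_of`
(MAPT/PAMT), and over `is_a` on the pathology side. The emitted hierarchy is
the transitive reduction of the union graph (both source taxonomies, all
compound classes, one fresh `owl:Thing` top), which is what a reasoner's
de-duplicated inferred hierarchy looks like. The test suite checks the
emitted graph against a brute-force O(n²) pairwise application of the rule
plus a reachability-based minimality check on dozens of random worlds.

Two deliberate modelling choices:

* **Backbone attachment for the T variants.** `∃part_of.A ⊓ …` is not
  logically a subclass of A, but attaching each compound class beneath its
  anatomy (or pathology) class is what keeps the result a single rooted
  taxonomy, and mirrors the shape of the published inferred hierarchies.
  We accept this approximation knowingly.
* **Contextualization equivalences.** A compound class whose non-backbone
  side is that side's root (e.g. "heart with *some* lesion") is logically
  equivalent to its backbone class under the contextualization axioms. Such
  classes are merged into the backbone class, with the compound ID kept as
  a synonym, so the graph stays a simple DAG instead of carrying
  equivalence nodes.

The structural rule also implies two invariants the tests assert: the MAP
and PAM hierarchies induce the *same* partial order on compound classes
(they differ only in backbone attachment), and the T variants' relations are
supersets of their non-T counterparts.

## OQuaRE metrics: conventions

Tangledness (TMOnto) is the fraction of classes with more than one direct
`is_a` parent; WMCOnto is the mean depth of leaf classes; DITOnto the
maximum leaf depth. Published tables rarely pin down the depth convention,
so it is explicit and configurable here: the default is the **longest**
`is_a` path from the root, with the root at depth 0. Only `is_a` edges
count — these are taxonomy metrics. When the analysis is restricted to newly
created classes, the class and leaf sets (and the denominator N) are
intersected with the restriction while depths remain those of the full
graph. Classification can only add parents, so tangledness of a classified
compound ontology is never below that of its asserted (attachment-only)
form; the suite checks this direction on random builds.

## Information content and similarity

The IC corpus counts one occurrence per (mouse, class) pair after
deduplication — repeated identical line items from one necropsy are almost
always transcription granularity, not independent evidence. A class's
cumulative count sums direct counts over its `is_a` descendants-or-self;
`p(x)` divides by the total number of direct annotations, so the root always
has `p = 1` and `IC = 0`. (Reading the normalising constant as "number of
classes" instead would leave `p(root) ≠ 1`; we use the standard corpus-size
normalisation.) Logs are natural by default and configurable. Classes never
observed get the `1/N` smoothing but are flagged and excluded from MICA
search: their IC is an artefact, not evidence of specificity.

Resnik similarity is the IC of the most informative common `is_a` ancestor;
mouse-to-mouse similarity is the best-match average of Resnik values over
the two annotation sets. Healthy mice carry exactly the root annotation, so
they never drop out — their similarity to everything (including each other)
is 0, which is the honest statement that "no findings" carries no
discriminative information in this framework.

## Purity, ROC, and ranks

Similarity matrices convert to distances by `d = s_max − s` with the global
maximum (the convention is unstated in the literature this follows; it is a
monotone flip, which is all the rank-based clusterers need), diagonal
zeroed. Four clusterers run directly on the distance matrix; neighbor
joining records its join order so that "clusters at k" are the components
after undoing the last k − 1 joins, and k-medoids uses PAM's deterministic
BUILD + SWAP. Purity assigns each cluster its modal strain (ties broken by
lexicographically smallest strain name). The purity AUC is the trapezoid
over k = 2..M divided by M − 1, so a perfect clustering approaches 1 from
below.

The ROC treats similarity as a same-strain retrieval problem: per probe
mouse, all other mice are ranked by descending similarity with ties broken
deterministically by ascending mouse ID (an average-rank tie mode is
available behind a flag); rates are pooled over probes per threshold. Its
trapezoid AUC provably equals the pooled pair-ordering probability — the
fraction of (same-strain, cross-strain) candidate pairs ranked correctly —
and the test suite verifies that identity exhaustively on 6-mouse instances.
Self-similarity is excluded, so each probe has M − 1 candidates.

Cross-view comparisons use Kendall's τ-b over pooled (strain, anatomy,
pathology) keys — compound classes are unprojected to their source pair so
that rankings from different patterns align — and the Wilcoxon rank-sum
test (normal approximation, tie-corrected) for score samples, with
Bonferroni correction left to the caller. Where the sampling unit of such a
comparison is ambiguous (pairwise similarities versus per-mouse one-vs-rest
AUCs), this package takes per-mouse scores as the unit and says so, rather
than claiming either as canonical.

## Enrichment

Per strain, a hypergeometric upper-tail test compares annotation frequency
in the strain versus the rest, after closing every annotation set under
`is_a` ancestors up to a shared `owl:Thing` stand-in. Family-wise error is
estimated from random sets: case/control labels are permuted with group
sizes preserved, the minimum p per permutation recorded, and a class's FWER
is the fraction of permutations whose minimum is at or below the class's
observed p. 1,000 random sets is the conventional default; the suite
verifies the estimator against exhaustive permutation on tiny cohorts.
Ranks order by raw p ascending with class-ID tie-breaks, so every class has
a unique rank.

## The synthetic world

The generator's defaults state the cohort it emulates: 28 strains of ~57
mice (~1,600 mice), a mean of 13 diagnoses per mouse, 5% of mice healthy
(the source data guarantee "some" healthy mice without giving a rate; 5% is
a realistic necropsy-cohort figure chosen once). Toy ontologies default to
60 anatomy / 40 pathology classes at depths 5 and 4 — scaled down from
thousands of classes at depths 8–9 while keeping a comparable branching
factor — with `part_of` edges drawn from deeper to strictly shallower
non-ancestral classes (acyclic by construction) and a vocabulary of 150
distinct diagnosis pairs. Strain propensities are Dirichlet draws over the
vocabulary; the concentration parameter moves the world between strongly
strain-specific lesion spectra (low values) and a single shared spectrum
(high values), under which strain-identification AUC collapses to 0.5.

The `combination_only` scenario is the crux case: L anatomy leaves are
paired with L pathology leaves under a per-strain cyclic shift, every strain
drawing uniformly over its own L pairs. Anatomy and pathology margins are
then identical and uniform across strains — single-ontology views are blind
by construction (the suite confirms chi-square flatness of both margins and
ROC AUC ≈ 0.5) — while the pairing is strain-disjoint, so compound views
separate strains strongly. A green result here establishes that the
compound patterns recover pair-level signal; it does **not** establish
anything about real necropsy data, where margins are informative too,
lesion co-occurrence is correlated with age and attrition, and annotation
depth varies by pathologist. Survival/attrition structure, severity grades
and sex-specific lesion biology are deliberately not simulated.

Sex and study group are assigned round-robin within strain, so (group, sex)
strata stay balanced and carry no signal; evaluation within strata (the
confounder-controlled design for real data) and pooled evaluation give the
same qualitative picture on synthetic cohorts.

## Numerical and degenerate-input choices

* Single global seed per simulated world; the cohort sampler derives its
  stream deterministically from it, so a seed reproduces byte-identical
  TSVs.
* Monte-Carlo checks in the test suite are sized so that sampling noise is
  small against the asserted band (e.g. the null-ROC check uses 60-mouse
  instances, putting ~4 standard deviations inside the ±0.05 band).
* `is_a` cycles are fatal ("cyclic hierarchy", naming a member); `part_of`
  cycles only warn, since no metric here traverses them upward exclusively.
* OBO edges pointing at obsolete terms are dropped with the term; edges to
  genuinely unknown IDs are errors.
* Empty corpora, empty annotation sets, single-strain ROC groups and
  strata where no mouse has a strain-mate are errors, not silent NaNs.

## Known limitations

* The structural classifier is sound and complete only for the four stated
  axiom templates; it is not a general EL reasoner, and ontologies whose
  mixed `is_a`/`part_of` reachability contains cycles are rejected rather
  than handled as class equivalences.
* Resnik + BMA is the only similarity measure implemented; conclusions from
  the evaluation repertoire are conditional on that choice.
* The OBO reader interprets the minimal tag set (`id`, `name`, `is_a`,
  `relationship: part_of`, `is_obsolete`) — no cross-products, annotations
  or imports.
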