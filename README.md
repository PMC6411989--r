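# ontocombine

Histopathology data are typically annotated with *two* ontologies at once:
an anatomy ontology saying *where* a lesion sits and a pathology ontology
saying *what* the lesion is. Keeping the two apart at annotation time avoids
combinatorial class bloat, but it cripples downstream analysis — enrichment
tests and semantic-similarity measures each see only one axis. `ontocombine`
is for researchers who want to combine such ontology pairs into a single
compound ontology and, crucially, to *measure* whether a particular way of
combining them is any good.

## The design patterns

Given an anatomy ontology (classes A with `is_a` and `part_of` relations)
and a pathology ontology (classes P with `is_a`), one compound class is
created per (A, P) pair observed in the data, under one of four axiom
templates:

| kind | definition                     | backbone  |
|------|--------------------------------|-----------|
| MAP  | `A ⊓ ∃has_lesion.P`            | anatomy   |
| MAPT | `∃part_of.A ⊓ ∃has_lesion.P`   | anatomy   |
| PAM  | `P ⊓ ∃affects.A`               | pathology |
| PAMT | `P ⊓ ∃affects.∃part_of.A`      | pathology |

together with top-level contextualization axioms (`⊤ ≡ ∃has_lesion.⊤`,
`⊤ ≡ ∃affects.⊤`). For this axiom fragment the inferred class hierarchy is
computed *structurally*: (A₂, P₂) subsumes (A₁, P₁) iff A₂ is reachable from
A₁ (via `is_a`, plus transitive `part_of` for the T variants) and P₂ is an
`is_a` ancestor-or-self of P₁ — no description-logic reasoner needed, and
the result is emitted as the transitive reduction of the union DAG.

## The evaluation repertoire

* **OQuaRE structural metrics** — tangledness `TMOnto = Σᵢ DP(Cᵢ)/N`
  (fraction of multi-parent classes), `WMCOnto` (mean leaf depth) and
  `DITOnto` (maximum leaf depth).
* **Semantic similarity** — information content `IC(x) = −log p(x)` with
  `p(x)` accumulated over subclasses; Resnik similarity
  `sim(x₁,x₂) = IC(MICA(x₁,x₂))`; best-match-average (BMA) aggregation to
  mouse-to-mouse similarity matrices.
* **Clustering purity** — k-medoids (PAM), complete linkage, UPGMA and
  neighbor joining on the derived distance matrices; purity against the
  strain ground truth at every cluster count k, summarised as the area
  under the purity curve `AUC = (1/2(M−1)) Σₙ (Purityₙ + Purityₙ₊₁)`.
* **ROC analysis** — similarity as a same-strain classifier: per mouse, are
  the t most similar mice strain-mates? Pooled TPR/FPR per threshold, AUC
  by trapezoid.
* **Enrichment** — per-strain hypergeometric over-representation with
  family-wise error from label-permuted random sets, plus Kendall τ-b and
  Wilcoxon rank-sum comparisons of results across ontology views.
* **Synthetic cohorts** — strain-structured diagnosis tables with tunable
  propensity concentration, healthy fraction, and a *combination-only*
  scenario in which anatomy and pathology margins are identical across
  strains and only their pairing carries signal.

## Worked example

```r
library(ontocombine)

cfg  <- sim_config(n_strains = 8, mice_per_strain = 20,
                   combination_only = TRUE, seed = 1)
onts <- generate_toy_ontologies(cfg)
coh  <- simulate_cohort(cfg, onts$anatomy, onts$pathology)
pats <- build_all_patterns(coh, onts$anatomy, onts$pathology)

res <- roc_auc_by_view(coh, onts$anatomy, onts$pathology,
                       combined = pats, by_group = FALSE)
round(attr(res, "weighted"), 4)
#>     MA  MPATH    MAP   MAPT    PAM   PAMT
#> 0.4988 0.5006 0.8134 0.8129 0.8287 0.8246
```

In this cohort every strain uses the same anatomy classes and the same
pathology classes at the same frequencies — only the *pairing* differs per
strain. The single-ontology views are therefore blind (ROC AUC ≈ 0.5: a
mouse's most similar neighbours are no likelier to be strain-mates than
chance), while every compound view identifies strain-mates with AUC ≈ 0.81
to 0.83. Clustering tells the same story:

```r
purity_auc_by_view(coh, onts$anatomy, onts$pathology,
                   views = c("MA", "MAP"), combined = pats,
                   methods = c("upgma", "kmedoids"), by_group = FALSE)
#>   view group   method   n       auc
#> 1   MA   all    upgma 160 0.5941234
#> 2   MA   all kmedoids 160 0.6054049
#> 3  MAP   all    upgma 160 0.9228970
#> 4  MAP   all kmedoids 160 0.9679835
```

## Command line

A thin wrapper over the same functions lives at `inst/cli/ontocombine.R`:

```sh
Rscript inst/cli/ontocombine.R simulate --seed 3 --strains 6 \
    --mice-per-strain 20 --out cohort.tsv --mice mice.tsv \
    --anatomy-out a.obo --pathology-out p.obo
Rscript inst/cli/ontocombine.R build --anatomy a.obo --pathology p.obo \
    --diagnoses cohort.tsv --mice mice.tsv --pattern MAPT --out mapt.obo
Rscript inst/cli/ontocombine.R oquare --ontology mapt.obo
Rscript inst/cli/ontocombine.R evaluate --anatomy a.obo --pathology p.obo \
    --diagnoses cohort.tsv --mice mice.tsv --out report.tsv
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates the synthetic world from the given seed and recomputes the full
pipeline with the installed package — compound-ontology construction and
classification, OQuaRE metrics for all four patterns, per-view
strain-identification ROC AUCs, clustering purity AUCs, and the
enrichment-rank τ between the two backbone choices — logging each quantity
and writing the machine-readable report to `--out`.

## Vignette

`vignettes/design-pattern-evaluation.Rmd` documents the model choices,
conventions (depth, tie-breaking, IC corpus), what the synthetic generator
does and does not emulate, and known limitations.
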