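test_that("generation is deterministic under the seed", {
  cfg <- sim_config(n_strains = 3L, mice_per_strain = 5L,
                    anatomy_size = 15L, pathology_size = 10L,
                    anatomy_depth = 3L, pathology_depth = 3L,
                    diagnoses_per_mouse = 3, vocab_size = 12L, seed = 42L)
  o1 <- generate_toy_ontologies(cfg)
  o2 <- generate_toy_ontologies(cfg)
  expect_identical(o1, o2)
  c1 <- simulate_cohort(cfg, o1$anatomy, o1$pathology)
  c2 <- simulate_cohort(cfg, o2$anatomy, o2$pathology)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_cohort_tsv(c1, p1); write_cohort_tsv(c2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("generated graphs satisfy the ontology invariants", {
  for (seed in 1:6) {
    w <- random_world(seed)
    for (g in list(w$anatomy, w$pathology)) {
      # single root, acyclic, all classes rooted: the constructor re-checks
      expect_silent(ontology_graph(g$classes, g$labels, g$is_a_edges,
                                   g$part_of_edges, g$root))
      expect_true(all(g$part_of_edges %in% g$classes))
    }
  }
  expect_error(sim_config(anatomy_size = 2L, anatomy_depth = 5L) |>
                 generate_toy_ontologies(), "infeasible shape")
})

test_that("zero part_of density collapses MAPT onto MAP", {
  w <- random_world(9, part_of_density = 0)
  expect_equal(nrow(w$anatomy$part_of_edges), 0L)
  pairs <- enumerate_pairs(w$cohort$records, w$anatomy, w$pathology)
  map <- build_pattern_ontology(w$anatomy, w$pathology, pairs, "MAP")
  mapt <- build_pattern_ontology(w$anatomy, w$pathology, pairs, "MAPT")
  strip <- function(co) {
    e <- co$graph$is_a_edges
    gsub("^(MAPT|MAP):", "X:", paste(e[, 1], e[, 2]))
  }
  expect_setequal(strip(map), strip(mapt))
})

test_that("an all-healthy cohort degenerates to root annotations and zero BMA", {
  cfg <- sim_config(n_strains = 2L, mice_per_strain = 4L,
                    anatomy_size = 12L, pathology_size = 8L,
                    anatomy_depth = 3L, pathology_depth = 2L,
                    healthy_fraction = 1, seed = 5L)
  onts <- generate_toy_ontologies(cfg)
  co <- simulate_cohort(cfg, onts$anatomy, onts$pathology)
  expect_equal(nrow(co$records), 0L)
  v <- project_annotations(co, "MA", anatomy = onts$anatomy)
  expect_true(all(vapply(v$annotations, identical, TRUE,
                         onts$anatomy$root)))
  sm <- similarity_matrix(v)
  expect_true(all(sm$values == 0))
})

test_that("the pair vocabulary is bounded by the configured size", {
  for (seed in 1:4) {
    w <- random_world(seed, vocab_size = 9L)
    pairs <- enumerate_pairs(w$cohort$records, w$anatomy, w$pathology)
    expect_lte(nrow(pairs), 9L)
  }
})

test_that("combination-only cohorts share anatomy and pathology marginals", {
  for (seed in 1:5) {
    cfg <- sim_config(n_strains = 4L, mice_per_strain = 25L,
                      anatomy_size = 30L, pathology_size = 25L,
                      anatomy_depth = 4L, pathology_depth = 3L,
                      diagnoses_per_mouse = 6, combination_only = TRUE,
                      seed = seed)
    onts <- generate_toy_ontologies(cfg)
    co <- simulate_cohort(cfg, onts$anatomy, onts$pathology)
    strain_of <- setNames(co$mice$strain, co$mice$mouse_id)
    rec <- co$records
    rec$strain <- strain_of[rec$mouse_id]
    # chi-square on the strain x anatomy-class contingency table: the
    # anatomy margin carries no strain signal by construction
    for (side in c("anatomy_id", "pathology_id")) {
      tab <- table(rec$strain, rec[[side]])
      p <- suppressWarnings(stats::chisq.test(tab)$p.value)
      expect_gt(p, 0.01)
    }
    # while the pairing itself is strain-specific
    tabp <- table(rec$strain, paste(rec$anatomy_id, rec$pathology_id))
    pp <- suppressWarnings(stats::chisq.test(tabp)$p.value)
    expect_lt(pp, 1e-6)
  }
})

test_that("a shared global propensity drives strain ROC AUC to chance", {
  aucs <- vapply(c(low = 0.3, high = 500), function(conc) {
    cfg <- sim_config(n_strains = 4L, mice_per_strain = 15L,
                      anatomy_size = 20L, pathology_size = 15L,
                      anatomy_depth = 3L, pathology_depth = 3L,
                      diagnoses_per_mouse = 5, vocab_size = 25L,
                      concentration = conc, seed = 17L)
    onts <- generate_toy_ontologies(cfg)
    co <- simulate_cohort(cfg, onts$anatomy, onts$pathology)
    res <- roc_auc_by_view(co, onts$anatomy, onts$pathology, views = "MAP",
                           by_group = FALSE)
    attr(res, "weighted")[["MAP"]]
  }, numeric(1L))
  expect_lt(abs(aucs[["high"]] - 0.5), 0.08)
  expect_gt(aucs[["low"]], aucs[["high"]])
})

test_that("strain-propensity concentration tracks mean ROC AUC", {
  # sharper strain propensities (smaller Dirichlet alpha) should raise the
  # strain-identification AUC; Spearman over level means must be positive
  alphas <- c(0.2, 0.5, 1, 5, 50)
  mean_auc <- vapply(alphas, function(a) {
    mean(vapply(1:3, function(r) {
      cfg <- sim_config(n_strains = 4L, mice_per_strain = 10L,
                        anatomy_size = 20L, pathology_size = 15L,
                        anatomy_depth = 3L, pathology_depth = 3L,
                        diagnoses_per_mouse = 5, vocab_size = 25L,
                        concentration = a, seed = 100L * r + 7L)
      onts <- generate_toy_ontologies(cfg)
      co <- simulate_cohort(cfg, onts$anatomy, onts$pathology)
      res <- roc_auc_by_view(co, onts$anatomy, onts$pathology,
                             views = "MAP", by_group = FALSE)
      attr(res, "weighted")[["MAP"]]
    }, numeric(1L)))
  }, numeric(1L))
  rho <- cor(1 / alphas, mean_auc, method = "spearman")
  expect_gt(rho, 0)
})
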