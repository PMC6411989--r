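path <- toy_pathology()
anat <- toy_anatomy()

test_that("propagation closes annotation sets up to the shared top", {
  co <- toy_cohort()
  v <- project_annotations(co, "MPATH", pathology = path)
  pv <- propagate(v)
  # {Ad, N} closes to {Ad, N, root, TOP}
  expect_setequal(pv$annotations[["m1"]],
                  c("P:Ad", "P:N", "P:R", "ROOT:thing"))
  # a healthy mouse carries {root, TOP}
  expect_setequal(pv$annotations[["m4"]], c("P:R", "ROOT:thing"))
  # idempotent
  pv2 <- propagate(pv)
  expect_identical(pv2$annotations, pv$annotations)
})

test_that("hypergeometric upper tail matches exact combinatorics", {
  # M=10, K=4, n=4, k=3: (C(4,3)C(6,1) + C(4,4)C(6,0)) / C(10,4) = 25/210
  expect_equal(hypergeometric_pvalue(K = 4, n = 4, k = 3, M = 10),
               25 / 210, tolerance = 1e-12)
  expect_equal(hypergeometric_pvalue(K = 4, n = 4, k = 0, M = 10), 1)
  expect_equal(hypergeometric_pvalue(K = 10, n = 4, k = 4, M = 10), 1)
  expect_error(hypergeometric_pvalue(K = 4, n = 4, k = 5, M = 10),
               "inconsistent")
})

strain_block_cohort <- function() {
  # 10 mice, strain S1 = 4 mice annotated with a class private to them
  cohort(
    mice = data.frame(mouse_id = sprintf("m%02d", 1:10),
                      strain = rep(c("S1", "S2"), c(4L, 6L)),
                      sex = "F", group = "12m"),
    records = data.frame(
      mouse_id = sprintf("m%02d", 1:10),
      anatomy_id = "A:H",
      pathology_id = rep(c("P:Ad", "P:I"), c(4L, 6L))))
}

test_that("strain enrichment reproduces the exact private-class tail", {
  co <- strain_block_cohort()
  v <- project_annotations(co, "MPATH", pathology = path)
  res <- enrich_strain(v, co, "S1", n_random = 100, seed = 5)
  tab <- res$table
  # P:Ad (and its closure through P:N) is annotated only in the 4 case mice
  expect_equal(tab$p[tab$class_id == "P:Ad"], 1 / choose(10, 4),
               tolerance = 1e-12)
  expect_equal(tab$p[tab$class_id == "P:N"], 1 / choose(10, 4),
               tolerance = 1e-12)
  # classes present in everyone are uninformative
  expect_equal(tab$p[tab$class_id == "ROOT:thing"], 1)
  # ranks are a permutation with the stated tie rule (p asc, then class ID)
  expect_setequal(tab$rank, seq_len(nrow(tab)))
  expect_equal(tab$class_id[order(tab$rank)][1:2], c("P:Ad", "P:N"))
  expect_error(enrich_strain(v, co, "S9"), "absent")
})

test_that("enrichment is invariant to mouse ordering and label-exchangeable nulls are flat", {
  co <- strain_block_cohort()
  v <- project_annotations(co, "MPATH", pathology = path)
  res1 <- enrich_strain(v, co, "S1", n_random = 50, seed = 9)
  perm <- co
  ord <- c(7, 2, 10, 1, 4, 3, 9, 5, 8, 6)
  perm$mice <- perm$mice[ord, ]
  perm$records <- perm$records[rev(seq_len(nrow(perm$records))), ]
  res2 <- enrich_strain(project_annotations(perm, "MPATH", pathology = path),
                        perm, "S1", n_random = 50, seed = 9)
  expect_equal(res1$table, res2$table)

  # exchangeable labels: every mouse annotated identically, FWER near 1
  co_null <- cohort(
    mice = data.frame(mouse_id = sprintf("m%02d", 1:10),
                      strain = rep(c("S1", "S2"), 5L),
                      sex = "F", group = "12m"),
    records = data.frame(mouse_id = sprintf("m%02d", 1:10),
                         anatomy_id = "A:H", pathology_id = "P:Ad"))
  vn <- project_annotations(co_null, "MPATH", pathology = path)
  resn <- enrich_strain(vn, co_null, "S1", n_random = 400, seed = 2)
  expect_true(all(resn$table$fwer == 1))
})

test_that("permutation FWER tracks the exhaustive-permutation value", {
  # 8 mice, 3 cases: only choose(8, 3) = 56 case sets exist
  co <- cohort(
    mice = data.frame(mouse_id = sprintf("m%d", 1:8),
                      strain = rep(c("S1", "S2"), c(3L, 5L)),
                      sex = "F", group = "12m"),
    records = data.frame(
      mouse_id = sprintf("m%d", c(1, 2, 3, 4, 5, 6)),
      anatomy_id = "A:H",
      pathology_id = c("P:Ad", "P:Ad", "P:I", "P:I", "P:N", "P:Ad")))
  v <- propagate(project_annotations(co, "MPATH", pathology = path))
  res <- enrich_strain(v, co, "S1", n_random = 2000, seed = 11)
  mice <- sort(co$mice$mouse_id)
  classes <- res$table$class_id
  A <- vapply(classes, function(cl)
    vapply(v$annotations[mice], function(s) cl %in% s, logical(1L)),
    logical(length(mice)))
  exact <- oracle_fwer_exhaustive(A, n_case = 3L, p_obs = res$table$p)
  # Monte-Carlo error: 3 binomial SDs at n = 2000
  tol <- 3 * sqrt(pmax(exact * (1 - exact), 0.25 / 2000) / 2000)
  expect_true(all(abs(res$table$fwer - exact) <= tol + 1e-9))
})

test_that("Kendall tau-b handles ties and matches enumerated examples", {
  r1 <- setNames(1:5, letters[1:5])
  expect_equal(kendall_tau_b(r1, r1), 1)
  expect_equal(kendall_tau_b(r1, setNames(5:1, letters[1:5])), -1)
  expect_equal(kendall_tau_b(setNames(c(1, 2, 3, 4), letters[1:4]),
                             setNames(c(1, 3, 2, 4), letters[1:4])),
               4 / 6)
  # tie-corrected value agrees with base R's tau-b on tied data
  set.seed(4)
  x <- setNames(sample(1:4, 15, TRUE), paste0("k", 1:15))
  y <- setNames(sample(1:4, 15, TRUE), paste0("k", 1:15))
  expect_equal(kendall_tau_b(x, y), cor(x, y, method = "kendall"))
  expect_error(kendall_tau_b(r1, setNames(1:5, letters[2:6])),
               "key mismatch")
})

test_that("MAP and PAM enrichment ranks are nearly identical", {
  w <- random_world(13, n_strains = 4L, mice_per_strain = 8L)
  pats <- build_all_patterns(w$cohort, w$anatomy, w$pathology,
                             c("MAP", "PAM"))
  views <- project_views(w$cohort, w$anatomy, w$pathology,
                         c("MAP", "PAM"), combined = pats)
  strains <- unique(w$cohort$mice$strain)
  res <- lapply(c("MAP", "PAM"), function(vn) {
    lapply(strains, function(s)
      enrich_strain(views[[vn]], w$cohort, s, n_random = 20, seed = 3))
  })
  tau <- compare_enrichment_ranks(res[[1]], res[[2]],
                                  combined_a = pats$MAP,
                                  combined_b = pats$PAM)
  expect_gt(tau, 0.9)
})
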