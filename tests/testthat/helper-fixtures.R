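# Shared fixtures and independent oracles.  Oracles deliberately use a
# different algorithmic route than the package (edge-expansion fixpoints,
# exhaustive scans) so that agreement is evidence, not tautology.

# anatomy toy: organ system with a parthood edge that is not a subclass edge
# (ventricle part_of heart, ventricle NOT is_a heart)
toy_anatomy <- function() {
  ontology_graph(
    classes = c("A:R", "A:org", "A:H", "A:Lu", "A:V"),
    labels = c("A:R" = "anatomical entity", "A:org" = "organ",
               "A:H" = "heart", "A:Lu" = "lung", "A:V" = "ventricle"),
    is_a = rbind(c("A:org", "A:R"), c("A:H", "A:org"),
                 c("A:Lu", "A:org"), c("A:V", "A:org")),
    part_of = rbind(c("A:V", "A:H")),
    root = "A:R")
}

# pathology toy: adenoma is_a neoplasm is_a root; inflammation is_a root
toy_pathology <- function() {
  ontology_graph(
    classes = c("P:R", "P:N", "P:Ad", "P:I"),
    labels = c("P:R" = "pathological process", "P:N" = "neoplasm",
               "P:Ad" = "adenoma", "P:I" = "inflammation"),
    is_a = rbind(c("P:N", "P:R"), c("P:Ad", "P:N"), c("P:I", "P:R")),
    root = "P:R")
}

# 5-class taxonomy with one diamond (V under both H and Lu)
toy_diamond <- function() {
  ontology_graph(
    classes = c("R", "O", "H", "Lu", "V"),
    is_a = rbind(c("O", "R"), c("H", "O"), c("Lu", "O"),
                 c("V", "H"), c("V", "Lu")),
    root = "R")
}

# a 4-mouse cohort over the anatomy/pathology toys
toy_cohort <- function() {
  cohort(
    mice = data.frame(
      mouse_id = c("m1", "m2", "m3", "m4"),
      strain = c("S1", "S1", "S2", "S2"),
      sex = c("F", "M", "F", "M"),
      group = c("12m", "12m", "20m", "20m"),
      stringsAsFactors = FALSE),
    records = data.frame(
      mouse_id = c("m1", "m1", "m2", "m3"),
      anatomy_id = c("A:H", "A:H", "A:H", "A:Lu"),
      pathology_id = c("P:Ad", "P:Ad", "P:N", "P:I"),
      stringsAsFactors = FALSE))
}

# random toy world for property tests; everything derives from one seed
random_world <- function(seed, n_strains = 3L, mice_per_strain = 6L,
                         anatomy_size = 14L, pathology_size = 10L,
                         vocab_size = 20L, ...) {
  cfg <- sim_config(n_strains = n_strains, mice_per_strain = mice_per_strain,
                    anatomy_size = anatomy_size,
                    pathology_size = pathology_size,
                    anatomy_depth = 3L, pathology_depth = 3L,
                    diagnoses_per_mouse = 4, vocab_size = vocab_size,
                    seed = seed, ...)
  onts <- generate_toy_ontologies(cfg)
  list(config = cfg, anatomy = onts$anatomy, pathology = onts$pathology,
       cohort = simulate_cohort(cfg, onts$anatomy, onts$pathology))
}

# --- oracles ---------------------------------------------------------------

# reachability by repeated edge expansion to fixpoint (no recursion, no BFS)
oracle_ancestors <- function(graph, class_id, relations = "is_a",
                             reflexive = FALSE) {
  edges <- NULL
  if ("is_a" %in% relations) edges <- rbind(edges, graph$is_a_edges)
  if ("part_of" %in% relations) edges <- rbind(edges, graph$part_of_edges)
  reach <- class_id
  repeat {
    new <- unique(edges[edges[, "child"] %in% reach, "parent"])
    new <- setdiff(new, reach)
    if (!length(new)) break
    reach <- c(reach, new)
  }
  if (reflexive) reach else setdiff(reach, class_id)
}

# exhaustive MICA: scan every common ancestor for the max IC
oracle_resnik <- function(ic, x1, x2) {
  common <- intersect(oracle_ancestors(ic$graph, x1, reflexive = TRUE),
                      oracle_ancestors(ic$graph, x2, reflexive = TRUE))
  common <- setdiff(common, ic$zero_count)
  if (!length(common)) 0 else max(ic$ic[common])
}

# trapezoid integration over arbitrary (x, y) points
oracle_trapz <- function(x, y) {
  o <- order(x)
  x <- x[o]; y <- y[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# pooled pair-ordering probability: over all probes, the fraction of
# (same-strain, different-strain) candidate pairs ranked in the right order
# (ties in rank position count half)
oracle_roc_auc <- function(V, strains, ids = rownames(V)) {
  M <- nrow(V)
  if (is.null(ids)) ids <- sprintf("m%03d", seq_len(M))
  rank_pos <- integer(); rank_neg <- integer()
  for (j in seq_len(M)) {
    cand <- setdiff(seq_len(M), j)
    ord <- cand[order(-V[j, cand], ids[cand])]
    rk <- seq_along(ord)                       # rank position within probe
    pos <- strains[ord] == strains[j]
    rank_pos <- c(rank_pos, rk[pos])
    rank_neg <- c(rank_neg, rk[!pos])
  }
  cmp <- outer(rank_pos, rank_neg, function(a, b) (a < b) + 0.5 * (a == b))
  mean(cmp)
}

# is `anc` reachable from `node` following is_a child->parent edges?
graph_reaches <- function(graph, node, anc) {
  anc %in% oracle_ancestors(graph, node, "is_a", reflexive = TRUE)
}

# exhaustive-permutation FWER oracle for enrich_strain on tiny cohorts
oracle_fwer_exhaustive <- function(A, n_case, p_obs) {
  M <- nrow(A)
  sets <- utils::combn(M, n_case)
  Kv <- colSums(A)
  min_p <- apply(sets, 2L, function(idx) {
    kv <- colSums(A[idx, , drop = FALSE])
    min(stats::phyper(kv - 1, m = Kv, n = M - Kv, k = n_case,
                      lower.tail = FALSE))
  })
  vapply(p_obs, function(p) mean(min_p <= p), numeric(1L))
}

# write a minimal OBO file from stanza text, returning the path
write_obo_fixture <- function(text) {
  path <- withr::local_tempfile(fileext = ".obo",
                                .local_envir = parent.frame())
  writeLines(text, path)
  path
}
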