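#' Close annotations under is_a ancestors
#'
#' Standard prerequisite of ontology over-representation analysis: every
#' mouse's annotation set is replaced by its reflexive `is_a` ancestor
#' closure, up to a top node standing in for `owl:Thing`.  If the view
#' graph's root is not already such a top node (the compound ontologies
#' carry one; the source ontologies do not), a fresh `ROOT:thing` class is
#' added above the root so that all six views share a common top.
#' Propagation is idempotent.
#'
#' @param view an [project_annotations()] result.
#' @param top class ID used for the owl:Thing stand-in.
#' @return A propagated `annotation_view` (attribute `propagated` set).
#' @export
propagate <- function(view, top = "ROOT:thing") {
  stopifnot(inherits(view, "annotation_view"))
  graph <- view$graph
  if (graph$root != top) {
    graph <- ontology_graph(
      c(top, graph$classes),
      c(setNames("owl:Thing", top), graph$labels),
      is_a = rbind(cbind(child = graph$root, parent = top), graph$is_a_edges),
      part_of = graph$part_of_edges,
      root = top, check = FALSE)
  }
  closed <- lapply(view$annotations, function(cls) {
    sort(unique(c(top, unlist(lapply(cls, function(cl)
      ancestors(graph, cl, relations = "is_a", reflexive = TRUE))))))
  })
  structure(list(view = view$view, graph = graph, annotations = closed),
            class = "annotation_view", propagated = TRUE)
}

#' Upper-tail hypergeometric p-value
#'
#' Probability of observing at least `k` annotated mice in a strain of size
#' `n`, when `K` of the `M` mice in the cohort are annotated:
#' `P(X >= k)` for `X ~ Hypergeometric(M, K, n)`.
#'
#' @param K number of annotated mice in the whole cohort.
#' @param n strain (case-group) size.
#' @param k annotated mice within the strain.
#' @param M cohort size.
#' @return p-value in `[0, 1]`.
#' @export
hypergeometric_pvalue <- function(K, n, k, M) {
  if (any(c(K, n, k, M) < 0) || k > min(K, n) || K > M || n > M) {
    stop("inconsistent counts: need 0 <= k <= min(K, n) <= M")
  }
  stats::phyper(k - 1, m = K, n = M - K, k = n, lower.tail = FALSE)
}

#' Per-strain over-representation analysis with permutation FWER
#'
#' For every class occurring in the propagated annotations, tests whether
#' mice of the given strain are annotated with it more often than expected
#' by a hypergeometric draw, strain versus rest.  Family-wise error is
#' estimated FUNC-style from random sets: the case/control labels are
#' permuted `n_random` times (group sizes preserved), the minimum p-value
#' over all classes is recorded for each permutation, and a class's FWER is
#' the fraction of permutations whose minimum p is at or below the class's
#' observed p.  Classes are ranked by raw p ascending, ties broken by class
#' ID, so ranks are a permutation of 1..n_classes.
#'
#' @param view an annotation view (propagated automatically if needed).
#' @param cohort the matching [cohort()].
#' @param strain case strain name.
#' @param n_random number of random sets (label permutations).
#' @param seed integer seed for the permutation generator.
#' @return Object of class `enrichment_result`: `table` (data frame with
#'   `class_id`, `K`, `k`, `p`, `fwer`, `rank`) plus `strain`, `view`,
#'   `n_random`, `seed`, `n_case`, `n_total`.
#' @export
enrich_strain <- function(view, cohort, strain, n_random = 1000L,
                          seed = 1L) {
  stopifnot(inherits(view, "annotation_view"), inherits(cohort, "cohort"))
  if (n_random < 1L) stop("n_random must be >= 1")
  if (!strain %in% cohort$mice$strain) stop("strain absent: ", strain)
  if (is.null(attr(view, "propagated"))) view <- propagate(view)

  mice <- sort(intersect(cohort$mice$mouse_id, names(view$annotations)))
  strain_of <- setNames(cohort$mice$strain, cohort$mice$mouse_id)[mice]
  case <- strain_of == strain
  if (!any(case) || all(case)) stop("empty case or control group")

  classes <- sort(unique(unlist(view$annotations[mice], use.names = FALSE)))
  A <- vapply(classes, function(cl) {
    vapply(view$annotations[mice], function(s) cl %in% s, logical(1L))
  }, logical(length(mice)))          # mice x classes incidence

  M <- length(mice); n <- sum(case)
  Kv <- colSums(A)
  kv <- colSums(A[case, , drop = FALSE])
  p_obs <- stats::phyper(kv - 1, m = Kv, n = M - Kv, k = n,
                         lower.tail = FALSE)

  prev_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(prev_seed)) assign(".Random.seed", prev_seed,
                                          envir = globalenv()))
  set.seed(as.integer(seed))
  min_p <- vapply(seq_len(n_random), function(r) {
    idx <- sample.int(M, n)
    kr <- colSums(A[idx, , drop = FALSE])
    min(stats::phyper(kr - 1, m = Kv, n = M - Kv, k = n, lower.tail = FALSE))
  }, numeric(1L))
  fwer <- vapply(p_obs, function(p) mean(min_p <= p), numeric(1L))

  ord <- order(p_obs, classes)
  rank <- integer(length(classes)); rank[ord] <- seq_along(classes)
  structure(list(
    table = data.frame(class_id = classes, K = Kv, k = kv, p = p_obs,
                       fwer = fwer, rank = rank, row.names = NULL,
                       stringsAsFactors = FALSE),
    strain = strain, view = view$view, n_random = n_random, seed = seed,
    n_case = n, n_total = M), class = "enrichment_result")
}

#' Kendall's tau-b between two rankings of the same objects
#'
#' Rank correlation with tie correction: `(C - D) / sqrt((n0 - n1)(n0 - n2))`
#' where C and D count concordant and discordant pairs, n0 = n(n-1)/2, and
#' n1, n2 are the tie terms of the two rankings.
#'
#' @param ranks1,ranks2 numeric vectors named by a shared key set (any
#'   scores; only their order matters).
#' @return tau-b in `[-1, 1]`.
#' @export
kendall_tau_b <- function(ranks1, ranks2) {
  if (is.null(names(ranks1)) || is.null(names(ranks2))) {
    stop("rank vectors must be named by their keys")
  }
  if (!setequal(names(ranks1), names(ranks2)) ||
      length(ranks1) != length(ranks2)) {
    stop("key mismatch between rankings")
  }
  x <- as.numeric(ranks1)
  y <- as.numeric(ranks2[names(ranks1)])
  n <- length(x)
  if (n < 2L) stop("need at least two keys")
  dx <- sign(outer(x, x, "-")); dy <- sign(outer(y, y, "-"))
  up <- upper.tri(dx)
  prod <- dx[up] * dy[up]
  C <- sum(prod > 0); D <- sum(prod < 0)
  n0 <- n * (n - 1) / 2
  tie_term <- function(v) {
    t <- table(v); sum(t * (t - 1) / 2)
  }
  denom <- sqrt((n0 - tie_term(x)) * (n0 - tie_term(y)))
  if (denom == 0) stop("all values tied in one ranking; tau-b undefined")
  (C - D) / denom
}

#' Compare enrichment ranks across two views
#'
#' Pools per-strain enrichment ranks over (strain, anatomy, pathology) keys
#' and computes Kendall's tau-b.  Pattern-view classes are unprojected to
#' their source pairs so that rankings from different compound ontologies
#' are paired on a common key; only keys present in both views are compared.
#'
#' @param results_a,results_b lists of [enrich_strain()] results (one per
#'   strain) from two views.
#' @param combined_a,combined_b the matching combined ontologies, or `NULL`
#'   for the source views (keys then use the class ID on the missing side).
#' @return tau-b over the pooled shared keys.
#' @export
compare_enrichment_ranks <- function(results_a, results_b,
                                     combined_a = NULL, combined_b = NULL) {
  key_ranks <- function(results, combined) {
    out <- numeric(); keys <- character()
    for (res in results) {
      tab <- res$table
      if (!is.null(combined)) {
        pc <- combined$pattern_classes
        idx <- match(tab$class_id, pc$class_id)
        keep <- !is.na(idx)
        kk <- paste(res$strain, pc$anatomy_id[idx[keep]],
                    pc$pathology_id[idx[keep]], sep = "|")
        rr <- tab$rank[keep]
      } else {
        kk <- paste(res$strain, tab$class_id, sep = "|")
        rr <- tab$rank
      }
      keys <- c(keys, kk); out <- c(out, rr)
    }
    setNames(out, keys)
  }
  ra <- key_ranks(results_a, combined_a)
  rb <- key_ranks(results_b, combined_b)
  shared <- intersect(names(ra), names(rb))
  if (length(shared) < 2L) stop("fewer than two shared keys between views")
  kendall_tau_b(ra[shared], rb[shared])
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment [%s] strain %s: %d classes, %d/%d case mice, %d random sets\n",
              x$view, x$strain, nrow(x$table), x$n_case, x$n_total, x$n_random))
  print(utils::head(x$table[order(x$table$rank), ], 5L))
  invisible(x)
}
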