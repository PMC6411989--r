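#' Convert a similarity matrix to a distance matrix
#'
#' `d_ij = s_max - s_ij` with `s_max` the global maximum of the similarity
#' matrix; the diagonal is forced to zero.
#'
#' @param sim a [similarity_matrix()] or a plain symmetric numeric matrix.
#' @param tol symmetry tolerance.
#' @return Symmetric numeric matrix of non-negative distances, zero diagonal.
#' @export
to_distance <- function(sim, tol = 1e-8) {
  V <- if (inherits(sim, "similarity_matrix")) sim$values else sim
  stopifnot(is.matrix(V), nrow(V) == ncol(V))
  if (max(abs(V - t(V))) > tol) stop("similarity matrix is not symmetric")
  d <- max(V) - V
  diag(d) <- 0
  d
}

#' Cluster a distance matrix
#'
#' Four methods, all operating directly on the precomputed distance matrix:
#'
#' * `"complete"` — complete-linkage agglomerative clustering;
#' * `"upgma"` — average-linkage (UPGMA) agglomerative clustering;
#' * `"nj"` — neighbor joining with the canonical Q-criterion; clusters at
#'   `k` are the connected components after undoing the last `k - 1` joins;
#' * `"kmedoids"` — PAM with the deterministic BUILD initialisation and SWAP
#'   phase (via the `cluster` package), run per requested `k`.
#'
#' @param d distance matrix (square symmetric, as from [to_distance()]).
#' @param method one of `"complete"`, `"upgma"`, `"nj"`, `"kmedoids"`.
#' @return Object of class `clustering_result` with `method`, `M`, and
#'   `labels(k)`: a function returning an integer label vector with exactly
#'   `k` distinct labels, named by the matrix row names.
#' @export
cluster_distance <- function(d, method = c("complete", "upgma", "nj",
                                           "kmedoids")) {
  method <- match.arg(method)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  M <- nrow(d)
  ids <- rownames(d)
  if (is.null(ids)) ids <- as.character(seq_len(M))

  labels_fn <- switch(method,
    complete = ,
    upgma = {
      hc <- stats::hclust(stats::as.dist(d),
                          method = if (method == "upgma") "average"
                                   else "complete")
      function(k) {
        check_k(k, M)
        setNames(unname(stats::cutree(hc, k = k)), ids)
      }
    },
    nj = {
      merges <- nj_join_order(d)
      function(k) {
        check_k(k, M)
        labels_from_merges(merges, M, k, ids)
      }
    },
    kmedoids = {
      cache <- new.env(parent = emptyenv())
      function(k) {
        check_k(k, M)
        key <- as.character(k)
        if (is.null(cache[[key]])) {
          cache[[key]] <- if (k == M) seq_len(M) else if (k == 1L)
            rep(1L, M) else
            cluster::pam(stats::as.dist(d), k = k, cluster.only = TRUE)
        }
        setNames(as.integer(cache[[key]]), ids)
      }
    })
  structure(list(method = method, M = M, ids = ids, labels = labels_fn),
            class = "clustering_result")
}

check_k <- function(k, M) {
  if (k < 1L || k > M) stop("k out of range [1, ", M, "]")
}

# Canonical neighbor joining, recording the join sequence as a merge list.
# Returns a list of length M - 1; element t joins two clusters (each a
# vector of leaf indices).  After n - 3 Q-criterion joins three nodes
# remain; they are folded in by ascending branch-sum order so that the
# sequence defines a full binary merge history.
nj_join_order <- function(d) {
  M <- nrow(d)
  if (M < 2L) return(list())
  D <- d
  members <- as.list(seq_len(M))
  merges <- list()
  active <- seq_len(M)
  while (length(active) > 3L) {
    n <- length(active)
    Dv <- D[active, active]
    r <- rowSums(Dv)
    Q <- (n - 2) * Dv - outer(r, r, "+")
    diag(Q) <- Inf
    ij <- which(Q == min(Q), arr.ind = TRUE)[1L, ]   # deterministic tie-break
    i <- active[ij[1L]]; j <- active[ij[2L]]
    # distances from the new node u to the remaining nodes
    rest <- setdiff(active, c(i, j))
    du <- 0.5 * (D[i, rest] + D[j, rest] - D[i, j])
    u <- nrow(D) + 1L
    D <- rbind(cbind(D, 0), 0)
    D[u, rest] <- du; D[rest, u] <- du
    members[[u]] <- c(members[[i]], members[[j]])
    merges[[length(merges) + 1L]] <- list(members[[i]], members[[j]])
    active <- c(rest, u)
  }
  # fold the last <= 3 nodes: join the closest pair, then the remainder
  while (length(active) > 1L) {
    Dv <- D[active, active, drop = FALSE]
    diag(Dv) <- Inf
    ij <- which(Dv == min(Dv), arr.ind = TRUE)[1L, ]
    i <- active[ij[1L]]; j <- active[ij[2L]]
    rest <- setdiff(active, c(i, j))
    u <- nrow(D) + 1L
    D <- rbind(cbind(D, 0), 0)
    if (length(rest)) {
      du <- 0.5 * (D[i, rest] + D[j, rest] - D[i, j])
      D[u, rest] <- du; D[rest, u] <- du
    }
    members[[u]] <- c(members[[i]], members[[j]])
    merges[[length(merges) + 1L]] <- list(members[[i]], members[[j]])
    active <- c(rest, u)
  }
  merges
}

# replay the first M - k merges to obtain k clusters
labels_from_merges <- function(merges, M, k, ids) {
  lab <- seq_len(M)
  n_replay <- M - k
  for (t in seq_len(n_replay)) {
    a <- merges[[t]][[1L]]; b <- merges[[t]][[2L]]
    lab[lab %in% lab[b]] <- lab[a[1L]]
  }
  setNames(as.integer(factor(lab)), ids)
}

#' Cluster purity
#'
#' Assign each cluster to its most frequent strain (modal ties broken by
#' lexicographically smallest strain name); purity is the fraction of mice
#' whose strain matches their cluster's modal strain.
#'
#' @param labels cluster label vector.
#' @param strains strain vector, same length and order.
#' @return Purity in `[0, 1]`.
#' @export
purity <- function(labels, strains) {
  if (length(labels) != length(strains)) stop("length mismatch")
  modal <- vapply(split(as.character(strains), labels), function(s) {
    tab <- table(s)
    names(tab)[which.max(tab)]          # ties: first name = lexicographic
  }, character(1L))
  mean(modal[as.character(labels)] == as.character(strains))
}

#' Area under the purity curve
#'
#' Trapezoidal area of the purity-versus-cluster-count curve over
#' `k = 2..M`, normalised by the number of mice:
#' `AUC = (1 / (2(M - 1))) * sum_{n=2}^{M-1} (Purity_n + Purity_{n+1})`.
#'
#' @param purity_at_k numeric vector of purities named by `k`, covering all
#'   integers `2..M` (the names may be omitted if the vector starts at
#'   `k = 2` and is contiguous).
#' @return AUC in `[0, 1]`.
#' @export
purity_auc <- function(purity_at_k) {
  ks <- if (is.null(names(purity_at_k))) {
    seq(2L, length.out = length(purity_at_k))
  } else as.integer(names(purity_at_k))
  M <- max(ks)
  if (!identical(sort(ks), seq(2L, M))) {
    stop("purity must be given for every k in 2..M (missing k)")
  }
  p <- purity_at_k[order(ks)]
  sum(p[-length(p)] + p[-1L]) / (2 * (M - 1))
}

#' Purity curve and its AUC for one clustering of one group
#'
#' @param clustering a [cluster_distance()] result.
#' @param strains strain vector in the clustering's mouse order.
#' @param ks cluster counts to evaluate (default all of `2..M`).
#' @return Object of class `purity_curve`: `purity_at_k` (named vector),
#'   `auc`, `M`.
#' @export
purity_curve <- function(clustering, strains, ks = NULL) {
  stopifnot(inherits(clustering, "clustering_result"))
  M <- clustering$M
  if (is.null(ks)) ks <- seq(2L, M)
  pk <- vapply(ks, function(k) purity(clustering$labels(k), strains),
               numeric(1L))
  names(pk) <- ks
  auc <- if (identical(as.integer(ks), seq(2L, M))) purity_auc(pk) else NA_real_
  structure(list(purity_at_k = pk, auc = auc, M = M),
            class = "purity_curve")
}

#' Per-individual ROC curve from a similarity matrix
#'
#' Treats similarity as a same-strain classifier: for each mouse (probe),
#' all other mice are ranked by descending similarity (ties broken by
#' ascending mouse ID, or shared fractionally with `ties = "average"`), and
#' `P_j(t)` counts the probe's strain-mates among its top `t` candidates.
#' Pooled over probes, `TPR(t) = sum_j P_j(t) / sum_j P_j(Mc)` and
#' `FPR(t) = sum_j (t - P_j(t)) / sum_j (Mc - P_j(Mc))` with
#' `Mc = M - 1` candidates per probe; the AUC is the trapezoidal area under
#' (FPR, TPR).
#'
#' @param sim a [similarity_matrix()] or plain symmetric matrix with mouse
#'   IDs as dimnames.
#' @param strains strain vector in matrix order.
#' @param ties `"id"` (deterministic, default) or `"average"` (tied
#'   candidates share credit fractionally).
#' @return Object of class `roc_curve`: `t`, `tpr`, `fpr` (each of length
#'   `M`, i.e. thresholds `0..Mc` including the origin) and `auc`.
#' @export
roc_curve <- function(sim, strains, ties = c("id", "average")) {
  ties <- match.arg(ties)
  V <- if (inherits(sim, "similarity_matrix")) sim$values else sim
  M <- nrow(V)
  ids <- rownames(V)
  if (is.null(ids)) ids <- sprintf("m%03d", seq_len(M))
  strains <- as.character(strains)
  if (length(strains) != M) stop("length mismatch")
  if (length(unique(strains)) < 2L) {
    stop("single-strain group: false-positive rate undefined")
  }
  Mc <- M - 1L
  P <- matrix(0, M, Mc)     # P[j, t] = same-strain count in top t of probe j
  for (j in seq_len(M)) {
    cand <- setdiff(seq_len(M), j)
    s <- V[j, cand]
    pos <- strains[cand] == strains[j]
    if (ties == "id") {
      ord <- cand[order(-s, ids[cand])]
      P[j, ] <- cumsum(strains[ord] == strains[j])
    } else {
      r <- rank(-s, ties.method = "average")
      # fractional inclusion of candidate with average rank r at cutoff t
      incl <- function(t) pmin(1, pmax(0, t - r + 1))
      P[j, ] <- vapply(seq_len(Mc), function(t) sum(incl(t) * pos),
                       numeric(1L))
    }
  }
  tp_total <- sum(P[, Mc])
  fp_total <- sum(Mc - P[, Mc])
  if (tp_total == 0) {
    stop("no mouse has a same-strain candidate: true-positive rate undefined")
  }
  tpr <- c(0, colSums(P) / tp_total)
  fpr <- c(0, (seq_len(Mc) * M - colSums(P)) / fp_total)
  auc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
  structure(list(t = 0:Mc, tpr = tpr, fpr = fpr, auc = auc),
            class = "roc_curve")
}

#' Wilcoxon rank-sum comparison of two score samples
#'
#' Two-sided Mann-Whitney U test with normal approximation and tie
#' correction, used to compare per-mouse scores (e.g. one-vs-rest ROC AUCs)
#' between two ontology views.  Bonferroni correction over view pairs is the
#' caller's responsibility.
#'
#' @param scores_a,scores_b numeric vectors.
#' @return List with `statistic` (U for the first sample) and `p.value`.
#' @export
wilcoxon_compare <- function(scores_a, scores_b) {
  if (!length(scores_a) || !length(scores_b)) stop("empty input")
  wt <- stats::wilcox.test(scores_a, scores_b, exact = FALSE,
                           correct = FALSE)
  list(statistic = unname(wt$statistic), p.value = wt$p.value)
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: %d thresholds, AUC %.4f\n", length(x$t) - 1L, x$auc))
  invisible(x)
}

#' @export
print.purity_curve <- function(x, ...) {
  cat(sprintf("purity_curve: M = %d, AUC %s\n", x$M,
              ifelse(is.na(x$auc), "NA", sprintf("%.4f", x$auc))))
  invisible(x)
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("clustering_result [%s]: %d observations\n", x$method, x$M))
  invisible(x)
}
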