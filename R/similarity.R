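#' Information content of ontology classes from a view's annotation corpus
#'
#' Direct counts tally one occurrence per (mouse, class) pair after
#' deduplication — repeated necropsy line items do not over-weight a class.
#' The cumulative count of a class is the sum of direct counts over its
#' `is_a` descendants-or-self, its probability is cumulative count over the
#' corpus size N (total number of direct annotations), and its information
#' content is `-log p` (natural log by default).  The root therefore always
#' has probability 1 and IC 0, and IC can only grow when moving from a class
#' to its descendants.  Classes never observed (cumulative count zero) get a
#' smoothed `p = 1/N`, are flagged, and are excluded from MICA search unless
#' requested.
#'
#' @param view an [project_annotations()] result.
#' @param log_base base of the logarithm; `exp(1)` (nats) by default.
#' @return Object of class `ic_table`: list with `graph`, `count` (direct),
#'   `cumulative`, `total` (N), `ic` (named numeric over all classes),
#'   `zero_count` (flagged class IDs), `view`.
#' @export
compute_ic <- function(view, log_base = exp(1)) {
  stopifnot(inherits(view, "annotation_view"))
  ann <- view$annotations
  if (!length(ann) || !length(unlist(ann))) stop("empty corpus")
  graph <- view$graph
  direct <- table(unlist(ann, use.names = FALSE))
  unknown <- setdiff(names(direct), graph$classes)
  if (length(unknown)) stop("unknown class: ", unknown[[1L]])
  n_total <- sum(direct)

  cum <- setNames(numeric(length(graph$classes)), graph$classes)
  for (cl in names(direct)) {
    up <- ancestors(graph, cl, relations = "is_a", reflexive = TRUE)
    cum[up] <- cum[up] + direct[[cl]]
  }
  zero <- names(cum)[cum == 0]
  p <- pmax(cum, 1) / n_total
  ic <- -log(p) / log(log_base)
  structure(list(graph = graph,
                 count = setNames(as.numeric(direct), names(direct)),
                 cumulative = cum, total = n_total, ic = ic,
                 zero_count = zero, view = view$view),
            class = "ic_table")
}

#' Resnik similarity of two classes
#'
#' The information content of the most informative common ancestor (MICA):
#' the common `is_a` ancestor-or-self with maximal IC.  Unobserved
#' (zero-count) classes are skipped in the MICA search by default, since
#' their IC is a smoothing artefact.  The MICA's identity is attached as
#' attribute `"mica"`.
#'
#' @param ic an [compute_ic()] result.
#' @param x1,x2 class IDs.
#' @param include_zero also consider zero-count classes as MICA candidates.
#' @return Non-negative similarity, with attribute `mica`.
#' @export
resnik <- function(ic, x1, x2, include_zero = FALSE) {
  stopifnot(inherits(ic, "ic_table"))
  common <- intersect(
    ancestors(ic$graph, x1, relations = "is_a", reflexive = TRUE),
    ancestors(ic$graph, x2, relations = "is_a", reflexive = TRUE))
  if (!include_zero) common <- setdiff(common, ic$zero_count)
  if (!length(common)) {
    return(structure(0, mica = NA_character_))
  }
  vals <- ic$ic[common]
  best <- which.max(vals)
  structure(unname(vals[best]), mica = names(vals)[best])
}

#' Best-match-average similarity of two annotation sets
#'
#' For each class in either set, take the Resnik similarity of its best
#' match in the other set; sum the best matches in both directions and
#' divide by the total number of classes (m1 + m2).
#'
#' @inheritParams resnik
#' @param set1,set2 non-empty character vectors of class IDs (healthy mice
#'   carry the root class, never an empty set).
#' @return Non-negative similarity value.
#' @export
bma <- function(ic, set1, set2) {
  if (!length(set1) || !length(set2)) stop("empty annotation set")
  S <- pairwise_resnik(ic, union(set1, set2))
  bma_from_matrix(S, set1, set2)
}

bma_from_matrix <- function(S, set1, set2) {
  sub <- S[set1, set2, drop = FALSE]
  rmax <- sub[cbind(seq_len(nrow(sub)), max.col(sub, ties.method = "first"))]
  cmax <- sub[cbind(max.col(t(sub), ties.method = "first"),
                    seq_len(ncol(sub)))]
  (sum(rmax) + sum(cmax)) / (length(set1) + length(set2))
}

# Resnik similarity matrix over a vocabulary of classes, via each class's
# reflexive is_a ancestor profile (zero-count classes masked out).
pairwise_resnik <- function(ic, classes, include_zero = FALSE) {
  graph <- ic$graph
  keep <- if (include_zero) graph$classes else
    setdiff(graph$classes, ic$zero_count)
  prof <- vapply(classes, function(cl) {
    graph$classes %in%
      intersect(ancestors(graph, cl, "is_a", reflexive = TRUE), keep)
  }, logical(length(graph$classes)))
  icv <- ic$ic[graph$classes]
  K <- length(classes)
  S <- matrix(0, K, K, dimnames = list(classes, classes))
  for (i in seq_len(K)) {
    pi <- prof[, i]
    for (j in i:K) {
      common <- pi & prof[, j]
      S[i, j] <- S[j, i] <- if (any(common)) max(icv[common]) else 0
    }
  }
  S
}

#' Pairwise mouse-to-mouse similarity matrix
#'
#' Best-match-average Resnik similarity for every pair of mice in a group,
#' in the given (sorted, explicit) mouse order.  The diagonal holds each
#' mouse's self-BMA.
#'
#' @param view an [project_annotations()] result.
#' @param mice mouse IDs defining the matrix order.
#' @param ic the view's [compute_ic()] table; computed from `view` when
#'   omitted.
#' @return Object of class `similarity_matrix`: list with `mice`, `values`
#'   (symmetric numeric matrix) and `view`.
#' @export
similarity_matrix <- function(view, mice = names(view$annotations),
                              ic = NULL) {
  stopifnot(inherits(view, "annotation_view"))
  missing_mice <- setdiff(mice, names(view$annotations))
  if (length(missing_mice)) {
    stop("mouse missing from view: ", missing_mice[[1L]])
  }
  if (is.null(ic)) ic <- compute_ic(view)
  ann <- view$annotations[mice]
  vocab <- sort(unique(unlist(ann, use.names = FALSE)))
  S <- pairwise_resnik(ic, vocab)
  M <- length(mice)
  V <- matrix(0, M, M, dimnames = list(mice, mice))
  for (i in seq_len(M)) {
    for (j in i:M) {
      V[i, j] <- V[j, i] <- bma_from_matrix(S, ann[[i]], ann[[j]])
    }
  }
  structure(list(mice = mice, values = V, view = view$view),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("similarity_matrix [%s]: %d x %d, range [%.4f, %.4f]\n",
              x$view, length(x$mice), length(x$mice),
              min(x$values), max(x$values)))
  invisible(x)
}
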