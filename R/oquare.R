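#' Depth of a class in the is_a taxonomy
#'
#' Number of `is_a` edges on a path from the class up to the root, with the
#' root at depth 0.  The default convention is the longest such path;
#' `mode = "shortest"` is available because published depth tables rarely
#' state which convention they used.
#'
#' @inheritParams ancestors
#' @param mode `"longest"` (default) or `"shortest"` path to the root.
#' @return Non-negative integer depth.
#' @export
class_depth <- function(graph, class_id, mode = c("longest", "shortest")) {
  mode <- match.arg(mode)
  if (!class_id %in% graph$classes) stop("unknown class: ", class_id)
  all_class_depths(graph, mode)[[class_id]]
}

# depths for every class at once (single pass, memoised recursion)
all_class_depths <- function(graph, mode = "longest") {
  agg <- if (mode == "longest") max else min
  depth <- new.env(parent = emptyenv())
  get_depth <- function(cl) {
    if (!is.null(depth[[cl]])) return(depth[[cl]])
    ps <- graph$parents_isa[[cl]]
    d <- if (!length(ps)) 0L else 1L + agg(vapply(ps, get_depth, 0L))
    depth[[cl]] <- d
    d
  }
  setNames(vapply(graph$classes, get_depth, 0L), graph$classes)
}

#' OQuaRE structural metrics
#'
#' Computes the three structural quality metrics used to compare compound
#' ontologies with their sources:
#'
#' * `tangledness` (TMOnto) — fraction of classes with more than one direct
#'   `is_a` parent;
#' * `weighted_method_count` (WMCOnto) — mean depth of leaf classes;
#' * `depth_of_hierarchy` (DITOnto) — maximum leaf depth.
#'
#' Only `is_a` edges count for parents and depth: these are taxonomy
#' metrics.  `restrict_to` intersects the class and leaf sets (and the
#' denominator N) with a subset, which is how the analysis is limited to
#' newly created compound classes; depths are still measured in the full
#' graph.
#'
#' @inheritParams ancestors
#' @param restrict_to optional character vector of class IDs.
#' @param depth_mode passed to [class_depth()].
#' @return List of class `oquare_metrics` with fields `tangledness`,
#'   `weighted_method_count`, `depth_of_hierarchy`, `n_classes`, `n_leaves`.
#' @export
compute_oquare <- function(graph, restrict_to = NULL,
                           depth_mode = c("longest", "shortest")) {
  depth_mode <- match.arg(depth_mode)
  if (inherits(graph, "combined_ontology")) graph <- graph$graph
  stopifnot(inherits(graph, "ontology_graph"))
  cls <- graph$classes
  lvs <- leaves(graph)
  if (!is.null(restrict_to)) {
    unknown <- setdiff(restrict_to, cls)
    if (length(unknown)) stop("unknown class: ", unknown[[1L]])
    cls <- intersect(cls, restrict_to)
    lvs <- intersect(lvs, restrict_to)
  }
  if (!length(cls)) stop("empty graph (no classes after restriction)")
  depths <- all_class_depths(graph, depth_mode)
  multi_parent <- vapply(graph$parents_isa[cls], function(p) length(p) > 1L,
                         logical(1L))
  structure(
    list(tangledness = mean(multi_parent),
         weighted_method_count = if (length(lvs)) mean(depths[lvs]) else NA_real_,
         depth_of_hierarchy = if (length(lvs)) max(depths[lvs]) else 0L,
         n_classes = length(cls),
         n_leaves = length(lvs)),
    class = "oquare_metrics")
}

#' @export
print.oquare_metrics <- function(x, ...) {
  cat(sprintf("TMOnto %.4f  WMCOnto %.4f  DITOnto %d  (N = %d, leaves = %d)\n",
              x$tangledness, x$weighted_method_count,
              as.integer(x$depth_of_hierarchy), x$n_classes, x$n_leaves))
  invisible(x)
}
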