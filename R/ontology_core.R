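#' Construct an ontology graph
#'
#' An `ontology_graph` is a rooted directed acyclic graph of named classes
#' with two typed edge sets: `is_a` (the subsumption taxonomy) and `part_of`
#' (anatomical parthood).  Edges point from child to parent.  The `is_a`
#' relation must be acyclic and every class must reach the single root by
#' `is_a` edges; `part_of` edges may in principle form cycles, which are
#' tolerated but flagged with a warning because only the taxonomy metrics
#' require acyclicity.
#'
#' @param classes character vector of class IDs (CURIE-style strings, e.g.
#'   `"MA:0000001"`); IDs are case-sensitive exact strings and are never
#'   expanded or normalised.
#' @param labels named character vector mapping class IDs to human-readable
#'   names; missing labels default to the ID itself.
#' @param is_a two-column matrix or data frame of `is_a` edges
#'   (child, parent), or `NULL` for none.
#' @param part_of two-column matrix or data frame of `part_of` edges
#'   (part, whole), or `NULL` for none.
#' @param root class ID of the root; if `NULL` it is inferred as the unique
#'   class without `is_a` parents.
#' @param check validate invariants (acyclicity, rootedness, edge targets).
#'
#' @return An object of class `ontology_graph`: a list with elements
#'   `classes`, `labels`, `parents_isa`, `parents_partof` (named lists of
#'   parent IDs per child), `root`, and the raw edge matrices `is_a_edges`,
#'   `part_of_edges`.
#' @export
ontology_graph <- function(classes, labels = NULL, is_a = NULL,
                           part_of = NULL, root = NULL, check = TRUE) {
  classes <- as.character(classes)
  if (anyDuplicated(classes)) {
    stop("duplicate class IDs: ", paste(unique(classes[duplicated(classes)]),
                                        collapse = ", "))
  }
  if (length(classes) == 0L) stop("empty graph: no classes")
  lab <- setNames(classes, classes)
  if (!is.null(labels) && length(labels)) {
    labels <- labels[names(labels) %in% classes]
    lab[names(labels)] <- unname(labels)
  }
  is_a <- normalize_edges(is_a)
  part_of <- normalize_edges(part_of)

  if (check) {
    check_edge_targets(is_a, classes, "is_a")
    check_edge_targets(part_of, classes, "part_of")
  }

  parents_isa <- edges_to_parent_list(is_a, classes)
  parents_partof <- edges_to_parent_list(part_of, classes)

  if (is.null(root)) {
    tops <- classes[vapply(parents_isa[classes], length, 1L) == 0L]
    if (length(tops) != 1L) {
      stop("cannot infer root: ", length(tops),
           " classes without is_a parents (pass `root` or use load_ontology)")
    }
    root <- tops
  }

  g <- structure(
    list(classes = classes, labels = lab,
         parents_isa = parents_isa, parents_partof = parents_partof,
         root = root, is_a_edges = is_a, part_of_edges = part_of),
    class = "ontology_graph")

  if (check) {
    if (!root %in% classes) stop("unknown class: root ", root)
    cyc <- find_isa_cycle(g)
    if (!is.null(cyc)) {
      stop("cyclic hierarchy: is_a cycle involving class ", cyc)
    }
    # every non-root class must reach the root via is_a
    reach <- descendants_or_self(g, root)
    stray <- setdiff(classes, reach)
    if (length(stray)) {
      stop("class ", stray[[1L]], " has no is_a path to root ", root)
    }
    if (nrow(part_of) && has_partof_cycle(g)) {
      warning("part_of relation contains a cycle; taxonomy metrics are unaffected")
    }
  }
  g
}

normalize_edges <- function(e) {
  if (is.null(e) || (is.data.frame(e) && nrow(e) == 0L)) {
    return(matrix(character(), ncol = 2L,
                  dimnames = list(NULL, c("child", "parent"))))
  }
  if (is.data.frame(e)) e <- as.matrix(e)
  if (is.vector(e) && length(e) == 2L) e <- matrix(e, ncol = 2L)
  storage.mode(e) <- "character"
  if (ncol(e) != 2L) stop("edges must have two columns (child, parent)")
  colnames(e) <- c("child", "parent")
  unique(e)
}

check_edge_targets <- function(edges, classes, what) {
  if (!nrow(edges)) return(invisible())
  bad <- setdiff(c(edges), classes)
  if (length(bad)) {
    stop("unknown class in ", what, " edge: ", paste(bad, collapse = ", "))
  }
  invisible()
}

edges_to_parent_list <- function(edges, classes) {
  pl <- setNames(vector("list", length(classes)), classes)
  pl[] <- list(character())
  if (nrow(edges)) {
    sp <- split(edges[, "parent"], edges[, "child"])
    pl[names(sp)] <- lapply(sp, unique)
  }
  pl
}

# Kahn-style peeling on is_a; returns NULL if acyclic, else one cycle member.
find_isa_cycle <- function(g) {
  remaining <- g$classes
  repeat {
    if (!length(remaining)) return(NULL)
    blocked <- vapply(remaining, function(cl) {
      any(g$parents_isa[[cl]] %in% remaining)
    }, logical(1L))
    if (all(blocked)) return(remaining[[1L]])
    remaining <- remaining[blocked]
  }
}

has_partof_cycle <- function(g) {
  remaining <- g$classes
  repeat {
    if (!length(remaining)) return(FALSE)
    blocked <- vapply(remaining, function(cl) {
      any(g$parents_partof[[cl]] %in% remaining)
    }, logical(1L))
    if (!any(blocked)) return(FALSE)
    if (all(blocked)) return(TRUE)
    remaining <- remaining[blocked]
  }
}

#' Ancestors of a class
#'
#' Classes reachable from `class_id` by following edges of the chosen
#' relation types in the child-to-parent direction.
#'
#' @param graph an [ontology_graph()].
#' @param class_id class ID present in the graph.
#' @param relations character subset of `c("is_a", "part_of")`.
#' @param reflexive include `class_id` itself.
#' @return Character vector of ancestor class IDs (unordered).
#' @export
ancestors <- function(graph, class_id, relations = "is_a", reflexive = FALSE) {
  stopifnot(inherits(graph, "ontology_graph"))
  if (!class_id %in% graph$classes) stop("unknown class: ", class_id)
  relations <- match.arg(relations, c("is_a", "part_of"), several.ok = TRUE)
  traverse_up(graph, class_id, relations, reflexive)
}

traverse_up <- function(graph, class_id, relations, reflexive) {
  seen <- character()
  frontier <- class_id
  use_isa <- "is_a" %in% relations
  use_po <- "part_of" %in% relations
  while (length(frontier)) {
    nxt <- character()
    for (cl in frontier) {
      if (use_isa) nxt <- c(nxt, graph$parents_isa[[cl]])
      if (use_po) nxt <- c(nxt, graph$parents_partof[[cl]])
    }
    nxt <- setdiff(unique(nxt), c(seen, class_id))
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  if (reflexive) unique(c(class_id, seen)) else seen
}

# All classes reachable downward from `class_id` by is_a (including itself).
descendants_or_self <- function(graph, class_id) {
  kids <- children_index(graph)
  seen <- class_id
  frontier <- class_id
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(kids[frontier], use.names = FALSE)), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

# child lists keyed by parent, for the is_a relation (memoised on the graph)
children_index <- function(graph) {
  idx <- attr(graph, "children_isa")
  if (!is.null(idx)) return(idx)
  idx <- setNames(vector("list", length(graph$classes)), graph$classes)
  idx[] <- list(character())
  e <- graph$is_a_edges
  if (nrow(e)) {
    sp <- split(e[, "child"], e[, "parent"])
    idx[names(sp)] <- lapply(sp, unique)
  }
  idx
}

#' Does class `a` subsume class `b`?
#'
#' `a` subsumes `b` when `a` is an `is_a` ancestor of `b` or equal to it.
#'
#' @inheritParams ancestors
#' @param a,b class IDs.
#' @return Logical flag.
#' @export
subsumes <- function(graph, a, b) {
  if (!a %in% graph$classes) stop("unknown class: ", a)
  a %in% ancestors(graph, b, relations = "is_a", reflexive = TRUE)
}

#' Leaf classes of the is_a taxonomy
#'
#' @inheritParams ancestors
#' @return Character vector of classes with no `is_a` children.
#' @export
leaves <- function(graph) {
  kids <- children_index(graph)
  graph$classes[vapply(kids[graph$classes], length, 1L) == 0L]
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf(
    "ontology_graph: %d classes, %d is_a edges, %d part_of edges, root %s\n",
    length(x$classes), nrow(x$is_a_edges), nrow(x$part_of_edges), x$root))
  invisible(x)
}
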