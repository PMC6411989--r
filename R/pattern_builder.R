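#' @name pattern_kinds
#' @title The four compound-ontology design patterns
#'
#' @description
#' A compound class pairs one anatomy class A with one pathology class P.
#' The four patterns differ in two choices:
#'
#' * **backbone** — which source taxonomy structures the compound ontology.
#'   MAP and MAPT read "an A that bears lesion P" and attach each compound
#'   class under its anatomy class; PAM and PAMT read "a P that affects A"
#'   and attach under the pathology class (an adenoma that affects the lung
#'   is still a type of adenoma).
#' * **parthood transitivity (the trailing T)** — whether the anatomy side
#'   of subsumption may traverse `part_of` in addition to `is_a`, so that a
#'   lesion observed in the lung also counts as observed in (some part of)
#'   the respiratory system.
#'
#' Subsumption between two compound classes of the same kind is decided
#' structurally: (A2, P2) subsumes (A1, P1) iff A2 is reachable from A1
#' (via `is_a`, plus `part_of` for MAPT/PAMT) and P2 is an `is_a`
#' ancestor-or-self of P1.  For this axiom fragment — a named class
#' conjoined with one existential restriction, a transitive `part_of`
#' role, and the top-level contextualization axioms — the rule reproduces
#' what a description-logic reasoner infers, without running one.
NULL

PATTERN_KINDS <- c("MAP", "MAPT", "PAM", "PAMT")

#' Deterministic compound-class ID
#'
#' `"<KIND>:<anatomy-local-id>-<pathology-local-id>"`, where the local ID is
#' the part after the CURIE prefix colon (the full ID if there is none).
#'
#' @param kind one of `"MAP"`, `"MAPT"`, `"PAM"`, `"PAMT"`.
#' @param anatomy_id,pathology_id source class IDs.
#' @return Character vector of compound IDs.
#' @export
compound_id <- function(kind, anatomy_id, pathology_id) {
  kind <- match.arg(kind, PATTERN_KINDS)
  local <- function(x) sub("^[^:]+:", "", x)
  paste0(kind, ":", local(anatomy_id), "-", local(pathology_id))
}

#' Distinct (anatomy, pathology) pairs observed in diagnosis records
#'
#' @param records data frame with columns `anatomy_id` and `pathology_id`
#'   (a cohort's `records` element qualifies).
#' @param anatomy,pathology the source [ontology_graph()]s, used to validate
#'   that every recorded class exists.
#' @return Data frame with columns `anatomy_id`, `pathology_id`, one row per
#'   distinct pair, ordered lexicographically (order-independent content).
#' @export
enumerate_pairs <- function(records, anatomy, pathology) {
  if (inherits(records, "cohort")) records <- records$records
  stopifnot(all(c("anatomy_id", "pathology_id") %in% names(records)))
  bad_a <- !records$anatomy_id %in% anatomy$classes
  bad_p <- !records$pathology_id %in% pathology$classes
  if (any(bad_a | bad_p)) {
    i <- which(bad_a | bad_p)[[1L]]
    stop("unknown class in record ", i, ": ",
         records$anatomy_id[i], " / ", records$pathology_id[i])
  }
  pairs <- unique(data.frame(anatomy_id = records$anatomy_id,
                             pathology_id = records$pathology_id,
                             stringsAsFactors = FALSE))
  pairs <- pairs[order(pairs$anatomy_id, pairs$pathology_id), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Structural subsumption between two compound classes
#'
#' Decides whether compound class `a` subsumes compound class `b` (both of
#' the same pattern kind) using the pattern's structural rule; see
#' [pattern_kinds].
#'
#' @inheritParams compound_id
#' @param anatomy,pathology the source [ontology_graph()]s.
#' @param a,b lists or one-row data frames with `anatomy_id` and
#'   `pathology_id` fields.
#' @return Logical: `TRUE` iff `a` subsumes `b`.
#' @export
pattern_subsumes <- function(kind, anatomy, pathology, a, b) {
  kind <- match.arg(kind, PATTERN_KINDS)
  arel <- if (kind %in% c("MAPT", "PAMT")) c("is_a", "part_of") else "is_a"
  a$anatomy_id %in%
    ancestors(anatomy, b$anatomy_id, relations = arel, reflexive = TRUE) &&
  a$pathology_id %in%
    ancestors(pathology, b$pathology_id, relations = "is_a", reflexive = TRUE)
}

#' Build and classify a compound ontology
#'
#' Creates one compound class per observed (anatomy, pathology) pair,
#' computes the full subsumption relation among them with the structural
#' rule of [pattern_subsumes()], attaches each compound class to its
#' backbone class (anatomy for MAP/MAPT, pathology for PAM/PAMT), and emits
#' the transitive reduction of the union graph: all anatomy classes, all
#' pathology classes, all compound classes, under a fresh top node standing
#' in for `owl:Thing`.
#'
#' Compound classes whose non-backbone side is that side's root are logically
#' equivalent to their backbone class under the contextualization axioms
#' (everything bears a lesion / every lesion affects something); they are
#' merged into the backbone class, with the compound ID recorded as a
#' synonym, so the result stays a simple DAG.
#'
#' @inheritParams pattern_subsumes
#' @param pairs data frame of distinct pairs from [enumerate_pairs()].
#' @param classify if `FALSE`, skip the structural classification: compound
#'   classes are attached to their backbone class only, as in the asserted
#'   (pre-reasoning) hierarchy.  The default emits the classified hierarchy.
#' @return An object of class `combined_ontology`: list with `kind`,
#'   `graph` (the classified union [ontology_graph()]), `pattern_classes`
#'   (data frame: `anatomy_id`, `pathology_id`, `compound_id`, `class_id` —
#'   the node actually carrying the pair, after equivalence merging),
#'   and `provenance` (the two source roots).
#' @export
build_pattern_ontology <- function(anatomy, pathology, pairs, kind,
                                   classify = TRUE) {
  kind <- match.arg(kind, PATTERN_KINDS)
  if (!nrow(pairs)) stop("empty pair set")
  bad <- !(pairs$anatomy_id %in% anatomy$classes) |
         !(pairs$pathology_id %in% pathology$classes)
  if (any(bad)) {
    stop("pair references unknown class: ",
         pairs$anatomy_id[bad][1L], " / ", pairs$pathology_id[bad][1L])
  }
  pairs <- unique(pairs[, c("anatomy_id", "pathology_id")])
  rownames(pairs) <- NULL
  n <- nrow(pairs)
  cid <- compound_id(kind, pairs$anatomy_id, pairs$pathology_id)
  backbone_side <- if (kind %in% c("MAP", "MAPT")) "anatomy" else "pathology"

  # contextualization equivalence: non-backbone side at its root collapses
  # the compound class onto its backbone class
  context_root <- if (backbone_side == "anatomy") pathology$root else anatomy$root
  merged <- if (backbone_side == "anatomy") {
    pairs$pathology_id == context_root
  } else {
    pairs$anatomy_id == context_root
  }
  backbone_of <- if (backbone_side == "anatomy") pairs$anatomy_id else pairs$pathology_id
  class_id <- ifelse(merged, backbone_of, cid)

  # pairwise structural subsumption among (unmerged) compound classes
  arel <- if (kind %in% c("MAPT", "PAMT")) c("is_a", "part_of") else "is_a"
  anc_a <- lapply(pairs$anatomy_id, function(x)
    ancestors(anatomy, x, relations = arel, reflexive = TRUE))
  anc_p <- lapply(pairs$pathology_id, function(x)
    ancestors(pathology, x, relations = "is_a", reflexive = TRUE))
  sub <- matrix(FALSE, n, n)  # sub[i, j]: class i subsumes class j
  if (classify) {
    for (j in seq_len(n)) {
      sub[, j] <- (pairs$anatomy_id %in% anc_a[[j]]) &
                  (pairs$pathology_id %in% anc_p[[j]])
    }
  }

  # union-graph parent lists: compound -> {subsuming compounds, backbone class}
  # (full relation; redundancy removed by the global transitive reduction)
  top <- "ROOT:thing"
  node_parents <- list()
  for (j in seq_len(n)) {
    if (merged[j]) next
    sup <- class_id[sub[, j]]
    sup <- setdiff(unique(sup), class_id[j])
    node_parents[[class_id[j]]] <- unique(c(sup, backbone_of[j]))
  }
  src_edges <- rbind(anatomy$is_a_edges, pathology$is_a_edges)
  for (i in seq_len(nrow(src_edges))) {
    ch <- src_edges[i, "child"]
    node_parents[[ch]] <- unique(c(node_parents[[ch]], src_edges[i, "parent"]))
  }
  node_parents[[anatomy$root]] <- top
  node_parents[[pathology$root]] <- top

  all_nodes <- unique(c(top, anatomy$classes, pathology$classes,
                        class_id[!merged]))
  node_parents <- reduce_parent_lists(node_parents, all_nodes)

  edges <- do.call(rbind, lapply(names(node_parents), function(ch) {
    if (!length(node_parents[[ch]])) return(NULL)
    cbind(child = ch, parent = node_parents[[ch]])
  }))

  labels <- c(setNames("owl:Thing", top),
              anatomy$labels, pathology$labels,
              setNames(sprintf("%s [%s] %s",
                               anatomy$labels[pairs$anatomy_id[!merged]],
                               kind,
                               pathology$labels[pairs$pathology_id[!merged]]),
                       class_id[!merged]))
  graph <- ontology_graph(all_nodes, labels, is_a = edges,
                          part_of = anatomy$part_of_edges, root = top)
  syn <- setNames(cid[merged], class_id[merged])
  if (length(syn)) attr(graph, "synonyms") <- syn

  structure(
    list(kind = kind,
         graph = graph,
         pattern_classes = data.frame(anatomy_id = pairs$anatomy_id,
                                      pathology_id = pairs$pathology_id,
                                      compound_id = cid,
                                      class_id = class_id,
                                      merged = merged,
                                      stringsAsFactors = FALSE),
         provenance = c(anatomy = anatomy$root, pathology = pathology$root)),
    class = "combined_ontology")
}

# Transitive reduction on parent lists: drop parent p of c when p is a
# strict ancestor of another parent of c.  Operates on the union DAG.
reduce_parent_lists <- function(node_parents, all_nodes) {
  anc_cache <- new.env(parent = emptyenv())
  anc_of <- function(node) {
    if (!is.null(anc_cache[[node]])) return(anc_cache[[node]])
    ps <- node_parents[[node]]
    out <- ps
    for (p in ps) out <- c(out, anc_of(p))
    out <- unique(out)
    anc_cache[[node]] <- out
    out
  }
  for (ch in names(node_parents)) {
    ps <- unique(node_parents[[ch]])
    if (length(ps) < 2L) { node_parents[[ch]] <- ps; next }
    redundant <- vapply(ps, function(p) {
      any(vapply(setdiff(ps, p), function(q) p %in% anc_of(q), logical(1L)))
    }, logical(1L))
    node_parents[[ch]] <- ps[!redundant]
  }
  node_parents
}

#' @export
print.combined_ontology <- function(x, ...) {
  cat(sprintf("combined_ontology [%s]: %d pattern classes (%d merged into backbone), %d nodes\n",
              x$kind, nrow(x$pattern_classes), sum(x$pattern_classes$merged),
              length(x$graph$classes)))
  invisible(x)
}
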