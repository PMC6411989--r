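#' Load an ontology from an OBO flat file
#'
#' Reads the minimal OBO 1.2/1.4 dialect needed for taxonomy work: `[Term]`
#' stanzas with `id`, `name`, `is_a`, `relationship: part_of` and
#' `is_obsolete` tags; every other tag is ignored.  Obsolete terms are
#' dropped, together with any edge pointing at them.  If the file has a
#' single top-level class it becomes the root; otherwise a fresh root class
#' with ID `ROOT:<label-slug>` and the given label is inserted and every
#' top-level class is attached beneath it (the usual root-augmentation step
#' for anatomy ontologies whose organ systems are mutually disconnected).
#'
#' @param path path to an OBO file.
#' @param root_label label for the inserted root when the source has more
#'   than one top-level class.
#' @return An [ontology_graph()].
#' @export
load_ontology <- function(path, root_label = "root") {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s*!.*$", "", lines)      # strip trailing OBO comments
  lines <- trimws(lines)

  stanza_starts <- grep("^\\[", lines)
  if (!length(stanza_starts)) stop("no stanzas found in OBO file: ", path)

  ids <- character(); labels <- character()
  obsolete <- character()
  isa_child <- character(); isa_parent <- character()
  po_child <- character(); po_parent <- character()

  bounds <- c(stanza_starts, length(lines) + 1L)
  for (s in seq_along(stanza_starts)) {
    if (lines[stanza_starts[s]] != "[Term]") next
    block <- lines[(stanza_starts[s] + 1L):(bounds[s + 1L] - 1L)]
    id <- sub("^id:\\s*", "", grep("^id:", block, value = TRUE))
    if (length(id) != 1L) next
    if (any(grepl("^is_obsolete:\\s*true", block))) {
      obsolete <- c(obsolete, id)
      next
    }
    nm <- sub("^name:\\s*", "", grep("^name:", block, value = TRUE))
    ids <- c(ids, id)
    labels <- c(labels, if (length(nm)) nm[[1L]] else id)
    par <- sub("^is_a:\\s*", "", grep("^is_a:", block, value = TRUE))
    if (length(par)) {
      isa_child <- c(isa_child, rep(id, length(par)))
      isa_parent <- c(isa_parent, par)
    }
    po <- sub("^relationship:\\s*part_of\\s+", "",
              grep("^relationship:\\s*part_of\\s", block, value = TRUE))
    if (length(po)) {
      po_child <- c(po_child, rep(id, length(po)))
      po_parent <- c(po_parent, po)
    }
  }
  if (!length(ids)) stop("no non-obsolete [Term] stanzas in ", path)
  names(labels) <- ids

  drop_dangling <- function(child, parent) {
    keep_obs <- !(parent %in% obsolete | child %in% obsolete)
    child <- child[keep_obs]; parent <- parent[keep_obs]
    bad <- setdiff(c(child, parent), ids)
    if (length(bad)) stop("unknown class in edge: ", paste(bad, collapse = ", "))
    cbind(child = child, parent = parent)
  }
  isa <- drop_dangling(isa_child, isa_parent)
  po <- drop_dangling(po_child, po_parent)

  # root handling: unique orphan class, or insert a fresh root
  orphans <- setdiff(ids, isa[, "child"])
  if (length(orphans) == 1L) {
    root <- orphans
  } else {
    root <- paste0("ROOT:", slugify(root_label))
    ids <- c(root, ids)
    labels <- c(setNames(root_label, root), labels)
    if (length(orphans)) {
      isa <- rbind(cbind(child = orphans, parent = root), isa)
    }
  }
  ontology_graph(ids, labels, is_a = isa, part_of = po, root = root)
}

slugify <- function(x) {
  x <- tolower(gsub("[^A-Za-z0-9]+", "-", x))
  gsub("^-+|-+$", "", x)
}

#' Write an ontology to an OBO flat file
#'
#' Emits `[Term]` stanzas with `id`, `name` and `is_a` tags only (the
#' classified compound ontologies carry their whole structure in `is_a`).
#' `part_of` edges, when present, are written as `relationship: part_of`.
#'
#' @param graph an [ontology_graph()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (cl in graph$classes) {
    out <- c("[Term]", paste0("id: ", cl), paste0("name: ", graph$labels[[cl]]))
    for (p in sort(graph$parents_isa[[cl]])) out <- c(out, paste0("is_a: ", p))
    for (p in sort(graph$parents_partof[[cl]])) {
      out <- c(out, paste0("relationship: part_of ", p))
    }
    syn <- attr(graph, "synonyms")
    if (!is.null(syn) && cl %in% names(syn)) {
      out <- c(out, paste0("alt_id: ", syn[[cl]]))
    }
    writeLines(c(out, ""), con)
  }
  invisible(path)
}

#' Write the is_a edge list of an ontology as TSV
#'
#' @inheritParams write_obo
#' @return `path`, invisibly.
#' @export
write_edges_tsv <- function(graph, path) {
  e <- graph$is_a_edges
  utils::write.table(as.data.frame(e), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
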