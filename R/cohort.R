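VIEW_NAMES <- c("MA", "MPATH", "MAP", "MAPT", "PAM", "PAMT")

#' Construct a cohort of diagnosed individuals
#'
#' @param mice data frame with columns `mouse_id`, `strain`, `sex` (`"F"` or
#'   `"M"`), `group` (study arm, e.g. `"12m"`, `"20m"`, `"LONG"`); one row
#'   per mouse.  Mice with no diagnoses (healthy) are allowed and expected.
#' @param records data frame with columns `mouse_id`, `anatomy_id`,
#'   `pathology_id`; one row per diagnosis.  Duplicate identical diagnoses
#'   are preserved here and collapsed only when projecting annotation views.
#' @param excluded_strains strains that were filtered out, kept for
#'   provenance.
#' @return Object of class `cohort`.
#' @export
cohort <- function(mice, records, excluded_strains = character()) {
  req_m <- c("mouse_id", "strain", "sex", "group")
  if (!all(req_m %in% names(mice))) {
    stop("mouse table must have columns: ", paste(req_m, collapse = ", "))
  }
  req_r <- c("mouse_id", "anatomy_id", "pathology_id")
  if (!all(req_r %in% names(records))) {
    stop("records must have columns: ", paste(req_r, collapse = ", "))
  }
  if (anyDuplicated(mice$mouse_id)) stop("duplicate mouse_id in mouse table")
  orphan <- setdiff(records$mouse_id, mice$mouse_id)
  if (length(orphan)) {
    stop("diagnosis for unknown mouse: ", paste(utils::head(orphan, 3L),
                                                collapse = ", "))
  }
  bad_sex <- setdiff(mice$sex, c("F", "M"))
  if (length(bad_sex)) stop("sex must be F or M, got: ", bad_sex[[1L]])
  mice <- mice[order(mice$mouse_id), req_m, drop = FALSE]
  rownames(mice) <- NULL
  rownames(records) <- NULL
  structure(list(mice = mice, records = records,
                 excluded_strains = excluded_strains),
            class = "cohort")
}

#' Read a diagnosis table and mouse table from TSV
#'
#' The diagnosis TSV has a header and one row per diagnosis with columns
#' `mouse_id`, `strain`, `sex`, `group`, `anatomy_id`, `pathology_id`.
#' The optional mouse table (`mouse_id`, `strain`, `sex`, `group`) lists
#' every individual, including healthy mice that never appear in the
#' diagnosis table.  Strain and group exclusions mirror the usual cohort
#' curation step (e.g. dropping short-lived strains and a study arm that
#' was scored differently).
#'
#' @param path diagnosis TSV path.
#' @param mouse_table optional TSV path with one row per mouse.
#' @param exclude_strains,exclude_groups values to drop, with a warning if a
#'   listed strain never occurs.
#' @return A [cohort()].
#' @export
load_diagnoses <- function(path, mouse_table = NULL,
                           exclude_strains = character(),
                           exclude_groups = character()) {
  rec <- read_tsv_checked(path,
    c("mouse_id", "strain", "sex", "group", "anatomy_id", "pathology_id"))
  if (!is.null(mouse_table)) {
    mice <- read_tsv_checked(mouse_table,
                             c("mouse_id", "strain", "sex", "group"))
  } else {
    mice <- unique(rec[, c("mouse_id", "strain", "sex", "group")])
  }
  # consistency: a mouse's metadata in the record table must match
  joint <- merge(unique(rec[, c("mouse_id", "strain", "sex", "group")]),
                 mice, by = "mouse_id", suffixes = c(".rec", ".mouse"))
  mism <- joint$strain.rec != joint$strain.mouse |
          joint$sex.rec != joint$sex.mouse | joint$group.rec != joint$group.mouse
  if (any(mism)) {
    stop("metadata mismatch between tables for mouse ",
         joint$mouse_id[mism][[1L]])
  }
  unknown <- setdiff(exclude_strains, mice$strain)
  if (length(unknown)) {
    warning("excluded strain(s) not present: ", paste(unknown, collapse = ", "))
  }
  keep <- !(mice$strain %in% exclude_strains) &
          !(mice$group %in% exclude_groups)
  mice <- mice[keep, , drop = FALSE]
  rec <- rec[rec$mouse_id %in% mice$mouse_id,
             c("mouse_id", "anatomy_id", "pathology_id"), drop = FALSE]
  cohort(mice, rec, excluded_strains = exclude_strains)
}

read_tsv_checked <- function(path, required) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          blank.lines.skip = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(path, ": missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  bad <- which(apply(df[required] == "" | is.na(df[required]), 1L, any))
  if (length(bad)) {
    stop(path, ": malformed row at line ", bad[[1L]] + 1L,
         " (empty required field)")
  }
  df
}

#' Write a cohort as the diagnosis-TSV / mouse-TSV pair read by
#' [load_diagnoses()]
#'
#' @param x a [cohort()].
#' @param path diagnosis TSV path.
#' @param mouse_path optional mouse-table TSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_tsv <- function(x, path, mouse_path = NULL) {
  stopifnot(inherits(x, "cohort"))
  meta <- x$mice[match(x$records$mouse_id, x$mice$mouse_id), ]
  out <- data.frame(mouse_id = x$records$mouse_id,
                    strain = meta$strain, sex = meta$sex, group = meta$group,
                    anatomy_id = x$records$anatomy_id,
                    pathology_id = x$records$pathology_id)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(mouse_path)) {
    utils::write.table(x$mice, mouse_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Project cohort diagnoses into an ontology view
#'
#' Six views exist: the two source ontologies (`MA` keeps anatomy IDs,
#' `MPATH` keeps pathology IDs) and the four compound ontologies, where each
#' (anatomy, pathology) diagnosis maps to its compound class.  Duplicate
#' annotations collapse.  Healthy mice — mice with no diagnosis — are
#' annotated with exactly the view graph's root, so they participate in
#' similarity and enrichment rather than dropping out.
#'
#' @param cohort a [cohort()].
#' @param view one of `"MA"`, `"MPATH"`, `"MAP"`, `"MAPT"`, `"PAM"`, `"PAMT"`.
#' @param anatomy,pathology the source [ontology_graph()]s (used for the MA
#'   and MPATH views).
#' @param combined the matching [build_pattern_ontology()] result; required
#'   for pattern views.
#' @return Object of class `annotation_view`: list with `view`, `graph`,
#'   `annotations` (named list mouse_id -> character vector of class IDs).
#' @export
project_annotations <- function(cohort, view, anatomy = NULL,
                                pathology = NULL, combined = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  view <- match.arg(view, VIEW_NAMES)
  rec <- cohort$records
  if (view %in% c("MA", "MPATH")) {
    graph <- if (view == "MA") anatomy else pathology
    if (is.null(graph)) stop("view ", view, " needs its source graph")
    ids <- if (view == "MA") rec$anatomy_id else rec$pathology_id
    missing_ids <- setdiff(ids, graph$classes)
    if (length(missing_ids)) stop("unknown class: ", missing_ids[[1L]])
  } else {
    if (is.null(combined) || !inherits(combined, "combined_ontology")) {
      stop("view ", view, " needs the matching combined ontology")
    }
    if (combined$kind != view) {
      stop("combined ontology is ", combined$kind, ", not ", view)
    }
    pc <- combined$pattern_classes
    key <- paste(rec$anatomy_id, rec$pathology_id, sep = "\r")
    idx <- match(key, paste(pc$anatomy_id, pc$pathology_id, sep = "\r"))
    if (anyNA(idx)) {
      i <- which(is.na(idx))[[1L]]
      stop("pair absent from combined ontology: ",
           rec$anatomy_id[i], " / ", rec$pathology_id[i])
    }
    graph <- combined$graph
    ids <- pc$class_id[idx]
  }
  ann <- lapply(split(ids, rec$mouse_id), function(x) sort(unique(x)))
  healthy <- setdiff(cohort$mice$mouse_id, names(ann))
  ann[healthy] <- list(graph$root)
  ann <- ann[sort(cohort$mice$mouse_id)]
  structure(list(view = view, graph = graph, annotations = ann),
            class = "annotation_view")
}

#' Split a cohort into (group, sex) strata
#'
#' Confounder control for the similarity analyses: similarity matrices and
#' ROC/purity evaluation are computed within strata defined by study arm and
#' sex (e.g. `"12m-F"`).
#'
#' @param cohort a [cohort()].
#' @return Named list of sorted mouse-ID vectors, names `"<group>-<sex>"`.
#' @export
split_groups <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  if (!nrow(cohort$mice)) return(setNames(list(), character()))
  key <- paste(cohort$mice$group, cohort$mice$sex, sep = "-")
  lapply(split(cohort$mice$mouse_id, key), sort)
}

#' Recover the (anatomy, pathology) pairs behind a pattern-view annotation
#'
#' Inverse of the pattern projection: maps compound class IDs (including
#' merged, backbone-carried ones) back to their source pairs.
#'
#' @param combined a [build_pattern_ontology()] result.
#' @param class_ids compound class IDs as found in a pattern view.
#' @return Data frame with columns `anatomy_id`, `pathology_id`.
#' @export
unproject_pairs <- function(combined, class_ids) {
  pc <- combined$pattern_classes
  idx <- match(class_ids, pc$class_id)
  if (anyNA(idx)) stop("not a pattern class: ", class_ids[is.na(idx)][[1L]])
  pc[idx, c("anatomy_id", "pathology_id"), drop = FALSE]
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d mice, %d strains, %d diagnoses (%d healthy mice)\n",
              nrow(x$mice), length(unique(x$mice$strain)), nrow(x$records),
              sum(!x$mice$mouse_id %in% x$records$mouse_id)))
  invisible(x)
}

#' @export
print.annotation_view <- function(x, ...) {
  cat(sprintf("annotation_view [%s]: %d mice over %d classes\n",
              x$view, length(x$annotations),
              length(unique(unlist(x$annotations)))))
  invisible(x)
}
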