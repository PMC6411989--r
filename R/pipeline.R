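#' Build all four compound ontologies from a cohort
#'
#' @param cohort a [cohort()].
#' @param anatomy,pathology source [ontology_graph()]s.
#' @param kinds pattern kinds to build.
#' @return Named list of [build_pattern_ontology()] results.
#' @export
build_all_patterns <- function(cohort, anatomy, pathology,
                               kinds = PATTERN_KINDS) {
  pairs <- enumerate_pairs(cohort$records, anatomy, pathology)
  setNames(lapply(kinds, function(k)
    build_pattern_ontology(anatomy, pathology, pairs, k)), kinds)
}

#' Project a cohort into several ontology views at once
#'
#' @inheritParams build_all_patterns
#' @param views view names among `"MA"`, `"MPATH"`, `"MAP"`, `"MAPT"`,
#'   `"PAM"`, `"PAMT"`.
#' @param combined named list of combined ontologies (built on demand when
#'   `NULL`).
#' @return Named list of [project_annotations()] results.
#' @export
project_views <- function(cohort, anatomy, pathology,
                          views = VIEW_NAMES, combined = NULL) {
  views <- match.arg(views, VIEW_NAMES, several.ok = TRUE)
  pattern_views <- intersect(views, PATTERN_KINDS)
  if (length(pattern_views) && is.null(combined)) {
    combined <- build_all_patterns(cohort, anatomy, pathology, pattern_views)
  }
  setNames(lapply(views, function(v) {
    project_annotations(cohort, v, anatomy = anatomy, pathology = pathology,
                        combined = combined[[v]])
  }), views)
}

#' Per-view ROC AUC for strain identification
#'
#' Runs the similarity half of the evaluation pipeline: per view, compute
#' information content over the whole cohort, then per (group, sex) stratum
#' a pairwise BMA similarity matrix and its strain-identification ROC AUC;
#' strata are combined by mouse-count-weighted average.  Strata with fewer
#' than `min_group` mice or a single strain are skipped.
#'
#' @inheritParams project_views
#' @param by_group evaluate within (group, sex) strata (`TRUE`, the
#'   confounder-controlled design) or on the pooled cohort (`FALSE`).
#' @param min_group smallest stratum size evaluated.
#' @return Data frame with columns `view`, `group`, `n`, `auc`; the pooled
#'   run uses group `"all"`.  Attribute `weighted` holds the named vector of
#'   weighted-average AUCs per view.
#' @export
roc_auc_by_view <- function(cohort, anatomy, pathology, views = VIEW_NAMES,
                            combined = NULL, by_group = TRUE,
                            min_group = 4L) {
  view_objs <- project_views(cohort, anatomy, pathology, views, combined)
  strain_of <- setNames(cohort$mice$strain, cohort$mice$mouse_id)
  strata <- if (by_group) split_groups(cohort) else
    list(all = sort(cohort$mice$mouse_id))
  rows <- list()
  for (v in names(view_objs)) {
    ic <- compute_ic(view_objs[[v]])
    for (gname in names(strata)) {
      mice <- strata[[gname]]
      if (length(mice) < min_group ||
          length(unique(strain_of[mice])) < 2L ||
          max(table(strain_of[mice])) < 2L) next
      sm <- similarity_matrix(view_objs[[v]], mice, ic)
      roc <- roc_curve(sm, strain_of[mice])
      rows[[length(rows) + 1L]] <- data.frame(
        view = v, group = gname, n = length(mice), auc = roc$auc,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    stop("no stratum is evaluable (need >= ", min_group,
         " mice, >= 2 strains and a strain with >= 2 mice); ",
         "consider by_group = FALSE")
  }
  out <- do.call(rbind, rows)
  w <- vapply(split(out, out$view), function(d) sum(d$auc * d$n) / sum(d$n),
              numeric(1L))
  attr(out, "weighted") <- w[intersect(names(view_objs), names(w))]
  out
}

#' Purity AUC per view, clustering method and stratum
#'
#' The clustering half of the evaluation: per view and (group, sex) stratum,
#' convert the BMA similarity matrix to distances, cluster with the
#' requested methods, and report the area under the purity curve.
#'
#' @inheritParams roc_auc_by_view
#' @param methods clustering methods (see [cluster_distance()]).
#' @return Data frame with columns `view`, `group`, `method`, `n`, `auc`.
#' @export
purity_auc_by_view <- function(cohort, anatomy, pathology,
                               views = VIEW_NAMES, combined = NULL,
                               methods = c("complete", "upgma", "nj",
                                           "kmedoids"),
                               by_group = TRUE, min_group = 4L) {
  view_objs <- project_views(cohort, anatomy, pathology, views, combined)
  strain_of <- setNames(cohort$mice$strain, cohort$mice$mouse_id)
  strata <- if (by_group) split_groups(cohort) else
    list(all = sort(cohort$mice$mouse_id))
  rows <- list()
  for (v in names(view_objs)) {
    ic <- compute_ic(view_objs[[v]])
    for (gname in names(strata)) {
      mice <- strata[[gname]]
      if (length(mice) < min_group ||
          length(unique(strain_of[mice])) < 2L ||
          max(table(strain_of[mice])) < 2L) next
      d <- to_distance(similarity_matrix(view_objs[[v]], mice, ic))
      for (m in methods) {
        cl <- cluster_distance(d, m)
        pc <- purity_curve(cl, strain_of[mice])
        rows[[length(rows) + 1L]] <- data.frame(
          view = v, group = gname, method = m, n = length(mice),
          auc = pc$auc, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
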