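#' Temporal replicate variation analysis
#'
#' Tracks recovery of a CV distribution after an acute stress: every
#' timepoint-labelled group is compared against one fixed unstressed
#' reference group, and the series of comparisons is ordered by time. During
#' recovery the K-S d against the reference shrinks toward 0 while the mean
#' and median CV climb back toward the reference's values.
#'
#' The reference for every timepoint is the same untreated group, not the
#' previous timepoint. Every non-reference group must carry a timepoint in
#' the design; duplicated timepoints across differently-labelled groups are
#' kept as distinct groups but timepoints must be unique per group label.
#'
#' @param table a [feature_table].
#' @param design a [sample_design] with a `timepoint` column (hours).
#' @param reference_group label of the unstressed reference.
#' @return Object of class `rva_temporal`: list with `reference_group` and
#'   `points`, a list of `(timepoint, group, comparison)` records sorted by
#'   ascending timepoint (comparison a = reference, b = timepoint group).
#' @export
rva_temporal <- function(table, design, reference_group) {
  if (is.null(design$timepoint))
    stop("design has no 'timepoint' column")
  if (!reference_group %in% design$group)
    stop("reference group not found in design: '", reference_group, "'")
  others <- design[design$group != reference_group, , drop = FALSE]
  unlabeled <- unique(others$sample_id[is.na(others$timepoint)])
  if (length(unlabeled))
    stop("samples without a timepoint: ", paste(unlabeled, collapse = ", "))
  grp_tp <- unique(others[, c("group", "timepoint")])
  if (anyDuplicated(grp_tp$group))
    stop("group '", grp_tp$group[duplicated(grp_tp$group)][1L],
         "' spans multiple timepoints")
  if (nrow(grp_tp) < 2L)
    stop("temporal analysis needs >= 2 timepointed groups")
  grp_tp <- grp_tp[order(grp_tp$timepoint), , drop = FALSE]
  ref <- cv_profile(table, design, reference_group)
  points <- lapply(seq_len(nrow(grp_tp)), function(i) {
    prof <- cv_profile(table, design, grp_tp$group[i])
    list(timepoint = grp_tp$timepoint[i], group = grp_tp$group[i],
         comparison = rva_compare(ref, prof))
  })
  structure(list(reference_group = reference_group, points = points),
            class = "rva_temporal")
}

#' Tabular summary of a temporal series
#'
#' One row per timepoint with the K-S d against the reference, the
#' timepoint group's mean and median CV, and a direction flag saying
#' whether d decreased relative to the previous timepoint (recovery looks
#' like a run of "decreasing" flags).
#'
#' @param series an [rva_temporal] object.
#' @return data frame with columns `timepoint`, `group`, `ks_d`, `ks_p`,
#'   `mean_cv`, `median_cv`, `direction` (`""` for the first row).
#' @export
recovery_summary <- function(series) {
  stopifnot(inherits(series, "rva_temporal"))
  if (!length(series$points)) stop("empty temporal series")
  rows <- lapply(series$points, function(p) {
    data.frame(timepoint = p$timepoint, group = p$group,
               ks_d = p$comparison$ks_d, ks_p = p$comparison$ks_p,
               mean_cv = p$comparison$mean_cv_b,
               median_cv = p$comparison$median_cv_b,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$direction <- c("", ifelse(diff(out$ks_d) < 0, "decreasing",
                                ifelse(diff(out$ks_d) > 0, "increasing", "flat")))
  out
}

#' @export
print.rva_temporal <- function(x, ...) {
  cat(sprintf("Temporal RVA vs reference '%s' (%d timepoints)\n",
              x$reference_group, length(x$points)))
  print(recovery_summary(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.rva_temporal <- function(x, ...) {
  s <- recovery_summary(x)
  graphics::plot(s$timepoint, s$ks_d, type = "b", pch = 19,
                 xlab = "time post-stress (h)",
                 ylab = "K-S d vs reference",
                 main = paste("Recovery toward", x$reference_group), ...)
  invisible(s)
}
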