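#' Per-feature CV profile of a replicate group
#'
#' For every feature, the coefficient of variation across the group's
#' biological replicates: CV = 100 * s / mu (percent), with s the sample
#' standard deviation (n - 1 denominator) and mu the arithmetic mean. The
#' collection of per-feature CVs is the group's CV profile — the object whose
#' distribution replicate variation analysis compares between conditions.
#'
#' A feature's CV is computed over its non-missing replicates only, and the
#' feature is dropped from the profile when fewer than 3 non-missing
#' replicates remain (no imputation). Features with mean <= 0 are excluded;
#' the counts of both exclusions are kept on the returned object.
#'
#' @param table a [feature_table].
#' @param design a [sample_design] covering the table's samples.
#' @param group group label to profile; needs >= 3 samples present in the
#'   table.
#' @return Object of class `cv_profile`: list with `group`, `feature_ids`,
#'   `cv` (percent), `n_replicates`, `summary` (`mean_cv`, `median_cv`),
#'   `n_dropped_missing`, `n_dropped_nonpos`.
#' @examples
#' tab <- feature_table(matrix(c(2, 4, 6, 5, 5, 5), nrow = 2, byrow = TRUE,
#'                             dimnames = list(c("a", "b"), c("s1", "s2", "s3"))))
#' des <- sample_design(c("s1", "s2", "s3"), rep("ctrl", 3))
#' cv_profile(tab, des, "ctrl")$cv   # a: 50, b: 0
#' @export
cv_profile <- function(table, design, group) {
  stopifnot(inherits(table, "feature_table"))
  ids <- group_samples(design, table, group)
  if (length(ids) < 3L)
    stop("group '", group, "' below minimum replicates: has ", length(ids),
         " samples in the table, needs >= 3")
  m <- table$values[, ids, drop = FALSE]
  n_ok <- rowSums(!is.na(m))
  keep_n <- n_ok >= 3L
  mu <- rowMeans(m, na.rm = TRUE)
  s <- apply(m, 1L, stats::sd, na.rm = TRUE)
  keep_mu <- !is.na(mu) & mu > 0
  keep <- keep_n & keep_mu
  if (!any(keep)) stop("empty profile: no feature of group '", group,
                       "' has >= 3 non-missing replicates and positive mean")
  cv <- 100 * s[keep] / mu[keep]
  new_cv_profile(group = group,
                 feature_ids = table$feature_ids[keep],
                 cv = unname(cv),
                 n_replicates = length(ids),
                 n_dropped_missing = sum(!keep_n),
                 n_dropped_nonpos = sum(keep_n & !keep_mu))
}

#' Build a CV profile from precomputed per-feature CVs
#'
#' Some studies distribute per-feature CV tables rather than raw replicate
#' intensities (supplementary "protein CV" tables are the common case). This
#' constructor wraps such a vector so it can enter [rva_compare()] and
#' [delta_cv_table()] like a profile computed from raw data.
#'
#' @param cv numeric vector of per-feature CVs, in percent, all >= 0.
#' @param feature_ids character vector of ids, same length as `cv`.
#' @param group group label.
#' @param n_replicates number of replicates the CVs were computed from, if
#'   known (`NA` otherwise).
#' @return A `cv_profile`.
#' @export
cv_profile_from_values <- function(cv, feature_ids, group,
                                   n_replicates = NA_integer_) {
  cv <- as.numeric(cv)
  feature_ids <- as.character(feature_ids)
  if (length(cv) != length(feature_ids))
    stop("'cv' and 'feature_ids' lengths differ")
  if (anyDuplicated(feature_ids))
    stop("duplicate feature id: ", feature_ids[duplicated(feature_ids)][1L])
  if (any(!is.finite(cv)) || any(cv < 0))
    stop("CV values must be finite and >= 0")
  new_cv_profile(group = group, feature_ids = feature_ids, cv = cv,
                 n_replicates = as.integer(n_replicates),
                 n_dropped_missing = 0L, n_dropped_nonpos = 0L)
}

new_cv_profile <- function(group, feature_ids, cv, n_replicates,
                           n_dropped_missing, n_dropped_nonpos) {
  structure(list(group = group,
                 feature_ids = feature_ids,
                 cv = cv,
                 n_replicates = n_replicates,
                 summary = c(mean_cv = mean(cv), median_cv = stats::median(cv)),
                 n_dropped_missing = n_dropped_missing,
                 n_dropped_nonpos = n_dropped_nonpos),
            class = "cv_profile")
}

#' @export
print.cv_profile <- function(x, ...) {
  cat(sprintf("CV profile '%s': %d features, %s replicates\n", x$group,
              length(x$cv),
              if (is.na(x$n_replicates)) "?" else x$n_replicates))
  cat(sprintf("  mean CV %.1f%%, median CV %.1f%%\n",
              x$summary[["mean_cv"]], x$summary[["median_cv"]]))
  if (x$n_dropped_missing) cat("  dropped (<3 non-missing replicates):",
                               x$n_dropped_missing, "\n")
  if (x$n_dropped_nonpos) cat("  dropped (mean <= 0):", x$n_dropped_nonpos, "\n")
  invisible(x)
}

#' @export
summary.cv_profile <- function(object, ...) {
  c(n_features = length(object$cv),
    n_replicates = object$n_replicates,
    mean_cv = unname(object$summary[["mean_cv"]]),
    median_cv = unname(object$summary[["median_cv"]]),
    stats::quantile(object$cv, c(0.25, 0.5, 0.75)))
}

#' @export
plot.cv_profile <- function(x, ...) {
  plot_cv_profiles(list(x), ...)
}
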