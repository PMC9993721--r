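#' Mean-variance relationship within a replicate group
#'
#' Ordinary least-squares fit of per-feature variance on per-feature mean
#' over one group's replicates. Instruments that record high-intensity
#' features more precisely would produce a negative mean-variance
#' relationship and make the CV an artifact of intensity; biological
#' replicate data instead show a strongly positive relationship (with
#' roughly constant CV, s^2 grows like mu^2), which is the sanity check this
#' fit provides before interpreting CV shifts as canalization.
#'
#' @param table a [feature_table].
#' @param design a [sample_design].
#' @param group group label with >= 3 replicates.
#' @param scale `"raw"` (default) fits var on mean directly; `"log10"` fits
#'   log10(var) on log10(mean), excluding features with mean <= 0 or zero
#'   variance (their count is recorded).
#' @return Object of class `meanvar_fit`: list with `group`, `scale`,
#'   `slope`, `intercept`, `r` (Pearson correlation of the fitted pairs),
#'   `n_features`, `n_excluded`, and `data` (the fitted mean/variance pairs).
#' @export
mean_variance_fit <- function(table, design, group, scale = c("raw", "log10")) {
  scale <- match.arg(scale)
  ids <- group_samples(design, table, group)
  if (length(ids) < 3L)
    stop("group '", group, "' below minimum replicates")
  m <- table$values[, ids, drop = FALSE]
  ok <- rowSums(!is.na(m)) >= 3L
  mu <- rowMeans(m, na.rm = TRUE)[ok]
  v <- apply(m[ok, , drop = FALSE], 1L, stats::var, na.rm = TRUE)
  n_excl <- sum(!ok)
  if (scale == "log10") {
    keep <- mu > 0 & v > 0
    n_excl <- n_excl + sum(!keep)
    mu <- log10(mu[keep]); v <- log10(v[keep])
  }
  if (length(mu) < 3L) stop("fewer than 3 usable features for the fit")
  fit <- stats::lm(v ~ mu)
  structure(list(group = group, scale = scale,
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r = stats::cor(mu, v),
                 n_features = length(mu), n_excluded = n_excl,
                 data = data.frame(mean = mu, variance = v)),
            class = "meanvar_fit")
}

#' @export
print.meanvar_fit <- function(x, ...) {
  cat(sprintf("Mean-variance fit, group '%s' (%s scale, %d features):\n",
              x$group, x$scale, x$n_features))
  cat(sprintf("  variance = %.4g + %.4g * mean,  Pearson r = %.3f\n",
              x$intercept, x$slope, x$r))
  if (x$n_excluded) cat("  excluded features:", x$n_excluded, "\n")
  invisible(x)
}

#' @export
coef.meanvar_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
plot.meanvar_fit <- function(x, ...) {
  graphics::plot(x$data$mean, x$data$variance,
                 xlab = paste0("feature mean (", x$scale, ")"),
                 ylab = paste0("feature variance (", x$scale, ")"),
                 main = sprintf("group '%s': r = %.3f", x$group, x$r), ...)
  graphics::abline(x$intercept, x$slope, col = "red3", lwd = 2)
  invisible(x)
}

#' PCA score coordinates for selected groups
#'
#' Standard sample-space principal component analysis of a feature table:
#' features are mean-centered and (by default) unit-variance scaled across
#' the selected samples, zero-variance features dropped, and the samples
#' projected onto the leading components. Used for the usual score plot in
#' which a canalized (stressed) group clusters more tightly than its
#' control.
#'
#' @param table a [feature_table].
#' @param design a [sample_design].
#' @param groups character vector of group labels to include.
#' @param n_components number of components (must not exceed
#'   min(samples - 1, features)).
#' @param autoscale unit-variance scale features before the decomposition
#'   (default TRUE; mixed-magnitude omics features otherwise let the most
#'   intense features dominate).
#' @return Object of class `rva_pca`: list with `scores` (samples x
#'   components), `group` (per-sample labels), `explained` (variance
#'   fractions) and `n_dropped` (zero-variance or incomplete features).
#' @export
pca_scores <- function(table, design, groups, n_components = 2L,
                       autoscale = TRUE) {
  ids <- unlist(lapply(groups, function(g) group_samples(design, table, g)))
  if (length(ids) < 2L) stop("need >= 2 samples across the chosen groups")
  m <- table$values[, ids, drop = FALSE]
  keep <- rowSums(is.na(m)) == 0L
  m <- m[keep, , drop = FALSE]
  sds <- apply(m, 1L, stats::sd)
  m <- m[sds > 0, , drop = FALSE]
  n_dropped <- nrow(table$values) - nrow(m)
  max_comp <- min(ncol(m) - 1L, nrow(m))
  if (n_components > max_comp)
    stop("n_components = ", n_components, " exceeds min(samples - 1, features) = ",
         max_comp)
  pc <- stats::prcomp(t(m), center = TRUE, scale. = autoscale)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x[, seq_len(n_components), drop = FALSE],
                 group = design$group[match(ids, design$sample_id)],
                 explained = expl[seq_len(n_components)],
                 n_dropped = n_dropped),
            class = "rva_pca")
}

#' @export
print.rva_pca <- function(x, ...) {
  cat("PCA scores:", nrow(x$scores), "samples,",
      ncol(x$scores), "components\n")
  cat("  explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.rva_pca <- function(x, ...) {
  grp <- factor(x$group)
  graphics::plot(x$scores[, 1L], x$scores[, 2L], col = as.integer(grp),
                 pch = 19,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * x$explained[1L]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * x$explained[2L]), ...)
  graphics::legend("topright", legend = levels(grp),
                   col = seq_along(levels(grp)), pch = 19, bty = "n")
  invisible(x)
}
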