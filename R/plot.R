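#' Overlaid kernel-density plot of CV profiles
#'
#' The standard distribution-profile figure: CV (%) on the x axis, density
#' on the y axis, one unit-area kernel-density curve per group. A canalized
#' group draws a taller, narrower curve peaked at a lower CV than its
#' control.
#'
#' @param profiles list of non-empty [cv_profile] objects.
#' @param out optional path; when given, a PNG is written there instead of
#'   drawing on the current device.
#' @param bw kernel bandwidth passed to [stats::density()] (default
#'   `"nrd0"`, Scott-type rule).
#' @param xlim optional x range; default covers all profiles.
#' @param ... further arguments to [graphics::plot()].
#' @return invisibly, a data frame with one row per profile: `group`,
#'   `peak_cv` (CV at the density maximum) and `peak_density`.
#' @export
plot_cv_profiles <- function(profiles, out = NULL, bw = "nrd0",
                             xlim = NULL, ...) {
  if (inherits(profiles, "cv_profile")) profiles <- list(profiles)
  if (!length(profiles)) stop("no profiles to plot")
  for (p in profiles) {
    if (!inherits(p, "cv_profile")) stop("'profiles' must be cv_profile objects")
    if (!length(p$cv)) stop("empty profile: '", p$group, "'")
  }
  dens <- lapply(profiles, function(p) {
    # a zero-variance profile (all features at one CV) has no data-driven
    # bandwidth; fall back to a 1-percentage-point kernel
    if (stats::var(p$cv) == 0) stats::density(p$cv, bw = 1)
    else stats::density(p$cv, bw = bw)
  })
  peaks <- data.frame(
    group = vapply(profiles, function(p) p$group, character(1L)),
    peak_cv = vapply(dens, function(d) d$x[which.max(d$y)], numeric(1L)),
    peak_density = vapply(dens, function(d) max(d$y), numeric(1L)),
    stringsAsFactors = FALSE)
  if (!is.null(out)) {
    grDevices::png(out, width = 900, height = 600, res = 120)
    on.exit(grDevices::dev.off())
  }
  if (is.null(xlim))
    xlim <- range(unlist(lapply(dens, function(d) d$x)))
  ylim <- c(0, max(peaks$peak_density))
  cols <- grDevices::hcl.colors(max(2L, length(dens)), "Dark 2")
  graphics::plot(NA, xlim = xlim, ylim = ylim, xlab = "CV (%)",
                 ylab = "density", ...)
  for (i in seq_along(dens))
    graphics::lines(dens[[i]], col = cols[i], lwd = 2)
  graphics::legend("topright", legend = peaks$group,
                   col = cols[seq_along(dens)], lwd = 2, bty = "n")
  invisible(peaks)
}
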