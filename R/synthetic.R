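#' Specification for the synthetic control/stress generator
#'
#' Describes a control/stress pair of replicate tables with known ground
#' truth. Feature means are log-normal (exp of Normal(mu_log, sigma_log)),
#' shared by both groups; per-feature control CVs are drawn
#' Normal(cv_center, cv_spread), truncated below at 0.01 (clamped); the
#' stress group's per-feature CVs are the control CVs multiplied by the
#' canalization factor c in (0, 1] — c < 1 shrinks both the location and
#' the spread of the CV distribution at once, which is the empirical
#' signature of acute-stress canalization (profiles both lower and
#' narrower). Replicate values are Normal(mean, mean * CV).
#'
#' Defaults emulate a global LC-MS metabolomics experiment of the scale used
#' in acute-stress studies: 2000 features, 8 biological replicates per
#' group, and a control CV distribution centered at 67% (the unstressed
#' wild-oat metabolome's median CV) with spread 25%.
#'
#' @param n_features number of features (default 2000).
#' @param n_replicates replicates per group (default 8).
#' @param mu_log,sigma_log log-scale mean parameters of the feature means
#'   (defaults 14 and 1.5, typical of TOF MS intensity scales).
#' @param cv_center control-group mean CV as a fraction (default 0.67).
#' @param cv_spread SD of the per-feature CV distribution (default 0.25).
#' @param canalization factor c in (0, 1] applied to every control CV in the
#'   stress group (default 1 = no canalization).
#' @param timepoints optional recovery course: data frame or list with
#'   `hours` and `c` (canalization per timepoint); `c` must be
#'   non-decreasing toward 1 over time.
#' @param seed integer seed (required: generated tables are fixtures and
#'   must be reproducible).
#' @return object of class `generator_spec`.
#' @export
generator_spec <- function(n_features = 2000L, n_replicates = 8L,
                           mu_log = 14, sigma_log = 1.5,
                           cv_center = 0.67, cv_spread = 0.25,
                           canalization = 1, timepoints = NULL, seed) {
  if (canalization <= 0 || canalization > 1)
    stop("canalization must be in (0, 1]")
  if (cv_center <= 0) stop("cv_center must be > 0")
  if (cv_spread < 0) stop("cv_spread must be >= 0")
  if (n_features < 1L || n_replicates < 3L)
    stop("need n_features >= 1 and n_replicates >= 3")
  if (!is.null(timepoints)) {
    timepoints <- as.data.frame(timepoints)
    if (!all(c("hours", "c") %in% colnames(timepoints)))
      stop("timepoints needs columns 'hours' and 'c'")
    timepoints <- timepoints[order(timepoints$hours), , drop = FALSE]
    if (any(timepoints$c <= 0 | timepoints$c > 1))
      stop("timepoint canalization factors must be in (0, 1]")
    if (is.unsorted(timepoints$c))
      stop("recovery course requires c(t) non-decreasing toward 1")
  }
  structure(list(n_features = as.integer(n_features),
                 n_replicates = as.integer(n_replicates),
                 mu_log = mu_log, sigma_log = sigma_log,
                 cv_center = cv_center, cv_spread = cv_spread,
                 canalization = canalization, timepoints = timepoints,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

# one group's replicate matrix given per-feature means and CVs
draw_group <- function(means, cvs, n_replicates, sample_prefix) {
  n <- length(means)
  x <- matrix(stats::rnorm(n * n_replicates, mean = means, sd = means * cvs),
              nrow = n, ncol = n_replicates)
  x[x < 0] <- 0   # clip at the detection floor; abundances are nonnegative
  colnames(x) <- paste0(sample_prefix, seq_len(n_replicates))
  x
}

#' Generate a control/stress table pair with known canalization
#'
#' @param spec a [generator_spec].
#' @return list with `table` (a [feature_table] holding both groups'
#'   samples), `design` (a [sample_design] with groups `"control"` and
#'   `"stress"`), and `truth` (list: per-feature `means`, `cv_control`,
#'   `cv_stress`, and `canalization`).
#' @examples
#' g <- generate_pair(generator_spec(n_features = 100, n_replicates = 6,
#'                                   canalization = 0.5, seed = 7))
#' rva(g$table, g$design, "control", "stress")
#' @export
generate_pair <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  means <- exp(stats::rnorm(spec$n_features, spec$mu_log, spec$sigma_log))
  cv_ctrl <- pmax(stats::rnorm(spec$n_features, spec$cv_center,
                               spec$cv_spread), 0.01)
  cv_str <- spec$canalization * cv_ctrl
  vals <- cbind(draw_group(means, cv_ctrl, spec$n_replicates, "ctrl_"),
                draw_group(means, cv_str, spec$n_replicates, "str_"))
  rownames(vals) <- sprintf("feat_%04d", seq_len(spec$n_features))
  tab <- feature_table(vals)
  des <- sample_design(colnames(vals),
                       rep(c("control", "stress"), each = spec$n_replicates))
  list(table = tab, design = des,
       truth = list(means = means, cv_control = cv_ctrl, cv_stress = cv_str,
                    canalization = spec$canalization))
}

#' Generate a stress-recovery time course
#'
#' One replicate group per timepoint, each with canalization c(t) applied to
#' the same per-feature control CVs, plus an unstressed reference group with
#' c = 1. Mirrors a recovery experiment where the stressed CV distribution
#' relaxes back toward the control's over time.
#'
#' @param spec a [generator_spec] with non-empty `timepoints`.
#' @return list with `table`, `design` (reference group `"reference"`,
#'   timepoint groups `"t<hours>"` with timepoints in the design), and
#'   `truth`.
#' @export
generate_timecourse <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  if (is.null(spec$timepoints) || !nrow(spec$timepoints))
    stop("spec has no timepoints")
  set.seed(spec$seed)
  means <- exp(stats::rnorm(spec$n_features, spec$mu_log, spec$sigma_log))
  cv_ctrl <- pmax(stats::rnorm(spec$n_features, spec$cv_center,
                               spec$cv_spread), 0.01)
  tp <- spec$timepoints
  groups <- paste0("t", tp$hours)
  blocks <- c(list(draw_group(means, cv_ctrl, spec$n_replicates, "ref_")),
              lapply(seq_len(nrow(tp)), function(i)
                draw_group(means, tp$c[i] * cv_ctrl, spec$n_replicates,
                           paste0(groups[i], "_"))))
  vals <- do.call(cbind, blocks)
  rownames(vals) <- sprintf("feat_%04d", seq_len(spec$n_features))
  des <- sample_design(colnames(vals),
                       rep(c("reference", groups), each = spec$n_replicates),
                       timepoint = rep(c(NA, tp$hours), each = spec$n_replicates))
  list(table = feature_table(vals), design = des,
       truth = list(means = means, cv_control = cv_ctrl,
                    timepoints = tp))
}

#' Write a generated dataset to table + design files
#'
#' @param generated result of [generate_pair()] or [generate_timecourse()].
#' @param prefix output path prefix; writes `<prefix>_table.tsv` and
#'   `<prefix>_design.tsv`.
#' @return invisibly, the two paths.
#' @export
write_generated <- function(generated, prefix) {
  tab_path <- paste0(prefix, "_table.tsv")
  des_path <- paste0(prefix, "_design.tsv")
  vals <- generated$table$values
  df <- data.frame(feature_id = rownames(vals),
                   signif(vals, 10), check.names = FALSE)
  utils::write.table(df, tab_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(generated$design), des_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(table = tab_path, design = des_path))
}
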