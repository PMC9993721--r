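#' Two-sample Kolmogorov-Smirnov statistic and asymptotic p-value
#'
#' d is the supremum over t of |Fx(t) - Fy(t)| for the two right-continuous
#' empirical CDFs, evaluated at the pooled sample values. The p-value uses
#' the two-sided asymptotic Kolmogorov distribution with effective sample
#' size n*m/(n+m) — CV profiles routinely hold thousands of features, where
#' the exact distribution is both unnecessary and expensive. A larger d
#' means a larger difference in shape and/or location between the two
#' distributions.
#'
#' Ties violate the continuity assumption of the K-S test; when present, the
#' statistic is still the exact ECDF supremum (differences are taken at the
#' last index of each tied run) but a warning is emitted.
#'
#' @param x,y numeric vectors, each with >= 3 finite values.
#' @return list with elements `d` (in \[0, 1\]) and `p` (in (0, 1\]).
#' @examples
#' ks_two_sample(c(1, 2, 3, 4), c(2.5, 3.5, 4.5))$d
#' @export
ks_two_sample <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 3L || any(!is.finite(x)))
    stop("'x' needs >= 3 finite values")
  if (length(y) < 3L || any(!is.finite(y)))
    stop("'y' needs >= 3 finite values")
  d <- ks_statistic(x, y)
  n_eff <- length(x) * length(y) / (length(x) + length(y))
  p <- 1 - pkolmogorov(sqrt(n_eff) * d)
  p <- min(1, max(p, .Machine$double.xmin))
  list(d = d, p = p)
}

# ECDF-sup statistic; pooled-order cumulative-difference formulation.
# At tied pooled values only the last position of the tie run is a valid
# evaluation point of Fx - Fy.
ks_statistic <- function(x, y) {
  n_x <- length(x); n_y <- length(y)
  w <- c(x, y)
  ord <- order(w)
  z <- cumsum(ifelse(ord <= n_x, 1 / n_x, -1 / n_y))
  ws <- w[ord]
  if (anyDuplicated(ws)) {
    warning("ties present in K-S input; the test assumes continuous distributions")
    keep <- c(diff(ws) != 0, TRUE)
    z <- z[keep]
  }
  max(abs(z))
}

# Asymptotic CDF of the Kolmogorov distribution, K(t) = P(sup|B(s)| <= t).
pkolmogorov <- function(t) {
  if (t <= 0) return(0)
  k <- seq_len(100L)
  1 - 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
}

#' Wilcoxon test between two CV profiles
#'
#' Matched mode runs a two-sided Wilcoxon signed-rank test on the paired
#' per-feature CV differences (zero differences dropped, tied ranks
#' mid-ranked, as in [stats::wilcox.test]); the vectors must then be aligned
#' on shared feature ids. Unmatched mode runs the two-sided Wilcoxon
#' rank-sum test. If all matched differences are zero the test is degenerate:
#' p = 1 is returned with a warning.
#'
#' @param cv_a,cv_b numeric CV vectors (percent).
#' @param matched if `TRUE` (default), vectors are feature-aligned pairs.
#' @return p-value in (0, 1].
#' @export
wilcoxon_cv_test <- function(cv_a, cv_b, matched = TRUE) {
  cv_a <- as.numeric(cv_a); cv_b <- as.numeric(cv_b)
  if (matched) {
    if (length(cv_a) != length(cv_b))
      stop("matched mode needs equal-length, feature-aligned vectors")
    if (all(cv_a == cv_b)) {
      warning("degenerate paired test: all CV differences are zero; p = 1")
      return(1)
    }
    p <- suppressWarnings(
      stats::wilcox.test(cv_a, cv_b, paired = TRUE, alternative = "two.sided")$p.value)
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(cv_a, cv_b, alternative = "two.sided")$p.value)
  }
  min(1, max(p, .Machine$double.xmin))
}

#' Compare two CV profiles (replicate variation analysis)
#'
#' The core comparison: how does the distribution of per-feature CVs differ
#' between two replicate groups? Acute stress canalizes variation — the
#' stressed group's CV distribution narrows and shifts toward lower CVs —
#' which shows up as a large K-S d with the stressed mean/median CV below
#' the control's.
#'
#' The Wilcoxon test runs in matched (signed-rank) mode over the
#' intersection of feature ids, falling back to the unmatched rank-sum test
#' when fewer than 3 features are shared.
#'
#' @param profile_a,profile_b [cv_profile] objects (conventionally a =
#'   control, b = treatment).
#' @return Object of class `rva_comparison` with fields `group_a`,
#'   `group_b`, `ks_d`, `ks_p`, `wilcoxon_p`, `wilcoxon_mode`, `mean_cv_a`,
#'   `mean_cv_b`, `median_cv_a`, `median_cv_b`, `n_features_a`,
#'   `n_features_b`, `n_matched`.
#' @seealso [rva()] for the one-call interface from a table and design.
#' @export
rva_compare <- function(profile_a, profile_b) {
  stopifnot(inherits(profile_a, "cv_profile"), inherits(profile_b, "cv_profile"))
  if (!length(profile_a$cv) || !length(profile_b$cv))
    stop("empty profile")
  ks <- ks_two_sample(profile_a$cv, profile_b$cv)
  shared <- intersect(profile_a$feature_ids, profile_b$feature_ids)
  if (length(shared) >= 3L) {
    ia <- match(shared, profile_a$feature_ids)
    ib <- match(shared, profile_b$feature_ids)
    wp <- wilcoxon_cv_test(profile_a$cv[ia], profile_b$cv[ib], matched = TRUE)
    mode <- "matched"
  } else {
    wp <- wilcoxon_cv_test(profile_a$cv, profile_b$cv, matched = FALSE)
    mode <- "unmatched"
  }
  structure(list(group_a = profile_a$group, group_b = profile_b$group,
                 ks_d = ks$d, ks_p = ks$p,
                 wilcoxon_p = wp, wilcoxon_mode = mode,
                 mean_cv_a = unname(profile_a$summary[["mean_cv"]]),
                 mean_cv_b = unname(profile_b$summary[["mean_cv"]]),
                 median_cv_a = unname(profile_a$summary[["median_cv"]]),
                 median_cv_b = unname(profile_b$summary[["median_cv"]]),
                 n_features_a = length(profile_a$cv),
                 n_features_b = length(profile_b$cv),
                 n_matched = length(shared)),
            class = "rva_comparison")
}

#' Replicate variation analysis of two groups in one call
#'
#' Convenience wrapper: computes both groups' CV profiles from a feature
#' table and design, then compares them with [rva_compare()].
#'
#' @param table a [feature_table].
#' @param design a [sample_design].
#' @param control,treatment group labels.
#' @return An `rva_comparison` (a of the comparison is the control group).
#' @examples
#' g <- generate_pair(generator_spec(n_features = 200, n_replicates = 6,
#'                                   canalization = 0.5, seed = 1))
#' rva(g$table, g$design, control = "control", treatment = "stress")
#' @export
rva <- function(table, design, control, treatment) {
  rva_compare(cv_profile(table, design, control),
              cv_profile(table, design, treatment))
}

#' @export
print.rva_comparison <- function(x, ...) {
  cat(sprintf("Replicate variation analysis: %s (a) vs %s (b)\n",
              x$group_a, x$group_b))
  cat(sprintf("  K-S d = %.5g, p = %.3g\n", x$ks_d, x$ks_p))
  cat(sprintf("  Wilcoxon (%s) p = %.3g\n", x$wilcoxon_mode, x$wilcoxon_p))
  cat(sprintf("  mean CV   %.1f%% -> %.1f%%\n", x$mean_cv_a, x$mean_cv_b))
  cat(sprintf("  median CV %.1f%% -> %.1f%%\n", x$median_cv_a, x$median_cv_b))
  cat(sprintf("  features: %d (a), %d (b), %d matched\n",
              x$n_features_a, x$n_features_b, x$n_matched))
  invisible(x)
}

#' @export
summary.rva_comparison <- function(object, ...) {
  cat(sprintf(
    "CV distribution of '%s' is %s relative to '%s' (K-S d = %.3g, p = %.3g).\n",
    object$group_b,
    if (object$median_cv_b < object$median_cv_a) "canalized (narrower/lower)"
    else "not reduced",
    object$group_a, object$ks_d, object$ks_p))
  invisible(as.data.frame(object))
}

#' @export
as.data.frame.rva_comparison <- function(x, ...) {
  data.frame(group_a = x$group_a, group_b = x$group_b,
             ks_d = x$ks_d, ks_p = x$ks_p,
             wilcoxon_p = x$wilcoxon_p, wilcoxon_mode = x$wilcoxon_mode,
             mean_cv_a = x$mean_cv_a, mean_cv_b = x$mean_cv_b,
             median_cv_a = x$median_cv_a, median_cv_b = x$median_cv_b,
             n_features_a = x$n_features_a, n_features_b = x$n_features_b,
             n_matched = x$n_matched, stringsAsFactors = FALSE)
}

#' Per-feature delta-CV table
#'
#' One row per feature shared by the two profiles, with its CV in each
#' group, the difference delta = cv_b - cv_a, and whether the feature's CV
#' is strictly smaller in group b (ties count as not lower). With an
#' annotation map, per-category counts of lower-in-b features are attached —
#' the "pathway lens" view of which functional classes canalized.
#'
#' @param profile_a,profile_b [cv_profile] objects sharing >= 1 feature id.
#' @param annotations optional named character vector, feature id -> category.
#' @return data frame of class `delta_cv_table` with columns `feature_id`,
#'   `cv_a`, `cv_b`, `delta`, `lower_in_b` and optionally `category`;
#'   attributes `n_lower` and (if annotated) `category_counts`.
#' @export
delta_cv_table <- function(profile_a, profile_b, annotations = NULL) {
  stopifnot(inherits(profile_a, "cv_profile"), inherits(profile_b, "cv_profile"))
  shared <- intersect(profile_a$feature_ids, profile_b$feature_ids)
  if (!length(shared)) stop("profiles share no feature ids")
  cv_a <- profile_a$cv[match(shared, profile_a$feature_ids)]
  cv_b <- profile_b$cv[match(shared, profile_b$feature_ids)]
  out <- data.frame(feature_id = shared, cv_a = cv_a, cv_b = cv_b,
                    delta = cv_b - cv_a, lower_in_b = cv_b < cv_a,
                    stringsAsFactors = FALSE)
  if (!is.null(annotations)) {
    out$category <- unname(annotations[out$feature_id])
    tab <- table(category = out$category, lower_in_b = out$lower_in_b)
    attr(out, "category_counts") <- tab
  }
  attr(out, "n_lower") <- sum(out$lower_in_b)
  class(out) <- c("delta_cv_table", "data.frame")
  out
}

#' @export
print.delta_cv_table <- function(x, ...) {
  cat(sprintf("Delta-CV table: %d of %d shared features have a smaller CV in '%s'\n",
              attr(x, "n_lower"), nrow(x), "group b"))
  if (!is.null(attr(x, "category_counts"))) {
    cat("Per-category counts (lower_in_b):\n")
    print(attr(x, "category_counts"))
  }
  NextMethod()
}

#' Recompute the pyrite-vs-sulfide methanogen proteome statistics
#'
#' Runs the full matched comparison on a supplementary per-protein CV table
#' for *Methanococcus voltae* grown on Fe(II)/HS- (sulfide) versus FeS2
#' (pyrite): two-sample K-S d and p, the mean/median CV of each condition,
#' the paired Wilcoxon p, and the count of proteins with a strictly smaller
#' CV under pyrite. The table itself is distributed as journal supplementary
#' material and is not bundled here; export it to a delimited file with
#' columns `protein_id`, `cv_sulfide`, `cv_pyrite` (CVs in percent).
#'
#' @param path path to the exported per-protein CV table (TSV or CSV).
#' @return list with `comparison` (an `rva_comparison`), `delta`
#'   (a [delta_cv_table]), `n_lower_pyrite` and `n_shared`.
#' @export
reproduce_mvoltae <- function(path) {
  if (!file.exists(path))
    stop("per-protein CV table not found: ", path,
         "\nExport the supplementary 'Protein CVs' table with columns ",
         "protein_id, cv_sulfide, cv_pyrite")
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  need <- c("protein_id", "cv_sulfide", "cv_pyrite")
  if (!all(need %in% colnames(d)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  d <- d[stats::complete.cases(d[need]), ]
  sulfide <- cv_profile_from_values(d$cv_sulfide, d$protein_id, "sulfide")
  pyrite <- cv_profile_from_values(d$cv_pyrite, d$protein_id, "pyrite")
  cmp <- rva_compare(sulfide, pyrite)
  dl <- delta_cv_table(sulfide, pyrite)
  list(comparison = cmp, delta = dl,
       n_lower_pyrite = attr(dl, "n_lower"), n_shared = nrow(dl))
}
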