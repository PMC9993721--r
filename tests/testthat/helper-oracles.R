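# Independent oracles and tiny fixtures used across the suite.

# Brute-force two-sample K-S statistic: evaluate |Fx - Fy| at every data
# point from both samples (right-continuous ECDFs).
brute_force_ks_d <- function(x, y) {
  pts <- c(x, y)
  max(vapply(pts, function(t) abs(mean(x <= t) - mean(y <= t)), numeric(1L)))
}

# Exact two-sided signed-rank p by exhaustive enumeration of all 2^n sign
# assignments (no zeros, no tied |d| assumed).
signed_rank_exact_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% r
  p <- 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs))
  min(1, p)
}

# Feature table from a plain matrix with auto ids.
toy_table <- function(values, feature_ids = NULL, sample_ids = NULL) {
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(values)))
  dimnames(values) <- list(feature_ids, sample_ids)
  feature_table(values)
}

toy_design <- function(table, groups_per_sample) {
  sample_design(table$sample_ids, groups_per_sample)
}

# Replicate triple with exact mean m and sample variance v.
triple_with <- function(m, v) c(m - sqrt(v), m, m + sqrt(v))

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
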