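test_that("exactly linear mean-variance data recover slope and r = 1", {
  mus <- c(10, 20, 40, 80)
  vals <- t(vapply(mus, function(m) triple_with(m, 0.1 * m), numeric(3)))
  tab <- toy_table(vals)
  des <- toy_design(tab, rep("g", 3))
  fit <- mean_variance_fit(tab, des, "g")
  expect_equal(fit$slope, 0.1, tolerance = 1e-10)
  expect_equal(fit$intercept, 0, tolerance = 1e-8)
  expect_equal(fit$r, 1, tolerance = 1e-10)
})

test_that("the three-point toy fit matches the normal equations", {
  # (mu, s^2) = (1,1), (2,2), (3,4): slope 3/2, intercept 7/3 - 3 = -2/3
  vals <- rbind(triple_with(1, 1), triple_with(2, 2), triple_with(3, 4))
  tab <- toy_table(vals)
  des <- toy_design(tab, rep("g", 3))
  fit <- mean_variance_fit(tab, des, "g")
  expect_equal(fit$slope, 1.5, tolerance = 1e-10)
  expect_equal(fit$intercept, -2 / 3, tolerance = 1e-10)
  expect_equal(coef(fit), c(intercept = -2 / 3, slope = 1.5), tolerance = 1e-10)
})

test_that("constant-CV synthetic data show the strongly positive relationship", {
  g <- generate_pair(generator_spec(n_features = 1000, n_replicates = 8,
                                    cv_center = 0.3, cv_spread = 0.02,
                                    seed = 81))
  # raw scale: the direction that excludes the intensity artifact
  fit <- mean_variance_fit(g$table, g$design, "control")
  expect_gt(fit$slope, 0)
  expect_gt(fit$r, 0)
  # log10 scale: constant CV means var ~ cv^2 * mu^2, i.e. slope ~ 2 and a
  # tight linear law (the raw-scale Pearson r is attenuated by the
  # chi-square noise of per-feature variances over few replicates)
  lfit <- mean_variance_fit(g$table, g$design, "control", scale = "log10")
  expect_equal(lfit$slope, 2, tolerance = 0.1)
  expect_gt(lfit$r, 0.95)
})

test_that("log10 scale excludes degenerate features and small fits abort", {
  vals <- rbind(triple_with(10, 2), triple_with(20, 3), triple_with(30, 4),
                c(5, 5, 5),          # zero variance
                c(0, 0, 0))          # zero mean
  tab <- toy_table(vals)
  des <- toy_design(tab, rep("g", 3))
  fit <- mean_variance_fit(tab, des, "g", scale = "log10")
  expect_identical(fit$n_features, 3L)
  expect_identical(fit$n_excluded, 2L)

  small <- toy_table(matrix(runif(6, 1, 5), 2, 3))
  expect_error(mean_variance_fit(small, toy_design(small, rep("g", 3)), "g"),
               "fewer than 3 usable features")
})

test_that("duplicated samples land on identical PCA scores", {
  set.seed(82)
  vals <- matrix(runif(40, 1, 100), 10, 4)
  vals[, 4] <- vals[, 3]   # s4 duplicates s3
  tab <- toy_table(vals)
  des <- toy_design(tab, rep("g", 4))
  pc <- pca_scores(tab, des, "g", n_components = 2)
  expect_equal(pc$scores[3, ], pc$scores[4, ], tolerance = 1e-10)
  expect_true(all(pc$explained >= 0) && sum(pc$explained) <= 1 + 1e-10)
})

test_that("a dominant rank-1 axis captures over 90% of the variance", {
  set.seed(83)
  n_feat <- 60; n_samp <- 12
  t_s <- seq(-2, 2, length.out = n_samp)
  load <- runif(n_feat, 0.5, 2)
  vals <- 100 + outer(load, t_s) + matrix(rnorm(n_feat * n_samp, 0, 0.02),
                                          n_feat, n_samp)
  tab <- toy_table(vals)
  des <- toy_design(tab, rep("g", n_samp))
  pc <- pca_scores(tab, des, "g", n_components = 3)
  expect_gt(pc$explained[1], 0.9)
})

test_that("scores are sample-order invariant up to per-axis sign", {
  set.seed(84)
  g <- generate_pair(generator_spec(n_features = 200, n_replicates = 5,
                                    canalization = 0.5, seed = 84))
  pc1 <- pca_scores(g$table, g$design, c("control", "stress"))
  perm <- sample(ncol(g$table$values))
  tab2 <- feature_table(g$table$values[, perm])
  pc2 <- pca_scores(tab2, g$design, c("control", "stress"))
  m2 <- pc2$scores[match(rownames(pc1$scores), rownames(pc2$scores)), ]
  for (k in 1:2) {
    flip <- sign(sum(pc1$scores[, k] * m2[, k]))
    expect_equal(pc1$scores[, k], flip * m2[, k], tolerance = 1e-8)
  }
  expect_equal(pc1$explained, pc2$explained, tolerance = 1e-10)
})

test_that("a canalized group clusters more tightly in score space", {
  g <- generate_pair(generator_spec(n_features = 500, n_replicates = 8,
                                    canalization = 0.3, seed = 85))
  pc <- pca_scores(g$table, g$design, c("control", "stress"))
  disp <- function(grp) {
    s <- pc$scores[pc$group == grp, ]
    mean(sqrt(rowSums(scale(s, scale = FALSE)^2)))
  }
  expect_lt(disp("stress"), disp("control"))
})

test_that("component counts beyond the data rank are refused", {
  tab <- toy_table(matrix(runif(30, 1, 10), 10, 3))
  des <- toy_design(tab, rep("g", 3))
  expect_error(pca_scores(tab, des, "g", n_components = 3), "exceeds")
})
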