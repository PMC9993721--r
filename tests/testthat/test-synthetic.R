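test_that("identical generator specs give bit-identical tables", {
  spec <- generator_spec(n_features = 80, n_replicates = 4,
                         canalization = 0.5, seed = 101)
  g1 <- generate_pair(spec)
  g2 <- generate_pair(spec)
  expect_identical(g1$table$values, g2$table$values)
  expect_identical(g1$truth, g2$truth)
  g3 <- generate_pair(generator_spec(n_features = 80, n_replicates = 4,
                                     canalization = 0.5, seed = 102))
  expect_false(identical(g1$table$values, g3$table$values))
})

test_that("the truth record matches its own construction rules", {
  g <- generate_pair(generator_spec(n_features = 500, n_replicates = 6,
                                    canalization = 0.7, seed = 103))
  expect_equal(g$truth$cv_stress, 0.7 * g$truth$cv_control)
  expect_true(all(g$truth$cv_control >= 0.01))
  expect_true(all(g$truth$means > 0))
  expect_identical(dim(g$table$values), c(500L, 12L))
  expect_identical(sort(unique(g$design$group)), c("control", "stress"))
})

test_that("the stress-to-control median CV ratio tracks the canalization factor", {
  g <- generate_pair(generator_spec(canalization = 0.5, n_features = 2000,
                                    n_replicates = 8, seed = 104))
  cmp <- rva(g$table, g$design, "control", "stress")
  expect_equal(cmp$median_cv_b / cmp$median_cv_a, 0.5, tolerance = 0.1)
})

test_that("without canalization the comparison raises no false alarm", {
  ps <- vapply(1:20, function(s) {
    g <- generate_pair(generator_spec(n_features = 500, n_replicates = 8,
                                      seed = 110 + s))
    rva(g$table, g$design, "control", "stress")$ks_p
  }, numeric(1))
  # shared per-feature true CVs pair the two groups, so if anything the
  # test is conservative; rejections at 0.05 should stay rare
  expect_lte(sum(ps < 0.05), 3)
})

test_that("time courses cover the reference plus each requested timepoint", {
  tp <- data.frame(hours = c(0, 6, 24, 48, 100), c = c(0.4, 0.5, 0.7, 0.9, 1))
  tc <- generate_timecourse(generator_spec(n_features = 60, n_replicates = 4,
                                           timepoints = tp, seed = 105))
  expect_identical(sort(unique(tc$design$group)),
                   sort(c("reference", paste0("t", tp$hours))))
  expect_identical(sort(unique(tc$design$timepoint[!is.na(tc$design$timepoint)])),
                   tp$hours)
  expect_identical(dim(tc$table$values), c(60L, 24L))
  expect_identical(tc$truth$timepoints$c, tp$c)
})

test_that("invalid generator specifications are rejected", {
  expect_error(generator_spec(canalization = 0, seed = 1), "canalization")
  expect_error(generator_spec(canalization = 1.2, seed = 1), "canalization")
  expect_error(generator_spec(cv_center = -1, seed = 1), "cv_center")
  expect_error(generator_spec(n_replicates = 2, seed = 1), "n_replicates >= 3")
  expect_error(generator_spec(timepoints = data.frame(hours = c(0, 6),
                                                      c = c(0.9, 0.4)),
                              seed = 1),
               "non-decreasing")
  expect_error(generate_timecourse(generator_spec(seed = 1)), "no timepoints")
})

test_that("generated datasets round-trip through their file representation", {
  g <- generate_pair(generator_spec(n_features = 40, n_replicates = 4,
                                    canalization = 0.6, seed = 106))
  prefix <- file.path(withr::local_tempdir(), "demo")
  paths <- write_generated(g, prefix)
  tab <- read_feature_table(paths[["table"]])
  des <- read_design(paths[["design"]])
  expect_identical(dim(tab), dim(g$table))
  cmp_file <- rva(tab, des, "control", "stress")
  cmp_mem <- rva(g$table, g$design, "control", "stress")
  expect_equal(cmp_file$ks_d, cmp_mem$ks_d, tolerance = 1e-6)
  expect_equal(cmp_file$median_cv_b, cmp_mem$median_cv_b, tolerance = 1e-4)
})
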