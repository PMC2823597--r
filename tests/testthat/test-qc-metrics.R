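test_that("replicate SD computes group-wise means and sample SDs", {
  m <- rbind(gA = c(1, 1, 1, 1), gB = c(0, 2, 5, 5))
  colnames(m) <- paste0("a", 1:4)
  groups <- c(a1 = "X", a2 = "X", a3 = "Y", a4 = "Y")
  prof <- replicate_sd(m, groups)
  expect_named(prof, c("X", "Y"))
  expect_equal(prof$X$mean_log2, c(1, 1))
  expect_equal(prof$X$sd_log2, c(0, sqrt(2)))
  expect_equal(prof$Y$sd_log2, c(0, 0))
  # shifting one group's arrays moves the mean, not the SD
  m2 <- m; m2[, c("a1", "a2")] <- m2[, c("a1", "a2")] + 3
  prof2 <- replicate_sd(m2, groups)
  expect_equal(prof2$X$mean_log2, prof$X$mean_log2 + 3)
  expect_equal(prof2$X$sd_log2, prof$X$sd_log2)
  expect_error(replicate_sd(m, c(a1 = "X", a2 = "Y", a3 = "Y", a4 = "Y")),
               "fewer than 2")
})

test_that("spline trend reproduces affine data and constant data exactly", {
  set.seed(21)
  x <- sort(runif(60, 0, 10))
  line <- data.frame(mean_log2 = x, sd_log2 = 0.3 + 0.2 * x)
  tr <- fit_sd_trend(line)
  expect_equal(tr$fitted$y, 0.3 + 0.2 * tr$fitted$x, tolerance = 1e-9)
  flat <- data.frame(mean_log2 = x, sd_log2 = rep(0.7, 60))
  expect_equal(fit_sd_trend(flat)$fitted$y, rep(0.7, 100), tolerance = 1e-9)
  expect_equal(length(tr$knots), 5L)
  expect_error(fit_sd_trend(data.frame(mean_log2 = rep(1, 60),
                                       sd_log2 = rep(1, 60))),
               "degenerate")
})

test_that("spline trend matches the explicit natural-basis least squares", {
  set.seed(33)
  x <- runif(500, 0, 2 * pi)
  y <- sin(x) + rnorm(500, 0, 0.2)
  tr <- fit_sd_trend(data.frame(mean_log2 = x, sd_log2 = y))
  oracle <- ns_oracle_fit(x, y, knots = tr$knots, grid = tr$fitted$x)
  expect_equal(tr$fitted$y, oracle, tolerance = 1e-8)
})

test_that("RLE centers rows on their across-array medians", {
  m1 <- matrix(c(1, 2, 3), 1L, dimnames = list("g", paste0("a", 1:3)))
  expect_equal(unname(rle_stats(m1)$rle_matrix[1, ]), c(-1, 0, 1))
  m2 <- rbind(g1 = c(4, 4 + 0.6), g2 = c(1, 1.6))
  colnames(m2) <- c("a1", "a2")
  expect_equal(unname(rle_stats(m2)$rle_matrix),
               matrix(c(-0.3, -0.3, 0.3, 0.3), 2L))
  # row medians of the RLE matrix are zero (odd array count: exactly)
  set.seed(3)
  m3 <- matrix(rnorm(35), 7L, 5L,
               dimnames = list(paste0("g", 1:7), paste0("a", 1:5)))
  r <- rle_stats(m3)$rle_matrix
  expect_equal(unname(apply(r, 1L, median)), rep(0, 7L))
  # per-array RLE sums are invariant to gene-specific constants
  m4 <- m3 + rnorm(7L)
  expect_equal(colSums(rle_stats(m4)$rle_matrix), colSums(r))
})

test_that("quantile-based routes give RLE medians near zero on synthetic data", {
  sim <- simulate_experiment(small_config(seed = 8L))
  for (mth in c("norQ", "norRMA")) {
    em <- process_arrays(sim$tables, method = mth, design = sim$design)
    s <- rle_stats(unclass(em))$summary
    expect_lt(max(abs(s$median)), 0.05)
  }
})

test_that("method comparison bundles all requested methods", {
  sim <- simulate_experiment(small_config(seed = 14L))
  groups <- sim$truth$group_of
  cmp <- compare_methods(sim$tables, groups,
                         methods = c("norQ", "norRMA"),
                         design = sim$design)
  expect_named(cmp, c("norQ", "norRMA", "sd_table"))
  expect_setequal(unique(cmp$sd_table$method), c("norQ", "norRMA"))
  expect_equal(nrow(cmp$sd_table),
               2L * 2L * length(sim$design$gene_ids))
  expect_s3_class(cmp$norQ$trends[[1L]], "SplineTrend")
})

test_that("zero-noise replicates give zero SD under every method", {
  cfg <- small_config(seed = 4L, noise_sd = 0, bg_sigma = 0)
  sim <- simulate_experiment(cfg)
  groups <- sim$truth$group_of
  for (mth in c("nor75", "norQ", "norRMA")) {
    em <- process_arrays(sim$tables, method = mth, design = sim$design)
    prof <- replicate_sd(em, groups)
    for (p in prof) expect_lt(max(p$sd_log2), 1e-10)
  }
})

test_that("low-intensity replicate SD ranks norRMA under norRMAbg", {
  # desk-scale check of the precision ordering; the full-design
  # multi-seed version lives with the acceptance checks
  hits <- 0L
  for (s in 1:3) {
    sim <- simulate_experiment(small_config(seed = 300L + s,
                                            n_arrays_per_group = 4L))
    groups <- sim$truth$group_of
    sds <- sapply(c("norRMA", "norRMAbg"), function(mth) {
      em <- process_arrays(sim$tables, method = mth, design = sim$design)
      df <- do.call(rbind, replicate_sd(em, groups))
      cut <- quantile(df$mean_log2, 1 / 3)
      mean(df$sd_log2[df$mean_log2 <= cut])
    })
    hits <- hits + (sds[["norRMA"]] < sds[["norRMAbg"]])
  }
  expect_gte(hits, 2L)
})
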