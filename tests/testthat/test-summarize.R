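test_that("replicate features collapse to per-probe medians", {
  vals <- matrix(c(1, 2, 9,  4,   # arr1: p1 replicates 1,2,9; p2 single 4
                   1, 3, 5,  6), ncol = 2L)
  tabs <- toy_experiment(vals, probes = c("p1", "p1", "p1", "p2"),
                         genes = c("g1", "g1", "g1", "g2"))
  d <- infer_design(tabs)
  fm <- assemble_features(tabs, d, channel = "bgsub")
  pm <- collapse_replicates(fm, d)
  expect_equal(pm["p1", ], c(arr1 = 2, arr2 = 3))     # odd count: middle
  expect_equal(pm["p2", ], c(arr1 = 4, arr2 = 6))     # singleton: identity
  # even count: mean of the two middle values
  vals2 <- matrix(c(1, 3, 1, 3), ncol = 2L)
  tabs2 <- toy_experiment(vals2, probes = c("p1", "p1"), genes = c("g1", "g1"))
  d2 <- infer_design(tabs2)
  pm2 <- collapse_replicates(assemble_features(tabs2, d2), d2)
  expect_equal(unname(pm2["p1", ]), c(2, 2))
})

test_that("median polish handles degenerate and additive tables exactly", {
  z <- median_polish(matrix(0, 2L, 2L))
  expect_equal(z$overall, 0)
  expect_equal(unname(z$row_effects), c(0, 0))
  expect_equal(unname(z$col_effects), c(0, 0))
  expect_equal(z$residuals, matrix(0, 2L, 2L))
  expect_true(z$converged)

  r <- c(0, 2); cc <- c(1, 5, 3)
  m <- outer(r, cc, "+")
  f <- median_polish(m)
  expect_equal(max(abs(f$residuals)), 0)
  # identifiability convention: effects have median zero
  expect_equal(median(f$row_effects), 0)
  expect_equal(median(f$col_effects), 0)
  # fitted values reproduce the additive table
  fit <- f$overall + outer(f$row_effects, f$col_effects, "+")
  expect_equal(fit, m, ignore_attr = TRUE)
})

test_that("median polish reconstruction identity is exact on random tables", {
  set.seed(13)
  for (i in 1:20) {
    m <- matrix(rnorm(30, sd = 4), 5L, 6L)
    f <- median_polish(m)
    # residuals are defined against the fit, so the identity is exact
    fit <- f$overall + outer(f$row_effects, f$col_effects, "+")
    expect_identical(f$residuals, m - fit)
    expect_lt(max(abs(fit + f$residuals - m)), 1e-12)
  }
})

test_that("median polish matches the independent classical implementation", {
  set.seed(42)
  for (i in 1:30) {
    nr <- sample(2:6, 1L); nc <- sample(2:6, 1L)
    m <- matrix(rnorm(nr * nc, sd = 3), nr, nc)
    if (i %% 5L == 0L) m[sample(nr, 1L), sample(nc, 1L)] <- 50
    f <- median_polish(m)
    o <- stats::medpolish(m, eps = 0.01, maxiter = 10L, trace.iter = FALSE)
    expect_equal(f$overall, o$overall, tolerance = 1e-12)
    expect_equal(unname(f$row_effects), unname(o$row), tolerance = 1e-12)
    expect_equal(unname(f$col_effects), unname(o$col), tolerance = 1e-12)
    expect_equal(f$residuals, o$residuals, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("summarization passes single probes through and pools identical ones", {
  pm <- rbind(g1_p1 = c(1, 2, 3),
              g2_p1 = c(5, 6, 7),
              g2_p2 = c(5, 6, 7))
  colnames(pm) <- paste0("a", 1:3)
  design <- list(gene_ids = c("g1", "g2"),
                 probes_per_gene = list(g1 = "g1_p1",
                                        g2 = c("g2_p1", "g2_p2")),
                 replicates_per_probe = c(g1_p1 = 1L, g2_p1 = 1L,
                                          g2_p2 = 1L),
                 gene_of = c(g1_p1 = "g1", g2_p1 = "g2", g2_p2 = "g2"))
  attr(pm, "gene_of") <- design$gene_of[rownames(pm)]
  em <- rma_summarize(pm, design)
  expect_equal(unname(em["g1", ]), c(1, 2, 3))
  expect_equal(unname(em["g2", ]), c(5, 6, 7))
  expect_error(rma_summarize(pm[1:2, ],
                             within(design, gene_ids <- c("g1", "g2", "g3"))),
               "absent")
})

test_that("summarization cancels probe affinities on synthetic genes", {
  set.seed(7)
  theta <- rnorm(8L, 8, 1)                    # true per-array expression
  phi <- rnorm(4L, 0, 0.8)                    # probe affinities
  pm <- outer(phi, theta, "+") + matrix(rnorm(32L, 0, 0.05), 4L)
  dimnames(pm) <- list(paste0("g1_p", 1:4), paste0("a", 1:8))
  design <- list(gene_ids = "g1",
                 probes_per_gene = list(g1 = rownames(pm)),
                 replicates_per_probe = setNames(rep(1L, 4L), rownames(pm)),
                 gene_of = setNames(rep("g1", 4L), rownames(pm)))
  attr(pm, "gene_of") <- design$gene_of
  em <- rma_summarize(pm, design)
  # recovered values track theta up to a constant (median of phi)
  resid <- em["g1", ] - theta
  expect_lt(diff(range(resid)), 0.2)
  # permuting probe rows leaves the estimate unchanged
  perm <- c(3L, 1L, 4L, 2L)
  pm2 <- pm[perm, ]
  attr(pm2, "gene_of") <- design$gene_of[perm]
  expect_equal(rma_summarize(pm2, design), em)
  # adding a constant to the probe matrix shifts the gene by that constant
  pm3 <- pm + 1.5
  attr(pm3, "gene_of") <- design$gene_of
  expect_equal(unclass(rma_summarize(pm3, design)),
               unclass(em) + 1.5)
})

test_that("total gene signal follows the robust-average formula", {
  # gene with 2 probes x 4 replicates, every replicate equal to v
  v <- 3.5
  vals <- matrix(v, nrow = 8L, ncol = 2L)
  tabs <- toy_experiment(vals, probes = rep(c("p1", "p2"), each = 4L),
                         genes = rep("g1", 8L))
  d <- infer_design(tabs)
  tgs <- compute_tgs(tabs, d)
  expect_equal(unname(tgs["g1", ]), c(8 * v, 8 * v))

  # single probe, single replicate: TGS is the value itself
  tabs1 <- toy_experiment(matrix(c(2.5, 4.5), 1L), probes = "p1",
                          genes = "g1")
  expect_equal(unname(compute_tgs(tabs1, infer_design(tabs1))["g1", ]),
               c(2.5, 4.5))

  # median ignores a wild outlier among 8 replicates
  w <- c(rep(10, 7L), 1e6)
  tabs2 <- toy_experiment(cbind(w, w), probes = rep("p1", 8L),
                          genes = rep("g1", 8L))
  expect_equal(unname(compute_tgs(tabs2, infer_design(tabs2))["g1", ]),
               c(80, 80))

  # linearity under the median when order is unchanged
  vals3 <- matrix(c(1, 2, 3, 2, 4, 6), ncol = 2L)
  tabs3 <- toy_experiment(vals3, probes = rep("p1", 3L),
                          genes = rep("g1", 3L))
  tgs3 <- compute_tgs(tabs3, infer_design(tabs3))
  expect_equal(unname(tgs3["g1", 2L]), 2 * unname(tgs3["g1", 1L]))
})

test_that("all four processing routes run end to end on synthetic data", {
  sim <- simulate_experiment(small_config(seed = 5L))
  d <- sim$design
  for (mth in c("nor75", "norQ", "norRMA", "norRMAbg")) {
    em <- process_arrays(sim$tables, method = mth, design = d)
    expect_equal(nrow(em), length(d$gene_ids))
    expect_equal(ncol(em), length(sim$tables))
    expect_true(all(is.finite(em)))
    expect_identical(attr(em, "method"), mth)
  }
})

test_that("background correction is a near-identity when background vanishes", {
  cfg <- small_config(seed = 3L, noise_sd = 0, bg_sigma = 0, bg_mu = 0)
  sim <- simulate_experiment(cfg)
  bg <- rep(list(bg_params(alpha = 1e-6, mu = 0, sigma = 1e-8)),
            length(sim$tables))
  e1 <- process_arrays(sim$tables, method = "norRMA", design = sim$design)
  e2 <- process_arrays(sim$tables, method = "norRMAbg", design = sim$design,
                       bg = bg)
  expect_equal(unclass(e1), unclass(e2), tolerance = 1e-6,
               ignore_attr = TRUE)
})
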