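test_that("mean squared volume error matches direct arithmetic and its invariances", {
  expect_equal(rmse(c(2, 2), c(1, 3)), 1)
  expect_equal(rmse(5, 8), 9)
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  # order invariance and quadratic scaling under volume rescaling
  vm <- c(10, 40, 90); vd <- c(12, 35, 100)
  expect_equal(rmse(vm, vd), rmse(rev(vm), rev(vd)))
  expect_equal(rmse(3 * vm, 3 * vd), 9 * rmse(vm, vd))
  # normalized variant is scale-free
  expect_equal(rmse(3 * vm, 3 * vd, normalized = TRUE),
               rmse(vm, vd, normalized = TRUE))
  expect_error(rmse(c(1, 2), c(1, 2, 3)), "lengths differ")
})

test_that("percent error is absolute, relative and zero only at equality", {
  expect_equal(percent_error(0.025, 0.025), 0)
  expect_equal(percent_error(1.05 * 4000, 4000), 5)
  expect_equal(percent_error(0.95 * 4000, 4000), 5)
  expect_error(percent_error(3, 0), "undefined")
})

test_that("significance tiers are a pure function of the three thresholds", {
  expect_identical(significance_tier(c(0.5, 0.009, 0.004, 0.0009)),
                   c("none", "p<0.01", "p<0.005", "p<0.001"))
  expect_identical(significance_tier(0.01), "none")
  expect_identical(significance_tier(1), "none")
})

test_that("Mann-Whitney U matches hand-computable cases", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)  # 2 * 1/C(6,3)
  expect_true(res$exact)
  # rank-symmetric interleaving gives the central U
  expect_equal(mann_whitney_u(c(1, 4), c(2, 3))$U, 2)
  # identical samples: maximal overlap, p = 1
  expect_equal(mann_whitney_u(c(5, 5, 5), c(5, 5, 5))$p, 1)
  expect_error(mann_whitney_u(numeric(0), 1:3))
})

test_that("swapping samples reflects U about n1*n2/2 with identical p", {
  set.seed(8)
  for (i in 1:20) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1))
    a <- mann_whitney_u(x, y); b <- mann_whitney_u(y, x)
    expect_equal(a$U + b$U, length(x) * length(y))
    expect_equal(a$p, b$p)
  }
})

test_that("exact p-values agree with the rank-enumeration oracle", {
  set.seed(15)
  for (i in 1:25) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    vals <- sample(1:60, n1 + n2) + runif(n1 + n2, -0.2, 0.2)
    x <- vals[seq_len(n1)]; y <- vals[-seq_len(n1)]
    or <- mwu_enumeration_oracle(x, y)
    res <- mann_whitney_u(x, y)
    expect_equal(res$U, or$U)
    expect_equal(res$p, or$p, tolerance = 1e-12)
  }
})

test_that("adjacent measurement-count comparisons produce exactly three results", {
  set.seed(2)
  errs <- data.frame(m = rep(3:6, each = 30),
                     rmse = rexp(120) / rep(1:4, each = 30))
  cmp <- compare_measurement_counts(errs, "rmse")
  expect_identical(nrow(cmp), 3L)
  expect_equal(cmp$m1, c(3, 4, 5))
  expect_equal(cmp$m2, c(4, 5, 6))
  expect_true(all(cmp$U >= 0 & cmp$U <= 30 * 30))
  # a stratum compared against itself is maximally overlapping
  self <- compare_measurement_counts(errs, "rmse", pairs = list(c(3, 3)))
  expect_equal(self$p, 1)
  expect_error(compare_measurement_counts(errs[errs$m != 5, ], "rmse"),
               "m = 5")
})

test_that("the median summary covers the full factorial grid", {
  grid <- expand.grid(alpha_truth = study_rates,
                      noise_level = c(0, 0.05, 0.1, 0.2), m = 3:6,
                      replicate = 1:4)
  grid$converged <- TRUE
  grid$rmse <- 0; grid$pct_err_alpha <- 0; grid$pct_err_k <- 0
  s <- median_error_summary(grid)
  expect_identical(nrow(s), 48L)  # 3 rates x 4 levels x 4 counts
  expect_true(all(s$n == 4))
  expect_true(all(s$med_rmse == 0 & s$med_pct_err_k == 0))
  # non-converged fits are excluded from medians but counted
  grid2 <- grid
  bad <- grid2$replicate == 1
  grid2$converged[bad] <- FALSE
  grid2$pct_err_k[bad] <- 1e6
  s2 <- median_error_summary(grid2)
  expect_true(all(s2$n_failed == 1))
  expect_true(all(s2$med_pct_err_k == 0))
})
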