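test_that("closed-form carrying capacity matches the root-solve oracle", {
  # frozen value computed with the uniroot oracle over logistic_volume
  expect_equal(carrying_capacity_for(100, 200, 40, 0.025), 478.442238,
               tolerance = 1e-8)
  set.seed(11)
  for (i in 1:25) {
    v0 <- runif(1, 50, 500)
    vt <- v0 * runif(1, 1.2, 12)
    t <- runif(1, 30, 500)
    alpha <- (log(vt) - log(v0)) / t * runif(1, 1.05, 5)
    k <- carrying_capacity_for(v0, vt, t, alpha)
    expect_equal(k, k_root_oracle(v0, vt, t, alpha), tolerance = 1e-8)
    # refeeding the parameters reproduces the clinical point
    expect_equal(logistic_volume(t, v0, alpha, k), vt, tolerance = 1e-9)
    expect_gt(k, vt)
  }
})

test_that("carrying capacity saturates to vt for fast growth and rejects infeasible rates", {
  expect_equal(carrying_capacity_for(100, 200, 40, 1), 200, tolerance = 1e-6)
  expect_gt(carrying_capacity_for(100, 200, 40, 0.3), 200)
  # alpha below the two-point exponential rate ln2/40 ~ 0.01733 is infeasible
  expect_error(carrying_capacity_for(100, 200, 40, 0.0125),
               "minimum feasible alpha")
  expect_error(carrying_capacity_for(100, 100, 40, 0.025), "no growth")
})

test_that("cohort calibration passes every ground-truth curve through both clinical points", {
  one <- data.frame(patient_id = "p", v0_mm3 = 100, vt_mm3 = 200,
                    t_final_days = 40)
  cal1 <- calibrate_cohort(one, 0.025)
  expect_equal(cal1$k_mm3, 478.442238, tolerance = 1e-8)

  vols <- test_cohort_volumes()
  for (alpha in study_rates) {
    cal <- calibrate_cohort(vols, alpha)
    expect_identical(nrow(cal), 18L)
    v_at_tf <- logistic_volume(cal$t_final_days, cal$v0_mm3, alpha, cal$k_mm3)
    expect_equal(v_at_tf, vols$vt_mm3, tolerance = 1e-6)
    expect_equal(cal$v0_mm3, vols$v0_mm3)
    # all clinical volumes within the cohort envelope
    expect_true(all(c(cal$v0_mm3, cal$v_final_mm3) >= 80))
    expect_true(all(c(cal$v0_mm3, cal$v_final_mm3) <= 11000))
  }
  expect_error(calibrate_cohort(vols, 1e-4), "infeasible for patient")
})

test_that("noiseless 3-point fits recover the generating parameters", {
  for (alpha in study_rates) {
    tm <- c(0, 7, 30)
    v <- logistic_volume(tm, 150, alpha, 5000)
    fit <- fit_logistic(tm, v)
    expect_true(fit$converged)
    expect_true(fit$identifiable)
    expect_equal(fit$alpha_hat, alpha, tolerance = 1e-4)
    expect_equal(fit$k_hat, 5000, tolerance = 1e-4)
  }
})

test_that("two-point fits are flagged non-identifiable with a residual-degenerate ridge", {
  tm <- c(0, 7)
  v <- logistic_volume(tm, 150, 0.025, 5000)
  fit <- fit_logistic(tm, v)
  expect_false(fit$identifiable)
  # every start reaches ~zero residual yet the growth-rate solutions spread
  scale2 <- mean(v)^2
  expect_true(all(fit$starts$objective / scale2 < 1e-12))
  spread <- diff(range(fit$starts$alpha_hat))
  expect_gt(spread / min(fit$starts$alpha_hat), 0.05)
})

test_that("fixed-rate optimization agrees with the closed-form carrying capacity", {
  set.seed(23)
  for (i in 1:10) {
    v0 <- runif(1, 80, 400)
    vt <- v0 * runif(1, 1.5, 8)
    t <- runif(1, 60, 400)
    alpha <- (log(vt) - log(v0)) / t * runif(1, 1.1, 3)
    k_closed <- carrying_capacity_for(v0, vt, t, alpha)
    fit <- fit_logistic(c(0, t), c(v0, vt), fix_alpha = alpha)
    expect_equal(fit$k_hat, k_closed, tolerance = 1e-6)
  }
})

test_that("the optimum never exceeds the initialization objective", {
  set.seed(31)
  for (i in 1:10) {
    alpha <- runif(1, 0.01, 0.06)
    k <- runif(1, 2000, 9000)
    tm <- c(0, 7, 30, 60)
    v <- logistic_volume(tm, 150, alpha, k) * (1 + runif(4, -0.2, 0.2))
    v[1] <- 150
    fit <- fit_logistic(tm, v)
    # initialization: nominal K = last training volume, data-driven alpha
    a0 <- (log(v[2]) - log(v[1])) / 7
    k0 <- max(v[4], v[1] * (1 + 1e-6))
    obj_init <- sum((logistic_volume(tm, v[1], max(a0, 1e-4), k0) - v)^2)
    expect_lte(fit$objective, obj_init + 1e-9)
  }
})

test_that("training series not starting at day zero are rejected", {
  expect_error(fit_logistic(c(7, 30), c(100, 150)), "day 0")
  expect_error(fit_logistic(c(0, 30), c(100, -5)))
})
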