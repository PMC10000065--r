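test_that("effective radius reduces to d/2 for circular lesions and rejects bad axes", {
  expect_equal(radius_from_axes(12, 12), 6)
  expect_equal(radius_from_axes(14, 8), 6)
  expect_error(radius_from_axes(0, 5), "positive")
  expect_error(radius_from_axes(-3, 2), "positive")
  expect_error(radius_from_axes(8, 14), "minor axis exceeds")
})

test_that("shape volumes match the solid formulas and degenerate consistently", {
  expect_equal(shape_volume("sphere", r = 1), 4 * pi / 3)
  expect_equal(shape_volume("cylinder", r = 1, h = 1), pi)
  # equal semi-axes: oblate spheroid is a sphere
  expect_equal(shape_volume("oblate", a_semi = 2, b_semi = 2),
               shape_volume("sphere", r = 2))
  # cylinder volume is linear in height
  expect_equal(shape_volume("cylinder", r = 3, h = 8),
               2 * shape_volume("cylinder", r = 3, h = 4))
  expect_error(shape_volume("cylinder", r = 1), "'h' is required")
})

test_that("doubling time and exponential rate satisfy the log-growth identities", {
  expect_equal(doubling_time(100, 200, 30), 30)
  expect_equal(doubling_time(100, 400, 30), 15)
  expect_error(doubling_time(100, 100, 30), "no growth")
  expect_error(doubling_time(100, 50, 30), "no growth")
  expect_equal(exponential_rate(100, 200, 40), log(2) / 40)
  expect_equal(exponential_rate(100, 100, 40), 0)
  # DT * y = ln 2 for any valid growth, and exponential series round-trip
  set.seed(4)
  for (i in 1:20) {
    v0 <- runif(1, 50, 500); y <- runif(1, 1e-3, 0.05); t <- runif(1, 10, 400)
    vt <- v0 * exp(y * t)
    expect_equal(doubling_time(v0, vt, t) * exponential_rate(v0, vt, t), log(2))
    expect_equal(doubling_time(v0, vt, t), log(2) / y)
  }
})

test_that("patient records validate axes and flag missing doubling times as excluded", {
  rec <- patient_record("p1", 300, 14, 8, 20, 12, reported_dt_days = 90)
  expect_false(rec$excluded)
  expect_true(patient_record("p2", 300, 14, 8, 20, 12)$excluded)
  expect_error(patient_record("p3", 300, 8, 14, 20, 12, reported_dt_days = 90),
               "minor axis")
  expect_error(patient_record("p4", 300, -1, -2, 20, 12, reported_dt_days = 90),
               "positive")
})

test_that("cylinder volume with equal axes matches the direct formula", {
  rec <- patient_record("p1", 100, 12, 12, 12, 12, h0_mm = 12, h1_mm = 12,
                        reported_dt_days = 90)
  pv <- patient_volumes(rec, "cylinder")
  expect_equal(pv$v0_mm3, pi * 36 * 12)
  expect_equal(pv$vt_mm3, pi * 36 * 12)
  excl <- patient_record("p2", 100, 12, 12, 14, 13)
  expect_error(patient_volumes(excl, "cylinder"), "excluded")
})

test_that("shape selection picks the shape whose implied doubling time matches", {
  # record built so the cylinder-implied doubling time equals the reported one
  co <- generate_cohort(cohort_spec(n = 6, seed = 5, mode = "cylinder-axes"))
  for (i in seq_len(nrow(co))) {
    rec <- patient_record(co$patient_id[i], co$t1_days[i],
                          co$a0_mm[i], co$b0_mm[i], co$a1_mm[i], co$b1_mm[i],
                          h0_mm = co$h0_mm[i], h1_mm = co$h1_mm[i],
                          reported_dt_days = co$reported_dt_days[i])
    sel <- select_best_shape(rec)
    expect_identical(sel$selected_shape, "cylinder")
    expect_lt(sel$discrepancy_days, 1e-6)
    expect_identical(nrow(sel$candidates), 3L)
  }
  excl <- patient_record("px", 100, 12, 10, 14, 13)
  expect_error(select_best_shape(excl), "excluded")
})

test_that("a full 18-patient cylinder-geometry cohort selects cylinder for every patient", {
  co <- generate_cohort(cohort_spec(seed = 101, mode = "cylinder-axes"))
  vols <- cohort_volumes(co)
  expect_identical(nrow(vols), 18L)
  expect_true(all(vols$shape == "cylinder"))
})

test_that("cohort CSV round-trips in both dialects and counts exclusions", {
  co <- generate_cohort(cohort_spec(n = 5, seed = 9))
  co$reported_dt_days[2] <- NA  # one patient without a listed doubling time
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(co[setdiff(names(co), "excluded")], path, row.names = FALSE)
  back <- read_cohort(path)
  expect_identical(attr(back, "mode"), "volumes")
  expect_identical(sum(back$excluded), 1L)
  expect_message(vols <- cohort_volumes(back), "1 patient")
  expect_identical(nrow(vols), 4L)
  expect_equal(vols$v0_mm3, co$v0_mm3[-2])

  ax <- generate_cohort(cohort_spec(n = 5, seed = 9, mode = "cylinder-axes"))
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(ax[setdiff(names(ax), "excluded")], path2, row.names = FALSE)
  back2 <- read_cohort(path2)
  expect_identical(attr(back2, "mode"), "axes")
  vols2 <- cohort_volumes(back2)
  # same seed draws the same underlying volumes in either dialect
  expect_equal(vols2$v0_mm3, co$v0_mm3, tolerance = 1e-10)
  expect_equal(vols2$vt_mm3, co$v1_mm3, tolerance = 1e-10)
})
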