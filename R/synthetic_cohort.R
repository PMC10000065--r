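#' Specification for a synthetic two-timepoint cohort
#'
#' Virtual patients with the statistical envelope of the clinical cohort
#' the study design assumes: 18 untreated breast cancer patients, initial
#' volumes of order 80-500 mm^3, all volumes within 80-11,000 mm^3, final
#' observations between 120 and 750 days, and volume doubling times slow
#' enough (>= 60 days > ln2/0.0125 ~ 55.45 days) that every patient is
#' feasible at the slowest study growth rate. Between its two observations
#' each virtual patient grows exponentially at its doubling time — the
#' same summary the clinical source reported — and the study's logistic
#' ground truth is then imposed by calibration.
#'
#' @param n Number of patients.
#' @param v0_range Initial-volume range, mm^3.
#' @param v_cap Final-volume cap, mm^3.
#' @param dt_range Doubling-time range, days (lower bound must exceed
#'   ln2 / min study growth rate).
#' @param tfinal_range Final-observation time range, days (must start
#'   beyond the last scan day, 120).
#' @param seed RNG seed.
#' @param mode `"volumes"` emits volume-mode records; `"cylinder-axes"`
#'   back-solves tumor axes so the cylinder shape reproduces the volumes
#'   exactly.
#' @return A list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n = 18L, v0_range = c(80, 500), v_cap = 11000,
                        dt_range = c(60, 300), tfinal_range = c(120, 750),
                        seed = 1L, mode = c("volumes", "cylinder-axes")) {
  mode <- match.arg(mode)
  stopifnot(n >= 1L, v0_range[1] > 0, diff(v0_range) > 0,
            v_cap > v0_range[2], dt_range[1] > 0, diff(dt_range) > 0,
            tfinal_range[1] >= 120, diff(tfinal_range) > 0)
  if (dt_range[1] <= log(2) / 0.0125) {
    stop(sprintf("cohort_spec: doubling-time lower bound must exceed %.2f d for feasibility at alpha = 0.0125/day",
                 log(2) / 0.0125))
  }
  structure(list(n = as.integer(n), v0_range = v0_range, v_cap = v_cap,
                 dt_range = dt_range, tfinal_range = tfinal_range,
                 seed = as.integer(seed), mode = mode),
            class = "cohort_spec")
}

# invert V = pi * r^2 * h with r = (2a + b)/6, h = b, a = rho * b:
# V = pi * b^3 * (2 rho + 1)^2 / 36  =>  b = (36 V / (pi (2 rho + 1)^2))^(1/3)
axes_for_cylinder_volume <- function(v, rho) {
  b <- (36 * v / (pi * (2 * rho + 1)^2))^(1 / 3)
  list(a = rho * b, b = b, h = b)
}

#' Generate a synthetic two-timepoint patient cohort
#'
#' Draws, per patient, V0 ~ U(v0_range), doubling time ~ U(dt_range) and a
#' final time ~ U(tfinal_range), resampling the final time while
#' Vt = V0 * 2^(t/DT) exceeds the cap. The reported doubling time is the
#' exact implied one. In cylinder-axes mode the tumor aspect ratio a/b is
#' drawn independently at the two visits, and axes (a, b, h = b) are
#' back-solved so the cylinder formula reproduces the volumes exactly —
#' the cylinder-implied doubling time then matches the reported one while
#' sphere and oblate implied doubling times generically differ.
#'
#' @param spec A [cohort_spec()].
#' @return Cohort data frame in the matching CSV dialect (see
#'   [read_cohort()]), with an `excluded` column (all `FALSE`) and `mode`
#'   attribute.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    v0 <- stats::runif(spec$n, spec$v0_range[1], spec$v0_range[2])
    dt <- stats::runif(spec$n, spec$dt_range[1], spec$dt_range[2])
    tf <- numeric(spec$n)
    vt <- numeric(spec$n)
    for (i in seq_len(spec$n)) {
      for (try in 1:1000) {
        tf[i] <- stats::runif(1, spec$tfinal_range[1], spec$tfinal_range[2])
        vt[i] <- v0[i] * 2^(tf[i] / dt[i])
        if (vt[i] <= spec$v_cap) break
        if (try == 1000) stop("generate_cohort: cannot satisfy volume cap; widen ranges")
      }
    }
    stopifnot(all(vt > v0), all(vt <= spec$v_cap),
              all(tf > 120), all(tf <= spec$tfinal_range[2]))
    ids <- sprintf("P%02d", seq_len(spec$n))
    if (spec$mode == "volumes") {
      out <- data.frame(patient_id = ids, t1_days = tf, v0_mm3 = v0,
                        v1_mm3 = vt, reported_dt_days = dt,
                        excluded = FALSE, stringsAsFactors = FALSE)
    } else {
      rho0 <- stats::runif(spec$n, 1.1, 2.0)
      rho1 <- stats::runif(spec$n, 1.1, 2.0)
      g0 <- axes_for_cylinder_volume(v0, rho0)
      g1 <- axes_for_cylinder_volume(vt, rho1)
      out <- data.frame(patient_id = ids, t1_days = tf,
                        a0_mm = g0$a, b0_mm = g0$b, h0_mm = g0$h,
                        a1_mm = g1$a, b1_mm = g1$b, h1_mm = g1$h,
                        reported_dt_days = dt, excluded = FALSE,
                        stringsAsFactors = FALSE)
    }
    attr(out, "mode") <- if (spec$mode == "volumes") "volumes" else "axes"
    out
  })
}

#' Generate a cohort with known logistic ground truth
#'
#' Parameter-recovery fixture: draws true (V0, alpha, K) per patient,
#' places both clinical observations exactly on the logistic curve, and
#' returns the cohort alongside the hidden truth so calibration and
#' fitting can be scored against known parameters. Draws with K <= V0 are
#' rejected and resampled.
#'
#' @param spec A [cohort_spec()] (volume mode).
#' @param alpha True growth rate, 1/day.
#' @param k_range Carrying-capacity range, mm^3, within
#'   (max V0, `spec$v_cap`].
#' @return A list `cohort` (volume-mode data frame) and `truth`
#'   (`patient_id, v0_mm3, alpha_per_day, k_mm3, t_final_days,
#'   v_final_mm3`).
#' @export
generate_known_truth_cohort <- function(spec, alpha, k_range = c(1000, 11000)) {
  stopifnot(inherits(spec, "cohort_spec"), alpha > 0,
            k_range[1] < k_range[2], k_range[2] <= spec$v_cap)
  withr::with_seed(spec$seed, {
    v0 <- stats::runif(spec$n, spec$v0_range[1], spec$v0_range[2])
    k <- numeric(spec$n)
    for (i in seq_len(spec$n)) {
      repeat {
        k[i] <- stats::runif(1, k_range[1], k_range[2])
        if (k[i] > v0[i]) break
      }
    }
    tf <- stats::runif(spec$n, spec$tfinal_range[1], spec$tfinal_range[2])
    vt <- logistic_volume(tf, v0, alpha, k)
    ids <- sprintf("T%02d", seq_len(spec$n))
    dt_rep <- log(2) * tf / (log(vt) - log(v0))
    cohort <- data.frame(patient_id = ids, t1_days = tf, v0_mm3 = v0,
                         v1_mm3 = vt, reported_dt_days = dt_rep,
                         excluded = FALSE, stringsAsFactors = FALSE)
    attr(cohort, "mode") <- "volumes"
    truth <- data.frame(patient_id = ids, v0_mm3 = v0, alpha_per_day = alpha,
                        k_mm3 = k, t_final_days = tf, v_final_mm3 = vt,
                        stringsAsFactors = FALSE)
    list(cohort = cohort, truth = truth)
  })
}
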