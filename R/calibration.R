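#' Patient-specific carrying capacity for a given growth rate
#'
#' Closed-form inversion of the logistic solution through two clinical
#' points: given V(0) = `v0` and V(`t`) = `vt`, the carrying capacity that
#' makes the logistic curve with rate `alpha` pass through both is
#' K = Vt * V0 * (e^{alpha t} - 1) / (V0 * e^{alpha t} - Vt), evaluated
#' here in the overflow-safe form K = Vt (1 - e^{-alpha t}) /
#' (1 - (Vt/V0) e^{-alpha t}).
#'
#' Feasibility requires `alpha` to exceed the two-point exponential rate
#' (ln Vt - ln V0)/t: logistic growth at rate alpha is everywhere slower
#' than exponential growth at the same rate, so a slower alpha cannot reach
#' `vt` in time for any finite K. As `alpha` grows large, K decreases to
#' `vt` from above.
#'
#' @param v0,vt The two clinical volumes, mm^3, with `vt > v0 > 0`.
#' @param t Time between them, days (> 0).
#' @param alpha Uniform growth rate, 1/day.
#' @return Carrying capacity K, mm^3 (always `> vt`).
#' @examples
#' carrying_capacity_for(100, 200, 40, 0.025)
#' @export
carrying_capacity_for <- function(v0, vt, t, alpha) {
  stopifnot(v0 > 0, t > 0, alpha > 0)
  if (vt <= v0) stop("carrying_capacity_for: vt <= v0 (no growth), K undefined")
  y <- (log(vt) - log(v0)) / t
  if (alpha <= y) {
    stop(sprintf(paste0("carrying_capacity_for: alpha = %.6g is infeasible; ",
                        "minimum feasible alpha is %.6g /day"), alpha, y))
  }
  e <- exp(-alpha * t)
  vt * (1 - e) / (1 - (vt / v0) * e)
}

#' Calibrate a cohort of ground-truth logistic curves
#'
#' The nested calibration scheme: one growth rate `alpha` is shared by the
#' whole cohort while each patient's carrying capacity is solved
#' individually so that the logistic curve passes exactly through both of
#' that patient's clinical volumes. The returned curves are the study's
#' ground truth, from which all scan-day measurements are interpolated.
#'
#' @param volumes Data frame from [cohort_volumes()] (columns `patient_id`,
#'   `v0_mm3`, `vt_mm3`, `t_final_days`).
#' @param alpha Uniform growth rate, 1/day.
#' @return Data frame `patient_id, alpha_per_day, k_mm3, v0_mm3,
#'   t_final_days, v_final_mm3`, one row per patient.
#' @export
calibrate_cohort <- function(volumes, alpha) {
  need <- c("patient_id", "v0_mm3", "vt_mm3", "t_final_days")
  stopifnot(all(need %in% names(volumes)), nrow(volumes) >= 1L, alpha > 0)
  ymin <- (log(volumes$vt_mm3) - log(volumes$v0_mm3)) / volumes$t_final_days
  bad <- which(alpha <= ymin)
  if (length(bad)) {
    stop(sprintf("calibrate_cohort: alpha = %.6g infeasible for patient(s) %s (max required rate %.6g)",
                 alpha, paste(volumes$patient_id[bad], collapse = ", "), max(ymin)))
  }
  k <- vapply(seq_len(nrow(volumes)), function(i) {
    carrying_capacity_for(volumes$v0_mm3[i], volumes$vt_mm3[i],
                          volumes$t_final_days[i], alpha)
  }, numeric(1))
  data.frame(patient_id = as.character(volumes$patient_id),
             alpha_per_day = alpha, k_mm3 = k, v0_mm3 = volumes$v0_mm3,
             t_final_days = volumes$t_final_days,
             v_final_mm3 = volumes$vt_mm3, stringsAsFactors = FALSE)
}

#' Optimizer settings for logistic parameter estimation
#'
#' Box bounds and multistart policy for the bounded Levenberg-Marquardt
#' fits. The growth-rate bounds span the study's rates with headroom; the
#' carrying-capacity upper bound comfortably exceeds the largest clinical
#' volume. The carrying capacity is always initialized at the last training
#' volume (the "nominal carrying capacity"); the growth rate starts at the
#' exponential estimate from the first two training points plus
#' `n_starts - 1` log-spaced fallback starts that guard against the flat
#' ridge in the (alpha, K) objective when few points are available.
#'
#' @param alpha_bounds Growth-rate bounds, 1/day.
#' @param k_max Carrying-capacity upper bound, mm^3 (lower bound is
#'   `v0 * (1 + 1e-6)` per fit).
#' @param n_starts Total number of multistart growth-rate initializations.
#' @param ftol,ptol Levenberg-Marquardt convergence tolerances.
#' @param maxiter Iteration cap per start.
#' @return A list of class `"optimizer_settings"`.
#' @export
optimizer_settings <- function(alpha_bounds = c(1e-4, 1), k_max = 1e7,
                               n_starts = 5L, ftol = 1e-12, ptol = 1e-12,
                               maxiter = 200L) {
  stopifnot(length(alpha_bounds) == 2L, alpha_bounds[1] > 0,
            alpha_bounds[2] > alpha_bounds[1], k_max > 0, n_starts >= 1L)
  structure(list(alpha_bounds = alpha_bounds, k_max = k_max,
                 n_starts = as.integer(n_starts), ftol = ftol, ptol = ptol,
                 maxiter = as.integer(maxiter)),
            class = "optimizer_settings")
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Fit the logistic model to a training series
#'
#' Least-squares estimation of (alpha, K) from m measurements, minimizing
#' the sum of squared volume residuals with V0 fixed to the day-0
#' measurement. Optimization runs in log-parameter space (better
#' conditioning across the four-decade K range) with bounded
#' Levenberg-Marquardt from multiple growth-rate starts; the best objective
#' wins, ties going to the earliest start.
#'
#' With only two points the problem is degenerate: V0 is fixed, leaving two
#' unknowns against one residual, so a continuum of (alpha, K) pairs
#' achieves ~zero residual and the fit is flagged `identifiable = FALSE`.
#' The per-start solutions are returned so callers can inspect the spread
#' along that ridge.
#'
#' @param time Training times, days, strictly increasing, first must be 0.
#' @param volume Training volumes, mm^3.
#' @param settings An [optimizer_settings()] object.
#' @param fix_alpha If non-`NULL`, hold the growth rate at this value and
#'   optimize the carrying capacity alone.
#' @return A list of class `"fit_result"`: `alpha_hat`, `k_hat`,
#'   `objective` (sum of squared residuals, mm^6), `converged`,
#'   `n_points`, `identifiable`, `v0`, and `starts` (per-start data frame).
#' @export
fit_logistic <- function(time, volume, settings = optimizer_settings(),
                         fix_alpha = NULL) {
  stopifnot(is.numeric(time), is.numeric(volume),
            length(time) == length(volume), length(time) >= 2L,
            all(diff(time) > 0), all(volume > 0))
  if (time[1] != 0) stop("fit_logistic: training series must start at day 0")
  v0 <- volume[1]
  k_lo <- v0 * (1 + 1e-6)
  k_init <- clip(volume[length(volume)], k_lo * (1 + 1e-9), settings$k_max)
  ab <- settings$alpha_bounds

  resid_fun <- function(par) {
    a <- exp(par[["la"]])
    k <- exp(par[["lk"]])
    logistic_volume(time, v0, a, k) - volume
  }

  if (!is.null(fix_alpha)) {
    stopifnot(fix_alpha > 0)
    fit <- minpack.lm::nls.lm(
      par = c(lk = log(k_init)),
      lower = log(k_lo), upper = log(settings$k_max),
      fn = function(par) {
        logistic_volume(time, v0, fix_alpha, exp(par[["lk"]])) - volume
      },
      control = minpack.lm::nls.lm.control(ftol = settings$ftol,
                                           ptol = settings$ptol,
                                           maxiter = settings$maxiter))
    return(structure(list(alpha_hat = fix_alpha, k_hat = exp(fit$par[["lk"]]),
                          objective = fit$deviance,
                          converged = fit$info %in% 1:4,
                          n_points = length(time),
                          identifiable = length(time) >= 2L, v0 = v0,
                          starts = NULL),
                     class = "fit_result"))
  }

  a_data <- (log(volume[2]) - log(volume[1])) / (time[2] - time[1])
  if (!is.finite(a_data) || a_data <= 0) a_data <- 0.01
  a_data <- clip(a_data, ab[1] * (1 + 1e-9), ab[2] * (1 - 1e-9))
  a_grid <- exp(seq(log(1e-3), log(0.5), length.out = settings$n_starts - 1L))
  a_starts <- c(a_data, clip(a_grid, ab[1], ab[2]))[seq_len(settings$n_starts)]

  runs <- lapply(a_starts, function(a0) {
    fit <- minpack.lm::nls.lm(
      par = c(la = log(a0), lk = log(k_init)),
      lower = log(c(ab[1], k_lo)), upper = log(c(ab[2], settings$k_max)),
      fn = resid_fun,
      control = minpack.lm::nls.lm.control(ftol = settings$ftol,
                                           ptol = settings$ptol,
                                           maxiter = settings$maxiter))
    c(alpha_start = a0, alpha_hat = exp(fit$par[["la"]]),
      k_hat = exp(fit$par[["lk"]]), objective = fit$deviance,
      converged = as.numeric(fit$info %in% 1:4))
  })
  starts <- as.data.frame(do.call(rbind, runs))
  best <- which.min(starts$objective)

  structure(list(alpha_hat = starts$alpha_hat[best],
                 k_hat = starts$k_hat[best],
                 objective = starts$objective[best],
                 converged = starts$converged[best] == 1,
                 n_points = length(time),
                 identifiable = length(time) >= 3L,
                 v0 = v0, starts = starts),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(paste0("logistic fit (%d points): alpha_hat = %.6g /day, ",
                     "k_hat = %.6g mm^3, SSR = %.4g, %s%s\n"),
              x$n_points, x$alpha_hat, x$k_hat, x$objective,
              if (x$converged) "converged" else "NOT converged",
              if (x$identifiable) "" else ", non-identifiable (2-point ridge)"))
  invisible(x)
}
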