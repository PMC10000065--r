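#' Logistic growth parameters
#'
#' Bundle and validate the three quantities that fully specify one logistic
#' tumor growth trajectory: the initial volume `V0` (mm^3), the intrinsic
#' (early-exponential) growth rate `alpha` (1/day), and the carrying capacity
#' `K` (mm^3), the maximum volume the patient's tumor environment sustains.
#'
#' Growth scenarios require `V0 <= K`; `V0 == K` is the stationary fixed
#' point. `V0 > K` (decay towards K) is rejected because it is not part of
#' the study design.
#'
#' @param v0 Initial tumor volume in mm^3, strictly positive.
#' @param alpha Intrinsic growth rate in 1/day, strictly positive.
#' @param k Carrying capacity in mm^3, strictly positive, `k >= v0`.
#' @return A list of class `"logistic_params"` with elements `v0`, `alpha`,
#'   `k`.
#' @examples
#' p <- logistic_params(100, 0.025, 5000)
#' logistic_volume(0, p$v0, p$alpha, p$k)
#' @export
logistic_params <- function(v0, alpha, k) {
  stopifnot(is.numeric(v0), length(v0) == 1L, is.finite(v0),
            is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(k), length(k) == 1L, is.finite(k))
  if (v0 <= 0 || alpha <= 0 || k <= 0) {
    stop("logistic_params: v0, alpha and k must all be strictly positive")
  }
  if (v0 > k) {
    stop("logistic_params: v0 > k (shrinking tumors are outside the study design)")
  }
  structure(list(v0 = v0, alpha = alpha, k = k), class = "logistic_params")
}

#' @export
print.logistic_params <- function(x, ...) {
  cat(sprintf("logistic growth curve: V0 = %.6g mm^3, alpha = %.6g /day, K = %.6g mm^3\n",
              x$v0, x$alpha, x$k))
  invisible(x)
}

#' Closed-form logistic tumor volume
#'
#' Analytic solution of dV/dt = alpha * V * (1 - V/K) with V(0) = V0,
#' evaluated as V(t) = K / (1 + (K/V0 - 1) * exp(-alpha * t)). This form is
#' overflow-safe for large `alpha * t` (the naive `exp(alpha * t)` form is
#' not) and is the canonical evaluator throughout the package; numerical
#' integration (see [simulate_curve()]) exists to validate it.
#'
#' Negative `t` is permitted for back-extrapolation before the first
#' observation.
#'
#' @param t Time(s) in days since the first observation; vectorized.
#' @param v0 Initial volume, mm^3.
#' @param alpha Intrinsic growth rate, 1/day.
#' @param k Carrying capacity, mm^3.
#' @return Volume(s) in mm^3, same length as `t`.
#' @examples
#' logistic_volume(c(0, 30, 750), 100, 0.025, 5000)
#' @export
logistic_volume <- function(t, v0, alpha, k) {
  stopifnot(is.numeric(t), v0 > 0, alpha > 0, k > 0)
  k / (1 + (k / v0 - 1) * exp(-alpha * t))
}

#' Simulate a logistic growth curve by numerical integration
#'
#' Integrates dV/dt = alpha * V * (1 - V/K) with an adaptive solver and
#' returns the trajectory at the requested times. Agreement with
#' [logistic_volume()] to ~1e-6 relative is part of the package's test
#' contract; the ODE route also keeps the door open for growth laws without
#' a closed form.
#'
#' @param params A [logistic_params()] object.
#' @param times Strictly increasing times in days, first `>= 0`.
#' @param rtol,atol Solver tolerances (defaults 1e-9, 1e-9).
#' @return A data frame with columns `time_days`, `volume_mm3`.
#' @export
simulate_curve <- function(params, times, rtol = 1e-9, atol = 1e-9) {
  stopifnot(inherits(params, "logistic_params"), is.numeric(times),
            length(times) >= 1L, all(diff(times) > 0), times[1] >= 0)
  rhs <- function(t, y, p) list(p$alpha * y[1] * (1 - y[1] / p$k))
  # the solver needs the state at the first requested time, not at day 0
  y0 <- logistic_volume(times[1], params$v0, params$alpha, params$k)
  sol <- deSolve::ode(y = c(V = y0), times = times, func = rhs, parms = params,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop(sprintf("simulate_curve: integration failed for (v0=%g, alpha=%g, k=%g)",
                 params$v0, params$alpha, params$k))
  }
  data.frame(time_days = as.numeric(sol[, "time"]),
             volume_mm3 = as.numeric(sol[, "V"]))
}
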