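#' Mean squared volume error between model and data
#'
#' rMSE = (1/N) * sum (Vm - Vd)^2 over the evaluation points (the
#' interpolated scan-day grid plus the final clinical volume), with Vm the
#' model volume and Vd the ground-truth volume at each time. The formula
#' is a plain mean of squared residuals in mm^6; an optional normalized
#' variant divides each residual by Vd first.
#'
#' @param vm Model volumes, mm^3.
#' @param vd Data volumes, mm^3 (same length and time order).
#' @param normalized If `TRUE`, residuals are relative (`(vm - vd)/vd`),
#'   giving a dimensionless value. Default `FALSE` (canonical).
#' @return Nonnegative scalar; 0 iff the series agree pointwise.
#' @export
rmse <- function(vm, vd, normalized = FALSE) {
  if (length(vm) != length(vd)) stop("rmse: series lengths differ")
  if (length(vm) == 0L) stop("rmse: empty series")
  res <- vm - vd
  if (normalized) res <- res / vd
  mean(res^2)
}

#' Absolute percent error of an estimate
#'
#' 100 * |estimate - truth| / truth.
#'
#' @param estimate,truth Numeric; `truth` must be nonzero.
#' @return Percent error, `>= 0`.
#' @export
percent_error <- function(estimate, truth) {
  if (any(truth == 0)) stop("percent_error: truth is zero, error undefined")
  100 * abs(estimate - truth) / abs(truth)
}

#' Significance tier for a p-value
#'
#' The three thresholds used to annotate comparisons: `"p<0.001"`,
#' `"p<0.005"`, `"p<0.01"`, else `"none"`.
#'
#' @param p p-value(s) in (0, 1].
#' @return Character vector of tiers.
#' @export
significance_tier <- function(p) {
  stopifnot(all(p > 0), all(p <= 1))
  ifelse(p < 0.001, "p<0.001",
         ifelse(p < 0.005, "p<0.005",
                ifelse(p < 0.01, "p<0.01", "none")))
}

#' Mann-Whitney U test between two error distributions
#'
#' U is computed from midrank sums (U = R_x - n1(n1+1)/2 with R_x the rank
#' sum of `x` in the pooled sample). The two-sided p-value is exact (full
#' rank-assignment distribution) for tie-free samples with n1 + n2 <= 14,
#' and otherwise uses the normal approximation with tie and continuity
#' corrections. Swapping the samples maps U to n1*n2 - U with the same p.
#'
#' @param x,y Numeric samples (both nonempty).
#' @return A list of class `"mwu_result"`: `U`, `p`, `n1`, `n2`, `exact`,
#'   `tier`.
#' @export
mann_whitney_u <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) >= 1L, length(y) >= 1L)
  n1 <- length(x); n2 <- length(y)
  rk <- rank(c(x, y))
  u <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  exact <- !ties && (n1 + n2) <= 14L
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
  )
  # degenerate pooled sample (all values tied): zero-variance approximation
  if (!is.finite(p)) p <- 1
  p <- min(max(p, .Machine$double.xmin), 1)
  structure(list(U = u, p = p, n1 = n1, n2 = n2, exact = exact,
                 tier = significance_tier(p)),
            class = "mwu_result")
}

#' @export
print.mwu_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n1 = %d, n2 = %d), two-sided p = %.4g (%s)%s\n",
              x$U, x$n1, x$n2, x$p, if (x$exact) "exact" else "normal approx.",
              if (x$tier == "none") "" else paste0(" [", x$tier, "]")))
  invisible(x)
}

#' Compare error distributions across adjacent measurement counts
#'
#' For one (growth rate, noise level) cell, runs the Mann-Whitney U test on
#' a chosen error metric between adjacent measurement counts: 3 vs 4,
#' 4 vs 5, and 5 vs 6 points.
#'
#' @param errors Error-record data frame (one study cell) with columns `m`
#'   and the metric.
#' @param metric Column to compare: `"rmse"`, `"pct_err_alpha"` or
#'   `"pct_err_k"`.
#' @param pairs List of length-2 measurement-count pairs.
#' @return Data frame `metric, m1, m2, U, p, tier`, one row per pair.
#' @export
compare_measurement_counts <- function(errors,
                                       metric = c("rmse", "pct_err_alpha", "pct_err_k"),
                                       pairs = list(c(3, 4), c(4, 5), c(5, 6))) {
  metric <- match.arg(metric)
  stopifnot(metric %in% names(errors), "m" %in% names(errors))
  out <- lapply(pairs, function(pr) {
    for (mm in pr) {
      if (!any(errors$m == mm)) {
        stop(sprintf("compare_measurement_counts: no records with m = %d", mm))
      }
    }
    res <- mann_whitney_u(errors[[metric]][errors$m == pr[1]],
                          errors[[metric]][errors$m == pr[2]])
    data.frame(metric = metric, m1 = pr[1], m2 = pr[2],
               U = res$U, p = res$p, tier = res$tier,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Median error per study cell
#'
#' Collapses the error-record table to one median per metric per
#' (growth rate x noise level x measurement count) cell — the tabular
#' analogue of plotting median error against the number of measurements
#' for each noise level. Non-converged fits are excluded from the medians
#' but counted.
#'
#' @param errors Full error-record data frame from [run_study()].
#' @return Data frame with one row per cell: `alpha_truth, noise_level, m,
#'   n, n_failed, med_rmse, med_pct_err_alpha, med_pct_err_k`.
#' @export
median_error_summary <- function(errors) {
  need <- c("alpha_truth", "noise_level", "m", "converged",
            "rmse", "pct_err_alpha", "pct_err_k")
  stopifnot(all(need %in% names(errors)), nrow(errors) >= 1L)
  key <- interaction(errors$alpha_truth, errors$noise_level, errors$m,
                     drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(errors, key), function(cell) {
    ok <- cell[cell$converged, , drop = FALSE]
    data.frame(alpha_truth = cell$alpha_truth[1],
               noise_level = cell$noise_level[1], m = cell$m[1],
               n = nrow(cell), n_failed = sum(!cell$converged),
               med_rmse = stats::median(ok$rmse),
               med_pct_err_alpha = stats::median(ok$pct_err_alpha),
               med_pct_err_k = stats::median(ok$pct_err_k))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$alpha_truth, out$noise_level, out$m), , drop = FALSE]
}
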