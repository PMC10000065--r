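#' Study configuration
#'
#' The factorial design of the measurement-sufficiency experiment. The
#' defaults are the study conditions: three uniform growth rates spanning
#' slow to fast breast tumor growth, scan days 0/7/30/60/90/120, noise
#' levels 0-20%, training subsets of 3-6 measurements, and 10 noisy
#' replicates per cell (the noiseless level always runs a single,
#' deterministic replicate).
#'
#' @param growth_rates Uniform growth rates, 1/day.
#' @param sampling_days Scan-day grid, starting at 0.
#' @param noise_levels Noise levels (fractions); 0 means noiseless.
#' @param measurement_counts Training sizes m.
#' @param replicates Replicates per noisy level.
#' @param seed Master seed for all noise draws.
#' @param optimizer An [optimizer_settings()] object.
#' @param sufficiency_tolerance Acceptable median percent error on both
#'   parameters (default 1), used by
#'   [minimal_sufficient_measurements()].
#' @return A list of class `"study_config"`.
#' @export
study_config <- function(growth_rates = c(0.0125, 0.025, 0.0545),
                         sampling_days = c(0, 7, 30, 60, 90, 120),
                         noise_levels = c(0, 0.05, 0.10, 0.20),
                         measurement_counts = 3:6,
                         replicates = 10L,
                         seed = 1L,
                         optimizer = optimizer_settings(),
                         sufficiency_tolerance = 1) {
  stopifnot(all(growth_rates > 0), sampling_days[1] == 0,
            all(diff(sampling_days) > 0), all(noise_levels >= 0),
            all(noise_levels < 1),
            all(measurement_counts >= 2),
            all(measurement_counts <= length(sampling_days)),
            replicates >= 1L, sufficiency_tolerance > 0)
  structure(list(growth_rates = growth_rates, sampling_days = sampling_days,
                 noise_levels = noise_levels,
                 measurement_counts = as.integer(measurement_counts),
                 replicates = as.integer(replicates), seed = as.integer(seed),
                 optimizer = optimizer,
                 sufficiency_tolerance = sufficiency_tolerance),
            class = "study_config")
}

#' Run the full measurement-sufficiency study
#'
#' For every configured growth rate the cohort is calibrated (uniform
#' alpha, patient-specific K), each patient's ground-truth curve is
#' interpolated at the scan days, noise is injected per level and
#' replicate, and the logistic model is refit from the first m
#' measurements for every configured m. One noisy series per (patient,
#' alpha, level, replicate) is reused across all m, so comparisons across
#' measurement counts are paired. Every fit yields one error record:
#' the mean squared error of the fitted curve against the ground-truth
#' grid plus the final clinical volume, percent errors to both true
#' parameters, and the predicted final volume.
#'
#' The run is deterministic given (config, cohort): noise streams derive
#' from the master seed via [child_seed()] and the optimizer is
#' deterministic.
#'
#' @param config A [study_config()].
#' @param volumes Two-point cohort volumes from [cohort_volumes()].
#' @return A list of class `"study_results"`: `errors` (one row per fit),
#'   `comparisons`, `summary`, `config`, `provenance`.
#' @export
run_study <- function(config, volumes) {
  stopifnot(inherits(config, "study_config"))
  rows <- vector("list", 5000L)
  n_rows <- 0L
  push <- function(rec) {
    n_rows <<- n_rows + 1L
    if (n_rows > length(rows)) length(rows) <<- 2L * n_rows
    rows[[n_rows]] <<- rec
  }

  for (ai in seq_along(config$growth_rates)) {
    alpha <- config$growth_rates[ai]
    truth <- calibrate_cohort(volumes, alpha)
    for (pi in seq_len(nrow(truth))) {
      tr <- truth[pi, ]
      series0 <- sample_at_days(tr, config$sampling_days)
      eval_times <- series0$time_days
      eval_true <- series0$volume_mm3
      for (li in seq_along(config$noise_levels)) {
        level <- config$noise_levels[li]
        reps <- if (level == 0) 1L else config$replicates
        for (rep_i in seq_len(reps)) {
          noisy <- if (level == 0) {
            s <- series0; s$volume_true_mm3 <- s$volume_mm3; s
          } else {
            add_noise(series0, level,
                      seed = child_seed(config$seed, pi, ai, li, rep_i))
          }
          for (m in config$measurement_counts) {
            train <- training_subset(noisy, m)
            fit <- fit_logistic(train$time_days, train$volume_mm3,
                                config$optimizer)
            vm <- logistic_volume(eval_times, fit$v0, fit$alpha_hat, fit$k_hat)
            push(data.frame(
              patient_id = tr$patient_id, alpha_truth = alpha,
              noise_level = level, replicate = rep_i, m = m,
              alpha_hat = fit$alpha_hat, k_hat = fit$k_hat,
              k_truth = tr$k_mm3,
              rmse = rmse(vm, eval_true),
              pct_err_alpha = percent_error(fit$alpha_hat, alpha),
              pct_err_k = percent_error(fit$k_hat, tr$k_mm3),
              pred_final_mm3 = vm[length(vm)],
              true_final_mm3 = tr$v_final_mm3,
              converged = fit$converged, identifiable = fit$identifiable,
              objective = fit$objective, stringsAsFactors = FALSE))
          }
        }
      }
    }
  }
  errors <- do.call(rbind, rows[seq_len(n_rows)])
  rownames(errors) <- NULL

  comparisons <- study_comparisons(errors, config)
  summary <- median_error_summary(errors)
  cfg_json <- jsonlite::toJSON(config[setdiff(names(config), "optimizer")],
                               auto_unbox = TRUE, digits = NA)
  provenance <- list(
    seed = config$seed,
    n_patients = nrow(volumes),
    n_fits = nrow(errors),
    config_json = as.character(cfg_json),
    config_hash = string_hash(as.character(cfg_json)),
    package_version = as.character(utils::packageVersion("logisuff"))
  )
  structure(list(errors = errors, comparisons = comparisons,
                 summary = summary, config = config, provenance = provenance),
            class = "study_results")
}

# stable 32-bit rolling hash of a string (provenance fingerprint)
string_hash <- function(s) {
  h <- 0
  for (x in utf8ToInt(s)) h <- (h * 31 + x) %% 2147483647
  sprintf("%08x", h)
}

# Mann-Whitney comparisons of adjacent measurement counts, all cells and
# metrics for which the configured m values allow them.
study_comparisons <- function(errors, config) {
  mc <- sort(config$measurement_counts)
  pairs <- Filter(function(pr) all(pr %in% mc),
                  list(c(3, 4), c(4, 5), c(5, 6)))
  if (length(pairs) == 0L) return(NULL)
  out <- list()
  for (alpha in config$growth_rates) {
    for (level in config$noise_levels) {
      cell <- errors[errors$alpha_truth == alpha & errors$noise_level == level, ]
      for (metric in c("rmse", "pct_err_alpha", "pct_err_k")) {
        cmp <- compare_measurement_counts(cell, metric, pairs)
        cmp <- cbind(alpha_truth = alpha, noise_level = level, cmp)
        out[[length(out) + 1L]] <- cmp
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Smallest sufficient number of measurements per study cell
#'
#' For each (growth rate, noise level) cell, the smallest configured
#' measurement count whose median absolute percent errors on both the
#' growth rate and the carrying capacity fall at or below the tolerance.
#' `NA` means no configured m qualifies. Larger tolerance can only lower
#' (never raise) the returned m.
#'
#' @param results A [run_study()] result, or a [median_error_summary()]
#'   data frame (e.g. read back from a written `summary.csv`).
#' @param tolerance Acceptable median percent error (default from the
#'   config when a full result is given).
#' @return Data frame `alpha_truth, noise_level, m_star`.
#' @export
minimal_sufficient_measurements <- function(results, tolerance = NULL) {
  if (inherits(results, "study_results")) {
    if (is.null(tolerance)) tolerance <- results$config$sufficiency_tolerance
    s <- results$summary
  } else {
    stopifnot(is.data.frame(results),
              all(c("alpha_truth", "noise_level", "m",
                    "med_pct_err_alpha", "med_pct_err_k") %in% names(results)))
    if (is.null(tolerance)) stop("minimal_sufficient_measurements: tolerance required with a summary table")
    s <- results
  }
  stopifnot(tolerance > 0)
  if (nrow(s) == 0L) stop("minimal_sufficient_measurements: empty results")
  key <- interaction(s$alpha_truth, s$noise_level, drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(s, key), function(cell) {
    ok <- cell$med_pct_err_alpha <= tolerance & cell$med_pct_err_k <= tolerance
    data.frame(alpha_truth = cell$alpha_truth[1],
               noise_level = cell$noise_level[1],
               m_star = if (any(ok)) min(cell$m[ok]) else NA_integer_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$alpha_truth, out$noise_level), , drop = FALSE]
}

#' Write study tables and provenance to a directory
#'
#' Emits `errors.csv`, `comparisons.csv`, `summary.csv`, `sufficiency.csv`
#' and `provenance.json`.
#'
#' @param results A [run_study()] result.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the named vector of written paths.
#' @export
write_report <- function(results, out_dir) {
  stopifnot(inherits(results, "study_results"))
  if (is.null(results$errors) || nrow(results$errors) == 0L) {
    stop("write_report: empty results")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(errors = file.path(out_dir, "errors.csv"),
             comparisons = file.path(out_dir, "comparisons.csv"),
             summary = file.path(out_dir, "summary.csv"),
             sufficiency = file.path(out_dir, "sufficiency.csv"),
             provenance = file.path(out_dir, "provenance.json"))
  utils::write.csv(results$errors, paths["errors"], row.names = FALSE)
  utils::write.csv(results$comparisons, paths["comparisons"], row.names = FALSE)
  utils::write.csv(results$summary, paths["summary"], row.names = FALSE)
  utils::write.csv(minimal_sufficient_measurements(results),
                   paths["sufficiency"], row.names = FALSE)
  jsonlite::write_json(results$provenance, paths["provenance"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' @export
print.study_results <- function(x, ...) {
  cat(sprintf(paste0("measurement-sufficiency study: %d fits ",
                     "(%d patients x %d rates x %d noise levels, seed %d)\n"),
              nrow(x$errors), x$provenance$n_patients,
              length(x$config$growth_rates), length(x$config$noise_levels),
              x$config$seed))
  invisible(x)
}
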