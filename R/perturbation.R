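#' Noise specification for the perturbation stage
#'
#' Multiplicative uniform measurement noise: each unprotected volume V is
#' replaced by VN = V * (1 + level * noise) with noise = 1 - 2r and r drawn
#' uniformly on [0, 1], i.e. `noise = a + (b - a) r` with the fixed bound
#' constants a = 1, b = -1. The study levels are 0 (none), 0.05, 0.10 and
#' 0.20; a noiseless level forces a single replicate since the perturbation
#' is then the identity.
#'
#' @param level Noise level in [0, 1); fraction of the volume.
#' @param replicates Replicates per noisy condition (default 10).
#' @param seed Master seed for the replicate streams.
#' @return A list of class `"noise_spec"`.
#' @export
noise_spec <- function(level, replicates = 10L, seed = 1L) {
  stopifnot(is.numeric(level), length(level) == 1L, level >= 0, level < 1,
            replicates >= 1L)
  if (level == 0) replicates <- 1L
  structure(list(level = level, replicates = as.integer(replicates),
                 seed = as.integer(seed), a = 1, b = -1),
            class = "noise_spec")
}

#' Deterministic child seed for one study cell
#'
#' Derives an independent, reproducible RNG stream seed for a single
#' (patient, growth rate, noise level, replicate) cell from the master
#' seed, by a fixed multiply-accumulate hash modulo 2^31 - 1. Any cell of
#' the study can thus be regenerated in isolation.
#'
#' @param master Master seed (integer).
#' @param ... Non-negative integer indices identifying the cell.
#' @return An integer seed in [1, 2^31 - 2].
#' @export
child_seed <- function(master, ...) {
  m <- 2147483647  # 2^31 - 1, keeps products exact in doubles
  idx <- c(as.numeric(master) %% m, as.numeric(c(...)))
  h <- 0
  for (x in idx) h <- ((h * 48271) %% m + (x + 1) * 1299721) %% m
  as.integer(h %% (m - 2) + 1)
}

#' Interpolate a ground-truth curve at clinical scan days
#'
#' Evaluates one patient's calibrated logistic curve at the scan-day grid
#' (default days 0, 7, 30, 60, 90, 120: first abnormal mammogram, a
#' follow-up screening, and typical pre-treatment wait times) and appends
#' the patient's final clinical observation as an evaluation-only point.
#' The day-0 and final clinical volumes are flagged `protected`: they are
#' taken to be without measurement error.
#'
#' @param truth One row of a [calibrate_cohort()] table (or any list with
#'   `v0_mm3`, `alpha_per_day`, `k_mm3`, `t_final_days`, `v_final_mm3`).
#' @param days Strictly increasing scan days starting at 0.
#' @return A data frame `time_days, volume_mm3, protected, is_final` with
#'   `length(days) + 1` rows.
#' @export
sample_at_days <- function(truth, days = c(0, 7, 30, 60, 90, 120)) {
  stopifnot(is.numeric(days), days[1] == 0, all(diff(days) > 0))
  if (truth$t_final_days <= max(days)) {
    stop(sprintf(paste0("sample_at_days: final clinical time (%g d) must lie ",
                        "beyond the training grid (last day %g)"),
                 truth$t_final_days, max(days)))
  }
  v <- logistic_volume(days, truth$v0_mm3, truth$alpha_per_day, truth$k_mm3)
  data.frame(
    time_days = c(days, truth$t_final_days),
    volume_mm3 = c(v, truth$v_final_mm3),
    protected = c(days == 0, TRUE),
    is_final = c(rep(FALSE, length(days)), TRUE)
  )
}

#' Inject multiplicative uniform noise into a measurement series
#'
#' Applies VN = V * (1 + level * (1 - 2r)), r ~ U(0, 1) independently per
#' unprotected point; protected points (day 0 and the final clinical
#' volume) keep their exact values. Level 0 is the identity. The bound
#' |VN/V - 1| <= level is asserted on every generated point.
#'
#' @param series Data frame from [sample_at_days()].
#' @param level Noise level in [0, 1).
#' @param seed RNG seed for this replicate's draws (see [child_seed()]);
#'   ignored when `r` is supplied.
#' @param r Optional explicit uniform draws on [0, 1], one per unprotected
#'   point (for deterministic checks).
#' @return The series with noisy volumes and the original volumes kept in
#'   `volume_true_mm3`.
#' @export
add_noise <- function(series, level, seed = NULL, r = NULL) {
  stopifnot(all(c("time_days", "volume_mm3", "protected") %in% names(series)),
            level >= 0, level < 1)
  out <- series
  out$volume_true_mm3 <- series$volume_mm3
  open <- !series$protected
  n_open <- sum(open)
  if (level > 0 && n_open > 0) {
    if (is.null(r)) {
      if (is.null(seed)) stop("add_noise: supply either seed or explicit draws r")
      r <- withr::with_seed(seed, stats::runif(n_open))
    }
    stopifnot(length(r) == n_open, all(r >= 0), all(r <= 1))
    noise <- 1 - 2 * r
    vn <- series$volume_mm3[open] * (1 + level * noise)
    stopifnot(all(vn > 0),
              all(abs(vn / series$volume_mm3[open] - 1) <= level + 1e-12))
    out$volume_mm3[open] <- vn
  }
  out
}

#' First m scan-day measurements as a training set
#'
#' m = 3 uses days 0, 7, 30; each additional measurement appends the next
#' scan day (60, 90, 120). The final clinical point is evaluation-only and
#' never enters training. The last training volume is the optimizer's
#' nominal carrying capacity.
#'
#' @param series Data frame from [sample_at_days()] / [add_noise()].
#' @param m Number of training measurements, `2 <= m <=` grid length.
#' @return The first `m` grid rows.
#' @export
training_subset <- function(series, m) {
  grid <- series[!series$is_final, , drop = FALSE]
  if (m < 2 || m > nrow(grid)) {
    stop(sprintf("training_subset: m = %d outside [2, %d]", m, nrow(grid)))
  }
  grid[seq_len(m), , drop = FALSE]
}
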