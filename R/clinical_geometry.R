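#' Tumor radius from major and minor axes
#'
#' The effective radius used for the sphere and cylinder volume formulas,
#' r = (2a + b) / 6, where `a` and `b` are the full major and minor axes in
#' mm. For a circular lesion (a = b = d) this reduces to d/2.
#'
#' @param a Major axis, mm (> 0).
#' @param b Minor axis, mm (> 0, `b <= a`).
#' @return Radius in mm.
#' @examples
#' radius_from_axes(12, 12) # 6
#' radius_from_axes(14, 8)  # 6
#' @export
radius_from_axes <- function(a, b) {
  if (any(!is.finite(a)) || any(!is.finite(b)) || any(a <= 0) || any(b <= 0)) {
    stop("radius_from_axes: axes must be finite and strictly positive")
  }
  if (any(b > a)) stop("radius_from_axes: minor axis exceeds major axis")
  (2 * a + b) / 6
}

#' Solid-shape tumor volume
#'
#' Volume of the three candidate solids used to reconstruct tumor volume
#' from two-dimensional measurements:
#' sphere V = 4*pi*r^3/3; cylinder V = pi*r^2*h; oblate spheroid
#' V = 4*pi*a^2*b/3 with `a_semi`, `b_semi` the semi-axes. With equal
#' semi-axes the oblate spheroid degenerates to the sphere.
#'
#' @param shape One of `"sphere"`, `"cylinder"`, `"oblate"`.
#' @param r Radius, mm (sphere, cylinder).
#' @param h Cylinder height, mm.
#' @param a_semi,b_semi Oblate spheroid semi-axes, mm.
#' @return Volume, mm^3.
#' @export
shape_volume <- function(shape = c("sphere", "cylinder", "oblate"),
                         r = NULL, h = NULL, a_semi = NULL, b_semi = NULL) {
  shape <- match.arg(shape)
  pos <- function(x, nm) {
    if (is.null(x)) stop(sprintf("shape_volume: '%s' is required for shape '%s'", nm, shape))
    if (any(!is.finite(x)) || any(x <= 0)) {
      stop(sprintf("shape_volume: '%s' must be finite and strictly positive", nm))
    }
    x
  }
  switch(shape,
    sphere   = 4 * pi * pos(r, "r")^3 / 3,
    cylinder = pi * pos(r, "r")^2 * pos(h, "h"),
    oblate   = 4 * pi * pos(a_semi, "a_semi")^2 * pos(b_semi, "b_semi") / 3
  )
}

#' Per-day exponential log growth rate between two volumes
#'
#' y = (ln Vt - ln V0) / t, the constant exponential rate implied by two
#' volume observations `t` days apart. Satisfies DT * y = ln 2 with DT the
#' doubling time.
#'
#' @param v0,vt Volumes, mm^3 (> 0).
#' @param t Elapsed time, days (> 0).
#' @return Rate in 1/day (0 when `vt == v0`, negative if shrinking).
#' @export
exponential_rate <- function(v0, vt, t) {
  if (any(v0 <= 0) || any(vt <= 0) || any(t <= 0)) {
    stop("exponential_rate: volumes must be positive and t > 0")
  }
  (log(vt) - log(v0)) / t
}

#' Tumor volume doubling time
#'
#' DT = ln(2) / y with y the per-day log growth rate between the two
#' observations (see [exponential_rate()]). Defined only for growing tumors
#' (`vt > v0`); one exact doubling over `t` days gives DT = t.
#'
#' @inheritParams exponential_rate
#' @return Doubling time, days.
#' @export
doubling_time <- function(v0, vt, t) {
  y <- exponential_rate(v0, vt, t)
  if (any(y <= 0)) {
    stop("doubling_time: no growth between observations (vt <= v0); DT undefined")
  }
  log(2) / y
}

shape_names <- c("sphere", "cylinder", "oblate")

# Volumes of all three candidate shapes for one axis observation.
# a, b are full axes (mm); the oblate formula uses semi-axes a/2, b/2;
# the cylinder height defaults to the minor axis when not recorded.
all_shape_volumes <- function(a, b, h = NULL) {
  if (is.null(h) || is.na(h)) h <- b
  r <- radius_from_axes(a, b)
  c(sphere   = shape_volume("sphere", r = r),
    cylinder = shape_volume("cylinder", r = r, h = h),
    oblate   = shape_volume("oblate", a_semi = a / 2, b_semi = b / 2))
}

#' One patient's two-timepoint clinical record
#'
#' The raw material of the study: tumor axis measurements at the first
#' abnormal mammogram (day 0) and at one later visit, plus the doubling
#' time reported in the clinical source. Patients with no reported doubling
#' time are retained but flagged `excluded` and skipped downstream.
#'
#' @param patient_id Identifier string.
#' @param t1_days Time of the second observation, days (> 0).
#' @param a0_mm,b0_mm,a1_mm,b1_mm Major/minor axes at the two visits, mm.
#' @param h0_mm,h1_mm Optional cylinder heights, mm; default minor axis.
#' @param reported_dt_days Reported doubling time, days; `NA` excludes the
#'   patient.
#' @return A list of class `"patient_record"`.
#' @export
patient_record <- function(patient_id, t1_days, a0_mm, b0_mm, a1_mm, b1_mm,
                           h0_mm = NA_real_, h1_mm = NA_real_,
                           reported_dt_days = NA_real_) {
  stopifnot(length(patient_id) == 1L, is.numeric(t1_days), t1_days > 0)
  for (x in list(a0_mm, b0_mm, a1_mm, b1_mm)) {
    if (!is.finite(x) || x <= 0) stop("patient_record: axes must be positive")
  }
  if (b0_mm > a0_mm || b1_mm > a1_mm) {
    stop("patient_record: minor axis exceeds major axis")
  }
  structure(list(patient_id = as.character(patient_id), t1_days = t1_days,
                 a0_mm = a0_mm, b0_mm = b0_mm, h0_mm = h0_mm,
                 a1_mm = a1_mm, b1_mm = b1_mm, h1_mm = h1_mm,
                 reported_dt_days = reported_dt_days,
                 excluded = is.na(reported_dt_days)),
            class = "patient_record")
}

#' Select the solid shape whose implied doubling time matches the record
#'
#' Computes initial and final volumes under all three candidate shapes,
#' derives each shape's implied doubling time from the two observations,
#' and selects the shape closest to the reported doubling time. Shapes with
#' non-growing implied volumes have no defined doubling time and cannot be
#' selected; ties are broken by the fixed order sphere, cylinder, oblate
#' for reproducibility.
#'
#' @param record A [patient_record()] with a reported doubling time.
#' @return A list of class `"shape_volume_set"`: `candidates` (data frame
#'   with per-shape `v0_mm3`, `vt_mm3`, `implied_dt_days`),
#'   `selected_shape`, and `discrepancy_days`.
#' @export
select_best_shape <- function(record) {
  stopifnot(inherits(record, "patient_record"))
  if (record$excluded) {
    stop(sprintf("select_best_shape: patient '%s' has no reported doubling time (excluded)",
                 record$patient_id))
  }
  v0 <- all_shape_volumes(record$a0_mm, record$b0_mm, record$h0_mm)
  vt <- all_shape_volumes(record$a1_mm, record$b1_mm, record$h1_mm)
  dt <- rep(NA_real_, 3L)
  growing <- vt > v0
  dt[growing] <- log(2) * record$t1_days / (log(vt[growing]) - log(v0[growing]))
  if (!any(growing)) {
    stop(sprintf("select_best_shape: no shape implies growth for patient '%s'",
                 record$patient_id))
  }
  disc <- abs(dt - record$reported_dt_days)
  sel <- which.min(disc)  # ties: first in fixed order sphere < cylinder < oblate
  structure(list(
    candidates = data.frame(shape = shape_names, v0_mm3 = unname(v0),
                            vt_mm3 = unname(vt), implied_dt_days = unname(dt)),
    selected_shape = shape_names[sel],
    discrepancy_days = unname(disc[sel])
  ), class = "shape_volume_set")
}

#' Two-point volume data for one patient under a given shape
#'
#' @param record A [patient_record()].
#' @param shape One of `"sphere"`, `"cylinder"`, `"oblate"`.
#' @return A list `(v0_mm3, vt_mm3, t_days)` consumed by calibration.
#' @export
patient_volumes <- function(record, shape = c("cylinder", "sphere", "oblate")) {
  stopifnot(inherits(record, "patient_record"))
  shape <- match.arg(shape)
  if (record$excluded) {
    stop(sprintf("patient_volumes: patient '%s' is excluded (no reported doubling time)",
                 record$patient_id))
  }
  v0 <- all_shape_volumes(record$a0_mm, record$b0_mm, record$h0_mm)[[shape]]
  vt <- all_shape_volumes(record$a1_mm, record$b1_mm, record$h1_mm)[[shape]]
  list(v0_mm3 = v0, vt_mm3 = vt, t_days = record$t1_days)
}

#' Read a two-timepoint cohort CSV
#'
#' Accepts either dialect: axes mode (`patient_id, t1_days, a0_mm, b0_mm,
#' h0_mm, a1_mm, b1_mm, h1_mm, reported_dt_days`, the `h` columns optional)
#' or volume mode (`patient_id, t1_days, v0_mm3, v1_mm3, reported_dt_days`).
#' A blank reported doubling time flags the patient excluded.
#'
#' @param path CSV file path.
#' @return The cohort data frame with an `excluded` logical column and a
#'   `"mode"` attribute (`"axes"` or `"volumes"`).
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "t1_days", "reported_dt_days")
  if (!all(need %in% names(df))) {
    stop("read_cohort: missing required columns ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  mode <- if (all(c("v0_mm3", "v1_mm3") %in% names(df))) "volumes"
          else if (all(c("a0_mm", "b0_mm", "a1_mm", "b1_mm") %in% names(df))) "axes"
          else stop("read_cohort: neither axes columns nor volume columns found")
  df$excluded <- is.na(df$reported_dt_days)
  attr(df, "mode") <- mode
  df
}

#' Reduce a cohort table to two-point volume data
#'
#' For an axes-mode cohort each included patient is run through
#' [select_best_shape()] and the selected shape's volumes are used; a
#' volume-mode cohort is passed through. Excluded patients are dropped with
#' a message reporting the count.
#'
#' @param cohort Data frame from [read_cohort()] or [generate_cohort()].
#' @return Data frame `patient_id, v0_mm3, vt_mm3, t_final_days,
#'   reported_dt_days, shape` (shape `NA` in volume mode), one row per
#'   included patient.
#' @export
cohort_volumes <- function(cohort) {
  mode <- attr(cohort, "mode")
  if (is.null(mode)) {
    mode <- if ("v0_mm3" %in% names(cohort)) "volumes" else "axes"
  }
  excl <- if ("excluded" %in% names(cohort)) cohort$excluded else is.na(cohort$reported_dt_days)
  if (any(excl)) {
    message(sprintf("cohort_volumes: %d patient(s) excluded (no reported doubling time)",
                    sum(excl)))
  }
  kept <- cohort[!excl, , drop = FALSE]
  if (nrow(kept) == 0L) stop("cohort_volumes: no included patients")
  if (mode == "volumes") {
    return(data.frame(patient_id = as.character(kept$patient_id),
                      v0_mm3 = kept$v0_mm3, vt_mm3 = kept$v1_mm3,
                      t_final_days = kept$t1_days,
                      reported_dt_days = kept$reported_dt_days,
                      shape = NA_character_, stringsAsFactors = FALSE))
  }
  h0 <- if ("h0_mm" %in% names(kept)) kept$h0_mm else rep(NA_real_, nrow(kept))
  h1 <- if ("h1_mm" %in% names(kept)) kept$h1_mm else rep(NA_real_, nrow(kept))
  out <- lapply(seq_len(nrow(kept)), function(i) {
    rec <- patient_record(kept$patient_id[i], kept$t1_days[i],
                          kept$a0_mm[i], kept$b0_mm[i], kept$a1_mm[i],
                          kept$b1_mm[i], h0_mm = h0[i], h1_mm = h1[i],
                          reported_dt_days = kept$reported_dt_days[i])
    sel <- select_best_shape(rec)
    pv <- patient_volumes(rec, sel$selected_shape)
    data.frame(patient_id = rec$patient_id, v0_mm3 = pv$v0_mm3,
               vt_mm3 = pv$vt_mm3, t_final_days = pv$t_days,
               reported_dt_days = rec$reported_dt_days,
               shape = sel$selected_shape, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
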