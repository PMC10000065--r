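---
title: "How many tumor volume measurements are enough? Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How many tumor volume measurements are enough? Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`logisuff` asks a practical question in mathematical oncology: given that
breast tumor volumes measured in the clinic carry noise, how many serial
measurements does it take to identify the two parameters of the logistic
growth model well enough to predict a patient's growth trajectory? This
vignette documents the model, the simulation design, every tunable
parameter with its default and rationale, and the places where the design
was genuinely open and a choice had to be made.

## The model

Tumor volume $V$ (mm$^3$) follows logistic growth,

$$\frac{dV}{dt} = \alpha V \left(1 - \frac{V}{K}\right),$$

with $\alpha$ (day$^{-1}$) the intrinsic, early-exponential growth rate and
$K$ (mm$^3$) the carrying capacity — the largest volume the patient's tumor
biology sustains. The closed form

$$V(t) = \frac{K}{1 + (K/V_0 - 1)\,e^{-\alpha t}}$$

is the canonical evaluator everywhere in the package (`logistic_volume()`);
it is written in terms of $e^{-\alpha t}$ so it cannot overflow for large
$\alpha t$. An adaptive ODE integration (`simulate_curve()`, `deSolve`,
relative tolerance $10^{-9}$) exists to validate the closed form — the test
suite holds them to $10^{-6}$ relative agreement over a 0–750 day grid —
and to keep the pipeline open to growth laws without a closed form
(Gompertz comparison is deliberately out of scope).

## From clinical axes to volumes

Two-timepoint clinical records carry tumor major/minor axes, not volumes.
The geometry module reconstructs an effective radius $r = (2a + b)/6$ from
the full axes and candidate volumes for three solids: sphere
($4\pi r^3/3$), cylinder ($\pi r^2 h$) and oblate spheroid
($4\pi a^2 b/3$ on the *semi*-axes). Each shape implies a volume doubling
time from the two visits, $DT = \ln 2 / y$ with
$y = (\ln V_t - \ln V_0)/t$; the shape whose implied doubling time is
closest to the reported one is selected per patient
(`select_best_shape()`). Three conventions had to be fixed where the
source measurement protocol is underspecified:

* **Cylinder height.** No per-tumor height exists in a two-axis record;
  the default is $h = b$ (the minor axis), overridable per record. This
  is an assumption, stated as such.
* **Axes vs semi-axes.** The radius formula takes full axes (so a
  circular lesion of diameter $d$ gives $r = d/2$); the oblate formula
  takes semi-axes. Conversion is explicit at call sites.
* **Ties.** Equal discrepancies are broken in the fixed order sphere,
  cylinder, oblate, purely for reproducibility.

Patients with no reported doubling time cannot be shape-checked and are
flagged excluded; they stay in the input file, are counted, and are
skipped downstream.

## Ground truth by nested calibration

Each patient contributes only two volumes, which cannot identify two
parameters per patient. The study therefore fixes one growth rate for the
whole cohort and solves each patient's carrying capacity in closed form so
the curve passes exactly through both clinical points
(`carrying_capacity_for()`):

$$K = \frac{V_t V_0 (e^{\alpha t} - 1)}{V_0 e^{\alpha t} - V_t},$$

defined whenever $\alpha$ exceeds the patient's two-point exponential rate
$y$ (an infeasible rate raises an error naming the minimum feasible one).
Three rates spanning slow to fast breast tumor growth are used in turn:
$\alpha \in \{0.0125, 0.025, 0.0545\}$ day$^{-1}$. The resulting
$3 \times 18$ curves are the ground truth for everything downstream.

## Sampling, noise, training subsets

Ground-truth curves are read off at scan days 0, 7, 30, 60, 90 and 120 —
first abnormal mammogram, follow-up screening, and typical pre-treatment
wait times — and the patient's final clinical observation
($t_{final} \in$ 120–750 days) is appended as an evaluation-only point
(`sample_at_days()`).

Measurement noise is multiplicative and bounded: each unprotected point
becomes $V_N = V (1 + \text{level} \cdot \text{noise})$ with
$\text{noise} = 1 - 2r$, $r \sim U(0,1)$ drawn independently per point,
at levels 5%, 10% and 20% (`add_noise()`). Two points are *protected* —
taken without error: the day-0 volume and the **final clinical** volume.
The day-120 scan is an interpolated point like any other and does receive
noise when used for training; only the patient's actual final observation
is treated as exact. Ten replicates per noisy cell emulate the stochastic
design; the noiseless level is deterministic and runs once. Independence
of draws across time points is the simplest reading of the noise recipe
and is the one implemented.

Training sets are nested prefixes of the grid: $m = 3$ uses days 0/7/30,
each further measurement appends the next scan day (`training_subset()`).
One noisy series per (patient, rate, level, replicate) is reused across
all $m$, so comparisons across measurement counts are paired. RNG
discipline: a master seed plus a fixed multiply-accumulate hash
(`child_seed()`) gives every cell its own reproducible stream, so any
single fit can be regenerated in isolation.

## Fitting

`fit_logistic()` minimizes the sum of squared *volume* residuals over
$(\alpha, K)$ with $V_0$ fixed to the day-0 measurement — volume space
because the study's error metric is defined on volumes. Numerical
choices:

* **Bounds** $\alpha \in (10^{-4}, 1]$ day$^{-1}$,
  $K \in (V_0(1+10^{-6}), 10^7]$ mm$^3$: the study's rates and volume
  range with generous headroom.
* **Initialization.** $K$ starts at the last training volume (the
  "nominal carrying capacity": the day-30/60/90/120 volume for
  $m = 3,4,5,6$). $\alpha$ starts at the exponential estimate from the
  first two points, plus four log-spaced fallback starts across
  $[10^{-3}, 0.5]$; five starts total, best final objective wins, ties to
  the earliest start. The multistart guards against the flat
  $\alpha$–$K$ ridge that short, near-exponential series produce.
* **Optimizer.** Bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) in
  log-parameter space (conditioning: $K$ spans four decades), tolerances
  $10^{-12}$, 200 iterations per start. The whole fit is deterministic,
  so identical inputs give bitwise-identical results.
* **Two-point fits** are structurally degenerate (one residual, two
  unknowns): they are flagged `identifiable = FALSE` and the per-start
  solutions are returned so the residual-degenerate ridge is visible.
  With three or more noiseless model-generated points the fit recovers
  the truth to $10^{-4}$ relative or better.

## Error metrics and statistics

Per fit (`run_study()` records one row each):

* the mean squared volume error $\frac{1}{N}\sum (V_m - V_d)^2$ over the
  full interpolated grid **plus** the final clinical volume ($N = 7$), so
  it mixes fit and prediction error. The quantity is a plain mean of
  squared residuals (mm$^6$) despite being conventionally called a
  *relative* MSE; a normalized variant (residuals divided by $V_d$) is
  available behind a flag, off by default. The comparison data $V_d$ are
  the noiseless ground-truth volumes;
* absolute percent errors $100|\hat\theta - \theta|/\theta$ to both true
  parameters;
* the predicted final volume.

Error distributions for adjacent measurement counts (3 vs 4, 4 vs 5,
5 vs 6) are compared with the two-sided Mann–Whitney U test
(`mann_whitney_u()`: midrank U, exact p for tie-free pooled samples up to
14 values, otherwise normal approximation with tie and continuity
corrections), annotated at the p < 0.01 / 0.005 / 0.001 tiers. Two
statistical choices are inherited from the study design and implemented
as stated rather than "improved": the replicate design is paired, yet the
unpaired Mann–Whitney test is specified — we flag but keep this — and no
multiple-testing correction is applied.

The decision output, `minimal_sufficient_measurements()`, reports per
(rate, level) the smallest $m$ whose **median** percent errors on both
parameters fall at or below a tolerance. Acceptable error is a clinical
judgment, so the tolerance is a knob (default 1%); medians are used
because occasional ridge-stranded fits make means unstable, and
non-converged fits are excluded from medians but counted.

## The synthetic cohort

The clinical table the design references (18 untreated breast cancer
patients, two visits each) is not public, so `generate_cohort()` draws
virtual patients matching its published envelope: $V_0 \sim U(80, 500)$
mm$^3$, doubling time $\sim U(60, 300)$ days, final visit
$\sim U(120, 750)$ days, final volume $V_t = V_0 2^{t/DT}$ capped at
11,000 mm$^3$ (the final time is resampled if the cap is exceeded).
Uniform draws are used because only ranges are known; the doubling-time
floor of 60 days keeps every patient feasible at the slowest study rate
($\ln 2 / 0.0125 \approx 55.45$ days), and between its two visits a
virtual patient grows exponentially at constant doubling time — the same
summary statistic the clinical source reported — with the logistic ground
truth imposed afterwards by calibration, exactly as with the real data.
In cylinder-axes mode the generator draws a visit-specific aspect ratio
$a/b \sim U(1.1, 2)$ and back-solves axes so the cylinder formula
reproduces the volumes exactly; because the aspect ratio changes between
visits, sphere and oblate reconstructions imply different doubling times
and the geometry module correctly selects the cylinder for every patient.

What the generator does *not* emulate: real lesions are measured on
discrete imaging grids (no rounding/quantization here), growth between
visits need not be exponential, doubling times are unlikely to be
uniform, and axes at the two visits are drawn without within-patient
shape correlation beyond volume. Passing tests therefore demonstrate the
pipeline's correctness and the identifiability structure of the design —
not that three measurements suffice for any particular clinical
population.

## Problem sizes and reproducibility

The default factorial — 18 patients × 3 rates × (1 noiseless + 3 noisy
levels × 10 replicates) × 4 measurement counts = 6,696 fits — is the
study design and is what `analysis/03_run_study.R` runs. For the
*directional* claims (error grows with noise, shrinks with measurement
count; slow growth overestimates the final volume), 10 replicates leave
visible Monte-Carlo wobble in cell medians, so the test suite scales that
one check to 100 replicates per cell (65,016 fits) and asserts direction
with one-sided sign tests at the 1% level, pairing by (patient,
replicate) and dropping ties. Everything is deterministic given the
master seed; reruns produce byte-identical error tables.

## Known limitations

* The sufficiency decision depends on the synthetic cohort's envelope;
  cohorts with later final visits or faster growth shift $m^*$.
* At the slowest rate with 3 noisy points the carrying-capacity error
  saturates (the fit collapses onto the ridge), so median errors there
  discriminate poorly between noise levels even though the sign tests
  still resolve the ordering.
* Point estimation only — no profile likelihood or posterior, matching
  the study design; the ridge is diagnosed via multistart spread rather
  than quantified.
* One growth law. The module boundaries (closed-form evaluator +
  ODE validator + fitter) are arranged so a Gompertz variant could be
  swapped in, but none is provided.
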