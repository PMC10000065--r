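#!/usr/bin/env Rscript
# Step 4: decision outputs. How many measurements are enough? The smallest
# m whose median percent errors on both parameters fall below a
# clinician-chosen tolerance, per (growth rate, noise level) cell, plus
# the Mann-Whitney U comparisons between error distributions for adjacent
# measurement counts (3 vs 4, 4 vs 5, 5 vs 6).

library(logisuff)

errors <- read.csv("results/study/errors.csv")
summary_tab <- read.csv("results/study/summary.csv")
comparisons <- read.csv("results/study/comparisons.csv")

cat("Smallest sufficient m by acceptable median parameter error:\n")
suff <- do.call(rbind, lapply(c(1, 5, 10, 25), function(tol) {
  s <- minimal_sufficient_measurements(summary_tab, tolerance = tol)
  s$tolerance_pct <- tol
  s
}))
suff <- suff[, c("tolerance_pct", "alpha_truth", "noise_level", "m_star")]
write.csv(suff, "results/sufficiency_by_tolerance.csv", row.names = FALSE)
print(reshape(suff, idvar = c("tolerance_pct", "alpha_truth"),
              timevar = "noise_level", direction = "wide"), row.names = FALSE)
cat("(NA: no configured measurement count reaches that tolerance)\n\n")

sig <- comparisons[comparisons$tier != "none", ]
cat(sprintf("Mann-Whitney comparisons: %d of %d significant below p = 0.01\n",
            nrow(sig), nrow(comparisons)))
if (nrow(sig) > 0) {
  print(sig[order(sig$alpha_truth, sig$noise_level, sig$metric, sig$m1),
            c("alpha_truth", "noise_level", "metric", "m1", "m2", "p", "tier")],
        row.names = FALSE)
}

cat("\nNoiseless headline: smallest sufficient m at a 1% tolerance is",
    max(minimal_sufficient_measurements(
      summary_tab[summary_tab$noise_level == 0, ], tolerance = 1)$m_star),
    "for every growth rate.\n")
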