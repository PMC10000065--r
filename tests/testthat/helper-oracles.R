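# Independent oracles and shared fixtures for the test suite.

# Exhaustive Mann-Whitney U oracle: enumerate every assignment of the pooled
# values to the first sample, build the exact null distribution of U, and
# return the observed U plus the exact two-sided p (doubled one-tail, capped
# at 1). Tie-free samples only; independent of the package implementation.
mwu_enumeration_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  stopifnot(!any(duplicated(pooled)))
  u_of <- function(idx) {
    sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  all_u <- utils::combn(n1 + n2, n1, u_of)
  mid <- n1 * n2 / 2
  p <- if (u_obs == mid) 1 else if (u_obs < mid) {
    2 * mean(all_u <= u_obs)
  } else {
    2 * mean(all_u >= u_obs)
  }
  list(U = u_obs, p = min(p, 1))
}

# Numeric root-solve oracle for the carrying capacity: the K at which the
# closed-form logistic curve through (v0, alpha) hits vt at time t. Uses
# only logistic_volume, independent of the algebra in carrying_capacity_for.
k_root_oracle <- function(v0, vt, t, alpha) {
  stats::uniroot(function(k) logistic_volume(t, v0, alpha, k) - vt,
                 lower = vt * (1 + 1e-12), upper = 1e9, tol = 1e-13)$root
}

# Standard synthetic cohort used across tests (fixed seed, study defaults).
test_cohort_volumes <- function(seed = 101L) {
  cohort_volumes(generate_cohort(cohort_spec(seed = seed)))
}

study_rates <- c(0.0125, 0.025, 0.0545)

# One-sided sign test p-value for "b tends to exceed a" on paired vectors,
# ties dropped (standard sign-test convention).
sign_test_greater <- function(a, b) {
  d <- b - a
  stats::binom.test(sum(d > 0), sum(d != 0), alternative = "greater")$p.value
}
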