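# Independent oracles used across the test files.  Each deliberately avoids
# the code path it checks.

# Bisection solver for mu = lambda (1 - p) / (1 - exp(-lambda)); independent
# of the Lambert-W route used by the package.
oracle_lambda <- function(mu, p, tol = 1e-12) {
  f <- function(l) l * (1 - p) / (1 - exp(-l)) - mu
  lo <- 1e-12
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  for (k in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# Combinatorial hypergeometric pmf for the overlap |s n U0|.
oracle_hyper_pmf <- function(k, n_s, N0, N) {
  choose(N0, k) * choose(N - N0, n_s - k) / choose(N, n_s)
}

# Independently coded three-phase closed-form variance (the explicit
# two-term + carried-fraction form, as opposed to the compact product form
# the package uses).
oracle_var_l3 <- function(strata, nu, n_s1, N) {
  stopifnot(strata$L == 3L)
  S2 <- strata$M$S2_M[1]
  (1 / n_s1 - 1 / N) * S2 +
    (1 / n_s1) * (1 / nu[2] - 1) * strata$M$W_M[2] * strata$M$S2_M[2] +
    (1 / n_s1) * (1 / nu[2]) * (1 / nu[3] - 1) *
      strata$M$W_M[3] * strata$M$S2_M[3]
}

# Random valid two-phase dataset with full response at the last phase (the
# regime in which the Hansen-Hurwitz and El-Badry formulas are defined).
rand_two_phase <- function() {
  N <- sample(50:300, 1)
  n_s1 <- sample(10:40, 1)
  n_r1 <- sample(2:(n_s1 - 4), 1)
  n_m1 <- n_s1 - n_r1
  n_s2 <- sample(2:n_m1, 1)
  list(p1 = phase_data(1, n_s1, n_r1, n_m1, rpois(n_r1, 2)),
       p2 = phase_data(2, n_s2, n_s2, 0, rpois(n_s2, 1)),
       N = N)
}

# Random valid L-phase dataset (nonresponse allowed at mailing waves, full
# response at the last phase); sizes kept clear of degenerate divisors.
rand_multiphase <- function(L) {
  # fixed valid size chain (nonresponse at every mailing wave, full response
  # at the interview phase); randomness lives in the bag values
  n_s <- c(40, 20, 10, 4)[seq_len(L)]
  n_m <- c(30, 12, 5, 0)[seq_len(L)]
  n_m[L] <- 0
  n_r <- n_s - n_m
  phases <- lapply(seq_len(L), function(i)
    phase_data(i, n_s[i], n_r[i], n_m[i], rpois(n_r[i], 1.5)))
  list(phases = phases, N = 2000)
}

# Exact design-space expectation for the two-phase design on a toy
# population: enumerates every first-phase sample, every randomized-rounding
# branch of n_s2 = nu_m * n_m1, and every subsample, with full response at
# phase 2 and a fixed respondent stratum R.  Returns exact E(t_hat),
# V(t_hat) and E(V_hat) for both variance estimators.
oracle_enumerate_two_phase <- function(y, R_idx, n_s1, nu_m) {
  N <- length(y)
  Et <- Et2 <- EV_hh <- EV_eb <- wsum <- 0
  for (s1 in utils::combn(N, n_s1, simplify = FALSE)) {
    r1 <- intersect(s1, R_idx)
    m1 <- setdiff(s1, R_idx)
    n_m1 <- length(m1)
    alpha <- n_m1 * nu_m
    omega <- alpha - floor(alpha)
    for (x in 0:1) {
      w_round <- if (x == 1) omega else 1 - omega
      if (w_round == 0) next
      n_s2 <- floor(alpha) + x
      stopifnot(n_s2 >= 1, n_s2 <= n_m1)  # fixture must avoid empty draws
      for (s2 in utils::combn(n_m1, n_s2, simplify = FALSE)) {
        w <- w_round / choose(N, n_s1) / choose(n_m1, n_s2)
        p1 <- phase_data(1, n_s1, length(r1), n_m1, y[r1])
        p2 <- phase_data(2, n_s2, n_s2, 0, y[m1[s2]])
        th <- hh_estimate(p1, p2, N)$total_hat
        Et <- Et + w * th
        Et2 <- Et2 + w * th^2
        EV_hh <- EV_hh + w * hh_variance_estimate(p1, p2, N) * N^2
        EV_eb <- EV_eb + w * eb_variance_estimate(list(p1, p2), N)
        wsum <- wsum + w
      }
    }
  }
  list(Et = Et, Vt = Et2 - Et^2, EV_hh = EV_hh, EV_eb = EV_eb, wsum = wsum)
}

# Small fixed test population; generated in code, no fixture files.
make_test_pop <- function(N = 400, p = 0.7, lambda = 2, seed = 99) {
  generate_population(N, hurdle_model(p = p, lambda = lambda), seed = seed)
}
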