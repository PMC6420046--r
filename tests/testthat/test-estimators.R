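# Shared toy datasets -------------------------------------------------------
toy_p1 <- phase_data(1, n_s = 10, n_r = 4, n_m = 6, y_r = c(2, 0, 0, 1))
toy_p2 <- phase_data(2, n_s = 3, n_r = 3, n_m = 0, y_r = c(0, 0, 1))

# An exact-fraction three-phase dataset: N = 100, nu = (0.2, 0.5, 0.5)
toy3 <- local({
  set.seed(44)
  list(p1 = phase_data(1, 20, 8, 12, rpois(8, 2)),
       p2 = phase_data(2, 6, 2, 4, rpois(2, 1)),
       p3 = phase_data(3, 2, 2, 0, rpois(2, 1)),
       N = 100, nu = c(0.2, 0.5, 0.5))
})

test_that("the two-phase point estimator matches hand evaluation and its reductions", {
  est <- hh_estimate(toy_p1, toy_p2, N = 100)
  expect_equal(est$mean_hat, (4 * 0.75 + 6 * (1 / 3)) / 10)  # = 0.5
  expect_equal(est$total_hat, 50)
  expect_equal(unname(est$phase_weights[1]), 4 / 10)
  expect_equal(unname(est$phase_weights["W_final"]), 0)
  # full response at phase 1: reduces to the SRSWOR mean
  full <- phase_data(1, 5, 5, 0, c(1, 2, 0, 0, 3))
  expect_equal(hh_estimate(full, NULL, 50)$mean_hat, mean(c(1, 2, 0, 0, 3)))
  # errors
  expect_error(hh_estimate(phase_data(1, 0, 0, 0, numeric(0)), NULL, 10),
               "empty")
  expect_error(hh_estimate(toy_p1, phase_data(2, 7, 7, 0, rep(0, 7)), 100),
               "exceeds")
})

test_that("the multiphase estimator agrees with the explicit three-phase form and the fraction form", {
  est <- eb_estimate(list(toy3$p1, toy3$p2, toy3$p3), toy3$N)
  # explicit three-phase form: (1/n_s1)(n_r1 yb_r1 + n_r2/v2 yb_r2 + n_m2/v2 yb_r3)
  v2 <- toy3$p2$n_s / toy3$p1$n_m
  direct <- (toy3$p1$n_r * mean(toy3$p1$y_r) +
             toy3$p2$n_r / v2 * mean(toy3$p2$y_r) +
             toy3$p2$n_m / v2 * mean(toy3$p3$y_r)) / toy3$p1$n_s
  expect_equal(est$mean_hat, direct, tolerance = 1e-12)
  # fraction form with exact integer sizes: sum n_ri/Pi_i yb_ri + n_ml/Pi_l yb_rL
  Pi <- cumprod(toy3$nu)
  t_nu <- (toy3$p1$n_r / Pi[1] * mean(toy3$p1$y_r) +
           toy3$p2$n_r / Pi[2] * mean(toy3$p2$y_r) +
           toy3$p2$n_m / Pi[2] * mean(toy3$p3$y_r))
  expect_equal(est$total_hat, t_nu, tolerance = 1e-12)
  # estimated stratum weights sum to the full-population weight here
  expect_equal(sum(est$phase_weights), 1, tolerance = 1e-12)
  expect_error(eb_estimate(list(toy3$p1), 100), "at least two")
})

test_that("two- and L=2 multiphase estimators coincide on random valid data", {
  set.seed(45)
  for (k in 1:300) {
    d <- rand_two_phase()
    a <- hh_estimate(d$p1, d$p2, d$N)
    b <- eb_estimate(list(d$p1, d$p2), d$N)
    expect_equal(a$mean_hat, b$mean_hat, tolerance = 1e-12)
    va <- hh_variance_estimate(d$p1, d$p2, d$N) * d$N^2
    vb <- eb_variance_estimate(list(d$p1, d$p2), d$N)
    expect_equal(va, vb, tolerance = 1e-10)
  }
})

test_that("variance estimators reduce correctly under full response", {
  set.seed(46)
  y <- rpois(12, 2)
  full <- phase_data(1, 12, 12, 0, y)
  # textbook SRSWOR variance estimator (1/n - 1/N) S^2_r
  expect_equal(hh_variance_estimate(full, NULL, 60),
               (1 / 12 - 1 / 60) * var(y), tolerance = 1e-12)
})

test_that("degenerate sizes yield NaN with a structured warning, never silent zero", {
  one <- phase_data(1, 1, 1, 0, 3)
  expect_warning(v <- hh_variance_estimate(one, NULL, 10),
                 class = "multibag_degenerate_variance")
  expect_true(is.nan(v))
  # a single phase-2 respondent leaves the needed dispersion undefined
  p2_single <- phase_data(2, 1, 1, 0, 2)
  expect_warning(v2 <- hh_variance_estimate(toy_p1, p2_single, 100),
                 class = "multibag_degenerate_variance")
  expect_true(is.nan(v2))
  # same policy for the general estimator
  expect_warning(
    v3 <- eb_variance_estimate(list(toy_p1, p2_single), 100),
    class = "multibag_degenerate_variance")
  expect_true(is.nan(v3))
})

test_that("theoretical variances: SRSWOR limit, L=2 reduction, and the three-phase oracle", {
  set.seed(47)
  y <- rpois(40, 1.5)
  memb2 <- sample(1:2, 40, replace = TRUE, prob = c(0.4, 0.6))
  st2 <- strata_summary(y, memb2)
  # nu_m = 1 (census of nonrespondents): plain SRSWOR variance
  expect_equal(hh_variance_true(st2, n_s1 = 10, N = 40, nu_m = 1),
               (1 / 10 - 1 / 40) * var(y), tolerance = 1e-12)
  # compact L-phase form at L = 2 equals the two-phase formula term-by-term
  expect_equal(
    unname(eb_variance_true(st2, phase_plan(c(0.25, 0.5)), 40)["mean"]),
    hh_variance_true(st2, n_s1 = 10, N = 40, nu_m = 0.5),
    tolerance = 1e-12)
  # L = 3 compact form against the independently coded explicit form
  memb3 <- sample(1:3, 40, replace = TRUE)
  st3 <- strata_summary(y, memb3)
  nu <- c(0.25, 0.5, 0.8)
  expect_equal(
    unname(eb_variance_true(st3, phase_plan(nu), 40)["mean"]),
    oracle_var_l3(st3, nu, n_s1 = 10, N = 40),
    tolerance = 1e-12)
  expect_error(hh_variance_true(st2, 10, 40, nu_m = 0), "\\(0, 1\\]")
})

test_that("exhaustive enumeration confirms exact unbiasedness of point and variance estimators", {
  # toy population, fixed respondent stratum, every design path enumerated
  y <- c(0, 0, 3, 1, 0, 2, 0, 5, 1)
  R_idx <- c(3, 4, 6, 9)
  en <- oracle_enumerate_two_phase(y, R_idx, n_s1 = 7, nu_m = 0.7)
  expect_equal(en$wsum, 1, tolerance = 1e-12)
  expect_equal(en$Et, sum(y), tolerance = 1e-10)           # E(t_hat) = t
  expect_equal(en$EV_hh, en$Vt, tolerance = 1e-10)         # E(V_hat) = V
  expect_equal(en$EV_eb, en$Vt, tolerance = 1e-10)
})

test_that("the census-first-phase subsampling variance is exact", {
  # nu_1 = 1 removes the first-phase term; enumerate the subsample draws
  y <- c(0, 2, 0, 4, 1, 0, 3, 0)
  memb <- c(1, 1, 1, 1, 2, 2, 2, 2)
  st <- strata_summary(y, memb)
  theo <- hh_variance_true(st, n_s1 = 8, N = 8, nu_m = 0.5)
  M <- which(memb == 2)
  p1 <- phase_data(1, 8, 4, 4, y[memb == 1])
  ests <- sapply(utils::combn(4, 2, simplify = FALSE), function(s2) {
    hh_estimate(p1, phase_data(2, 2, 2, 0, y[M[s2]]), 8)$mean_hat
  })
  n <- length(ests)
  expect_equal(mean(ests), mean(y), tolerance = 1e-12)
  expect_equal(sum((ests - mean(ests))^2) / n, theo, tolerance = 1e-12)
})

test_that("variance estimators are nonnegative on valid data", {
  set.seed(48)
  for (k in 1:200) {
    d <- rand_two_phase()
    expect_gte(hh_variance_estimate(d$p1, d$p2, d$N), 0)
  }
  for (L in 3:4) {
    for (k in 1:100) {
      d <- rand_multiphase(L)
      expect_gte(eb_variance_estimate(d$phases, d$N), 0)
    }
  }
})

test_that("the theoretical nonresponse bias follows the propensity product", {
  # pi_z = 0: ignorable nonresponse, zero bias
  expect_equal(nrbias_theoretical(0.85, 0, 2)$bias, 0)
  expect_equal(nrbias_theoretical(0.85, 0, 2)$bias_index, 1)
  # reference settings: ~34% and ~20% overestimation
  expect_equal(nrbias_theoretical(0.85, 0.30)$bias_index, 1 / 0.745)
  expect_equal(round(nrbias_theoretical(0.85, 0.30)$bias_index, 2), 1.34)
  expect_equal(round(nrbias_theoretical(0.85, 0.20)$bias_index, 2), 1.20)
  expect_equal(nrbias_theoretical(0.5, 0.4, 2)$bias, 0.4 * 0.5 * 2)
  expect_error(nrbias_theoretical(1, 0.2), "\\[0, 1\\)")
  expect_error(nrbias_theoretical(0.5, 1.2), "\\[0, 1\\]")
})

test_that("strata summaries satisfy the nested-weight recurrence", {
  set.seed(49)
  y <- rpois(60, 1)
  memb <- sample(1:4, 60, replace = TRUE)
  st <- strata_summary(y, memb)
  expect_identical(st$L, 4L)
  expect_equal(st$M$W_M[1], 1)                       # M_0 = U
  # W_Mi = W_R,i+1 + W_M,i+1 (with W_Ml = W_RL at the end)
  for (i in 0:2)
    expect_equal(st$M$W_M[i + 1], st$R$W_R[i + 1] + st$M$W_M[i + 2],
                 tolerance = 1e-12)
  expect_equal(st$M$W_M[4], st$R$W_R[4], tolerance = 1e-12)
  expect_equal(st$M$W_M[2], 1 - st$R$W_R[1], tolerance = 1e-12)
  expect_equal(st$M$S2_M[1], var(y), tolerance = 1e-12)
})

test_that("the estimation wrapper dispatches on the number of phases", {
  # L = 1: respondent mean with the SRSWOR variance estimator
  p1 <- phase_data(1, 8, 5, 3, c(1, 0, 2, 0, 0))
  e1 <- estimate_survey(list(p1), 50)
  expect_equal(e1$mean_hat, mean(c(1, 0, 2, 0, 0)))
  expect_equal(e1$var_hat_mean, (1 / 5 - 1 / 50) * var(c(1, 0, 2, 0, 0)))
  # L = 2 equals the two-phase pair
  e2 <- estimate_survey(list(toy_p1, toy_p2), 100)
  expect_equal(e2$mean_hat, 0.5)
  expect_equal(e2$var_hat_mean, hh_variance_estimate(toy_p1, toy_p2, 100))
  # L = 3 equals the general pair
  e3 <- estimate_survey(list(toy3$p1, toy3$p2, toy3$p3), toy3$N)
  expect_equal(e3$mean_hat,
               eb_estimate(list(toy3$p1, toy3$p2, toy3$p3), toy3$N)$mean_hat)
  expect_equal(e3$var_hat_total,
               eb_variance_estimate(list(toy3$p1, toy3$p2, toy3$p3), toy3$N))
})
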