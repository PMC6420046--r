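test_that("pool partitions satisfy their structural invariants", {
  set.seed(51)
  pop <- make_test_pop()
  pool <- seq_len(pop$N)
  for (k in 1:20) {
    part <- partition_pool(pool, pop$y, pi_m = 0.6, pi_z = 0.5)
    expect_setequal(c(part$R, part$M), pool)
    expect_length(intersect(part$R, part$M), 0)
    expect_true(all(part$Z %in% part$M))
    expect_true(all(pop$y[part$Z] == 0))
    expect_identical(length(part$R), part$N_R)
    expect_lte(part$N_Z, part$N_M)
  }
  # degenerate propensities
  p0 <- partition_pool(pool, pop$y, pi_m = 0, pi_z = 0.5)
  expect_setequal(p0$R, pool)
  expect_length(p0$M, 0)
  pz0 <- partition_pool(pool, pop$y, pi_m = 0.6, pi_z = 0)
  expect_length(pz0$Z, 0)
})

test_that("partition and sample sizes have the stated expectations", {
  set.seed(52)
  pop <- make_test_pop(N = 300)
  pool <- seq_len(300)
  reps <- 4000
  NM <- NZ <- nm <- nz <- numeric(reps)
  clipped <- 0L
  for (k in seq_len(reps)) {
    part <- partition_pool(pool, pop$y, pi_m = 0.5, pi_z = 0.4)
    sm <- apply_sample(pool, part, n_s = 150, n_units = 300)
    NM[k] <- part$N_M; NZ[k] <- part$N_Z
    nm[k] <- length(sm$m); nz[k] <- length(sm$z)
    clipped <- clipped + part$clipped
  }
  expect_identical(clipped, 0L)  # clipping is rare away from extremes
  # E(N_M) = N pi_m, E(N_Z) = N pi_z pi_m at the pool level (here hit
  # exactly: integer targets make the randomized rounding degenerate)
  expect_lte(abs(mean(NM) - 300 * 0.5), 4 * sd(NM) / sqrt(reps))
  expect_lte(abs(mean(NZ) - 300 * 0.4 * 0.5), 4 * sd(NZ) / sqrt(reps))
  # E(n_m) = n_s pi_m, E(n_z) = n_s pi_z pi_m in the sample
  expect_lt(abs(mean(nm) - 150 * 0.5), 4 * sd(nm) / sqrt(reps))
  expect_lt(abs(mean(nz) - 150 * 0.4 * 0.5), 4 * sd(nz) / sqrt(reps))
})

test_that("infeasible null-driven nonresponse is clipped and flagged", {
  # a population with no null bags cannot host any Z
  pop <- finite_population(rep(2L, 50))
  set.seed(53)
  part <- partition_pool(seq_len(50), pop$y, pi_m = 0.5, pi_z = 1)
  expect_identical(part$N_Z, 0L)
  expect_true(part$clipped)
  plan <- phase_plan(0.5)
  nr <- nonresponse_plan(0.5, 1)
  sv <- run_survey(pop, plan, nr)
  expect_gte(sv$clip_events, 1L)
})

test_that("survey realizations nest correctly across phases", {
  set.seed(54)
  pop <- make_test_pop()
  plan <- phase_plan(c(0.5, 0.5, 0.5))
  nr <- nonresponse_plan(c(0.6, 0.6, 0.3), 0.4)
  for (k in 1:10) {
    sv <- run_survey(pop, plan, nr, keep_sets = TRUE)
    prev_m <- seq_len(pop$N)
    for (i in seq_along(sv$phases)) {
      ph <- sv$phases[[i]]
      st <- sv$sets[[i]]
      expect_true(all(st$s %in% prev_m))               # s_{i+1} subset m_i
      expect_setequal(c(st$r, st$m), st$s)             # r u m = s
      expect_true(all(st$z %in% st$m))                 # z subset m
      expect_true(all(pop$y[st$z] == 0))
      expect_identical(ph$n_s, length(st$s))
      expect_identical(ph$n_r, length(st$r))
      expect_equal(ph$y_r, as.numeric(pop$y[st$r]))
      prev_m <- st$m
    }
  }
  expect_error(run_survey(pop, phase_plan(0.5), nr), "phases")
})

test_that("pi_z = 0 makes the mechanism ignorable (MCAR limit)", {
  pop <- make_test_pop()
  res <- mc_bias_index(pop, nu = 0.5, pi_m = 0.6, pi_z = 0,
                       reps = 3000, seed = 55)
  expect_lt(abs(res$r - 1), 4 * res$se)
})

test_that("the uni-phase bias index ignores the sampling fraction and is symmetric in the propensities", {
  pop <- make_test_pop()
  # invariance to nu at fixed (pi_m, pi_z)
  r1 <- mc_bias_index(pop, nu = 0.1, pi_m = 0.6, pi_z = 0.5,
                      reps = 4000, seed = 56)
  r2 <- mc_bias_index(pop, nu = 0.5, pi_m = 0.6, pi_z = 0.5,
                      reps = 4000, seed = 57)
  expect_lt(abs(r1$r - r2$r), 4 * sqrt(r1$se^2 + r2$se^2))
  # symmetry: only the product pi_z pi_m matters
  s1 <- mc_bias_index(pop, nu = 0.5, pi_m = 0.4, pi_z = 0.3,
                      reps = 4000, seed = 58)
  s2 <- mc_bias_index(pop, nu = 0.5, pi_m = 0.3, pi_z = 0.4,
                      reps = 4000, seed = 59)
  expect_lt(abs(s1$r - s2$r), 4 * sqrt(s1$se^2 + s2$se^2))
  # both sit near the closed-form index 1/(1 - pi_z pi_m)
  closed <- nrbias_theoretical(0.4, 0.3)$bias_index
  expect_lt(abs(s1$r - closed), 4 * s1$se)
})

test_that("nonresponse plans validate and recycle their propensities", {
  nr <- nonresponse_plan(c(0.85, 0.2), 0.3)
  expect_identical(nr$pi_z, c(0.3, 0.3))
  nr2 <- nonresponse_plan(c(0.85, 0.2), c(0.3, 0.1))
  expect_identical(nr2$pi_z, c(0.3, 0.1))
  expect_error(nonresponse_plan(1, 0.3), "\\[0, 1\\)")
  expect_error(nonresponse_plan(0.5, 1.2), "\\[0, 1\\]")
  expect_error(nonresponse_plan(c(0.5, 0.5), c(0.1, 0.2, 0.3)), "per phase")
})
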