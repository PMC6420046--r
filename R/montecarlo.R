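#' Bias index of a replicated estimator
#'
#' The bias index of an estimator \eqn{\hat\omega} of \eqn{\omega} is
#' \eqn{r = E(\hat\omega)/\omega}: overestimation for \eqn{r > 1},
#' unbiasedness for \eqn{r = 1}, underestimation for \eqn{r < 1}.  The
#' Monte Carlo standard error of `r` is reported alongside it.
#'
#' @param estimates numeric vector of replicate estimates.
#' @param truth the target value \eqn{\omega} (nonzero).
#' @return List with `r`, `se` (`NA` for a single replicate), `n`.
#' @export
bias_index <- function(estimates, truth) {
  if (!is.numeric(truth) || length(truth) != 1L || !is.finite(truth) ||
      truth == 0)
    stop("'truth' must be a single nonzero number (relative index undefined)")
  n <- length(estimates)
  if (n < 1L) stop("at least one estimate is required")
  list(r = mean(estimates) / truth,
       se = if (n > 1L) sd(estimates) / sqrt(n) / abs(truth) else NA_real_,
       n = n)
}

#' Bias index of a variance estimator
#'
#' \eqn{r_V = E(\hat V)/V_{MC}}, the mean of the replicate variance
#' estimates divided by the empirical (Monte Carlo) variance of the point
#' estimates.  The reported `se` reflects the numerator's Monte Carlo error
#' only (the denominator is treated as the reference).
#'
#' @param variance_estimates replicate variance estimates \eqn{\hat V}.
#' @param point_estimates the matching replicate point estimates.
#' @return List with `r_V`, `se`, `n`, `v_mc` (the empirical variance).
#' @export
variance_bias_index <- function(variance_estimates, point_estimates) {
  n <- length(point_estimates)
  if (n < 2L) stop("at least two replicates are required")
  if (length(variance_estimates) != n)
    stop("'variance_estimates' and 'point_estimates' lengths differ")
  v_mc <- var(point_estimates)
  if (v_mc == 0) stop("empirical variance of the point estimates is zero")
  list(r_V = mean(variance_estimates) / v_mc,
       se = sd(variance_estimates) / sqrt(n) / v_mc,
       n = n, v_mc = v_mc)
}

# --- RNG substreams ---------------------------------------------------------
# One MRG32k3a ("L'Ecuyer-CMRG") substream per replicate, chained
# deterministically from the master seed; cells of a scenario grid continue
# the same chain in row order, so a full run is reproducible bit-for-bit
# from (config, seed).

mc_stream_init <- function(seed) {
  set.seed(seed, kind = "L'Ecuyer-CMRG")
  get(".Random.seed", envir = globalenv())
}

mc_stream_next <- function(state) {
  state <- parallel::nextRNGStream(state)
  assign(".Random.seed", state, envir = globalenv())
  state
}

rng_snapshot <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

rng_restore <- function(snapshot) {
  if (!is.null(snapshot)) assign(".Random.seed", snapshot, envir = globalenv())
  invisible(NULL)
}

# One grid cell: replicate the survey + estimation, return summaries.
mc_cell <- function(pop, nu, pi_m, pi_z, reps, state,
                    estimator = c("auto", "respondent_mean"),
                    want_variance = FALSE) {
  estimator <- match.arg(estimator)
  L <- length(pi_m)
  if (length(nu) == 1L) nu <- rep(nu, L)
  plan <- phase_plan(nu)
  nrplan <- nonresponse_plan(pi_m, pi_z)
  use_resp_mean <- estimator == "respondent_mean" || L == 1L
  points <- numeric(reps)
  varests <- if (want_variance) numeric(reps) else NULL
  clip <- 0L
  for (j in seq_len(reps)) {
    state <- mc_stream_next(state)
    sv <- run_survey(pop, plan, nrplan)
    clip <- clip + sv$clip_events
    ph <- sv$phases
    points[j] <- if (use_resp_mean) {
      p1 <- ph[[1]]
      if (p1$n_r > 0L) mean(p1$y_r) else NA_real_
    } else eb_point_core(ph, pop$N)$total / pop$N
    if (want_variance) {
      varests[j] <- if (length(ph) >= 3L)
        eb_variance_estimate(ph, pop$N) / pop$N^2
      else if (length(ph) == 2L)
        hh_variance_estimate(ph[[1]], ph[[2]], pop$N)
      else {
        # chain ended at phase 1 (full response): SRSWOR variance estimator
        p1 <- ph[[1]]
        if (p1$n_r > 1L) (1 / p1$n_r - 1 / pop$N) * var(p1$y_r) else NaN
      }
    }
  }
  list(points = points, varests = varests, clip_events = clip, state = state)
}

#' Monte Carlo bias index of a multiphase estimator
#'
#' Replicates the nonresponse mechanism and the L-phase design on a fixed
#' finite population and returns the bias index \eqn{r = E(\hat{\bar y})/
#' \bar y} of the point estimator (the respondent mean for L = 1, the
#' Hansen-Hurwitz / El-Badry estimator otherwise) and, optionally, the
#' variance-estimator bias index \eqn{r_V = E(\hat V)/V_{MC}}.
#'
#' The truth is the fixed population's \eqn{\bar y} (design-based frame),
#' not the superpopulation mean.
#'
#' @param pop a [finite_population()], held fixed across replicates.
#' @param nu sampling fraction(s); scalar recycled to all phases.
#' @param pi_m per-phase nonresponse propensities (length = L).
#' @param pi_z null-harvest propensity (scalar or per-phase).
#' @param reps number of replicates.
#' @param seed master seed for the replicate substreams; `NULL` draws one
#'   from the current RNG.
#' @param estimator `"auto"` (respondent mean for L = 1, design estimator
#'   otherwise) or `"respondent_mean"`.
#' @param want_variance also compute per-replicate variance estimates and
#'   \eqn{r_V}.
#' @return List with `r`, `se`, `reps`, `clip_events`, `truth`,
#'   `mean_estimate` and, when requested, `r_V`, `se_rV`, `v_mc`,
#'   `mean_varest`.
#' @examples
#' m <- hurdle_model(p = 0.9, lambda = 3)
#' pop <- generate_population(500, m, seed = 7)
#' mc_bias_index(pop, nu = 0.5, pi_m = c(0.85, 0), pi_z = 0.2,
#'               reps = 50, seed = 1)$r  # ~1: unbiased at pi_m(L) = 0
#' @export
mc_bias_index <- function(pop, nu, pi_m, pi_z, reps, seed = NULL,
                          estimator = c("auto", "respondent_mean"),
                          want_variance = FALSE) {
  stopifnot(inherits(pop, "finite_population"))
  if (reps < 1L) stop("'reps' must be at least 1")
  snap <- rng_snapshot()
  on.exit(rng_restore(snap))
  if (is.null(seed)) seed <- sample.int(2^30, 1L)
  state <- mc_stream_init(seed)
  cell <- mc_cell(pop, nu, pi_m, pi_z, reps, state,
                  estimator = match.arg(estimator),
                  want_variance = want_variance)
  summarize_cell(cell, pop$ybar, reps, want_variance)
}

summarize_cell <- function(cell, truth, reps, want_variance) {
  pts <- cell$points[!is.na(cell$points)]
  bi <- bias_index(pts, truth)
  out <- list(r = bi$r, se = bi$se, reps = reps, used = length(pts),
              clip_events = cell$clip_events, truth = truth,
              mean_estimate = mean(pts))
  if (want_variance) {
    ok <- !is.na(cell$points) & is.finite(cell$varests)
    vb <- variance_bias_index(cell$varests[ok], cell$points[ok])
    out$r_V <- vb$r_V
    out$se_rV <- vb$se
    out$v_mc <- vb$v_mc
    out$mean_varest <- mean(cell$varests[ok])
  }
  out
}

#' Scenario configuration for the Monte Carlo engine
#'
#' Bundles a population specification, a design/nonresponse grid and
#' replication settings for [run_scenario()].  The grid is a data frame
#' whose recognized columns are `L`, `nu`, `pi_m_early` (the propensity at
#' phases 1..L-1), `pi_m_last` (the propensity at phase L; the only one for
#' L = 1) and `pi_z`; missing columns are filled from the scalar defaults.
#'
#' @param N,p,lambda,mu population specification (hurdle-at-zero Poisson;
#'   give `lambda` or `mu`).
#' @param grid data frame of cells, or `NULL` for a single cell.
#' @param L,nu,pi_m_early,pi_m_last,pi_z scalar defaults for grid cells.
#' @param reps replicates per cell.
#' @param seed master seed (replicate substreams).
#' @param pop_seed seed for the one fixed population (defaults to `seed`);
#'   the population is generated once per scenario and shared by all cells.
#' @param want_variance compute \eqn{r_V} per cell.
#' @param estimator passed to [mc_bias_index()].
#' @return An object of class `"scenario_config"`.
#' @export
scenario_config <- function(N = 10000, p = 0.955, lambda = 7, mu = NULL,
                            grid = NULL, L = 1, nu = 0.5,
                            pi_m_early = 0.85, pi_m_last = 0.85, pi_z = 0.2,
                            reps = 1000, seed = 1, pop_seed = NULL,
                            want_variance = FALSE, estimator = "auto") {
  defaults <- data.frame(L = L, nu = nu, pi_m_early = pi_m_early,
                         pi_m_last = pi_m_last, pi_z = pi_z)
  if (is.null(grid)) grid <- defaults
  for (col in names(defaults))
    if (is.null(grid[[col]])) grid[[col]] <- defaults[[col]]
  if (nrow(grid) < 1L) stop("the scenario grid is empty")
  if (reps < 1L) stop("'reps' must be at least 1")
  structure(list(N = N, p = p, lambda = lambda, mu = mu,
                 grid = grid, reps = reps, seed = seed,
                 pop_seed = if (is.null(pop_seed)) seed else pop_seed,
                 want_variance = want_variance, estimator = estimator),
            class = "scenario_config")
}

#' Run a Monte Carlo scenario over a parameter grid
#'
#' Generates one fixed finite population, then for every grid cell
#' replicates the multiphase survey and computes the bias index of the
#' point estimator (and of the variance estimator when requested).  The
#' whole run is deterministic given the configuration and seed; replicate
#' substreams are chained across cells in row order.
#'
#' @param config a [scenario_config()].
#' @return A long-format data frame: one row per cell with the grid
#'   coordinates, estimator name, `r`, `se`, optional `r_V`/`se_rV`,
#'   `reps`, `clip_events` and `seed`.  The generated population is
#'   attached as attribute `"population"`.
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  model <- if (is.null(config$mu)) hurdle_model(config$p, lambda = config$lambda)
           else hurdle_model(config$p, mu = config$mu)
  pop <- generate_population(config$N, model, seed = config$pop_seed)
  snap <- rng_snapshot()
  on.exit(rng_restore(snap))
  state <- mc_stream_init(config$seed)
  grid <- config$grid
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cell <- grid[g, ]
    L <- cell$L
    pi_m <- if (L == 1L) cell$pi_m_last
            else c(rep(cell$pi_m_early, L - 1L), cell$pi_m_last)
    res <- mc_cell(pop, cell$nu, pi_m, cell$pi_z, config$reps, state,
                   estimator = config$estimator,
                   want_variance = config$want_variance)
    state <- res$state
    s <- summarize_cell(res, pop$ybar, config$reps, config$want_variance)
    est_name <- if (L == 1L || config$estimator == "respondent_mean")
      "respondent_mean" else if (L == 2L) "hansen_hurwitz" else "el_badry"
    row <- data.frame(L = L, nu = cell$nu,
                      pi_m_early = if (L == 1L) NA_real_ else cell$pi_m_early,
                      pi_m_last = cell$pi_m_last, pi_z = cell$pi_z,
                      estimator = est_name, r = s$r, se = s$se)
    if (config$want_variance) {
      row$r_V <- s$r_V
      row$se_rV <- s$se_rV
    }
    row$reps <- config$reps
    row$clip_events <- s$clip_events
    row$seed <- config$seed
    rows[[g]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "population") <- pop
  out
}

#' Preset scenario configurations
#'
#' Ready-made [scenario_config()]s for the package's reference Monte Carlo
#' experiments on the standard study population (N = 10 000 hunters,
#' hurdle-at-zero Poisson with p = 0.955, lambda = 7):
#' \describe{
#'   \item{`bias_surface`}{uni-phase respondent-mean bias index over the
#'     \eqn{\pi_m \times \pi_z} grid 0(0.05)0.9, \eqn{\nu} = 0.5.}
#'   \item{`twophase_fractions`}{two-phase \eqn{r_{HH}} over
#'     \eqn{\nu = \nu_m} = 0.1(0.1)0.5 and \eqn{\pi_m(2)} = 0(0.1)0.9, with
#'     \eqn{\pi_m(1)} = 0.85, \eqn{\pi_z} = 0.2 (the fraction-invariance
#'     table).}
#'   \item{`twophase_lastphase`}{two-phase \eqn{r_{HH}} versus
#'     \eqn{\pi_m(2)} at \eqn{\nu = \nu_m} = 0.5.}
#'   \item{`twophase_variance`}{as `twophase_lastphase` but computing
#'     \eqn{r_V} of the variance estimator.}
#'   \item{`multiphase_L`}{\eqn{r_{EB}} for L = 2..6 versus
#'     \eqn{\pi_m(L)} = 0(0.1)0.9.}
#'   \item{`multiphase_moderate`}{detail for moderate last-phase
#'     nonresponse, L = 2..4, \eqn{\pi_m(L)} = 0(0.01)0.1.}
#'   \item{`multiphase_piz`}{L = 3, \eqn{\pi_z} = 0(0.1)0.9 versus
#'     \eqn{\pi_m(L)} = 0(0.1)0.9.}
#' }
#'
#' @param name preset name.
#' @param reps replicates per cell; defaults to the preset's reference
#'   count (reduce for quick runs).
#' @param seed master seed.
#' @return A [scenario_config()].
#' @export
scenario_presets <- function(name = c("bias_surface", "twophase_fractions",
                                      "twophase_lastphase",
                                      "twophase_variance", "multiphase_L",
                                      "multiphase_moderate",
                                      "multiphase_piz"),
                             reps = NULL, seed = 1) {
  name <- match.arg(name)
  pmgrid <- seq(0, 0.9, by = 0.1)
  cfg <- switch(name,
    bias_surface = list(
      grid = expand.grid(pi_m_last = seq(0, 0.9, by = 0.05),
                         pi_z = seq(0, 0.9, by = 0.05)),
      L = 1, reps = 100000),
    twophase_fractions = list(
      grid = expand.grid(nu = seq(0.1, 0.5, by = 0.1), pi_m_last = pmgrid),
      L = 2, reps = 1000),
    twophase_lastphase = list(
      grid = data.frame(pi_m_last = pmgrid), L = 2, reps = 1000),
    twophase_variance = list(
      grid = data.frame(pi_m_last = pmgrid), L = 2, reps = 1000000,
      want_variance = TRUE),
    multiphase_L = list(
      grid = expand.grid(L = 2:6, pi_m_last = pmgrid), reps = 10000),
    multiphase_moderate = list(
      grid = expand.grid(L = 2:4, pi_m_last = seq(0, 0.1, by = 0.01)),
      reps = 100000),
    multiphase_piz = list(
      grid = expand.grid(pi_m_last = pmgrid, pi_z = pmgrid),
      L = 3, reps = 10000))
  if (!is.null(reps)) cfg$reps <- reps
  cfg$seed <- seed
  do.call(scenario_config, cfg)
}
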