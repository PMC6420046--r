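#' Nonresponse plan for a multiphase survey
#'
#' Parameterizes the null-harvest-driven nonresponse mechanism applied at
#' each phase: `pi_m[i]` is the propensity to nonrespond at phase i (all
#' causes confounded) and `pi_z` the propensity, among the nonrespondents,
#' to nonrespond because the hunting bag was zero.  `pi_z = 0` makes the
#' mechanism ignorable (MCAR); the product \eqn{\pi_z \pi_m} drives the
#' upward bias of the respondent mean.  `pi_z` is a single value shared by
#' all phases by default, but a per-phase vector is accepted for
#' sensitivity analyses.
#'
#' @param pi_m numeric vector of per-phase nonresponse propensities, each in
#'   \eqn{[0, 1)}; its length is the number of phases L.
#' @param pi_z propensity in \eqn{[0, 1]}; scalar or length-L vector.
#' @return An object of class `"nonresponse_plan"` with `pi_m`, `pi_z`, `L`.
#' @export
nonresponse_plan <- function(pi_m, pi_z) {
  if (!is.numeric(pi_m) || length(pi_m) < 1L || any(!is.finite(pi_m)) ||
      any(pi_m < 0) || any(pi_m >= 1))
    stop("'pi_m' values must lie in [0, 1)")
  L <- length(pi_m)
  if (!is.numeric(pi_z) || any(!is.finite(pi_z)) ||
      any(pi_z < 0) || any(pi_z > 1))
    stop("'pi_z' values must lie in [0, 1]")
  if (length(pi_z) == 1L) pi_z <- rep(pi_z, L)
  if (length(pi_z) != L)
    stop("'pi_z' must be a scalar or have one value per phase")
  structure(list(pi_m = as.numeric(pi_m), pi_z = as.numeric(pi_z), L = L),
            class = "nonresponse_plan")
}

#' Partition a pool into respondents and nonrespondents
#'
#' Implements the null-harvest nonresponse mechanism on a pool of units:
#' draw \eqn{N_M} with \eqn{E(N_M) = N\pi_m} and \eqn{N_Z} with
#' \eqn{E(N_Z) = N\pi_z\pi_m} (both by randomized rounding); draw Z by
#' SRSWOR from the pool's zero-bag units; remove Z from the pool
#' (\eqn{C = U - Z}) and draw the respondent set R of size \eqn{N - N_M}
#' from C by SRSWOR; the nonrespondents are \eqn{M = U - R \supset Z}.
#' The "hole" Z makes null bags overrepresented among nonrespondents, which
#' is the sole nonignorable cause modeled.
#'
#' \eqn{N_Z} is clipped to \eqn{\min(N_M, N_0)} where \eqn{N_0} is the
#' pool's count of zero-bag units; clipping events are flagged so regimes
#' where they distort \eqn{E(N_Z)} can be detected (they are rare at
#' realistic parameter values).
#'
#' @param pool integer vector of unit indices (into `y`).
#' @param y population bag counts.
#' @param pi_m,pi_z propensities for this phase.
#' @return A list of class `"partition_realization"`: index vectors `R`,
#'   `M`, `Z`, sizes `N_R`, `N_M`, `N_Z`, and logical `clipped`.
#' @export
partition_pool <- function(pool, y, pi_m, pi_z) {
  Np <- length(pool)
  if (Np == 0L) stop("'pool' is empty")
  N_M <- randomized_round(Np * pi_m)
  N_Z <- randomized_round(Np * pi_z * pi_m)
  zero_pos <- which(y[pool] == 0)
  N_Z_clip <- min(N_Z, N_M, length(zero_pos))
  in_Z <- logical(Np)
  if (N_Z_clip > 0L)
    in_Z[zero_pos[sample.int(length(zero_pos), N_Z_clip)]] <- TRUE
  C <- pool[!in_Z]
  N_R <- Np - N_M
  R <- if (N_R > 0L) C[sample.int(length(C), N_R)] else integer(0)
  in_R <- logical(length(y))
  in_R[R] <- TRUE
  M <- pool[!in_R[pool]]
  structure(list(R = R, M = M, Z = pool[in_Z],
                 N_R = N_R, N_M = N_M, N_Z = N_Z_clip,
                 clipped = N_Z_clip < N_Z),
            class = "partition_realization")
}

#' Draw a sample and intersect it with a response partition
#'
#' Draws `s` of size `n_s` from the pool by SRSWOR and splits it by the
#' realized partition: respondents \eqn{r = s \cap R}, nonrespondents
#' \eqn{m = s \cap M}, and null-driven nonrespondents \eqn{z = s \cap Z}.
#' Over replicates, \eqn{E(n_m) = n_s\pi_m} and \eqn{E(n_z) =
#' n_s\pi_z\pi_m}.
#'
#' @param pool integer vector of unit indices.
#' @param partition a [partition_pool()] realization of the same pool.
#' @param n_s sample size, at most `length(pool)`.
#' @param n_units total number of population units (for index lookup
#'   tables); defaults to the largest index in the pool.
#' @return List with index vectors `s`, `r`, `m`, `z`.
#' @export
apply_sample <- function(pool, partition, n_s, n_units = max(pool)) {
  s <- srswor(pool, n_s)
  in_R <- logical(n_units); in_R[partition$R] <- TRUE
  in_Z <- logical(n_units); in_Z[partition$Z] <- TRUE
  keep <- in_R[s]
  list(s = s, r = s[keep], m = s[!keep], z = s[in_Z[s]])
}

#' Simulate one realization of a multiphase hunting bag survey
#'
#' Applies the nonresponse mechanism and the sampling design successively
#' to the nonrespondent pools \eqn{m_0 = U, m_1, \dots, m_\ell}: at each
#' phase i a fresh response partition of the pool is drawn with
#' \eqn{(\pi_m(i), \pi_z)} (respondence is redrawn independently per phase),
#' the target size \eqn{n_{si} = |pool| \cdot \nu_i} is materialized by
#' randomized rounding, and the drawn sample is split into respondents and
#' nonrespondents.  The chain stops early if a pool empties or a drawn size
#' is zero.
#'
#' @param pop a [finite_population()].
#' @param plan a [phase_plan()].
#' @param nrplan a [nonresponse_plan()] with the same number of phases.
#' @param keep_sets if `TRUE`, the per-phase index sets (`s`, `r`, `m`,
#'   `z`) and the pool each phase sampled from are retained (for
#'   diagnostics; the estimators only need the sizes and respondent bags).
#' @return An object of class `"survey_realization"`: list with `phases`
#'   (list of [phase_data()]), `N`, `clip_events` (count of \eqn{N_Z}
#'   clipping events), `n_z` (per-phase null-driven nonrespondent counts in
#'   the sample) and, if requested, `sets`.
#' @export
run_survey <- function(pop, plan, nrplan, keep_sets = FALSE) {
  stopifnot(inherits(pop, "finite_population"),
            inherits(plan, "phase_plan"),
            inherits(nrplan, "nonresponse_plan"))
  if (plan$L != nrplan$L)
    stop("sampling plan has ", plan$L, " phases but nonresponse plan has ",
         nrplan$L)
  y <- pop$y
  N <- pop$N
  pool <- seq_len(N)
  phases <- vector("list", plan$L)
  sets <- if (keep_sets) vector("list", plan$L) else NULL
  n_z <- integer(plan$L)
  clip_events <- 0L
  realized <- 0L
  for (i in seq_len(plan$L)) {
    if (length(pool) == 0L) break
    n_s <- randomized_round(length(pool) * plan$nu[i])
    if (n_s == 0L) break
    part <- partition_pool(pool, y, nrplan$pi_m[i], nrplan$pi_z[i])
    if (part$clipped) clip_events <- clip_events + 1L
    sm <- apply_sample(pool, part, n_s, n_units = N)
    phases[[i]] <- new_phase_data(i, n_s, length(sm$r), length(sm$m),
                                  as.numeric(y[sm$r]))
    n_z[i] <- length(sm$z)
    if (keep_sets) sets[[i]] <- c(sm, list(pool = pool))
    pool <- sm$m
    realized <- i
  }
  structure(list(phases = phases[seq_len(realized)], N = N,
                 clip_events = clip_events, n_z = n_z[seq_len(realized)],
                 sets = if (keep_sets) sets[seq_len(realized)]),
            class = "survey_realization")
}

#' Simulate a multiphase survey with a fixed respondent-stratum partition
#'
#' Deterministic-response variant of [run_survey()] used to study the
#' design itself: each unit belongs permanently to a respondent stratum
#' \eqn{R_i} (it responds at phase i and not before), so phase i's
#' respondents are \eqn{r_i = s_i \cap R_i} and its nonrespondents
#' \eqn{m_i = s_i \cap M_i}.  Under this regime the El-Badry estimator is
#' design-unbiased and its variance follows [eb_variance_true()] for the
#' matching [strata_summary()].
#'
#' @param pop a [finite_population()].
#' @param membership integer vector assigning each unit to its respondent
#'   stratum (values `1..L`).
#' @param plan a [phase_plan()] with L phases.
#' @return A `"survey_realization"` (without nonresponse diagnostics).
#' @export
run_survey_strata <- function(pop, membership, plan) {
  stopifnot(inherits(pop, "finite_population"), inherits(plan, "phase_plan"))
  if (length(membership) != pop$N)
    stop("'membership' must assign every population unit")
  if (max(membership) != plan$L)
    stop("'membership' uses ", max(membership), " strata but the plan has ",
         plan$L, " phases")
  y <- pop$y
  pool <- seq_len(pop$N)
  phases <- vector("list", plan$L)
  realized <- 0L
  for (i in seq_len(plan$L)) {
    if (length(pool) == 0L) break
    n_s <- randomized_round(length(pool) * plan$nu[i])
    if (n_s == 0L) break
    s <- srswor(pool, n_s)
    keep <- membership[s] == i
    r <- s[keep]
    m <- s[!keep]
    phases[[i]] <- new_phase_data(i, n_s, length(r), length(m),
                                  as.numeric(y[r]))
    pool <- m
    realized <- i
  }
  structure(list(phases = phases[seq_len(realized)], N = pop$N,
                 clip_events = 0L, n_z = NULL, sets = NULL),
            class = "survey_realization")
}

#' @export
print.survey_realization <- function(x, ...) {
  cat(sprintf("Multiphase survey realization (N = %d, %d phase(s))\n",
              x$N, length(x$phases)))
  for (ph in x$phases) print(ph)
  if (!is.null(x$clip_events) && x$clip_events > 0)
    cat("  N_Z clipping events:", x$clip_events, "\n")
  invisible(x)
}
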