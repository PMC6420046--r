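#' Per-phase survey data
#'
#' Holds what one phase of a nonrespondent-subsampling survey observes: the
#' drawn sample size \eqn{n_{si}}, the respondent count \eqn{n_{ri}}, the
#' nonrespondent count \eqn{n_{mi} = n_{si} - n_{ri}}, and the respondents'
#' bags.  Phase i+1 is always drawn from phase i's nonrespondents.
#'
#' @param i phase index (1-based).
#' @param n_s drawn sample size at this phase.
#' @param n_r respondent count.
#' @param n_m nonrespondent count; must satisfy `n_s == n_r + n_m`.
#' @param y_r numeric vector of the `n_r` respondent bag counts.
#' @return An object of class `"phase_data"`.
#' @export
phase_data <- function(i, n_s, n_r, n_m, y_r) {
  if (n_s != n_r + n_m)
    stop("phase ", i, ": n_s (", n_s, ") != n_r + n_m (", n_r + n_m, ")")
  if (length(y_r) != n_r)
    stop("phase ", i, ": length(y_r) is ", length(y_r), ", expected ", n_r)
  if (any(y_r < 0)) stop("phase ", i, ": bag counts must be non-negative")
  if (min(n_s, n_r, n_m) < 0) stop("phase ", i, ": negative size")
  new_phase_data(as.integer(i), as.integer(n_s), as.integer(n_r),
                 as.integer(n_m), as.numeric(y_r))
}

# fast unvalidated constructor for the simulation inner loop
new_phase_data <- function(i, n_s, n_r, n_m, y_r) {
  structure(list(i = i, n_s = n_s, n_r = n_r, n_m = n_m, y_r = y_r),
            class = "phase_data")
}

#' @export
print.phase_data <- function(x, ...) {
  cat(sprintf("Phase %d: n_s = %d, n_r = %d, n_m = %d, respondent mean = %s\n",
              x$i, x$n_s, x$n_r, x$n_m,
              if (x$n_r > 0) format(mean(x$y_r), digits = 5) else "-"))
  invisible(x)
}

check_nesting <- function(phases, N) {
  n_m_prev <- N
  for (ph in phases) {
    if (!inherits(ph, "phase_data")) stop("'phases' must contain phase_data")
    if (ph$n_s > n_m_prev)
      stop("phase ", ph$i, ": sample size ", ph$n_s,
           " exceeds the previous phase's nonrespondent count ", n_m_prev)
    n_m_prev <- ph$n_m
  }
  invisible(TRUE)
}

degenerate_variance <- function(msg) {
  warning(warningCondition(
    paste0("variance estimate undefined: ", msg),
    class = "multibag_degenerate_variance"))
  NaN
}

#' Nested respondent/nonrespondent strata summary
#'
#' Conditionally on the nonresponse, the population is stratified into
#' respondent strata \eqn{R_1, \dots, R_L} (units that would respond at
#' wave i) with nested nonrespondent strata \eqn{M_0 \supset M_1 \supset
#' \dots}, where \eqn{M_0 = U}, \eqn{M_i = \cup_{j > i} R_j} and
#' \eqn{M_\ell = R_L}.  This function computes the stratum sizes, weights,
#' means and dispersions needed by the theoretical variance formulas
#' ([hh_variance_true()], [eb_variance_true()]).
#'
#' @param y population bag counts.
#' @param membership integer vector assigning each unit to its respondent
#'   stratum, values in `1..L`.
#' @return An object of class `"strata_summary"`: a list with `L`, a data
#'   frame `M` (rows i = 0..L-1: `N_M`, `W_M`, `ybar_M`, `S2_M`) and a data
#'   frame `R` (rows i = 1..L: `N_R`, `W_R`, `ybar_R`).
#' @export
strata_summary <- function(y, membership) {
  if (length(y) != length(membership))
    stop("'y' and 'membership' must have equal length")
  if (any(membership < 1) || any(membership != floor(membership)))
    stop("'membership' must contain positive integers")
  L <- max(membership)
  N <- length(y)
  M <- data.frame(i = 0:(L - 1), N_M = NA_integer_, W_M = NA_real_,
                  ybar_M = NA_real_, S2_M = NA_real_)
  for (i in 0:(L - 1)) {
    idx <- membership > i
    ym <- y[idx]
    M$N_M[i + 1] <- length(ym)
    M$W_M[i + 1] <- length(ym) / N
    M$ybar_M[i + 1] <- if (length(ym) > 0) mean(ym) else NA_real_
    M$S2_M[i + 1] <- if (length(ym) > 1) var(ym) else NA_real_
  }
  R <- data.frame(i = 1:L,
                  N_R = as.integer(tabulate(membership, L)))
  R$W_R <- R$N_R / N
  R$ybar_R <- vapply(1:L, function(i) {
    yr <- y[membership == i]
    if (length(yr) > 0) mean(yr) else NA_real_
  }, numeric(1))
  structure(list(L = L, N = N, M = M, R = R), class = "strata_summary")
}

make_result <- function(estimator, N, mean_hat, var_hat_mean, phase_weights) {
  structure(
    list(estimator = estimator, N = N,
         mean_hat = mean_hat, total_hat = N * mean_hat,
         var_hat_mean = var_hat_mean,
         var_hat_total = N^2 * var_hat_mean,
         se_total = N * sqrt(var_hat_mean),
         phase_weights = phase_weights),
    class = "estimate_result")
}

#' @export
print.estimate_result <- function(x, ...) {
  cat(sprintf("%s estimate (N = %d)\n", x$estimator, x$N))
  cat(sprintf("  mean bag:  %.6g\n  total bag: %.6g\n", x$mean_hat, x$total_hat))
  if (!is.null(x$var_hat_total) && !is.na(x$var_hat_total))
    cat(sprintf("  var(total): %.6g  (SE %.6g)\n", x$var_hat_total, x$se_total))
  if (length(x$phase_weights))
    cat("  estimated stratum weights:",
        paste(format(x$phase_weights, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

# Shared point-estimator core: t_hat = sum_i (sum_{k in r_i} y_k) * c_i with
# c_i = prod_{j<=i} n_m,j-1 / n_sj.  When the last phase has full response
# this is exactly the El-Badry estimator (and Hansen-Hurwitz at L = 2); when
# some final nonrespondents are never interviewed their stratum contributes
# a vacuous term, which is what produces the downward bias studied by the
# Monte Carlo engine.
eb_point_core <- function(phases, N) {
  L <- length(phases)
  cum <- 1
  total <- 0
  W <- numeric(L)
  n_m_prev <- N
  realized <- 0L
  for (i in seq_len(L)) {
    ph <- phases[[i]]
    if (n_m_prev == 0L || ph$n_s == 0L) break   # vacuous chain tail
    cum <- cum * n_m_prev / ph$n_s
    total <- total + sum(ph$y_r) * cum
    W[i] <- ph$n_r * cum / N
    n_m_prev <- ph$n_m
    realized <- i
  }
  W_final <- if (realized > 0L) phases[[realized]]$n_m * cum / N else 1
  list(total = total, W = W[seq_len(realized)], W_final = W_final)
}

#' Hansen-Hurwitz two-phase estimator of the mean and total
#'
#' Phase 1 mails a questionnaire to an SRSWOR sample \eqn{s_1}; phase 2
#' interviews an SRSWOR subsample \eqn{s_2} of the phase-1 nonrespondents.
#' With full response at phase 2 the unbiased estimator is
#' \deqn{\bar y_{HH} = (n_{r1}\bar y_{r1} + n_{m1}\bar y_{r2}) / n_{s1}.}
#' If phase 2 itself suffers nonresponse, the interviewed respondents carry
#' the subsample's weight (\eqn{\bar y_{r2}} is replaced by
#' \eqn{\sum_{k \in r_2} y_k / n_{s2}}): the never-reached nonrespondents
#' contribute a vacuous term and the estimator is biased downwards.
#'
#' @param phase1,phase2 [phase_data()] objects; `phase2` may be `NULL` when
#'   phase 1 had full response (`n_m == 0`).
#' @param N population size.
#' @return An `"estimate_result"`: mean and total estimates plus the
#'   estimated stratum weights \eqn{(\hat W_{R1}, \hat W_{R2})}.  Variance
#'   estimation is separate, see [hh_variance_estimate()].
#' @examples
#' p1 <- phase_data(1, n_s = 10, n_r = 4, n_m = 6, y_r = c(2, 0, 0, 1))
#' p2 <- phase_data(2, n_s = 3, n_r = 3, n_m = 0, y_r = c(0, 0, 1))
#' hh_estimate(p1, p2, N = 100)$mean_hat  # 0.5
#' @export
hh_estimate <- function(phase1, phase2 = NULL, N) {
  stopifnot(inherits(phase1, "phase_data"))
  if (phase1$n_s == 0L) stop("phase 1 sample is empty")
  if (phase1$n_m > 0L && is.null(phase2))
    stop("phase 1 has nonrespondents: 'phase2' is required")
  phases <- if (is.null(phase2) || phase1$n_m == 0L) list(phase1)
            else list(phase1, phase2)
  check_nesting(phases, N)
  core <- eb_point_core(phases, N)
  make_result("Hansen-Hurwitz (two-phase)", N, core$total / N, NA_real_,
              c(core$W, W_final = core$W_final))
}

#' El-Badry multiphase estimator of the mean and total
#'
#' Generalizes [hh_estimate()] to \eqn{\ell} mailing waves followed by an
#' interview phase \eqn{L = \ell + 1}.  Written with the realized sample
#' sizes (the form robust to randomized rounding),
#' \deqn{\hat t_{EB} = \sum_{i=1}^{L} \Big(\sum_{k \in r_i} y_k\Big)
#'       \prod_{j=1}^{i} \frac{n_{m,j-1}}{n_{sj}}, \qquad n_{m0} = N,}
#' which is unbiased when the response rate at phase L is 100\%.  A phase
#' with `n_m == 0` (or a drawn size of zero) terminates the chain; later
#' phases are vacuous and only realized terms are summed.  Unreached
#' last-phase nonrespondents likewise contribute nothing, making the
#' estimator biased downwards when \eqn{\pi_m(L) > 0}.
#'
#' @param phases list of [phase_data()] for phases 1..L (L >= 2), each drawn
#'   from the previous phase's nonrespondents.
#' @param N population size.
#' @return An `"estimate_result"` with the estimated stratum weights
#'   \eqn{\hat W_{Ri} = n_{ri}/(N\hat\Pi_i)} and, as `W_final`, the weight
#'   estimated for the never-interviewed final nonrespondent stratum.
#' @export
eb_estimate <- function(phases, N) {
  if (length(phases) < 2L)
    stop("'phases' must contain at least two phases; see hh_estimate for L = 2")
  check_nesting(phases, N)
  if (phases[[1]]$n_s == 0L) stop("phase 1 sample is empty")
  core <- eb_point_core(phases, N)
  make_result(sprintf("El-Badry (%d-phase)", length(phases)), N,
              core$total / N, NA_real_, c(core$W, W_final = core$W_final))
}

#' Theoretical sampling variance of the Hansen-Hurwitz estimator
#'
#' \deqn{V_p(\bar y_{HH}) = \Big(\frac{1}{n_{s1}} - \frac{1}{N}\Big) S^2 +
#'   \frac{1}{n_{s1}}\Big(\frac{1}{\nu_m} - 1\Big) W_M S_M^2,}
#' requiring the full-population respondent/nonrespondent partition, so it
#' is available in simulations only.  At \eqn{\nu_m = 1} it reduces to the
#' SRSWOR variance.  Assumes exact (unrounded) subsample sizes
#' \eqn{n_{s2} = \nu_m n_{m1}}; randomized rounding adds a small convexity
#' term not included here.
#'
#' @param strata a two-stratum [strata_summary()] (L = 2).
#' @param n_s1 first-phase sample size.
#' @param N population size.
#' @param nu_m subsampling fraction of nonrespondents, in (0, 1].
#' @return The variance of the mean estimator; multiply by \eqn{N^2} for the
#'   total.
#' @export
hh_variance_true <- function(strata, n_s1, N, nu_m) {
  stopifnot(inherits(strata, "strata_summary"))
  if (strata$L != 2L) stop("'strata' must describe a two-phase partition")
  if (!is.numeric(nu_m) || length(nu_m) != 1L || nu_m <= 0 || nu_m > 1)
    stop("'nu_m' must lie in (0, 1]")
  S2 <- strata$M$S2_M[1]   # i = 0: the whole population
  (1 / n_s1 - 1 / N) * S2 +
    (1 / n_s1) * (1 / nu_m - 1) * strata$M$W_M[2] * strata$M$S2_M[2]
}

#' Theoretical sampling variance of the El-Badry estimator
#'
#' The compact L-phase form
#' \deqn{V_p(\bar y_{EB}) = \frac{1}{N} \sum_{i=1}^{L} \Pi_i
#'   \Big(\frac{1}{\nu_i} - 1\Big) W_{M_{i-1}} S^2_{M_{i-1}},}
#' where the inverse-fraction product is \eqn{\Pi_1 = 1} and \eqn{\Pi_i =
#' \prod_{j=1}^{i-1} 1/\nu_j} for \eqn{i > 1} (note: a different product
#' from the forward-fraction \eqn{\Pi_i = \prod_{j \le i}\nu_j} used by the
#' stratum-weight estimators, and from the size-ratio products of
#' [eb_variance_estimate()]).  For L = 2 this is [hh_variance_true()]
#' term-by-term.
#'
#' @param strata a [strata_summary()] with L strata.
#' @param plan a [phase_plan()] with the same number of phases.
#' @param N population size.
#' @return Named vector `c(mean = V_p(ybar_EB), total = N^2 V_p(ybar_EB))`.
#' @export
eb_variance_true <- function(strata, plan, N) {
  stopifnot(inherits(strata, "strata_summary"), inherits(plan, "phase_plan"))
  if (plan$L != strata$L)
    stop("plan has ", plan$L, " phases but strata describe ", strata$L)
  nu <- plan$nu
  L <- plan$L
  inv_prod <- c(1, cumprod(1 / nu[-L]))   # Pi_i = prod_{j<i} 1/nu_j
  v <- sum(inv_prod * (1 / nu - 1) * strata$M$W_M * strata$M$S2_M) / N
  c(mean = v, total = N^2 * v)
}

#' Unbiased variance estimator for the Hansen-Hurwitz estimator
#'
#' The nonnegative unbiased estimator of \eqn{V_p(\bar y_{HH})} (unbiased
#' under full response at phase 2):
#' \deqn{\hat V_p(\bar y_{HH}) =
#'  \frac{(n_{r1}-1)(N-n_{s1})}{N(n_{s1}-1)n_{s1}} S^2_{r1}
#'  + \frac{N-1}{N}\Big(\frac{n_{m1}-1}{n_{s1}-1} -
#'      \frac{n_{r2}-1}{N-1}\Big)\frac{w_m}{n_{r2}} S^2_{r2}
#'  + \frac{N-n_{s1}}{N(n_{s1}-1)}\big[w_r(\bar y_{r1}-\bar y_{HH})^2 +
#'      w_m(\bar y_{r2}-\bar y_{HH})^2\big]}
#' with \eqn{w_r = n_{r1}/n_{s1}}, \eqn{w_m = n_{m1}/n_{s1}}.  The formula
#' is written for full response at the interview phase (\eqn{n_{r2} =
#' n_{s2}}); if the realization nevertheless records phase-2 nonrespondents,
#' they are treated as null harvests, the same convention the point
#' estimator embodies.  \eqn{\bar y_{HH}} is the realized point estimate.
#' At \eqn{n_{m1} = 0} it reduces to the textbook SRSWOR variance estimator
#' \eqn{(1/n_{s1} - 1/N) S^2_{r1}}.
#'
#' Degenerate sizes: a dispersion whose algebraic coefficient is zero is
#' never evaluated; a dispersion that is needed but has fewer than two
#' contributing units yields `NaN` with a warning of class
#' `"multibag_degenerate_variance"` (never silently zero).
#'
#' @inheritParams hh_estimate
#' @return Estimated variance of the mean estimator (multiply by \eqn{N^2}
#'   for the total), or `NaN` for degenerate inputs.
#' @export
hh_variance_estimate <- function(phase1, phase2 = NULL, N) {
  stopifnot(inherits(phase1, "phase_data"))
  n_s1 <- phase1$n_s; n_r1 <- phase1$n_r; n_m1 <- phase1$n_m
  if (n_s1 < 2L)
    return(degenerate_variance("first-phase sample size below 2"))
  if (n_m1 > 0L && is.null(phase2))
    stop("phase 1 has nonrespondents: 'phase2' is required")
  ybar_hh <- hh_estimate(phase1, phase2, N)$mean_hat
  w_r <- n_r1 / n_s1; w_m <- n_m1 / n_s1

  coef1 <- (n_r1 - 1) * (N - n_s1) / (N * (n_s1 - 1) * n_s1)
  if (coef1 == 0) term1 <- 0
  else if (n_r1 < 2L)
    return(degenerate_variance("fewer than 2 phase-1 respondents"))
  else term1 <- coef1 * var(phase1$y_r)

  if (n_m1 == 0L) {
    term2 <- 0
    term3 <- (N - n_s1) / (N * (n_s1 - 1)) *
      w_r * (mean(phase1$y_r) - ybar_hh)^2
  } else {
    y2 <- last_phase_bags(phase2)
    n_r2 <- length(y2)
    if (n_r2 < 2L)
      return(degenerate_variance("fewer than 2 phase-2 observations"))
    ybar_r2 <- mean(y2)
    term2 <- (N - 1) / N *
      ((n_m1 - 1) / (n_s1 - 1) - (n_r2 - 1) / (N - 1)) *
      w_m / n_r2 * var(y2)
    ybar_r1 <- if (n_r1 > 0L) mean(phase1$y_r) else 0  # w_r = 0 then
    term3 <- (N - n_s1) / (N * (n_s1 - 1)) *
      (w_r * (ybar_r1 - ybar_hh)^2 + w_m * (ybar_r2 - ybar_hh)^2)
  }
  term1 + term2 + term3
}

# Last-phase data under the null-imputation convention: the interview phase
# is designed to reach everyone, so its formulas are written for n_rL =
# n_sL.  If the realization nevertheless records last-phase nonrespondents,
# they are treated as null harvests (the convention the point estimator
# embodies: unreached units contribute nothing to the respondent total).
last_phase_bags <- function(ph) {
  if (ph$n_m > 0L) c(ph$y_r, numeric(ph$n_m)) else ph$y_r
}

#' Unbiased variance estimator for the El-Badry estimator (any L)
#'
#' The general unbiased estimator of \eqn{V_p(\hat t_{EB})},
#' \deqn{\hat V_p(\hat t_{EB}) = \sum_{i=1}^{\ell} \Pi_i
#'   \frac{n_{m,i-1}(n_{m,i-1} - n_{si})}{n_{si}(n_{si}-1)}
#'   \Big(z_i - \frac{t_i^2}{n_{si}}\Big) +
#'   \Pi_L\, n_{m\ell}^2\Big(\frac{1}{n_{sL}} - \frac{1}{n_{m\ell}}\Big)
#'   S^2_{rL},}
#' where the size-ratio products are \eqn{\Pi_1 = 1} and
#' \eqn{\Pi_i = \prod_{j=1}^{i-1} n_{m,j-1}(n_{m,j-1}-1) /
#' (n_{sj}(n_{sj}-1))}, and the backward recursions are
#' \eqn{t_L = \sum_{k \in r_L} y_k}, \eqn{t_i = \sum_{k \in r_i} y_k +
#' (n_{mi}/n_{s,i+1})\, t_{i+1}} (and \eqn{z} likewise with \eqn{y_k^2}).
#' Unbiased for \eqn{V_p(\hat t_{EB})} under full response at phase L; for
#' L = 2 it equals \eqn{N^2} times [hh_variance_estimate()].  Last-phase
#' nonrespondents, if any, are treated as null harvests (see
#' [hh_variance_estimate()]).
#'
#' The degenerate-size policy of [hh_variance_estimate()] applies: any
#' divisor \eqn{(n_{si} - 1)} with \eqn{n_{si} \le 1}, or a needed
#' \eqn{S^2_{rL}} with fewer than two last-phase respondents, yields `NaN`
#' with a structured warning.
#'
#' @inheritParams eb_estimate
#' @return Estimated variance of the total estimator (divide by \eqn{N^2}
#'   for the mean), or `NaN` for degenerate inputs.
#' @export
eb_variance_estimate <- function(phases, N) {
  L <- length(phases)
  if (L < 2L) stop("'phases' must contain at least two phases")
  check_nesting(phases, N)
  ell <- L - 1L
  n_s <- vapply(phases, `[[`, integer(1), "n_s")
  n_m <- vapply(phases, `[[`, integer(1), "n_m")
  n_m_prev <- c(N, n_m[-L])            # n_m,i-1 with n_m0 = N
  if (any(n_s[seq_len(ell)] < 2L))
    return(degenerate_variance("a mailing-wave sample size is below 2"))

  # backward recursions over respondent totals (zero-imputed at phase L)
  yL <- last_phase_bags(phases[[L]])
  t_i <- z_i <- numeric(L)
  t_i[L] <- sum(yL)
  z_i[L] <- sum(yL^2)
  for (i in rev(seq_len(ell))) {
    t_i[i] <- sum(phases[[i]]$y_r) + n_m[i] / n_s[i + 1] * t_i[i + 1]
    z_i[i] <- sum(phases[[i]]$y_r^2) + n_m[i] / n_s[i + 1] * z_i[i + 1]
  }

  size_prod <- cumprod(c(1, n_m_prev[seq_len(ell)] *
                              (n_m_prev[seq_len(ell)] - 1) /
                              (n_s[seq_len(ell)] * (n_s[seq_len(ell)] - 1))))
  idx <- seq_len(ell)
  waves <- sum(size_prod[idx] *
                 n_m_prev[idx] * (n_m_prev[idx] - n_s[idx]) /
                 (n_s[idx] * (n_s[idx] - 1)) *
                 (z_i[idx] - t_i[idx]^2 / n_s[idx]))

  if (n_m[ell] > 0L && n_s[L] == 0L)
    return(degenerate_variance("last phase drew no sample"))
  coef_last <- if (n_m[ell] == 0L) 0
               else size_prod[L] * n_m[ell]^2 * (1 / n_s[L] - 1 / n_m[ell])
  if (coef_last == 0) last <- 0
  else if (length(yL) < 2L)
    return(degenerate_variance("fewer than 2 last-phase observations"))
  else last <- coef_last * var(yL)
  waves + last
}

#' Theoretical nonresponse bias of the respondent mean
#'
#' Under the null-harvest nonresponse mechanism the bias of the uni-phase
#' respondent mean is \eqn{\mathrm{NRBias}(\bar y_r) = \pi_z \pi_m
#' E(\bar y_r)}, so that solving \eqn{E(\bar y_r)(1 - \pi_z\pi_m) = \bar y}
#' gives the bias index \eqn{r = 1/(1 - \pi_z\pi_m)}: the product
#' \eqn{\pi_z\pi_m} alone drives the overestimation, and the sampling
#' fraction plays no role.
#'
#' @param pi_m propensity to nonrespond, in \eqn{[0, 1)}.
#' @param pi_z propensity, among nonrespondents, to nonrespond because of a
#'   null bag, in \eqn{[0, 1]}.
#' @param respondent_mean expected respondent mean \eqn{E(\bar y_r)}
#'   (optional; `NA` gives `bias = NA` but still returns the index).
#' @return List with `bias` (\eqn{\pi_z\pi_m E(\bar y_r)}) and `bias_index`
#'   (\eqn{1/(1 - \pi_z\pi_m)}).
#' @examples
#' nrbias_theoretical(0.85, 0.30, NA)$bias_index  # ~1.34: 34% overestimation
#' @export
nrbias_theoretical <- function(pi_m, pi_z, respondent_mean = NA_real_) {
  if (pi_m < 0 || pi_m >= 1) stop("'pi_m' must lie in [0, 1)")
  if (pi_z < 0 || pi_z > 1) stop("'pi_z' must lie in [0, 1]")
  list(bias = pi_z * pi_m * respondent_mean,
       bias_index = 1 / (1 - pi_z * pi_m))
}

#' Estimate mean, total and sampling variance from multiphase survey data
#'
#' Convenience wrapper dispatching on the number of phases: the respondent
#' mean with the SRSWOR variance estimator for L = 1, [hh_estimate()] +
#' [hh_variance_estimate()] for L = 2, and [eb_estimate()] +
#' [eb_variance_estimate()] for L >= 3.
#'
#' @param phases a list of [phase_data()] (or a `"survey_realization"` from
#'   [run_survey()]).
#' @param N population size.
#' @return A complete `"estimate_result"` (point estimates, variance
#'   estimates, standard error, per-phase stratum weights).
#' @export
estimate_survey <- function(phases, N) {
  if (inherits(phases, "survey_realization")) {
    N <- phases$N
    phases <- phases$phases
  }
  L <- length(phases)
  if (L == 0L) stop("no phase data")
  if (L == 1L) {
    ph <- phases[[1]]
    if (ph$n_r == 0L) stop("no respondents in the uni-phase sample")
    vhat <- if (ph$n_r > 1L) (1 / ph$n_r - 1 / N) * var(ph$y_r) else NaN
    res <- make_result("Respondent mean (uni-phase)", N, mean(ph$y_r), vhat,
                       c(W_R1 = ph$n_r / ph$n_s))
  } else if (L == 2L) {
    res <- hh_estimate(phases[[1]], phases[[2]], N)
    v <- hh_variance_estimate(phases[[1]], phases[[2]], N)
    res <- make_result(res$estimator, N, res$mean_hat, v, res$phase_weights)
  } else {
    res <- eb_estimate(phases, N)
    v <- eb_variance_estimate(phases, N) / N^2
    res <- make_result(res$estimator, N, res$mean_hat, v, res$phase_weights)
  }
  res
}
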