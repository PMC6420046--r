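#' Multiphase sampling plan
#'
#' Records the per-phase sampling fractions \eqn{\nu_1, \dots, \nu_L} of an
#' L-phase nonrespondent-subsampling design.  Phase 1 samples the population
#' (\eqn{n_{s1} = N\nu_1}); each later phase i samples the nonrespondents of
#' phase i-1 (\eqn{n_{si} = n_{m,i-1}\,\nu_i}).  The first \eqn{\ell = L-1}
#' phases are mailing waves; phase L is the personal-interview phase.
#'
#' @param nu numeric vector of sampling fractions, each in (0, 1]; its
#'   length is the number of phases L.
#' @return An object of class `"phase_plan"` with elements `nu`, `L`, `ell`.
#' @export
phase_plan <- function(nu) {
  if (!is.numeric(nu) || length(nu) < 1L || any(!is.finite(nu)) ||
      any(nu <= 0) || any(nu > 1))
    stop("'nu' must be a non-empty vector of fractions in (0, 1]")
  structure(list(nu = as.numeric(nu), L = length(nu), ell = length(nu) - 1L),
            class = "phase_plan")
}

#' Randomized rounding of an expected set size
#'
#' Returns an integer with expectation exactly `alpha`: \eqn{\lfloor\alpha
#' \rfloor + 1} with probability \eqn{\omega = \alpha - \lfloor\alpha\rfloor}
#' and \eqn{\lfloor\alpha\rfloor} otherwise (variance
#' \eqn{\omega(1-\omega)}).  Deterministic rounding of the per-phase target
#' sizes \eqn{n_{si} = n_{m,i-1}\nu_i} would bias their expectations, so
#' every set size drawn in this package goes through this two-point
#' distribution.
#'
#' @param alpha non-negative expected size(s); vectorized.
#' @return Integer vector of the same length as `alpha`.
#' @export
randomized_round <- function(alpha) {
  if (!is.numeric(alpha) || any(!is.finite(alpha)) || any(alpha < 0))
    stop("'alpha' must be non-negative and finite")
  f <- floor(alpha)
  as.integer(f + (runif(length(alpha)) < (alpha - f)))
}

#' Simple random sampling without replacement
#'
#' Draws a uniformly random `n`-subset of `pool`; every unit has inclusion
#' probability `n / length(pool)`.
#'
#' @param pool vector of unit identifiers (typically population indices).
#' @param n integer sample size, `0 <= n <= length(pool)`.
#' @return A vector of `n` distinct elements of `pool` (the pool itself when
#'   `n == length(pool)`).
#' @export
srswor <- function(pool, n) {
  np <- length(pool)
  if (!is.numeric(n) || length(n) != 1L || n != floor(n) || n < 0)
    stop("'n' must be a single non-negative integer")
  if (n > np)
    stop("sample size ", n, " exceeds pool size ", np)
  if (n == np) return(pool)
  pool[sample.int(np, n)]
}
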