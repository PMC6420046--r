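#' Hurdle-at-zero Poisson superpopulation model
#'
#' Builds the two-parameter count model used as a superpopulation for
#' individual hunting bags: a point mass `p` at zero and a rescaled Poisson
#' on the positive counts,
#' \deqn{\Pr(Y = y) = p \;\; (y = 0), \qquad
#'       \Pr(Y = y) = \phi e^{-\lambda}\lambda^y / y! \;\; (y \ge 1),}
#' with hurdle factor \eqn{\phi = (1 - p)/(1 - e^{-\lambda})}.  The model is
#' over- or underdispersed relative to the Poisson according to
#' \eqn{\phi \ne 1}; at \eqn{\phi = 1} (i.e. \eqn{p = e^{-\lambda}}) it is
#' exactly Poisson.  Mean and variance are \eqn{\mu = \phi\lambda} and
#' \eqn{\mu_2 = \phi\lambda(1 + \lambda) - \phi^2\lambda^2}.
#'
#' Exactly one of `lambda` and `mu` must be supplied; when `mu` is given,
#' `lambda` is recovered with [solve_lambda()].
#'
#' @param p probability of a null bag, in \eqn{[0, 1]}.
#' @param lambda Poisson rate \eqn{\lambda > 0} of the positive branch.
#' @param mu model mean, an alternative to `lambda`.
#' @return An object of class `"hurdle_model"`: a list with elements `p`,
#'   `lambda`, `phi`, `mu`, `mu2`.
#' @seealso [hurdle_pmf()], [hurdle_moments()], [generate_population()]
#' @examples
#' m <- hurdle_model(p = 0.955, lambda = 7)
#' m$mu   # about 0.315 bags per hunter
#' @export
hurdle_model <- function(p, lambda = NULL, mu = NULL) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("'p' must be a single probability in [0, 1]")
  if (is.null(lambda) == is.null(mu))
    stop("supply exactly one of 'lambda' and 'mu'")
  if (is.null(lambda)) lambda <- solve_lambda(mu, p)
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda <= 0)
    stop("'lambda' must be a single positive number")
  phi <- (1 - p) / (1 - exp(-lambda))
  structure(
    list(p = p, lambda = lambda, phi = phi,
         mu = phi * lambda,
         mu2 = phi * lambda * (1 + lambda) - phi^2 * lambda^2),
    class = "hurdle_model")
}

#' @export
print.hurdle_model <- function(x, ...) {
  cat("Hurdle-at-zero Poisson model\n")
  cat(sprintf("  p = %.6g, lambda = %.6g, phi = %.6g\n", x$p, x$lambda, x$phi))
  cat(sprintf("  mean mu = %.6g, variance mu2 = %.6g\n", x$mu, x$mu2))
  invisible(x)
}

#' Solve for the Poisson rate of a hurdle model from its mean
#'
#' Inverts \eqn{\mu = \lambda(1 - p)/(1 - e^{-\lambda})} for \eqn{\lambda}.
#' The closed form uses the upper branch \eqn{W_0} of the Lambert function:
#' \eqn{\lambda = W_0(D e^D) - D} with \eqn{D = \mu/(p - 1)}.  A bisection
#' fallback on the transcendental equation is used if the Lambert evaluation
#' is numerically unreliable (the two routes agree to at least 1e-8 wherever
#' both apply).
#'
#' A solution with \eqn{\lambda > 0} exists iff \eqn{\mu > 1 - p}
#' (equivalently \eqn{D < -1}), since \eqn{\mu \to 1 - p} as
#' \eqn{\lambda \to 0}.
#'
#' @param mu target model mean, `mu > 1 - p`.
#' @param p probability of a null bag, strictly inside (0, 1).
#' @return The rate `lambda` satisfying the mean equation to relative
#'   accuracy better than 1e-10.
#' @examples
#' solve_lambda(0.3153, 0.955)  # about 7
#' @export
solve_lambda <- function(mu, p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p >= 1)
    stop("'p' must lie strictly inside (0, 1)")
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu <= 0)
    stop("'mu' must be a single positive number")
  if (mu <= 1 - p)
    stop("no positive solution: 'mu' must exceed 1 - p (here ",
         format(1 - p), ")")
  D <- mu / (p - 1)                      # D < -1 by the check above
  lam <- pracma::lambertWp(D * exp(D)) - D
  f <- function(l) l * (1 - p) / (1 - exp(-l)) - mu
  if (!is.finite(lam) || lam <= 0 || abs(f(lam)) > 1e-10 * mu) {
    upper <- 2 * mu / (1 - p) + 10       # mu(l) ~ (1-p) l for large l
    lam <- stats::uniroot(f, c(1e-12, upper), tol = 1e-14)$root
  }
  lam
}

#' Probability mass function of the hurdle-at-zero Poisson model
#'
#' @param y vector of non-negative integer counts.
#' @param model a [hurdle_model()].
#' @return `Pr(Y = y)` for each element of `y`.
#' @examples
#' m <- hurdle_model(p = 0.955, lambda = 7)
#' hurdle_pmf(0:3, m)
#' @export
hurdle_pmf <- function(y, model) {
  stopifnot(inherits(model, "hurdle_model"))
  if (!is.numeric(y) || any(!is.finite(y)) || any(y < 0) ||
      any(y != floor(y)))
    stop("'y' must contain non-negative integers")
  ifelse(y == 0, model$p, model$phi * dpois(y, model$lambda))
}

#' Mean and variance of a hurdle-at-zero Poisson model
#'
#' @param model a [hurdle_model()].
#' @return A named numeric vector `c(mu = ..., mu2 = ...)` with the model
#'   mean \eqn{\phi\lambda} and variance
#'   \eqn{\phi\lambda(1+\lambda) - \phi^2\lambda^2}.
#' @export
hurdle_moments <- function(model) {
  stopifnot(inherits(model, "hurdle_model"))
  c(mu = model$mu, mu2 = model$mu2)
}

#' Draw counts from a hurdle-at-zero Poisson model
#'
#' Zeros occur with probability `p`; positive draws come from the
#' zero-truncated Poisson via inverse-cdf sampling.
#'
#' @param n number of draws.
#' @param model a [hurdle_model()].
#' @return An integer vector of length `n`.
#' @export
rhurdle <- function(n, model) {
  stopifnot(inherits(model, "hurdle_model"))
  y <- integer(n)
  pos <- runif(n) >= model$p
  k <- sum(pos)
  if (k > 0) {
    p0 <- ppois(0, model$lambda)
    y[pos] <- qpois(runif(k, p0, 1), model$lambda)
  }
  y
}

#' Finite population of hunting bags
#'
#' Wraps a vector of `N` non-negative integer bags \eqn{y_k} with the
#' derived quantities used throughout: the null-bag stratum size
#' \eqn{N_0 = |\{k : y_k = 0\}|} and its weight \eqn{W_0 = N_0/N}, the mean
#' \eqn{\bar y}, the total \eqn{t = N\bar y}, and the dispersion
#' \eqn{S^2 = (N-1)^{-1}\sum_k (y_k - \bar y)^2} (the 1/(N-1) convention is
#' used for every dispersion in this package).
#'
#' @param y vector of non-negative integer bag counts.
#' @return An object of class `"finite_population"`: a list with elements
#'   `y`, `N`, `N0`, `W0`, `ybar`, `total`, `S2`.
#' @export
finite_population <- function(y) {
  if (!is.numeric(y) || length(y) < 1L || any(!is.finite(y)) ||
      any(y < 0) || any(y != floor(y)))
    stop("'y' must be a non-empty vector of non-negative integers")
  y <- as.integer(y)
  N <- length(y)
  structure(
    list(y = y, N = N, N0 = sum(y == 0L), W0 = mean(y == 0L),
         ybar = mean(y), total = sum(y),
         S2 = if (N > 1L) var(y) else NA_real_),
    class = "finite_population")
}

#' @export
print.finite_population <- function(x, ...) {
  cat(sprintf("Finite population: N = %d hunters, N0 = %d null bags (W0 = %.4f)\n",
              x$N, x$N0, x$W0))
  cat(sprintf("  total bag t = %d, mean = %.5g, S2 = %.5g\n",
              x$total, x$ybar, x$S2))
  invisible(x)
}

#' Generate a finite population from a superpopulation model
#'
#' Draws `N` i.i.d. bags from a hurdle-at-zero Poisson model.  In a
#' design-based simulation the population is generated once and held fixed
#' across replicates; only the sampling and the nonresponse mechanism are
#' replicated.
#'
#' @param N population size.
#' @param model a [hurdle_model()].
#' @param seed optional integer; when given, the population is drawn from a
#'   private RNG stream and the caller's RNG state is left untouched.
#' @return A [finite_population()].  The model parameters and seed are
#'   attached as attribute `"meta"`.
#' @export
generate_population <- function(N, model, seed = NULL) {
  stopifnot(inherits(model, "hurdle_model"))
  if (!is.numeric(N) || length(N) != 1L || N < 1 || N != floor(N))
    stop("'N' must be a positive integer")
  draw <- function() rhurdle(N, model)
  y <- if (is.null(seed)) draw() else with_preserved_rng(seed, draw())
  pop <- finite_population(y)
  attr(pop, "meta") <- list(p = model$p, lambda = model$lambda,
                            seed = if (is.null(seed)) NA_integer_ else seed)
  pop
}

# Evaluate expr under set.seed(seed) without disturbing the caller's stream.
with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
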