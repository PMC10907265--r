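#' Saturating growth curve for expected parity by age
#'
#' Expected cumulative parity rises from 0 at `a0` toward the asymptote `M`
#' as \eqn{\lambda(a) = M (1 - e^{-k (a - a0)})^b}. With `b = 1` this is the
#' monomolecular (von Bertalanffy-type) curve; `b > 1` delays the take-off,
#' giving the slow start typical of reproductive careers.
#'
#' @param age Age in years (vector allowed). Must be non-negative.
#' @param M Asymptotic expected parity (> 0).
#' @param k Rate of approach to the asymptote, per year (> 0).
#' @param b Shape/elasticity parameter (> 0).
#' @param a0 Age at which the curve leaves zero (default 0). Ages below `a0`
#'   return 0.
#' @return Expected parity \eqn{\lambda(age)}, same length as `age`.
#' @examples
#' growth_curve(20, M = 4, k = 0.1, b = 2)
#' @export
growth_curve <- function(age, M, k, b, a0 = 0) {
  if (any(!is.finite(age)) || any(age < 0)) {
    stop("'age' must be finite and non-negative")
  }
  if (any(M <= 0) || any(k <= 0) || any(b <= 0)) {
    stop("growth parameters M, k, b must all be positive")
  }
  s <- pmax(0, 1 - exp(-k * (age - a0)))
  M * s^b
}

#' One-inflated Poisson distribution
#'
#' Mixture placing extra probability mass `theta` on the count 1 and mass
#' `1 - theta` on a Poisson with rate `lambda`:
#' \eqn{P(y) = \theta [y = 1] + (1 - \theta) Pois(y; \lambda)}.
#' Parity distributions in reproductive-history data show excess mass at
#' parity 1 relative to a Poisson fit; `theta` absorbs it.
#'
#' @param y Non-negative integer count(s).
#' @param lambda Poisson rate (> 0).
#' @param theta One-inflation probability in \eqn{[0, 1)}.
#' @param log Return log-probability?
#' @return Probability mass (or its log) at `y`.
#' @examples
#' doip(1, lambda = 2, theta = 0.1, log = TRUE)
#' @export
doip <- function(y, lambda, theta, log = FALSE) {
  if (any(y < 0) || any(y != floor(y))) stop("'y' must be non-negative integer")
  if (any(lambda <= 0)) stop("'lambda' must be positive")
  if (any(theta < 0) || any(theta >= 1)) stop("'theta' must lie in [0, 1)")
  p <- (1 - theta) * stats::dpois(y, lambda)
  p <- p + theta * (y == 1)
  if (log) base::log(p) else p
}

#' @rdname doip
#' @param n Number of draws.
#' @details `roip()` additionally accepts `theta = 1` (all mass on parity 1),
#'   which is useful for degenerate simulation checks.
#' @export
roip <- function(n, lambda, theta) {
  if (any(lambda <= 0)) stop("'lambda' must be positive")
  if (any(theta < 0) || any(theta > 1)) stop("'theta' must lie in [0, 1]")
  inflate <- stats::runif(n) < theta
  y <- stats::rpois(n, lambda)
  y[inflate] <- 1L
  y
}

#' @rdname doip
#' @details `oip_mean()` is the closed-form expectation
#'   \eqn{E[y] = \theta + (1 - \theta)\lambda}, the quantity reported as
#'   predicted cumulative fertility when evaluated at age 60.
#' @export
oip_mean <- function(lambda, theta) {
  theta + (1 - theta) * lambda
}

#' Dataset log-likelihood under the one-inflated Poisson growth model
#'
#' Sums the one-inflated Poisson log-probability of each woman's parity at
#' the growth-curve rate implied by her age and asymptote. Primarily a
#' checking device: the fitted model computes the same quantity internally.
#'
#' @param records Data frame with columns `age`, `live_births`, and `M`
#'   (per-woman asymptote; recycle a scalar for a common asymptote).
#' @param k,b,a0 Growth-curve parameters shared across women.
#' @param theta One-inflation probability.
#' @return Scalar total log-likelihood.
#' @export
oip_growth_loglik <- function(records, k, b, theta, a0 = 0) {
  stopifnot(all(c("age", "live_births", "M") %in% names(records)))
  lam <- growth_curve(records$age, records$M, k, b, a0)
  ll <- doip(records$live_births, lam, theta, log = TRUE)
  bad <- which(!is.finite(ll))
  if (length(bad)) {
    stop("non-finite log-likelihood contribution at record(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  sum(ll)
}
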