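#' Highest posterior density interval
#'
#' Shortest contiguous interval over the sorted draws containing at least
#' `ceiling(mass * n)` of the `n` draws. Deterministic sorted-window method;
#' ties between equally short windows are broken toward the lowest lower
#' bound. For multimodal draws this is the shortest single interval, not a
#' union of disjoint regions.
#'
#' @param draws Numeric vector of posterior draws (n >= 10, finite).
#' @param mass Probability mass to cover (default 0.90, the reporting
#'   convention used throughout the package).
#' @return List of class `hpdi`: `lower`, `upper`, `mass`.
#' @examples
#' hpdi(rnorm(1000))
#' @export
hpdi <- function(draws, mass = 0.9) {
  if (length(draws) < 10L) stop("need at least 10 draws")
  if (any(!is.finite(draws))) stop("draws must be finite")
  if (mass <= 0 || mass >= 1) stop("'mass' must lie in (0, 1)")
  x <- sort(draws)
  n <- length(x)
  m <- ceiling(mass * n)
  starts <- seq_len(n - m + 1L)
  widths <- x[starts + m - 1L] - x[starts]
  i <- starts[which.min(widths)]  # which.min takes the first, i.e. lowest start
  structure(list(lower = x[i], upper = x[i + m - 1L], mass = mass),
            class = "hpdi")
}

#' @export
print.hpdi <- function(x, ...) {
  cat(sprintf("%.0f%% HPDI [%.4g, %.4g]\n", 100 * x$mass, x$lower, x$upper))
  invisible(x)
}

#' Equal-tailed credible interval
#'
#' Companion to [hpdi()]: the central interval with `((1 - mass) / 2)` tail
#' mass on each side (type-7 quantiles). Reported alongside the HPDI since
#' the two differ for skewed posteriors.
#'
#' @inheritParams hpdi
#' @return List with `lower`, `upper`, `mass`.
#' @export
eti <- function(draws, mass = 0.9) {
  if (any(!is.finite(draws))) stop("draws must be finite")
  q <- stats::quantile(draws, c((1 - mass) / 2, 1 - (1 - mass) / 2), names = FALSE)
  list(lower = q[1], upper = q[2], mass = mass)
}

#' Posterior probability of a consistent sign
#'
#' The posterior mass on the dominant side of zero:
#' `max(Pr(d > 0), Pr(d < 0))`, with draws exactly at zero split evenly
#' between the two sides. Always in \[0.5, 1\]; 1 means every draw shares
#' one sign, 0.5 means the posterior is balanced around zero.
#'
#' @param draws Numeric vector of posterior draws of a contrast.
#' @return Probability in \[0.5, 1\].
#' @examples
#' posterior_prob(c(-1, 1, 1, 1))  # 0.75
#' @export
posterior_prob <- function(draws) {
  if (length(draws) == 0L) stop("empty draws")
  if (any(!is.finite(draws))) stop("draws must be finite")
  n <- length(draws)
  nz <- sum(draws == 0)
  pos <- sum(draws > 0) + nz / 2
  neg <- sum(draws < 0) + nz / 2
  max(pos, neg) / n
}

#' Evidence label for a posterior sign probability
#'
#' Associations are labelled `strong` when at least 90% of the posterior
#' lies on one side of zero (PP >= 0.9), `moderate` when at least 80%
#' (0.8 <= PP < 0.9), and `weak` otherwise.
#'
#' @param pp Posterior sign probability from [posterior_prob()], in
#'   \[0.5, 1\].
#' @return One of `"strong"`, `"moderate"`, `"weak"`.
#' @examples
#' evidence_label(0.981)  # strong
#' evidence_label(0.89)   # moderate
#' @export
evidence_label <- function(pp) {
  if (!is.finite(pp) || pp < 0.5 || pp > 1) stop("'pp' must lie in [0.5, 1]")
  if (pp >= 0.9) "strong" else if (pp >= 0.8) "moderate" else "weak"
}

#' Summarize a contrast draw vector
#'
#' Bundles the package's standard reporting of a posterior quantity:
#' posterior median, 90% HPDI, equal-tailed interval, posterior sign
#' probability and evidence label.
#'
#' @param draws Posterior draws of the quantity.
#' @param mass Interval mass (default 0.9).
#' @return List with `median`, `hpdi`, `eti`, `pp`, `label`.
#' @export
summarize_draws <- function(draws, mass = 0.9) {
  pp <- posterior_prob(draws)
  list(median = stats::median(draws), hpdi = hpdi(draws, mass),
       eti = eti(draws, mass), pp = pp, label = evidence_label(pp))
}
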