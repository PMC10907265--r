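# Hamiltonian Monte Carlo with dual-averaging step-size adaptation and
# diagonal mass-matrix estimation. Internal engine behind oipgrowth().
#
# lp_grad(q) must return list(lp = scalar log posterior, grad = gradient).
# Warmup schedule: an initial step-size phase on the unit metric, a variance
# accumulation window, then a final step-size phase on the adapted metric.

hmc_run_chain <- function(lp_grad, init, warmup, iter, seed = NULL,
                          target_accept = 0.8, max_leapfrog = 20L,
                          divergence_threshold = 1000) {
  if (!is.null(seed)) set.seed(seed)
  d <- length(init)
  q <- init
  cur <- lp_grad(q)
  if (!is.finite(cur$lp)) stop("non-finite log posterior at initial values")

  m_inv <- rep(1, d)           # inverse diagonal mass
  sqrt_m <- rep(1, d)
  eps <- 0.1 / d^0.25
  # dual averaging state
  da_init <- function(eps0) list(mu = log(10 * eps0), log_eps_bar = 0,
                                 h_bar = 0, count = 0)
  da <- da_init(eps)
  gamma <- 0.05; t0 <- 10; kappa <- 0.75

  win_lo <- max(20L, floor(warmup * 0.25))
  win_hi <- floor(warmup * 0.8)
  win_sum <- numeric(d); win_sq <- numeric(d); win_n <- 0L
  l_lo <- max(1L, floor(max_leapfrog / 2))

  draws <- matrix(NA_real_, iter, d)
  lp_store <- numeric(iter)
  accept_sum <- 0
  divergences <- 0L
  total <- warmup + iter

  for (it in seq_len(total)) {
    p <- stats::rnorm(d) * sqrt_m
    L <- if (l_lo < max_leapfrog) sample.int(max_leapfrog - l_lo + 1L, 1L) + l_lo - 1L
         else max_leapfrog
    h0 <- -cur$lp + 0.5 * sum(p^2 * m_inv)
    qp <- q; gp <- cur$grad
    p_half <- p + 0.5 * eps * gp
    divergent <- FALSE
    lpp <- NA_real_
    for (l in seq_len(L)) {
      qp <- qp + eps * (m_inv * p_half)
      prop <- lp_grad(qp)
      lpp <- prop$lp
      if (!is.finite(lpp) || any(!is.finite(prop$grad))) { divergent <- TRUE; break }
      gp <- prop$grad
      if (l < L) p_half <- p_half + eps * gp
    }
    if (!divergent) {
      p_end <- p_half + 0.5 * eps * gp
      h1 <- -lpp + 0.5 * sum(p_end^2 * m_inv)
      dh <- h1 - h0
      if (!is.finite(dh) || dh > divergence_threshold) divergent <- TRUE
    }
    if (divergent) {
      a_prob <- 0
      if (it > warmup) divergences <- divergences + 1L
    } else {
      a_prob <- min(1, exp(-dh))
      if (stats::runif(1) < a_prob) {
        q <- qp
        cur <- prop
      }
    }

    if (it <= warmup) {
      # dual averaging toward the target acceptance rate
      da$count <- da$count + 1
      da$h_bar <- (1 - 1 / (da$count + t0)) * da$h_bar +
        (target_accept - a_prob) / (da$count + t0)
      log_eps <- da$mu - sqrt(da$count) / gamma * da$h_bar
      w <- da$count^(-kappa)
      da$log_eps_bar <- w * log_eps + (1 - w) * da$log_eps_bar
      eps <- exp(log_eps)
      if (it > win_lo && it <= win_hi) {
        win_sum <- win_sum + q
        win_sq <- win_sq + q^2
        win_n <- win_n + 1L
      }
      if (it == win_hi && win_n > 10L) {
        v <- (win_sq - win_sum^2 / win_n) / (win_n - 1L)
        # regularize toward unit scale as short windows are noisy
        v <- (win_n / (win_n + 5)) * v + (5 / (win_n + 5)) * 1
        m_inv <- pmax(v, 1e-8)
        sqrt_m <- 1 / sqrt(m_inv)
        eps <- exp(da$log_eps_bar)
        da <- da_init(eps)
      }
      if (it == warmup) eps <- exp(da$log_eps_bar)
    } else {
      draws[it - warmup, ] <- q
      lp_store[it - warmup] <- cur$lp
      accept_sum <- accept_sum + a_prob
    }
  }
  list(draws = draws, lp = lp_store, eps = eps,
       accept_rate = accept_sum / iter, divergences = divergences)
}

hmc_sample <- function(lp_grad, init_fn, chains, warmup, iter, seed, control) {
  ctrl <- list(target_accept = 0.8, max_leapfrog = 48L,
               divergence_threshold = 1000)
  ctrl[names(control)] <- control
  res <- vector("list", chains)
  for (ch in seq_len(chains)) {
    chain_seed <- (seed * 97L + ch) %% .Machine$integer.max
    set.seed(chain_seed)
    init <- init_fn()
    res[[ch]] <- hmc_run_chain(lp_grad, init, warmup, iter, seed = NULL,
                               target_accept = ctrl$target_accept,
                               max_leapfrog = ctrl$max_leapfrog,
                               divergence_threshold = ctrl$divergence_threshold)
  }
  res
}

# Split R-hat (Gelman-Rubin) on an iterations x chains matrix.
split_rhat <- function(x) {
  n <- nrow(x)
  half <- floor(n / 2)
  sub <- cbind(x[seq_len(half), , drop = FALSE],
               x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  nn <- nrow(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, stats::var)
  b <- nn * stats::var(means)
  w <- mean(vars)
  if (w == 0) return(1)
  sqrt(((nn - 1) / nn * w + b / nn) / w)
}

# Effective sample size, summed over chains via coda.
ess_chains <- function(x) {
  lst <- coda::mcmc.list(lapply(seq_len(ncol(x)), function(j) coda::mcmc(x[, j])))
  unname(coda::effectiveSize(lst))
}
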