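# Shared fixtures and independent oracles. Everything is generated in code;
# no stored data files.

# --- independent oracles -----------------------------------------------------

# Brute-force shortest-window HPDI: try every contiguous window of the
# sorted sample that holds ceiling(mass * n) draws.
oracle_hpdi <- function(x, mass = 0.9) {
  x <- sort(x)
  n <- length(x)
  m <- ceiling(mass * n)
  best <- c(-Inf, Inf)
  for (i in seq_len(n - m + 1L)) {
    if (x[i + m - 1L] - x[i] < best[2] - best[1]) {
      best <- c(x[i], x[i + m - 1L])
    }
  }
  best
}

# Naive per-row one-inflated Poisson log-likelihood (no vectorized shortcuts).
oracle_loglik <- function(records, k, b, theta, a0 = 0) {
  total <- 0
  for (i in seq_len(nrow(records))) {
    lam <- records$M[i] * (1 - exp(-k * (records$age[i] - a0)))^b
    y <- records$live_births[i]
    p <- theta * (y == 1) + (1 - theta) * exp(-lam) * lam^y / factorial(y)
    total <- total + log(p)
  }
  total
}

# --- CSV fixture -------------------------------------------------------------

write_toy_csv <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  records <- data.frame(
    woman_id = c("w1", "w2", "w3"),
    population_id = c("popA", "popA", "popB"),
    age = c(20, 35, 61),
    live_births = c(1L, 4L, 7L),
    livestock = c(0, 5, 50))
  meta <- data.frame(
    population_id = c("popA", "popB"),
    subsistence_type = c("hunter_gatherer", "agriculturalist"),
    market_integration = c("low", "high"))
  paths <- list(records = file.path(dir, "records.csv"),
                meta = file.path(dir, "meta.csv"))
  utils::write.csv(records, paths$records, row.names = FALSE, quote = FALSE)
  utils::write.csv(meta, paths$meta, row.names = FALSE, quote = FALSE)
  paths
}

# --- fake fitted model with fully controlled draws ---------------------------

# Builds an oipgrowth-classed object whose "posterior" is an arbitrary draw
# matrix, so contrast arithmetic can be checked against closed forms without
# running MCMC.
make_fake_fit <- function(n_draws = 50,
                          alpha = log(5), mu_beta = NULL,
                          k = 5, b = 1, theta = 0,
                          pop_levels = c("p1", "p2"),
                          alpha_pop = NULL, beta_pop = NULL,
                          group_levels = NULL, pop_group = NULL,
                          gamma = NULL, a0 = 0) {
  J <- length(pop_levels)
  if (is.null(alpha_pop)) alpha_pop <- rep(0, J)
  cols <- list(alpha = rep(alpha, n_draws))
  if (!is.null(mu_beta)) cols$mu_beta <- rep(mu_beta, n_draws)
  if (!is.null(group_levels)) {
    for (g in group_levels[-1]) {
      cols[[paste0("gamma_", g)]] <- rep(gamma[[g]], n_draws)
    }
  }
  cols$k <- rep(k, n_draws)
  cols$b <- rep(b, n_draws)
  cols$theta <- rep(theta, n_draws)
  cols$sigma_pop <- rep(0.1, n_draws)
  for (jj in seq_len(J)) {
    cols[[paste0("alpha_pop_", pop_levels[jj])]] <- rep(alpha_pop[jj], n_draws)
  }
  if (!is.null(mu_beta)) {
    cols$sigma_beta <- rep(0.1, n_draws)
    if (is.null(beta_pop)) beta_pop <- rep(0, J)
    for (jj in seq_len(J)) {
      cols[[paste0("beta_pop_", pop_levels[jj])]] <- rep(beta_pop[jj], n_draws)
    }
  }
  draws <- do.call(cbind, cols)
  data <- data.frame(population_id = rep(pop_levels, each = 5),
                     age = 40, live_births = 3L)
  structure(list(draws = draws, pop_levels = pop_levels,
                 group_levels = group_levels, pop_group = pop_group,
                 group_var = if (!is.null(group_levels)) "grp",
                 predictor = if (!is.null(mu_beta)) "z",
                 zcol = if (!is.null(mu_beta)) "z",
                 theta_scope = "global", a0 = a0,
                 woman_effect = FALSE, n = nrow(data), J = J,
                 data = data),
            class = "oipgrowth")
}

# --- one shared small MCMC fit, reused across test files ---------------------

.fixture_cache <- new.env(parent = emptyenv())

small_slope_fit <- function() {
  if (is.null(.fixture_cache$slope)) {
    truth <- fert_truth(n_populations = 3, n_women = 450,
                        mu_beta = c(z = 0.4), theta = 0.1,
                        sigma_pop = 0.1, sigma_beta = 0.05, seed = 401)
    sim <- simulate_fertility(truth)
    fit <- suppressWarnings(
      oipgrowth(sim, predictor = "z", chains = 2, warmup = 250, iter = 250,
                seed = 42, control = list(max_leapfrog = 32), quiet = TRUE))
    .fixture_cache$slope <- list(truth = truth, sim = sim, fit = fit)
  }
  .fixture_cache$slope
}
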