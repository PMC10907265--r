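test_that("fitting is deterministic given seed, chains and data", {
  truth <- fert_truth(n_populations = 2, n_women = 150,
                      mu_beta = c(z = 0.3), seed = 12)
  sim <- simulate_fertility(truth)
  f1 <- suppressWarnings(oipgrowth(sim, predictor = "z", chains = 2,
                                   warmup = 120, iter = 80, seed = 7,
                                   control = list(max_leapfrog = 12),
                                   quiet = TRUE))
  f2 <- suppressWarnings(oipgrowth(sim, predictor = "z", chains = 2,
                                   warmup = 120, iter = 80, seed = 7,
                                   control = list(max_leapfrog = 12),
                                   quiet = TRUE))
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$diagnostics, f2$diagnostics)

  f3 <- suppressWarnings(oipgrowth(sim, predictor = "z", chains = 2,
                                   warmup = 120, iter = 80, seed = 8,
                                   control = list(max_leapfrog = 12),
                                   quiet = TRUE))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("posterior recovers generating parameters on a small dataset", {
  fx <- small_slope_fit()
  fit <- fx$fit
  truth <- fx$truth

  # diagnostics cover every reported parameter
  expect_true(all(c("alpha", "mu_beta", "log_k", "log_b", "logit_theta",
                    "log_sigma_pop", "log_sigma_beta") %in%
                    fit$diagnostics$parameter))
  expect_true(all(is.finite(fit$diagnostics$rhat)))
  expect_gte(min(fit$diagnostics$ess), 10)

  # one-inflation and slope land near truth (generous desk-scale bands)
  th <- fit$draws[, "theta"]
  expect_lt(abs(median(th) - truth$theta), 0.05)
  mb <- fit$draws[, "mu_beta"]
  expect_lt(abs(median(mb) - truth$mu_beta[["z"]]), 0.25)

  # summary and print run and expose the HPDI columns
  s <- summary(fit)
  expect_true(all(c("median", "lower", "upper", "rhat", "ess") %in%
                    colnames(s$table)))
  expect_output(print(fit), "One-inflated Poisson growth model")
})

test_that("an uninformative predictor returns the slope prior", {
  set.seed(41)
  truth <- fert_truth(n_populations = 2, n_women = 160,
                      mu_beta = numeric(0), seed = 19)
  sim <- simulate_fertility(truth)
  sim$records$z_z <- 0  # no within-population variation reaches the model
  fit <- suppressWarnings(oipgrowth(sim, predictor = "z", chains = 2,
                                    warmup = 200, iter = 200, seed = 3,
                                    control = list(max_leapfrog = 16),
                                    quiet = TRUE))
  mb <- fit$draws[, "mu_beta"]
  # posterior should match the Normal(0, 0.5) prior, not sharpen
  expect_lt(abs(median(mb)), 0.25)
  expect_gt(sd(mb), 0.3)
  expect_lt(sd(mb), 0.7)
})

test_that("model variants and input guards behave", {
  truth <- fert_truth(n_populations = 2, n_women = 120,
                      mu_beta = c(z = 0.3), seed = 23)
  sim <- simulate_fertility(truth)

  expect_error(oipgrowth(sim, predictor = "z", group = "market_integration"),
               "not both")
  expect_error(oipgrowth(sim, predictor = "nope"), "not found")
  expect_error(oipgrowth(sim$records[0, ], chains = 1), "missing required|empty")

  # woman-level heterogeneity variant runs and exposes its scale
  fit_u <- suppressWarnings(oipgrowth(sim, predictor = "z", woman_effect = TRUE,
                                      chains = 1, warmup = 120, iter = 80,
                                      seed = 2, control = list(max_leapfrog = 12),
                                      quiet = TRUE))
  expect_true("sigma_u" %in% colnames(fit_u$draws))

  # per-population one-inflation variant
  fit_t <- suppressWarnings(oipgrowth(sim, predictor = "z",
                                      theta_scope = "population",
                                      chains = 1, warmup = 120, iter = 80,
                                      seed = 2, control = list(max_leapfrog = 12),
                                      quiet = TRUE))
  expect_true(all(paste0("theta_", c("pop01", "pop02")) %in%
                    colnames(fit_t$draws)))

  # birth-year control needs the column
  expect_error(oipgrowth(sim, predictor = "z", birth_year = TRUE),
               "birth_year")
})

test_that("fitted-model methods are internally consistent", {
  fx <- small_slope_fit()
  fit <- fx$fit

  # logLik at the posterior median equals the standalone likelihood
  med <- coef(fit)
  rec <- fit$data
  j <- match(rec$population_id, fit$pop_levels)
  eta <- med["alpha"] + med[paste0("alpha_pop_", fit$pop_levels)][j] +
    (med["mu_beta"] + med[paste0("beta_pop_", fit$pop_levels)][j]) * rec$z_z
  manual <- oip_growth_loglik(
    data.frame(age = rec$age, live_births = rec$live_births, M = exp(eta)),
    k = med[["k"]], b = med[["b"]], theta = med[["theta"]])
  expect_equal(as.numeric(logLik(fit)), manual, tolerance = 1e-10)

  # predictions rise with age and respect the asymptote-side expectation
  pr <- predict(fit, data.frame(age = c(20, 40, 60)), scope = "pooled")
  expect_true(all(diff(pr) > 0))

  # residuals have the right length and a near-zero mean
  r <- residuals(fit)
  expect_length(r, fit$n)
  expect_lt(abs(mean(r)), 0.5)

  # posterior-predictive simulation reproduces data scale
  yr <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(yr), c(fit$n, 3))
  expect_true(all(yr >= 0))
  expect_lt(abs(mean(as.matrix(yr)) - mean(fit$data$live_births)), 1)

  # plot method draws without error
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f)
  curve_df <- plot(fit)
  grDevices::dev.off()
  expect_true(all(diff(curve_df$median) >= 0))
})
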