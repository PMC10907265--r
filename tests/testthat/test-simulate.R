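test_that("simulation is deterministic: same truth, byte-identical CSV", {
  truth <- fert_truth(n_populations = 4, n_women = 200, seed = 33)
  d1 <- simulate_fertility(truth)
  d2 <- simulate_fertility(truth)
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "a.csv"); f2 <- file.path(dir, "b.csv")
  write_records(d1, f1); write_records(d2, f2)
  expect_identical(readLines(f1), readLines(f2))

  # a different seed changes the data
  d3 <- simulate_fertility(truth, seed = 34)
  expect_false(identical(d1$records$live_births, d3$records$live_births))
})

test_that("degenerate and limiting truths behave as the model dictates", {
  # full one-inflation: every woman has exactly one live birth
  t1 <- fert_truth(n_populations = 2, n_women = 120, theta = 1,
                   mu_beta = numeric(0), seed = 5)
  expect_true(all(simulate_fertility(t1)$records$live_births == 1))

  # saturated ages, no noise, b = 1, large k: mean parity converges on exp(alpha)
  t2 <- fert_truth(n_populations = 1, n_women = 1000, alpha = log(5),
                   k = 2, b = 1, theta = 0, sigma_pop = 0, sigma_beta = 0,
                   mu_beta = numeric(0), age_range = c(85, 85), seed = 6)
  y <- simulate_fertility(t2)$records$live_births
  expect_lt(abs(mean(y) - 5), 3 * sqrt(5 / 1000))

  # degenerate truth: one woman and no hierarchy scales is refused
  expect_error(fert_truth(n_populations = 1, n_women = 1, theta = 0,
                          sigma_pop = 0, sigma_beta = 0, sigma_u = 0,
                          mu_beta = numeric(0), seed = 1),
               "degenerate")
  expect_error(fert_truth(n_populations = 3, n_women = 100, theta = 1.4,
                          seed = 1), "theta")
})

test_that("generated data show the one-inflation signature and pass validation", {
  truth <- fert_truth(n_populations = 5, n_women = 4000, theta = 0.15,
                      mu_beta = c(z = 0.2), seed = 88)
  sim <- simulate_fertility(truth)
  expect_silent(validate_records(sim$records, sim$meta))

  # parity-1 frequency exceeds what the Poisson component alone implies
  rec <- sim$records
  lam_hat <- growth_curve(rec$age,
                          exp(sim$truth$realized$alpha_pop[
                            match(rec$population_id,
                                  sprintf("pop%02d", 1:5))] +
                            truth$mu_beta[["z"]] * rec$z_z),
                          truth$k, truth$b)
  pois_p1 <- mean(dpois(1, lam_hat))
  excess <- mean(rec$live_births == 1) - pois_p1
  expect_gt(excess, 0.5 * truth$theta * (1 - pois_p1))

  # within-population predictor moments are near standard normal
  for (p in unique(rec$population_id)) {
    z <- rec$z_z[rec$population_id == p]
    expect_lt(abs(mean(z)), 0.15)
    expect_lt(abs(sd(z) - 1), 0.15)
  }
})

test_that("missingness injection blanks cells, reports counts and refuses a wipe-out", {
  truth <- paperlike_truth(n_women = 540, seed = 2)
  sim <- simulate_fertility(truth)
  pops <- sprintf("pop%02d", 1:27)

  # leave the predictor in 8 of 27 sites, as foraging-style coverage
  blank <- pops[9:27]
  sim2 <- inject_missingness(sim, list(farming = blank))
  sub <- suppressMessages(build_model_subset(sim2, "farming"))
  expect_equal(length(sub$pop_n), 8)
  n_blanked <- attr(sim2, "n_blanked")
  expect_equal(unname(n_blanked["farming"]),
               sum(sim$records$population_id %in% blank))
  # complement bookkeeping is exact
  expect_equal(nrow(sub$records),
               sum(!sim$records$population_id %in% blank))

  # empty spec is the identity
  expect_identical(inject_missingness(sim, list())$records, sim$records)
  expect_error(inject_missingness(sim, list(nope = "pop01")), "not found")
})

test_that("truth scenarios serialize to YAML and restore exactly", {
  truth <- paperlike_truth(n_women = 270, seed = 9)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_truth(truth, f)
  back <- read_truth(f)
  expect_s3_class(back, "fert_truth")
  expect_equal(back$mu_beta, truth$mu_beta, tolerance = 1e-12)
  expect_equal(back$log_M_base, truth$log_M_base, tolerance = 1e-12)
  expect_identical(back$mi_assign, truth$mi_assign)
  # restored truth regenerates the same dataset
  expect_identical(simulate_fertility(back)$records,
                   simulate_fertility(truth)$records)
})

test_that("the study-scale scenario carries the published group targets", {
  truth <- paperlike_truth(seed = 1)
  expect_equal(truth$n_women, 10250)
  expect_equal(truth$n_populations, 27)
  expect_equal(truth$subsistence_targets[["hunter_gatherer"]], 4.6)
  expect_equal(truth$mi_targets[["low"]], 5.5)
  expect_equal(truth$mi_targets[["high"]], 3.53)
  # predictor effect is calibrated so the true pooled contrast is +0.33 births
  expect_equal(true_delta_cf(truth), 0.33, tolerance = 1e-10)

  # solved baselines keep group means close to their targets despite the
  # least-squares compromise between the two margin sets
  s60 <- (1 - exp(-truth$k * 60))^truth$b
  cf <- truth$theta + (1 - truth$theta) * exp(truth$log_M_base) * s60
  expect_equal(mean(cf[truth$mi_assign == "low"]), 5.5, tolerance = 0.05)
  expect_equal(mean(cf[truth$mi_assign == "high"]), 3.53, tolerance = 0.05)
  expect_equal(mean(cf[truth$sub_assign == "horticulturalist"]), 5.61,
               tolerance = 0.05)
})
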