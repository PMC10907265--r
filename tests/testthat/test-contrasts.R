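test_that("cumulative-fertility predictions follow the closed-form expectation", {
  # degenerate posterior, theta = 0, saturated curve: CF is the asymptote
  f0 <- make_fake_fit(alpha = log(5), k = 5, b = 1, theta = 0)
  cf <- predict_cf(f0, scope = "pooled")
  expect_equal(cf$median, 5, tolerance = 1e-8)

  # one-inflation shifts the expectation: 0.2 + 0.8 * 5 = 4.2
  f1 <- make_fake_fit(alpha = log(5), k = 5, b = 1, theta = 0.2)
  expect_equal(predict_cf(f1, scope = "pooled")$median, 4.2, tolerance = 1e-8)

  # population scope conditions on that population's intercept
  f2 <- make_fake_fit(alpha = log(4), theta = 0, alpha_pop = c(log(2), 0))
  expect_equal(predict_cf(f2, scope = "population", population = "p1")$median,
               8, tolerance = 1e-6)
  expect_error(predict_cf(f2, scope = "population", population = "zzz"),
               "not in the model subset")
})

test_that("1-SD contrasts match the asymptote closed form and its symmetries", {
  # alpha = log 4, mu_beta = 0.1, theta = 0, saturated: delta = 4(e^0.1 - 1)
  f <- make_fake_fit(alpha = log(4), mu_beta = 0.1, k = 5, b = 1, theta = 0)
  ct <- contrast_1sd(f, scope = "pooled")
  expect_equal(ct$table$median, 4 * (exp(0.1) - 1), tolerance = 1e-8)

  # null slope gives an exactly null contrast
  fnull <- make_fake_fit(alpha = log(4), mu_beta = 0, theta = 0)
  expect_equal(contrast_1sd(fnull, scope = "pooled")$table$median, 0,
               tolerance = 1e-12)

  # antisymmetry: reversing the contrast flips the sign exactly
  ns <- asNamespace("fertgrowth")
  fwd <- ns$cf_draws(f, z = 1) - ns$cf_draws(f, z = 0)
  rev <- ns$cf_draws(f, z = 0) - ns$cf_draws(f, z = 1)
  expect_equal(fwd, -rev, tolerance = 1e-12)

  # per-population contrasts use the partially pooled slope
  fp <- make_fake_fit(alpha = log(4), mu_beta = 0.1, k = 5, b = 1, theta = 0,
                      beta_pop = c(0.05, -0.05))
  ctp <- contrast_1sd(fp, scope = "population")
  expect_equal(ctp$table$median[ctp$table$scope_id == "p1"],
               4 * (exp(0.15) - 1), tolerance = 1e-8)

  # a model without a focal predictor refuses the contrast
  expect_error(contrast_1sd(make_fake_fit()), "no focal predictor")
})

test_that("group contrasts enumerate levels and pairs with the right arithmetic", {
  # three ordered groups, exchangeable parameters: all deltas 0, pp 0.5
  f3 <- make_fake_fit(alpha = log(4), theta = 0, k = 5, b = 1,
                      pop_levels = c("p1", "p2", "p3"),
                      alpha_pop = c(0, 0, 0),
                      group_levels = c("low", "medium", "high"),
                      pop_group = c(1, 2, 3),
                      gamma = list(medium = 0, high = 0))
  g <- group_cf_contrast(f3)
  expect_equal(sum(g$table$cf_or_delta == "cf"), 3)
  expect_equal(sum(g$table$cf_or_delta == "delta"), 3)
  expect_equal(g$table$scope_id[g$table$cf_or_delta == "delta"],
               c("medium-low", "high-low", "high-medium"))
  expect_true(all(abs(g$table$median[g$table$cf_or_delta == "delta"]) < 1e-10))
  expect_true(all(abs(g$table$pp[g$table$cf_or_delta == "delta"] - 0.5) < 1e-12))

  # a real difference: high CF 3.5 vs low 5.5 gives delta -2 on group scale
  f2 <- make_fake_fit(alpha = log(5.5), theta = 0, k = 5, b = 1,
                      pop_levels = c("p1", "p2"),
                      group_levels = c("low", "high"), pop_group = c(1, 2),
                      gamma = list(high = log(3.5 / 5.5)))
  g2 <- group_cf_contrast(f2)
  d <- g2$table[g2$table$scope_id == "high-low", ]
  expect_equal(d$median, -2, tolerance = 1e-8)

  expect_error(group_cf_contrast(make_fake_fit()), "grouping")
})

test_that("the reporting table keeps the fixed schema and vocabulary", {
  f <- make_fake_fit(alpha = log(4), mu_beta = 0.1, k = 5, b = 1, theta = 0,
                     pop_levels = paste0("p", 1:8),
                     alpha_pop = rep(0, 8), beta_pop = rep(0, 8))
  ct <- contrast_1sd(f)
  # 8 population rows plus one pooled row
  expect_equal(nrow(ct$table), 9)
  expect_equal(sum(ct$table$scope == "pooled"), 1)

  tab <- contrast_table(ct)
  expect_identical(names(tab),
                   c("predictor", "scope", "scope_id", "cf_or_delta",
                     "median", "hpdi_lower", "hpdi_upper", "pp", "label", "n"))
  expect_true(all(tab$label[!is.na(tab$label)] %in%
                    c("strong", "moderate", "weak")))

  # a pp this decisive must be labelled strong
  expect_true(all(tab$label[tab$pp >= 0.9 & !is.na(tab$pp)] == "strong"))

  # CSV emission round-trips the schema
  fcsv <- withr::local_tempfile(fileext = ".csv")
  contrast_table(ct, file = fcsv)
  back <- utils::read.csv(fcsv)
  expect_equal(nrow(back), 9)
  expect_identical(names(back), names(tab))

  # forest plot draws without error
  fpng <- withr::local_tempfile(fileext = ".png")
  grDevices::png(fpng)
  out <- plot_forest(ct)
  grDevices::dev.off()
  expect_true(nrow(out) >= 1)
})

test_that("pooled contrast sits inside the per-population envelope when pooling is tight", {
  fx <- small_slope_fit()
  ct <- contrast_1sd(fx$fit)
  pooled <- ct$table$median[ct$table$scope == "pooled"]
  pops <- ct$table$median[ct$table$scope == "population"]
  # generous envelope check: shrinkage keeps the pooled value near the pack
  expect_gte(pooled, min(pops) - 0.3)
  expect_lte(pooled, max(pops) + 0.3)
})
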