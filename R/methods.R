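#' @export
print.oipgrowth <- function(x, ...) {
  cat("One-inflated Poisson growth model of cumulative fertility\n")
  if (!is.null(x$predictor)) {
    cat("  focal predictor:", x$predictor, "\n")
  } else if (!is.null(x$group_var)) {
    cat("  grouping:", x$group_var, "(",
        paste(x$group_levels, collapse = " < "), ")\n")
  } else {
    cat("  intercept-only (no focal predictor)\n")
  }
  cat("  data:", x$n, "women,", x$J, "populations\n")
  cat("  draws:", nrow(x$draws), "(", x$mcmc$chains, "chains x",
      x$mcmc$iter, "iterations, seed", x$mcmc$seed, ")\n")
  cat(sprintf("  max R-hat %.3f, min ESS %.0f, %d divergent transition(s)\n",
              max(x$diagnostics$rhat), min(x$diagnostics$ess), x$divergences))
  cf <- predict_cf(x, scope = "pooled")
  cat(sprintf("  pooled CF~ at age 60: %.2f (90%% HPDI [%.2f, %.2f])\n",
              cf$median, cf$hpdi$lower, cf$hpdi$upper))
  invisible(x)
}

#' @export
summary.oipgrowth <- function(object, mass = 0.9, ...) {
  dr <- object$draws
  keep <- !grepl("^(alpha_pop_|beta_pop_)", colnames(dr))
  tab <- t(apply(dr[, keep, drop = FALSE], 2, function(v) {
    h <- hpdi(v, mass)
    c(median = stats::median(v), lower = h$lower, upper = h$upper)
  }))
  dg <- object$diagnostics
  # map natural names onto sampler diagnostics where they correspond 1:1
  map <- c(alpha = "alpha", mu_beta = "mu_beta", k = "log_k", b = "log_b",
           theta = "logit_theta", sigma_pop = "log_sigma_pop",
           sigma_beta = "log_sigma_beta", sigma_u = "log_sigma_u",
           delta_birth_year = "delta_birth_year")
  rn <- rownames(tab)
  src <- ifelse(rn %in% names(map), map[rn], rn)
  out <- data.frame(tab,
                    rhat = dg$rhat[match(src, dg$parameter)],
                    ess = dg$ess[match(src, dg$parameter)])
  structure(list(table = out, mass = mass, divergences = object$divergences,
                 n = object$n, J = object$J), class = "summary.oipgrowth")
}

#' @export
print.summary.oipgrowth <- function(x, digits = 3, ...) {
  cat("Posterior summary (", x$n, " women, ", x$J, " populations; ",
      100 * x$mass, "% HPDI)\n", sep = "")
  print(round(x$table, digits))
  cat(x$divergences, "divergent transition(s)\n")
  invisible(x)
}

#' @export
coef.oipgrowth <- function(object, ...) {
  apply(object$draws, 2, stats::median)
}

#' @export
logLik.oipgrowth <- function(object, ...) {
  med <- coef(object)
  lam <- fitted_lambda(object, med, age = object$data$age)
  th <- row_theta(object, med)
  val <- sum(doip(object$data$live_births, lam, th, log = TRUE))
  structure(val, df = attr(object$layout, "n_par"), class = "logLik")
}

# Per-row lambda at a named parameter vector (posterior medians by default).
fitted_lambda <- function(object, pars, age) {
  eta <- log_asymptote(object, pars)
  growth_curve(age, exp(eta), pars["k"], pars["b"], object$a0)
}

log_asymptote <- function(object, pars) {
  j <- match(as.character(object$data$population_id), object$pop_levels)
  eta <- pars["alpha"] + pars[paste0("alpha_pop_", object$pop_levels)][j]
  if (!is.null(object$predictor)) {
    z <- object$data[[object$zcol]]
    eta <- eta + (pars["mu_beta"] +
                    pars[paste0("beta_pop_", object$pop_levels)][j]) * z
  }
  if (!is.null(object$group_levels)) {
    gam <- c(0, pars[paste0("gamma_", object$group_levels[-1])])
    eta <- eta + gam[object$pop_group[j]]
  }
  unname(eta)
}

row_theta <- function(object, pars) {
  if (object$theta_scope == "population") {
    j <- match(as.character(object$data$population_id), object$pop_levels)
    unname(pars[paste0("theta_", object$pop_levels)][j])
  } else {
    unname(pars["theta"])
  }
}

#' Predicted expected parity for new ages
#'
#' Posterior expected cumulative live births \eqn{E[y] = \theta +
#' (1-\theta)\lambda(age)} at given ages, either for the pooled
#' population-mean woman or conditional on one population's effects.
#'
#' @param object A fitted `oipgrowth` model.
#' @param newdata Optional data frame with column `age` (and optionally a
#'   predictor z value column named like the fitted one, and
#'   `population_id`). Defaults to the training rows.
#' @param scope `"pooled"` (population effects set to zero) or
#'   `"population"` (use each row's population effects).
#' @param summary Return posterior medians (`TRUE`, default) or the full
#'   draw matrix (rows = draws).
#' @param ... Unused.
#' @return Numeric vector of posterior-median expected parities, or a
#'   draws x rows matrix when `summary = FALSE`.
#' @export
predict.oipgrowth <- function(object, newdata = NULL,
                              scope = c("population", "pooled"),
                              summary = TRUE, ...) {
  scope <- match.arg(scope)
  if (is.null(newdata)) newdata <- object$data
  if (!"age" %in% names(newdata)) stop("'newdata' needs an 'age' column")
  dr <- object$draws
  nd <- nrow(newdata)
  z <- NULL
  if (!is.null(object$predictor)) {
    zc <- if (object$zcol %in% names(newdata)) object$zcol else NULL
    z <- if (is.null(zc)) rep(0, nd) else newdata[[zc]]
  }
  eta <- matrix(dr[, "alpha"], nrow(dr), nd)
  if (scope == "population") {
    if (!"population_id" %in% names(newdata)) {
      stop("population scope needs 'population_id' in newdata")
    }
    j <- match(as.character(newdata$population_id), object$pop_levels)
    if (any(is.na(j))) stop("unknown population in newdata")
    eta <- eta + dr[, paste0("alpha_pop_", object$pop_levels), drop = FALSE][, j, drop = FALSE]
    if (!is.null(object$group_levels)) {
      gam <- cbind(0, dr[, paste0("gamma_", object$group_levels[-1]), drop = FALSE])
      eta <- eta + gam[, object$pop_group[j], drop = FALSE]
    }
    if (!is.null(z)) {
      slope <- dr[, "mu_beta"] +
        dr[, paste0("beta_pop_", object$pop_levels), drop = FALSE][, j, drop = FALSE]
      eta <- eta + slope * rep(z, each = nrow(dr))
    }
  } else {
    if (!is.null(z)) eta <- eta + outer(dr[, "mu_beta"], z)
  }
  th <- if (object$theta_scope == "global") dr[, "theta"] else {
    if (scope == "population") {
      j <- match(as.character(newdata$population_id), object$pop_levels)
      dr[, paste0("theta_", object$pop_levels), drop = FALSE][, j, drop = FALSE]
    } else {
      rowMeans(dr[, grep("^theta_", colnames(dr)), drop = FALSE])
    }
  }
  s <- pmax(0, 1 - exp(-outer(dr[, "k"], newdata$age - object$a0)))
  lam <- exp(eta) * s^dr[, "b"]
  ey <- th + (1 - th) * lam
  if (summary) apply(ey, 2, stats::median) else ey
}

#' @export
residuals.oipgrowth <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  med <- coef(object)
  lam <- fitted_lambda(object, med, object$data$age)
  th <- row_theta(object, med)
  mu <- oip_mean(lam, th)
  r <- object$data$live_births - mu
  if (type == "pearson") {
    # Var(y) = (1-th)(lam + lam^2) + th - mu^2 for the one-inflated mixture
    ey2 <- (1 - th) * (lam + lam^2) + th
    r <- r / sqrt(pmax(ey2 - mu^2, 1e-12))
  }
  r
}

#' Posterior-predictive simulation of parities
#'
#' Draws replicated parity counts for the training rows: for each
#' simulation, one posterior draw is selected and counts are generated from
#' the one-inflated Poisson at that draw's rates.
#'
#' @param object Fitted `oipgrowth` model.
#' @param nsim Number of replicated datasets.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return Data frame with `nsim` columns, `sim_1 ... sim_nsim`, one row per
#'   woman.
#' @export
simulate.oipgrowth <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  dr <- object$draws
  idx <- sample.int(nrow(dr), nsim, replace = nsim > nrow(dr))
  out <- lapply(idx, function(i) {
    pars <- dr[i, ]
    lam <- fitted_lambda(object, pars, object$data$age)
    th <- row_theta(object, pars)
    roip(length(lam), lam, th)
  })
  out <- as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
  attr(out, "seed") <- seed
  out
}

#' Plot the fitted age-parity growth curve
#'
#' Observed parities against age (jittered points), with the posterior
#' median pooled expectation curve and its 90% credible band.
#'
#' @param x Fitted `oipgrowth` model.
#' @param ages Grid of ages for the curve.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the data frame of curve summaries.
#' @export
plot.oipgrowth <- function(x, ages = seq(14, 85, by = 1), ...) {
  ey <- predict(x, data.frame(age = ages), scope = "pooled", summary = FALSE)
  med <- apply(ey, 2, stats::median)
  lo <- apply(ey, 2, stats::quantile, 0.05)
  hi <- apply(ey, 2, stats::quantile, 0.95)
  graphics::plot(jitter(x$data$age), jitter(x$data$live_births),
                 pch = 16, cex = 0.3, col = grDevices::grey(0.4, 0.35),
                 xlab = "Age (years)", ylab = "Cumulative live births", ...)
  graphics::polygon(c(ages, rev(ages)), c(lo, rev(hi)),
                    col = grDevices::adjustcolor("steelblue", 0.25), border = NA)
  graphics::lines(ages, med, col = "steelblue", lwd = 2)
  invisible(data.frame(age = ages, median = med, lower = lo, upper = hi))
}
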