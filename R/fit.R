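#' Prior settings for the fertility growth model
#'
#' Weakly informative defaults, chosen so the prior-predictive cumulative
#' fertility at age 60 spans roughly 1 to 15 births: intercept
#' `alpha ~ Normal(log 5, 1)` (asymptotic parity centred on 5), pooled slope
#' `mu_beta ~ Normal(0, 0.5)` per within-population SD, hierarchical scales
#' half-Normal(0.5), growth rate `log k ~ Normal(log 0.05, 0.5)` per year,
#' shape `log b ~ Normal(0, 0.5)`, one-inflation `theta ~ Beta(2, 18)`
#' (mean 0.1), group effects `Normal(0, 1)` and birth-year slope
#' `Normal(0, 0.5)`.
#'
#' @param ... Named overrides of any default listed above.
#' @return Named list of prior settings.
#' @export
oipgrowth_priors <- function(...) {
  p <- list(alpha_mean = log(5), alpha_sd = 1,
            mu_beta_sd = 0.5,
            sigma_sd = 0.5,
            logk_mean = log(0.05), logk_sd = 0.5,
            logb_mean = 0, logb_sd = 0.5,
            theta_a = 2, theta_b = 18,
            gamma_sd = 1, delta_sd = 0.5)
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown prior setting(s): ", paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  p
}

# Parameter layout: named blocks in the unconstrained vector.
build_layout <- function(J, n, has_slope, n_gamma, theta_scope,
                         woman_effect, birth_year) {
  blocks <- list(alpha = 1L)
  if (has_slope) blocks$mu_beta <- 1L
  if (n_gamma > 0L) blocks$gamma <- n_gamma
  blocks$logk <- 1L
  blocks$logb <- 1L
  blocks$psi <- if (theta_scope == "population") J else 1L
  blocks$lsp <- 1L
  if (has_slope) blocks$lsb <- 1L
  blocks$a_raw <- J
  if (has_slope) blocks$b_raw <- J
  if (birth_year) blocks$delta <- 1L
  if (woman_effect) {
    blocks$lsu <- 1L
    blocks$u_raw <- n
  }
  idx <- list(); off <- 0L
  for (nm in names(blocks)) {
    idx[[nm]] <- off + seq_len(blocks[[nm]])
    off <- off + blocks[[nm]]
  }
  attr(idx, "n_par") <- off
  idx
}

# Log posterior and gradient for the hierarchical one-inflated Poisson
# growth model. ctx holds data and flags; q is the unconstrained vector.
make_lp_grad <- function(ctx, priors) {
  ix <- ctx$layout
  y <- ctx$y; age <- ctx$age_off; j <- ctx$j; z <- ctx$z
  is1 <- y == 1L
  idx1 <- which(is1); idx0 <- which(!is1)
  y0 <- y[idx0]
  lgam0 <- lgamma(y0 + 1)  # Poisson normalizing constants, fixed by the data
  n <- length(y); J <- ctx$J
  has_slope <- ctx$has_slope
  theta_pop <- ctx$theta_scope == "population"
  gidx <- ctx$gidx  # per-row group column index into gamma (0 = reference)
  by <- ctx$by      # centered/scaled birth year, or NULL
  we <- ctx$woman_effect
  pr <- priors

  function(q) {
    alpha <- q[ix$alpha]
    logk <- q[ix$logk]; logb <- q[ix$logb]
    k <- exp(logk); b <- exp(logb)
    psi <- q[ix$psi]; th <- stats::plogis(psi)
    lsp <- q[ix$lsp]; sp <- exp(lsp)
    a_raw <- q[ix$a_raw]
    eta <- alpha + sp * a_raw[j]
    if (has_slope) {
      mu_beta <- q[ix$mu_beta]
      lsb <- q[ix$lsb]; sb <- exp(lsb)
      b_raw <- q[ix$b_raw]
      slope <- mu_beta + sb * b_raw[j]
      eta <- eta + slope * z
    }
    if (!is.null(gidx)) {
      gamma <- q[ix$gamma]
      gfull <- c(0, gamma)
      eta <- eta + gfull[gidx]
    }
    if (!is.null(by)) eta <- eta + q[ix$delta] * by
    if (we) {
      lsu <- q[ix$lsu]; su <- exp(lsu)
      u_raw <- q[ix$u_raw]
      eta <- eta + su * u_raw
    }
    M <- exp(eta)
    ek <- exp(-k * age)
    s <- 1 - ek
    lam <- M * s^b
    th1 <- if (theta_pop) th[j[idx1]] else th
    th0 <- if (theta_pop) th[j[idx0]] else th

    # log-likelihood, with dl/dlambda (g) and dl/dtheta (tt) per row
    g <- numeric(n); tt <- numeric(n)
    lam1 <- lam[idx1]
    e1 <- exp(-lam1)
    lam_e <- lam1 * e1
    p1 <- th1 + (1 - th1) * lam_e
    lam0 <- lam[idx0]
    lp <- sum(log(p1)) +
      sum(log1p(-th0) + y0 * log(lam0) - lam0 - lgam0)
    if (!is.finite(lp)) return(list(lp = -Inf, grad = rep(NA_real_, attr(ix, "n_par"))))
    g[idx1] <- (1 - th1) * e1 * (1 - lam1) / p1
    g[idx0] <- y0 / lam0 - 1
    tt[idx1] <- (1 - lam_e) / p1
    tt[idx0] <- -1 / (1 - th0)
    w <- g * lam  # dl/deta

    grad <- numeric(attr(ix, "n_par"))
    grad[ix$alpha] <- sum(w)
    w_by_pop <- rowsum(w, j, reorder = TRUE)  # J x 1 (j is 1..J, all present)
    grad[ix$a_raw] <- sp * w_by_pop + (-a_raw)
    grad[ix$lsp] <- sp * sum(w * a_raw[j]) + (1 - sp^2 / pr$sigma_sd^2)
    if (has_slope) {
      wz <- w * z
      grad[ix$mu_beta] <- sum(wz) - mu_beta / pr$mu_beta_sd^2
      wz_by_pop <- rowsum(wz, j, reorder = TRUE)
      grad[ix$b_raw] <- sb * wz_by_pop + (-b_raw)
      grad[ix$lsb] <- sb * sum(wz * b_raw[j]) + (1 - sb^2 / pr$sigma_sd^2)
      lp <- lp - 0.5 * (mu_beta / pr$mu_beta_sd)^2 - 0.5 * sum(b_raw^2) -
        sb^2 / (2 * pr$sigma_sd^2) + lsb
    }
    if (!is.null(gidx)) {
      wg <- rowsum(w, gidx, reorder = TRUE)
      lev <- as.integer(rownames(wg))
      full <- numeric(max(ctx$n_gamma + 1L, max(lev)))
      full[lev] <- wg
      grad[ix$gamma] <- full[-1][seq_len(ctx$n_gamma)] - gamma / pr$gamma_sd^2
      lp <- lp - 0.5 * sum((gamma / pr$gamma_sd)^2)
    }
    if (!is.null(by)) {
      delta <- q[ix$delta]
      grad[ix$delta] <- sum(w * by) - delta / pr$delta_sd^2
      lp <- lp - 0.5 * (delta / pr$delta_sd)^2
    }
    if (we) {
      grad[ix$u_raw] <- su * w - u_raw
      grad[ix$lsu] <- su * sum(w * u_raw) + (1 - su^2 / pr$sigma_sd^2)
      lp <- lp - 0.5 * sum(u_raw^2) - su^2 / (2 * pr$sigma_sd^2) + lsu
    }
    # growth-shape gradients
    dlam_dlogk <- lam * b * age * ek / s * k
    grad[ix$logk] <- sum(g * dlam_dlogk) - (logk - pr$logk_mean) / pr$logk_sd^2
    grad[ix$logb] <- b * sum(g * lam * log(s)) - (logb - pr$logb_mean) / pr$logb_sd^2
    # theta gradient and Beta prior (with logit Jacobian absorbed)
    if (theta_pop) {
      t_by_pop <- rowsum(tt, j, reorder = TRUE)
      grad[ix$psi] <- th * (1 - th) * t_by_pop +
        pr$theta_a * (1 - th) - pr$theta_b * th
      lp <- lp + sum(pr$theta_a * log(th) + pr$theta_b * log1p(-th))
    } else {
      grad[ix$psi] <- th * (1 - th) * sum(tt) +
        pr$theta_a * (1 - th) - pr$theta_b * th
      lp <- lp + pr$theta_a * log(th) + pr$theta_b * log1p(-th)
    }
    # remaining priors
    lp <- lp - 0.5 * ((alpha - pr$alpha_mean) / pr$alpha_sd)^2 -
      0.5 * ((logk - pr$logk_mean) / pr$logk_sd)^2 -
      0.5 * ((logb - pr$logb_mean) / pr$logb_sd)^2 -
      0.5 * sum(a_raw^2) - sp^2 / (2 * pr$sigma_sd^2) + lsp
    grad[ix$alpha] <- grad[ix$alpha] - (alpha - pr$alpha_mean) / pr$alpha_sd^2
    list(lp = lp, grad = grad)
  }
}

#' Fit the hierarchical one-inflated Poisson fertility growth model
#'
#' Models cumulative live births \eqn{y_i} of woman \eqn{i} in population
#' \eqn{j(i)} as one-inflated Poisson with inflation \eqn{\theta} and rate
#' \eqn{\lambda_i = M_i (1 - e^{-k(a_i - a0)})^b}, a saturating growth curve
#' of age. The log asymptote carries the hierarchy and the focal predictor:
#' \deqn{\log M_i = \alpha + \alpha_{pop[j]} + (\mu_\beta + \beta_{pop[j]}) z_i}
#' with \eqn{\alpha_{pop} \sim N(0, \sigma_{pop})} and partially pooled
#' slopes \eqn{\beta_{pop} \sim N(0, \sigma_\beta)}. Exactly one focal
#' predictor (continuous z-score or 0/1 binary) or one population-level
#' grouping factor is fitted per model. Posterior sampling is by the
#' package's Hamiltonian Monte Carlo engine (analytic gradients, dual
#' averaging, diagonal mass adaptation); the fit is deterministic given
#' `seed`, `chains` and the data.
#'
#' @param data A `model_dataset` from [build_model_subset()], a `fert_data`,
#'   or a records data frame (columns `population_id`, `age`, `live_births`,
#'   plus the predictor column).
#' @param predictor Name of the focal predictor. Its standardized column
#'   `<predictor>_z` is used if present, otherwise the column itself (it must
#'   then already be a z-score or 0/1 coding).
#' @param group Name of a population-level grouping column (in the metadata
#'   or the records), e.g. `"market_integration"` or `"subsistence_type"`;
#'   fitted as fixed effects on the log asymptote. Mutually exclusive with
#'   `predictor`.
#' @param woman_effect Add a woman-level normal deviation on the log
#'   asymptote (default `FALSE`; population-level estimands do not need it
#'   and it slows mixing considerably).
#' @param theta_scope `"global"` (one inflation parameter, default) or
#'   `"population"`.
#' @param birth_year Include a linear birth-year control on the log
#'   asymptote (column `birth_year` required).
#' @param a0 Age at which the growth curve leaves zero (years, default 0).
#' @param chains,warmup,iter MCMC settings: number of chains, warmup
#'   iterations per chain (discarded, used for adaptation), and retained
#'   posterior iterations per chain.
#' @param seed Integer seed; two runs with identical seed, settings and data
#'   produce identical draws.
#' @param priors From [oipgrowth_priors()].
#' @param control List: `target_accept` (default 0.8), `max_leapfrog`
#'   (default 48; trajectories this long are needed to traverse the
#'   correlated growth-shape posterior), `divergence_threshold`
#'   (default 1000).
#' @param quiet Suppress the convergence warning summary?
#' @return An object of class `oipgrowth` with components `draws` (matrix of
#'   posterior draws on natural scales, chains pooled), `diagnostics` (per
#'   parameter R-hat and effective sample size), `divergences`, and the data
#'   bookkeeping used by [predict_cf()], [contrast_1sd()] and
#'   [group_cf_contrast()]. Methods: `print`, `summary`, `coef`, `predict`,
#'   `plot`, `simulate`, `residuals`, `logLik`.
#' @export
oipgrowth <- function(data, predictor = NULL, group = NULL,
                      woman_effect = FALSE,
                      theta_scope = c("global", "population"),
                      birth_year = FALSE, a0 = 0,
                      chains = 2, warmup = 500, iter = 500, seed = 1,
                      priors = oipgrowth_priors(), control = list(),
                      quiet = FALSE) {
  theta_scope <- match.arg(theta_scope)
  if (!is.null(predictor) && !is.null(group)) {
    stop("supply either 'predictor' or 'group', not both (one focal term per model)")
  }

  if (inherits(data, "model_dataset")) {
    records <- data$records; meta <- data$meta
    if (is.null(predictor)) predictor <- data$predictor
  } else if (inherits(data, "fert_data")) {
    records <- data$records; meta <- data$meta
  } else {
    records <- data; meta <- NULL
  }
  validate_records(records, NULL)
  if (nrow(records) == 0L) stop("empty dataset")

  z <- NULL; zcol <- NULL
  if (!is.null(predictor)) {
    zcol <- if (paste0(predictor, "_z") %in% names(records))
      paste0(predictor, "_z") else predictor
    if (!zcol %in% names(records)) stop("predictor column not found: ", predictor)
    keep <- !is.na(records[[zcol]])
    records <- records[keep, , drop = FALSE]
    if (nrow(records) == 0L) stop("no populations provide predictor ", predictor)
    z <- records[[zcol]]
    if (any(!is.finite(z))) stop("non-finite predictor values")
  }

  pop_levels <- sort(unique(as.character(records$population_id)))
  j <- match(as.character(records$population_id), pop_levels)
  J <- length(pop_levels)
  age <- records$age
  if (any(age <= a0)) stop("all ages must exceed a0 = ", a0)

  # population-level grouping factor
  gidx <- NULL; group_levels <- NULL; pop_group <- NULL; n_gamma <- 0L
  if (!is.null(group)) {
    src <- if (!is.null(meta) && group %in% names(meta)) {
      meta[[group]][match(pop_levels, meta$population_id)]
    } else if (group %in% names(records)) {
      records[[group]][match(pop_levels, as.character(records$population_id))]
    } else stop("grouping column not found: ", group)
    if (any(is.na(src))) stop("grouping '", group, "' missing for some populations")
    group_levels <- if (all(src %in% MI_LEVELS)) {
      intersect(MI_LEVELS, unique(src))
    } else sort(unique(as.character(src)))
    pop_group <- match(as.character(src), group_levels)
    gidx <- pop_group[j]
    n_gamma <- length(group_levels) - 1L
    if (n_gamma == 0L) stop("grouping '", group, "' has a single level")
  }

  by <- NULL; by_center <- NULL; by_scale <- NULL
  if (birth_year) {
    if (!"birth_year" %in% names(records)) stop("no 'birth_year' column")
    byr <- records$birth_year
    if (any(is.na(byr))) stop("missing birth_year values")
    by_center <- mean(byr); by_scale <- stats::sd(byr)
    if (by_scale == 0) stop("birth_year has zero variance")
    by <- (byr - by_center) / by_scale
  }

  has_slope <- !is.null(z)
  n <- nrow(records)
  layout <- build_layout(J, n, has_slope, n_gamma, theta_scope,
                         woman_effect, birth_year)
  ctx <- list(y = as.integer(records$live_births), age_off = age - a0,
              j = j, J = J, z = z, gidx = gidx, n_gamma = n_gamma, by = by,
              theta_scope = theta_scope, woman_effect = woman_effect,
              has_slope = has_slope, layout = layout)
  lp_grad <- make_lp_grad(ctx, priors)

  mean_parity <- max(mean(ctx$y), 0.5)
  init_fn <- function() {
    q <- numeric(attr(layout, "n_par"))
    q[layout$alpha] <- log(mean_parity) + stats::rnorm(1, 0, 0.2)
    q[layout$logk] <- log(0.08) + stats::rnorm(1, 0, 0.2)
    q[layout$logb] <- stats::rnorm(1, 0, 0.2)
    q[layout$psi] <- stats::qlogis(0.1) + stats::rnorm(length(layout$psi), 0, 0.2)
    q[layout$lsp] <- log(0.2) + stats::rnorm(1, 0, 0.2)
    q[layout$a_raw] <- stats::rnorm(J, 0, 0.1)
    if (has_slope) {
      q[layout$mu_beta] <- stats::rnorm(1, 0, 0.1)
      q[layout$lsb] <- log(0.2) + stats::rnorm(1, 0, 0.2)
      q[layout$b_raw] <- stats::rnorm(J, 0, 0.1)
    }
    if (n_gamma > 0L) q[layout$gamma] <- stats::rnorm(n_gamma, 0, 0.1)
    if (birth_year) q[layout$delta] <- stats::rnorm(1, 0, 0.1)
    if (woman_effect) {
      q[layout$lsu] <- log(0.1) + stats::rnorm(1, 0, 0.2)
      q[layout$u_raw] <- stats::rnorm(n, 0, 0.1)
    }
    q
  }

  res <- hmc_sample(lp_grad, init_fn, chains, warmup, iter, seed, control)

  # diagnostics on the unconstrained draws (woman-level block summarized
  # through its scale parameter only)
  diag_idx <- unlist(layout[setdiff(names(layout), "u_raw")], use.names = FALSE)
  diag_names <- unconstrained_names(layout, pop_levels, group_levels)
  rhat <- numeric(length(diag_idx)); ess <- numeric(length(diag_idx))
  for (ii in seq_along(diag_idx)) {
    mat <- vapply(res, function(r) r$draws[, diag_idx[ii]], numeric(iter))
    rhat[ii] <- split_rhat(mat)
    ess[ii] <- sum(ess_chains(mat))
  }
  diagnostics <- data.frame(parameter = diag_names[diag_idx], rhat = rhat,
                            ess = ess, row.names = NULL)
  divergences <- sum(vapply(res, `[[`, integer(1), "divergences"))
  if (!quiet) {
    if (any(rhat > 1.01)) {
      warning("convergence: R-hat > 1.01 for ",
              paste(diagnostics$parameter[rhat > 1.01], collapse = ", "))
    }
    if (divergences > 0L) {
      warning("sampler reported ", divergences, " divergent transition(s)")
    }
  }

  un <- do.call(rbind, lapply(res, `[[`, "draws"))
  draws <- natural_draws(un, layout, pop_levels, group_levels)

  structure(list(
    draws = draws, unconstrained = un, layout = layout,
    diagnostics = diagnostics, divergences = divergences,
    accept_rate = mean(vapply(res, `[[`, numeric(1), "accept_rate")),
    lp = unlist(lapply(res, `[[`, "lp")),
    pop_levels = pop_levels, group_levels = group_levels,
    pop_group = pop_group, group_var = group,
    predictor = predictor, zcol = zcol, theta_scope = theta_scope,
    woman_effect = woman_effect, birth_year = birth_year, a0 = a0,
    priors = priors,
    mcmc = list(chains = chains, warmup = warmup, iter = iter, seed = seed),
    data = records, n = n, J = J,
    call = match.call()
  ), class = "oipgrowth")
}

unconstrained_names <- function(layout, pop_levels, group_levels) {
  nms <- character(attr(layout, "n_par"))
  lab <- function(block, labels) nms[layout[[block]]] <<- labels
  lab("alpha", "alpha")
  if (!is.null(layout$mu_beta)) lab("mu_beta", "mu_beta")
  if (!is.null(layout$gamma)) lab("gamma", paste0("gamma_", group_levels[-1]))
  lab("logk", "log_k"); lab("logb", "log_b")
  lab("psi", if (length(layout$psi) > 1L) paste0("logit_theta_", pop_levels)
             else "logit_theta")
  lab("lsp", "log_sigma_pop")
  if (!is.null(layout$lsb)) lab("lsb", "log_sigma_beta")
  lab("a_raw", paste0("alpha_pop_raw_", pop_levels))
  if (!is.null(layout$b_raw)) lab("b_raw", paste0("beta_pop_raw_", pop_levels))
  if (!is.null(layout$delta)) lab("delta", "delta_birth_year")
  if (!is.null(layout$lsu)) lab("lsu", "log_sigma_u")
  if (!is.null(layout$u_raw)) lab("u_raw", paste0("u_raw_", seq_along(layout$u_raw)))
  nms
}

# Transform pooled unconstrained draws to named natural-scale parameters.
natural_draws <- function(un, layout, pop_levels, group_levels) {
  out <- list(alpha = un[, layout$alpha])
  if (!is.null(layout$mu_beta)) out$mu_beta <- un[, layout$mu_beta]
  if (!is.null(layout$gamma)) {
    g <- un[, layout$gamma, drop = FALSE]
    colnames(g) <- paste0("gamma_", group_levels[-1])
    for (cn in colnames(g)) out[[cn]] <- g[, cn]
  }
  out$k <- exp(un[, layout$logk])
  out$b <- exp(un[, layout$logb])
  if (length(layout$psi) > 1L) {
    th <- stats::plogis(un[, layout$psi, drop = FALSE])
    colnames(th) <- paste0("theta_", pop_levels)
    for (cn in colnames(th)) out[[cn]] <- th[, cn]
  } else {
    out$theta <- stats::plogis(un[, layout$psi])
  }
  sp <- exp(un[, layout$lsp])
  out$sigma_pop <- sp
  ap <- un[, layout$a_raw, drop = FALSE] * sp
  colnames(ap) <- paste0("alpha_pop_", pop_levels)
  for (cn in colnames(ap)) out[[cn]] <- ap[, cn]
  if (!is.null(layout$lsb)) {
    sb <- exp(un[, layout$lsb])
    out$sigma_beta <- sb
    bp <- un[, layout$b_raw, drop = FALSE] * sb
    colnames(bp) <- paste0("beta_pop_", pop_levels)
    for (cn in colnames(bp)) out[[cn]] <- bp[, cn]
  }
  if (!is.null(layout$delta)) out$delta_birth_year <- un[, layout$delta]
  if (!is.null(layout$lsu)) out$sigma_u <- exp(un[, layout$lsu])
  do.call(cbind, out)
}
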