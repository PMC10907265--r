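# Posterior contrasts: predicted cumulative fertility at age 60 and its
# differences across predictor values and population groups.

draw_theta <- function(object, population = NULL) {
  dr <- object$draws
  if (object$theta_scope == "global") return(dr[, "theta"])
  if (!is.null(population)) return(dr[, paste0("theta_", population)])
  rowMeans(dr[, grep("^theta_", colnames(dr)), drop = FALSE])
}

cf_draws <- function(object, z = 0, population = NULL, group = NULL, age = 60) {
  dr <- object$draws
  eta <- dr[, "alpha"]
  if (!is.null(population)) {
    if (!population %in% object$pop_levels) {
      stop("population '", population, "' not in the model subset")
    }
    eta <- eta + dr[, paste0("alpha_pop_", population)]
    if (!is.null(object$group_levels)) {
      g <- object$pop_group[match(population, object$pop_levels)]
      if (g > 1L) eta <- eta + dr[, paste0("gamma_", object$group_levels[g])]
    }
  } else if (!is.null(group)) {
    if (!group %in% object$group_levels) {
      stop("group '", group, "' not among fitted levels: ",
           paste(object$group_levels, collapse = ", "))
    }
    if (group != object$group_levels[1L]) {
      eta <- eta + dr[, paste0("gamma_", group)]
    }
  }
  if (!is.null(object$predictor) && z != 0) {
    slope <- dr[, "mu_beta"]
    if (!is.null(population)) slope <- slope + dr[, paste0("beta_pop_", population)]
    eta <- eta + slope * z
  }
  th <- draw_theta(object, population)
  s <- 1 - exp(-dr[, "k"] * (age - object$a0))
  lam <- exp(eta) * s^dr[, "b"]
  oip_mean(lam, th)
}

#' Predicted cumulative fertility at age 60
#'
#' The model's headline prediction: per posterior draw, the expected
#' cumulative live births of a woman observed at age 60,
#' \eqn{E[y] = \theta + (1 - \theta)\lambda(60)}, then summarized as the
#' posterior median (CF~) with 90% HPDI. Summaries are always computed on
#' the per-draw CF values, never on summaries of parameters. The pooled
#' scope sets all population effects to zero (the population-mean woman);
#' the population scope conditions on one population's effects.
#'
#' @param object Fitted [oipgrowth()] model.
#' @param scope `"pooled"`, `"population"`, or `"group"` (group fits only).
#' @param z Focal predictor value (within-population SD units, or 0/1 for a
#'   binary predictor); default 0.
#' @param population Population id (required for `scope = "population"`).
#' @param group Group level (required for `scope = "group"`).
#' @param age Age at which to predict (default 60; the reporting convention).
#' @return List of class `cf_pred`: `draws`, `median`, `hpdi`, `eti`,
#'   `scope`, `scope_id`.
#' @export
predict_cf <- function(object, scope = c("pooled", "population", "group"),
                       z = 0, population = NULL, group = NULL, age = 60) {
  scope <- match.arg(scope)
  if (scope == "population" && is.null(population)) {
    stop("scope 'population' needs a 'population' id")
  }
  if (scope == "group") {
    if (is.null(object$group_levels)) stop("model was not fitted with a grouping")
    if (is.null(group)) stop("scope 'group' needs a 'group' level")
  }
  d <- cf_draws(object,
                z = z,
                population = if (scope == "population") population,
                group = if (scope == "group") group,
                age = age)
  structure(list(draws = d, median = stats::median(d), hpdi = hpdi(d),
                 eti = eti(d), scope = scope,
                 scope_id = switch(scope, pooled = "pooled",
                                   population = population, group = group),
                 age = age),
            class = "cf_pred")
}

#' @export
print.cf_pred <- function(x, ...) {
  cat(sprintf("CF~ at age %g (%s %s): %.3f, 90%% HPDI [%.3f, %.3f]\n",
              x$age, x$scope, x$scope_id, x$median, x$hpdi$lower, x$hpdi$upper))
  invisible(x)
}

contrast_row <- function(predictor, scope, scope_id, kind, draws, n) {
  s <- summarize_draws(draws)
  data.frame(predictor = predictor, scope = scope, scope_id = scope_id,
             cf_or_delta = kind, median = s$median,
             hpdi_lower = s$hpdi$lower, hpdi_upper = s$hpdi$upper,
             pp = s$pp, label = s$label, n = n, stringsAsFactors = FALSE)
}

#' One-SD contrast in predicted cumulative fertility
#'
#' Per posterior draw, the difference in predicted cumulative fertility at
#' age 60 between a woman one within-population SD above the mean of the
#' focal predictor and a woman at the mean (for binary predictors: category
#' 1 minus category 0). The pooled contrast uses the cross-population mean
#' slope \eqn{\mu_\beta} with population effects at zero; per-population
#' contrasts use the partially pooled population slope
#' \eqn{\mu_\beta + \beta_{pop}} conditional on that population's effects.
#'
#' @param object Fitted [oipgrowth()] model with a focal predictor.
#' @param scope `"both"` (default), `"pooled"`, or `"population"`.
#' @param age Prediction age (default 60).
#' @return Object of class `fert_contrasts`: `table` (one row per scope with
#'   median, 90% HPDI, posterior sign probability and evidence label) and
#'   `draws` (the pooled contrast draws).
#' @export
contrast_1sd <- function(object, scope = c("both", "pooled", "population"),
                         age = 60) {
  scope <- match.arg(scope)
  if (is.null(object$predictor)) {
    stop("model has no focal predictor; contrast_1sd() needs one")
  }
  rows <- list()
  pooled_draws <- cf_draws(object, z = 1, age = age) -
    cf_draws(object, z = 0, age = age)
  if (scope %in% c("both", "pooled")) {
    rows$pooled <- contrast_row(object$predictor, "pooled", "pooled", "delta",
                                pooled_draws, object$n)
  }
  if (scope %in% c("both", "population")) {
    for (pop in object$pop_levels) {
      d <- cf_draws(object, z = 1, population = pop, age = age) -
        cf_draws(object, z = 0, population = pop, age = age)
      rows[[pop]] <- contrast_row(
        object$predictor, "population", pop, "delta", d,
        sum(object$data$population_id == pop))
    }
  }
  structure(list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 draws = pooled_draws, predictor = object$predictor),
            class = "fert_contrasts")
}

#' Group-level cumulative fertility and pairwise contrasts
#'
#' For a model fitted with a population-level grouping (market-integration
#' level or subsistence typology): per-group predicted cumulative fertility
#' at age 60 (population effects at zero) and every pairwise difference,
#' later level minus earlier in the group ordering (market integration is
#' ordered low < medium < high, so `high - low` reproduces the reported
#' direction of the market-integration contrast).
#'
#' @param object Fitted [oipgrowth()] model with `group = ...`.
#' @param age Prediction age (default 60).
#' @return Object of class `fert_contrasts`: `table` with one `cf` row per
#'   group and one `delta` row per pair, and `draws`, a named list of the
#'   pairwise contrast draw vectors.
#' @export
group_cf_contrast <- function(object, age = 60) {
  if (is.null(object$group_levels)) {
    stop("model was not fitted with a grouping; pass group = ... to oipgrowth()")
  }
  lev <- object$group_levels
  gd <- lapply(lev, function(g) cf_draws(object, group = g, age = age))
  names(gd) <- lev
  n_by_group <- vapply(lev, function(g) {
    pops <- object$pop_levels[object$pop_group == match(g, lev)]
    sum(object$data$population_id %in% pops)
  }, numeric(1))
  rows <- lapply(lev, function(g) {
    s <- summarize_draws(gd[[g]])
    data.frame(predictor = object$group_var, scope = "group", scope_id = g,
               cf_or_delta = "cf", median = s$median,
               hpdi_lower = s$hpdi$lower, hpdi_upper = s$hpdi$upper,
               pp = NA_real_, label = NA_character_, n = n_by_group[g],
               stringsAsFactors = FALSE)
  })
  deltas <- list()
  if (length(lev) >= 2L) {
    for (a in seq_len(length(lev) - 1L)) {
      for (b in seq((a + 1L), length(lev))) {
        id <- paste0(lev[b], "-", lev[a])
        d <- gd[[b]] - gd[[a]]
        deltas[[id]] <- d
        rows[[length(rows) + 1L]] <- contrast_row(
          object$group_var, "group_contrast", id, "delta", d,
          n_by_group[lev[a]] + n_by_group[lev[b]])
      }
    }
  }
  structure(list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 draws = deltas, group_draws = gd, predictor = object$group_var),
            class = "fert_contrasts")
}

#' @export
print.fert_contrasts <- function(x, digits = 3, ...) {
  cat("Cumulative-fertility contrasts for '", x$predictor, "'\n", sep = "")
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Combine contrast results into the reporting table
#'
#' Binds any number of [contrast_1sd()] / [group_cf_contrast()] results into
#' one machine-readable table with the fixed column schema `predictor,
#' scope, scope_id, cf_or_delta, median, hpdi_lower, hpdi_upper, pp, label,
#' n`, optionally writing it to CSV.
#'
#' @param ... `fert_contrasts` objects.
#' @param file Optional CSV destination.
#' @return The combined data frame (invisibly if `file` is given).
#' @export
contrast_table <- function(..., file = NULL) {
  objs <- list(...)
  tab <- do.call(rbind, c(lapply(objs, `[[`, "table"),
                          list(make.row.names = FALSE)))
  if (!is.null(file)) {
    utils::write.csv(format(tab, digits = 15, trim = TRUE, scientific = FALSE),
                     file, row.names = FALSE, quote = FALSE)
    return(invisible(tab))
  }
  tab
}

#' Forest plot of per-population and pooled contrasts
#'
#' Point = posterior median, bar = 90% HPDI, one row per scope entry;
#' population rows are grouped by market-integration facet and coloured by
#' subsistence type when metadata is supplied.
#'
#' @param x A `fert_contrasts` object or a [contrast_table()] data frame.
#' @param meta Optional population metadata (for facet ordering by
#'   market-integration level and colouring by subsistence type).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the plotted table.
#' @export
plot_forest <- function(x, meta = NULL, ...) {
  tab <- if (inherits(x, "fert_contrasts")) x$table else x
  tab <- tab[tab$cf_or_delta == "delta" | tab$scope == "group", , drop = FALSE]
  if (!is.null(meta) && any(tab$scope == "population")) {
    ord <- order(match(tab$scope != "population", c(TRUE, FALSE)),
                 match(meta$market_integration[match(tab$scope_id,
                                                     meta$population_id)],
                       MI_LEVELS))
    tab <- tab[ord, , drop = FALSE]
  }
  n <- nrow(tab)
  cols <- rep("grey30", n)
  if (!is.null(meta)) {
    pal <- stats::setNames(grDevices::hcl.colors(length(SUBSISTENCE_TYPES),
                                                 "Dark 3"),
                           SUBSISTENCE_TYPES)
    st <- meta$subsistence_type[match(tab$scope_id, meta$population_id)]
    cols <- ifelse(is.na(st), "grey30", pal[st])
  }
  graphics::plot(tab$median, seq_len(n), xlim = range(tab$hpdi_lower,
                                                      tab$hpdi_upper, 0),
                 ylim = c(0.5, n + 0.5), yaxt = "n", pch = 16, col = cols,
                 xlab = "ΔCF~ (births)", ylab = "", ...)
  graphics::segments(tab$hpdi_lower, seq_len(n), tab$hpdi_upper, seq_len(n),
                     col = cols, lwd = 2)
  graphics::abline(v = 0, lty = 2, col = "grey60")
  graphics::axis(2, at = seq_len(n), labels = tab$scope_id, las = 1,
                 cex.axis = 0.7)
  invisible(tab)
}
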