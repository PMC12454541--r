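#' Join observed activity to energetics predictions
#'
#' Builds the per-individual-per-day deviation table: observed activity is
#' joined to the daily environment, the balance activity time is predicted
#' from that day's temperature and the individual's mass
#' ([required_activity_time()]; infeasible cold days keep `t_pred = 24` and
#' are flagged, not dropped), and the deviation is `t_obs - t_pred` --
#' positive when the animal was more active than energy balance requires.
#' Covariates are carried unstandardized; see [standardize_covariates()].
#'
#' @param records Activity tibble with `individual_id`, `date`, `sex`,
#'   `mass`, `t_obs`.
#' @param env Environment tibble with `date`, `day_of_winter`, `Ta`,
#'   `wind`, `snow`, `lunar_lum`.
#' @param p A [species_params()] object.
#' @return A tibble with columns `individual_id`, `date`, `t_obs`, `t_pred`,
#'   `deviation`, `feasible`, `below_tnz` (1 iff `Ta <= TLC`), `Ta`, `wind`,
#'   `snow`, `lunar`, `day_of_winter`, `sex`, `mass`.
#' @export
compute_deviations <- function(records, env, p) {
  stopifnot(inherits(p, "species_params"))
  if (any(is.na(records$mass))) stop("missing body mass for some records", call. = FALSE)
  joined <- dplyr::inner_join(
    dplyr::select(records, "individual_id", "date", "sex", "mass", "t_obs"),
    dplyr::select(env, "date", "day_of_winter", "Ta", "wind", "snow",
                  lunar = "lunar_lum"),
    by = "date"
  )
  if (nrow(joined) == 0) stop("no records join to the environment table by date", call. = FALSE)
  pred <- required_activity_time(joined$Ta, joined$mass, p)
  joined |>
    dplyr::mutate(
      t_pred = pred$t_pred,
      feasible = pred$feasible,
      deviation = .data$t_obs - .data$t_pred,
      below_tnz = as.integer(.data$Ta <= p$TLC)
    ) |>
    dplyr::select("individual_id", "date", "t_obs", "t_pred", "deviation",
                  "feasible", "below_tnz", "Ta", "wind", "snow", "lunar",
                  "day_of_winter", "sex", "mass")
}

#' Restrict a deviation table to the thermoneutral zone
#'
#' Keeps the rows with `below_tnz == 0` (ambient temperature above the lower
#' critical temperature), where the energetics prediction is constant in
#' temperature and environmental effects on the deviation can be read
#' without thermoregulatory confounding. If covariates had been standardized
#' on the full table, they are returned to the raw scale and re-standardized
#' on the subset.
#'
#' @param table A tibble from [compute_deviations()].
#' @return The filtered (and, if applicable, re-standardized) tibble.
#' @export
subset_tnz <- function(table) {
  stopifnot("below_tnz" %in% names(table))
  std <- attr(table, "standardization")
  if (!is.null(std)) {
    for (i in seq_len(nrow(std))) {
      cl <- std$column[i]
      table[[cl]] <- table[[cl]] * std$sd[i] + std$mean[i]
    }
    attr(table, "standardization") <- NULL
  }
  out <- dplyr::filter(table, .data$below_tnz == 0)
  if (nrow(out) == 0) stop("no records above the lower critical temperature", call. = FALSE)
  if (!is.null(std)) out <- standardize_covariates(out, std$column)
  out
}

#' Standardize covariate columns
#'
#' Mean-centers and scales each named column by its sample SD (n - 1
#' denominator), computed on the rows present, so effect sizes are
#' comparable across covariates. The means and SDs are stored in the
#' `"standardization"` attribute for back-transformation to the original
#' scale ([raw_scale_effects()]).
#'
#' @param table A tibble.
#' @param columns Character vector of column names (each with nonzero SD).
#' @return `table` with the named columns replaced by z-scores.
#' @export
standardize_covariates <- function(table, columns = c("wind", "snow", "lunar")) {
  stopifnot(all(columns %in% names(table)))
  std <- tibble::tibble(
    column = columns,
    mean = vapply(columns, function(cl) mean(table[[cl]]), 0, USE.NAMES = FALSE),
    sd = vapply(columns, function(cl) stats::sd(table[[cl]]), 0, USE.NAMES = FALSE)
  )
  if (any(std$sd == 0)) {
    stop("zero-SD column(s): ", paste(std$column[std$sd == 0], collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_along(columns)) {
    table[[columns[i]]] <- (table[[columns[i]]] - std$mean[i]) / std$sd[i]
  }
  attr(table, "standardization") <- std
  table
}

#' Fit the mixed-effects deviation model
#'
#' Fits `deviation ~ wind + snow + lunar + day_of_winter * sex` with a
#' per-individual random intercept by REML via [lme4::lmer()]. The
#' full-data variant adds the binary below-TNZ indicator
#' (`include_tnz_term = TRUE`); the state-dependence check adds body mass
#' (`include_mass = TRUE`). Because REML likelihoods are not comparable
#' across fixed-effect structures, AIC/AICc are computed from an ML refit by
#' default (`ml_for_ic`).
#'
#' Confidence intervals and p-values for the fixed effects use the Wald
#' normal approximation (estimate +/- z * SE); they are approximate, with no
#' small-sample degrees-of-freedom correction.
#'
#' @param table A deviation tibble (see [compute_deviations()]), typically
#'   standardized with [standardize_covariates()].
#' @param include_tnz_term Add `below_tnz` as a fixed effect.
#' @param include_mass Add `mass` as a fixed effect.
#' @param formula Optional full `lme4` formula overriding the default.
#' @param REML Fit variance components by REML (default) or ML.
#' @param ml_for_ic Compute AIC/AICc from an ML refit when `REML = TRUE`.
#' @param conf_level Confidence level for Wald intervals.
#' @return An object of class `deviation_lmm`: a list with `fit` (the
#'   `lmerMod`), `fixed` (tibble of term, estimate, SE, z, p, CI),
#'   `sigma2_b`, `sigma2_e`, `loglik`, `aic`, `aicc`, `n_obs`, `n_groups`,
#'   `standardization`.
#' @seealso [generics::tidy()], [generics::glance()],
#'   [random_intercept_share()], [raw_scale_effects()]
#' @export
fit_deviation_lmm <- function(table,
                              include_tnz_term = FALSE,
                              include_mass = FALSE,
                              formula = NULL,
                              REML = TRUE,
                              ml_for_ic = TRUE,
                              conf_level = 0.95) {
  if (is.null(formula)) {
    rhs <- c("wind", "snow", "lunar", "day_of_winter * sex",
             if (include_tnz_term) "below_tnz",
             if (include_mass) "mass")
    formula <- stats::as.formula(
      paste("deviation ~", paste(rhs, collapse = " + "), "+ (1 | individual_id)")
    )
  }
  if (length(unique(table$individual_id)) < 2) {
    stop("need at least 2 individuals to fit a random intercept", call. = FALSE)
  }
  fit <- lme4::lmer(formula, data = table, REML = REML)
  if (lme4::isSingular(fit)) {
    message("singular fit: the random-intercept variance is estimated at or near zero")
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma2_b <- vc$vcov[vc$grp == "individual_id"][1]
  sigma2_e <- vc$vcov[vc$grp == "Residual"][1]

  co <- summary(fit)$coefficients
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  est <- unname(co[, "Estimate"])
  se <- unname(co[, "Std. Error"])
  fixed <- tibble::tibble(
    term = rownames(co),
    estimate = est,
    std_error = se,
    statistic = est / se,
    p_value = 2 * stats::pnorm(-abs(est / se)),
    conf_low = est - z * se,
    conf_high = est + z * se
  )

  ic_fit <- if (REML && ml_for_ic) stats::update(fit, REML = FALSE) else fit
  aic <- stats::AIC(ic_fit)
  k <- attr(stats::logLik(ic_fit), "df")
  n <- stats::nobs(fit)
  structure(
    list(
      fit = fit,
      fixed = fixed,
      sigma2_b = sigma2_b,
      sigma2_e = sigma2_e,
      loglik = as.numeric(stats::logLik(fit)),
      aic = aic,
      aicc = aicc(aic, k, n),
      n_obs = n,
      n_groups = lme4::ngrps(fit)[["individual_id"]],
      REML = REML,
      conf_level = conf_level,
      standardization = attr(table, "standardization")
    ),
    class = "deviation_lmm"
  )
}

#' @export
print.deviation_lmm <- function(x, ...) {
  cat(sprintf("<deviation_lmm>  %d obs, %d individuals (%s)\n",
              x$n_obs, x$n_groups, if (x$REML) "REML" else "ML"))
  print(x$fixed, ...)
  cat(sprintf("random intercept var %.4f, residual var %.4f (intercept share %.1f%%)\n",
              x$sigma2_b, x$sigma2_e, 100 * random_intercept_share(x)))
  cat(sprintf("logLik %.2f  AIC %.2f  AICc %.2f\n", x$loglik, x$aic, x$aicc))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the fixed effects of a deviation model
#'
#' @param x A `deviation_lmm` object.
#' @param ... Unused.
#' @return A tibble with one row per fixed-effect term: `term`, `estimate`,
#'   `std_error`, `statistic`, `p_value`, `conf_low`, `conf_high`.
#' @method tidy deviation_lmm
#' @export
tidy.deviation_lmm <- function(x, ...) x$fixed

#' One-row model summary of a deviation model
#'
#' @param x A `deviation_lmm` object.
#' @param ... Unused.
#' @return A one-row tibble: variance components, the random-intercept
#'   share, log-likelihood, AIC, AICc, `n_obs`, `n_groups`.
#' @method glance deviation_lmm
#' @export
glance.deviation_lmm <- function(x, ...) {
  tibble::tibble(
    sigma2_b = x$sigma2_b,
    sigma2_e = x$sigma2_e,
    intercept_share = random_intercept_share(x),
    loglik = x$loglik,
    aic = x$aic,
    aicc = x$aicc,
    n_obs = x$n_obs,
    n_groups = x$n_groups
  )
}

#' Small-sample corrected AIC
#'
#' `AICc = AIC + 2 k (k + 1) / (n - k - 1)`; converges to AIC as `n` grows.
#'
#' @param aic AIC value.
#' @param k Number of estimated parameters.
#' @param n Number of observations (must exceed `k + 1`).
#' @return The corrected criterion.
#' @export
aicc <- function(aic, k, n) {
  stopifnot(n > k + 1)
  aic + 2 * k * (k + 1) / (n - k - 1)
}

#' Share of residual variance due to stable individual differences
#'
#' `sigma2_b / (sigma2_b + sigma2_e)`: the fraction of the variance left
#' unexplained by the fixed effects that is attributable to the
#' per-individual random intercept (an intraclass correlation).
#'
#' @param res A `deviation_lmm` object, or a list with numeric `sigma2_b`
#'   and `sigma2_e`.
#' @return A fraction in \[0, 1\].
#' @export
random_intercept_share <- function(res) {
  stopifnot(res$sigma2_b >= 0, res$sigma2_e >= 0)
  tot <- res$sigma2_b + res$sigma2_e
  if (tot == 0) stop("both variance components are zero", call. = FALSE)
  res$sigma2_b / tot
}

#' Back-transform standardized coefficients to the original covariate scale
#'
#' A coefficient fitted on a z-scored covariate is hours per SD; dividing by
#' the stored SD gives hours per original unit (km/h, cm, luminosity unit),
#' the scale needed to translate effects into energy.
#'
#' @param res A `deviation_lmm` fitted on a table that went through
#'   [standardize_covariates()].
#' @return A tibble: `term`, `estimate` (per SD), `sd`, `estimate_raw`
#'   (per original unit), for the standardized terms only.
#' @export
raw_scale_effects <- function(res) {
  std <- res$standardization
  if (is.null(std)) stop("model was not fitted on standardized covariates", call. = FALSE)
  res$fixed |>
    dplyr::inner_join(std, by = c(term = "column")) |>
    dplyr::transmute(
      term = .data$term,
      estimate = .data$estimate,
      sd = .data$sd,
      estimate_raw = .data$estimate / .data$sd
    )
}

#' Translate an activity-time effect into daily energy
#'
#' Converts a covariate effect on activity time (hours per original
#' covariate unit) into its daily energetic consequence for an average
#' individual: the activity change `delta_t = beta * delta_covariate`, the
#' resulting change in daily net energy gain
#' `delta_neg = delta_t * d(NEG)/dt` ([marginal_energy_per_hour()]), and the
#' two relative measures -- `delta_t` as a percentage of the balance
#' activity time, and `delta_neg` as a percentage of the daily energy
#' expenditure at balance (`A * RMR * t + r_i * (24 - t)` evaluated at the
#' balance point).
#'
#' @param beta Effect on activity time per original covariate unit, h
#'   (back-transformed from a standardized fit; see [raw_scale_effects()]).
#' @param delta_covariate Covariate change to translate (e.g. 20 km/h).
#' @param Ta Ambient temperature defining the regime (must give a feasible
#'   balance).
#' @param M Body mass, kg.
#' @param p A [species_params()] object.
#' @return A one-row tibble: `delta_t_h`, `delta_neg_kj`,
#'   `pct_of_balance_time`, `pct_of_daily_ee`.
#' @export
#' @examples
#' coefficient_to_energy(-0.065, 20, Ta = 0, M = 1.35, p = hare_params())
coefficient_to_energy <- function(beta, delta_covariate, Ta, M, p) {
  stopifnot(inherits(p, "species_params"), length(beta) == 1, M > 0)
  bal <- required_activity_time(Ta, M, p)
  if (!bal$feasible) stop("energy balance is infeasible at this temperature", call. = FALSE)
  ind <- scale_to_individual(p, M)
  delta_t <- beta * delta_covariate
  delta_neg <- delta_t * marginal_energy_per_hour(Ta, M, p)
  therm_active <- if (Ta <= p$TLC) ind$C * (p$TLC - Ta) else 0
  ee_day <- ind$A * (therm_active + ind$RMR) * bal$t_pred +
    inactive_cost_rate(Ta, ind) * (24 - bal$t_pred)
  tibble::tibble(
    delta_t_h = delta_t,
    delta_neg_kj = delta_neg,
    pct_of_balance_time = 100 * delta_t / bal$t_pred,
    pct_of_daily_ee = 100 * delta_neg / ee_day
  )
}
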