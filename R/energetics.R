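#' Scale species coefficients to an individual
#'
#' Resolves mass-specific rate coefficients to absolute per-individual rates:
#' `I = I0 * M^b`, `RMR = RMR0 * M^b`, `C = C0 * M^b`. The dimensionless
#' parameters (`A`, `Q`, `fat_fraction`) and `TLC` are mass-invariant.
#'
#' @param p A [species_params()] object.
#' @param M Body mass in kg (vectorized; all > 0).
#' @return A tibble with one row per mass: `mass`, `I`, `A`, `RMR`, `C`,
#'   `TLC`, `Q`, `fat_fraction`.
#' @export
#' @examples
#' scale_to_individual(hare_params(), M = c(1.1, 1.35, 1.6))
scale_to_individual <- function(p, M) {
  stopifnot(inherits(p, "species_params"), is.numeric(M), all(M > 0))
  s <- M^p$b
  tibble::tibble(
    mass = M,
    I = p$I0 * s,
    A = p$A,
    RMR = p$RMR0 * s,
    C = p$C0 * s,
    TLC = p$TLC,
    Q = p$Q,
    fat_fraction = p$fat_fraction
  )
}

#' Net energy gain rate while active
#'
#' Hourly net gain during activity: intake minus active expenditure. Within
#' the thermoneutral zone (`Ta > TLC`) active expenditure is `A * RMR`; at or
#' below the lower critical temperature the thermoregulatory cost
#' `C * (TLC - Ta)` is added before the activity multiplier, giving
#' `I - A * (C * (TLC - Ta) + RMR)`. Continuous at `Ta = TLC`.
#'
#' @param Ta Ambient temperature, degC (vectorized).
#' @param ind One row of [scale_to_individual()] output (or any list with
#'   numeric `I`, `A`, `RMR`, `C`, `TLC`).
#' @return Net gain rate, kJ/h.
#' @export
active_net_rate <- function(Ta, ind) {
  cold <- Ta <= ind$TLC
  therm <- ifelse(cold, ind$C * (ind$TLC - Ta), 0)
  ind$I - ind$A * (therm + ind$RMR)
}

#' Energy expenditure rate while inactive
#'
#' Hourly cost of the inactive state: `RMR` within the thermoneutral zone; at
#' or below `TLC` the thermoregulatory increment `C * (TLC - Ta)` is added,
#' discounted by the thermal-refuge quality `Q` so the increment is
#' `(C - C * Q) * (TLC - Ta)`. With `Q = 1` a refuge fully shelters the
#' resting animal and the rate is `RMR` at any temperature.
#'
#' @inheritParams active_net_rate
#' @param ind As in [active_net_rate()], additionally requiring `Q`.
#' @return Cost rate, kJ/h (positive).
#' @export
inactive_cost_rate <- function(Ta, ind) {
  cold <- Ta <= ind$TLC
  therm <- ifelse(cold, (ind$C - ind$C * ind$Q) * (ind$TLC - Ta), 0)
  therm + ind$RMR
}

#' Daily energy-balance target
#'
#' The net daily energy gain an individual must achieve: 0 for species that
#' must break even from foraging alone (`fat_fraction = 0`), and
#' `-f * maint_coeff * M^b` kJ for species that subsidize a fraction `f` of
#' the daily maintenance requirement from fat reserves (a negative target:
#' the day may end in deficit covered by catabolism).
#'
#' @param p A [species_params()] object.
#' @param M Body mass in kg (vectorized; all > 0).
#' @return Target net energy gain, kJ/day (<= 0).
#' @export
#' @examples
#' balance_target(porcupine_params(), M = 1) # -39.8 kJ
balance_target <- function(p, M) {
  stopifnot(inherits(p, "species_params"), is.numeric(M), all(M > 0))
  if (p$fat_fraction == 0) return(rep(0, length(M)))
  -p$fat_fraction * p$maint_coeff * M^p$b
}

#' Minimum daily activity time for energy balance
#'
#' Solves the daily budget `r_a * t - r_i * (24 - t) = target` for the
#' activity time `t`, where `r_a` is the hourly net gain while active
#' ([active_net_rate()]) and `r_i` the hourly cost while inactive
#' ([inactive_cost_rate()]). The closed form is
#' `t = (target + 24 * r_i) / (r_a + r_i)`, clamped to \[0, 24\].
#'
#' Infeasible days -- where even 24 h of activity cannot reach the target
#' (`r_a + r_i <= 0`, or the unclamped solution exceeds 24 h) -- are reported
#' with `t_pred = 24` and `feasible = FALSE` rather than dropped, so cold-day
#' records stay in downstream pipelines. When the fat subsidy covers the
#' whole inactive-day cost (`target + 24 * r_i <= 0`) the prediction is 0 h
#' and feasible.
#'
#' @param Ta Ambient temperature, degC (vectorized).
#' @param M Body mass, kg (vectorized, recycled against `Ta`).
#' @param p A [species_params()] object.
#' @return A tibble with columns `Ta`, `mass`, `t_pred` (hours in \[0, 24\]),
#'   `feasible` (logical), `neg_at_tpred` (kJ; equals the balance target when
#'   feasible).
#' @export
#' @examples
#' required_activity_time(Ta = c(5, -10, -30), M = 1.35, p = hare_params())
required_activity_time <- function(Ta, M, p) {
  stopifnot(inherits(p, "species_params"), is.numeric(Ta), is.numeric(M), all(M > 0))
  n <- max(length(Ta), length(M))
  Ta <- rep_len(Ta, n)
  M <- rep_len(M, n)
  ind <- scale_to_individual(p, M)
  r_a <- active_net_rate(Ta, ind)
  r_i <- inactive_cost_rate(Ta, ind)
  target <- balance_target(p, M)
  denom <- r_a + r_i
  numer <- target + 24 * r_i
  t_raw <- ifelse(denom > 0, numer / denom, Inf)
  t_raw[numer <= 0] <- 0
  feasible <- is.finite(t_raw) & t_raw <= 24
  t_pred <- pmin(pmax(t_raw, 0), 24)
  t_pred[!is.finite(t_raw)] <- 24
  tibble::tibble(
    Ta = Ta, mass = M,
    t_pred = t_pred,
    feasible = feasible,
    neg_at_tpred = predict_daily_neg(Ta, t_pred, M, p)
  )
}

#' Predicted daily net energy gain at an observed activity time
#'
#' Evaluates the daily budget at any activity time:
#' `NEG(t) = r_a * t - r_i * (24 - t)`, linear in `t` with slope
#' `r_a + r_i` (see [marginal_energy_per_hour()]).
#'
#' @param Ta Ambient temperature, degC.
#' @param t_obs Activity time, hours in \[0, 24\].
#' @param M Body mass, kg.
#' @param p A [species_params()] object.
#' @return Daily net energy gain, kJ.
#' @export
predict_daily_neg <- function(Ta, t_obs, M, p) {
  stopifnot(inherits(p, "species_params"),
            is.numeric(t_obs), all(t_obs >= 0 & t_obs <= 24),
            is.numeric(M), all(M > 0))
  n <- max(length(Ta), length(t_obs), length(M))
  Ta <- rep_len(Ta, n)
  t_obs <- rep_len(t_obs, n)
  M <- rep_len(M, n)
  ind <- scale_to_individual(p, M)
  active_net_rate(Ta, ind) * t_obs - inactive_cost_rate(Ta, ind) * (24 - t_obs)
}

#' Marginal energy value of an active hour
#'
#' The slope `d(NEG)/dt = r_a + r_i`: each extra active hour earns the active
#' net rate and avoids the inactive cost. Used to translate behavioural
#' changes in activity time into daily energy (see
#' [coefficient_to_energy()]). In the thermoneutral zone it reduces to
#' `I - (A - 1) * RMR`.
#'
#' @inheritParams predict_daily_neg
#' @return kJ per active hour.
#' @export
marginal_energy_per_hour <- function(Ta, M, p) {
  stopifnot(inherits(p, "species_params"), is.numeric(M), all(M > 0))
  n <- max(length(Ta), length(M))
  ind <- scale_to_individual(p, rep_len(M, n))
  Ta <- rep_len(Ta, n)
  active_net_rate(Ta, ind) + inactive_cost_rate(Ta, ind)
}

#' Calibrate the intake rate against observed activity
#'
#' Energy intake varies with resource quality and availability, so the
#' intake coefficient is the least certain rate parameter. This perturbs
#' `I0` over a relative grid (default -10%, 0, +10%), predicts the balance
#' activity time for every observed individual-day under each candidate, and
#' keeps the candidate minimizing the root-mean-squared residual of
#' predicted against observed activity time. Ties break toward the
#' unperturbed value.
#'
#' @param records Activity table with columns `date`, `t_obs` and `mass`
#'   (one row per individual-day), as produced by [simulate_activity()].
#' @param env Environment table with columns `date` and `Ta`, as produced by
#'   [simulate_environment()].
#' @param p A [species_params()] object.
#' @param grid Numeric vector of relative offsets to `I0`.
#' @return `p` with `I0` replaced by the selected candidate; the evaluated
#'   grid is attached as attribute `"calibration"` (a tibble of offset,
#'   candidate `I0` and RMSE).
#' @export
calibrate_intake <- function(records, env, p, grid = c(-0.10, 0, 0.10)) {
  stopifnot(inherits(p, "species_params"), length(grid) >= 1)
  joined <- dplyr::inner_join(
    dplyr::select(records, "date", "t_obs", "mass"),
    dplyr::select(env, "date", "Ta"),
    by = "date"
  )
  if (nrow(joined) == 0) stop("no records join to the environment table by date", call. = FALSE)
  eval_grid <- purrr::map_dbl(grid, function(off) {
    cand <- p
    cand$I0 <- p$I0 * (1 + off)
    pred <- required_activity_time(joined$Ta, joined$mass, cand)$t_pred
    sqrt(mean((pred - joined$t_obs)^2))
  })
  # tie-break toward the unperturbed value: order candidates by |offset|
  ord <- order(abs(grid))
  best <- ord[which.min(eval_grid[ord])]
  out <- p
  out$I0 <- p$I0 * (1 + grid[best])
  attr(out, "calibration") <- tibble::tibble(
    offset = grid, I0 = p$I0 * (1 + grid), rmse = eval_grid
  )
  out
}

#' Coefficient of variation of model fit
#'
#' Goodness-of-fit of predicted against observed activity times: the ratio
#' of the root-mean-squared error to the mean of the observed values. Zero
#' iff the prediction is exact; invariant to jointly rescaling observed and
#' predicted values.
#'
#' @param obs Observed values (mean must be nonzero).
#' @param pred Predicted values, same length.
#' @return A nonnegative scalar.
#' @export
#' @examples
#' model_cv(c(10, 12), c(8, 10)) # 2 / 11
model_cv <- function(obs, pred) {
  stopifnot(length(obs) == length(pred), length(obs) >= 1)
  m <- mean(obs)
  if (m == 0) stop("mean of observed values is zero; CV undefined", call. = FALSE)
  sqrt(mean((obs - pred)^2)) / m
}
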