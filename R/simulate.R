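#' Effect parameters of the generative deviation model
#'
#' The synthetic activity generator adds covariate effects, a stable
#' per-individual offset and residual noise on top of the energetics
#' prediction; this object holds those generative parameters. Defaults are
#' all-zero (a pure energetics generator); see [hare_effects()] and
#' [porcupine_effects()] for the two study-condition presets.
#'
#' @param beta_wind Hours of activity per km/h of wind.
#' @param beta_snow Hours per cm of snow depth.
#' @param beta_lunar Hours per unit lunar luminosity.
#' @param beta_time Hours per day of winter (shared across sexes).
#' @param beta_time_sex Additional hours per day for males (M minus F).
#' @param sigma_b SD of the per-individual random intercept, hours.
#' @param sigma_e Residual SD, hours.
#' @param nocturnality Fraction of daily activity placed at night, in \[0, 1\].
#' @return An object of class `effect_params` (named list).
#' @export
effect_params <- function(beta_wind = 0, beta_snow = 0, beta_lunar = 0,
                          beta_time = 0, beta_time_sex = 0,
                          sigma_b = 0, sigma_e = 0, nocturnality = 0.5) {
  stopifnot(sigma_b >= 0, sigma_e >= 0,
            nocturnality >= 0, nocturnality <= 1)
  structure(
    list(beta_wind = beta_wind, beta_snow = beta_snow,
         beta_lunar = beta_lunar, beta_time = beta_time,
         beta_time_sex = beta_time_sex,
         sigma_b = sigma_b, sigma_e = sigma_e,
         nocturnality = nocturnality),
    class = "effect_params"
  )
}

#' Study-condition effect presets
#'
#' `hare_effects()`: strong, shared environmental responses (wind and snow
#' each worth 1.3 h of activity per 20 units; lunar brightness the weakest
#' predictor), a mild seasonal decline, small between-individual variance
#' (intercept share of residual variance about 18%) and strong nocturnality.
#'
#' `porcupine_effects()`: null environmental responses, a mild positive
#' seasonal trend with a small additional male slope, and between-individual
#' variance dominating (intercept share about 44%).
#'
#' @return An [effect_params()] object.
#' @export
hare_effects <- function() {
  effect_params(
    beta_wind = -0.065, beta_snow = -0.065, beta_lunar = -0.3,
    beta_time = -0.01, beta_time_sex = 0,
    sigma_b = 0.46, sigma_e = 1.0, nocturnality = 0.77
  )
}

#' @rdname hare_effects
#' @export
porcupine_effects <- function() {
  effect_params(
    beta_wind = 0, beta_snow = 0, beta_lunar = 0,
    beta_time = 0.01, beta_time_sex = 0.005,
    sigma_b = 1.05, sigma_e = 1.2, nocturnality = 0.63
  )
}

#' Lunar luminosity from moon phase and cloud cover
#'
#' Nighttime brightness proxy: the moonlit fraction attenuated by
#' multiplicative cloud occlusion, `moon_frac * (1 - cloud)`. Monotone
#' increasing in the illuminated fraction, decreasing in cloud cover; a
#' fully overcast sky gives 0 regardless of phase.
#'
#' @param moon_frac Fraction of the moon illuminated, in \[0, 1\].
#' @param cloud Cloud-cover fraction, in \[0, 1\].
#' @return Luminosity in \[0, 1\].
#' @export
lunar_luminosity <- function(moon_frac, cloud) {
  stopifnot(all(moon_frac >= 0 & moon_frac <= 1),
            all(cloud >= 0 & cloud <= 1))
  moon_frac * (1 - cloud)
}

#' Moon-illuminated fraction on a given winter day
#'
#' Sinusoidal synodic cycle: `(1 - cos(2 * pi * (d + offset) / 29.53)) / 2`,
#' new moon at `d + offset = 0`, full at half period, period 29.53 days.
#'
#' @param day_of_winter Days since December 1 (0-based, >= 0).
#' @param phase_offset Phase shift in days.
#' @return Illuminated fraction in \[0, 1\].
#' @export
moon_fraction <- function(day_of_winter, phase_offset = 0) {
  stopifnot(all(day_of_winter >= 0))
  (1 - cos(2 * pi * (day_of_winter + phase_offset) / 29.53)) / 2
}

#' Night length over the winter
#'
#' Linear mid-latitude decline from 15.0 h on December 1 (`d = 0`) to 10.5 h
#' on day 135, roughly the photoperiod ramp at 45 degrees N.
#'
#' @param day_of_winter Days since December 1 (0-based, in \[0, 150\]).
#' @return Night length, hours.
#' @export
night_length <- function(day_of_winter) {
  stopifnot(all(day_of_winter >= 0), all(day_of_winter <= 150))
  15.0 - (15.0 - 10.5) * day_of_winter / 135
}

#' Default weather-generator configuration
#'
#' Mid-continental mid-latitude winter: mean temperature ramping down from
#' `ta_start` at 0.08 degC/day with AR(1) day-to-day persistence; lognormal
#' daily wind; snow depth as a reflected random walk; Beta-distributed cloud
#' cover.
#'
#' @param ta_start Seasonal mean temperature on December 1, degC.
#' @param ta_slope Change in mean temperature per day, degC/day.
#' @param ta_phi AR(1) coefficient of daily temperature anomalies.
#' @param ta_sd Innovation SD of the AR(1) anomalies, degC.
#' @param wind_meanlog,wind_sdlog Lognormal parameters of daily wind, km/h.
#' @param snow_start Initial snow depth, cm.
#' @param snow_sd Daily random-walk step SD, cm.
#' @param cloud_shape1,cloud_shape2 Beta parameters of cloud cover.
#' @param moon_phase_offset Phase shift of the lunar cycle, days.
#' @return A named list.
#' @export
environment_config <- function(ta_start = -2, ta_slope = -0.08,
                               ta_phi = 0.7, ta_sd = 3,
                               wind_meanlog = log(8), wind_sdlog = 0.5,
                               snow_start = 15, snow_sd = 2,
                               cloud_shape1 = 2, cloud_shape2 = 2,
                               moon_phase_offset = 0) {
  list(ta_start = ta_start, ta_slope = ta_slope, ta_phi = ta_phi,
       ta_sd = ta_sd, wind_meanlog = wind_meanlog, wind_sdlog = wind_sdlog,
       snow_start = snow_start, snow_sd = snow_sd,
       cloud_shape1 = cloud_shape1, cloud_shape2 = cloud_shape2,
       moon_phase_offset = moon_phase_offset)
}

#' Simulate a daily winter weather series
#'
#' Generates the per-date covariate table the analysis consumes: mean daily
#' temperature (seasonal ramp plus AR(1) anomalies), wind speed (lognormal),
#' snow depth (reflected random walk, never negative), cloud cover (Beta),
#' the moon-illuminated fraction ([moon_fraction()]), the derived lunar
#' luminosity ([lunar_luminosity()]) and night length ([night_length()]).
#' Fully reproducible under a fixed `seed`.
#'
#' @param n_days Number of days (>= 1), starting December 1.
#' @param seed Integer RNG seed.
#' @param config A list from [environment_config()].
#' @param start_date First calendar date (a `Date`).
#' @return A tibble with columns `date`, `day_of_winter`, `Ta`, `wind`,
#'   `snow`, `cloud`, `moon_frac`, `lunar_lum`, `night_h`.
#' @export
#' @examples
#' simulate_environment(5, seed = 1)
simulate_environment <- function(n_days, seed, config = environment_config(),
                                 start_date = as.Date("2022-12-01")) {
  stopifnot(n_days >= 1)
  set.seed(seed)
  d <- seq_len(n_days) - 1L
  anom <- numeric(n_days)
  innov <- stats::rnorm(n_days, 0, config$ta_sd)
  for (i in seq_len(n_days)) {
    anom[i] <- if (i == 1) innov[1] else config$ta_phi * anom[i - 1] + innov[i]
  }
  snow <- abs(config$snow_start + cumsum(stats::rnorm(n_days, 0, config$snow_sd)))
  moon <- moon_fraction(d, config$moon_phase_offset)
  cloud <- stats::rbeta(n_days, config$cloud_shape1, config$cloud_shape2)
  tibble::tibble(
    date = start_date + d,
    day_of_winter = d,
    Ta = config$ta_start + config$ta_slope * d + anom,
    wind = stats::rlnorm(n_days, config$wind_meanlog, config$wind_sdlog),
    snow = snow,
    cloud = cloud,
    moon_frac = moon,
    lunar_lum = lunar_luminosity(moon, cloud),
    night_h = night_length(pmin(d, 150))
  )
}

#' Simulate a monitored cohort
#'
#' Draws `n` individuals of one species: body masses truncated-normal
#' (floored at 0.1 kg), balanced-random sexes, and latent per-individual
#' activity intercepts `b_i ~ Normal(0, sigma_b)` that are stored so
#' downstream variance-recovery tests can compare against truth.
#'
#' @param n Cohort size (>= 1).
#' @param species A [species_params()] object (used for the species label).
#' @param mass_mean,mass_sd Mean and SD of body mass, kg.
#' @param sigma_b SD of the individual random intercepts, hours.
#' @param seed Integer RNG seed.
#' @return A tibble with columns `id`, `species`, `sex`, `mass`,
#'   `random_intercept`.
#' @export
simulate_cohort <- function(n, species, mass_mean, mass_sd, sigma_b, seed) {
  stopifnot(n >= 1, mass_mean > 0, mass_sd >= 0, sigma_b >= 0,
            inherits(species, "species_params"))
  set.seed(seed)
  mass <- stats::rnorm(n, mass_mean, mass_sd)
  while (any(mass <= 0.1)) {
    bad <- mass <= 0.1
    mass[bad] <- stats::rnorm(sum(bad), mass_mean, mass_sd)
  }
  sex <- sample(rep_len(c("F", "M"), n))
  tibble::tibble(
    id = sprintf("%s_%02d", substr(species$species_name, 1, 1), seq_len(n)),
    species = species$species_name,
    sex = sex,
    mass = mass,
    random_intercept = stats::rnorm(n, 0, sigma_b)
  )
}

#' Simulate per-individual daily activity records
#'
#' The generative inverse of the deviation analysis: for every
#' individual-day, observed activity is the energetics-based balance
#' prediction ([required_activity_time()]; infeasible days enter at 24 h)
#' plus linear covariate effects, the individual's latent intercept, and
#' Gaussian residual noise, clamped to \[0, 24\]:
#'
#' `t_obs = clamp( t_pred + bw*wind + bs*snow + bl*lunar_lum +
#'   (bt + bts * 1[male]) * day_of_winter + b_i + e )`, `e ~ N(0, sigma_e)`.
#'
#' A `nocturnality` share of each day's activity is placed at night,
#' respecting the night- and day-length bounds (`t_night <= night_h`,
#' `t_day <= 24 - night_h`, `t_night + t_day = t_obs`). Rows clamped at
#' either bound are flagged so censoring-sensitive analyses can filter them.
#'
#' @param cohort A tibble from [simulate_cohort()].
#' @param env A tibble from [simulate_environment()].
#' @param species A [species_params()] object.
#' @param eff An [effect_params()] object (its `sigma_b` is not re-drawn
#'   here; intercepts come from the cohort).
#' @param seed Integer RNG seed for the residual noise.
#' @return A tibble with one row per individual-day: `individual_id`,
#'   `date`, `species`, `sex`, `mass`, `t_obs`, `t_night`, `t_day`,
#'   `t_pred`, `feasible`, `clamped`.
#' @export
simulate_activity <- function(cohort, env, species, eff, seed) {
  stopifnot(nrow(cohort) >= 1, nrow(env) >= 1,
            inherits(species, "species_params"),
            inherits(eff, "effect_params"))
  set.seed(seed)
  grid <- tidyr::crossing(
    dplyr::select(cohort, individual_id = "id", "sex", "mass",
                  b_i = "random_intercept"),
    dplyr::select(env, "date", "day_of_winter", "Ta", "wind", "snow",
                  "lunar_lum", "night_h")
  )
  pred <- required_activity_time(grid$Ta, grid$mass, species)
  male <- as.numeric(grid$sex == "M")
  mu <- pred$t_pred +
    eff$beta_wind * grid$wind +
    eff$beta_snow * grid$snow +
    eff$beta_lunar * grid$lunar_lum +
    (eff$beta_time + eff$beta_time_sex * male) * grid$day_of_winter +
    grid$b_i
  t_raw <- mu + stats::rnorm(nrow(grid), 0, eff$sigma_e)
  t_obs <- pmin(pmax(t_raw, 0), 24)
  t_night <- pmin(pmax(eff$nocturnality * t_obs,
                       t_obs - (24 - grid$night_h)),
                  grid$night_h)
  dplyr::tibble(
    individual_id = grid$individual_id,
    date = grid$date,
    species = species$species_name,
    sex = grid$sex,
    mass = grid$mass,
    t_obs = t_obs,
    t_night = t_night,
    t_day = t_obs - t_night,
    t_pred = pred$t_pred,
    feasible = pred$feasible,
    clamped = t_raw < 0 | t_raw > 24
  ) |>
    dplyr::arrange(.data$date, .data$individual_id)
}

#' Simulate a complete two-table study dataset
#'
#' Convenience wrapper tying the weather, cohort and activity generators
#' together under one seed, at the study-condition defaults: a hare-like
#' cohort of 29 monitored for 28 days (~800 individual-days) or a
#' porcupine-like cohort of 21 for 18 days (~380 individual-days).
#'
#' @param species `"hare-like"` or `"porcupine-like"`, or a
#'   [species_params()] object (then `n`, `n_days`, `eff`, `mass_mean`,
#'   `mass_sd` must suit it).
#' @param seed Integer RNG seed; sub-seeds for the three generators are
#'   derived from it deterministically.
#' @param n,n_days,mass_mean,mass_sd,eff,config Overrides of the
#'   species-specific defaults.
#' @return A list with elements `env`, `cohort`, `activity` (tibbles) and
#'   `params`, `effects`.
#' @export
#' @examples
#' d <- simulate_study("hare-like", seed = 42, n = 4, n_days = 5)
#' d$activity
simulate_study <- function(species = c("hare-like", "porcupine-like"),
                           seed = 1, n = NULL, n_days = NULL,
                           mass_mean = NULL, mass_sd = NULL,
                           eff = NULL, config = environment_config()) {
  if (is.character(species)) {
    species <- match.arg(species)
    defaults <- if (species == "hare-like") {
      list(p = hare_params(), eff = hare_effects(),
           n = 29L, n_days = 28L, mass_mean = 1.35, mass_sd = 0.15)
    } else {
      list(p = porcupine_params(), eff = porcupine_effects(),
           n = 21L, n_days = 18L, mass_mean = 8, mass_sd = 1.2)
    }
    p <- defaults$p
    if (is.null(eff)) eff <- defaults$eff
    if (is.null(n)) n <- defaults$n
    if (is.null(n_days)) n_days <- defaults$n_days
    if (is.null(mass_mean)) mass_mean <- defaults$mass_mean
    if (is.null(mass_sd)) mass_sd <- defaults$mass_sd
  } else {
    stopifnot(inherits(species, "species_params"),
              !is.null(n), !is.null(n_days), !is.null(mass_mean),
              !is.null(mass_sd), !is.null(eff))
    p <- species
  }
  env <- simulate_environment(n_days, seed = seed %% 1000003L + 1L, config = config)
  cohort <- simulate_cohort(n, p, mass_mean, mass_sd, eff$sigma_b,
                            seed = seed %% 1000003L + 2L)
  activity <- simulate_activity(cohort, env, p, eff,
                                seed = seed %% 1000003L + 3L)
  list(env = env, cohort = cohort, activity = activity,
       params = p, effects = eff)
}
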