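# Independent oracles and fixture builders shared across the suite.

# Bisection root-finder for the balance activity time: finds t in [0, 24]
# with NEG(t) = target by interval halving on the (monotone) daily budget,
# independent of the closed-form solution in required_activity_time().
bisect_balance_time <- function(Ta, M, p, tol = 1e-9) {
  ind <- scale_to_individual(p, M)
  r_a <- active_net_rate(Ta, ind)
  r_i <- inactive_cost_rate(Ta, ind)
  target <- balance_target(p, M)
  g <- function(t) r_a * t - r_i * (24 - t) - target
  if (g(0) >= 0) return(list(t = 0, feasible = TRUE))
  if (g(24) < 0) return(list(t = 24, feasible = FALSE))
  lo <- 0; hi <- 24
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(mid) < 0) lo <- mid else hi <- mid
  }
  list(t = (lo + hi) / 2, feasible = TRUE)
}

# Random but physically plausible species parameter sets for property sweeps.
random_species <- function() {
  species_params(
    "sweep",
    I0 = runif(1, 20, 80),
    A = runif(1, 1, 3),
    RMR0 = runif(1, 5, 20),
    C0 = runif(1, 0.2, 2),
    TLC = runif(1, -15, 5),
    Q = runif(1, 0, 1),
    fat_fraction = sample(c(0, 0.1, 0.2), 1),
    maint_coeff = 398,
    b = 0.75
  )
}

# Minimal activity/environment fixture pair: k individuals x n_days, with
# observed activity supplied by the caller (recycled over the grid).
tiny_tables <- function(t_obs, k = 2, n_days = 2, Ta = 5, night_h = 13,
                        mass = 1.35, start = as.Date("2023-01-05")) {
  env <- tibble::tibble(
    date = start + seq_len(n_days) - 1,
    day_of_winter = as.integer(date - as.Date("2022-12-01")),
    Ta = rep_len(Ta, n_days),
    wind = seq(4, 12, length.out = n_days),
    snow = seq(10, 20, length.out = n_days),
    cloud = 0.5,
    moon_frac = 0.5,
    lunar_lum = 0.25,
    night_h = rep_len(night_h, n_days)
  )
  grid <- tidyr::crossing(
    individual_id = sprintf("id%02d", seq_len(k)),
    date = env$date
  )
  records <- dplyr::mutate(
    grid,
    species = "hare-like",
    sex = rep_len(c("F", "M"), nrow(grid)),
    mass = rep_len(mass, nrow(grid)),
    t_obs = rep_len(t_obs, nrow(grid)),
    t_night = pmin(t_obs, rep_len(night_h, nrow(grid))),
    t_day = t_obs - t_night
  )
  list(records = records, env = env)
}
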