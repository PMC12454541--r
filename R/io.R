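#' Read and write the two study tables
#'
#' The pipeline exchanges two flat CSV schemas: an activity table (one row
#' per individual-day: `individual_id`, `date`, `species`, `sex`, `mass`,
#' `t_obs`, `t_night`, `t_day`) and an environment table (one row per date:
#' `date`, `day_of_winter`, `Ta`, `wind`, `snow`, `cloud`, `moon_frac`,
#' `lunar_lum`, `night_h`). Dates are ISO-8601. Extra columns are preserved.
#'
#' @param path File path.
#' @return A tibble.
#' @name study_io
NULL

#' @rdname study_io
#' @export
read_activity_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(date = readr::col_date()))
}

#' @rdname study_io
#' @export
read_environment_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(date = readr::col_date()))
}

#' @rdname study_io
#' @param x Tibble to write.
#' @export
write_study_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' Per-day activity predictions in the exchange schema
#'
#' Runs the energetics model over every observed individual-day and returns
#' the flat prediction table: predicted balance activity time, feasibility,
#' the daily balance target, and the net energy gain implied by the
#' observed activity time.
#'
#' @param records Activity tibble (`individual_id`, `date`, `mass`, `t_obs`).
#' @param env Environment tibble (`date`, `Ta`).
#' @param p A [species_params()] object.
#' @return A tibble with columns `individual_id`, `date`, `Ta_C`, `mass_kg`,
#'   `t_pred_h`, `feasible`, `neg_target_kJ`, `neg_obs_kJ`.
#' @export
predict_activity <- function(records, env, p) {
  stopifnot(inherits(p, "species_params"))
  joined <- dplyr::inner_join(
    dplyr::select(records, "individual_id", "date", "mass", "t_obs"),
    dplyr::select(env, "date", "Ta"),
    by = "date"
  )
  if (nrow(joined) == 0) stop("no records join to the environment table by date", call. = FALSE)
  pred <- required_activity_time(joined$Ta, joined$mass, p)
  tibble::tibble(
    individual_id = joined$individual_id,
    date = joined$date,
    Ta_C = joined$Ta,
    mass_kg = joined$mass,
    t_pred_h = pred$t_pred,
    feasible = pred$feasible,
    neg_target_kJ = balance_target(p, joined$mass),
    neg_obs_kJ = predict_daily_neg(joined$Ta, joined$t_obs, joined$mass, p)
  )
}
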