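#' Diel activity summary
#'
#' Means and SDs of total, nighttime and daytime daily activity over all
#' whole-day records, plus the mean proportion of the night spent active
#' (per-record ratio `t_night / night_h`, averaged; the ratio-of-sums
#' variant is reported alongside for transparency).
#'
#' @param records Activity tibble with `date`, `t_obs`, `t_night`, `t_day`.
#' @param env Environment tibble with `date` and `night_h`.
#' @return A one-row tibble: `n`, `mean_total_h`, `sd_total_h`,
#'   `mean_night_h`, `sd_night_h`, `mean_day_h`, `sd_day_h`,
#'   `prop_active_night` (mean of ratios), `prop_active_night_pooled`
#'   (ratio of sums).
#' @export
diel_summary <- function(records, env) {
  stopifnot(nrow(records) >= 1)
  joined <- dplyr::inner_join(records,
                              dplyr::select(env, "date", "night_h"),
                              by = "date")
  if (nrow(joined) == 0) stop("no records join to the environment table by date", call. = FALSE)
  dplyr::summarise(
    joined,
    n = dplyr::n(),
    mean_total_h = mean(.data$t_obs),
    sd_total_h = stats::sd(.data$t_obs),
    mean_night_h = mean(.data$t_night),
    sd_night_h = stats::sd(.data$t_night),
    mean_day_h = mean(.data$t_day),
    sd_day_h = stats::sd(.data$t_day),
    prop_active_night = mean(.data$t_night / .data$night_h),
    prop_active_night_pooled = sum(.data$t_night) / sum(.data$night_h)
  )
}

#' Correlation between daytime and nighttime activity
#'
#' Pearson correlation of same-day daytime and nighttime activity hours
#' pooled over all records. A strongly negative value indicates diel
#' compensation (a fixed activity budget shifted between phases).
#'
#' @param records Activity tibble with `t_day` and `t_night`.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
day_night_correlation <- function(records) {
  stopifnot(nrow(records) >= 3)
  if (stats::sd(records$t_day) == 0 || stats::sd(records$t_night) == 0) {
    stop("degenerate variance: day or night activity is constant", call. = FALSE)
  }
  stats::cor(records$t_day, records$t_night)
}

#' Enumerate same-day pairs of monitored individuals
#'
#' For each date, every unordered pair of individuals with a record that
#' day is emitted exactly once, ordered lexicographically (`id_a < id_b`).
#' A day with `k` monitored individuals contributes `k * (k - 1) / 2` pairs.
#' With `pair_ordering = "both"` each pair is emitted in both orientations,
#' symmetrizing the scatter.
#'
#' @param records Activity tibble with `individual_id`, `date`, `t_obs`.
#' @param pair_ordering `"single"` (default; one row per unordered pair) or
#'   `"both"`.
#' @return A tibble with columns `date`, `id_a`, `id_b`, `x_a`, `x_b`.
#' @export
#' @examples
#' r <- tibble::tibble(
#'   individual_id = c("a", "b", "c", "d"),
#'   date = as.Date("2023-01-01"), t_obs = c(10, 11, 12, 13)
#' )
#' enumerate_same_day_pairs(r) # 6 pairs
enumerate_same_day_pairs <- function(records, pair_ordering = c("single", "both")) {
  pair_ordering <- match.arg(pair_ordering)
  if (nrow(records) == 0) {
    return(tibble::tibble(date = records$date[0], id_a = character(),
                          id_b = character(), x_a = numeric(), x_b = numeric()))
  }
  pairs <- records |>
    dplyr::select(date = "date", id_a = "individual_id", x_a = "t_obs") |>
    dplyr::inner_join(
      dplyr::select(records, date = "date", id_b = "individual_id", x_b = "t_obs"),
      by = "date", relationship = "many-to-many"
    ) |>
    dplyr::filter(.data$id_a < .data$id_b) |>
    dplyr::arrange(.data$date, .data$id_a, .data$id_b)
  if (pair_ordering == "both") {
    pairs <- dplyr::bind_rows(
      pairs,
      dplyr::rename(pairs, id_a = "id_b", id_b = "id_a", x_a = "x_b", x_b = "x_a")
    )
  }
  pairs
}

#' Inter-individual activity synchrony
#'
#' Pearson correlation of daily activity time between two individuals on
#' the same day, pooled over all same-day pairs and all dates into one
#' global coefficient. A strong positive value means different individuals
#' respond uniformly to shared conditions (environmental forcing dominates);
#' a value near zero means individual variation dominates.
#'
#' @inheritParams enumerate_same_day_pairs
#' @return Correlation coefficient in \[-1, 1\].
#' @export
interindividual_synchrony <- function(records, pair_ordering = c("single", "both")) {
  pairs <- enumerate_same_day_pairs(records, pair_ordering)
  if (nrow(pairs) < 3) stop("fewer than 3 same-day pair observations", call. = FALSE)
  if (stats::sd(pairs$x_a) == 0 || stats::sd(pairs$x_b) == 0) {
    stop("degenerate variance in pair observations", call. = FALSE)
  }
  stats::cor(pairs$x_a, pairs$x_b)
}
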