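#' Species energetic parameter set
#'
#' Bundles the coefficients of the Scholander-Irving daily energy budget for
#' one species. Rate coefficients (`I0`, `RMR0`, `C0`) are mass-specific:
#' the absolute per-individual rate is `coef * M^b` for body mass `M` in kg
#' (see [scale_to_individual()]).
#'
#' @param species_name Character label for the species.
#' @param I0 Metabolizable energy intake-rate coefficient while active,
#'   kJ h^-1 kg^-b.
#' @param A Activity multiplier (factor by which expenditure during activity
#'   exceeds resting expenditure); dimensionless, must be >= 1.
#' @param RMR0 Resting metabolic rate coefficient within the thermoneutral
#'   zone, kJ h^-1 kg^-b.
#' @param C0 Thermal conductance coefficient, kJ h^-1 degC^-1 kg^-b.
#' @param TLC Lower critical temperature (degC): below it, resting and active
#'   thermoregulatory costs rise linearly with `TLC - Ta`.
#' @param Q Thermal-refuge quality in \[0, 1\]: fraction of the below-TNZ
#'   thermoregulatory cost eliminated while resting in a shelter (0 = none,
#'   1 = complete elimination).
#' @param fat_fraction Fraction `f` in \[0, 1\] of the daily maintenance
#'   requirement met from fat catabolism rather than foraging. The daily
#'   energy-balance target is `-f * maint_coeff * M^b` kJ (see
#'   [balance_target()]); 0 means the animal must break even every day.
#' @param maint_coeff Daily maintenance requirement coefficient,
#'   kJ day^-1 kg^-b.
#' @param b Allometric scaling exponent applied to `I0`, `RMR0` and `C0`
#'   (default 0.75, classic metabolic scaling).
#'
#' @return An object of class `species_params` (a named list).
#' @seealso [hare_params()], [porcupine_params()], [read_species_config()]
#' @export
#' @examples
#' species_params("generic", I0 = 50, A = 2, RMR0 = 12, C0 = 1, TLC = -5)
species_params <- function(species_name,
                           I0, A, RMR0, C0, TLC,
                           Q = 0, fat_fraction = 0, maint_coeff = 398,
                           b = 0.75) {
  stopifnot(
    is.character(species_name), length(species_name) == 1L,
    is.numeric(I0), I0 > 0,
    is.numeric(A), A >= 1,
    is.numeric(RMR0), RMR0 > 0,
    is.numeric(C0), C0 > 0,
    is.numeric(TLC), is.finite(TLC),
    is.numeric(Q), Q >= 0, Q <= 1,
    is.numeric(fat_fraction), fat_fraction >= 0, fat_fraction <= 1,
    is.numeric(maint_coeff), maint_coeff >= 0,
    is.numeric(b), is.finite(b)
  )
  structure(
    list(
      species_name = species_name,
      I0 = I0, A = A, RMR0 = RMR0, C0 = C0, TLC = TLC,
      Q = Q, fat_fraction = fat_fraction, maint_coeff = maint_coeff,
      b = b
    ),
    class = "species_params"
  )
}

#' @export
print.species_params <- function(x, ...) {
  cat("<species_params> ", x$species_name, "\n", sep = "")
  cat(sprintf("  I0   = %8.4f kJ/h/kg^%.2f   A = %.4f\n", x$I0, x$b, x$A))
  cat(sprintf("  RMR0 = %8.4f kJ/h/kg^%.2f   C0 = %.4f kJ/h/degC/kg^%.2f\n",
              x$RMR0, x$b, x$C0, x$b))
  cat(sprintf("  TLC  = %.1f degC   Q = %.2f   fat_fraction = %.2f   maint = %.0f kJ/day/kg^%.2f\n",
              x$TLC, x$Q, x$fat_fraction, x$maint_coeff, x$b))
  invisible(x)
}

#' Solve rate coefficients from balance-point constraints
#'
#' Recovers the three rate parameters (`RMR`, `A`, `I`) of the activity-budget
#' model for one individual in the thermoneutral zone from three observable
#' constraints: the daily activity time `t_star` that exactly meets the
#' energy-balance target, the total daily energy expenditure `ee_day` at that
#' balance point, and the marginal energy value of an active hour
#' (`d NEG / d t`). Within the TNZ the three constraints are linear in
#' `(RMR, A*RMR, I)`, so the solve is exact.
#'
#' Used to calibrate the shipped hare-like parameter set from its documented
#' balance-point characteristics, and usable for any species whose balance
#' behaviour is known but whose physiological rates are not.
#'
#' @param t_star Balance activity time, hours in (0, 24).
#' @param ee_day Daily energy expenditure at balance, kJ/day.
#' @param marginal Marginal energy gain per active hour, kJ/h
#'   (`I - (A - 1) * RMR` in the TNZ).
#' @param target Daily energy-balance target, kJ (default 0).
#'
#' @return A tibble with one row: `RMR`, `A`, `I` (absolute rates, kJ/h).
#' @export
#' @examples
#' solve_balance_constraints(t_star = 10.54, ee_day = 754.3, marginal = 56 / 1.3)
solve_balance_constraints <- function(t_star, ee_day, marginal, target = 0) {
  stopifnot(t_star > 0, t_star < 24, ee_day > 0)
  rest <- 24 - t_star
  # unknowns x = (RMR, A*RMR, I):
  #  (I - A*RMR) * t_star - RMR * rest = target
  #  A*RMR * t_star + RMR * rest      = ee_day
  #  I - A*RMR + RMR                  = marginal
  m <- rbind(
    c(-rest, -t_star, t_star),
    c(rest, t_star, 0),
    c(1, -1, 1)
  )
  x <- solve(m, c(target, ee_day, marginal))
  if (x[1] <= 0 || x[3] <= 0 || x[2] / x[1] < 1) {
    stop("constraints imply a non-physical parameter set", call. = FALSE)
  }
  tibble::tibble(RMR = x[1], A = x[2] / x[1], I = x[3])
}

#' Default hare-like parameter set
#'
#' A lean mid-sized boreal herbivore: no fat reserve (daily break-even
#' target), no thermal refuge (`Q = 0`). The rate coefficients are calibrated
#' so that a 1.35 kg individual in the thermoneutral zone balances its budget
#' at 10.54 h of daily activity, spends 754.3 kJ/day doing so, and gains
#' 43.08 kJ per marginal active hour (see [solve_balance_constraints()]).
#' `TLC` and `C0` are plausible winter-acclimation values for a well-insulated
#' 1-2 kg lagomorph.
#'
#' @return A `species_params` object.
#' @export
hare_params <- function() {
  species_params(
    "hare-like",
    I0 = 57.14171, A = 2.50590, RMR0 = 15.10510,
    C0 = 0.8, TLC = -5,
    Q = 0, fat_fraction = 0, maint_coeff = 398, b = 0.75
  )
}

#' Default porcupine-like parameter set
#'
#' A large arboreal herbivore that under-eats in winter and subsidizes 10%
#' of its daily maintenance (398 M^0.75 kJ) from fat, and rests in dens that
#' eliminate most below-TNZ thermoregulatory cost (`Q = 0.8`). These defaults
#' are configuration, not ground truth: they are scale-plausible placeholder
#' values for an 8 kg winter-acclimatized porcupine, not literature-derived
#' measurements.
#'
#' @param fat_fraction Fat-subsidy fraction; 0.10 by default, 0.20 for
#'   sensitivity analyses.
#' @return A `species_params` object.
#' @export
porcupine_params <- function(fat_fraction = 0.10) {
  species_params(
    "porcupine-like",
    I0 = 41, A = 2, RMR0 = 8,
    C0 = 1, TLC = -15,
    Q = 0.8, fat_fraction = fat_fraction, maint_coeff = 398, b = 0.75
  )
}

#' Read species parameter sets from a plain-text config file
#'
#' Parses a minimal key-value format: one `[species-label]` section header
#' per species followed by `key = value` lines, keys being the arguments of
#' [species_params()] (`I0`, `A`, `RMR0`, `C0`, `TLC`, `Q`, `fat_fraction`,
#' `maint_coeff`, `b`). Blank lines and `#` comments are ignored.
#'
#' @param path Path to the config file.
#' @return A named list of `species_params`, one element per section.
#' @export
#' @examples
#' cfg <- system.file("extdata", "species_defaults.conf", package = "winterbudget")
#' read_species_config(cfg)
read_species_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  current <- NULL
  fields <- list()
  flush <- function() {
    if (is.null(current)) return(invisible())
    out[[current]] <<- do.call(
      species_params,
      c(list(species_name = current), lapply(fields, identity))
    )
  }
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      flush()
      current <- gsub("^\\[|\\]$", "", ln)
      fields <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(current)) stop("key-value line before any [section] header", call. = FALSE)
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      val <- suppressWarnings(as.numeric(trimws(paste(kv[-1], collapse = "="))))
      if (is.na(val)) stop("non-numeric value for key '", key, "'", call. = FALSE)
      fields[[key]] <- val
    } else {
      stop("unparseable config line: '", ln, "'", call. = FALSE)
    }
  }
  flush()
  out
}

#' Write species parameter sets to a plain-text config file
#'
#' Inverse of [read_species_config()].
#'
#' @param params A `species_params` object or a list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_species_config <- function(params, path) {
  if (inherits(params, "species_params")) params <- list(params)
  lines <- unlist(lapply(params, function(p) {
    keys <- setdiff(names(p), "species_name")
    c(sprintf("[%s]", p$species_name),
      vapply(keys, function(k) sprintf("%s = %.10g", k, p[[k]]), ""),
      "")
  }))
  writeLines(lines, path)
  invisible(path)
}
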