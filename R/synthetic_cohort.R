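#' Generator configuration for synthetic TOFR cohorts
#'
#' Builds and validates the configuration of the synthetic cohort generator.
#' Defaults emulate the monitoring setting the package targets: acceleromyographic
#' train-of-four ratio (TOFR, 0--100 percent scale) sampled every 15 seconds
#' during recovery from a nondepolarizing block, records 119--228 samples long,
#' adults aged 18--75 years with BMI below 35 kg/m^2, and an end-of-record TOFR
#' of at least 90 (records ending below 90 are excluded from such studies).
#'
#' Each virtual patient follows a logistic block-to-recovery curve whose
#' timing (`t50`, minutes) and steepness (`slope`, minutes) are modulated by
#' age and BMI, so that demographically similar patients have similar
#' recovery dynamics — the structure that transfer by patient similarity
#' exploits.
#'
#' @param n_patients number of patients in a cohort (>= 2).
#' @param length_range integer range of series lengths, in samples; the
#'   length of each record follows from the patient's recovery duration and
#'   is clamped into this range.
#' @param duration_ratio_range range of the ratio of recovery duration to
#'   sigmoid steepness; it controls how far past the recovery inflection the
#'   first (training) half of a record reaches.
#' @param sample_interval sampling interval in seconds (15 s grid).
#' @param age_range age range in years, within \[18, 75\].
#' @param bmi_range BMI range in kg/m^2; upper bound at most 35.
#' @param end_value_range range of the noiseless end-of-record TOFR.
#' @param beta_age,beta_bmi shift of `t50` (minutes) per year of age /
#'   per kg/m^2 of BMI, centred at 50 years and 25 kg/m^2.
#' @param gamma_age,gamma_bmi multiplicative (log-scale) effect of age / BMI
#'   on the sigmoid steepness `slope`, per year and per kg/m^2.
#' @param slope_base baseline sigmoid steepness in minutes.
#' @param slope_sd standard deviation of the patient-level log-slope effect.
#' @param patient_sd standard deviation (minutes) of the patient-level
#'   random effect on `t50`.
#' @param noise_sd standard deviation of additive observation noise, TOFR
#'   percent.
#' @param missing_rate probability that a sample is missing (< 0.5); the
#'   final sample is always observed so the end-of-record rule is checkable.
#' @param plateau_frac fraction of the curve plateau reached at the end of
#'   the record; with the default 0.995 the recovery is essentially complete
#'   when monitoring stops, as when surgery ends after the TOFR has returned
#'   above 90.
#' @param seed master seed of the generator.
#' @return a validated `tofr_generator_config` list.
#' @export
generator_config <- function(n_patients = 83,
                             length_range = c(119L, 228L),
                             duration_ratio_range = c(7.8, 9.3),
                             sample_interval = 15,
                             age_range = c(18, 75),
                             bmi_range = c(18, 35),
                             end_value_range = c(90, 100),
                             beta_age = 0.15,
                             beta_bmi = 0.2,
                             gamma_age = 0.008,
                             gamma_bmi = 0.01,
                             slope_base = 4,
                             slope_sd = 0.05,
                             patient_sd = 2,
                             noise_sd = 1.5,
                             missing_rate = 0.05,
                             plateau_frac = 0.995,
                             seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              length_range = as.integer(length_range),
              duration_ratio_range = duration_ratio_range,
              sample_interval = sample_interval,
              age_range = age_range, bmi_range = bmi_range,
              end_value_range = end_value_range,
              beta_age = beta_age, beta_bmi = beta_bmi,
              gamma_age = gamma_age, gamma_bmi = gamma_bmi,
              slope_base = slope_base, slope_sd = slope_sd,
              patient_sd = patient_sd, noise_sd = noise_sd,
              missing_rate = missing_rate, plateau_frac = plateau_frac,
              seed = as.integer(seed))
  class(cfg) <- "tofr_generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(inherits(cfg, "tofr_generator_config"))
  if (cfg$n_patients < 2L)
    stop("config error: n_patients must be >= 2 (pairwise and leave-one-out ",
         "experiments need at least two patients)")
  lr <- cfg$length_range
  if (length(lr) != 2L || any(lr < 1L) || lr[1] > lr[2])
    stop("config error: length_range must be positive integers low <= high")
  if (cfg$age_range[1] < 18 || cfg$age_range[2] > 75 ||
      cfg$age_range[1] > cfg$age_range[2])
    stop("config error: age_range must lie within [18, 75]")
  if (cfg$bmi_range[2] > 35 || cfg$bmi_range[1] >= cfg$bmi_range[2])
    stop("config error: bmi_range must be increasing with upper bound <= 35")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 0.5)
    stop("config error: missing_rate must be in [0, 0.5)")
  if (cfg$noise_sd < 0) stop("config error: noise_sd must be >= 0")
  if (cfg$slope_base <= 0) stop("config error: slope_base must be > 0")
  if (cfg$plateau_frac <= 0.9 || cfg$plateau_frac >= 1)
    stop("config error: plateau_frac must be in (0.9, 1)")
  dr <- cfg$duration_ratio_range
  if (length(dr) != 2L || dr[1] <= 0 || dr[1] > dr[2])
    stop("config error: duration_ratio_range must be positive and increasing")
  er <- cfg$end_value_range
  if (er[1] < 90 || er[2] > 100 || er[1] > er[2])
    stop("config error: end_value_range must lie within [90, 100]")
  invisible(cfg)
}

#' Strong-covariate generator preset for transfer experiments
#'
#' A generator configuration in which demographics dominate the recovery
#' dynamics: large age/BMI effects on both recovery timing and steepness,
#' small patient-level random effects, and modest observation noise.  This
#' is the regime in which donor selection by patient similarity should
#' visibly beat a randomly chosen donor, and it is used by the pairwise and
#' leave-one-out transfer experiments.
#'
#' @param n_patients cohort size (default 40).
#' @param seed master seed.
#' @param ... further overrides passed to [generator_config()].
#' @return a `tofr_generator_config`.
#' @export
strong_effect_config <- function(n_patients = 40, seed = 1L, ...) {
  preset <- list(n_patients = n_patients, seed = seed,
                 beta_age = 0.5, beta_bmi = 0.5,
                 gamma_age = 0.015, gamma_bmi = 0.025,
                 patient_sd = 0.5, slope_sd = 0.02,
                 noise_sd = 1.0, missing_rate = 0.02)
  do.call(generator_config, utils::modifyList(preset, list(...)))
}

#' Logistic block-to-recovery curve
#'
#' The latent noiseless TOFR trajectory: a logistic sigmoid rising from deep
#' block (0) to a plateau `t_max`, with half-maximal recovery at `t50`
#' minutes and steepness `slope` minutes.
#'
#' @param t time in minutes (vectorized).
#' @param params list with elements `t50`, `slope` (> 0) and `t_max`
#'   (in (0, 110]).
#' @return TOFR percent at each `t`; nondecreasing in `t`.
#' @export
tofr_curve <- function(t, params) {
  stopifnot(params$slope > 0, params$t_max > 0, params$t_max <= 110)
  params$t_max / (1 + exp(-(t - params$t50) / params$slope))
}

#' Solve for the recovery midpoint given an end-of-record value
#'
#' Inverts the logistic curve: returns the `t50` for which the curve passes
#' exactly through `end_value` at `end_time`, i.e.
#' `t50 = end_time + slope * log(t_max / end_value - 1)`.  Used to construct
#' synthetic patients that satisfy the end-of-record TOFR >= 90 rule exactly.
#'
#' @param end_time time of the final sample, minutes.
#' @param end_value target TOFR at `end_time`; must be in (0, `t_max`).
#' @param slope sigmoid steepness, minutes.
#' @param t_max curve plateau.
#' @return `t50` in minutes.
#' @export
solve_t50 <- function(end_time, end_value, slope, t_max = 100) {
  if (end_value <= 0 || end_value >= t_max)
    stop("domain error: end_value must lie strictly between 0 and t_max")
  end_time + slope * log(t_max / end_value - 1)
}

#' TOFR series constructor
#'
#' A TOFR temporal sequence on the 15-second sampling grid with a parallel
#' missingness mask.  Unobserved points carry `NA` values.
#'
#' @param values numeric TOFR percent; `NA` where unobserved.
#' @param observed logical mask, same length as `values`; defaults to
#'   `!is.na(values)`.
#' @return a `tofr_series` object.
#' @export
tofr_series <- function(values, observed = !is.na(values)) {
  stopifnot(length(values) == length(observed), is.logical(observed))
  v <- as.numeric(values)
  if (any(observed & (!is.finite(v) | v < 0)))
    stop("observed TOFR values must be finite and >= 0")
  v[!observed] <- NA_real_
  structure(list(values = v, observed = observed),
            class = "tofr_series")
}

#' @export
length.tofr_series <- function(x) length(x$values)

#' @export
print.tofr_series <- function(x, ...) {
  n <- length(x)
  cat(sprintf("<tofr_series> n = %d (%d observed), last = %.1f\n",
              n, sum(x$observed), x$values[n]))
  invisible(x)
}

# Latent curve + record geometry for one patient.  The demographic terms
# act on the recovery steepness (multiplicatively, via slope) and on the
# recovery timing (additively, via the recovery-completion time), BEFORE
# any clamping, so similar (age, bmi) implies similar dynamics.
#
# The record length is derived from the recovery duration rather than drawn
# independently: the TOFR is only measurable once twitch responses return,
# and monitoring stops shortly after recovery is attained, so slower
# recoveries produce longer records.  rho = record duration / slope is drawn
# so that the first half of the record reaches past the sigmoid inflection
# (the regime in which one-step dynamics are learnable from the training
# half); the result is clamped into length_range and the end value then
# re-anchored so the noiseless end-of-record TOFR stays >= 90.
patient_curve_params <- function(cfg, age, bmi, slope_z, end_target, rho,
                                 t50_z, n_fixed = NULL) {
  slope <- cfg$slope_base * exp(cfg$gamma_age * (age - 50) +
                                cfg$gamma_bmi * (bmi - 25) + slope_z)
  t_max <- end_target / cfg$plateau_frac
  # time at which the curve reaches plateau_frac * t_max = end_target
  t_rec <- rho * slope + cfg$beta_age * (age - 50) +
    cfg$beta_bmi * (bmi - 25) + t50_z
  t50 <- t_rec + slope * log(1 / cfg$plateau_frac - 1)
  if (is.null(n_fixed)) {
    n <- round(rho * slope * 60 / cfg$sample_interval) + 1
    n <- as.integer(min(max(n, cfg$length_range[1]), cfg$length_range[2]))
  } else {
    n <- as.integer(n_fixed)
  }
  duration <- (n - 1) * cfg$sample_interval / 60
  # The record is anchored at its END: the TOFR is only measurable once
  # twitch responses return, so when the deep block outlasts the recording
  # window the record opens mid-block rather than at injection.  When the
  # length was clamped upwards (fast recoveries), the extra duration pads
  # FORWARD past recovery (monitoring continues until surgery ends), never
  # backwards into the unmeasurable deep block.
  t_start <- max(0, t_rec - min(duration, rho * slope))
  end_time <- t_start + duration
  # clamp so the noiseless end-of-record value stays >= 90
  t50 <- min(t50, solve_t50(end_time, 90, slope, t_max))
  list(t50 = t50, slope = slope, t_max = t_max, n = n, t_start = t_start)
}

#' Generate one synthetic patient
#'
#' Draws demographics and a series length, builds the latent recovery curve
#' (timing and steepness modulated by age and BMI), adds observation noise,
#' and applies sporadic missingness.  The noiseless curve at the final
#' sample is at least 90 by construction, and the final sample is always
#' observed.
#'
#' @param config a [generator_config()].
#' @param patient_id identifier string.
#' @param seed integer seed for this patient (defaults to a seed derived
#'   from the config master seed and the id).
#' @param age,bmi,n optional fixed values overriding the random draws —
#'   useful for constructing patients with prescribed demographics.
#' @return a `tofr_patient` record: `patient_id`, `age`, `bmi`, `series`,
#'   plus the latent `curve` parameters (for diagnostics; models never see
#'   them).
#' @export
generate_patient <- function(config, patient_id = "p001",
                             seed = derive_seed(config$seed, "patient",
                                                patient_id),
                             age = NULL, bmi = NULL, n = NULL) {
  validate_generator_config(config)
  with_seed(seed, {
    a <- runif(1, config$age_range[1], config$age_range[2])
    b <- runif(1, config$bmi_range[1], config$bmi_range[2])
    if (!is.null(age)) a <- age
    if (!is.null(bmi)) b <- bmi
    slope_z <- rnorm(1, 0, config$slope_sd)
    end_target <- runif(1, config$end_value_range[1], config$end_value_range[2])
    rho <- runif(1, config$duration_ratio_range[1],
                 config$duration_ratio_range[2])
    t50_z <- rnorm(1, 0, config$patient_sd)
    pars <- patient_curve_params(config, a, b, slope_z, end_target, rho,
                                 t50_z, n_fixed = n)
    len <- pars$n
    tmin <- pars$t_start + (seq_len(len) - 1) * config$sample_interval / 60
    clean <- tofr_curve(tmin, pars)
    vals <- pmax(0, clean + rnorm(len, 0, config$noise_sd))
    obs <- runif(len) >= config$missing_rate
    obs[len] <- TRUE
    vals[!obs] <- NA_real_
    structure(list(patient_id = patient_id, age = a, bmi = b,
                   series = tofr_series(vals, obs), curve = pars),
              class = "tofr_patient")
  })
}

#' Generate a synthetic cohort
#'
#' @param config a [generator_config()].
#' @return a `tofr_cohort`: list of `tofr_patient` records with ids
#'   `p001`, `p002`, ...; fully reproducible from `config$seed`.
#' @export
generate_cohort <- function(config = generator_config()) {
  validate_generator_config(config)
  ids <- sprintf("p%03d", seq_len(config$n_patients))
  patients <- lapply(ids, function(id) generate_patient(config, id))
  names(patients) <- ids
  structure(patients, class = "tofr_cohort", config = config)
}

#' @export
print.tofr_cohort <- function(x, ...) {
  lens <- vapply(x, function(p) length(p$series), integer(1))
  cat(sprintf("<tofr_cohort> %d patients, series lengths %d-%d\n",
              length(x), min(lens), max(lens)))
  invisible(x)
}

#' Demographics table of a cohort
#'
#' @param cohort a `tofr_cohort` or list of `tofr_patient` records.
#' @return a data.frame with columns `patient_id`, `age_years`, `bmi`.
#' @export
cohort_demographics <- function(cohort) {
  data.frame(patient_id = vapply(cohort, `[[`, "", "patient_id"),
             age_years = vapply(cohort, `[[`, 0, "age"),
             bmi = vapply(cohort, `[[`, 0, "bmi"),
             row.names = NULL)
}
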