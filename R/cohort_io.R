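#' Write a cohort to the two-file CSV layout
#'
#' Demographics file: `patient_id,age_years,bmi`, one row per patient.
#' Series file (long format): `patient_id,t_index,tofr,observed` with
#' 0-based `t_index`; missing samples are written with an empty `tofr`
#' field and `observed = 0`.
#'
#' @param cohort a `tofr_cohort` or list of `tofr_patient` records.
#' @param demographics_path,series_path output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_cohort <- function(cohort, demographics_path, series_path) {
  demo <- cohort_demographics(cohort)
  series <- do.call(rbind, lapply(cohort, function(p) {
    s <- p$series
    data.frame(patient_id = p$patient_id,
               t_index = seq_along(s$values) - 1L,
               tofr = s$values,
               observed = as.integer(s$observed))
  }))
  write.csv(demo, demographics_path, row.names = FALSE, quote = FALSE, na = "")
  write.csv(series, series_path, row.names = FALSE, quote = FALSE, na = "")
  invisible(c(demographics_path, series_path))
}

#' Read a cohort from the two-file CSV layout
#'
#' Joins the demographics and long-format series tables on `patient_id`,
#' ordering each series by `t_index`.  Rows with an empty `tofr` field or
#' `observed = 0` become missing-masked points.
#'
#' @param demographics_path,series_path input CSV paths (layout as in
#'   [write_cohort()]).
#' @return a `tofr_cohort`.
#' @export
read_cohort <- function(demographics_path, series_path) {
  demo <- read.csv(demographics_path, colClasses = "character")
  ser <- read.csv(series_path, colClasses = "character")
  need_d <- c("patient_id", "age_years", "bmi")
  need_s <- c("patient_id", "t_index", "tofr", "observed")
  if (!all(need_d %in% names(demo)))
    stop("schema error: demographics file must have columns ",
         paste(need_d, collapse = ", "))
  if (!all(need_s %in% names(ser)))
    stop("schema error: series file must have columns ",
         paste(need_s, collapse = ", "))
  age <- suppressWarnings(as.numeric(demo$age_years))
  bmi <- suppressWarnings(as.numeric(demo$bmi))
  if (anyNA(age) || anyNA(bmi))
    stop("parse error: non-numeric age_years or bmi in demographics file")
  orphans <- setdiff(unique(ser$patient_id), demo$patient_id)
  if (length(orphans))
    stop("schema error: series rows reference unknown patient_id: ",
         paste(orphans, collapse = ", "))
  if (anyDuplicated(ser[c("patient_id", "t_index")]))
    stop("schema error: duplicate (patient_id, t_index) rows in series file")
  patients <- lapply(seq_len(nrow(demo)), function(k) {
    id <- demo$patient_id[k]
    rows <- ser[ser$patient_id == id, , drop = FALSE]
    if (nrow(rows) == 0)
      stop("schema error: patient ", id, " has no series points")
    rows <- rows[order(as.integer(rows$t_index)), , drop = FALSE]
    vals <- suppressWarnings(as.numeric(rows$tofr))
    obs <- as.integer(rows$observed) == 1L & !is.na(vals)
    vals[!obs] <- NA_real_
    structure(list(patient_id = id, age = age[k], bmi = bmi[k],
                   series = tofr_series(vals, obs)),
              class = "tofr_patient")
  })
  names(patients) <- demo$patient_id
  structure(patients, class = "tofr_cohort")
}

#' Write an experiment report to JSON
#'
#' Full-precision JSON with top-level keys `experiment`, `model_kind`,
#' `config_echo`, `seeds`, `per_patient_rmse`, `group_stats`, `comparison`
#' and `skipped`.  No timestamps or hostnames, so identical runs produce
#' byte-identical files.
#'
#' @param report a `tofr_report`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_report <- function(report, path) {
  payload <- list(
    experiment = report$experiment,
    model_kind = report$model_kind,
    config_echo = report$config_echo,
    seeds = report$seeds,
    per_patient_rmse = as.list(report$per_patient_rmse),
    group_stats = lapply(report$group_stats, as.list),
    comparison = report$comparison,
    skipped = report$skipped)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Run the full pipeline end to end
#'
#' Generates (or loads) a cohort, trains the shared per-patient predictors
#' for each requested model kind, runs the selected experiments, and writes
#' one report JSON per (experiment, kind) into the output directory.  The
#' master seed deterministically derives every stage seed, so two runs with
#' the same configuration produce byte-identical reports.
#'
#' @param generator a [generator_config()]; ignored when `cohort` is given.
#' @param cohort optional pre-built `tofr_cohort` (e.g. from
#'   [read_cohort()]).
#' @param kinds model kinds to evaluate.
#' @param experiments subset of `"per_patient"`, `"pairwise"`, `"loocv"`.
#' @param rule a [similarity_rule()].
#' @param n_random_draws random donors per held-out patient in the
#'   leave-one-out experiment.
#' @param out_dir output directory, created if absent.
#' @param master_seed master seed.
#' @param spec_template a [model_spec()] whose kind and seed are overridden
#'   per run; use it to change hyperparameters globally.
#' @return named character vector of written report paths.
#' @export
run_all <- function(generator = generator_config(), cohort = NULL,
                    kinds = c("GRU", "RNN", "LSTM"),
                    experiments = c("per_patient", "pairwise", "loocv"),
                    rule = similarity_rule(), n_random_draws = 10,
                    out_dir = "results", master_seed = 1L,
                    spec_template = model_spec()) {
  experiments <- match.arg(experiments, several.ok = TRUE)
  if (is.null(cohort)) {
    generator$seed <- derive_seed(master_seed, "cohort")
    cohort <- generate_cohort(generator)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  out <- character(0)
  for (kind in kinds) {
    spec <- spec_template
    spec$kind <- kind
    spec$seed <- derive_seed(master_seed, "model", kind)
    predictors <- train_cohort_predictors(cohort, spec)
    for (exp in experiments) {
      report <- switch(exp,
        per_patient = run_per_patient(cohort, spec, predictors),
        pairwise = run_pairwise(cohort, spec, rule, predictors),
        loocv = run_loocv_transfer(cohort, spec, rule, n_random_draws,
                                   seed = derive_seed(master_seed, "loocv", kind),
                                   predictors = predictors))
      path <- file.path(out_dir, paste0(exp, "_", tolower(kind), ".json"))
      write_report(report, path)
      out[paste(exp, kind, sep = ":")] <- path
    }
  }
  out
}
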