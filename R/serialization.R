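#' Save trained predictors to a directory
#'
#' Writes one weight file per (donor, model kind) named
#' `<patient_id>.<kind>.model` (JSON at full precision) plus an
#' `index.json` mapping each donor id to its file and model
#' specification.
#'
#' @param predictors named list from [train_cohort_predictors()].
#' @param dir output directory, created if absent.
#' @return invisibly, the index path.
#' @export
save_predictors <- function(predictors, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  index <- list()
  for (id in names(predictors)) {
    pr <- predictors[[id]]
    fname <- paste0(id, ".", tolower(pr$spec$kind), ".model")
    payload <- list(params = lapply(pr$params, unclass),
                    increment_bounds = pr$increment_bounds,
                    loss_trace = pr$loss_trace)
    jsonlite::write_json(payload, file.path(dir, fname), digits = NA,
                         matrix = "rowmajor")
    index[[id]] <- list(file = fname, spec = unclass(pr$spec))
  }
  path <- file.path(dir, "index.json")
  jsonlite::write_json(index, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load trained predictors saved by [save_predictors()]
#'
#' @param dir directory containing `index.json` and the weight files.
#' @return named list of `tofr_predictor` objects.
#' @export
load_predictors <- function(dir) {
  index <- jsonlite::read_json(file.path(dir, "index.json"))
  out <- lapply(names(index), function(id) {
    entry <- index[[id]]
    payload <- jsonlite::read_json(file.path(dir, entry$file),
                                   simplifyVector = TRUE)
    spec <- entry$spec
    spec$kind <- match.arg(spec$kind, c("GRU", "RNN", "LSTM"))
    spec <- do.call(model_spec, spec)
    structure(list(spec = spec, donor_id = id,
                   params = lapply(payload$params, function(m)
                     if (is.matrix(m)) m else matrix(m, ncol = 1)),
                   increment_bounds = payload$increment_bounds,
                   loss_trace = payload$loss_trace),
              class = "tofr_predictor")
  })
  names(out) <- names(index)
  out
}

#' Read a generator configuration from a YAML or JSON file
#'
#' The file's keys mirror the [generator_config()] argument names exactly;
#' missing keys take the package defaults, unknown keys are an error.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a validated `tofr_generator_config`.
#' @export
read_generator_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(generator_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("config error: unknown generator fields: ",
         paste(unknown, collapse = ", "))
  do.call(generator_config, vals)
}
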