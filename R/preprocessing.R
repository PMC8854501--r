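#' Split a TOFR series into training and testing halves
#'
#' The first half of the sequence is the training part and the second half
#' the testing part.  For odd lengths the training part receives the extra
#' sample (`ceiling(n/2)`), favouring training data on the shortest records.
#'
#' @param series a [tofr_series()] with at least 10 samples.
#' @param train_frac fraction of the series assigned to training;
#'   default 0.5 (the half split).
#' @return a `tofr_split`: `train` (raw first part), `test` (raw second
#'   part), `split_index` (number of training samples).
#' @export
split_half <- function(series, train_frac = 0.5) {
  n <- length(series)
  if (n < 10) stop("series too short: need at least 10 samples, got ", n)
  k <- ceiling(n * train_frac)
  structure(list(
    train = tofr_series(series$values[1:k], series$observed[1:k]),
    test = tofr_series(series$values[(k + 1):n], series$observed[(k + 1):n]),
    split_index = k), class = "tofr_split")
}

#' Fill missing samples by linear interpolation
#'
#' Interior runs of missing samples are filled linearly between their
#' flanking observed values on the sample-index grid; leading or trailing
#' missing runs are filled with the nearest observed value.  Observed values
#' are never altered, and the result is fully observed.  This is applied to
#' the training part only — filling the testing part this way would use
#' future observations and break the real-time contract.
#'
#' @param series a [tofr_series()] with at least one observed value.
#' @return a fully observed `tofr_series`.
#' @export
interpolate_missing <- function(series) {
  obs <- which(series$observed)
  if (length(obs) == 0) stop("empty series: no observed values to interpolate from")
  n <- length(series)
  if (length(obs) == n) return(series)
  if (length(obs) == 1) {
    filled <- rep(series$values[obs], n)
  } else {
    filled <- approx(x = obs, y = series$values[obs], xout = seq_len(n),
                     method = "linear", rule = 2)$y
  }
  filled[obs] <- series$values[obs]
  tofr_series(filled, rep(TRUE, n))
}

#' Last-observation-carried-forward fill (causal)
#'
#' Replaces each missing sample with the most recent observed value at or
#' before it; a leading missing run is filled with the first observed value.
#' Unlike [interpolate_missing()], this never looks ahead, so it is the fill
#' used for model inputs in the testing part.
#'
#' @param values numeric vector with `NA` for missing samples.
#' @return numeric vector with no `NA`.
#' @export
locf_fill <- function(values) {
  obs <- which(!is.na(values))
  if (length(obs) == 0) stop("empty series: no observed values to fill from")
  idx <- findInterval(seq_along(values), obs)
  values[obs[pmax(idx, 1)]]
}

#' Build one-step supervised windows from a series
#'
#' Slides a window of `window_size` consecutive samples over a fully
#' observed series; each window is an input pattern and the following
#' sample its target.  Patterns are kept in temporal order.
#'
#' @param series a fully observed [tofr_series()].
#' @param window_size number of lagged inputs per pattern (default 4).
#' @return a `tofr_windows` object: `inputs` (matrix, one pattern per row),
#'   `targets` (numeric), `window_size`.
#' @export
make_windows <- function(series, window_size = 4L) {
  if (!all(series$observed))
    stop("make_windows requires a fully observed series; fill gaps first")
  n <- length(series)
  w <- as.integer(window_size)
  if (n <= w)
    stop("insufficient data: need more than ", w, " samples, got ", n)
  m <- n - w
  inputs <- vapply(seq_len(w), function(j) series$values[j:(j + m - 1)],
                   numeric(m))
  if (m == 1) inputs <- matrix(inputs, nrow = 1)
  structure(list(inputs = inputs, targets = series$values[(w + 1):n],
                 window_size = w), class = "tofr_windows")
}

#' Scale TOFR values to the unit range used for training
#'
#' Models are trained on TOFR divided by the constant 100 so that inputs
#' from every patient share one scale — a per-patient min-max scaling would
#' make cross-patient transfer meaningless.  Errors are always reported on
#' the original 0--100 scale.
#'
#' @param x TOFR percent values.
#' @return `x / 100`.
#' @export
scale_tofr <- function(x) x / 100

#' @rdname scale_tofr
#' @export
unscale_tofr <- function(x) x * 100
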