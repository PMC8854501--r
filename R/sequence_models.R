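KIND_CODES <- c(RNN = 0L, GRU = 1L, LSTM = 2L)

#' Specification of a one-step recurrent predictor
#'
#' A single recurrent layer (simple recurrent, gated recurrent unit, or
#' long short-term memory cell) with a linear output head read from the
#' last hidden state, trained with mean squared error and Adam.  Training
#' is fully deterministic given the seed: weight initialization and batch
#' shuffling come from an internal stream, never from R's global RNG.
#'
#' @param kind one of `"RNN"`, `"GRU"`, `"LSTM"`.
#' @param hidden_units recurrent layer width (default 16).
#' @param epochs training epochs (default 1000).
#' @param learning_rate base Adam step size (default 5e-3), decayed
#'   linearly over training.
#' @param batch_size minibatch size (default 16).
#' @param weight_decay decoupled L2 weight decay applied at each Adam step;
#'   regularizes against memorizing observation noise.
#' @param clip_increment clamp the predicted one-step change into the range
#'   of changes seen in training (widened by `clip_margin` times that
#'   range's span), on by default.  A one-step TOFR change is
#'   physiologically bounded; the clamp guards against extreme
#'   extrapolation errors when lag windows fall outside the value range the
#'   model was fitted on, and because the bounds come from the donor's own
#'   training changes a transferred model remains characteristic of its
#'   donor.
#' @param clip_margin fractional widening of the clamp range.
#' @param window_size number of lagged inputs (default 4).
#' @param seed integer seed controlling initialization and shuffling.
#' @return a `tofr_model_spec`.
#' @export
model_spec <- function(kind = c("GRU", "RNN", "LSTM"), hidden_units = 16L,
                       epochs = 1000L, learning_rate = 5e-3,
                       batch_size = 16L, window_size = 4L,
                       weight_decay = 0, clip_increment = TRUE,
                       clip_margin = 0.5, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(hidden_units >= 1, epochs >= 1, learning_rate > 0,
            batch_size >= 1, window_size >= 1, weight_decay >= 0)
  structure(list(kind = kind, hidden_units = as.integer(hidden_units),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 window_size = as.integer(window_size),
                 weight_decay = weight_decay,
                 clip_increment = isTRUE(clip_increment),
                 clip_margin = clip_margin,
                 seed = as.integer(seed)),
            class = "tofr_model_spec")
}

#' Train a one-step-ahead recurrent predictor
#'
#' Fits the recurrent cell named in `spec` to the supervised windows of one
#' patient's (scaled) training half.  The fitted weights are frozen: when a
#' predictor is transferred to another patient it is applied as-is, with no
#' retraining or fine-tuning.
#'
#' @param windows a [make_windows()] result on the scaled (0--~1.1) range.
#' @param spec a [model_spec()].
#' @param donor_id identifier of the patient the predictor was trained on.
#' @return a `tofr_predictor`: `spec`, `donor_id`, `params` (opaque weight
#'   list), `increment_bounds` (clamp on the predicted one-step change:
#'   the training change range widened by a 50% margin), `loss_trace`
#'   (per-epoch training MSE).
#' @export
train_predictor <- function(windows, spec, donor_id = NA_character_) {
  stopifnot(inherits(windows, "tofr_windows"), inherits(spec, "tofr_model_spec"))
  x <- windows$inputs
  if (is.null(dim(x)) || nrow(x) == 0)
    stop("insufficient data: no training windows")
  if (!all(is.finite(x)) || !all(is.finite(windows$targets)))
    stop("data error: training windows contain non-finite values")
  if (ncol(x) != spec$window_size)
    stop("shape error: windows have ", ncol(x), " lags but spec expects ",
         spec$window_size)
  fit <- cpp_train_recurrent(x, windows$targets, KIND_CODES[[spec$kind]],
                             spec$hidden_units, spec$epochs,
                             spec$learning_rate, spec$batch_size,
                             as.double(spec$seed),
                             if (is.null(spec$weight_decay)) 0 else spec$weight_decay)
  # physiologic bound on the predicted one-step change: the training set's
  # observed change range plus a 50% margin.  Keeps the predictor sane when
  # lag windows fall outside the value range it was fitted on.
  d <- windows$targets - x[, ncol(x)]
  m <- if (is.null(spec$clip_margin)) 0.5 else spec$clip_margin
  span <- max(d) - min(d)
  bounds <- c(min(d) - m * span - 1e-9, max(d) + m * span + 1e-9)
  structure(list(spec = spec, donor_id = donor_id, params = fit$params,
                 increment_bounds = bounds,
                 loss_trace = as.numeric(fit$loss_trace)),
            class = "tofr_predictor")
}

#' @export
print.tofr_predictor <- function(x, ...) {
  cat(sprintf("<tofr_predictor> %s(%d) donor=%s, final loss %.3g\n",
              x$spec$kind, x$spec$hidden_units, x$donor_id,
              x$loss_trace[length(x$loss_trace)]))
  invisible(x)
}

#' Predict the next scaled TOFR value from a lag window
#'
#' A pure function of the frozen weights and the lag vector.
#'
#' @param predictor a [train_predictor()] result.
#' @param lags numeric vector (or matrix, one window per row) of
#'   `window_size` scaled lags.
#' @return predicted scaled value(s).
#' @export
predict_one_step <- function(predictor, lags) {
  if (!inherits(predictor, "tofr_predictor") || is.null(predictor$params))
    stop("usage error: 'predictor' must be a trained tofr_predictor")
  x <- if (is.matrix(lags)) lags else matrix(lags, nrow = 1)
  if (ncol(x) != predictor$spec$window_size)
    stop("shape error: expected ", predictor$spec$window_size,
         " lags, got ", ncol(x))
  if (!all(is.finite(x))) stop("data error: lags must be finite")
  raw <- as.numeric(cpp_predict_recurrent(predictor$params,
                                          KIND_CODES[[predictor$spec$kind]], x))
  if (!isTRUE(predictor$spec$clip_increment)) return(raw)
  b <- predictor$increment_bounds
  last <- x[, ncol(x)]
  last + pmin(pmax(raw - last, b[1]), b[2])
}

# Lag source for walk-forward forecasting of the test half: the training
# part gap-filled by linear interpolation (as used in training) followed by
# the test part filled causally (last observation carried forward, seeded
# with the last observed training value).  Never looks ahead of t - 1.
lag_source <- function(split) {
  train_filled <- interpolate_missing(split$train)$values
  test_vals <- split$test$values
  full <- c(train_filled, test_vals)
  locf_fill(full)
}

#' Walk-forward one-step forecast of the testing half
#'
#' For every test index the predictor receives the `window_size` most recent
#' causally filled values ending one step earlier (the first test points
#' take their lags from the end of the training part) and emits one
#' prediction.  The walk is re-anchored on observations at every step —
#' never recursive — which is the real-time mode of the method.
#'
#' @param predictor a trained `tofr_predictor`.
#' @param split a [split_half()] result.
#' @return a data.frame with `t_index` (0-based global sample index),
#'   `observed` (raw test value, `NA` where missing) and `predicted`
#'   (unscaled TOFR).
#' @export
forecast_test_half <- function(predictor, split) {
  stopifnot(inherits(split, "tofr_split"))
  w <- predictor$spec$window_size
  k <- split$split_index
  L <- length(split$test)
  if (L < 1) stop("test half is empty")
  if (k < w) stop("training part shorter than the lag window")
  src <- scale_tofr(lag_source(split))
  lagmat <- vapply(seq_len(w), function(j) src[(k - w + j - 1) + seq_len(L)],
                   numeric(L))
  if (L == 1) lagmat <- matrix(lagmat, nrow = 1)
  pred <- unscale_tofr(predict_one_step(predictor, lagmat))
  data.frame(t_index = (k:(k + L - 1)), observed = split$test$values,
             predicted = pred)
}

#' Persistence baseline forecast
#'
#' Predicts each test value by the previous causally filled value — the
#' naive sanity floor every sequence model must beat on smooth series.
#'
#' @param split a [split_half()] result.
#' @return same shape as [forecast_test_half()].
#' @export
baseline_persistence <- function(split) {
  stopifnot(inherits(split, "tofr_split"))
  k <- split$split_index
  L <- length(split$test)
  if (L < 1) stop("test half is empty")
  src <- lag_source(split)
  data.frame(t_index = (k:(k + L - 1)), observed = split$test$values,
             predicted = src[k:(k + L - 1)])
}

#' RMSE of a forecast table on its observed targets
#'
#' @param forecast a data.frame from [forecast_test_half()] or
#'   [baseline_persistence()].
#' @return RMSE on the 0--100 TOFR scale, over observed targets only.
#' @export
forecast_rmse <- function(forecast) {
  keep <- !is.na(forecast$observed)
  rmse(forecast$observed[keep], forecast$predicted[keep])
}

# Full per-patient pipeline from a raw series to a trained predictor:
# split -> interpolate the training part -> scale -> window -> train.
fit_patient_predictor <- function(patient, spec) {
  split <- split_half(patient$series)
  train <- interpolate_missing(split$train)
  train$values <- scale_tofr(train$values)
  w <- make_windows(train, spec$window_size)
  spec$seed <- derive_seed(spec$seed, "train", patient$patient_id)
  train_predictor(w, spec, donor_id = patient$patient_id)
}

#' Train one predictor per cohort patient
#'
#' Fits the model named in `spec` on each patient's training half (gap-filled
#' and scaled).  Each patient's training seed is derived from `spec$seed`
#' and the patient id, so cohort training is reproducible yet no two
#' patients share an initialization.  These shared pre-trained predictors
#' are reused across the per-patient, pairwise, and leave-one-out
#' experiments.
#'
#' @param cohort a `tofr_cohort` or list of `tofr_patient` records.
#' @param spec a [model_spec()].
#' @return named list of `tofr_predictor` objects.
#' @export
train_cohort_predictors <- function(cohort, spec) {
  preds <- lapply(cohort, fit_patient_predictor, spec = spec)
  names(preds) <- vapply(cohort, `[[`, "", "patient_id")
  preds
}
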