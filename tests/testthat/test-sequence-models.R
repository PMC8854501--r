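test_that("a predictor trained on a constant series predicts that constant", {
  w <- make_windows(tofr_series(rep(0.5, 34)))
  for (kind in c("RNN", "GRU", "LSTM")) {
    pr <- train_predictor(w, model_spec(kind, seed = 3))
    expect_lt(abs(predict_one_step(pr, rep(0.5, 4)) - 0.5), 0.02)
  }
})

test_that("training is deterministic given windows and spec", {
  p <- generate_patient(generator_config(seed = 13), "p001")
  sp <- split_half(p$series)
  spec <- tiny_spec(seed = 7)
  pr1 <- tofrcast:::fit_patient_predictor(p, spec)
  pr2 <- tofrcast:::fit_patient_predictor(p, spec)
  f1 <- forecast_test_half(pr1, sp)
  f2 <- forecast_test_half(pr2, sp)
  expect_lt(max(abs(f1$predicted - f2$predicted)), 1e-6)
  # and a different seed gives a different fit
  spec2 <- tiny_spec(seed = 8)
  pr3 <- tofrcast:::fit_patient_predictor(p, spec2)
  expect_false(identical(pr1$params, pr3$params))
})

test_that("training reduces the loss and records a finite trace", {
  w <- make_windows(sigmoid_series(80))
  w$inputs <- scale_tofr(w$inputs); w$targets <- scale_tofr(w$targets)
  for (kind in c("RNN", "GRU", "LSTM")) {
    pr <- train_predictor(w, model_spec(kind, hidden_units = 8, epochs = 100,
                                        seed = 2))
    expect_true(all(is.finite(pr$loss_trace)))
    expect_lte(pr$loss_trace[length(pr$loss_trace)], pr$loss_trace[1])
  }
})

test_that("prediction is a pure function with strict shape checks", {
  w <- make_windows(tofr_series(seq(0.1, 0.9, length.out = 30)))
  pr <- train_predictor(w, tiny_spec())
  lags <- c(0.2, 0.3, 0.4, 0.5)
  expect_identical(predict_one_step(pr, lags), predict_one_step(pr, lags))
  expect_true(is.finite(predict_one_step(pr, c(0, 0, 0, 0))))
  expect_error(predict_one_step(pr, c(0.1, 0.2)), "shape")
  expect_error(predict_one_step(pr, c(0.1, NA, 0.2, 0.3)), "finite")
  expect_error(predict_one_step(structure(list(), class = "tofr_predictor"),
                                lags), "usage")
  expect_error(train_predictor(structure(list(inputs = matrix(numeric(0), 0, 4),
                                              targets = numeric(0),
                                              window_size = 4L),
                                         class = "tofr_windows"),
                               tiny_spec()), "insufficient")
})

test_that("walk-forward forecasting covers every test index and spans the boundary", {
  s <- sigmoid_series(120)
  sp <- split_half(s)
  pr <- tofrcast:::fit_patient_predictor(
    make_patient("d", 50, 25, s$values), tiny_spec())
  fc <- forecast_test_half(pr, sp)
  expect_equal(nrow(fc), length(sp$test))
  expect_equal(fc$t_index, sp$split_index:(length(s) - 1))
  # first test prediction uses the last 4 training samples as lags
  lags <- scale_tofr(sp$train$values[(sp$split_index - 3):sp$split_index])
  expect_equal(fc$predicted[1], unscale_tofr(predict_one_step(pr, lags)),
               tolerance = 1e-12)
})

test_that("forecasts are causal: later observations never change earlier predictions", {
  s <- sigmoid_series(120)
  pr <- tofrcast:::fit_patient_predictor(
    make_patient("d", 50, 25, s$values), tiny_spec())
  sp <- split_half(s)
  base <- forecast_test_half(pr, sp)
  j <- 30  # perturb the j-th test sample
  s2 <- s; s2$values[sp$split_index + j] <- s2$values[sp$split_index + j] + 25
  fc2 <- forecast_test_half(pr, split_half(s2))
  expect_equal(fc2$predicted[1:j], base$predicted[1:j], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(fc2$predicted[j + 1], base$predicted[j + 1])))
})

test_that("persistence predicts the previous observed value", {
  const <- tofr_series(rep(70, 40))
  expect_equal(forecast_rmse(baseline_persistence(split_half(const))), 0)
  inc <- tofr_series(seq(10, 88, by = 2))
  fc <- baseline_persistence(split_half(inc))
  expect_true(all(fc$predicted < fc$observed))  # under-predicts a rising series
  expect_equal(fc$predicted[nrow(fc)], inc$values[length(inc) - 1])
})

test_that("every model kind beats persistence on a noiseless recovery curve", {
  p <- generate_patient(generator_config(noise_sd = 0, missing_rate = 0,
                                         seed = 31), "p001")
  sp <- split_half(p$series)
  r_persist <- forecast_rmse(baseline_persistence(sp))
  for (kind in c("RNN", "GRU", "LSTM")) {
    pr <- tofrcast:::fit_patient_predictor(p, model_spec(kind, seed = 5))
    expect_lt(forecast_rmse(forecast_test_half(pr, sp)), r_persist)
  }
})

test_that("missing test values are causally filled for lags and excluded from RMSE", {
  s <- sigmoid_series(120)
  k <- split_half(s)$split_index
  s$values[c(k + 10, k + 11)] <- NA
  s$observed[c(k + 10, k + 11)] <- FALSE
  sp <- split_half(s)
  fc <- baseline_persistence(sp)
  expect_equal(nrow(fc), length(sp$test))
  expect_true(all(is.na(fc$observed[c(10, 11)])))
  # the prediction after the gap uses the last observed value, not NA
  expect_equal(fc$predicted[12], s$values[k + 9])
  expect_true(is.finite(forecast_rmse(fc)))
})
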