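# Shared fixtures, built in code.

# a patient record with prescribed demographics (and optionally a series)
make_patient <- function(id, age, bmi, values = NULL) {
  structure(list(patient_id = id, age = age, bmi = bmi,
                 series = if (!is.null(values)) tofr_series(values)),
            class = "tofr_patient")
}

# a clean logistic recovery series (no noise, fully observed)
sigmoid_series <- function(n = 120, t50 = 10, slope = 3, t_max = 95) {
  t <- (seq_len(n) - 1) * 15 / 60
  tofr_series(tofr_curve(t, list(t50 = t50, slope = slope, t_max = t_max)))
}

# independent brute-force donor selection: sort every candidate by the full
# tie-break key and take the head
brute_force_most_similar <- function(target, candidates, rule) {
  ids <- vapply(candidates, `[[`, "", "patient_id")
  dage <- abs(vapply(candidates, `[[`, 0, "age") - target$age)
  dbmi <- abs(vapply(candidates, `[[`, 0, "bmi") - target$bmi)
  inw <- dage <= rule$age_window
  if (any(inw)) {
    k <- which(inw)[order(dbmi[inw], dage[inw], ids[inw])[1]]
  } else {
    k <- order(dage, dbmi, ids)[1]
  }
  ids[k]
}

# small, fast model spec for harness-logic tests (model quality irrelevant)
tiny_spec <- function(kind = "GRU", seed = 1L) {
  model_spec(kind, hidden_units = 8, epochs = 40, seed = seed)
}

# generator limit in which demographics fully determine the series
deterministic_config <- function(...) {
  generator_config(noise_sd = 0, patient_sd = 0, slope_sd = 0,
                   missing_rate = 0, end_value_range = c(95, 95),
                   duration_ratio_range = c(8.5, 8.5), ...)
}

# noiseless final value of a generated patient's latent curve (the sample
# grid opens at the record's start time, not necessarily at injection)
noiseless_final <- function(p) {
  tofr_curve(p$curve$t_start + (length(p$series) - 1) * 15 / 60, p$curve)
}
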