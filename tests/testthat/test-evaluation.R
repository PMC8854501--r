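test_that("rmse matches hand evaluation and a brute-force loop", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  expect_equal(rmse(c(90, 92, 95), c(91, 91, 96)), 1)
  expect_error(rmse(1:3, 1:4), "mismatch")
  expect_error(rmse(numeric(0), numeric(0)), "zero")
  expect_error(rmse(c(1, NA), c(1, 2)), "finite")
  set.seed(7)
  for (k in 1:200) {
    n <- sample(1:50, 1)
    o <- runif(n, 0, 100); p <- runif(n, 0, 100)
    brute <- 0
    for (j in seq_len(n)) brute <- brute + (o[j] - p[j])^2
    expect_equal(rmse(o, p), sqrt(brute / n), tolerance = 1e-12)
    # scale equivariance
    expect_equal(rmse(3 * o, 3 * p), 3 * rmse(o, p), tolerance = 1e-12)
  }
})

test_that("the t-test reproduces the Welch statistic and handles degeneracy", {
  r <- welch_t_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$t_statistic, -1.224745, tolerance = 1e-6)
  expect_equal(r$p_value, 0.2878641, tolerance = 1e-6)
  same <- welch_t_test(c(1, 5, 9), c(1, 5, 9))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  const <- welch_t_test(c(2, 2), c(2, 2))
  expect_equal(const$t_statistic, 0)
  expect_equal(const$p_value, 1)
  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
  # cross-check against the stats implementation on random groups
  set.seed(11)
  for (k in 1:50) {
    a <- rnorm(sample(3:20, 1)); b <- rnorm(sample(3:20, 1), 0.3)
    ref <- stats::t.test(a, b)
    got <- welch_t_test(a, b)
    expect_equal(got$t_statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
    refs <- stats::t.test(a, b, var.equal = TRUE)
    gots <- welch_t_test(a, b, var_equal = TRUE)
    expect_equal(gots$p_value, refs$p.value, tolerance = 1e-10)
  }
})

test_that("the per-patient experiment is internally consistent and deterministic", {
  coh <- generate_cohort(generator_config(n_patients = 4, seed = 51))
  spec <- tiny_spec(seed = 2)
  r1 <- run_per_patient(coh, spec)
  expect_length(r1$per_patient_rmse, 4)
  expect_true(all(r1$per_patient_rmse >= 0))
  expect_equal(unname(r1$group_stats$all["mean"]),
               mean(r1$per_patient_rmse), tolerance = 1e-12)
  expect_equal(unname(r1$group_stats$all["n"]), 4)
  r2 <- run_per_patient(coh, spec)
  expect_identical(r1$per_patient_rmse, r2$per_patient_rmse)
  # single-patient report has sd 0 by convention
  one <- run_per_patient(coh[1], spec)
  expect_equal(unname(one$group_stats$all["sd"]), 0)
  # persistence baseline shares the report shape
  rp <- run_per_patient(coh, "persistence")
  expect_equal(rp$model_kind, "persistence")
  expect_length(rp$per_patient_rmse, 4)
})

test_that("the pairwise experiment evaluates all ordered pairs and compares groups", {
  coh <- generate_cohort(strong_effect_config(n_patients = 5, seed = 61))
  spec <- tiny_spec(seed = 3)
  rep <- suppressWarnings(run_pairwise(coh, spec))
  expect_equal(nrow(rep$pairs), 5 * 4)
  expect_true(all(rep$pairs$target_id != rep$pairs$donor_id))
  ns <- vapply(rep$group_stats, function(s) unname(s["n"]), 0)
  expect_equal(sum(ns), 20)
  if (!is.null(rep$comparison))
    expect_true(rep$comparison$p_value >= 0 && rep$comparison$p_value <= 1)
  # unordered variant halves the table
  rep_u <- suppressWarnings(run_pairwise(coh, spec, ordered = FALSE))
  expect_equal(nrow(rep_u$pairs), 10)
})

test_that("a cohort of clones makes both transfer arms identical", {
  cfg <- deterministic_config(n_patients = 3, seed = 71)
  clones <- lapply(c("p1", "p2", "p3"), function(id)
    generate_patient(cfg, id, seed = 500, age = 45, bmi = 26))
  names(clones) <- c("p1", "p2", "p3")
  clones <- structure(clones, class = "tofr_cohort")
  spec <- tiny_spec(seed = 4)
  shared <- train_predictor(make_windows(tofr_series(
    scale_tofr(interpolate_missing(split_half(clones$p1$series)$train)$values))),
    spec, donor_id = "shared")
  preds <- list(p1 = shared, p2 = shared, p3 = shared)
  rep <- suppressWarnings(
    run_loocv_transfer(clones, spec, n_random_draws = 3, seed = 5,
                       predictors = preds))
  expect_equal(rep$arms$rmse_similarity, rep$arms$rmse_random,
               tolerance = 1e-12)
})

test_that("leave-one-out similarity entries equal the pairwise table entries", {
  coh <- generate_cohort(strong_effect_config(n_patients = 5, seed = 81))
  spec <- tiny_spec(seed = 6)
  preds <- train_cohort_predictors(coh, spec)
  pw <- suppressWarnings(run_pairwise(coh, spec, predictors = preds))
  lo <- suppressWarnings(
    run_loocv_transfer(coh, spec, n_random_draws = 2, seed = 7,
                       predictors = preds))
  for (k in seq_len(nrow(lo$arms))) {
    row <- lo$arms[k, ]
    pair_rmse <- pw$pairs$rmse[pw$pairs$target_id == row$patient_id &
                               pw$pairs$donor_id == row$similar_donor]
    expect_equal(row$rmse_similarity, pair_rmse, tolerance = 1e-12)
  }
  # the random arm is reproducible under the same seed
  lo2 <- suppressWarnings(
    run_loocv_transfer(coh, spec, n_random_draws = 2, seed = 7,
                       predictors = preds))
  expect_identical(lo$arms$rmse_random, lo2$arms$rmse_random)
})
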