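test_that("logistic recovery curve has the right midpoint, limits and shape", {
  p <- list(t50 = 20, slope = 3, t_max = 100)
  expect_equal(tofr_curve(20, p), 50)
  expect_equal(tofr_curve(-1e6, p), 0, tolerance = 1e-12)
  expect_equal(tofr_curve(1e6, p), 100)
  # analytic 90% point: t = t50 + slope * log(9)
  expect_equal(tofr_curve(20 + 3 * log(9), p), 90, tolerance = 1e-9)
  # nondecreasing over a dense grid for assorted parameter sets
  for (s in c(0.5, 2, 6)) for (tm in c(91, 100, 105)) {
    v <- tofr_curve(seq(-10, 80, by = 0.1), list(t50 = 17, slope = s, t_max = tm))
    expect_true(all(diff(v) >= 0))
  }
})

test_that("t50 inversion hits the requested end value exactly", {
  expect_equal(solve_t50(40, 50, 3, 100), 40)
  t50 <- solve_t50(40, 90, 3, 100)
  expect_equal(t50, 40 - 3 * log(9), tolerance = 1e-12)
  expect_equal(tofr_curve(40, list(t50 = t50, slope = 3, t_max = 100)), 90,
               tolerance = 1e-9)
  expect_error(solve_t50(40, 100, 3, 100), "domain")
  expect_error(solve_t50(40, 0, 3, 100), "domain")
})

test_that("patient generation is seed-deterministic and honours missing_rate", {
  cfg <- generator_config(missing_rate = 0, seed = 3)
  p1 <- generate_patient(cfg, "p001")
  p2 <- generate_patient(cfg, "p001")
  expect_identical(p1, p2)
  expect_true(all(p1$series$observed))
  cfg2 <- generator_config(missing_rate = 0.2, seed = 3)
  p3 <- generate_patient(cfg2, "p001")
  expect_false(all(p3$series$observed))
  expect_true(p3$series$observed[length(p3$series)])  # final always observed
  expect_true(all(is.na(p3$series$values[!p3$series$observed])))
})

test_that("the noiseless end-of-record value respects the >= 90 rule", {
  cfg <- deterministic_config(seed = 5)
  p <- generate_patient(cfg, "p001")
  fin <- noiseless_final(p)
  expect_gte(fin, 90)
  expect_lte(fin, 95 / cfg$plateau_frac + 1e-9)  # never above the plateau
  # also under strong demographic shifts, thanks to the clamp
  cfgs <- strong_effect_config(seed = 5, noise_sd = 0, missing_rate = 0)
  coh <- generate_cohort(cfgs)
  expect_true(all(vapply(coh, noiseless_final, 0) >= 90 - 1e-9))
})

test_that("demographics fully determine the series in the zero-noise limit", {
  cfg <- deterministic_config(seed = 9)
  a <- generate_patient(cfg, "pA", age = 44, bmi = 27)
  b <- generate_patient(cfg, "pB", age = 44, bmi = 27)  # different id => seed
  expect_equal(a$series$values, b$series$values, tolerance = 1e-12)
  c <- generate_patient(cfg, "pC", age = 64, bmi = 27)
  expect_false(isTRUE(all.equal(a$series$values, c$series$values)))
})

test_that("cohorts have the requested size, unique ids and in-range lengths", {
  cfg <- generator_config(n_patients = 12, seed = 21)
  coh <- generate_cohort(cfg)
  expect_length(coh, 12)
  ids <- vapply(coh, `[[`, "", "patient_id")
  expect_false(anyDuplicated(ids) > 0)
  lens <- vapply(coh, function(p) length(p$series), integer(1))
  expect_true(all(lens >= 119 & lens <= 228))
  coh2 <- generate_cohort(generator_config(n_patients = 12, seed = 22))
  expect_false(identical(coh, coh2))
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(n_patients = 1), "n_patients")
  expect_error(generator_config(missing_rate = 0.6), "missing_rate")
  expect_error(generator_config(bmi_range = c(20, 40)), "bmi_range")
  expect_error(generator_config(age_range = c(10, 75)), "age_range")
  expect_error(generator_config(noise_sd = -1), "noise_sd")
})
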