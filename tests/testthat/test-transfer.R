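test_that("donor selection follows the age-window-then-BMI rule with tie-breaks", {
  rule <- similarity_rule()
  target <- make_patient("t", 50, 25)
  # B is in the age window with the smallest BMI difference
  cands <- list(make_patient("A", 49, 27), make_patient("B", 51, 24),
                make_patient("C", 55, 25))
  expect_equal(find_most_similar(target, cands, rule), "B")
  # fallback: nobody within 2 years -> nearest age, with a warning
  far <- list(make_patient("D", 60, 25), make_patient("E", 57, 25))
  expect_warning(sel <- find_most_similar(target, far, rule), "falling back")
  expect_equal(sel, "E")
  # BMI tie, age tie -> lexicographically smallest id
  tie <- list(make_patient("B", 51, 26), make_patient("A", 49, 24))
  expect_equal(find_most_similar(target, tie, rule), "A")
  expect_error(find_most_similar(target, list(), rule), "empty")
  expect_error(find_most_similar(target, list(target), rule), "present")
})

test_that("donor selection agrees with the brute-force oracle on random cohorts", {
  rule <- similarity_rule()
  set.seed(99)
  for (k in 1:300) {
    m <- sample(2:30, 1)
    cands <- lapply(seq_len(m), function(j)
      make_patient(sprintf("c%02d", j), runif(1, 18, 75), runif(1, 18, 35)))
    target <- make_patient("t", runif(1, 18, 75), runif(1, 18, 35))
    got <- suppressWarnings(find_most_similar(target, cands, rule))
    want <- brute_force_most_similar(target, cands, rule)
    expect_identical(got, want)
  }
})

test_that("pair similarity uses both thresholds inclusively and is symmetric", {
  rule <- similarity_rule()
  p <- make_patient("p", 50, 25)
  expect_true(is_similar_pair(p, make_patient("q", 52, 28), rule))   # boundary
  expect_false(is_similar_pair(p, make_patient("q", 53, 25), rule))  # age 3 > 2
  expect_false(is_similar_pair(p, make_patient("q", 50, 28.0001), rule))
  strict <- similarity_rule(inclusive = FALSE)
  expect_false(is_similar_pair(p, make_patient("q", 52, 28), strict))
  set.seed(4)
  for (k in 1:100) {
    a <- make_patient("a", runif(1, 18, 75), runif(1, 18, 35))
    b <- make_patient("b", runif(1, 18, 75), runif(1, 18, 35))
    expect_identical(is_similar_pair(a, b, rule), is_similar_pair(b, a, rule))
  }
})

test_that("random donor selection is uniform, seeded and leaves the RNG alone", {
  target <- make_patient("t", 50, 25)
  cands <- lapply(1:5, function(j) make_patient(paste0("c", j), 30 + j, 22))
  expect_equal(select_random_donor(target, cands[1], seed = 1), "c1")
  expect_identical(select_random_donor(target, cands, seed = 42),
                   select_random_donor(target, cands, seed = 42))
  draws <- vapply(1:10000, function(s) select_random_donor(target, cands, s), "")
  freq <- table(draws) / length(draws)
  expect_true(all(abs(freq - 0.2) < 0.02))
  # global RNG stream is untouched
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(select_random_donor(target, cands, seed = 9))
  expect_identical(runif(1), before)
  expect_error(select_random_donor(target, list(), 1), "empty")
  expect_error(select_random_donor(target, c(cands, list(target)), 1), "present")
})
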