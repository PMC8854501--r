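#' Root mean square error
#'
#' `sqrt(mean((observed - predicted)^2))`, the study's sole performance
#' metric, always reported on the 0--100 TOFR scale.
#'
#' @param observed,predicted equal-length finite numeric vectors.
#' @return nonnegative RMSE; 0 iff the sequences are identical.
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("length mismatch: ", length(observed), " vs ", length(predicted))
  if (length(observed) == 0) stop("rmse of zero points is undefined")
  if (!all(is.finite(observed)) || !all(is.finite(predicted)))
    stop("rmse inputs must be finite")
  sqrt(mean((observed - predicted)^2))
}

#' Welch's two-sample t-test
#'
#' Two-sided t-test with unequal variances (Welch--Satterthwaite degrees of
#' freedom); a pooled-variance Student variant is available via
#' `var_equal = TRUE`.  When both groups are constant the statistic is
#' defined by convention as `t = 0, p = 1` if the means agree; a mean
#' difference with zero variance yields `p = 0`.
#'
#' @param a,b numeric vectors of length >= 2.
#' @param var_equal pool the variances (Student's test) instead.
#' @return list with `t_statistic`, `p_value`, `df`, `test_name`.
#' @export
welch_t_test <- function(a, b, var_equal = FALSE) {
  if (length(a) < 2 || length(b) < 2)
    stop("both groups need at least 2 values")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("t-test inputs must be finite")
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  d <- mean(a) - mean(b)
  name <- if (var_equal) "Student two-sample t-test" else "Welch two-sample t-test"
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- na + nb - 2
  } else {
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  if (se2 == 0 || !is.finite(df)) {
    if (d == 0) return(list(t_statistic = 0, p_value = 1, df = NA_real_,
                            test_name = name))
    return(list(t_statistic = sign(d) * Inf, p_value = 0, df = NA_real_,
                test_name = name))
  }
  t <- d / sqrt(se2)
  list(t_statistic = t, p_value = 2 * pt(-abs(t), df), df = df,
       test_name = name)
}

# sample standard deviation with the single-observation convention sd = 0
sd0 <- function(x) if (length(x) < 2) 0 else sd(x)

group_stat <- function(x) c(mean = mean(x), sd = sd0(x), n = length(x))

new_report <- function(experiment, model_kind, per_patient_rmse, group_stats,
                       comparison = NULL, config_echo = list(), seeds = list(),
                       skipped = character(0), extra = list()) {
  structure(c(list(experiment = experiment, model_kind = model_kind,
                   per_patient_rmse = per_patient_rmse,
                   group_stats = group_stats, comparison = comparison,
                   config_echo = config_echo, seeds = seeds,
                   skipped = skipped), extra),
            class = "tofr_report")
}

#' @export
print.tofr_report <- function(x, ...) {
  cat(sprintf("<tofr_report> %s [%s]\n", x$experiment, x$model_kind))
  for (g in names(x$group_stats)) {
    s <- x$group_stats[[g]]
    cat(sprintf("  %-20s RMSE %.3f +/- %.3f (n = %d)\n", g, s["mean"],
                s["sd"], as.integer(s["n"])))
  }
  if (!is.null(x$comparison))
    cat(sprintf("  %s: t = %.3f, p = %.4g\n", x$comparison$test_name,
                x$comparison$t_statistic, x$comparison$p_value))
  if (length(x$skipped)) cat("  skipped:", length(x$skipped), "patient(s)\n")
  invisible(x)
}

config_echo_of <- function(cohort, spec, rule = NULL) {
  e <- list(generator = unclass(attr(cohort, "config")),
            model = if (inherits(spec, "tofr_model_spec")) unclass(spec) else spec)
  if (!is.null(rule)) e$similarity <- unclass(rule)
  e
}

#' Per-patient prediction experiment
#'
#' For each patient: split the series in half, gap-fill the training part,
#' train the patient's own predictor, walk-forward forecast the testing
#' half, and record the RMSE.  Reports the mean and sample standard
#' deviation over patients.  `spec = "persistence"` runs the naive baseline
#' instead of a recurrent model.
#'
#' @param cohort a `tofr_cohort`.
#' @param spec a [model_spec()], or the string `"persistence"`.
#' @param predictors optional pre-trained predictors from
#'   [train_cohort_predictors()] (reused if supplied).
#' @return a `tofr_report`.
#' @export
run_per_patient <- function(cohort, spec, predictors = NULL) {
  baseline <- identical(spec, "persistence")
  if (!baseline && is.null(predictors))
    predictors <- train_cohort_predictors(cohort, spec)
  rmses <- numeric(0)
  skipped <- character(0)
  for (p in cohort) {
    r <- tryCatch({
      split <- split_half(p$series)
      fc <- if (baseline) baseline_persistence(split)
            else forecast_test_half(predictors[[p$patient_id]], split)
      forecast_rmse(fc)
    }, error = function(e) {
      warning("skipping ", p$patient_id, ": ", conditionMessage(e))
      NA_real_
    })
    if (is.na(r)) skipped <- c(skipped, p$patient_id)
    else rmses[p$patient_id] <- r
  }
  new_report("per_patient", if (baseline) "persistence" else spec$kind,
             rmses, list(all = group_stat(rmses)),
             config_echo = config_echo_of(cohort, if (baseline) "persistence" else spec),
             seeds = if (baseline) list() else list(model_seed = spec$seed),
             skipped = skipped)
}

#' Pairwise similar-versus-dissimilar transfer experiment
#'
#' Every ordered pair (target, donor) of distinct patients is evaluated by
#' forecasting the target's testing half with the donor's pre-trained
#' predictor (no retraining).  Pair RMSEs are partitioned into "similar"
#' and "dissimilar" groups by [is_similar_pair()] and compared with a
#' two-sided t-test.
#'
#' @param cohort a `tofr_cohort` of at least 3 patients.
#' @param spec a [model_spec()].
#' @param rule a [similarity_rule()].
#' @param predictors optional shared pre-trained predictors.
#' @param ordered keep (i, j) and (j, i) as distinct records (default);
#'   `FALSE` de-duplicates to unordered pairs, averaging the two directions.
#' @return a `tofr_report` whose `pairs` element holds the full pair table
#'   (`target_id`, `donor_id`, `rmse`, `similar`).
#' @export
run_pairwise <- function(cohort, spec, rule = similarity_rule(),
                         predictors = NULL, ordered = TRUE) {
  if (length(cohort) < 3) stop("pairwise experiment needs at least 3 patients")
  if (is.null(predictors)) predictors <- train_cohort_predictors(cohort, spec)
  ids <- vapply(cohort, `[[`, "", "patient_id")
  splits <- lapply(cohort, function(p) split_half(p$series))
  names(splits) <- ids
  rows <- list()
  for (ti in ids) for (dj in ids) {
    if (ti == dj) next
    fc <- forecast_test_half(predictors[[dj]], splits[[ti]])
    rows[[length(rows) + 1]] <- data.frame(
      target_id = ti, donor_id = dj, rmse = forecast_rmse(fc),
      similar = is_similar_pair(cohort[[ti]], cohort[[dj]], rule))
  }
  pairs <- do.call(rbind, rows)
  if (!ordered) {
    key <- apply(cbind(pmin(pairs$target_id, pairs$donor_id),
                       pmax(pairs$target_id, pairs$donor_id)), 1, paste,
                 collapse = "|")
    pairs <- do.call(rbind, lapply(split(pairs, key), function(d)
      data.frame(target_id = d$target_id[1], donor_id = d$donor_id[1],
                 rmse = mean(d$rmse), similar = d$similar[1])))
    rownames(pairs) <- NULL
  }
  sim <- pairs$rmse[pairs$similar]
  dis <- pairs$rmse[!pairs$similar]
  stats <- list(with_similarity = group_stat(sim),
                without_similarity = group_stat(dis))
  comparison <- NULL
  if (length(sim) >= 2 && length(dis) >= 2) {
    comparison <- welch_t_test(sim, dis)
  } else {
    warning("one similarity group is too small; comparison omitted")
  }
  new_report("pairwise", spec$kind, NULL, stats, comparison,
             config_echo = config_echo_of(cohort, spec, rule),
             seeds = list(model_seed = spec$seed),
             extra = list(pairs = pairs, ordered = ordered))
}

#' Leave-one-out transfer experiment: similarity versus random donor
#'
#' Each patient in turn is held out; all others form the donor pool.  The
#' similarity arm forecasts the held-out patient's testing half with the
#' donor chosen by [find_most_similar()]; the random arm averages the RMSE
#' of `n_random_draws` uniformly drawn donors.  Donor predictors are the
#' shared pre-trained models (trained on each donor's own first half), so
#' similarity-arm entries coincide exactly with the corresponding rows of
#' the pairwise experiment.
#'
#' @param cohort a `tofr_cohort` of at least 3 patients.
#' @param spec a [model_spec()].
#' @param rule a [similarity_rule()].
#' @param n_random_draws random donors averaged per held-out patient.
#' @param seed master seed of the random arm.
#' @param predictors optional shared pre-trained predictors.
#' @return a `tofr_report` with groups `similarity` and `random`; its
#'   `arms` element maps each patient to the chosen donor and both RMSEs.
#' @export
run_loocv_transfer <- function(cohort, spec, rule = similarity_rule(),
                               n_random_draws = 10, seed = 1L,
                               predictors = NULL) {
  if (length(cohort) < 3) stop("leave-one-out needs at least 3 patients")
  if (is.null(predictors)) predictors <- train_cohort_predictors(cohort, spec)
  ids <- vapply(cohort, `[[`, "", "patient_id")
  rows <- list()
  skipped <- character(0)
  for (ti in ids) {
    res <- tryCatch({
      target <- cohort[[ti]]
      donors <- cohort[ids != ti]
      split <- split_half(target$series)
      sim_id <- find_most_similar(target, donors, rule)
      r_sim <- forecast_rmse(forecast_test_half(predictors[[sim_id]], split))
      r_rand <- vapply(seq_len(n_random_draws), function(d) {
        did <- select_random_donor(target, donors,
                                   derive_seed(seed, "draw",
                                               paste(ti, d, sep = "/")))
        forecast_rmse(forecast_test_half(predictors[[did]], split))
      }, numeric(1))
      data.frame(patient_id = ti, similar_donor = sim_id,
                 rmse_similarity = r_sim, rmse_random = mean(r_rand))
    }, error = function(e) {
      warning("skipping ", ti, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) skipped <- c(skipped, ti) else
      rows[[length(rows) + 1]] <- res
  }
  arms <- do.call(rbind, rows)
  per_patient <- arms$rmse_similarity
  names(per_patient) <- arms$patient_id
  new_report("loocv_transfer", spec$kind, per_patient,
             list(similarity = group_stat(arms$rmse_similarity),
                  random = group_stat(arms$rmse_random)),
             config_echo = config_echo_of(cohort, spec, rule),
             seeds = list(model_seed = spec$seed, random_arm_seed = seed,
                          n_random_draws = n_random_draws),
             skipped = skipped, extra = list(arms = arms))
}
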