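#' Patient-similarity rule
#'
#' Donor selection works in two stages: restrict to candidates within
#' `age_window` years of the target, then pick the one with the minimum
#' absolute BMI difference.  Group membership for the pairwise comparison
#' uses both thresholds jointly: within `group_age_threshold` years AND
#' `group_bmi_threshold` kg/m^2.
#'
#' @param age_window age window (years) of the donor-selection stage.
#' @param group_age_threshold,group_bmi_threshold thresholds defining a
#'   "similar" pair of patients.
#' @param inclusive treat "within" as `<=` (default) rather than `<`.
#' @return a `tofr_similarity_rule`.
#' @export
similarity_rule <- function(age_window = 2, group_age_threshold = 2,
                            group_bmi_threshold = 3, inclusive = TRUE) {
  stopifnot(age_window > 0, group_age_threshold > 0, group_bmi_threshold > 0)
  structure(list(age_window = age_window,
                 group_age_threshold = group_age_threshold,
                 group_bmi_threshold = group_bmi_threshold,
                 inclusive = isTRUE(inclusive)),
            class = "tofr_similarity_rule")
}

within_thr <- function(x, thr, inclusive) if (inclusive) x <= thr else x < thr

#' Find the most similar donor patient
#'
#' Among candidates within the age window, returns the one minimizing the
#' absolute BMI difference; ties are broken by smaller absolute age
#' difference, then by lexicographically smallest patient id.  If no
#' candidate falls inside the age window the nearest-age candidate is
#' returned instead (ties by BMI difference, then id) with a warning —
#' leaving age-isolated patients without a donor would make leave-one-out
#' evaluation undefined.
#'
#' @param target a `tofr_patient`.
#' @param candidates list of `tofr_patient` records, not containing the
#'   target.
#' @param rule a [similarity_rule()].
#' @return the selected donor's `patient_id`.
#' @export
find_most_similar <- function(target, candidates, rule = similarity_rule()) {
  if (length(candidates) == 0) stop("candidate list is empty")
  ids <- vapply(candidates, `[[`, "", "patient_id")
  if (target$patient_id %in% ids)
    stop("target patient ", target$patient_id, " present among candidates")
  dage <- abs(vapply(candidates, `[[`, 0, "age") - target$age)
  dbmi <- abs(vapply(candidates, `[[`, 0, "bmi") - target$bmi)
  in_win <- within_thr(dage, rule$age_window, rule$inclusive)
  if (any(in_win)) {
    ord <- order(!in_win, dbmi, dage, ids)  # filter first, then bmi, age, id
  } else {
    warning("no candidate within ", rule$age_window,
            "-year age window of ", target$patient_id,
            "; falling back to nearest age")
    ord <- order(dage, dbmi, ids)
  }
  ids[ord[1]]
}

#' Are two patients demographically similar?
#'
#' @param p,q distinct `tofr_patient` records.
#' @param rule a [similarity_rule()].
#' @return `TRUE` iff the absolute age difference is within
#'   `group_age_threshold` AND the absolute BMI difference is within
#'   `group_bmi_threshold`; symmetric in `p`, `q`.
#' @export
is_similar_pair <- function(p, q, rule = similarity_rule()) {
  within_thr(abs(p$age - q$age), rule$group_age_threshold, rule$inclusive) &&
    within_thr(abs(p$bmi - q$bmi), rule$group_bmi_threshold, rule$inclusive)
}

#' Select a random donor
#'
#' Uniform draw over the candidate list, deterministic given the seed; the
#' baseline arm of the transfer comparison.
#'
#' @param target a `tofr_patient` (must not be among candidates).
#' @param candidates nonempty list of `tofr_patient` records.
#' @param seed integer seed.
#' @return the selected donor's `patient_id`.
#' @export
select_random_donor <- function(target, candidates, seed) {
  if (length(candidates) == 0) stop("candidate list is empty")
  ids <- vapply(candidates, `[[`, "", "patient_id")
  if (target$patient_id %in% ids)
    stop("target patient ", target$patient_id, " present among candidates")
  with_seed(seed, ids[sample.int(length(ids), 1)])
}
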