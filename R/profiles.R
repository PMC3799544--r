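# Classification of promiscuous compounds against the prevalent
# promiscuity profile - sub-uM activity against two to five same-family
# targets with potency differences within one or two orders of magnitude -
# and detection of the rarer selectivity-outlier pattern (highly potent
# against one primary target, weakly potent against the rest).

#' Prevalent-profile classification rule
#'
#' @param min_targets,max_targets target-count window of the profile.
#' @param sub_uM_threshold potency cutoff in nM; every aggregated potency
#'   must be strictly below it ("sub-uM" with the 1000 nM default).
#' @param require_same_family must all targets share one family?
#' @param max_spread_log maximum allowed potency spread (max - min
#'   pPotency) in log10 units; spreads within 1.0 are flagged separately.
#' @return a `profile_rule` list.
#' @export
profile_rule <- function(min_targets = 2L, max_targets = 5L,
                         sub_uM_threshold = 1000, require_same_family = TRUE,
                         max_spread_log = 2.0) {
  if (min_targets > max_targets) abort("min_targets must be <= max_targets")
  if (min_targets < 2L) abort("the profile is defined for promiscuous compounds (min_targets >= 2)")
  if (sub_uM_threshold <= 0 || max_spread_log <= 0) {
    abort("thresholds must be positive")
  }
  structure(
    list(min_targets = as.integer(min_targets),
         max_targets = as.integer(max_targets),
         sub_uM_threshold = sub_uM_threshold,
         require_same_family = isTRUE(require_same_family),
         max_spread_log = max_spread_log),
    class = "profile_rule"
  )
}

.assess_group <- function(p_potency, target_family, rule) {
  n <- length(p_potency)
  spread <- max(p_potency) - min(p_potency)
  all_sub_uM <- all(potency_nM(p_potency) < rule$sub_uM_threshold)
  same_family <- length(unique(target_family)) == 1L
  matches <- n >= rule$min_targets && n <= rule$max_targets &&
    all_sub_uM && (same_family || !rule$require_same_family) &&
    spread <= rule$max_spread_log
  tibble::tibble(
    n_targets = n, all_sub_uM = all_sub_uM, same_family = same_family,
    spread_log = spread, matches_prevalent = matches,
    within_one_log = spread <= 1.0
  )
}

#' Assess one promiscuous compound against the prevalent profile
#'
#' Computes, from a compound's aggregated per-target potencies of a single
#' measurement type, the potency spread (max minus min pPotency), whether
#' every target is hit in the sub-uM range, whether all targets share one
#' family, and the resulting profile flags. The profile is defined for
#' promiscuous compounds only; fewer than two pairs is an error
#' (`assess_profiles()` silently skips such compounds instead).
#'
#' @param pairs aggregated pairs of one compound, one measurement type.
#' @param rule a [profile_rule()].
#' @return a one-row assessment tibble with `compound_id`, `n_targets`,
#'   `all_sub_uM`, `same_family`, `spread_log`, `matches_prevalent`,
#'   `within_one_log`, `selectivity_outlier`.
#' @export
assess_profile <- function(pairs, rule = profile_rule()) {
  .assert_pairs(pairs)
  if (dplyr::n_distinct(pairs$compound_id) > 1) {
    abort("assess_profile expects pairs of a single compound; see assess_profiles()")
  }
  if (dplyr::n_distinct(pairs$measurement_type) > 1) {
    abort("Ki and IC50 potencies must not be mixed in one assessment")
  }
  if (nrow(pairs) < 2) {
    abort("profile not assessable: fewer than two compound-target pairs")
  }
  out <- .assess_group(pairs$p_potency, pairs$target_family, rule)
  out$selectivity_outlier <- detect_selectivity_outlier(pairs)
  dplyr::bind_cols(tibble::tibble(compound_id = pairs$compound_id[1]), out)
}

#' Assess all promiscuous compounds in a pair table
#'
#' @param pairs aggregated pairs of one measurement type (several
#'   compounds). Compounds with a single pair are not assessable and are
#'   skipped; their number is available as `attr(result, "n_not_assessable")`.
#' @param potent_threshold,weak_threshold nM cutoffs for the
#'   selectivity-outlier test (see [detect_selectivity_outlier()]).
#' @rdname assess_profile
#' @export
assess_profiles <- function(pairs, rule = profile_rule(),
                            potent_threshold = 100, weak_threshold = 10000) {
  .assert_pairs(pairs)
  if (dplyr::n_distinct(pairs$measurement_type) > 1) {
    abort("Ki and IC50 potencies must not be mixed; assess each subset separately")
  }
  n_pairs <- table(pairs$compound_id)
  assessable <- names(n_pairs)[n_pairs >= 2]
  sub <- pairs[pairs$compound_id %in% assessable, , drop = FALSE]
  out <- if (nrow(sub) == 0) {
    tibble::tibble(
      compound_id = character(0), n_targets = integer(0),
      all_sub_uM = logical(0), same_family = logical(0),
      spread_log = numeric(0), matches_prevalent = logical(0),
      within_one_log = logical(0), selectivity_outlier = logical(0)
    )
  } else {
    sub |>
      dplyr::group_by(.data$compound_id) |>
      dplyr::group_modify(function(g, key) {
        a <- .assess_group(g$p_potency, g$target_family, rule)
        a$selectivity_outlier <- .outlier_from_p(
          g$p_potency, potent_threshold, weak_threshold
        )
        a
      }) |>
      dplyr::ungroup()
  }
  attr(out, "n_not_assessable") <- length(n_pairs) - length(assessable)
  out
}

.outlier_from_p <- function(p, potent_threshold, weak_threshold) {
  v <- sort(potency_nM(p))  # ascending nM: v[1] is the most potent
  v[1] <= potent_threshold && all(v[-1] >= weak_threshold)
}

#' Detect a selectivity outlier
#'
#' TRUE iff the compound's best (lowest-nM) aggregated potency is at or
#' below `potent_threshold` while every other target is hit at or above
#' `weak_threshold` - the "highly potent against a primary target, weakly
#' potent against others" pattern, which is rare among real promiscuous
#' compounds.
#'
#' @param pairs aggregated pairs of one compound (>= 2 pairs).
#' @param potent_threshold nM cutoff defining "highly potent".
#' @param weak_threshold nM cutoff defining "weakly potent".
#' @return a single logical.
#' @export
detect_selectivity_outlier <- function(pairs, potent_threshold = 100,
                                       weak_threshold = 10000) {
  .assert_pairs(pairs)
  if (nrow(pairs) < 2) {
    abort("selectivity not assessable: fewer than two compound-target pairs")
  }
  .outlier_from_p(pairs$p_potency, potent_threshold, weak_threshold)
}

#' Prevalence of profile patterns among promiscuous compounds
#'
#' @param assessments assessment table from [assess_profiles()].
#' @return a one-row tibble with the denominator (`n_promiscuous`) and the
#'   fractions of compounds matching the prevalent profile, staying within
#'   one log unit of potency spread, and showing the selectivity-outlier
#'   pattern; fractions are `NA` on empty input.
#' @export
profile_prevalence <- function(assessments) {
  n <- nrow(assessments)
  if (n == 0) {
    return(tibble::tibble(
      n_promiscuous = 0L, frac_matches_prevalent = NA_real_,
      frac_within_one_log = NA_real_, frac_selectivity_outlier = NA_real_
    ))
  }
  tibble::tibble(
    n_promiscuous = n,
    frac_matches_prevalent = mean(assessments$matches_prevalent),
    frac_within_one_log = mean(assessments$within_one_log),
    frac_selectivity_outlier = mean(assessments$selectivity_outlier)
  )
}
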