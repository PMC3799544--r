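pairs_from_nM <- function(values_nM, families = "GPCR_A",
                          compound_id = "C1") {
  aggregate_pairs(record_row(
    compound_id = compound_id,
    target_id = sprintf("T%d", seq_along(values_nM)),
    target_family = families,
    value_nM = values_nM
  ))
}

test_that("hand-worked potency sets classify exactly", {
  a <- assess_profile(pairs_from_nM(c(100, 300, 500)))
  expect_true(a$matches_prevalent)
  expect_true(a$all_sub_uM)
  expect_true(a$same_family)
  expect_equal(a$spread_log, log10(500 / 100), tolerance = 1e-12)
  expect_true(a$within_one_log)
  expect_false(a$selectivity_outlier)

  six <- assess_profile(pairs_from_nM(rep(c(100, 200), 3)[1:6] * c(1, 1.1)))
  expect_equal(six$n_targets, 6L)
  expect_false(six$matches_prevalent)  # past the five-target bound

  wide <- assess_profile(pairs_from_nM(c(10, 50000)))
  expect_equal(wide$spread_log, log10(5000), tolerance = 1e-12)
  expect_false(wide$matches_prevalent)
  expect_false(wide$within_one_log)

  cross <- assess_profile(pairs_from_nM(c(100, 300),
                                        families = c("GPCR_A", "kinase")))
  expect_false(cross$same_family)
  expect_false(cross$matches_prevalent)

  expect_error(assess_profile(pairs_from_nM(500)), "fewer than two")
})

test_that("selectivity outliers need one potent and only weak other targets", {
  expect_true(detect_selectivity_outlier(pairs_from_nM(c(50, 20000, 80000))))
  expect_false(detect_selectivity_outlier(pairs_from_nM(c(50, 200))))
  expect_false(detect_selectivity_outlier(pairs_from_nM(c(500, 20000))))
  expect_false(detect_selectivity_outlier(pairs_from_nM(c(50, 20000, 500))))
  expect_error(detect_selectivity_outlier(pairs_from_nM(100)), "fewer than two")
})

test_that("spread is invariant to target relabeling and neutral replicates", {
  base <- record_row(
    compound_id = "C1", target_id = c("T1", "T2", "T3"),
    value_nM = c(20, 90, 400)
  )
  a1 <- assess_profile(aggregate_pairs(base))
  relabeled <- base
  relabeled$target_id <- c("TX", "TY", "TZ")
  a2 <- assess_profile(aggregate_pairs(relabeled))
  expect_equal(a1$spread_log, a2$spread_log)
  expect_equal(a1$matches_prevalent, a2$matches_prevalent)

  # a duplicate measurement with the same value leaves aggregates unchanged
  with_rep <- dplyr::bind_rows(base, base[2, ])
  a3 <- assess_profile(aggregate_pairs(with_rep))
  expect_equal(a3$spread_log, a1$spread_log)
})

test_that("prevalent-profile matching is monotone in rule strictness", {
  set.seed(51)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    pairs <- pairs_from_nM(10^runif(n, 1, 4.5))
    loose <- assess_profile(pairs, profile_rule(max_spread_log = 2))
    tight <- assess_profile(pairs, profile_rule(max_spread_log = 1))
    expect_true(loose$matches_prevalent || !tight$matches_prevalent)
    strict_sub <- assess_profile(pairs, profile_rule(sub_uM_threshold = 100))
    expect_true(loose$matches_prevalent || !strict_sub$matches_prevalent)
  }
})

test_that("a compound cannot both match the profile and be a selectivity outlier", {
  set.seed(52)
  for (i in 1:30) {
    n <- sample(2:5, 1)
    a <- assess_profile(pairs_from_nM(10^runif(n, 0.5, 5.5)))
    # weak_threshold (10 uM) exceeds the sub-uM cutoff, so the patterns
    # are mutually exclusive
    expect_false(a$matches_prevalent && a$selectivity_outlier)
  }
})

test_that("prevalence fractions equal a brute-force tally", {
  recs <- dplyr::bind_rows(
    record_row(compound_id = "C1", target_id = c("T1", "T2"),
               value_nM = c(100, 500)),                     # matches
    record_row(compound_id = "C2", target_id = c("T1", "T2"),
               value_nM = c(50, 50000)),                    # outlier
    record_row(compound_id = "C3", target_id = c("T1", "T2"),
               value_nM = c(100, 5000)),                    # neither
    record_row(compound_id = "C4", target_id = "T1", value_nM = 10)  # single
  )
  assessments <- assess_profiles(aggregate_pairs(recs))
  expect_equal(nrow(assessments), 3)
  expect_equal(attr(assessments, "n_not_assessable"), 1L)
  prev <- profile_prevalence(assessments)
  expect_equal(prev$n_promiscuous, 3L)
  expect_equal(prev$frac_matches_prevalent, 1 / 3)
  expect_equal(prev$frac_selectivity_outlier, 1 / 3)

  all_match <- assess_profiles(aggregate_pairs(dplyr::bind_rows(
    record_row(compound_id = "C1", target_id = c("T1", "T2"),
               value_nM = c(100, 200)),
    record_row(compound_id = "C2", target_id = c("T1", "T2"),
               value_nM = c(300, 400))
  )))
  expect_equal(profile_prevalence(all_match)$frac_matches_prevalent, 1)

  empty <- profile_prevalence(all_match[0, ])
  expect_equal(empty$n_promiscuous, 0L)
  expect_true(is.na(empty$frac_matches_prevalent))
})
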