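test_that("generation is deterministic for a fixed seed", {
  cfg <- synthetic_config(n_compounds = 60, seed = 123)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$activities, d2$activities)
  expect_identical(d1$meta, d2$meta)
  expect_identical(d1$drugs, d2$drugs)
  expect_identical(d1$assays, d2$assays)

  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  write_dataset(d1, dir1)
  write_dataset(generate_dataset(cfg), dir2)
  for (f in list.files(dir1)) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }

  d3 <- generate_dataset(synthetic_config(n_compounds = 60, seed = 124))
  expect_false(identical(d1$activities, d3$activities))
})

test_that("a point-mass count law yields exclusively single-target compounds", {
  cfg <- synthetic_config(
    n_compounds = 150, seed = 5,
    target_count_law = count_law_explicit(1, counts = 1)
  )
  ds <- generate_dataset(cfg)
  counts <- count_targets(aggregate_pairs(
    split_by_measurement(filter_high_confidence(ds$activities))$Ki
  ))
  s <- promiscuity_summary(counts)
  expect_equal(s$p_ge2, 0)
  expect_equal(s$avg_all, 1)
})

test_that("closed-form law statistics match hand arithmetic and brute force", {
  law <- count_law_explicit(c(0.62, 0.36, 0.02), counts = c(1, 2, 10))
  es <- expected_statistics(law)
  expect_equal(es$mean_n, 0.62 + 0.72 + 0.20)
  expect_equal(es$p_ge2, 0.38)
  expect_equal(es$p_gt5, 0.02)

  point <- expected_statistics(count_law_explicit(1, counts = 3))
  expect_equal(point$mean_n, 3)
  expect_equal(point$p_ge2, 1)
  expect_equal(point$p_gt5, 0)

  # truncated geometric against direct summation over 1..K
  for (q in c(0.3, 0.62, 0.9)) {
    K <- 10
    g <- expected_statistics(count_law_geometric(q, K))
    w <- (1 - q)^(0:(K - 1))
    p <- w / sum(w)
    expect_equal(g$mean_n, sum((1:K) * p))
    expect_equal(g$p_ge2, sum(p[2:K]))
    expect_equal(g$p_gt5, sum(p[6:K]))
    expect_equal(g$var_n, sum((1:K)^2 * p) - sum((1:K) * p)^2)
  }
})

test_that("full intra-family bias produces no cross-family compounds", {
  cfg <- synthetic_config(n_compounds = 300, seed = 17,
                          intra_family_bias = 1,
                          high_confidence_fraction = 1,
                          qualified_fraction = 0)
  ds <- generate_dataset(cfg)
  expect_false(any(ds$ground_truth$compounds$scope == "cross_family"))
  for (type in c("Ki", "IC50")) {
    pairs <- aggregate_pairs(
      split_by_measurement(filter_high_confidence(ds$activities))[[type]]
    )
    res <- classify_family_scope(count_targets(pairs))
    expect_equal(res$breakdown$frac_cross_family, 0)
  }
})

test_that("ground-truth counts and scopes agree with the pipeline on clean data", {
  cfg <- synthetic_config(n_compounds = 400, seed = 29,
                          high_confidence_fraction = 1,
                          qualified_fraction = 0,
                          measurement_mix = c(Ki = 1, IC50 = 0, both = 0))
  ds <- generate_dataset(cfg)
  counts <- count_targets(aggregate_pairs(
    split_by_measurement(filter_high_confidence(ds$activities))$Ki
  ))
  truth <- ds$ground_truth$compounds
  merged <- dplyr::inner_join(counts, truth, by = "compound_id")
  expect_equal(nrow(merged), 400)
  expect_equal(merged$n_targets.x, merged$n_targets.y)

  scope <- classify_family_scope(counts)$labels
  merged <- dplyr::inner_join(scope, truth, by = "compound_id")
  expect_equal(merged$scope.x, merged$scope.y)
})

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(synthetic_config(n_compounds = 0), "n_compounds")
  expect_error(synthetic_config(intra_family_bias = 1.4), "intra_family_bias")
  expect_error(synthetic_config(measurement_mix = c(Ki = 1, IC50 = 1, both = 0)),
               "measurement_mix")
  expect_error(synthetic_config(target_count_law = "geometric"), "count law")
  expect_error(count_law_geometric(q = 1.2), "q must be")
  expect_error(count_law_explicit(c(0.5, 0.4)), "sum to 1")
})
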