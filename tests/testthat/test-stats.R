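test_that("target counting deduplicates targets and matches a naive tally", {
  pairs <- aggregate_pairs(record_row(
    compound_id = "C1", target_id = c("TA", "TB", "TB"), value_nM = 100
  ))
  cnt <- count_targets(pairs)
  expect_equal(cnt$n_targets, 2)

  expect_equal(nrow(count_targets(pairs[0, ])), 0)

  set.seed(21)
  rnd <- record_row(
    compound_id = sprintf("C%d", sample(1:4, 30, TRUE)),
    target_id = sprintf("T%d", sample(1:6, 30, TRUE)),
    value_nM = 100
  )
  got <- count_targets(aggregate_pairs(rnd))
  ref <- naive_count_targets(rnd)
  ref <- ref[order(ref$compound_id), ]
  expect_equal(got$n_targets, ref$n_targets)
})

test_that("promiscuity summary reproduces hand arithmetic and handles degenerate input", {
  s <- promiscuity_summary(c(1, 1, 1, 2, 3))
  expect_equal(s$avg_all, 1.6)
  expect_equal(s$p_ge2, 0.4)
  expect_equal(s$p_gt5, 0)
  expect_equal(s$avg_promiscuous, 2.5)
  expect_equal(s$median_promiscuous, 2.5)

  ones <- promiscuity_summary(rep(1, 5))
  expect_equal(ones$avg_all, 1)
  expect_equal(ones$p_ge2, 0)
  expect_true(is.na(ones$avg_promiscuous))
  expect_true(is.na(ones$median_promiscuous))

  empty <- promiscuity_summary(integer(0))
  expect_equal(empty$n_compounds, 0L)
  expect_true(is.na(empty$avg_all))

  expect_error(promiscuity_summary(c(0, 1)), ">= 1")
})

test_that("summary fields match the naive oracle on simulated counts", {
  for (seed in 1:20) {
    set.seed(seed)
    counts <- sample(1:10, sample(5:300, 1), replace = TRUE,
                     prob = 0.6^(1:10))
    expect_summary_matches_naive(promiscuity_summary(counts), counts)
  }
})

test_that("mixture identity reconstructs the overall average", {
  expect_equal(mixture_identity(0.379, 2.9), 1.7201)
  expect_equal(round(mixture_identity(0.379, 2.9), 1), 1.7)
  expect_equal(mixture_identity(0, NA), 1)
  expect_equal(mixture_identity(1, 3), 3)
  expect_error(mixture_identity(0.5, 1.5), ">= 2")
  expect_error(mixture_identity(1.2, 3), "probability")
})

test_that("adding a target annotation never decreases the headline statistics", {
  set.seed(5)
  for (i in 1:20) {
    counts <- sample(1:8, 50, replace = TRUE, prob = 0.5^(1:8))
    s0 <- promiscuity_summary(counts)
    j <- sample(50, 1)
    counts[j] <- counts[j] + 1L
    s1 <- promiscuity_summary(counts)
    expect_gte(s1$avg_all, s0$avg_all)
    expect_gte(s1$p_ge2, s0$p_ge2)
    expect_gte(s1$p_gt5, s0$p_gt5)
    expect_lte(s1$p_gt5, s1$p_ge2)
    expect_true(s0$median_promiscuous >= 2 || is.na(s0$median_promiscuous))
  }
})

test_that("family scope classification separates single, intra- and cross-family activity", {
  pairs <- dplyr::bind_rows(
    record_row(compound_id = "C1", target_id = c("T1", "T2", "T3"),
               target_family = "GPCR_A"),
    record_row(compound_id = "C2", target_id = "T4", target_family = "kinase"),
    record_row(compound_id = "C3", target_id = c("T1", "T5"),
               target_family = c("GPCR_A", "kinase"))
  ) |> aggregate_pairs()
  res <- classify_family_scope(count_targets(pairs))
  scope <- setNames(res$labels$scope, res$labels$compound_id)
  expect_equal(unname(scope[c("C1", "C2", "C3")]),
               c("intra_family", "single", "cross_family"))
  expect_equal(res$breakdown$frac_single +
                 res$breakdown$frac_intra_family +
                 res$breakdown$frac_cross_family, 1, tolerance = 1e-12)

  # brute-force tally on a random fixture
  set.seed(33)
  rnd <- record_row(
    compound_id = sprintf("C%d", sample(1:10, 40, TRUE)),
    target_id = sprintf("T%d", sample(1:12, 40, TRUE)),
    value_nM = 100
  )
  fam_of <- setNames(rep(c("GPCR_A", "kinase", "protease"), 4),
                     sprintf("T%d", 1:12))
  rnd$target_family <- unname(fam_of[rnd$target_id])
  res <- classify_family_scope(count_targets(aggregate_pairs(rnd)))
  for (cid in unique(rnd$compound_id)) {
    tg <- unique(rnd$target_id[rnd$compound_id == cid])
    expected <- if (length(tg) == 1) "single"
      else if (length(unique(fam_of[tg])) == 1) "intra_family"
      else "cross_family"
    expect_equal(res$labels$scope[res$labels$compound_id == cid], expected)
  }

  bad <- count_targets(aggregate_pairs(record_row(target_family = "")))
  expect_error(classify_family_scope(bad), "missing family")
})

test_that("category summaries count drug and screening targets correctly", {
  drugs <- tibble::tibble(
    drug_id = rep("D1", 6), drug_status = "approved",
    target_id = sprintf("T%d", 1:6)
  )
  s <- category_summary(drugs, "approved")
  expect_equal(s$n_compounds, 1L)
  expect_equal(s$avg_all, 6)
  expect_equal(s$p_ge2, 1)
  expect_equal(s$median_threshold, 5L)

  assays <- tibble::tibble(
    compound_id = "S1", assay_id = c("A1", "A2", "A3"),
    target_id = c("T1", "T1", "T2"), outcome = "active"
  )
  expect_equal(screen_target_counts(assays)$n_targets, 2)

  expect_error(category_summary(drugs, "fictional"), "unknown category")

  # 20-drug fixture against a naive recomputation
  set.seed(8)
  ann <- tibble::tibble(
    drug_id = sprintf("D%02d", sample(1:20, 60, TRUE)),
    drug_status = "experimental",
    target_id = sprintf("T%d", sample(1:15, 60, TRUE))
  ) |> dplyr::distinct(drug_id, target_id, .keep_all = TRUE)
  s <- category_summary(ann, "experimental")
  counts <- naive_count_targets(
    data.frame(compound_id = ann$drug_id, target_id = ann$target_id)
  )$n_targets
  expect_summary_matches_naive(s, counts, median_threshold = 2)
})

test_that("assay coverage uses a strict cutoff over distinct tested assays", {
  one <- tibble::tibble(
    compound_id = "S1", assay_id = sprintf("A%d", 1:51),
    target_id = "T1", outcome = c("active", rep("inactive", 50))
  )
  expect_equal(assay_coverage(one)$fraction, 1)

  fifty <- one[1:50, ]
  expect_equal(assay_coverage(fifty)$fraction, 0)

  # naive tally on a random fixture
  set.seed(14)
  rows <- tibble::tibble(
    compound_id = sprintf("S%d", sample(1:8, 400, TRUE)),
    assay_id = sprintf("A%d", sample(1:120, 400, TRUE)),
    target_id = "T1",
    outcome = sample(c("active", "inactive"), 400, TRUE, prob = c(0.3, 0.7))
  ) |> dplyr::distinct(compound_id, assay_id, .keep_all = TRUE)
  got <- assay_coverage(rows, min_assays = 30)
  actives <- unique(rows$compound_id[rows$outcome == "active"])
  covered <- 0
  for (cid in actives) {
    if (length(unique(rows$assay_id[rows$compound_id == cid])) > 30) {
      covered <- covered + 1
    }
  }
  expect_equal(got$fraction, covered / length(actives))
})
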