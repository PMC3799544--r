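# Fixture builders and independent naive oracles used across the suite.
# The oracles recompute every statistic with explicit loops over rows,
# deliberately avoiding the package's own code paths.

record_row <- function(compound_id = "C1", target_id = "T1",
                       target_family = "GPCR_A", measurement_type = "Ki",
                       value_nM = 100, relation = "eq",
                       confidence_level = 9L, direct_interaction = TRUE,
                       source = "chembl_like") {
  tibble::tibble(
    compound_id = compound_id, target_id = target_id,
    target_family = target_family, measurement_type = measurement_type,
    value_nM = value_nM, relation = relation,
    confidence_level = as.integer(confidence_level),
    direct_interaction = direct_interaction, source = source
  )
}

random_records <- function(n, seed) {
  set.seed(seed)
  record_row(
    compound_id = sprintf("C%02d", sample(1:12, n, TRUE)),
    target_id = sprintf("T%02d", sample(1:15, n, TRUE)),
    target_family = sample(c("GPCR_A", "kinase", "protease"), n, TRUE),
    measurement_type = sample(c("Ki", "IC50", "other"), n, TRUE,
                              prob = c(0.45, 0.45, 0.1)),
    value_nM = 10^runif(n, -1, 5),
    relation = sample(c("eq", "lt", "gt"), n, TRUE, prob = c(0.8, 0.1, 0.1)),
    confidence_level = sample(0:9, n, TRUE),
    direct_interaction = sample(c(TRUE, FALSE), n, TRUE, prob = c(0.8, 0.2))
  )
}

write_fixture <- function(df, ext = "tsv") {
  path <- withr::local_tempfile(fileext = paste0(".", ext),
                                .local_envir = parent.frame())
  if (ext == "csv") readr::write_csv(df, path) else readr::write_tsv(df, path)
  path
}

# --- naive oracles -------------------------------------------------------

naive_count_targets <- function(pairs) {
  ids <- unique(pairs$compound_id)
  n <- integer(length(ids))
  for (i in seq_along(ids)) {
    n[i] <- length(unique(pairs$target_id[pairs$compound_id == ids[i]]))
  }
  data.frame(compound_id = ids, n_targets = n)
}

naive_summary <- function(counts, threshold = 2, median_threshold = threshold) {
  naive_median <- function(x) {
    x <- sort(x)
    m <- length(x)
    if (m %% 2 == 1) x[(m + 1) / 2] else (x[m / 2] + x[m / 2 + 1]) / 2
  }
  prom <- counts[counts >= threshold]
  med <- counts[counts >= median_threshold]
  list(
    n_compounds = length(counts),
    avg_all = sum(counts) / length(counts),
    avg_promiscuous = if (length(prom)) sum(prom) / length(prom) else NA_real_,
    median_promiscuous = if (length(med)) naive_median(med) else NA_real_,
    p_ge2 = sum(counts >= 2) / length(counts),
    p_gt5 = sum(counts > 5) / length(counts)
  )
}

expect_summary_matches_naive <- function(summary, counts,
                                         threshold = 2,
                                         median_threshold = threshold) {
  ref <- naive_summary(counts, threshold, median_threshold)
  expect_identical(summary$n_compounds, as.integer(ref$n_compounds))
  expect_equal(summary$avg_all, ref$avg_all)
  expect_equal(summary$avg_promiscuous, ref$avg_promiscuous)
  expect_equal(as.numeric(summary$median_promiscuous),
               as.numeric(ref$median_promiscuous))
  expect_equal(summary$p_ge2, ref$p_ge2)
  expect_equal(summary$p_gt5, ref$p_gt5)
}
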