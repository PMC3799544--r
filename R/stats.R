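# Per-compound target counting and the core promiscuity statistics:
# averages, medians, probabilities of multi-target activity, family-scope
# classification, assay coverage, and the mixture identity that ties them
# together. A compound is promiscuous if it is annotated with at least two
# distinct targets after confidence filtering.

#' Count distinct targets per compound
#'
#' @param pairs compound-target pairs from [aggregate_pairs()] (deduplicated
#'   records also work: counting is over distinct target ids).
#' @return a tibble with one row per compound: `compound_id`,
#'   `measurement_type`, `n_targets` (distinct targets) and `families`
#'   (list-column with the set of family labels hit).
#' @export
count_targets <- function(pairs) {
  if (nrow(pairs) == 0) {
    return(tibble::tibble(
      compound_id = character(0), measurement_type = character(0),
      n_targets = integer(0), families = list()
    ))
  }
  pairs |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::summarise(
      measurement_type = dplyr::first(.data$measurement_type),
      n_targets = dplyr::n_distinct(.data$target_id),
      families = list(sort(unique(.data$target_family))),
      .groups = "drop"
    )
}

.empty_summary <- function(threshold = 2L, median_threshold = threshold) {
  tibble::tibble(
    n_compounds = 0L, avg_all = NA_real_,
    avg_promiscuous = NA_real_, median_promiscuous = NA_real_,
    p_ge2 = NA_real_, p_gt5 = NA_real_,
    threshold = as.integer(threshold),
    median_threshold = as.integer(median_threshold)
  )
}

#' Promiscuity summary statistics for a set of target counts
#'
#' Computes the statistic bundle reported per compound category: the mean
#' target count over all compounds (`avg_all`), the mean and median
#' restricted to promiscuous compounds (`n_targets >= threshold`), and the
#' probabilities of activity against two or more (`p_ge2`) and more than
#' five (`p_gt5`, strict) targets. With the default threshold of 2 the
#' exact mixture identity `avg_all = p_ge2 * avg_promiscuous + (1 - p_ge2)`
#' holds, because non-promiscuous compounds have exactly one target.
#'
#' The median of an even-sized set is the mean of the two middle values.
#' Some compound categories are conventionally summarised with a different
#' cutoff for the median (e.g. approved drugs with more than four targets);
#' `median_threshold` restricts the median only, leaving the promiscuous
#' mean and the mixture identity untouched.
#'
#' @param counts a target-count table from [count_targets()], or an integer
#'   vector of counts.
#' @param threshold minimum target count defining a promiscuous compound.
#' @param median_threshold minimum target count entering the median
#'   (defaults to `threshold`).
#' @return a one-row tibble; `n_compounds == 0` signals an empty summary,
#'   and promiscuous fields are `NA` (undefined, not zero) when no compound
#'   reaches the threshold.
#' @export
promiscuity_summary <- function(counts, threshold = 2L,
                                median_threshold = threshold) {
  n <- if (is.data.frame(counts)) counts$n_targets else as.integer(counts)
  threshold <- as.integer(threshold)
  median_threshold <- as.integer(median_threshold)
  if (threshold < 2L) abort("threshold must be >= 2")
  if (length(n) == 0) {
    return(.empty_summary(threshold, median_threshold))
  }
  if (any(is.na(n)) || any(n < 1L)) {
    abort("target counts must be >= 1 for every compound present")
  }
  prom <- n[n >= threshold]
  med_set <- n[n >= median_threshold]
  tibble::tibble(
    n_compounds = length(n),
    avg_all = mean(n),
    avg_promiscuous = if (length(prom) > 0) mean(prom) else NA_real_,
    median_promiscuous = if (length(med_set) > 0) median(med_set) else NA_real_,
    p_ge2 = mean(n >= 2L),
    p_gt5 = mean(n > 5L),
    threshold = threshold,
    median_threshold = median_threshold
  )
}

#' Reconstruct the overall average from the promiscuity mixture
#'
#' Every compound set splits into promiscuous compounds (>= 2 targets, mean
#' count m) and single-target compounds (exactly 1 target), so the overall
#' average target count is the mixture `p * m + (1 - p) * 1` where p is the
#' probability of promiscuity. This identity reconstructs printed overall
#' averages from printed probability/promiscuous-average pairs and serves
#' as an internal consistency check on every computed summary.
#'
#' @param p_ge2 probability of activity against two or more targets.
#' @param avg_promiscuous mean target count over promiscuous compounds
#'   (>= 2; may be `NA` when `p_ge2` is 0).
#' @return the implied overall average target count.
#' @export
mixture_identity <- function(p_ge2, avg_promiscuous) {
  if (any(is.na(p_ge2)) || any(p_ge2 < 0) || any(p_ge2 > 1)) {
    abort("p_ge2 must be a probability in [0, 1]")
  }
  avg <- avg_promiscuous
  bad <- p_ge2 > 0 & (is.na(avg) | avg < 2)
  if (any(bad)) {
    abort("avg_promiscuous must be >= 2 whenever p_ge2 > 0")
  }
  avg[p_ge2 == 0] <- 0  # unused term; avoids NA * 0
  p_ge2 * avg + (1 - p_ge2) * 1
}

#' Classify the family scope of each compound's activity
#'
#' Labels every compound `single` (one target), `intra_family` (two or more
#' targets, all from one family) or `cross_family` (targets from two or
#' more families), and tallies the three fractions. Intra-family
#' promiscuous compounds are candidates for privileged structures
#' preferentially active within a target family.
#'
#' @param counts target-count table from [count_targets()] (the `families`
#'   list-column is required).
#' @return a list with `labels` (tibble `compound_id`, `scope`) and
#'   `breakdown` (one-row tibble of the three fractions, summing to 1).
#' @export
classify_family_scope <- function(counts) {
  if (!"families" %in% names(counts)) {
    abort("counts must carry the 'families' list-column")
  }
  bad <- vapply(counts$families,
                function(f) length(f) == 0 || any(is.na(f) | f == ""),
                logical(1))
  if (any(bad)) {
    abort(sprintf("missing family label for target(s) of compound '%s'",
                  counts$compound_id[which(bad)[1]]))
  }
  nfam <- lengths(counts$families)
  scope <- ifelse(counts$n_targets == 1L, "single",
                  ifelse(nfam == 1L, "intra_family", "cross_family"))
  labels <- tibble::tibble(compound_id = counts$compound_id, scope = scope)
  n <- nrow(counts)
  breakdown <- tibble::tibble(
    frac_single = sum(scope == "single") / n,
    frac_intra_family = sum(scope == "intra_family") / n,
    frac_cross_family = sum(scope == "cross_family") / n
  )
  list(labels = labels, breakdown = breakdown)
}

# conventional median cutoffs per compound category
CATEGORY_MEDIAN_THRESHOLDS <- c(
  chembl = 2L, approved = 5L, experimental = 2L, screen_active = 3L
)

#' Target counts for drugs and for screening actives
#'
#' `drug_target_counts()` counts all annotated targets per drug (no
#' confidence filtering: every reported target category is taken into
#' account). `screen_target_counts()` counts, per compound with at least
#' one active confirmatory-assay outcome, the distinct targets of its
#' active assays.
#'
#' @param annotations drug-target annotations ([read_drug_annotations()]).
#' @param outcomes assay outcomes ([read_assay_outcomes()]).
#' @param status optionally restrict drugs to `approved` or `experimental`.
#' @return a target-count tibble (`compound_id`, `n_targets`).
#' @export
drug_target_counts <- function(annotations, status = NULL) {
  if (!is.null(status)) {
    if (!status %in% c("approved", "experimental")) {
      abort(sprintf("unknown drug status '%s'", status))
    }
    annotations <- annotations[annotations$drug_status == status, , drop = FALSE]
  }
  annotations |>
    dplyr::group_by(compound_id = .data$drug_id) |>
    dplyr::summarise(n_targets = dplyr::n_distinct(.data$target_id),
                     .groups = "drop")
}

#' @rdname drug_target_counts
#' @export
screen_target_counts <- function(outcomes) {
  active <- outcomes[outcomes$outcome == "active", , drop = FALSE]
  active |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::summarise(n_targets = dplyr::n_distinct(.data$target_id),
                     .groups = "drop")
}

#' Promiscuity summary for a compound category
#'
#' Convenience wrapper producing the per-category statistic bundle with the
#' category's conventional median cutoff: approved drugs with more than
#' four targets, experimental drugs with at least two, screening actives
#' with at least three, ChEMBL-style compounds with at least two.
#'
#' @param x drug annotations (for `approved`/`experimental`), assay
#'   outcomes (for `screen_active`) or a target-count table (for `chembl`).
#' @param category one of `chembl`, `approved`, `experimental`,
#'   `screen_active`.
#' @return a one-row summary tibble (see [promiscuity_summary()]).
#' @export
category_summary <- function(x, category) {
  if (!category %in% names(CATEGORY_MEDIAN_THRESHOLDS)) {
    abort(sprintf("unknown category '%s' (expected one of: %s)",
                  category,
                  paste(names(CATEGORY_MEDIAN_THRESHOLDS), collapse = ", ")))
  }
  counts <- switch(category,
    approved = drug_target_counts(x, "approved"),
    experimental = drug_target_counts(x, "experimental"),
    screen_active = screen_target_counts(x),
    chembl = if (is.data.frame(x) && "n_targets" %in% names(x)) x
             else count_targets(x)
  )
  promiscuity_summary(
    counts, threshold = 2L,
    median_threshold = CATEGORY_MEDIAN_THRESHOLDS[[category]]
  )
}

#' Assay coverage of confirmed active compounds
#'
#' Among compounds with at least one active confirmatory-assay outcome,
#' the fraction tested in strictly more than `min_assays` distinct assays.
#' Broad assay coverage is what makes screening actives a sound basis for
#' promiscuity assessment.
#'
#' @param outcomes assay outcomes ([read_assay_outcomes()]).
#' @param min_assays coverage cutoff (strict `>`).
#' @return a one-row tibble: `n_active_compounds`, `n_covered`, `fraction`.
#' @export
assay_coverage <- function(outcomes, min_assays = 50L) {
  active_ids <- unique(outcomes$compound_id[outcomes$outcome == "active"])
  if (length(active_ids) == 0) {
    return(tibble::tibble(n_active_compounds = 0L, n_covered = 0L,
                          fraction = NA_real_))
  }
  tested <- outcomes |>
    dplyr::filter(.data$compound_id %in% active_ids) |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::summarise(n_assays = dplyr::n_distinct(.data$assay_id),
                     .groups = "drop")
  covered <- sum(tested$n_assays > min_assays)
  tibble::tibble(
    n_active_compounds = length(active_ids),
    n_covered = covered,
    fraction = covered / length(active_ids)
  )
}
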