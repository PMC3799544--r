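# Seeded generator of synthetic activity tables, drug-target annotations
# and confirmatory-assay outcomes with the statistical structure the
# analysis assumes: per-compound target counts from a truncated-geometric
# (or explicit) law, same-family clustering of multi-target activity,
# log-normal potencies (normal on the pPotency scale), and normal
# molecular weights. Ground truth (true counts, family scope, profile
# flags) is carried alongside for recovery tests.

#' Target-count laws
#'
#' `count_law_geometric()` is a geometric law truncated to counts 1..K,
#' `P(k) proportional to (1-q)^(k-1)`: counts concentrate at 1-3 with a
#' thin tail, mirroring empirical bioactivity degree distributions.
#' `count_law_explicit()` takes an explicit probability vector over
#' arbitrary positive counts.
#'
#' @param q per-step success probability in (0, 1); larger q means fewer
#'   targets per compound.
#' @param K truncation point (maximum count).
#' @param probs probabilities (must sum to 1).
#' @param counts positive integer counts, one per probability.
#' @return a `count_law` list.
#' @export
count_law_geometric <- function(q = 0.62, K = 10L) {
  if (!is.numeric(q) || q <= 0 || q >= 1) abort("count law: q must be in (0, 1)")
  K <- as.integer(K)
  if (is.na(K) || K < 1L) abort("count law: K must be >= 1")
  structure(list(kind = "geometric", q = q, K = K), class = "count_law")
}

#' @rdname count_law_geometric
#' @export
count_law_explicit <- function(probs, counts = seq_along(probs)) {
  counts <- as.integer(counts)
  if (length(probs) != length(counts) || any(counts < 1L)) {
    abort("count law: counts must be positive integers, one per probability")
  }
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-9) {
    abort("count law: probs must be non-negative and sum to 1")
  }
  structure(list(kind = "explicit", probs = probs, counts = counts),
            class = "count_law")
}

# support and probabilities of a count law
.law_probs <- function(law) {
  stopifnot(inherits(law, "count_law"))
  if (law$kind == "geometric") {
    k <- seq_len(law$K)
    w <- (1 - law$q)^(k - 1)
    list(counts = k, probs = w / sum(w))
  } else {
    list(counts = law$counts, probs = law$probs)
  }
}

.sample_counts <- function(law, n) {
  lp <- .law_probs(law)
  if (length(lp$counts) == 1L) rep(lp$counts, n)
  else sample(lp$counts, n, replace = TRUE, prob = lp$probs)
}

#' Closed-form statistics of a target-count law
#'
#' Analytic mean, variance and tail probabilities of the configured
#' per-compound target-count law; the oracle against which pipeline
#' estimates are compared in parameter-recovery tests.
#'
#' @param x a `count_law` or a [synthetic_config()] (whose chembl target
#'   count law is used).
#' @return a list with `mean_n`, `var_n`, `p_ge2`, `p_gt5`.
#' @export
expected_statistics <- function(x) {
  law <- if (inherits(x, "synthetic_config")) x$target_count_law else x
  lp <- .law_probs(law)
  m <- sum(lp$counts * lp$probs)
  list(
    mean_n = m,
    var_n = sum((lp$counts - m)^2 * lp$probs),
    p_ge2 = sum(lp$probs[lp$counts >= 2]),
    p_gt5 = sum(lp$probs[lp$counts > 5])
  )
}

.default_family_sizes <- c(
  GPCR_A = 120L, kinase = 75L, ion_channel = 25L, protease = 90L,
  nuclear_receptor = 15L, other = 100L
)

#' Synthetic-dataset configuration
#'
#' Generative parameters for [generate_dataset()]. The defaults emulate a
#' high-confidence Ki/IC50 bioactivity extract: truncated-geometric target
#' counts with about 38% of compounds promiscuous and under 1% past five
#' targets, strong same-family clustering of additional targets (about
#' 36% intra-family vs 2% cross-family activity), potencies normal on the
#' pPotency scale around 100 nM, and molecular weights normal around 400
#' Da. Drug and screening sections use heavier count laws reflecting the
#' higher promiscuity of approved drugs and confirmed screening hits.
#'
#' @param n_compounds number of bioactive (ChEMBL-style) compounds.
#' @param n_targets_per_family named integer vector of targets per family.
#' @param target_count_law per-compound target-count law (`count_law`).
#' @param intra_family_bias probability that each additional target of a
#'   compound stays in its first target's family.
#' @param potency_mean_p,potency_sd_p normal law of true pPotencies.
#' @param mw_mean,mw_sd normal law of molecular weights (truncated > 0).
#' @param measurement_mix probabilities that a compound is measured by Ki
#'   only, IC50 only, or both (named, summing to 1).
#' @param replicate_prob probability that a measurement has a duplicate.
#' @param replicate_noise_sd pPotency noise of duplicates (0 = exact).
#' @param high_confidence_fraction fraction of records at confidence 9
#'   with the direct-interaction flag.
#' @param qualified_fraction fraction of records with a `<` qualifier
#'   instead of an explicit value.
#' @param n_drugs,approved_fraction drug section size and approved share.
#' @param approved_count_law,experimental_count_law drug target-count laws.
#' @param n_screen_compounds,n_assays,screen_count_law screening section:
#'   number of confirmed-active compounds, assay pool size and the law of
#'   active target counts.
#' @param assays_tested_meanlog,assays_tested_sdlog log-normal law of the
#'   number of assays a screening compound was tested in (defaults put
#'   roughly three quarters of compounds above 50 assays).
#' @param seed master seed; all sub-streams derive from it.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_compounds = 2000L,
                             n_targets_per_family = .default_family_sizes,
                             target_count_law = count_law_geometric(),
                             intra_family_bias = 0.97,
                             potency_mean_p = 7.0,
                             potency_sd_p = 1.0,
                             mw_mean = 400,
                             mw_sd = 100,
                             measurement_mix = c(Ki = 0.35, IC50 = 0.45,
                                                 both = 0.20),
                             replicate_prob = 0.2,
                             replicate_noise_sd = 0.2,
                             high_confidence_fraction = 0.9,
                             qualified_fraction = 0.02,
                             n_drugs = 300L,
                             approved_fraction = 0.25,
                             approved_count_law = count_law_geometric(0.17, 30L),
                             experimental_count_law = count_law_geometric(0.56, 30L),
                             n_screen_compounds = 400L,
                             n_assays = 1085L,
                             screen_count_law = count_law_geometric(0.49, 20L),
                             assays_tested_meanlog = log(80),
                             assays_tested_sdlog = 0.6,
                             seed = 1L) {
  .check_count <- function(x, name, min = 1) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min) {
      abort(sprintf("invalid config field '%s'", name))
    }
  }
  .check_prob <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
      abort(sprintf("invalid config field '%s' (probability expected)", name))
    }
  }
  .check_count(n_compounds, "n_compounds")
  .check_count(n_drugs, "n_drugs", min = 0)
  .check_count(n_screen_compounds, "n_screen_compounds", min = 0)
  .check_count(n_assays, "n_assays")
  if (length(n_targets_per_family) == 0 || is.null(names(n_targets_per_family)) ||
      any(n_targets_per_family < 1)) {
    abort("invalid config field 'n_targets_per_family' (named positive sizes)")
  }
  for (law in list(target_count_law, approved_count_law,
                   experimental_count_law, screen_count_law)) {
    if (!inherits(law, "count_law")) {
      abort("invalid config field: count laws must be built with count_law_geometric() or count_law_explicit()")
    }
  }
  .check_prob(intra_family_bias, "intra_family_bias")
  .check_prob(replicate_prob, "replicate_prob")
  .check_prob(high_confidence_fraction, "high_confidence_fraction")
  .check_prob(qualified_fraction, "qualified_fraction")
  .check_prob(approved_fraction, "approved_fraction")
  if (length(measurement_mix) != 3 ||
      !setequal(names(measurement_mix), c("Ki", "IC50", "both")) ||
      any(measurement_mix < 0) || abs(sum(measurement_mix) - 1) > 1e-9) {
    abort("invalid config field 'measurement_mix' (Ki/IC50/both probabilities summing to 1)")
  }
  if (potency_sd_p < 0 || replicate_noise_sd < 0 || mw_sd < 0) {
    abort("invalid config field: standard deviations must be >= 0")
  }
  if (mw_mean <= 0) abort("invalid config field 'mw_mean'")
  max_k <- max(.law_probs(target_count_law)$counts)
  if (max_k > sum(n_targets_per_family)) {
    abort("invalid config: target_count_law exceeds the total number of targets")
  }
  structure(
    list(
      n_compounds = as.integer(n_compounds),
      n_targets_per_family = n_targets_per_family,
      target_count_law = target_count_law,
      intra_family_bias = intra_family_bias,
      potency_mean_p = potency_mean_p, potency_sd_p = potency_sd_p,
      mw_mean = mw_mean, mw_sd = mw_sd,
      measurement_mix = measurement_mix[c("Ki", "IC50", "both")],
      replicate_prob = replicate_prob,
      replicate_noise_sd = replicate_noise_sd,
      high_confidence_fraction = high_confidence_fraction,
      qualified_fraction = qualified_fraction,
      n_drugs = as.integer(n_drugs),
      approved_fraction = approved_fraction,
      approved_count_law = approved_count_law,
      experimental_count_law = experimental_count_law,
      n_screen_compounds = as.integer(n_screen_compounds),
      n_assays = as.integer(n_assays),
      screen_count_law = screen_count_law,
      assays_tested_meanlog = assays_tested_meanlog,
      assays_tested_sdlog = assays_tested_sdlog,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

# deterministic sub-stream seed, keeping sections independent of each other
.sub_seed <- function(seed, section) {
  (as.numeric(seed) * 7919 + section * 104729) %% 2147483647
}

# normal truncated to (0, Inf) by resampling
.rnorm_pos <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  while (any(x <= 0)) {
    bad <- x <= 0
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  x
}

#' Generate a synthetic bioactivity dataset
#'
#' Produces, deterministically for a fixed seed, the four tables the
#' pipeline consumes (activity records, compound metadata, drug-target
#' annotations, assay outcomes) plus ground truth for recovery tests:
#' each bioactive compound's true target count and family scope, and the
#' per-measurement-type profile flags implied by its true potencies
#' (computed here with plain arithmetic, independently of the pipeline
#' operations they are later checked against).
#'
#' @param config a [synthetic_config()].
#' @return a list with `activities`, `meta`, `drugs`, `assays`,
#'   `ground_truth` (list of `compounds` and `profiles` tibbles), and the
#'   `config` used.
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  fams <- names(config$n_targets_per_family)
  fam_targets <- lapply(fams, function(f) {
    sprintf("T_%s_%03d", f, seq_len(config$n_targets_per_family[[f]]))
  })
  names(fam_targets) <- fams
  all_targets <- unlist(fam_targets, use.names = FALSE)
  target_family <- rep(fams, times = lengths(fam_targets))
  other_targets <- lapply(fams, function(f) {
    which(target_family != f)  # indices into all_targets
  })
  names(other_targets) <- fams

  chembl <- .generate_chembl(config, fams, fam_targets, all_targets,
                             target_family, other_targets)
  drugs <- .generate_drugs(config, all_targets)
  assays <- .generate_assays(config, all_targets)

  list(
    activities = chembl$activities,
    meta = chembl$meta,
    drugs = drugs,
    assays = assays,
    ground_truth = list(compounds = chembl$truth_compounds,
                        profiles = chembl$truth_profiles),
    config = config
  )
}

.generate_chembl <- function(config, fams, fam_targets, all_targets,
                             target_family, other_targets) {
  set.seed(.sub_seed(config$seed, 1))
  n <- config$n_compounds
  cid <- sprintf("CPD_%05d", seq_len(n))

  k <- .sample_counts(config$target_count_law, n)
  prim <- sample(fams, n, replace = TRUE,
                 prob = config$n_targets_per_family)
  # number of targets kept in the primary family (first target always is);
  # capped by the family size, surplus spills to other families
  m_in <- 1L + rbinom(n, k - 1L, config$intra_family_bias)
  cap <- config$n_targets_per_family[prim]
  m_in <- pmin(m_in, cap, k)
  n_out <- k - m_in

  target_sets <- lapply(seq_len(n), function(i) {
    inside <- sample(fam_targets[[prim[i]]], m_in[i])
    outside <- if (n_out[i] > 0) {
      all_targets[sample(other_targets[[prim[i]]], n_out[i])]
    } else character(0)
    c(inside, outside)
  })

  mix <- sample(c("Ki", "IC50", "both"), n, replace = TRUE,
                prob = config$measurement_mix)
  has_ki <- mix %in% c("Ki", "both")
  has_ic50 <- mix %in% c("IC50", "both")

  fam_of <- setNames(target_family, all_targets)
  base <- tibble::tibble(
    compound_id = rep(cid, times = k),
    target_id = unlist(target_sets, use.names = FALSE)
  )
  base$target_family <- unname(fam_of[base$target_id])

  # expand to one row per (pair, measurement type present for the compound)
  row_cpd <- rep(seq_len(n), times = k)
  ki_rows <- base[has_ki[row_cpd], , drop = FALSE]
  ic_rows <- base[has_ic50[row_cpd], , drop = FALSE]
  ki_rows$measurement_type <- "Ki"
  ic_rows$measurement_type <- "IC50"
  pairs <- dplyr::bind_rows(ki_rows, ic_rows)
  pairs$true_p <- rnorm(nrow(pairs), config$potency_mean_p,
                        config$potency_sd_p)

  # measurement records: original + optional noisy duplicate
  dup <- runif(nrow(pairs)) < config$replicate_prob
  records <- dplyr::bind_rows(pairs, pairs[dup, , drop = FALSE])
  noise <- c(rep(0, nrow(pairs)),
             rnorm(sum(dup), 0, config$replicate_noise_sd))
  records$value_nM <- potency_nM(records$true_p + noise)
  high <- runif(nrow(records)) < config$high_confidence_fraction
  records$confidence_level <- ifelse(high, 9L,
                                     sample(4:8, nrow(records), replace = TRUE))
  records$direct_interaction <- high
  records$relation <- ifelse(runif(nrow(records)) < config$qualified_fraction,
                             "lt", "eq")
  records$source <- "chembl_like"
  records$true_p <- NULL
  records <- records[, c("compound_id", "target_id", "target_family",
                         "measurement_type", "value_nM", "relation",
                         "confidence_level", "direct_interaction", "source")]
  records <- dplyr::arrange(records, .data$compound_id, .data$target_id,
                            .data$measurement_type, .data$value_nM)

  meta <- tibble::tibble(
    compound_id = cid,
    mw = round(.rnorm_pos(n, config$mw_mean, config$mw_sd), 1),
    category = "bioactive"
  )

  truth_compounds <- tibble::tibble(
    compound_id = cid,
    n_targets = as.integer(k),
    scope = ifelse(k == 1L, "single",
                   ifelse(n_out == 0L, "intra_family", "cross_family"))
  )
  truth_profiles <- .true_profiles(pairs)

  list(activities = records, meta = meta,
       truth_compounds = truth_compounds, truth_profiles = truth_profiles)
}

# ground-truth profile flags from true potencies, by plain arithmetic
# against the default rule constants (2-5 targets, < 1000 nM, spread <= 2
# log units; outlier: best <= 100 nM, others >= 10 uM)
.true_profiles <- function(pairs) {
  key <- paste(pairs$compound_id, pairs$measurement_type, sep = "\r")
  ord <- order(key, pairs$true_p)
  keyo <- key[ord]
  p <- pairs$true_p[ord]
  fam <- pairs$target_family[ord]
  r <- rle(keyo)
  n <- r$lengths
  ends <- cumsum(n)
  starts <- ends - n + 1L
  gi <- rep.int(seq_along(n), n)
  nfam <- as.vector(rowsum(
    as.integer(!duplicated(paste(keyo, fam, sep = "\r"))), gi
  ))
  minp <- p[starts]            # weakest (sorted ascending in p)
  maxp <- p[ends]              # most potent
  spread <- maxp - minp
  # best (lowest-nM) potency is the largest p; the second-best decides
  # whether every other target is weak
  best_nM <- 10^(9 - maxp)
  second_nM <- ifelse(n >= 2L, 10^(9 - p[pmax(ends - 1L, 1L)]), NA_real_)
  out <- tibble::tibble(
    compound_id = pairs$compound_id[ord][starts],
    measurement_type = pairs$measurement_type[ord][starts],
    n_targets = as.integer(n),
    spread_log = spread,
    all_sub_uM = minp > 6,
    same_family = nfam == 1L,
    matches_prevalent = n >= 2L & n <= 5L & minp > 6 & nfam == 1L &
      spread <= 2.0,
    within_one_log = spread <= 1.0,
    selectivity_outlier = best_nM <= 100 & second_nM >= 10000
  )
  out[out$n_targets >= 2L, , drop = FALSE]
}

.generate_drugs <- function(config, all_targets) {
  set.seed(.sub_seed(config$seed, 2))
  n <- config$n_drugs
  if (n == 0) {
    return(tibble::tibble(drug_id = character(0), drug_status = character(0),
                          target_id = character(0)))
  }
  status <- ifelse(runif(n) < config$approved_fraction,
                   "approved", "experimental")
  counts <- integer(n)
  counts[status == "approved"] <-
    .sample_counts(config$approved_count_law, sum(status == "approved"))
  counts[status == "experimental"] <-
    .sample_counts(config$experimental_count_law, sum(status == "experimental"))
  counts <- pmin(counts, length(all_targets))
  did <- sprintf("DRG_%04d", seq_len(n))
  tibble::tibble(
    drug_id = rep(did, times = counts),
    drug_status = rep(status, times = counts),
    target_id = unlist(lapply(counts, function(m) sample(all_targets, m)),
                       use.names = FALSE)
  )
}

.generate_assays <- function(config, all_targets) {
  set.seed(.sub_seed(config$seed, 3))
  n <- config$n_screen_compounds
  if (n == 0) {
    return(tibble::tibble(compound_id = character(0), assay_id = character(0),
                          target_id = character(0), outcome = character(0)))
  }
  n_assays <- config$n_assays
  assay_id <- sprintf("AID_%04d", seq_len(n_assays))
  # each confirmatory assay interrogates one target
  assay_target <- sample(rep(all_targets, length.out = n_assays))
  sid <- sprintf("SCR_%05d", seq_len(n))
  a <- .sample_counts(config$screen_count_law, n)  # active target counts
  tested_n <- pmin(pmax(
    round(rlnorm(n, config$assays_tested_meanlog, config$assays_tested_sdlog)),
    a, 1L), n_assays)
  rows <- lapply(seq_len(n), function(i) {
    tested <- sample(n_assays, tested_n[i])
    # mark active the first assays hitting distinct targets, up to a[i]
    first_hit <- !duplicated(assay_target[tested])
    active_pos <- which(first_hit)[seq_len(min(a[i], sum(first_hit)))]
    outcome <- rep("inactive", length(tested))
    outcome[active_pos] <- "active"
    tibble::tibble(
      compound_id = sid[i],
      assay_id = assay_id[tested],
      target_id = assay_target[tested],
      outcome = outcome
    )
  })
  dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$compound_id, .data$assay_id)
}

#' Write a synthetic dataset to disk
#'
#' Emits the four input tables (and the ground-truth compound table, for
#' reference) as TSVs that the package readers ingest. Output is
#' byte-identical across runs with the same config.
#'
#' @param dataset result of [generate_dataset()].
#' @param dir output directory, created if needed.
#' @return the directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_activity_table(dataset$activities, file.path(dir, "activities.tsv"))
  write_compound_meta(dataset$meta, file.path(dir, "compound_meta.tsv"))
  write_drug_annotations(dataset$drugs, file.path(dir, "drug_annotations.tsv"))
  write_assay_outcomes(dataset$assays, file.path(dir, "assay_outcomes.tsv"))
  readr::write_tsv(dataset$ground_truth$compounds,
                   file.path(dir, "synthetic_ground_truth.tsv"),
                   progress = FALSE)
  invisible(dir)
}
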