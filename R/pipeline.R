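# End-to-end orchestration: read -> filter -> split -> aggregate -> count
# -> summarise -> stratify -> profile -> report, with per-stage logging
# and stage-named errors, plus the internal consistency check that every
# emitted summary satisfies the promiscuity mixture identity.

.stage <- function(name, expr, verbose = FALSE) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)))
  })
}

.maybe_read <- function(x, reader, stage_name) {
  if (is.null(x) || is.data.frame(x)) return(x)
  if (is.character(x) && length(x) == 1) {
    return(.stage(stage_name, reader(x)))
  }
  abort(sprintf("pipeline stage '%s': expected a file path or a data frame",
                stage_name))
}

#' Run the full promiscuity-analysis pipeline
#'
#' Takes activity records (and optionally compound metadata, drug-target
#' annotations and assay outcomes), applies confidence filtering, splits
#' into Ki and IC50 subsets, aggregates replicates, counts targets per
#' compound, and produces the complete report bundle: per-category
#' summaries, per-family and per-MW-bin stratifications, family-scope
#' breakdowns, profile prevalence, assay coverage, and the consistency
#' check results. Inputs may be tibbles or file paths. Any stage failure
#' raises an error naming the stage.
#'
#' @param activities activity records or a path ([read_activity_table()]).
#' @param meta optional compound metadata or path ([read_compound_meta()]).
#' @param drugs optional drug annotations or path ([read_drug_annotations()]).
#' @param assays optional assay outcomes or path ([read_assay_outcomes()]).
#' @param criteria confidence [filter_criteria()].
#' @param bins molecular-weight bins ([mw_bins()]).
#' @param rule prevalent-profile [profile_rule()].
#' @param out_dir if non-NULL, report tables are written here.
#' @param seed recorded in the provenance block (the analysis itself is
#'   deterministic).
#' @param verbose log per-stage record counts?
#' @return a `promiscuity_report` bundle (list of summary tibbles,
#'   per-subset details in `$subsets`, provenance and consistency checks).
#' @export
run_pipeline <- function(activities, meta = NULL, drugs = NULL, assays = NULL,
                         criteria = filter_criteria(), bins = mw_bins(),
                         rule = profile_rule(), out_dir = NULL, seed = NULL,
                         verbose = FALSE) {
  input_paths <- list(
    activities = if (is.character(activities)) activities else "<in-memory>",
    meta = if (is.character(meta)) meta else if (is.null(meta)) NULL else "<in-memory>",
    drugs = if (is.character(drugs)) drugs else if (is.null(drugs)) NULL else "<in-memory>",
    assays = if (is.character(assays)) assays else if (is.null(assays)) NULL else "<in-memory>"
  )
  activities <- .maybe_read(activities, read_activity_table, "read")
  meta <- .maybe_read(meta, read_compound_meta, "read")
  drugs <- .maybe_read(drugs, read_drug_annotations, "read")
  assays <- .maybe_read(assays, read_assay_outcomes, "read")
  log <- function(fmt, ...) if (verbose) inform(sprintf(fmt, ...))
  log("read: %d activity records", nrow(activities))

  filtered <- .stage("filter", filter_high_confidence(activities, criteria))
  log("filter: %d of %d records kept", nrow(filtered), nrow(activities))

  subsets <- .stage("split", split_by_measurement(filtered))
  log("split: %d Ki / %d IC50 records", nrow(subsets$Ki), nrow(subsets$IC50))

  per_subset <- lapply(names(subsets), function(type) {
    pairs <- .stage("aggregate", aggregate_pairs(subsets[[type]]))
    counts <- .stage("count", count_targets(pairs))
    summary <- .stage("summarize", promiscuity_summary(counts))
    scope <- if (nrow(counts) > 0) {
      .stage("summarize", classify_family_scope(counts))
    } else NULL
    families <- .stage("stratify", stratify_by_families(pairs))
    mw <- if (!is.null(meta) && nrow(counts) > 0) {
      .stage("stratify", stratify_by_mw(counts, meta, bins))
    } else NULL
    assessments <- .stage("profile", assess_profiles(pairs, rule))
    log("%s: %d pairs, %d compounds, %d promiscuous assessed",
        type, nrow(pairs), nrow(counts), nrow(assessments))
    list(measurement_type = type, pairs = pairs, counts = counts,
         summary = summary, scope = scope, families = families, mw = mw,
         assessments = assessments)
  })
  names(per_subset) <- names(subsets)

  with_type <- function(element) {
    dplyr::bind_rows(lapply(per_subset, function(s) {
      x <- s[[element]]
      if (is.null(x) || nrow(x) == 0) return(NULL)
      dplyr::bind_cols(tibble::tibble(measurement_type = s$measurement_type), x)
    }))
  }

  category_summaries <- dplyr::bind_rows(
    dplyr::bind_rows(lapply(per_subset, function(s) {
      if (s$summary$n_compounds == 0) return(NULL)
      dplyr::bind_cols(
        tibble::tibble(category = "bioactive",
                       measurement_type = s$measurement_type),
        s$summary
      )
    })),
    if (!is.null(drugs)) dplyr::bind_rows(lapply(
      c("approved", "experimental"), function(st) {
        dplyr::bind_cols(
          tibble::tibble(category = paste0(st, "_drug"),
                         measurement_type = NA_character_),
          .stage("summarize", category_summary(drugs, st))
        )
      })),
    if (!is.null(assays)) dplyr::bind_cols(
      tibble::tibble(category = "screen_active",
                     measurement_type = NA_character_),
      .stage("summarize", category_summary(assays, "screen_active"))
    )
  )

  family_summaries <- with_type("families")
  mw_summaries <- with_type("mw")
  scope_breakdown <- dplyr::bind_rows(lapply(per_subset, function(s) {
    if (is.null(s$scope)) return(NULL)
    dplyr::bind_cols(
      tibble::tibble(measurement_type = s$measurement_type),
      s$scope$breakdown
    )
  }))
  prevalence <- dplyr::bind_rows(lapply(per_subset, function(s) {
    if (s$summary$n_compounds == 0) return(NULL)
    dplyr::bind_cols(
      tibble::tibble(measurement_type = s$measurement_type),
      profile_prevalence(s$assessments)
    )
  }))
  coverage <- if (!is.null(assays)) {
    .stage("summarize", assay_coverage(assays))
  } else NULL

  bundle <- structure(
    list(
      category_summaries = category_summaries,
      family_summaries = family_summaries,
      mw_summaries = mw_summaries,
      scope_breakdown = scope_breakdown,
      profile_prevalence = prevalence,
      assay_coverage = coverage,
      subsets = per_subset,
      provenance = list(
        inputs = input_paths,
        criteria = unclass(criteria),
        bins = bins$label,
        rule = unclass(rule),
        seed = seed,
        tool = paste0("promiscuitr ",
                      as.character(utils::packageVersion("promiscuitr")))
      )
    ),
    class = "promiscuity_report"
  )
  bundle$consistency <- .stage("report", verify_consistency(bundle))
  if (!all(bundle$consistency$pass)) {
    abort("pipeline stage 'report' failed: mixture identity violated in a summary")
  }
  if (!is.null(out_dir)) {
    .stage("report", write_report_tables(bundle, out_dir))
    log("report: written to %s", out_dir)
  }
  bundle
}

#' Simulate and analyse a synthetic dataset
#'
#' Generates a synthetic dataset from a config, optionally writes the
#' input tables, and runs the full pipeline on them. Two runs with the
#' same config produce byte-identical tables and reports.
#'
#' @param config a [synthetic_config()].
#' @param out_dir if non-NULL, input tables go to `out_dir/data` and
#'   report tables to `out_dir/report`.
#' @param ... passed to [run_pipeline()].
#' @return the report bundle, with the dataset attached as `$dataset`.
#' @export
simulate_pipeline <- function(config = synthetic_config(), out_dir = NULL,
                              ...) {
  ds <- generate_dataset(config)
  if (!is.null(out_dir)) {
    write_dataset(ds, file.path(out_dir, "data"))
  }
  bundle <- run_pipeline(
    ds$activities, meta = ds$meta, drugs = ds$drugs, assays = ds$assays,
    out_dir = if (is.null(out_dir)) NULL else file.path(out_dir, "report"),
    seed = config$seed, ...
  )
  bundle$dataset <- ds
  bundle
}

#' Verify the mixture identity across a report bundle
#'
#' Recomputes, for every summary row in the bundle with the standard
#' promiscuity threshold of 2, the overall average target count from the
#' probability of promiscuity and the promiscuous-only average via
#' [mixture_identity()], and reports the absolute gap to the stored
#' `avg_all`. Gaps must be below 1e-9 on unrounded values.
#'
#' @param bundle a `promiscuity_report` (or any tibble with `avg_all`,
#'   `p_ge2`, `avg_promiscuous`, `threshold` columns).
#' @param tol maximum tolerated absolute gap.
#' @return a tibble with one row per checked summary: `table`, `row`,
#'   `avg_all`, `reconstructed`, `gap`, `pass`.
#' @export
verify_consistency <- function(bundle, tol = 1e-9) {
  tables <- if (inherits(bundle, "promiscuity_report")) {
    list(category = bundle$category_summaries,
         family = bundle$family_summaries,
         mw_bin = bundle$mw_summaries)
  } else {
    list(summary = bundle)
  }
  proto <- tibble::tibble(
    table = character(0), row = integer(0), avg_all = numeric(0),
    reconstructed = numeric(0), gap = numeric(0), pass = logical(0)
  )
  out <- lapply(names(tables), function(tab) {
    df <- tables[[tab]]
    if (is.null(df) || nrow(df) == 0) return(NULL)
    df <- df[df$threshold == 2L & df$n_compounds > 0, , drop = FALSE]
    if (nrow(df) == 0) return(NULL)
    recon <- mixture_identity(
      df$p_ge2,
      ifelse(df$p_ge2 > 0, df$avg_promiscuous, NA_real_)
    )
    tibble::tibble(
      table = tab,
      row = seq_len(nrow(df)),
      avg_all = df$avg_all,
      reconstructed = recon,
      gap = abs(df$avg_all - recon),
      pass = abs(df$avg_all - recon) < tol
    )
  })
  dplyr::bind_rows(c(list(proto), out))
}
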