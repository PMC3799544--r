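# Writers. Record tables round-trip through the corresponding readers
# field-for-field; report tables follow the fixed rounding contract
# (averages to one decimal, probabilities to one-decimal percent) while the
# accompanying JSON keeps full precision.

.write_delim_by_ext <- function(df, path) {
  if (.delim_for(path) == ",") {
    readr::write_csv(df, path, progress = FALSE)
  } else {
    readr::write_tsv(df, path, progress = FALSE)
  }
  invisible(path)
}

#' Write record tables
#'
#' Counterparts of the readers in this package: each writes a `.tsv` or
#' `.csv` (by extension) that the corresponding `read_*()` reproduces
#' field-for-field. Activity potencies are written in nM.
#'
#' @param records,annotations,outcomes,meta tibbles as returned by the
#'   corresponding readers (or by [generate_dataset()]).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_activity_table <- function(records, path) {
  out <- tibble::tibble(
    compound_id = records$compound_id,
    target_id = records$target_id,
    target_family = records$target_family,
    measurement_type = records$measurement_type,
    value = records$value_nM,
    unit = rep("nM", nrow(records)),
    relation = records$relation,
    confidence_level = records$confidence_level,
    direct_interaction = tolower(as.character(records$direct_interaction))
  )
  .write_delim_by_ext(out, path)
}

#' @rdname write_activity_table
#' @export
write_drug_annotations <- function(annotations, path) {
  .write_delim_by_ext(
    annotations[, c("drug_id", "drug_status", "target_id")], path
  )
}

#' @rdname write_activity_table
#' @export
write_assay_outcomes <- function(outcomes, path) {
  .write_delim_by_ext(
    outcomes[, c("compound_id", "assay_id", "target_id", "outcome")], path
  )
}

#' @rdname write_activity_table
#' @export
write_compound_meta <- function(meta, path) {
  .write_delim_by_ext(meta[, c("compound_id", "mw", "category")], path)
}

# one-decimal fixed formatting for report cells ("1.7", "2.0"); NA -> ""
.fmt1 <- function(x) ifelse(is.na(x), "", formatC(x, format = "f", digits = 1))

.round_avg_table <- function(df) {
  for (col in intersect(c("avg_all", "avg_promiscuous", "median_promiscuous"),
                        names(df))) {
    df[[col]] <- .fmt1(df[[col]])
  }
  df[, setdiff(names(df), c("p_ge2", "p_gt5")), drop = FALSE]
}

.prob_table <- function(df, id_cols) {
  out <- df[, c(id_cols, "n_compounds", "p_ge2", "p_gt5"), drop = FALSE]
  out$p_ge2_pct <- .fmt1(100 * out$p_ge2)
  out$p_gt5_pct <- .fmt1(100 * out$p_gt5)
  out[, c(id_cols, "n_compounds", "p_ge2_pct", "p_gt5_pct"), drop = FALSE]
}

# header-only summary prototypes for tables empty at run time
.ensure_summary <- function(df, proto) {
  if (!is.null(df) && nrow(df) > 0) return(df)
  dplyr::bind_cols(proto, .empty_summary()[0, , drop = FALSE])
}

#' Write the report tables of a pipeline run
#'
#' Emits one TSV per report table (category averages and probabilities,
#' per-family and per-MW-bin analogues, profile prevalence) plus
#' `report.json` with every value at full precision. TSV averages are
#' rounded to one decimal and probabilities to one-decimal percentages;
#' the JSON is the authoritative, unrounded record.
#'
#' @param bundle a report bundle from [run_pipeline()].
#' @param out_dir output directory, created if needed.
#' @return the vector of files written, invisibly.
#' @export
write_report_tables <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "promiscuity_report"))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok || file.access(out_dir, mode = 2) != 0) {
    abort(sprintf("cannot write to output directory '%s'", out_dir))
  }
  files <- c(
    table1_category_averages      = "table1_category_averages.tsv",
    table2_category_probabilities = "table2_category_probabilities.tsv",
    table3_family_averages        = "table3_family_averages.tsv",
    table4_family_probabilities   = "table4_family_probabilities.tsv",
    table5_mw_averages            = "table5_mw_averages.tsv",
    table6_mw_probabilities       = "table6_mw_probabilities.tsv",
    profile_prevalence            = "profile_prevalence.tsv"
  )
  paths <- file.path(out_dir, files)
  names(paths) <- names(files)

  cat_id <- c("category", "measurement_type")
  fam_id <- c("measurement_type", "family", "n_targets_in_family")
  mw_id <- c("measurement_type", "mw_bin")
  cat_tab <- .ensure_summary(
    bundle$category_summaries,
    tibble::tibble(category = character(0), measurement_type = character(0))
  )
  fam_tab <- .ensure_summary(
    bundle$family_summaries,
    tibble::tibble(measurement_type = character(0), family = character(0),
                   n_targets_in_family = integer(0))
  )
  mw_tab <- .ensure_summary(
    bundle$mw_summaries,
    tibble::tibble(measurement_type = character(0), mw_bin = character(0))
  )

  readr::write_tsv(.round_avg_table(cat_tab),
                   paths["table1_category_averages"], progress = FALSE)
  readr::write_tsv(.prob_table(cat_tab, cat_id),
                   paths["table2_category_probabilities"], progress = FALSE)
  readr::write_tsv(.round_avg_table(fam_tab),
                   paths["table3_family_averages"], progress = FALSE)
  readr::write_tsv(.prob_table(fam_tab, fam_id),
                   paths["table4_family_probabilities"], progress = FALSE)
  readr::write_tsv(.round_avg_table(mw_tab),
                   paths["table5_mw_averages"], progress = FALSE)
  readr::write_tsv(.prob_table(mw_tab, mw_id),
                   paths["table6_mw_probabilities"], progress = FALSE)
  readr::write_tsv(bundle$profile_prevalence %||%
                     tibble::tibble(n_promiscuous = integer(0)),
                   paths["profile_prevalence"], progress = FALSE)

  json_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(
    list(
      category_summaries = bundle$category_summaries,
      family_summaries = bundle$family_summaries,
      mw_summaries = bundle$mw_summaries,
      profile_prevalence = bundle$profile_prevalence,
      assay_coverage = bundle$assay_coverage,
      consistency = bundle$consistency,
      provenance = bundle$provenance
    ),
    json_path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  invisible(c(paths, report_json = json_path))
}
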