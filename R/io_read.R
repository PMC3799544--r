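# Readers for the three flat-table schemas the pipeline consumes:
# ChEMBL-style activity records, DrugBank-style drug-target annotations and
# PubChem-style confirmatory-assay outcomes, plus per-compound metadata.
# All readers auto-detect the delimiter from the file extension (.tsv -> tab,
# .csv -> comma), validate the header, and report offending file lines
# (header = line 1) for row-level problems.

.delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

.read_raw_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("input file does not exist: '%s'", path))
  }
  readr::read_delim(
    path,
    delim = .delim_for(path),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE,
    show_col_types = FALSE
  )
}

.require_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "schema error in '%s': missing required column(s): %s",
      path, paste(missing, collapse = ", ")
    ))
  }
}

# file line number of data row i (header occupies line 1)
.file_line <- function(i) i + 1L

.parse_enum <- function(x, levels, column, path) {
  bad <- which(!is.na(x) & !(x %in% levels))
  if (length(bad) > 0) {
    abort(sprintf(
      "invalid %s '%s' on line %d of '%s' (expected one of: %s)",
      column, x[bad[1]], .file_line(bad[1]), path,
      paste(levels, collapse = ", ")
    ))
  }
  x
}

.parse_logical <- function(x, column, path) {
  out <- rep(NA, length(x))
  out[tolower(x) %in% c("true", "t", "1", "yes")] <- TRUE
  out[tolower(x) %in% c("false", "f", "0", "no")] <- FALSE
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0) {
    abort(sprintf(
      "invalid %s '%s' on line %d of '%s' (expected true/false)",
      column, x[bad[1]], .file_line(bad[1]), path
    ))
  }
  out
}

#' Read a compound-target activity table
#'
#' Reads a ChEMBL-style activity table with one measured compound-target
#' interaction per row. Potency values are normalised to nM using the `unit`
#' column (accepted units: `nM`, `uM`/`µM`, `mM`, `M`). Row order is
#' preserved; rows that are identical in every field are collapsed silently,
#' while rows sharing compound, target and measurement type but differing in
#' value are kept as replicates for the aggregation stage.
#'
#' Expected columns: `compound_id`, `target_id`, `target_family`,
#' `measurement_type` (`Ki`/`IC50`/`other`), `value` (positive number),
#' `unit`, `relation` (`eq`/`lt`/`gt`), `confidence_level` (integer 0-9),
#' `direct_interaction` (true/false).
#'
#' @param path path to a `.tsv` or `.csv` file with a header row.
#' @param source provenance tag attached to every record.
#' @return a tibble of activity records with potencies in `value_nM`.
#' @export
read_activity_table <- function(path,
                                source = c("chembl_like", "pubchem_like",
                                           "drugbank_like")) {
  source <- match.arg(source)
  raw <- .read_raw_table(path)
  .require_columns(raw, c(
    "compound_id", "target_id", "target_family", "measurement_type",
    "value", "unit", "relation", "confidence_level", "direct_interaction"
  ), path)
  if (nrow(raw) == 0) {
    return(.empty_activity_records(source))
  }

  value <- suppressWarnings(as.numeric(raw$value))
  bad <- which(is.na(value) | value <= 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "invalid potency value '%s' on line %d of '%s' (must be a positive number)",
      raw$value[bad[1]], .file_line(bad[1]), path
    ))
  }
  factor <- .unit_to_nM(raw$unit)
  bad <- which(is.na(factor))
  if (length(bad) > 0) {
    abort(sprintf(
      "unknown unit '%s' on line %d of '%s' (accepted: nM, uM, mM, M)",
      raw$unit[bad[1]], .file_line(bad[1]), path
    ))
  }
  .parse_enum(raw$measurement_type, MEASUREMENT_LEVELS, "measurement_type", path)
  .parse_enum(raw$relation, RELATION_LEVELS, "relation", path)
  conf <- suppressWarnings(as.integer(raw$confidence_level))
  bad <- which(is.na(conf) | conf < 0L | conf > 9L)
  if (length(bad) > 0) {
    abort(sprintf(
      "invalid confidence_level '%s' on line %d of '%s' (integer 0-9 expected)",
      raw$confidence_level[bad[1]], .file_line(bad[1]), path
    ))
  }
  direct <- .parse_logical(raw$direct_interaction, "direct_interaction", path)

  records <- tibble::tibble(
    compound_id = raw$compound_id,
    target_id = raw$target_id,
    target_family = raw$target_family,
    measurement_type = raw$measurement_type,
    value_nM = value * factor,
    relation = raw$relation,
    confidence_level = conf,
    direct_interaction = direct,
    source = source
  )
  dplyr::distinct(records)
}

.empty_activity_records <- function(source = character(0)) {
  tibble::tibble(
    compound_id = character(0), target_id = character(0),
    target_family = character(0), measurement_type = character(0),
    value_nM = numeric(0), relation = character(0),
    confidence_level = integer(0), direct_interaction = logical(0),
    source = character(0)
  )
}

#' Read drug-target annotations
#'
#' Reads a DrugBank-style annotation table (`drug_id`, `drug_status`,
#' `target_id`), with `drug_status` either `approved` or `experimental`.
#' Duplicate (drug, target) rows are collapsed to one with a warning.
#'
#' @param path path to a `.tsv` or `.csv` file.
#' @return a tibble of unique drug-target annotations.
#' @export
read_drug_annotations <- function(path) {
  raw <- .read_raw_table(path)
  .require_columns(raw, c("drug_id", "drug_status", "target_id"), path)
  if (nrow(raw) == 0) {
    return(tibble::tibble(drug_id = character(0), drug_status = character(0),
                          target_id = character(0)))
  }
  .parse_enum(raw$drug_status, c("approved", "experimental"), "drug_status", path)
  ann <- tibble::tibble(
    drug_id = raw$drug_id,
    drug_status = raw$drug_status,
    target_id = raw$target_id
  )
  kept <- dplyr::distinct(ann, .data$drug_id, .data$target_id, .keep_all = TRUE)
  if (nrow(kept) < nrow(ann)) {
    warn(sprintf(
      "'%s': %d duplicate (drug, target) row(s) collapsed (%d read, %d kept)",
      path, nrow(ann) - nrow(kept), nrow(ann), nrow(kept)
    ))
  }
  kept
}

#' Read confirmatory-assay outcomes
#'
#' Reads a PubChem-style assay outcome table (`compound_id`, `assay_id`,
#' `target_id`, `outcome`), with `outcome` either `active` or `inactive`.
#' Duplicate (compound, assay) rows are collapsed to one with a warning.
#'
#' @param path path to a `.tsv` or `.csv` file.
#' @return a tibble of assay outcomes.
#' @export
read_assay_outcomes <- function(path) {
  raw <- .read_raw_table(path)
  .require_columns(raw, c("compound_id", "assay_id", "target_id", "outcome"), path)
  if (nrow(raw) == 0) {
    return(tibble::tibble(compound_id = character(0), assay_id = character(0),
                          target_id = character(0), outcome = character(0)))
  }
  .parse_enum(raw$outcome, c("active", "inactive"), "outcome", path)
  out <- tibble::tibble(
    compound_id = raw$compound_id,
    assay_id = raw$assay_id,
    target_id = raw$target_id,
    outcome = raw$outcome
  )
  kept <- dplyr::distinct(out, .data$compound_id, .data$assay_id,
                          .keep_all = TRUE)
  if (nrow(kept) < nrow(out)) {
    warn(sprintf(
      "'%s': %d duplicate (compound, assay) row(s) collapsed (%d read, %d kept)",
      path, nrow(out) - nrow(kept), nrow(out), nrow(kept)
    ))
  }
  kept
}

#' Read per-compound metadata
#'
#' Reads a compound metadata table (`compound_id`, `mw`, `category`).
#' Molecular weight (`mw`, Daltons) may be empty/NA; compounds without a MW
#' are excluded from molecular-weight stratification downstream. `category`
#' is one of `bioactive`, `approved_drug`, `experimental_drug`,
#' `screen_active`.
#'
#' @param path path to a `.tsv` or `.csv` file.
#' @return a tibble of compound metadata, one row per compound.
#' @export
read_compound_meta <- function(path) {
  raw <- .read_raw_table(path)
  .require_columns(raw, c("compound_id", "mw", "category"), path)
  if (nrow(raw) == 0) {
    return(tibble::tibble(compound_id = character(0), mw = numeric(0),
                          category = character(0)))
  }
  mw <- suppressWarnings(as.numeric(raw$mw))
  bad <- which(!is.na(raw$mw) & raw$mw != "" & raw$mw != "NA" & is.na(mw))
  if (length(bad) > 0) {
    abort(sprintf(
      "invalid mw '%s' on line %d of '%s'",
      raw$mw[bad[1]], .file_line(bad[1]), path
    ))
  }
  bad <- which(!is.na(mw) & mw <= 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "non-positive mw on line %d of '%s'", .file_line(bad[1]), path
    ))
  }
  .parse_enum(raw$category,
              c("bioactive", "approved_drug", "experimental_drug",
                "screen_active"),
              "category", path)
  dplyr::distinct(tibble::tibble(
    compound_id = raw$compound_id, mw = mw, category = raw$category
  ))
}
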