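# Data-confidence filtering, Ki/IC50 subsetting and replicate aggregation.
# Promiscuity statistics are only meaningful on explicit, high-confidence
# measurements of direct ligand-target interactions: activity annotations
# from cell-based or reporter-gene assays measure assay promiscuity, not
# specific multi-target activity.

#' Data-confidence filter criteria
#'
#' Defaults keep only explicit (`relation == "eq"`) activity measurements at
#' the highest curation confidence level (9 on a ChEMBL-like 0-9 scale) with
#' evidence of a direct ligand-target interaction. Qualified values
#' (`<`/`>`) are excluded by default because they carry no usable magnitude
#' for potency-spread analysis.
#'
#' @param min_confidence minimum confidence level kept (integer 0-9).
#' @param require_direct drop records without the direct-interaction flag?
#' @param allowed_relations subset of `c("eq", "lt", "gt")` to keep.
#' @return a `filter_criteria` list.
#' @export
filter_criteria <- function(min_confidence = 9L,
                            require_direct = TRUE,
                            allowed_relations = "eq") {
  min_confidence <- as.integer(min_confidence)
  if (is.na(min_confidence) || min_confidence < 0L || min_confidence > 9L) {
    abort("min_confidence must be an integer in [0, 9]")
  }
  if (!is.logical(require_direct) || length(require_direct) != 1L) {
    abort("require_direct must be a single logical")
  }
  if (length(allowed_relations) == 0 ||
      !all(allowed_relations %in% RELATION_LEVELS)) {
    abort("allowed_relations must be a non-empty subset of eq/lt/gt")
  }
  structure(
    list(min_confidence = min_confidence,
         require_direct = require_direct,
         allowed_relations = allowed_relations),
    class = "filter_criteria"
  )
}

#' Keep only high-confidence activity records
#'
#' A record is kept iff its confidence level reaches `min_confidence`, it is
#' flagged as a direct interaction (unless `require_direct` is off), and its
#' relation qualifier is allowed. Raising `min_confidence` can only shrink
#' the result.
#'
#' @param records activity records (see [read_activity_table()]).
#' @param criteria a [filter_criteria()] object.
#' @param verbose log before/after record counts?
#' @return the kept records, order preserved.
#' @export
filter_high_confidence <- function(records, criteria = filter_criteria(),
                                   verbose = FALSE) {
  stopifnot(inherits(criteria, "filter_criteria"))
  keep <- records$confidence_level >= criteria$min_confidence &
    (records$direct_interaction | !criteria$require_direct) &
    records$relation %in% criteria$allowed_relations
  kept <- records[keep, , drop = FALSE]
  if (verbose) {
    inform(sprintf("confidence filter: %d of %d records kept",
                   nrow(kept), nrow(records)))
  }
  kept
}

#' Split records into Ki- and IC50-based subsets
#'
#' Ki (equilibrium constant) and IC50 (assay-dependent half-maximal
#' concentration) measurements are analysed separately throughout; a
#' compound measured in both ways contributes to both subsets. Records with
#' `measurement_type == "other"` enter neither.
#'
#' @param records filtered activity records.
#' @return a named list with elements `Ki` and `IC50`.
#' @export
split_by_measurement <- function(records) {
  list(
    Ki = records[records$measurement_type == "Ki", , drop = FALSE],
    IC50 = records[records$measurement_type == "IC50", , drop = FALSE]
  )
}

#' Aggregate replicate measurements into compound-target pairs
#'
#' Collapses replicate measurements of one (compound, target) interaction
#' within a single measurement type into one pair. Replicates are combined
#' by arithmetic mean on the pPotency scale, i.e. the geometric mean of the
#' nM values - the standard choice for log-normally distributed potencies.
#' Aggregation is idempotent: re-aggregating aggregated pairs is the
#' identity.
#'
#' @param records activity records of a single measurement type.
#' @return a tibble of pairs with columns `compound_id`, `target_id`,
#'   `target_family`, `measurement_type`, `p_potency`, `n_replicates`.
#' @export
aggregate_pairs <- function(records) {
  types <- unique(records$measurement_type)
  if (length(types) > 1) {
    abort("aggregate_pairs expects records of a single measurement type; use split_by_measurement() first")
  }
  if (nrow(records) == 0) {
    return(tibble::tibble(
      compound_id = character(0), target_id = character(0),
      target_family = character(0), measurement_type = character(0),
      p_potency = numeric(0), n_replicates = integer(0)
    ))
  }
  if (!"value_nM" %in% names(records) && "p_potency" %in% names(records)) {
    # already-aggregated pairs: one row per (compound, target), so
    # re-aggregation is the identity (replicate counts carried through)
    .assert_pairs(records)
    w <- if ("n_replicates" %in% names(records)) records$n_replicates else 1L
    return(
      dplyr::mutate(records, .w = w) |>
        dplyr::group_by(.data$compound_id, .data$target_id) |>
        dplyr::summarise(
          target_family = dplyr::first(.data$target_family),
          measurement_type = dplyr::first(.data$measurement_type),
          p_potency = sum(.data$p_potency * .data$.w) / sum(.data$.w),
          n_replicates = as.integer(sum(.data$.w)),
          .groups = "drop"
        )
    )
  }
  records |>
    dplyr::mutate(.p = p_potency(.data$value_nM)) |>
    dplyr::group_by(.data$compound_id, .data$target_id) |>
    dplyr::summarise(
      target_family = dplyr::first(.data$target_family),
      measurement_type = dplyr::first(.data$measurement_type),
      p_potency = mean(.p),
      n_replicates = dplyr::n(),
      .groups = "drop"
    )
}

# Re-aggregation entry point for already-aggregated pairs (idempotence):
# pairs are unique by construction, so this is a validity check.
.assert_pairs <- function(pairs) {
  required <- c("compound_id", "target_id", "target_family",
                "measurement_type", "p_potency")
  missing <- setdiff(required, names(pairs))
  if (length(missing) > 0) {
    abort(sprintf("not a pair table; missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  invisible(pairs)
}
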