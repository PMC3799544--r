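# Stratified promiscuity summaries: restricted to one target family, or
# binned by compound molecular weight.

#' Molecular-weight bins
#'
#' The default seven bins partition the positive MW axis into
#' `<=200, (200,300], (300,400], (400,500], (500,600], (600,700], >700`
#' Daltons. Bins are lower-open and upper-closed (the first bin includes
#' its upper boundary from below, i.e. is `(0, 200]`), so every positive MW
#' maps to exactly one bin and a boundary value such as 200 falls in the
#' lower-labelled bin.
#'
#' @param breaks increasing positive interior break points.
#' @return a tibble of bins with `label`, `lower`, `upper`.
#' @export
mw_bins <- function(breaks = c(200, 300, 400, 500, 600, 700)) {
  breaks <- sort(unique(as.numeric(breaks)))
  if (length(breaks) < 1 || any(breaks <= 0)) {
    abort("breaks must be positive and non-empty")
  }
  lower <- c(0, breaks)
  upper <- c(breaks, Inf)
  label <- c(
    sprintf("<=%g", breaks[1]),
    if (length(breaks) > 1) {
      sprintf("(%g,%g]", breaks[-length(breaks)], breaks[-1])
    },
    sprintf(">%g", breaks[length(breaks)])
  )
  tibble::tibble(label = label, lower = lower, upper = upper)
}

#' Assign molecular weights to bins
#'
#' @param mw numeric vector of molecular weights (Daltons, > 0; `NA`
#'   allowed and propagated).
#' @param bins a bin table from [mw_bins()].
#' @return a character vector of bin labels.
#' @export
assign_mw_bin <- function(mw, bins = mw_bins()) {
  if (any(!is.na(mw) & mw <= 0)) abort("mw must be positive")
  # interval i is (lower_i, upper_i]; with left.open findInterval returns
  # exactly that index over the break vector (0, upper_1, ..., Inf)
  idx <- findInterval(mw, c(bins$lower[1], bins$upper), left.open = TRUE)
  out <- bins$label[pmin(pmax(idx, 1L), nrow(bins))]
  out[is.na(mw)] <- NA_character_
  out
}

#' Family-restricted promiscuity summary
#'
#' Restricts compound-target pairs to the targets of one family and
#' summarises promiscuity within it: a compound active against two
#' same-family targets and one target elsewhere counts two targets here.
#' Compounds active in several families appear independently in each
#' family's summary.
#'
#' @param pairs aggregated compound-target pairs of one measurement type.
#' @param family family label to restrict to.
#' @return a one-row tibble: `family`, `n_targets_in_family`, then the
#'   [promiscuity_summary()] columns (empty summary if the family is absent).
#' @export
stratify_by_family <- function(pairs, family) {
  sub <- pairs[pairs$target_family == family, , drop = FALSE]
  summary <- if (nrow(sub) == 0) .empty_summary() else
    promiscuity_summary(count_targets(sub))
  dplyr::bind_cols(
    tibble::tibble(family = family,
                   n_targets_in_family = dplyr::n_distinct(sub$target_id)),
    summary
  )
}

#' @rdname stratify_by_family
#' @param families family labels to summarise (default: all present).
#' @export
stratify_by_families <- function(pairs, families = NULL) {
  families <- families %||% sort(unique(pairs$target_family))
  dplyr::bind_rows(lapply(families, function(f) stratify_by_family(pairs, f)))
}

#' Molecular-weight-binned promiscuity summaries
#'
#' Joins target counts to compound metadata and summarises promiscuity per
#' MW bin. Compounds without a known MW are excluded (their number is
#' reported via a message); each remaining compound contributes to exactly
#' one bin.
#'
#' @param counts target-count table from [count_targets()].
#' @param meta compound metadata with `compound_id` and `mw`.
#' @param bins a bin table from [mw_bins()].
#' @return a tibble with one row per bin: `mw_bin`, then the
#'   [promiscuity_summary()] columns.
#' @export
stratify_by_mw <- function(counts, meta, bins = mw_bins()) {
  joined <- dplyr::left_join(counts, meta[, c("compound_id", "mw")],
                             by = "compound_id")
  n_missing <- sum(is.na(joined$mw))
  if (n_missing > 0) {
    inform(sprintf(
      "%d of %d compounds without molecular weight excluded from MW stratification",
      n_missing, nrow(joined)
    ))
  }
  joined <- joined[!is.na(joined$mw), , drop = FALSE]
  joined$mw_bin <- assign_mw_bin(joined$mw, bins)
  dplyr::bind_rows(lapply(bins$label, function(b) {
    sub <- joined[joined$mw_bin == b, , drop = FALSE]
    summary <- if (nrow(sub) == 0) .empty_summary() else
      promiscuity_summary(sub)
    dplyr::bind_cols(tibble::tibble(mw_bin = b), summary)
  }))
}
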