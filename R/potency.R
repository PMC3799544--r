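#' Potency scale conversions
#'
#' Potencies are stored internally in nanomolar concentration units and
#' analysed on the pPotency scale, defined as -log10 of the potency in mol/L.
#' A 1 uM measurement (1000 nM) therefore has pPotency 6; "sub-uM" activity
#' corresponds to pPotency > 6.
#'
#' @param value_nM potency in nM (positive).
#' @param p pPotency in -log10 molar units.
#' @return `p_potency()` returns the pPotency; `potency_nM()` its inverse.
#' @examples
#' p_potency(1000)  # 6
#' potency_nM(7)    # 100 nM
#' @export
p_potency <- function(value_nM) {
  if (any(!is.na(value_nM) & value_nM <= 0)) {
    abort("potency values must be positive (nM)")
  }
  9 - log10(value_nM)
}

#' @rdname p_potency
#' @export
potency_nM <- function(p) 10^(9 - p)

# Unit conversion factors to nM. Both the micro sign and the ASCII "uM"
# spelling are accepted.
.unit_to_nM <- function(unit) {
  u <- trimws(unit)
  factor <- rep(NA_real_, length(u))
  factor[u %in% c("nM", "nm")] <- 1
  factor[u %in% c("uM", "um", "µM", "μM")] <- 1e3
  factor[u %in% c("mM", "mm")] <- 1e6
  factor[u == "M"] <- 1e9
  factor
}
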