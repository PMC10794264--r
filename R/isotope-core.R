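#' Isotope-system constants
#'
#' Registry of the physical constants and pipeline defaults used throughout
#' the package. All values can be overridden per call, but the defaults are
#' the standard parameterization for natural-abundance carbon CSIA:
#'
#' * `r_vpdb`: the 13C/12C isotope ratio of the Vienna Peedee Belemnite
#'   (VPDB) international reference, 0.0112372 (dimensionless).
#' * `delta_me`: delta-13C of the methyl carbon added during FAME
#'   derivatization, in mUr (determined from a methylated/unmethylated 17:0
#'   standard pair run by EA-IRMS).
#' * `r2_gate`: minimum R-squared expected of a CRM normalization fit.
#' * `alpha`: significance level for all hypothesis tests.
#' * `rout_q`: false-discovery level Q of the ROUT outlier screen.
#'
#' @param ... Named overrides for any constant, e.g. `delta_me = -41.2`.
#' @return A named list of constants.
#' @examples
#' iso_constants()$r_vpdb
#' iso_constants(alpha = 0.01)$alpha
#' @export
iso_constants <- function(...) {
  defaults <- list(
    r_vpdb  = 0.0112372,
    delta_me = -41.56,
    r2_gate = 0.999,
    alpha   = 0.05,
    rout_q  = 0.01
  )
  overrides <- list(...)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown)) {
      stop("Unknown constant(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    }
    defaults[names(overrides)] <- overrides
  }
  stopifnot(defaults$r_vpdb > 0)
  defaults
}

# delta values below -1000 mUr imply a negative isotope ratio: reject them.
check_delta <- function(delta, arg = "delta") {
  if (any(!is.finite(delta))) {
    stop("`", arg, "` must be finite", call. = FALSE)
  }
  if (any(delta <= -1000)) {
    stop("`", arg, "` must be > -1000 mUr (a delta of -1000 corresponds to ",
         "zero 13C; lower is physically impossible)", call. = FALSE)
  }
  invisible(delta)
}

#' Convert between delta-13C, isotope ratio and atom fraction
#'
#' The delta notation expresses a sample's 13C/12C ratio R relative to the
#' VPDB standard: `delta = 1000 * (R / R_VPDB - 1)` mUr (milli-Urey,
#' identical to per mil). The atom fraction is the share of carbon atoms
#' that are 13C, `F = R / (1 + R)`; figures conventionally report it as
#' percent 13C. All three representations are strictly monotone in one
#' another, so conversions round-trip exactly.
#'
#' @param delta delta-13C value(s) in mUr; must exceed -1000.
#' @param ratio 13C/12C isotope ratio(s); must be non-negative.
#' @param fraction atom fraction(s) 13C/(13C+12C) in `[0, 1)`.
#' @param r_vpdb 13C/12C ratio of the VPDB standard.
#' @return A numeric vector.
#' @examples
#' delta_to_ratio(0)               # the standard's own ratio, 0.0112372
#' ratio_to_delta(0.0112372)       # 0
#' delta_to_atom_fraction(-11.15)  # fraction of atoms that are 13C
#' @name delta-conversions
NULL

#' @rdname delta-conversions
#' @export
delta_to_ratio <- function(delta, r_vpdb = iso_constants()$r_vpdb) {
  check_delta(delta)
  r_vpdb * (1 + delta / 1000)
}

#' @rdname delta-conversions
#' @export
ratio_to_delta <- function(ratio, r_vpdb = iso_constants()$r_vpdb) {
  if (any(!is.finite(ratio)) || any(ratio < 0)) {
    stop("`ratio` must be finite and non-negative", call. = FALSE)
  }
  1000 * (ratio / r_vpdb - 1)
}

#' @rdname delta-conversions
#' @export
ratio_to_atom_fraction <- function(ratio) {
  if (any(!is.finite(ratio)) || any(ratio < 0)) {
    stop("`ratio` must be finite and non-negative", call. = FALSE)
  }
  ratio / (1 + ratio)
}

#' @rdname delta-conversions
#' @export
atom_fraction_to_ratio <- function(fraction) {
  if (any(!is.finite(fraction)) || any(fraction < 0) || any(fraction >= 1)) {
    stop("`fraction` must lie in [0, 1)", call. = FALSE)
  }
  fraction / (1 - fraction)
}

#' @rdname delta-conversions
#' @export
delta_to_atom_fraction <- function(delta, r_vpdb = iso_constants()$r_vpdb) {
  ratio_to_atom_fraction(delta_to_ratio(delta, r_vpdb))
}

#' @rdname delta-conversions
#' @export
atom_fraction_to_delta <- function(fraction, r_vpdb = iso_constants()$r_vpdb) {
  ratio_to_delta(atom_fraction_to_ratio(fraction), r_vpdb)
}

#' Percent 13C enrichment
#'
#' Presentation helper: atom fraction as percent 13C, the unit used in
#' enrichment bar plots. Values are stored internally as fractions and only
#' converted to percent at presentation.
#'
#' @inheritParams delta-conversions
#' @return Percent of carbon atoms that are 13C.
#' @examples
#' pct_13c(0)  # the VPDB standard itself, about 1.111 %13C
#' @export
pct_13c <- function(delta, r_vpdb = iso_constants()$r_vpdb) {
  100 * delta_to_atom_fraction(delta, r_vpdb)
}
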