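#' Determine the methyl-carbon delta from a standard pair
#'
#' FAME derivatization adds one exogenous methyl carbon to each fatty acid.
#' Running the same standard (conventionally 17:0) both unmethylated and
#' methylated determines the delta-13C of that added carbon by carbon mass
#' balance: `delta_ME = n_FAME * delta_FAME - n_FA * delta_FA`, where the
#' single methyl carbon carries an implicit weight of one.
#'
#' @param delta_fame delta-13C of the methylated standard (VPDB, mUr).
#' @param delta_fa delta-13C of the unmethylated standard (VPDB, mUr).
#' @param species Species shorthand (default `"17:0"`) or a one-row tibble
#'   from [fa_species()].
#' @return delta-13C of the derivatized methyl carbon, in mUr.
#' @examples
#' methyl_delta(-30.60, -30.00, "17:0")  # -40.80
#' @export
methyl_delta <- function(delta_fame, delta_fa, species = "17:0") {
  sp <- if (is.character(species)) fa_species(species) else species
  stopifnot(nrow(sp) == 1, sp$n_fame == sp$n_fa + 1L)
  check_delta(delta_fame, "delta_fame")
  check_delta(delta_fa, "delta_fa")
  sp$n_fame * delta_fame - sp$n_fa * delta_fa
}

#' Correct FAME delta-13C for the derivatization methyl carbon
#'
#' Inverts the carbon mass balance
#' `n_FAME * delta_FAME = delta_ME + n_FA * delta_FA`
#' to recover the native fatty acid's delta-13C from its methyl ester:
#' `delta_FA = (n_FAME * delta_FAME - delta_ME) / n_FA`. The correction is
#' linear with slope `n_FAME / n_FA > 1`, and its magnitude shrinks with
#' chain length as the single methyl carbon is diluted. When an input SD is
#' supplied, it is propagated exactly (linear map): `sd_FA = sd_FAME *
#' n_FAME / n_FA`.
#'
#' @param delta_fame delta-13C of the FAME on the VPDB scale (mUr).
#' @param species Species shorthand ("16:0") or tibble from [fa_species()];
#'   recycled against `delta_fame`.
#' @param delta_me delta-13C of the derivatized methyl carbon (mUr).
#' @param sd Optional 1-SD uncertainty of `delta_fame`, in mUr.
#' @return Native fatty-acid delta-13C (mUr), or a tibble with columns
#'   `delta_fa_mur` and `sd_mur` when `sd` is supplied.
#' @examples
#' correct_fame_delta(-17.50, "16:0")  # -15.996 with the default delta_me
#' @export
correct_fame_delta <- function(delta_fame, species,
                               delta_me = iso_constants()$delta_me,
                               sd = NULL) {
  sp <- if (is.character(species)) fa_species(species) else species
  stopifnot(all(sp$n_fa >= 1), all(sp$n_fame == sp$n_fa + 1L))
  check_delta(delta_fame, "delta_fame")
  check_delta(delta_me, "delta_me")
  delta_fa <- (sp$n_fame * delta_fame - delta_me) / sp$n_fa
  if (is.null(sd)) {
    return(delta_fa)
  }
  stopifnot(all(sd >= 0))
  tibble::tibble(
    delta_fa_mur = delta_fa,
    sd_mur = sd * sp$n_fame / sp$n_fa
  )
}

#' Forward mass balance: native fatty-acid delta to FAME delta
#'
#' The forward direction of the derivatization balance, used by the study
#' simulator and by round-trip checks:
#' `delta_FAME = (delta_ME + n_FA * delta_FA) / n_FAME`.
#'
#' @inheritParams correct_fame_delta
#' @param delta_fa Native fatty-acid delta-13C (VPDB, mUr).
#' @return FAME delta-13C (mUr).
#' @export
fame_from_fa_delta <- function(delta_fa, species,
                               delta_me = iso_constants()$delta_me) {
  sp <- if (is.character(species)) fa_species(species) else species
  stopifnot(all(sp$n_fame == sp$n_fa + 1L))
  check_delta(delta_fa, "delta_fa")
  check_delta(delta_me, "delta_me")
  (delta_me + sp$n_fa * delta_fa) / sp$n_fame
}

#' Methyl-correct a table of FAME deltas
#'
#' Data-frame verb applying [correct_fame_delta()] row-wise: takes a table
#' with a species column and a VPDB-normalized FAME delta column and adds
#' the corrected native fatty-acid delta.
#'
#' @param data Data frame with columns `species` (shorthand) and the column
#'   named by `delta_col`.
#' @param delta_col Name of the FAME delta column (default
#'   `"delta_vpdb_mur"`).
#' @param delta_me Methyl-carbon delta-13C (mUr).
#' @return `data` with an added `delta_fa_mur` column.
#' @export
correct_methyl <- function(data, delta_col = "delta_vpdb_mur",
                           delta_me = iso_constants()$delta_me) {
  stopifnot(is.data.frame(data))
  if ("delta_fa_mur" %in% names(data)) {
    stop("`data` already carries `delta_fa_mur` (correcting twice is not ",
         "meaningful)", call. = FALSE)
  }
  if (!all(c("species", delta_col) %in% names(data))) {
    stop("`data` needs columns `species` and `", delta_col, "`", call. = FALSE)
  }
  sp <- fa_species(data$species)
  dplyr::mutate(
    data,
    delta_fa_mur = correct_fame_delta(.data[[delta_col]], sp, delta_me)
  )
}
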