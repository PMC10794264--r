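#' Quantify fatty acids against an internal standard
#'
#' Converts integrated chromatographic peak areas into amounts by the
#' internal-standard area-ratio rule: a known mass of an exogenous fatty
#' acid (conventionally heptadecanoic acid, 17:0) is added to every tissue
#' homogenate, and each analyte's amount is its peak area divided by the
#' internal-standard area, times the known spike. Response factors default
#' to unity for all FAMEs; a per-species table can override them. Amounts
#' are expressed per gram of tissue and as relative percent of the total
#' quantified fatty acids, with the exogenous internal standard excluded
#' from the percentage denominator. Zero-area analytes are retained as
#' zeros so composition denominators stay comparable across samples.
#'
#' @param peaks Data frame of one sample's peaks: columns `species`
#'   (shorthand) and `area` (arbitrary units, >= 0); optionally
#'   `sample_id` and `retention_time`.
#' @param is_amount_ug Mass of internal standard added to the sample (ug).
#' @param tissue_mass_g Wet tissue mass of the homogenate (g).
#' @param is_species Internal-standard species (default `"17:0"`); must be
#'   present exactly once and must not be an endogenous analyte.
#' @param response_factors Optional named numeric vector of per-species
#'   response factors (area per amount relative to the internal standard).
#' @return A tibble with one row per analyte: `species`, `area`,
#'   `amount_ug`, `conc_ug_per_g`, `relative_percent`. Relative percents
#'   sum to 100 per sample.
#' @examples
#' peaks <- data.frame(
#'   species = c("16:0", "18:1n-9", "18:0", "17:0"),
#'   area = c(2e5, 1e5, 1e5, 1e5)
#' )
#' quantify_sample(peaks, is_amount_ug = 10, tissue_mass_g = 0.4)
#' @export
quantify_sample <- function(peaks, is_amount_ug, tissue_mass_g,
                            is_species = "17:0", response_factors = NULL) {
  stopifnot(is.data.frame(peaks), is_amount_ug > 0, tissue_mass_g > 0)
  if (!all(c("species", "area") %in% names(peaks))) {
    stop("`peaks` needs columns `species` and `area`", call. = FALSE)
  }
  if (any(peaks$area < 0)) stop("Peak areas must be non-negative", call. = FALSE)

  is_rows <- peaks$species == is_species
  if (sum(is_rows) != 1) {
    stop("Quantification error: expected exactly one internal-standard (",
         is_species, ") peak, found ", sum(is_rows), call. = FALSE)
  }
  area_is <- peaks$area[is_rows]
  if (area_is == 0) {
    stop("Quantification error: internal-standard peak has zero area",
         call. = FALSE)
  }
  analytes <- peaks[!is_rows, , drop = FALSE]
  dup <- unique(analytes$species[duplicated(analytes$species)])
  if (length(dup)) {
    stop("Duplicate peaks for species: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }

  rf <- rep(1, nrow(analytes))
  if (!is.null(response_factors)) {
    hit <- analytes$species %in% names(response_factors)
    rf[hit] <- response_factors[analytes$species[hit]]
    stopifnot(all(rf > 0))
  }

  amount <- (analytes$area / rf) / area_is * is_amount_ug
  total <- sum(amount)
  tibble::tibble(
    species = analytes$species,
    area = analytes$area,
    amount_ug = amount,
    conc_ug_per_g = amount / tissue_mass_g,
    relative_percent = if (total > 0) 100 * amount / total else rep(0, length(amount))
  )
}

#' Quantify a multi-sample peak table
#'
#' Applies [quantify_sample()] to every sample of a long peak table, joined
#' to per-sample metadata carrying the tissue mass and the internal-standard
#' spike.
#'
#' @param peaks Data frame with columns `sample_id`, `species`, `area`.
#' @param samples Data frame with columns `sample_id`, `tissue_mass_g`,
#'   `is_amount_ug`.
#' @inheritParams quantify_sample
#' @return A tibble of per-sample composition rows.
#' @export
quantify_samples <- function(peaks, samples, is_species = "17:0",
                             response_factors = NULL) {
  stopifnot(is.data.frame(peaks), is.data.frame(samples))
  if (!all(c("sample_id", "species", "area") %in% names(peaks))) {
    stop("`peaks` needs columns sample_id, species, area", call. = FALSE)
  }
  if (!all(c("sample_id", "tissue_mass_g", "is_amount_ug") %in% names(samples))) {
    stop("`samples` needs columns sample_id, tissue_mass_g, is_amount_ug",
         call. = FALSE)
  }
  meta <- stats::setNames(
    split(samples, seq_len(nrow(samples))),
    samples$sample_id
  )
  peaks |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_map(\(d, key) {
      m <- meta[[as.character(key$sample_id)]]
      if (is.null(m)) {
        stop("No sample metadata for sample_id ", key$sample_id, call. = FALSE)
      }
      dplyr::bind_cols(
        key,
        quantify_sample(d, m$is_amount_ug, m$tissue_mass_g,
                        is_species = is_species,
                        response_factors = response_factors)
      )
    }) |>
    dplyr::bind_rows()
}
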