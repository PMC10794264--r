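#' Fatty-acid species registry
#'
#' Maps shorthand fatty-acid notation ("16:0", "18:1n-9", "22:6n-3") to the
#' carbon counts needed by the methyl-correction mass balance: `n_fa`, the
#' carbon count of the native fatty acid, and `n_fame = n_fa + 1`, the
#' carbon count of its methyl ester. The chain length is parsed from the
#' shorthand itself, so any `C:D` or `C:Dn-x` species is supported without
#' registration. Common species carry a trivial-name label.
#'
#' @param shorthand Character vector of species in `C:D` shorthand.
#' @return A tibble with columns `shorthand`, `label`, `n_fa`, `n_fame`.
#' @examples
#' fa_species(c("16:0", "17:0", "22:6n-3"))
#' @export
fa_species <- function(shorthand) {
  stopifnot(is.character(shorthand), length(shorthand) >= 1)
  m <- regmatches(shorthand, regexec("^([0-9]+):([0-9]+)", shorthand))
  n_fa <- vapply(m, function(x) {
    if (length(x) < 2) NA_integer_ else as.integer(x[2])
  }, integer(1))
  if (any(is.na(n_fa))) {
    bad <- shorthand[is.na(n_fa)]
    stop("Cannot parse fatty-acid shorthand: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(n_fa < 2)) {
    stop("Fatty acids must have at least 2 carbons", call. = FALSE)
  }
  labels <- c(
    "16:0" = "palmitic acid (PAM)",
    "16:1n-7" = "palmitoleic acid (POA)",
    "17:0" = "heptadecanoic acid (internal standard)",
    "18:0" = "stearic acid (STA)",
    "18:1n-9" = "oleic acid (OLA)",
    "18:2n-6" = "linoleic acid (LNA)",
    "20:4n-6" = "arachidonic acid (ARA)",
    "22:6n-3" = "docosahexaenoic acid (DHA)"
  )
  tibble::tibble(
    shorthand = shorthand,
    label = unname(labels[shorthand]),
    n_fa = n_fa,
    n_fame = n_fa + 1L
  )
}
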