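# Shared fixtures built in code.

# CRM table distorted by a known affine map: raw = (certified - b) / a,
# so the fitted normalization must recover slope = a, intercept = b.
make_crms <- function(certified = c(-30, -10, -1), a = 1, b = 0,
                      noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    crm_id = paste0("crm", seq_along(certified)),
    certified_delta_mur = certified,
    measured_delta_mur = (certified - b) / a +
      stats::rnorm(length(certified), 0, noise_sd)
  )
}

# one sample's peak table with an internal standard
make_peaks <- function(areas, species = paste0(14 + 2 * seq_along(areas), ":0"),
                       is_area = 1e5) {
  data.frame(
    species = c(species, "17:0"),
    area = c(areas, is_area)
  )
}

# balanced two-factor dataset with known cell means
make_factorial <- function(n = 6, diet_shift = c(LP = 0, MP = 0, HP = 0),
                           time_shift = c(P0 = 0, P10 = 0, P21 = 0, P35 = 0),
                           interaction = 0, sd = 1, seed = 1) {
  set.seed(seed)
  g <- expand.grid(diet = names(diet_shift), timepoint = names(time_shift),
                   rep = seq_len(n), stringsAsFactors = FALSE)
  g$response <- diet_shift[g$diet] + time_shift[g$timepoint] +
    interaction * (g$diet == names(diet_shift)[1]) *
      (g$timepoint == names(time_shift)[1]) +
    rnorm(nrow(g), 0, sd)
  g
}
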