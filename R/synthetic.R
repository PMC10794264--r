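#' Default true DNL fractions for the simulated study
#'
#' Ground-truth sugar-derived (DNL) fractions per diet, timepoint and
#' tissue for the forward simulator. The profile mirrors the biology the
#' pipeline is built to detect: the DNL fraction rises as dietary palmitate
#' falls (LP > MP > HP everywhere), the liver responds more strongly than
#' the brain, LP brain enrichment grows with age while HP brain enrichment
#' declines. The values are generator parameters, not measurements.
#'
#' @param timepoints Character vector of postnatal-day labels.
#' @return A tibble with columns `diet`, `timepoint`, `tissue`, `f_true`.
#' @export
default_f_true <- function(timepoints = c("P0", "P10", "P21", "P35")) {
  nt <- length(timepoints)
  ramp <- function(from, to) seq(from, to, length.out = nt)
  dplyr::bind_rows(
    tibble::tibble(diet = "LP", timepoint = timepoints, tissue = "brain",
                   f_true = ramp(0.78, 0.84)),
    tibble::tibble(diet = "MP", timepoint = timepoints, tissue = "brain",
                   f_true = rep(0.72, nt)),
    tibble::tibble(diet = "HP", timepoint = timepoints, tissue = "brain",
                   f_true = ramp(0.68, 0.62)),
    tibble::tibble(diet = "LP", timepoint = timepoints, tissue = "liver",
                   f_true = ramp(0.92, 0.95)),
    tibble::tibble(diet = "MP", timepoint = timepoints, tissue = "liver",
                   f_true = ramp(0.72, 0.75)),
    tibble::tibble(diet = "HP", timepoint = timepoints, tissue = "liver",
                   f_true = ramp(0.55, 0.49))
  )
}

#' Configuration for the study simulator
#'
#' Assembles every knob of the forward model in one validated list. The
#' defaults are the simulated study's conditions: three diets (LP/MP/HP)
#' fed across four postnatal timepoints, six male pups per diet-timepoint
#' cell, brain and liver sampled from each, instrument drift of slope 1.02
#' and intercept 0.8 mUr, 0.3 mUr instrument noise, 0.5 mUr between-animal
#' biological spread, and 0.05 mUr noise on CRM injections.
#'
#' @param seed Integer RNG seed; every bundle is fully determined by it.
#' @param diets Diet composition table (default [diet_composition()]).
#' @param timepoints Postnatal-day labels.
#' @param n_per_cell Animals per diet-timepoint cell.
#' @param tissues Tissues sampled from each animal.
#' @param f_true Tibble `diet`-`timepoint`-`tissue`-`f_true` of true DNL
#'   fractions (default [default_f_true()]).
#' @param biological_sd Between-animal SD of the true tissue delta (mUr).
#' @param measurement_sd Instrument SD on each sample injection (mUr).
#' @param drift_slope,drift_intercept Affine instrument distortion: a
#'   sample with true VPDB delta `d` is read raw as
#'   `(d - drift_intercept) / drift_slope` plus noise, so the fitted
#'   normalization recovers exactly `slope = drift_slope`,
#'   `intercept = drift_intercept`.
#' @param noise_sd_crm Instrument SD on CRM injections (mUr).
#' @param crm_certified Tibble `crm_id`, `certified_delta_mur` of the CRM
#'   set injected once per sequence. The defaults are synthetic placeholder
#'   certificates spanning the natural-abundance range; replace them with
#'   your CRM certificates for real data.
#' @param delta_me Methyl-carbon delta used in the forward balance (mUr).
#' @param tissue_pam_percent Tibble `diet`-`tissue`-`pam_percent`: target
#'   relative percent of palmitate in each tissue's quantified pool.
#' @param milk_carryover Tibble `diet`-`pam_low`-`pam_high`: the percent-
#'   PAM range of pre-weaning stomach content per diet, emulating milk
#'   carry-over at P0/P10.
#' @param is_amount_ug Internal-standard spike per sample (ug).
#' @param sex Sex label assigned to simulated pups (the primary analysis
#'   stratum is male).
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(seed = 20240117,
                             diets = diet_composition(),
                             timepoints = c("P0", "P10", "P21", "P35"),
                             n_per_cell = 6,
                             tissues = c("brain", "liver"),
                             f_true = default_f_true(timepoints),
                             biological_sd = 0.5,
                             measurement_sd = 0.3,
                             drift_slope = 1.02,
                             drift_intercept = 0.8,
                             noise_sd_crm = 0.05,
                             crm_certified = crm_reference_values(),
                             delta_me = iso_constants()$delta_me,
                             tissue_pam_percent = default_tissue_pam(),
                             milk_carryover = default_milk_carryover(),
                             is_amount_ug = 10,
                             sex = "M") {
  stopifnot(
    is.numeric(seed), length(seed) == 1, seed == round(seed),
    n_per_cell >= 1,
    all(f_true$f_true >= 0), all(f_true$f_true <= 1),
    biological_sd >= 0, measurement_sd >= 0, noise_sd_crm >= 0,
    drift_slope != 0, is_amount_ug > 0
  )
  diet_ids <- unique(diets$diet)
  need <- tidyr::expand_grid(diet = diet_ids, timepoint = timepoints,
                             tissue = tissues)
  have <- dplyr::semi_join(need, f_true,
                           by = c("diet", "timepoint", "tissue"))
  if (nrow(have) < nrow(need)) {
    stop("`f_true` must cover every diet x timepoint x tissue cell",
         call. = FALSE)
  }
  structure(
    list(
      seed = as.integer(seed), diets = diets, timepoints = timepoints,
      n_per_cell = n_per_cell, tissues = tissues, f_true = f_true,
      biological_sd = biological_sd, measurement_sd = measurement_sd,
      drift_slope = drift_slope, drift_intercept = drift_intercept,
      noise_sd_crm = noise_sd_crm, crm_certified = crm_certified,
      delta_me = delta_me, tissue_pam_percent = tissue_pam_percent,
      milk_carryover = milk_carryover, is_amount_ug = is_amount_ug,
      sex = sex
    ),
    class = "generator_config"
  )
}

#' Synthetic placeholder CRM certificates
#'
#' Three certified reference materials spanning the natural-abundance
#' delta-13C range, in the spirit of the USGS70/71/72 FAME CRM set. These
#' are synthetic placeholder values for simulation and testing — real
#' analyses must substitute the certificate values of the CRMs actually
#' injected.
#'
#' @return A tibble with columns `crm_id`, `certified_delta_mur`.
#' @export
crm_reference_values <- function() {
  tibble::tibble(
    crm_id = c("CRM-A", "CRM-B", "CRM-C"),
    certified_delta_mur = c(-30.5, -10.5, -1.5)
  )
}

#' Default tissue palmitate composition targets
#'
#' Target relative percent of palmitate in the quantified fatty-acid pool
#' by diet and tissue. Brain composition is tightly conserved across diets;
#' liver tracks dietary supply.
#'
#' @return A tibble `diet`-`tissue`-`pam_percent`.
#' @export
default_tissue_pam <- function() {
  tidyr::expand_grid(diet = c("LP", "MP", "HP"),
                     tissue = c("brain", "liver")) |>
    dplyr::mutate(pam_percent = dplyr::case_when(
      .data$tissue == "brain" & .data$diet == "LP" ~ 20,
      .data$tissue == "brain" & .data$diet == "MP" ~ 21,
      .data$tissue == "brain" & .data$diet == "HP" ~ 22,
      .data$tissue == "liver" & .data$diet == "LP" ~ 16,
      .data$tissue == "liver" & .data$diet == "MP" ~ 21,
      .data$tissue == "liver" & .data$diet == "HP" ~ 26
    ))
}

#' Default pre-weaning milk carry-over ranges
#'
#' Percent-PAM ranges of P0/P10 stomach content per diet: dams fed less
#' palmitate produce milk with less palmitate, so pre-weaning pups already
#' receive graded PAM exposure (low 21-28%, medium 25-35%, high 31-41%).
#'
#' @return A tibble `diet`-`pam_low`-`pam_high`.
#' @export
default_milk_carryover <- function() {
  tibble::tibble(
    diet = c("LP", "MP", "HP"),
    pam_low = c(21, 25, 31),
    pam_high = c(28, 35, 41)
  )
}

#' Simulate a complete study data bundle
#'
#' Forward-simulates the whole measurement chain so every pipeline stage
#' can be tested against known truth:
#'
#' 1. each animal's true tissue fatty-acid delta is two-pool mixing,
#'    `f * delta_sugar + (1 - f) * delta_fat`, plus Gaussian biological
#'    noise;
#' 2. the FAME delta follows by the forward methyl mass balance;
#' 3. the raw instrument delta applies the inverse affine drift plus
#'    instrument noise, batched into one sequence per timepoint-tissue;
#' 4. each sequence carries its own CRM injections through the same drift;
#' 5. peak areas are laid down so that internal-standard quantification
#'    recovers the configured tissue composition exactly.
#'
#' The bundle is fully deterministic given `config$seed`; ground truth
#' lives in a separate element that pipeline-facing tables never see.
#'
#' @param config A [generator_config()].
#' @return A list of class `synthetic_bundle`: `crm_table`,
#'   `raw_delta_table`, `peak_table`, `sample_metadata`, `stomach_content`,
#'   `ground_truth` (with `f_true`, per-sample true deltas and amounts, and
#'   the end-members used).
#' @examples
#' bundle <- generate_study(generator_config(n_per_cell = 2))
#' names(bundle)
#' @export
generate_study <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)

  sugar <- sugar_signature(config$diets)
  diet_ids <- unique(config$diets$diet)
  fats <- purrr::map(diet_ids, \(d) fat_endmember(config$diets, d)) |>
    dplyr::bind_rows()

  meta <- tidyr::expand_grid(
    diet = diet_ids,
    timepoint = config$timepoints,
    replicate = seq_len(config$n_per_cell)
  ) |>
    dplyr::mutate(
      animal_id = sprintf("%s_%s_a%02d", .data$diet, .data$timepoint,
                          .data$replicate),
      sex = config$sex
    )

  samples <- dplyr::cross_join(meta, tibble::tibble(tissue = config$tissues)) |>
    dplyr::mutate(
      sample_id = paste0(.data$animal_id, "_", .data$tissue),
      sequence_id = paste0(.data$timepoint, "_", .data$tissue)
    ) |>
    dplyr::left_join(config$f_true, by = c("diet", "timepoint", "tissue")) |>
    dplyr::left_join(
      dplyr::select(fats, diet = "diet", delta_fat = "delta_mur",
                    substituted = "substituted"),
      by = "diet"
    )

  n <- nrow(samples)
  samples$delta_fa_true <- samples$f_true * sugar$delta_mur +
    (1 - samples$f_true) * samples$delta_fat +
    stats::rnorm(n, 0, config$biological_sd)
  samples$delta_fame_true <- fame_from_fa_delta(
    samples$delta_fa_true, fa_species(rep("16:0", n)),
    delta_me = config$delta_me
  )
  samples$delta_raw <- (samples$delta_fame_true - config$drift_intercept) /
    config$drift_slope + stats::rnorm(n, 0, config$measurement_sd)

  crm_table <- dplyr::cross_join(
    tibble::tibble(sequence_id = unique(samples$sequence_id)),
    config$crm_certified
  ) |>
    dplyr::mutate(
      measured_delta_mur = (.data$certified_delta_mur - config$drift_intercept) /
        config$drift_slope +
        stats::rnorm(dplyr::n(), 0, config$noise_sd_crm),
      sequence_position = dplyr::row_number()
    )

  # composition: PAM target per diet/tissue; the remainder split over the
  # other quantified species in fixed tissue-typical proportions
  others <- tibble::tibble(
    species = c("18:0", "18:1n-9", "16:1n-7", "22:6n-3"),
    share = c(0.35, 0.35, 0.05, 0.25)
  )
  total_ug <- c(brain = 400, liver = 1200)
  tissue_mass <- c(brain = 0.4, liver = 1.0)

  comp <- samples |>
    dplyr::select("sample_id", "diet", "tissue") |>
    dplyr::left_join(config$tissue_pam_percent, by = c("diet", "tissue")) |>
    dplyr::mutate(total = total_ug[.data$tissue])
  peak_rows <- purrr::pmap(
    list(comp$sample_id, comp$pam_percent, comp$total),
    function(sid, pam_pct, total) {
      amt <- c(total * pam_pct / 100,
               total * (1 - pam_pct / 100) * others$share)
      tibble::tibble(
        sample_id = sid,
        species = c("16:0", others$species),
        amount_true = amt
      )
    }
  )
  area_is <- 1e6
  peak_table <- dplyr::bind_rows(peak_rows) |>
    dplyr::mutate(area = .data$amount_true / config$is_amount_ug * area_is)
  is_rows <- tibble::tibble(
    sample_id = unique(peak_table$sample_id),
    species = "17:0",
    amount_true = NA_real_,
    area = area_is
  )
  true_amounts <- dplyr::select(peak_table, "sample_id", "species",
                                "amount_true")
  peak_table <- dplyr::bind_rows(peak_table, is_rows) |>
    dplyr::arrange(.data$sample_id, .data$species) |>
    dplyr::select("sample_id", "species", "area")

  stomach <- meta |>
    dplyr::filter(.data$timepoint %in% c("P0", "P10")) |>
    dplyr::left_join(config$milk_carryover, by = "diet") |>
    dplyr::mutate(
      stomach_pam_percent = stats::runif(dplyr::n(), .data$pam_low,
                                         .data$pam_high)
    ) |>
    dplyr::select("animal_id", "diet", "timepoint", "stomach_pam_percent")

  sample_metadata <- samples |>
    dplyr::mutate(
      tissue_mass_g = tissue_mass[.data$tissue],
      is_amount_ug = config$is_amount_ug,
      species = "16:0"
    ) |>
    dplyr::select("sample_id", "animal_id", "diet", "timepoint", "sex",
                  "tissue", "sequence_id", "tissue_mass_g", "is_amount_ug")

  raw_delta_table <- samples |>
    dplyr::mutate(species = "16:0") |>
    dplyr::select("sample_id", "sequence_id", "species",
                  delta_raw_mur = "delta_raw")

  ground_truth <- list(
    f_true = dplyr::select(samples, "sample_id", "diet", "timepoint",
                           "tissue", "f_true"),
    true_deltas = dplyr::select(samples, "sample_id",
                                delta_fa_true = "delta_fa_true",
                                delta_fame_true = "delta_fame_true"),
    true_amounts = true_amounts,
    endmembers = list(sugar = sugar, fats = fats),
    config = config
  )

  structure(
    list(
      crm_table = crm_table,
      raw_delta_table = raw_delta_table,
      peak_table = peak_table,
      sample_metadata = sample_metadata,
      stomach_content = stomach,
      ground_truth = ground_truth
    ),
    class = "synthetic_bundle"
  )
}

#' Simulate a null study (no diet or time effects)
#'
#' Identical to [generate_study()] except that every diet-timepoint-tissue
#' cell shares one true DNL fraction and one fat end-member delta, so any
#' significant diet or time effect downstream is a false positive. Used to
#' calibrate type-I error of the statistical layer.
#'
#' @param config A [generator_config()].
#' @param f_null The common true fraction (default: mean of the config's
#'   `f_true`).
#' @return A `synthetic_bundle`.
#' @export
generate_null <- function(config = generator_config(),
                          f_null = mean(config$f_true$f_true)) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  cfg$f_true <- dplyr::mutate(config$f_true, f_true = f_null)
  # one common fat end-member removes the diet-specific mixing offset
  common_fat <- mean(
    purrr::map_dbl(
      unique(cfg$diets$diet),
      \(d) fat_endmember(cfg$diets, d)$delta_mur
    )
  )
  cfg$diets <- cfg$diets |>
    dplyr::mutate(
      delta_mur = ifelse(!is.na(.data$species) & .data$species == "16:0" &
                           .data$pct_energy > 0,
                         common_fat, .data$delta_mur),
      pct_energy = ifelse(!is.na(.data$species) & .data$species == "16:0" &
                            .data$pct_energy == 0,
                          7.79, .data$pct_energy),
      delta_mur = ifelse(!is.na(.data$species) & .data$species == "16:0" &
                           is.na(.data$delta_mur),
                         common_fat, .data$delta_mur),
      sd_mur = ifelse(!is.na(.data$species) & .data$species == "16:0",
                      0.12, .data$sd_mur)
    )
  generate_study(cfg)
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("<synthetic_bundle>\n")
  cat("  samples:   ", nrow(x$sample_metadata), "\n")
  cat("  sequences: ", length(unique(x$crm_table$sequence_id)), "\n")
  cat("  peaks:     ", nrow(x$peak_table), "\n")
  cat("  seed:      ", x$ground_truth$config$seed, "\n")
  invisible(x)
}

#' Write a synthetic bundle to CSV files
#'
#' Writes the pipeline-facing tables as CSV and the ground truth as a JSON
#' sidecar (`ground_truth.json`), keeping truth out of the files the
#' pipeline reads.
#'
#' @param bundle A `synthetic_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("crm_table", "raw_delta_table", "peak_table",
              "sample_metadata", "stomach_content")
  paths <- character(0)
  for (tb in tables) {
    p <- file.path(dir, paste0(tb, ".csv"))
    utils::write.csv(bundle[[tb]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    p <- file.path(dir, "ground_truth.json")
    gt <- bundle$ground_truth
    gt$config <- unclass(gt$config)
    jsonlite::write_json(gt, p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  } else {
    p <- file.path(dir, "ground_truth_f_true.csv")
    utils::write.csv(bundle$ground_truth$f_true, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
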