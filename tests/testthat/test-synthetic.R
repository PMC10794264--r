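test_that("bundles are deterministic given the seed", {
  cfg <- generator_config(n_per_cell = 2)
  b1 <- generate_study(cfg)
  b2 <- generate_study(cfg)
  expect_identical(b1$raw_delta_table, b2$raw_delta_table)
  expect_identical(b1$crm_table, b2$crm_table)
  expect_identical(b1$peak_table, b2$peak_table)
  b3 <- generate_study(generator_config(seed = 7, n_per_cell = 2))
  expect_false(identical(b1$raw_delta_table, b3$raw_delta_table))
})

test_that("bundle tables cross-reference consistently", {
  b <- generate_study(generator_config(n_per_cell = 2))
  ids <- b$sample_metadata$sample_id
  expect_setequal(unique(b$raw_delta_table$sample_id), ids)
  expect_setequal(unique(b$peak_table$sample_id), ids)
  expect_setequal(unique(b$raw_delta_table$sequence_id),
                  unique(b$crm_table$sequence_id))
  # ground truth covers every sample and never leaks into facing tables
  expect_setequal(b$ground_truth$f_true$sample_id, ids)
  expect_false("f_true" %in% names(b$raw_delta_table))
  expect_false("f_true" %in% names(b$sample_metadata))
  # one sequence per timepoint-tissue batch
  expect_equal(length(unique(b$crm_table$sequence_id)), 4 * 2)
  # stomach content only for pre-weaning timepoints, within configured range
  expect_setequal(unique(b$stomach_content$timepoint), c("P0", "P10"))
  rng <- merge(b$stomach_content, default_milk_carryover(), by = "diet")
  expect_true(all(rng$stomach_pam_percent >= rng$pam_low &
                    rng$stomach_pam_percent <= rng$pam_high))
})

test_that("zero noise and identity drift reproduce truth through the chain", {
  cfg <- generator_config(
    n_per_cell = 2, biological_sd = 0, measurement_sd = 0,
    noise_sd_crm = 0, drift_slope = 1, drift_intercept = 0
  )
  b <- generate_study(cfg)
  res <- run_pipeline(b)
  # normalized deltas equal the true FAME deltas
  joined <- merge(res$deltas, b$ground_truth$true_deltas, by = "sample_id")
  expect_equal(joined$delta_vpdb_mur, joined$delta_fame_true,
               tolerance = 1e-9)
  # corrected deltas equal the true fatty-acid deltas
  expect_equal(joined$delta_fa_mur, joined$delta_fa_true, tolerance = 1e-9)
  # quantified amounts equal the configured truth
  amounts <- merge(res$composition, b$ground_truth$true_amounts,
                   by = c("sample_id", "species"))
  expect_equal(amounts$amount_ug, amounts$amount_true, tolerance = 1e-9)
  # recovered fractions equal f_true
  fr <- merge(res$mixing, b$ground_truth$f_true, by = "sample_id")
  expect_equal(fr$fraction_sugar, fr$f_true, tolerance = 1e-9)
})

test_that("an all-sugar pool lands exactly on the sugar end-member", {
  cfg <- generator_config(
    n_per_cell = 1, tissues = "brain", biological_sd = 0,
    measurement_sd = 0, noise_sd_crm = 0, drift_slope = 1,
    drift_intercept = 0,
    f_true = dplyr::mutate(default_f_true(), f_true = 1)
  )
  res <- run_pipeline(generate_study(cfg))
  expect_equal(res$deltas$delta_fa_mur,
               rep(sugar_signature()$delta_mur, nrow(res$deltas)),
               tolerance = 1e-9)
})

test_that("default-noise deltas stay in the physical mixing regime", {
  b <- generate_study(generator_config())
  res <- run_pipeline(b)
  sugar <- sugar_signature()$delta_mur
  fat_min <- min(-29.70, -29.44)
  total_sd <- sqrt(0.5^2 + 0.3^2)
  expect_true(all(res$deltas$delta_fa_mur > fat_min - 3 * total_sd))
  expect_true(all(res$deltas$delta_fa_mur < sugar + 3 * total_sd))
})

test_that("the null generator zeroes diet and time structure", {
  bn <- generate_null(generator_config(n_per_cell = 2))
  expect_equal(length(unique(bn$ground_truth$f_true$f_true)), 1)
  # same schema as the standard bundle
  b <- generate_study(generator_config(n_per_cell = 2))
  expect_identical(names(bn), names(b))
  expect_identical(names(bn$raw_delta_table), names(b$raw_delta_table))
  expect_identical(names(bn$crm_table), names(b$crm_table))
  # every diet now carries the same palmitate end-member
  fats <- purrr::map_dbl(
    c("LP", "MP", "HP"),
    \(d) fat_endmember(bn$ground_truth$config$diets, d)$delta_mur
  )
  expect_equal(diff(range(fats)), 0, tolerance = 1e-12)
})

test_that("configs are validated", {
  expect_error(generator_config(n_per_cell = 0))
  bad_f <- dplyr::mutate(default_f_true(), f_true = f_true + 1)
  expect_error(generator_config(f_true = bad_f))
  incomplete <- default_f_true()[-1, ]
  expect_error(generator_config(f_true = incomplete), "every diet")
})

test_that("write_bundle emits the pipeline-facing CSV dialects", {
  b <- generate_study(generator_config(n_per_cell = 1))
  dir <- withr::local_tempdir()
  paths <- write_bundle(b, dir)
  expect_true(file.exists(file.path(dir, "crm_table.csv")))
  crm <- utils::read.csv(file.path(dir, "crm_table.csv"))
  expect_true(all(c("sequence_id", "certified_delta_mur",
                    "measured_delta_mur") %in% names(crm)))
  raw <- utils::read.csv(file.path(dir, "raw_delta_table.csv"))
  meta <- utils::read.csv(file.path(dir, "sample_metadata.csv"))
  peaks <- utils::read.csv(file.path(dir, "peak_table.csv"))
  # the round trip through CSV still runs the pipeline
  res <- run_pipeline(list(crm_table = crm, raw_delta_table = raw,
                           peak_table = peaks, sample_metadata = meta))
  expect_equal(nrow(res$mixing), nrow(meta))
})
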