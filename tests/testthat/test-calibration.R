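test_that("identity and affine calibrations are recovered exactly", {
  fit <- fit_normalization(make_crms())
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$n_points, 3L)
  expect_true(fit$gate_passed)

  fit2 <- fit_normalization(make_crms(a = 1.02, b = 0.8))
  expect_equal(fit2$slope, 1.02, tolerance = 1e-9)
  expect_equal(fit2$intercept, 0.8, tolerance = 1e-9)
  expect_equal(fit2$r_squared, 1, tolerance = 1e-9)

  # independent closed-form least-squares oracle
  crms <- make_crms(a = 0.97, b = -2.3, certified = c(-28, -17, -5, 2))
  x <- crms$measured_delta_mur; y <- crms$certified_delta_mur
  slope_oracle <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept_oracle <- mean(y) - slope_oracle * mean(x)
  fit3 <- fit_normalization(crms)
  expect_equal(fit3$slope, slope_oracle, tolerance = 1e-12)
  expect_equal(fit3$intercept, intercept_oracle, tolerance = 1e-12)
})

test_that("applying a normalization is the fitted affine map", {
  m <- fit_normalization(make_crms())
  expect_equal(apply_normalization(m, -29.70), -29.70, tolerance = 1e-10)
  m2 <- fit_normalization(make_crms(a = 1.02, b = 0.8))
  expect_equal(apply_normalization(m2, -30), -29.8, tolerance = 1e-9)
  # held-out recovery at zero noise: raw values made with the generating
  # distortion come back to their true deltas
  truth <- c(-34.2, -22.7, -12.01, -3.3)
  raw <- (truth - 0.8) / 1.02
  expect_equal(apply_normalization(m2, raw), truth, tolerance = 1e-8)
  expect_error(apply_normalization(list(), -20), "vpdb_calibration")
})

test_that("noiseless affine recovery holds across slopes and intercepts", {
  set.seed(7)
  for (i in 1:25) {
    a <- runif(1, 0.9, 1.1)
    b <- runif(1, -5, 5)
    fit <- fit_normalization(make_crms(a = a, b = b))
    expect_equal(fit$slope, a, tolerance = 1e-9)
    expect_equal(fit$intercept, b, tolerance = 1e-9)
    expect_true(fit$gate_passed)
  }
})

test_that("degenerate CRM sets raise calibration failures", {
  expect_error(fit_normalization(make_crms(certified = -20)), ">= 2")
  crms <- make_crms()
  crms$measured_delta_mur <- -15 # all equal
  expect_error(fit_normalization(crms), "distinct")
  expect_error(fit_normalization(data.frame(x = 1)), "must contain columns")
})

test_that("the R^2 gate warns under heavy noise but passes clean fits", {
  # 20 mUr CRM span, 1 mUr injected noise: the gate should fire often
  fired <- vapply(1:100, function(s) {
    crms <- make_crms(certified = c(-30, -20, -10), noise_sd = 1, seed = s)
    fit <- suppressWarnings(fit_normalization(crms))
    !fit$gate_passed
  }, logical(1))
  expect_gt(mean(fired), 0.5)
  # and the warning is a warning, not an error
  crms_bad <- make_crms(certified = c(-30, -20, -10), noise_sd = 1, seed = 11)
  if (!suppressWarnings(fit_normalization(crms_bad))$gate_passed) {
    expect_warning(fit_normalization(crms_bad), "below gate")
  }
})

test_that("CRM order does not affect the fit", {
  crms <- make_crms(a = 1.01, b = 0.4, noise_sd = 0.05, seed = 3)
  f1 <- fit_normalization(crms)
  f2 <- fit_normalization(crms[c(3, 1, 2), ])
  expect_equal(f1$slope, f2$slope)
  expect_equal(f1$intercept, f2$intercept)
  expect_equal(f1$r_squared, f2$r_squared)
})

test_that("per-sequence normalization joins samples to their own fit", {
  crms <- rbind(
    cbind(sequence_id = "s1", make_crms(a = 1.02, b = 0.8)),
    cbind(sequence_id = "s2", make_crms(a = 0.98, b = -0.5))
  )
  samples <- data.frame(
    sample_id = c("x1", "x2"),
    sequence_id = c("s1", "s2"),
    delta_raw_mur = c((-25 - 0.8) / 1.02, (-25 + 0.5) / 0.98)
  )
  out <- normalize_sequences(samples, crms)
  expect_equal(out$delta_vpdb_mur, c(-25, -25), tolerance = 1e-8)
  log <- attr(out, "calibrations")
  expect_equal(nrow(log), 2)
  expect_equal(sort(log$slope), c(0.98, 1.02), tolerance = 1e-8)
  # scale mismatch: normalizing twice is rejected
  expect_error(normalize_sequences(out, crms), "Scale mismatch")
  # samples from a sequence with no CRMs
  samples$sequence_id[2] <- "s9"
  expect_error(normalize_sequences(samples, crms), "s9")
})

test_that("tidy and glance expose the calibration summary", {
  fit <- fit_normalization(make_crms(a = 1.02, b = 0.8))
  td <- tidy(fit)
  expect_equal(td$term, c("intercept", "slope"))
  expect_equal(td$estimate, c(0.8, 1.02), tolerance = 1e-9)
  gl <- glance(fit)
  expect_true(gl$gate.passed)
  expect_equal(gl$n, 3L)
})
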