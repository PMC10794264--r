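#' Fit a multipoint VPDB normalization from certified reference materials
#'
#' GC-C-IRMS reports delta-13C on an instrument-local scale; certified
#' reference materials (CRMs, e.g. USGS70/71/72) injected in each sequence
#' anchor it to the international VPDB scale. The normalization is an
#' ordinary least-squares line predicting the certified ("true") delta from
#' the measured delta, so the fitted equation applies directly to unknowns.
#' A quality gate warns when the fit's R-squared falls below `r2_gate`
#' (normalization fits on well-behaved sequences exceed 0.999); the warning
#' is recorded on the model, not fatal, because a low R-squared is a QC
#' observation rather than an exclusion rule.
#'
#' @param crms Data frame of CRM injections with at least the columns named
#'   by `measured` and `certified` (delta-13C in mUr).
#' @param measured,certified Column names (strings) holding the measured
#'   (raw instrument) and certified (VPDB) deltas.
#' @param r2_gate R-squared threshold below which a QC warning is raised.
#' @return An object of class `vpdb_calibration`: a list with `slope`,
#'   `intercept`, `r_squared`, `n_points`, `gate_passed` and the underlying
#'   `lm` fit. `tidy()` and `glance()` methods are provided.
#' @examples
#' crms <- data.frame(
#'   crm_id = c("A", "B", "C"),
#'   certified_delta_mur = c(-30, -10, -1),
#'   measured_delta_mur = (c(-30, -10, -1) - 0.8) / 1.02
#' )
#' fit <- fit_normalization(crms)
#' glance(fit)
#' @export
fit_normalization <- function(crms,
                              measured = "measured_delta_mur",
                              certified = "certified_delta_mur",
                              r2_gate = iso_constants()$r2_gate) {
  stopifnot(is.data.frame(crms))
  if (!all(c(measured, certified) %in% names(crms))) {
    stop("`crms` must contain columns `", measured, "` and `", certified, "`",
         call. = FALSE)
  }
  x <- crms[[measured]]
  y <- crms[[certified]]
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("CRM deltas must be finite", call. = FALSE)
  }
  if (length(x) < 2 || length(unique(x)) < 2) {
    stop("Calibration failure: need >= 2 CRMs with distinct measured deltas",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  # a perfect (noise-free) fit makes summary.lm warn; the R^2 is still valid
  smry <- suppressWarnings(summary(fit))
  r2 <- if (stats::var(y) == 0) 1 else smry$r.squared
  gate_passed <- r2 > r2_gate
  if (!gate_passed) {
    warning(sprintf("Normalization R^2 = %.6f below gate %.3f", r2, r2_gate),
            call. = FALSE)
  }
  structure(
    list(
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r_squared = r2,
      n_points = length(x),
      r2_gate = r2_gate,
      gate_passed = gate_passed,
      fit = fit
    ),
    class = "vpdb_calibration"
  )
}

#' @export
print.vpdb_calibration <- function(x, ...) {
  cat(sprintf(
    "<vpdb_calibration> delta_vpdb = %.5f * delta_raw + %+.4f (R^2 = %.6f, n = %d)%s\n",
    x$slope, x$intercept, x$r_squared, x$n_points,
    if (x$gate_passed) "" else "  [R^2 gate FAILED]"
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.vpdb_calibration <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = unname(suppressWarnings(summary(x$fit))$coefficients[, "Std. Error"])
  )
}

#' @export
glance.vpdb_calibration <- function(x, ...) {
  tibble::tibble(
    slope = x$slope,
    intercept = x$intercept,
    r.squared = x$r_squared,
    n = x$n_points,
    gate.passed = x$gate_passed
  )
}

#' Apply a VPDB normalization to raw instrument deltas
#'
#' @param model A `vpdb_calibration` from [fit_normalization()].
#' @param delta Numeric vector of raw instrument delta-13C values (mUr).
#' @return Normalized delta-13C on the VPDB scale.
#' @examples
#' m <- structure(list(slope = 1.02, intercept = 0.8), class = "vpdb_calibration")
#' apply_normalization(m, -30)  # -29.8
#' @export
apply_normalization <- function(model, delta) {
  if (!inherits(model, "vpdb_calibration")) {
    stop("`model` must be a vpdb_calibration", call. = FALSE)
  }
  check_delta(delta)
  model$slope * delta + model$intercept
}

#' Per-sequence calibration and normalization of a sample table
#'
#' Fits one normalization per instrument sequence from a CRM table and
#' applies it to every sample measured in that sequence. This mirrors
#' routine practice: each CRM set is injected at least once per sequence
#' and normalizes only that sequence's unknowns.
#'
#' @param samples Data frame with columns `sequence_id` and `delta_raw_mur`.
#' @param crms Data frame with columns `sequence_id`, `certified_delta_mur`,
#'   `measured_delta_mur`.
#' @param r2_gate R-squared QC gate (see [fit_normalization()]).
#' @return `samples` with an added `delta_vpdb_mur` column, and an attribute
#'   `"calibrations"`: a tibble of per-sequence slope, intercept, R-squared,
#'   n and gate status (the run log).
#' @export
normalize_sequences <- function(samples, crms,
                                r2_gate = iso_constants()$r2_gate) {
  stopifnot(is.data.frame(samples), is.data.frame(crms))
  if ("delta_vpdb_mur" %in% names(samples)) {
    stop("Scale mismatch: `samples` already carries `delta_vpdb_mur` ",
         "(normalizing twice is not meaningful)", call. = FALSE)
  }
  req_s <- c("sequence_id", "delta_raw_mur")
  req_c <- c("sequence_id", "certified_delta_mur", "measured_delta_mur")
  if (!all(req_s %in% names(samples))) {
    stop("`samples` needs columns: ", paste(req_s, collapse = ", "), call. = FALSE)
  }
  if (!all(req_c %in% names(crms))) {
    stop("`crms` needs columns: ", paste(req_c, collapse = ", "), call. = FALSE)
  }
  missing_seq <- setdiff(unique(samples$sequence_id), unique(crms$sequence_id))
  if (length(missing_seq)) {
    stop("No CRM injections for sequence(s): ",
         paste(missing_seq, collapse = ", "), call. = FALSE)
  }
  models <- crms |>
    dplyr::group_by(.data$sequence_id) |>
    dplyr::group_map(\(d, key) {
      fit <- fit_normalization(d, r2_gate = r2_gate)
      dplyr::bind_cols(key, glance(fit), tibble::tibble(model = list(fit)))
    }) |>
    dplyr::bind_rows()

  lookup <- stats::setNames(models$model, models$sequence_id)
  out <- samples |>
    dplyr::mutate(delta_vpdb_mur = purrr::map2_dbl(
      .data$sequence_id, .data$delta_raw_mur,
      \(sq, d) apply_normalization(lookup[[as.character(sq)]], d)
    ))
  attr(out, "calibrations") <- dplyr::select(models, -"model")
  out
}

#' Diagnostic plot of a VPDB calibration fit
#'
#' Measured vs certified CRM deltas with the fitted normalization line.
#'
#' @param model A `vpdb_calibration`.
#' @return A ggplot object.
#' @export
plot_calibration <- function(model) {
  stopifnot(inherits(model, "vpdb_calibration"))
  d <- tibble::tibble(
    measured = model$fit$model$x,
    certified = model$fit$model$y
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$measured, .data$certified)) +
    ggplot2::geom_abline(
      slope = model$slope, intercept = model$intercept,
      linetype = 2, colour = "grey40"
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = expression("Measured " * delta^13 * "C (mUr)"),
      y = expression("Certified " * delta^13 * "C (mUr, VPDB)"),
      subtitle = sprintf("slope %.4f, intercept %+.3f mUr, R² %.6f",
                         model$slope, model$intercept, model$r_squared)
    ) +
    ggplot2::theme_minimal()
}
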