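#' Two-end-member isotope mixing fraction
#'
#' Apportions a tissue fatty-acid pool between two isotopically distinct
#' sources: the 13C-enriched dietary-sugars end-member (the substrate of de
#' novo lipogenesis, DNL) and the 13C-depleted dietary-fat end-member
#' (direct incorporation of the dietary fatty acid). Linear two-pool mixing
#' in delta space gives the sugar-derived (DNL) fraction
#'
#'   `f = (delta_tissue - delta_fat) / (delta_sugar - delta_fat)`.
#'
#' At natural abundance, mixing in delta space and in atom-fraction space
#' differ by less than 0.1% of the fraction; both are available and delta
#' space is the default.
#'
#' The raw fraction can fall outside `[0, 1]` when the tissue is more
#' depleted than the fat end-member (other depleted molecules — ketones,
#' ketogenic amino acids — supplying acetyl-CoA) or more enriched than the
#' sugars. Such values are clamped and flagged rather than inventing a
#' third source. Uncertainty comes either from first-order (delta-method)
#' propagation of the three input SDs or from seeded Monte-Carlo draws
#' truncated at the physical bounds.
#'
#' @param delta_tissue Tissue fatty-acid delta-13C (VPDB, methyl-corrected,
#'   mUr). Vectorized.
#' @param sugar,fat End-member signatures: one-row data frames with
#'   `delta_mur` and `sd_mur` (as returned by [sugar_signature()] /
#'   [diet_fat_signature()]), or bare numbers.
#' @param sd_tissue Optional 1-SD uncertainty of `delta_tissue` (mUr),
#'   recycled.
#' @param method `"analytic"` (delta-method CI) or `"montecarlo"`.
#' @param space `"delta"` (default) or `"atom_fraction"` mixing space.
#' @param conf Confidence level for the interval.
#' @param n_draws,seed Monte-Carlo settings.
#' @param min_separation Minimum end-member separation (mUr) below which
#'   mixing is degenerate and an error is raised.
#' @return A tibble of class `mixing_estimate`, one row per tissue value:
#'   `delta_tissue_mur`, `raw_fraction`, `fraction_sugar` (clamped to
#'   `[0, 1]`), `ci_low`, `ci_high`, `clamped`, `method`.
#' @examples
#' mixing_fraction(-16.47, sugar = -11.15, fat = -29.70)  # f = 0.713
#' @export
mixing_fraction <- function(delta_tissue, sugar, fat, sd_tissue = NULL,
                            method = c("analytic", "montecarlo"),
                            space = c("delta", "atom_fraction"),
                            conf = 0.95, n_draws = 10000, seed = 20240117,
                            min_separation = 1) {
  method <- match.arg(method)
  space <- match.arg(space)
  get_dm <- function(x, what) {
    if (is.data.frame(x)) {
      if (isTRUE(x[["absent"]])) {
        stop("Absent ", what, " end-member: this diet lacks the target ",
             "fatty acid; supply a substitute end-member (see ",
             "`substitute_fat_endmember()`)", call. = FALSE)
      }
      c(x[["delta_mur"]][1], if ("sd_mur" %in% names(x)) x[["sd_mur"]][1] else 0)
    } else {
      c(x, 0)
    }
  }
  s <- get_dm(sugar, "sugar")
  f_ <- get_dm(fat, "fat")
  if (any(!is.finite(c(s[1], f_[1])))) {
    stop("End-member deltas must be finite", call. = FALSE)
  }
  check_delta(delta_tissue, "delta_tissue")
  sep <- s[1] - f_[1]
  if (abs(sep) < min_separation) {
    stop("Degenerate mixing: end-member separation ", signif(abs(sep), 3),
         " mUr is below the ", min_separation, " mUr minimum", call. = FALSE)
  }
  sd_t <- if (is.null(sd_tissue)) rep(0, length(delta_tissue)) else {
    stopifnot(all(sd_tissue >= 0))
    rep_len(sd_tissue, length(delta_tissue))
  }
  sd_s <- ifelse(is.finite(s[2]), s[2], 0)
  sd_f <- ifelse(is.finite(f_[2]), f_[2], 0)

  frac_of <- function(dt, ds, df) {
    if (space == "delta") {
      (dt - df) / (ds - df)
    } else {
      ft <- delta_to_atom_fraction(dt); fs <- delta_to_atom_fraction(ds)
      ff <- delta_to_atom_fraction(df)
      (ft - ff) / (fs - ff)
    }
  }
  raw <- frac_of(delta_tissue, s[1], f_[1])
  clamped_val <- pmin(1, pmax(0, raw))
  z <- stats::qnorm(1 - (1 - conf) / 2)

  if (method == "analytic") {
    # first-order propagation of var(f) for f = (dt - df)/(ds - df)
    se <- sqrt(sd_t^2 + raw^2 * sd_s^2 + (1 - raw)^2 * sd_f^2) / abs(sep)
    ci_low <- pmax(0, raw - z * se)
    ci_high <- pmin(1, raw + z * se)
  } else {
    set.seed(seed)
    ci_low <- ci_high <- numeric(length(raw))
    for (i in seq_along(raw)) {
      draws <- frac_of(
        stats::rnorm(n_draws, delta_tissue[i], sd_t[i]),
        stats::rnorm(n_draws, s[1], sd_s),
        stats::rnorm(n_draws, f_[1], sd_f)
      )
      draws <- pmin(1, pmax(0, draws))
      q <- stats::quantile(draws, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                           names = FALSE)
      ci_low[i] <- q[1]; ci_high[i] <- q[2]
    }
  }
  out <- tibble::tibble(
    delta_tissue_mur = delta_tissue,
    raw_fraction = raw,
    fraction_sugar = clamped_val,
    ci_low = pmin(ci_low, clamped_val),
    ci_high = pmax(ci_high, clamped_val),
    clamped = raw < 0 | raw > 1,
    method = method
  )
  class(out) <- c("mixing_estimate", class(out))
  attr(out, "endmembers") <- tibble::tibble(
    role = c("sugar", "fat"),
    delta_mur = c(s[1], f_[1]),
    sd_mur = c(sd_s, sd_f)
  )
  attr(out, "space") <- space
  if (method == "montecarlo") {
    attr(out, "n_draws") <- n_draws
    attr(out, "seed") <- seed
  }
  out
}

#' @export
glance.mixing_estimate <- function(x, ...) {
  tibble::tibble(
    n = nrow(x),
    mean_fraction = mean(x$fraction_sugar),
    n_clamped = sum(x$clamped),
    method = x$method[1],
    space = attr(x, "space")
  )
}

#' Substitute fat end-member for a diet lacking the target fatty acid
#'
#' The low-palmitate diet contains no palmitic acid, so it has no dietary
#' PAM delta of its own. The conventional substitute is the mean of the
#' other diets' measured deltas for the same species (SD pooled
#' quadratically), returned flagged as `substituted` so the provenance
#' stays visible in outputs.
#'
#' @param diets Diet composition table.
#' @param diet The diet missing the end-member (e.g. `"LP"`).
#' @param species Target species shorthand.
#' @param donors Diets to average over (default all others with a value).
#' @return A one-row signature tibble with `substituted = TRUE`.
#' @examples
#' substitute_fat_endmember(diet = "LP")  # mean of MP and HP dietary PAM
#' @export
substitute_fat_endmember <- function(diets = diet_composition(), diet,
                                     species = "16:0", donors = NULL) {
  all_diets <- setdiff(unique(diets$diet), diet)
  if (!is.null(donors)) all_diets <- intersect(all_diets, donors)
  sigs <- purrr::map(all_diets, \(d) diet_fat_signature(diets, d, species)) |>
    dplyr::bind_rows()
  if (nrow(sigs)) sigs <- dplyr::filter(sigs, !.data$absent)
  if (nrow(sigs) == 0) {
    stop("No donor diet carries a measured ", species, " delta", call. = FALSE)
  }
  tibble::tibble(
    label = paste0("dietary ", species, " (substituted for ", diet, ")"),
    delta_mur = mean(sigs$delta_mur),
    sd_mur = sqrt(mean(sigs$sd_mur^2)),
    diet = diet, species = species,
    absent = FALSE, substituted = TRUE
  )
}

#' Fat end-member for a diet, substituting when absent
#'
#' @inheritParams substitute_fat_endmember
#' @return A one-row signature tibble; `substituted` marks fallback use.
#' @export
fat_endmember <- function(diets = diet_composition(), diet, species = "16:0") {
  sig <- diet_fat_signature(diets, diet, species)
  if (sig$absent) {
    substitute_fat_endmember(diets, diet, species)
  } else {
    dplyr::mutate(sig, substituted = FALSE)
  }
}

#' Dose-response ordering of mixing fractions across diet groups
#'
#' The biological expectation is that the sugar-derived (DNL) fraction
#' rises as dietary supply of the fatty acid falls: f(LP) >= f(MP) >=
#' f(HP). This report checks that ordering on group-level estimates and
#' lists every violating pair with the propagated uncertainty of its
#' difference.
#'
#' @param estimates Data frame with columns `diet`, `fraction_sugar` and
#'   optionally `se` (or `ci_low`/`ci_high`, from which an SE is backed
#'   out). One row per diet group, or per-sample rows which are averaged.
#' @param order Expected ordering of diets from highest to lowest fraction.
#' @return A list of class `dose_response_report`: `monotone` (logical),
#'   `group_means`, `pairs` (each adjacent pair, its difference, SE and
#'   whether it conforms), `violations`.
#' @examples
#' est <- data.frame(diet = c("LP", "MP", "HP"),
#'                   fraction_sugar = c(0.9, 0.8, 0.7))
#' dose_response_profile(est)$monotone
#' @export
dose_response_profile <- function(estimates, order = c("LP", "MP", "HP")) {
  stopifnot(is.data.frame(estimates))
  if (!all(c("diet", "fraction_sugar") %in% names(estimates))) {
    stop("`estimates` needs columns `diet` and `fraction_sugar`", call. = FALSE)
  }
  present <- intersect(order, unique(estimates$diet))
  if (length(present) < 2) stop("Need estimates for >= 2 diet groups", call. = FALSE)

  groups <- estimates |>
    dplyr::filter(.data$diet %in% present) |>
    dplyr::group_by(.data$diet) |>
    dplyr::summarise(
      mean_fraction = mean(.data$fraction_sugar),
      se = if (dplyr::n() > 1) {
        stats::sd(.data$fraction_sugar) / sqrt(dplyr::n())
      } else if ("se" %in% names(estimates)) {
        .data$se[1]
      } else if (all(c("ci_low", "ci_high") %in% names(estimates))) {
        (.data$ci_high[1] - .data$ci_low[1]) / (2 * stats::qnorm(0.975))
      } else {
        NA_real_
      },
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$diet, order))

  pairs <- tibble::tibble(
    higher = utils::head(groups$diet, -1),
    lower = utils::tail(groups$diet, -1),
    difference = utils::head(groups$mean_fraction, -1) -
      utils::tail(groups$mean_fraction, -1),
    se_difference = sqrt(utils::head(groups$se, -1)^2 +
                           utils::tail(groups$se, -1)^2)
  ) |>
    dplyr::mutate(conforms = .data$difference >= 0)

  structure(
    list(
      monotone = all(pairs$conforms),
      group_means = groups,
      pairs = pairs,
      violations = dplyr::filter(pairs, !.data$conforms)
    ),
    class = "dose_response_report"
  )
}

#' @export
print.dose_response_report <- function(x, ...) {
  cat("<dose_response_report> monotone decreasing across diets:",
      if (x$monotone) "YES" else "NO", "\n")
  print(x$group_means)
  if (!x$monotone) {
    cat("Violating pairs:\n")
    print(x$violations)
  }
  invisible(x)
}

#' Plot mixing fractions by diet group and timepoint
#'
#' @param estimates Data frame with columns `diet`, `fraction_sugar`, and
#'   optionally `timepoint`.
#' @return A ggplot object.
#' @export
plot_mixing_fractions <- function(estimates) {
  stopifnot(is.data.frame(estimates))
  p <- ggplot2::ggplot(
    estimates,
    ggplot2::aes(.data$diet, .data$fraction_sugar, colour = .data$diet)
  )
  if ("timepoint" %in% names(estimates)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$timepoint), nrow = 1)
  }
  p +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar",
                          width = 0.4, linewidth = 0.3) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "Diet group",
      y = "Sugar-derived (DNL) fraction of pool",
      colour = NULL
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
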