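#' ROUT outlier screen for a single group of values
#'
#' Robust outlier detection at a controlled false-discovery rate, applied
#' to the constant (one-sample) model: location is the median, scale is the
#' robust standard deviation of the residuals (the 68.27th percentile of
#' their absolute values, inflated by n/(n - 1) for the one fitted
#' parameter). Residual t-scores are tested outermost-first against a
#' Benjamini-Hochberg-style threshold at FDR level Q: the i-th outermost
#' point is flagged while its two-sided t-tail probability stays below
#' `q * i / n`, and the sweep stops at the first non-significant point.
#'
#' @param values Numeric vector, n >= 3 (smaller inputs are returned
#'   unscreened with a message).
#' @param q FDR level Q in (0, 0.1]; default 0.01 (i.e. Q = 1%).
#' @return A list of class `rout_screen`: `retained`, `outliers`,
#'   `location`, `scale`, and `decisions`, a per-point log tibble with
#'   columns `value`, `abs_residual`, `t`, `p`, `threshold`, `outlier`.
#' @examples
#' rout_screen(c(5.0, 5.1, 4.9, 5.05, 50.0))$outliers
#' @export
rout_screen <- function(values, q = iso_constants()$rout_q) {
  stopifnot(is.numeric(values), q > 0, q <= 0.1)
  n <- length(values)
  if (n < 3) {
    message("ROUT screen skipped: need n >= 3, got ", n)
    return(structure(
      list(retained = values, outliers = numeric(0),
           location = stats::median(values), scale = NA_real_,
           decisions = tibble::tibble()),
      class = "rout_screen"
    ))
  }
  location <- stats::median(values)
  resid <- values - location
  # robust SD: 68.27th percentile of |residuals|, small-n inflated
  rsdr <- unname(stats::quantile(abs(resid), 0.6827, type = 7)) * n / (n - 1)
  df <- n - 1

  if (rsdr == 0) {
    decisions <- tibble::tibble(
      value = values, abs_residual = abs(resid), t = 0, p = 1,
      threshold = q / n, outlier = FALSE
    )
    return(structure(
      list(retained = values, outliers = numeric(0),
           location = location, scale = 0, decisions = decisions),
      class = "rout_screen"
    ))
  }

  ord <- order(abs(resid), decreasing = TRUE)
  t_stat <- abs(resid) / rsdr
  p_val <- 2 * stats::pt(t_stat, df = df, lower.tail = FALSE)
  outlier <- rep(FALSE, n)
  threshold <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    j <- ord[i]
    threshold[j] <- q * i / n
    if (p_val[j] < threshold[j]) outlier[j] <- TRUE else break
  }
  structure(
    list(
      retained = values[!outlier],
      outliers = values[outlier],
      location = location,
      scale = rsdr,
      decisions = tibble::tibble(
        value = values, abs_residual = abs(resid), t = t_stat,
        p = p_val, threshold = threshold, outlier = outlier
      )
    ),
    class = "rout_screen"
  )
}

#' @export
print.rout_screen <- function(x, ...) {
  cat(sprintf("<rout_screen> %d retained, %d outlier(s); median %.4g, robust SD %.4g\n",
              length(x$retained), length(x$outliers), x$location, x$scale))
  if (length(x$outliers)) cat("outliers:", paste(signif(x$outliers, 6), collapse = ", "), "\n")
  invisible(x)
}

#' ROUT-screen a response column within groups
#'
#' Data-frame verb applying [rout_screen()] within each combination of the
#' grouping columns and dropping flagged rows; removals are logged on the
#' `"rout_log"` attribute.
#'
#' @param data Data frame.
#' @param response Name of the response column (string).
#' @param ... Grouping columns (tidy-select style strings), e.g. `"diet"`,
#'   `"timepoint"`.
#' @param q FDR level Q.
#' @return Filtered tibble with attribute `"rout_log"`.
#' @export
rout_filter <- function(data, response, ..., q = iso_constants()$rout_q) {
  stopifnot(is.data.frame(data), response %in% names(data))
  groups <- c(...)
  keyed <- if (length(groups)) {
    dplyr::group_by(data, dplyr::across(dplyr::all_of(groups)))
  } else {
    dplyr::group_by(data)
  }
  log <- list()
  out <- keyed |>
    dplyr::group_map(\(d, key) {
      scr <- rout_screen(d[[response]], q = q)
      keep <- !(d[[response]] %in% scr$outliers)
      if (any(!keep)) {
        log[[length(log) + 1]] <<- dplyr::bind_cols(
          key[rep(1, sum(!keep)), , drop = FALSE],
          tibble::tibble(removed_value = d[[response]][!keep])
        )
      }
      dplyr::bind_cols(key[rep(1, sum(keep)), , drop = FALSE],
                       d[keep, setdiff(names(d), names(key)), drop = FALSE])
    }) |>
    dplyr::bind_rows()
  attr(out, "rout_log") <- if (length(log)) dplyr::bind_rows(log) else tibble::tibble()
  out
}

#' Two-way diet-by-time ANOVA with conditional Tukey post hoc
#'
#' Fixed-effects two-factor analysis of variance under the assumption of
#' normality, with type-III sums of squares (sum-to-zero contrasts) so that
#' mildly unbalanced designs — litters differing in n — are handled
#' sensibly. Tukey's multiple-comparisons test on the interaction cells is
#' appended only when the interaction is significant at `alpha`, following
#' standard practice for dose-by-time designs.
#'
#' @param data Data frame of per-sample measurements.
#' @param response Response column name (string): a delta-13C, a
#'   concentration, or a relative percent.
#' @param factor_a,factor_b Factor column names (strings); defaults `"diet"`
#'   and `"timepoint"`.
#' @param alpha Significance level gating the post hoc.
#' @return A list of class `fa_anova`: `effects` (term, df, F, p),
#'   `posthoc` (Tukey-adjusted pairwise interaction contrasts, or `NULL`),
#'   `alpha`, `n`. `tidy()` returns the effects table, `glance()` a
#'   one-row summary.
#' @export
two_way_anova <- function(data, response, factor_a = "diet",
                          factor_b = "timepoint",
                          alpha = iso_constants()$alpha) {
  stopifnot(is.data.frame(data),
            all(c(response, factor_a, factor_b) %in% names(data)))
  df <- data.frame(
    y = data[[response]],
    a = factor(data[[factor_a]]),
    b = factor(data[[factor_b]])
  )
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nlevels(droplevels(df$a)) < 2 || nlevels(droplevels(df$b)) < 2) {
    stop("Need >= 2 levels of each factor", call. = FALSE)
  }
  cells <- table(df$a, df$b)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    stop("Unbalanced design, empty cell(s): ",
         paste(rownames(cells)[empty[, 1]], colnames(cells)[empty[, 2]],
               sep = ":", collapse = ", "), call. = FALSE)
  }

  if (stats::var(df$y) == 0) {
    effects <- tibble::tibble(
      term = c(factor_a, factor_b, paste0(factor_a, ":", factor_b)),
      df = NA_real_, statistic = 0, p.value = 1
    )
    return(structure(list(effects = effects, posthoc = NULL,
                          alpha = alpha, n = nrow(df)),
                     class = "fa_anova"))
  }

  n_cells <- nlevels(droplevels(df$a)) * nlevels(droplevels(df$b))
  if (nrow(df) - n_cells < 1) {
    stop("No residual degrees of freedom: need more than one observation ",
         "in at least one cell to fit the interaction model", call. = FALSE)
  }
  fit <- stats::lm(y ~ a * b, data = df,
                   contrasts = list(a = "contr.sum", b = "contr.sum"))
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((df$y - mean(df$y))^2)
  if (rss <= 1e-10 * tss) {
    # deterministic cell means: every effect with non-zero SS is certain
    seq_tab <- suppressWarnings(stats::anova(stats::aov(y ~ a * b, data = df)))
    ss <- seq_tab[c("a", "b", "a:b"), "Sum Sq"]
    effects <- tibble::tibble(
      term = c(factor_a, factor_b, paste0(factor_a, ":", factor_b)),
      df = seq_tab[c("a", "b", "a:b"), "Df"],
      statistic = ifelse(ss > 1e-10 * tss, Inf, 0),
      p.value = ifelse(ss > 1e-10 * tss, 0, 1)
    )
    return(structure(list(effects = effects, posthoc = NULL,
                          alpha = alpha, n = nrow(df)),
                     class = "fa_anova"))
  }
  tab <- car::Anova(fit, type = 3)
  rows <- c("a", "b", "a:b")
  effects <- tibble::tibble(
    term = c(factor_a, factor_b, paste0(factor_a, ":", factor_b)),
    df = tab[rows, "Df"],
    statistic = tab[rows, "F value"],
    p.value = tab[rows, "Pr(>F)"]
  )

  posthoc <- NULL
  p_int <- effects$p.value[3]
  if (is.finite(p_int) && p_int < alpha) {
    aov_fit <- stats::aov(y ~ a * b, data = df)
    tk <- stats::TukeyHSD(aov_fit, which = "a:b")[["a:b"]]
    posthoc <- tibble::tibble(
      contrast = rownames(tk),
      difference = tk[, "diff"],
      conf.low = tk[, "lwr"],
      conf.high = tk[, "upr"],
      adj.p.value = tk[, "p adj"]
    )
  }
  structure(list(effects = effects, posthoc = posthoc,
                 alpha = alpha, n = nrow(df)),
            class = "fa_anova")
}

#' @export
tidy.fa_anova <- function(x, ...) x$effects

#' @export
glance.fa_anova <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    interaction.p = x$effects$p.value[3],
    posthoc.run = !is.null(x$posthoc),
    alpha = x$alpha
  )
}

#' @export
print.fa_anova <- function(x, ...) {
  cat("<fa_anova> type-III two-way ANOVA, n =", x$n, "\n")
  print(x$effects)
  if (!is.null(x$posthoc)) {
    cat("Tukey post hoc (interaction significant at alpha =", x$alpha, "):\n")
    print(x$posthoc, n = 6)
  }
  invisible(x)
}

#' Normality-gated one-way comparison
#'
#' Single-timepoint (or single-factor) group contrasts follow a Shapiro-
#' Wilk gate: if every group passes normality at `alpha`, a one-way ANOVA
#' is run; otherwise a Kruskal-Wallis rank test. Groups too small for the
#' Shapiro test (n < 3) route the comparison to the nonparametric branch
#' with a notice. The route taken is always recorded.
#'
#' @param data Data frame.
#' @param response Response column name (string).
#' @param group Grouping column name (string).
#' @param alpha Significance level, used for both the normality gate and
#'   downstream interpretation.
#' @return A list of class `gated_oneway`: `route` ("anova" or
#'   "kruskal"), `statistic`, `p.value`, `shapiro` (per-group tibble or
#'   `NULL`), `reason`.
#' @export
one_way_gate <- function(data, response, group,
                         alpha = iso_constants()$alpha) {
  stopifnot(is.data.frame(data), all(c(response, group) %in% names(data)))
  y <- data[[response]]
  g <- factor(data[[group]])
  ok <- is.finite(y) & !is.na(g)
  y <- y[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2) stop("Need >= 2 groups", call. = FALSE)

  sizes <- table(g)
  shapiro <- NULL
  if (any(sizes < 3)) {
    route <- "kruskal"
    reason <- "group n < 3: Shapiro-Wilk not applicable, nonparametric route"
    message(reason)
  } else {
    shapiro <- tibble::tibble(
      group = levels(g),
      statistic = NA_real_, p.value = NA_real_
    )
    for (i in seq_len(nlevels(g))) {
      yi <- y[g == levels(g)[i]]
      if (stats::var(yi) == 0) {
        # constant group: Shapiro undefined; treat as non-normal
        shapiro$statistic[i] <- NA_real_
        shapiro$p.value[i] <- 0
      } else {
        sw <- stats::shapiro.test(yi)
        shapiro$statistic[i] <- unname(sw$statistic)
        shapiro$p.value[i] <- sw$p.value
      }
    }
    if (all(shapiro$p.value > alpha)) {
      route <- "anova"
      reason <- "all groups pass Shapiro-Wilk"
    } else {
      route <- "kruskal"
      reason <- "at least one group fails Shapiro-Wilk"
    }
  }

  if (route == "anova") {
    fit <- stats::aov(y ~ g)
    tab <- summary(fit)[[1]]
    statistic <- tab[1, "F value"]
    p_value <- tab[1, "Pr(>F)"]
  } else {
    if (stats::var(y) == 0) {
      statistic <- 0; p_value <- 1
    } else {
      kw <- stats::kruskal.test(y, g)
      statistic <- unname(kw$statistic)
      p_value <- kw$p.value
    }
  }
  if (!is.finite(p_value)) p_value <- 1
  structure(
    list(route = route, statistic = statistic, p.value = p_value,
         shapiro = shapiro, reason = reason, alpha = alpha),
    class = "gated_oneway"
  )
}

#' @export
print.gated_oneway <- function(x, ...) {
  cat(sprintf("<gated_oneway> route: %s (%s); statistic = %.4g, p = %.4g\n",
              x$route, x$reason, x$statistic, x$p.value))
  invisible(x)
}

#' @export
tidy.gated_oneway <- function(x, ...) {
  tibble::tibble(route = x$route, statistic = x$statistic, p.value = x$p.value)
}
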