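test_that("ROUT flags a gross deviate and matches a leave-one-out oracle", {
  values <- c(5.0, 5.1, 4.9, 5.05, 50.0)
  scr <- rout_screen(values)
  expect_equal(scr$outliers, 50.0)
  expect_equal(sort(scr$retained), sort(values[values != 50]))
  # brute-force leave-one-out robust z: a point is an outlier when it sits
  # more than 10 robust SDs from the centre of the remaining points
  oracle <- vapply(seq_along(values), function(i) {
    rest <- values[-i]
    abs(values[i] - median(rest)) / max(mad(rest), 1e-12) > 10
  }, logical(1))
  expect_equal(scr$decisions$outlier, oracle)
})

test_that("ROUT spares tight clusters and degenerate inputs", {
  expect_equal(length(rout_screen(c(5.0, 5.1, 4.9, 5.05))$outliers), 0)
  # identical values: zero scale handled, nothing flagged
  const <- rout_screen(rep(3.2, 6))
  expect_equal(length(const$outliers), 0)
  expect_equal(const$scale, 0)
  # n < 3: screen skipped with a notice
  expect_message(small <- rout_screen(c(1, 2)), "skipped")
  expect_equal(small$retained, c(1, 2))
  expect_error(rout_screen(1:5, q = 0.5))
})

test_that("ROUT rarely flags anything in pure Gaussian samples", {
  flagged <- vapply(1:300, function(s) {
    set.seed(s)
    length(rout_screen(rnorm(8), q = 0.01)$outliers) > 0
  }, logical(1))
  expect_lte(mean(flagged), 0.02)
})

test_that("rout_filter removes within groups and logs removals", {
  d <- data.frame(
    diet = rep(c("LP", "HP"), each = 5),
    y = c(1.0, 1.1, 0.9, 1.05, 30, 5.0, 5.2, 4.8, 5.1, 4.9)
  )
  out <- rout_filter(d, "y", "diet")
  expect_equal(nrow(out), 9)
  log <- attr(out, "rout_log")
  expect_equal(log$removed_value, 30)
  expect_equal(log$diet, "LP")
})

test_that("two-way ANOVA agrees with the reference routine on balanced data", {
  d <- make_factorial(n = 4, diet_shift = c(LP = 2, MP = 0, HP = -1),
                      seed = 21)
  res <- two_way_anova(d, "response")
  # balanced design: type-III and sequential sums of squares coincide
  ref <- anova(lm(response ~ diet * timepoint, data = d))
  expect_equal(res$effects$statistic,
               ref[c("diet", "timepoint", "diet:timepoint"), "F value"],
               tolerance = 1e-8)
  expect_equal(res$effects$p.value,
               ref[c("diet", "timepoint", "diet:timepoint"), "Pr(>F)"],
               tolerance = 1e-8)
  expect_equal(res$n, nrow(d))
})

test_that("strong diet effects are detected and constants degrade gracefully", {
  d <- make_factorial(n = 6, diet_shift = c(LP = 4, MP = 0, HP = 0),
                      sd = 0.5, seed = 2)
  res <- two_way_anova(d, "response")
  expect_lt(res$effects$p.value[1], 1e-4)
  # constant response: no variance, p reported as 1
  d$response <- 5
  res0 <- two_way_anova(d, "response")
  expect_equal(res0$effects$p.value, rep(1, 3))
  # empty cells are named in the error
  d2 <- make_factorial(n = 2)
  d2 <- d2[!(d2$diet == "LP" & d2$timepoint == "P35"), ]
  expect_error(two_way_anova(d2, "response"), "LP:P35")
})

test_that("Tukey post hoc appears only with a significant interaction", {
  # no interaction built in
  null_d <- make_factorial(n = 6, seed = 30)
  expect_null(two_way_anova(null_d, "response")$posthoc)
  # strong interaction
  int_d <- make_factorial(n = 6, interaction = 5, sd = 0.5, seed = 31)
  res <- two_way_anova(int_d, "response")
  expect_lt(res$effects$p.value[3], 0.001)
  expect_false(is.null(res$posthoc))
  expect_true(all(res$posthoc$adj.p.value >= 0 & res$posthoc$adj.p.value <= 1))
  # Tukey adjustment never reports less than the unadjusted pairwise p
  cell <- interaction(int_d$diet, int_d$timepoint, sep = ":")
  fit <- aov(int_d$response ~ cell)
  mse <- summary(fit)[[1]]["Residuals", "Mean Sq"]
  dfres <- summary(fit)[[1]]["Residuals", "Df"]
  means <- tapply(int_d$response, cell, mean)
  ns <- tapply(int_d$response, cell, length)
  for (k in sample(nrow(res$posthoc), 10)) {
    pair <- strsplit(res$posthoc$contrast[k], "-")[[1]]
    g1 <- pair[1]
    g2 <- pair[2]
    se <- sqrt(mse * (1 / ns[[g1]] + 1 / ns[[g2]]))
    t_un <- abs(means[[g1]] - means[[g2]]) / se
    p_un <- 2 * pt(t_un, dfres, lower.tail = FALSE)
    expect_gte(res$posthoc$adj.p.value[k] + 1e-12, p_un)
  }
})

test_that("permuting labels destroys a strong effect", {
  d <- make_factorial(n = 6, diet_shift = c(LP = 3, MP = 0, HP = -3),
                      sd = 1, seed = 8)
  set.seed(77)
  p_perm <- vapply(1:200, function(i) {
    d$diet <- sample(d$diet)
    two_way_anova(d, "response")$effects$p.value[1]
  }, numeric(1))
  expect_gt(median(p_perm), 0.3)
})

test_that("the Shapiro gate routes to ANOVA or Kruskal-Wallis appropriately", {
  # Gaussian groups take the parametric route in the large majority of
  # draws (the Shapiro gate still trips at its nominal rate)
  routes_g <- vapply(1:30, function(s) {
    set.seed(100 + s)
    d <- data.frame(g = rep(c("a", "b", "c"), each = 10), y = rnorm(30))
    one_way_gate(d, "y", "g")$route
  }, character(1))
  expect_gt(mean(routes_g == "anova"), 0.6)
  set.seed(101)
  res_g <- one_way_gate(
    data.frame(g = rep(c("a", "b", "c"), each = 10), y = rnorm(30)), "y", "g")
  expect_equal(nrow(res_g$shapiro), 3)

  # heavy-tailed group forces the nonparametric route in most replicates
  routes <- vapply(1:30, function(s) {
    set.seed(400 + s)
    d <- data.frame(
      g = rep(c("a", "b", "c"), each = 12),
      y = c(rnorm(24), rcauchy(12))
    )
    one_way_gate(d, "y", "g")$route
  }, character(1))
  expect_gt(mean(routes == "kruskal"), 0.5)

  # identical groups: p approximately 1 whichever route is taken
  ident <- data.frame(g = rep(c("a", "b"), each = 5), y = rep(1, 10))
  res_i <- suppressMessages(one_way_gate(ident, "y", "g"))
  expect_gte(res_i$p.value, 0.99)

  # tiny groups route nonparametric with a notice
  tiny <- data.frame(g = rep(c("a", "b"), each = 2), y = rnorm(4))
  expect_message(res_t <- one_way_gate(tiny, "y", "g"), "n < 3")
  expect_equal(res_t$route, "kruskal")
})

test_that("gated comparison detects a real location shift", {
  set.seed(55)
  d <- data.frame(g = rep(c("a", "b", "c"), each = 8),
                  y = rnorm(24) + rep(c(0, 0, 3), each = 8))
  res <- one_way_gate(d, "y", "g")
  expect_lt(res$p.value, 0.001)
  td <- tidy(res)
  expect_equal(td$route, res$route)
})
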