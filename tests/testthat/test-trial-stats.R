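test_that("ANOVA from summaries is null at identical means", {
  g <- group_summary(c("a", "b", "c"), n = c(12, 12, 12),
                     mean = c(5, 5, 5), sd = c(1.3, 0.8, 2.1))
  res <- anova_from_summary(g)
  expect_equal(res$F, 0)
  expect_equal(res$eta2, 0)
  expect_equal(res$cohen_f, 0)
  expect_equal(res$df1, 2L)
  expect_equal(res$df2, 33L)
  expect_error(anova_from_summary(g[1, , drop = FALSE]), "2 groups")
  expect_error(group_summary("a", 1, 0, 1), "n >= 2")
})

test_that("summary ANOVA equals textbook ANOVA on rescaled raw data", {
  set.seed(71)
  g <- group_summary(c("a", "b", "c"), n = c(15, 15, 15),
                     mean = c(0, 0, 3), sd = c(1, 1, 1))
  raw <- mapply(raw_matching, g$n, g$mean, g$sd, SIMPLIFY = FALSE)
  want <- raw_anova(raw)
  got <- anova_from_summary(g)
  expect_equal(got$F, want$F, tolerance = 1e-9)
  expect_equal(got$p, want$p, tolerance = 1e-9)
  expect_equal(got$eta2, want$eta2, tolerance = 1e-9)
  expect_equal(got$cohen_f, sqrt(got$eta2 / (1 - got$eta2)), tolerance = 1e-12)

  for (i in 1:20) {
    k <- sample(2:5, 1)
    g <- group_summary(paste0("g", 1:k), n = sample(3:40, k, replace = TRUE),
                       mean = rnorm(k, 0, 4), sd = runif(k, 0.2, 5))
    raw <- mapply(raw_matching, g$n, g$mean, g$sd, SIMPLIFY = FALSE)
    expect_equal(anova_from_summary(g)$F, raw_anova(raw)$F,
                 tolerance = 1e-9)
  }
})

test_that("the trial's printed inner-motivation summaries give a large effect", {
  g <- trial_groups(trial_outcome_summary(), "inner_motivation")
  res <- anova_from_summary(g)
  expect_equal(res$df1, 2L)
  expect_equal(res$df2, 42L)
  expect_gt(res$F, 20)
  expect_lt(res$p, 0.001)
  expect_identical(as.character(classify_effect(res$cohen_f)), "large")
})

test_that("pooled t from summaries matches t.test on rescaled raw data", {
  g <- group_summary(c("a", "b"), n = c(15, 15), mean = c(2.2, 2.2),
                     sd = c(0.5, 0.7))
  same <- t_from_summary(g[1, ], g[2, ])
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(same$df, 28)

  set.seed(73)
  for (i in 1:10) {
    n1 <- sample(3:30, 1); n2 <- sample(3:30, 1)
    a <- group_summary("a", n1, rnorm(1), runif(1, 0.3, 2))
    b <- group_summary("b", n2, rnorm(1), runif(1, 0.3, 2))
    x <- raw_matching(n1, a$mean, a$sd)
    y <- raw_matching(n2, b$mean, b$sd)
    want <- stats::t.test(x, y, var.equal = TRUE)
    got <- t_from_summary(a, b)
    expect_equal(got$t, unname(want$statistic), tolerance = 1e-9)
    expect_equal(got$p, want$p.value, tolerance = 1e-9)
    ww <- stats::t.test(x, y)
    gw <- t_from_summary(a, b, welch = TRUE)
    expect_equal(gw$t, unname(ww$statistic), tolerance = 1e-9)
    expect_equal(gw$df, unname(ww$parameter), tolerance = 1e-9)
  }
  expect_error(t_from_summary(group_summary("a", 5, 0, 0),
                              group_summary("b", 5, 1, 0)),
               "degenerate")
})

test_that("for two equal-n groups F equals t squared", {
  set.seed(79)
  for (i in 1:10) {
    g <- group_summary(c("a", "b"), n = c(15, 15), mean = rnorm(2),
                       sd = runif(2, 0.3, 2))
    tt <- t_from_summary(g[1, ], g[2, ])
    ff <- anova_from_summary(g)
    expect_equal(ff$F, tt$t^2, tolerance = 1e-12)
    expect_equal(ff$p, tt$p, tolerance = 1e-12)
  }
})

test_that("Kruskal-Wallis H matches a hand rank computation", {
  expect_equal(kruskal_wallis(list(c(1, 1), c(1, 1)))$H, 0)

  samples <- list(c(1, 2), c(3, 4), c(5, 6))
  # ranks are the values themselves: H = 12/(N(N+1)) * sum R_i^2/n_i - 3(N+1)
  R <- c(1 + 2, 3 + 4, 5 + 6)
  H_hand <- 12 / (6 * 7) * sum(R^2 / 2) - 3 * 7
  got <- kruskal_wallis(samples)
  expect_equal(got$H, H_hand, tolerance = 1e-12)
  expect_equal(got$df, 2)
  expect_equal(got$p, stats::pchisq(H_hand, 2, lower.tail = FALSE))

  shifted <- lapply(samples, `+`, 100)
  expect_equal(kruskal_wallis(shifted)$H, got$H)
  # invariance under strictly monotone transformation
  expect_equal(kruskal_wallis(lapply(samples, exp))$H, got$H)
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty")
})

test_that("Mann-Whitney U counts exceeding pairs plus half ties", {
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$U, 0)
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$U, 4.5)  # n1 n2 / 2
  got <- mann_whitney(c(1, 3, 5), c(2, 4))
  # brute force: pairs (a > b): (3>2),(5>2),(5>4) = 3
  expect_equal(got$U, 3)
  expect_identical(got$method, "exact")
})

test_that("exact Mann-Whitney p agrees with wilcox.test for untied data", {
  set.seed(83)
  for (i in 1:10) {
    a <- rnorm(sample(3:6, 1))
    b <- rnorm(sample(3:6, 1))
    got <- mann_whitney(a, b)
    want <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(got$U, unname(want$statistic))
    expect_equal(got$p, want$p.value, tolerance = 1e-12)
  }
})

test_that("large-sample Mann-Whitney uses the tie-corrected normal approximation", {
  set.seed(89)
  a <- round(rnorm(20), 1)
  b <- round(rnorm(25, 0.5), 1)
  got <- mann_whitney(a, b)
  expect_identical(got$method, "normal")
  want <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(got$U, unname(want$statistic))
  expect_equal(got$p, want$p.value, tolerance = 1e-9)
  # rank tests are invariant under strictly monotone transformations
  expect_equal(mann_whitney(exp(a), exp(b))$p, got$p, tolerance = 1e-12)
})

test_that("sample size search meets the power target tightly", {
  N <- sample_size_anova(f = 0.48, k = 3, alpha = 0.05, power = 0.80)
  expect_equal(N, 45)
  expect_gte(anova_power(0.48, N, 3, 0.05), 0.80)
  expect_lt(anova_power(0.48, N - 3, 3, 0.05), 0.80)
  expect_equal(N %% 3, 0)

  # minimum viable design when the requirement vanishes
  expect_equal(sample_size_anova(f = 0.3, k = 3, power = 1e-6), 6)
  expect_equal(sample_size_anova(f = 0.3, k = 4, power = 1e-6), 8)

  Ns <- vapply(c(0.2, 0.4, 0.48, 0.8), sample_size_anova, numeric(1))
  expect_true(all(diff(Ns) <= 0))
})

test_that("Cohen f bands follow the 0.1 / 0.40 / 0.80 cutpoints, left-closed", {
  lab <- function(f) as.character(classify_effect(f))
  expect_identical(lab(0.117), "small")
  expect_identical(lab(0.265), "small")
  expect_identical(lab(1.204), "large")
  expect_identical(lab(0), "negligible")
  expect_identical(lab(0.1), "small")
  expect_identical(lab(0.40), "medium")
  expect_identical(lab(0.80), "large")
  expect_error(classify_effect(-0.1), "non-negative")
})

test_that("subscale aggregation is a plain sum or mean with range checks", {
  expect_equal(subscale_score(rep(0, 5), "sum"), 0)
  expect_equal(subscale_score(c(1, 2, 3), "mean"), 2)
  expect_equal(subscale_score(rep(7, 7), "sum", item_range = c(1, 7)), 49)
  expect_error(subscale_score(c(1, 8), "sum", item_range = c(1, 7)), "range")
  expect_error(subscale_score(numeric(0)), "no responses")
})

test_that("group summaries load from CSV", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("label,n,mean,sd",
               "control,15,26.06,1.87",
               "kinect,15,35.13,3.20",
               "monocular,15,34.00,4.41"), p)
  g <- read_group_summary(p)
  expect_s3_class(g, "group_summary")
  expect_equal(anova_from_summary(g)$df2, 42L)
  writeLines(c("label,n,mean", "a,5,1"), p)
  expect_error(read_group_summary(p), "sd")
})
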