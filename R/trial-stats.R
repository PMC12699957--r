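#' Group summary triplets
#'
#' Builds the `(label, n, mean, sd)` table that summary-statistics inference
#' consumes — the "mean (SD)" rows of a trial report.
#'
#' @param label Character vector of group labels.
#' @param n Integer group sizes (each >= 2).
#' @param mean,sd Numeric group means and standard deviations (sd >= 0).
#' @return Data frame of class `group_summary`.
#' @export
group_summary <- function(label, n, mean, sd) {
  if (any(n < 2)) stop("each group needs n >= 2", call. = FALSE)
  if (any(!is.finite(sd)) || any(sd < 0)) {
    stop("sd must be finite and non-negative", call. = FALSE)
  }
  structure(data.frame(label = as.character(label), n = as.integer(n),
                       mean = as.numeric(mean), sd = as.numeric(sd),
                       stringsAsFactors = FALSE),
            class = c("group_summary", "data.frame"))
}

#' Read a group-summary CSV
#'
#' Expected columns: `label,n,mean,sd`.
#'
#' @param path Path to the CSV file.
#' @return A [group_summary()] data frame.
#' @export
read_group_summary <- function(path) {
  df <- utils::read.csv(path)
  need <- c("label", "n", "mean", "sd")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("group-summary CSV missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  group_summary(df$label, df$n, df$mean, df$sd)
}

#' One-way ANOVA from group summaries
#'
#' Reconstructs the one-way ANOVA table from per-group `(n, mean, sd)`
#' triplets — the standard decomposition for `k` independent groups:
#' between-group sum of squares `SSB = sum n_i (m_i - m)^2` about the
#' n-weighted grand mean, within-group `SSW = sum (n_i - 1) s_i^2`,
#' `F = (SSB/(k-1)) / (SSW/(N-k))` with the upper-tail F p-value. Effect
#' sizes: `eta2 = SSB / (SSB + SSW)` and Cohen
#' `f = sqrt(eta2 / (1 - eta2))`. Identical to a raw-data ANOVA on any
#' samples matching the summaries exactly.
#'
#' @param groups A [group_summary()] (or data frame with `n`, `mean`, `sd`),
#'   at least 2 groups, each `n >= 2`.
#' @return An object of class `anova_result`: `F`, `df1`, `df2`, `p`,
#'   `eta2`, `cohen_f`, `ssb`, `ssw`.
#' @examples
#' g <- group_summary(c("a", "b", "c"), n = c(15, 15, 15),
#'                    mean = c(0, 0, 3), sd = c(1, 1, 1))
#' anova_from_summary(g)
#' @export
anova_from_summary <- function(groups) {
  if (nrow(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(groups$n < 2)) stop("each group needs n >= 2", call. = FALSE)
  n <- groups$n; m <- groups$mean; s <- groups$sd
  k <- length(n); N <- sum(n)
  grand <- sum(n * m) / N
  ssb <- sum(n * (m - grand)^2)
  ssw <- sum((n - 1) * s^2)
  df1 <- k - 1L; df2 <- N - k
  Fv <- if (ssw == 0) {
    if (ssb == 0) 0 else Inf
  } else {
    (ssb / df1) / (ssw / df2)
  }
  p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  eta2 <- if (ssb + ssw == 0) 0 else ssb / (ssb + ssw)
  structure(list(F = Fv, df1 = df1, df2 = df2, p = p, eta2 = eta2,
                 cohen_f = sqrt(eta2 / max(1 - eta2, .Machine$double.xmin)),
                 ssb = ssb, ssw = ssw),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA from summaries: F(%d, %d) = %.4g, p = %.4g\n",
              x$df1, x$df2, x$F, x$p))
  cat(sprintf("  eta^2 = %.4g, Cohen f = %.4g (%s)\n", x$eta2, x$cohen_f,
              classify_effect(x$cohen_f)))
  invisible(x)
}

#' Two-sample t test from group summaries
#'
#' Pooled-variance independent-samples two-tailed t test reconstructed from
#' `(n, mean, sd)` pairs; `df = n1 + n2 - 2`. Welch's unequal-variance
#' variant is available with `welch = TRUE` (Welch–Satterthwaite df). With
#' zero pooled variance the statistic is defined as 0 when the means agree
#' and is an error otherwise.
#'
#' @param g1,g2 Single-row [group_summary()]s (or lists with `n`, `mean`,
#'   `sd`).
#' @param welch If `TRUE` use Welch's t instead of the pooled test.
#' @return List with `t`, `df`, `p`.
#' @export
t_from_summary <- function(g1, g2, welch = FALSE) {
  n1 <- g1$n; n2 <- g2$n
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  d <- g1$mean - g2$mean
  if (welch) {
    se2 <- g1$sd^2 / n1 + g2$sd^2 / n2
    if (se2 == 0) {
      if (d == 0) return(list(t = 0, df = n1 + n2 - 2, p = 1))
      stop("degenerate variance: zero spread with unequal means", call. = FALSE)
    }
    tt <- d / sqrt(se2)
    df <- se2^2 / ((g1$sd^2 / n1)^2 / (n1 - 1) + (g2$sd^2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * g1$sd^2 + (n2 - 1) * g2$sd^2) / (n1 + n2 - 2)
    df <- n1 + n2 - 2
    if (sp2 == 0) {
      if (d == 0) return(list(t = 0, df = df, p = 1))
      stop("degenerate variance: zero spread with unequal means", call. = FALSE)
    }
    tt <- d / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
}

#' Kruskal–Wallis rank test
#'
#' Tie-corrected Kruskal–Wallis H for `k >= 2` samples, with the p-value
#' from the chi-square upper tail on `k - 1` degrees of freedom (the
#' large-sample approximation, applied at all sizes). Computation is
#' delegated to [stats::kruskal.test()], whose statistic is exactly the
#' tie-corrected H.
#'
#' @param samples List of non-empty numeric vectors.
#' @return List with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(samples) {
  if (length(samples) < 2L || any(vapply(samples, length, integer(1)) == 0L)) {
    stop("need at least 2 non-empty samples", call. = FALSE)
  }
  if (length(unique(unlist(samples))) == 1L) {
    # one big tie: the tie-corrected statistic degenerates to 0
    return(list(H = 0, df = length(samples) - 1L, p = 1))
  }
  kt <- stats::kruskal.test(samples)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

# U statistics over all labelings of the pooled data (exact null with ties)
mw_u_stat <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Mann–Whitney U test
#'
#' `U` counts the pairs `(a_i, b_j)` with `a_i > b_j`, plus half the tied
#' pairs. For pooled sizes `n1 + n2 <= 12` the two-sided p-value is exact by
#' enumeration of all `choose(n1+n2, n1)` group labelings of the pooled
#' data (valid with ties); for larger samples the normal approximation with
#' tie correction is used, without continuity correction. The switch is
#' size-based and deterministic.
#'
#' @param a,b Non-empty numeric vectors.
#' @return List with `U`, `p`, and `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  U <- mw_u_stat(a, b)
  mu <- n1 * n2 / 2
  if (N <= 12L) {
    pooled <- c(a, b)
    idx <- utils::combn(N, n1)
    dev_obs <- abs(U - mu)
    devs <- apply(idx, 2L, function(ii) {
      abs(mw_u_stat(pooled[ii], pooled[-ii]) - mu)
    })
    p <- mean(devs >= dev_obs - 1e-12)
    method <- "exact"
  } else {
    r <- rank(c(a, b))
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 == 0) {
      p <- 1
    } else {
      z <- (U - mu) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal"
  }
  list(U = U, p = min(1, p), method = method)
}

#' ANOVA power at a given total sample size
#'
#' Power of the one-way fixed-effects F test for Cohen effect size `f` at
#' total N (equal groups): noncentral F with `df1 = k - 1`,
#' `df2 = N - k` and noncentrality `lambda = f^2 N`.
#'
#' @param f Cohen f effect size (> 0).
#' @param N Total sample size (>= 2k).
#' @param k Number of groups (>= 2).
#' @param alpha Significance level.
#' @return Power in (0, 1).
#' @export
anova_power <- function(f, N, k = 3, alpha = 0.05) {
  stopifnot(f > 0, k >= 2, N >= 2 * k, alpha > 0, alpha < 1)
  crit <- stats::qf(1 - alpha, k - 1, N - k)
  stats::pf(crit, k - 1, N - k, ncp = f^2 * N, lower.tail = FALSE)
}

#' Total sample size for a one-way ANOVA
#'
#' Smallest total N, divisible by `k` (equal groups), whose noncentral-F
#' power ([anova_power()]) meets the target. The trial's own calculation —
#' `f = 0.48`, 3 groups, alpha .05, 80% power — yields N = 45 (15 per
#' group).
#'
#' @param f Cohen f effect size (> 0).
#' @param k Number of groups (>= 2).
#' @param alpha Significance level in (0, 1).
#' @param power Target power in (0, 1).
#' @param max_n Search bound on total N.
#' @return Total sample size N (integer, divisible by `k`).
#' @examples
#' sample_size_anova(f = 0.48, k = 3, alpha = 0.05, power = 0.80)  # 45
#' @export
sample_size_anova <- function(f, k = 3, alpha = 0.05, power = 0.80,
                              max_n = 1e6) {
  stopifnot(f > 0, k >= 2, alpha > 0, alpha < 1, power > 0, power < 1)
  N <- 2L * as.integer(k)
  while (anova_power(f, N, k, alpha) < power) {
    N <- N + as.integer(k)
    if (N > max_n) {
      stop("target power unattainable within the search bound", call. = FALSE)
    }
  }
  N
}

#' Classify a Cohen f effect size
#'
#' Left-closed bands at the conventional cutpoints 0.1 / 0.40 / 0.80:
#' `[0, 0.1)` negligible, `[0.1, 0.40)` small, `[0.40, 0.80)` medium,
#' `[0.80, Inf)` large.
#'
#' @param f Cohen f (>= 0; vectorized).
#' @param benchmarks Strictly increasing named cutpoints.
#' @return Factor with levels negligible/small/medium/large.
#' @export
classify_effect <- function(f, benchmarks = c(small = 0.1, medium = 0.40,
                                              large = 0.80)) {
  if (any(f < 0)) stop("Cohen f must be non-negative", call. = FALSE)
  if (any(diff(benchmarks) <= 0)) {
    stop("benchmarks must be strictly increasing", call. = FALSE)
  }
  cut(f, breaks = c(0, benchmarks, Inf), right = FALSE,
      labels = c("negligible", "small", "medium", "large"),
      include.lowest = TRUE)
}

#' Aggregate questionnaire subscale responses
#'
#' Generic item aggregator for self-report subscales (e.g. an
#' interest/enjoyment subscale): sum or mean of item responses, with an
#' optional declared item range enforced. No instrument's item bank is
#' bundled.
#'
#' @param responses Non-empty numeric vector of item responses.
#' @param rule `"sum"` or `"mean"`.
#' @param item_range Optional length-2 numeric `c(min, max)` the items must
#'   lie within.
#' @return The aggregated score.
#' @export
subscale_score <- function(responses, rule = c("sum", "mean"),
                           item_range = NULL) {
  rule <- match.arg(rule)
  if (length(responses) == 0L) stop("no responses", call. = FALSE)
  if (!is.null(item_range)) {
    if (any(responses < item_range[1]) || any(responses > item_range[2])) {
      stop(sprintf("item response outside declared range [%g, %g]",
                   item_range[1], item_range[2]), call. = FALSE)
    }
  }
  if (rule == "sum") sum(responses) else mean(responses)
}
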