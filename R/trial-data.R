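#' Summary tables of the three-arm exergame trial
#'
#' Printed group-level summary statistics of the randomized trial the engine
#' was built for: 45 community-dwelling adults at high risk of type 2
#' diabetes, allocated 1:1:1 (n = 15 per arm) to video-guided exercise
#' (control), a Kinect-based exergame, or the monocular-camera exergame.
#' Only group summaries — mean (SD) per arm — were reported; no
#' per-participant data are available, which is exactly the input the
#' summary-statistics module consumes.
#'
#' @return
#' `trial_baseline_summary()`: baseline characteristics (age, diabetes risk
#' score, resting heart rate, perceived fatigue) as a data frame with one
#' row per arm x variable: `variable`, `label`, `n`, `mean`, `sd`.
#'
#' `trial_outcome_summary()`: post-intervention outcomes (heart rate,
#' perceived fatigue on the Borg 6–20 scale, inner motivation) in the same
#' layout.
#'
#' `trial_geq_summary()`: game-experience dimensions for the two exergame
#' arms.
#'
#' `trial_engagement()`: completed sessions per arm over the unsupervised
#' week, plus the counts expressing intention to continue.
#' @name trial_tables
NULL

.arms3 <- c("control", "kinect", "monocular")

#' @rdname trial_tables
#' @export
trial_baseline_summary <- function() {
  rows <- rbind(
    data.frame(variable = "age", label = .arms3,
               mean = c(47.27, 47.93, 46.17), sd = c(6.59, 6.85, 7.33)),
    data.frame(variable = "t2d_risk", label = .arms3,
               mean = c(33.07, 33.60, 33.47), sd = c(5.02, 4.75, 5.36)),
    data.frame(variable = "heart_rate", label = .arms3,
               mean = c(79.46, 80.06, 78.02), sd = c(10.23, 10.01, 8.66)),
    data.frame(variable = "perceived_fatigue", label = .arms3,
               mean = c(9.27, 9.41, 9.28), sd = c(1.53, 1.12, 1.06)))
  rows$n <- 15L
  rows[, c("variable", "label", "n", "mean", "sd")]
}

#' @rdname trial_tables
#' @export
trial_outcome_summary <- function() {
  rows <- rbind(
    data.frame(variable = "heart_rate", label = .arms3,
               mean = c(86.34, 90.81, 89.29), sd = c(7.48, 7.71, 6.52)),
    data.frame(variable = "perceived_fatigue", label = .arms3,
               mean = c(11.60, 10.60, 10.33), sd = c(1.12, 1.45, 1.49)),
    data.frame(variable = "inner_motivation", label = .arms3,
               mean = c(26.06, 35.13, 34.00), sd = c(1.87, 3.20, 4.41)))
  rows$n <- 15L
  rows[, c("variable", "label", "n", "mean", "sd")]
}

#' @rdname trial_tables
#' @export
trial_geq_summary <- function() {
  dims <- c("immersion", "flow", "competence", "tension", "challenge",
            "positive_affect", "negative_affect")
  rows <- rbind(
    data.frame(variable = dims, label = "kinect",
               mean = c(3.40, 3.40, 2.90, 0.10, 2.96, 3.53, 0.33),
               sd = c(0.38, 0.54, 0.60, 0.38, 0.51, 0.44, 0.67)),
    data.frame(variable = dims, label = "monocular",
               mean = c(3.51, 3.58, 3.16, 0.08, 3.45, 3.79, 0.41),
               sd = c(0.79, 0.63, 0.71, 0.28, 0.39, 0.39, 0.70)))
  rows$n <- 15L
  rows[, c("variable", "label", "n", "mean", "sd")]
}

#' @rdname trial_tables
#' @export
trial_engagement <- function() {
  data.frame(label = .arms3, n = 15L,
             sessions_mean = c(2.33, 2.93, 3.60),
             sessions_sd = c(1.29, 1.79, 1.59),
             intend_to_continue = c(NA_integer_, 10L, 12L))
}

#' Extract one variable of a trial table as a group summary
#'
#' @param table A data frame from one of the [trial_tables] accessors.
#' @param variable Variable name to select.
#' @return A [group_summary()] ready for [anova_from_summary()] or
#'   [t_from_summary()].
#' @export
trial_groups <- function(table, variable) {
  sub <- table[table$variable == variable, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("variable not found in table: ", variable, call. = FALSE)
  }
  group_summary(sub$label, sub$n, sub$mean, sub$sd)
}
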