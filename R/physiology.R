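#' Age-predicted maximum heart rate
#'
#' `HRmax = 208 - 0.7 * age` (beats per minute), the age-based estimate used
#' to anchor exercise-intensity targets in middle-aged and older adults. A
#' warning is issued outside the 35–80 year band where the intervention
#' population plausibly lies.
#'
#' @param age Age in years, in \[18, 100\] (vectorized).
#' @return Estimated maximum heart rate in bpm.
#' @examples
#' max_heart_rate(40)  # 180
#' @export
max_heart_rate <- function(age) {
  if (any(!is.finite(age)) || any(age <= 0)) {
    stop("age must be finite and positive", call. = FALSE)
  }
  if (any(age < 18) || any(age > 100)) {
    stop("age must lie in [18, 100] years", call. = FALSE)
  }
  if (any(age < 35) || any(age > 80)) {
    warning("age outside the intervention's plausible band [35, 80] years",
            call. = FALSE)
  }
  208 - 0.7 * age
}

#' Target heart-rate zone
#'
#' The training target zone as fractions of the age-predicted maximum heart
#' rate; the intervention targets 50%–80% of HRmax, appropriate for adults
#' at elevated metabolic risk.
#'
#' @param age Age in years.
#' @param lo,hi Zone fractions of HRmax, `0 < lo < hi <= 1`; defaults 0.5
#'   and 0.8.
#' @return An object of class `heart_rate_zone` with `age`, `hr_max`,
#'   `lower`, `upper` (bpm) and `fractions`.
#' @examples
#' target_zone(40)  # 90 - 144 bpm
#' @export
target_zone <- function(age, lo = 0.5, hi = 0.8) {
  if (!is.numeric(lo) || !is.numeric(hi) || lo <= 0 || hi > 1 || lo >= hi) {
    stop("zone fractions must satisfy 0 < lo < hi <= 1", call. = FALSE)
  }
  hr_max <- max_heart_rate(age)
  structure(list(age = age, hr_max = hr_max,
                 lower = lo * hr_max, upper = hi * hr_max,
                 fractions = c(lo = lo, hi = hi)),
            class = "heart_rate_zone")
}

#' @export
print.heart_rate_zone <- function(x, ...) {
  cat(sprintf("<heart_rate_zone> age %.4g: HRmax %.4g bpm, target %.4g-%.4g bpm (%.0f-%.0f%%)\n",
              x$age, x$hr_max, x$lower, x$upper,
              100 * x$fractions[["lo"]], 100 * x$fractions[["hi"]]))
  invisible(x)
}

#' Classify a heart rate against a target zone
#'
#' Zone boundaries are inclusive: a heart rate exactly at the lower or upper
#' bound counts as in-zone.
#'
#' @param hr Heart rate in bpm (> 0; vectorized).
#' @param zone A [target_zone()].
#' @return Factor with levels `below`, `in`, `above`.
#' @export
in_zone <- function(hr, zone) {
  if (any(!is.finite(hr)) || any(hr <= 0)) {
    stop("heart rate must be finite and positive", call. = FALSE)
  }
  out <- ifelse(hr < zone$lower, "below", ifelse(hr > zone$upper, "above", "in"))
  factor(out, levels = c("below", "in", "above"))
}

#' Validate a Borg RPE rating
#'
#' The Borg Rating of Perceived Exertion scale runs from 6 (no exertion) to
#' 20 (maximal exertion); values outside that range are rejected.
#'
#' @param value Integer rating.
#' @return An object of class `borg_score` (the validated integer).
#' @export
validate_borg <- function(value) {
  if (length(value) != 1L || !is.finite(value) || value != round(value)) {
    stop("Borg rating must be a single integer", call. = FALSE)
  }
  if (value < 6 || value > 20) {
    stop("Borg rating must lie in [6, 20], got ", value, call. = FALSE)
  }
  structure(as.integer(value), class = "borg_score")
}
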