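#' Recognition score parameters
#'
#' The two tunable constants of the piecewise recognition score: `Dst`, the
#' recognition threshold — the total angular deviation (degrees) at or beyond
#' which a pose is flagged as an error and scored 0 — and `Sst`, the baseline
#' recognition rate — the score floor of the passing band, toward which the
#' score interpolates linearly as the deviation approaches `Dst`. Defaults
#' `Dst = 90`, `Sst = 60` are configuration conventions of this engine.
#'
#' @param Dst Recognition threshold in degrees, > 0.
#' @param Sst Baseline recognition rate in \[0, 100).
#' @return An object of class `score_params`.
#' @export
score_params <- function(Dst = 90, Sst = 60) {
  if (!is.numeric(Dst) || Dst <= 0) stop("Dst must be > 0", call. = FALSE)
  if (!is.numeric(Sst) || Sst < 0 || Sst >= 100) {
    stop("Sst must lie in [0, 100)", call. = FALSE)
  }
  structure(list(Dst = as.numeric(Dst), Sst = as.numeric(Sst)),
            class = "score_params")
}

#' Regulated reference pose
#'
#' The regulated posture a movement is scored against: a named vector of
#' regulated angles (theta-prime, degrees) matching the active angle set,
#' plus the score parameters. `angles` may also be a matrix with one row per
#' frame (a *tracking* reference that follows a demonstration over time); see
#' [tracking_reference()] for the variant built from a movement template.
#'
#' @param movement Movement identifier.
#' @param angles Named numeric vector (static reference) or matrix with
#'   named columns (per-frame reference) of regulated angles in \[0, 180\].
#' @param params A [score_params()].
#' @return An object of class `reference_pose`.
#' @export
reference_pose <- function(movement, angles, params = score_params()) {
  vals <- if (is.matrix(angles)) as.vector(angles) else angles
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 180)) {
    stop("regulated angles must be finite and within [0, 180] degrees",
         call. = FALSE)
  }
  nm <- if (is.matrix(angles)) colnames(angles) else names(angles)
  if (is.null(nm)) stop("regulated angles must be named", call. = FALSE)
  structure(list(movement = movement, angles = angles, params = params),
            class = "reference_pose")
}

#' Read a reference pose from a JSON or YAML file
#'
#' File layout: `{movement, angles: {name: degrees, ...}, Dst, Sst}`.
#'
#' @param path Path to the file.
#' @param params Optional [score_params()] overriding any `Dst`/`Sst` in the
#'   file.
#' @return A [reference_pose()].
#' @export
read_reference_pose <- function(path, params = NULL) {
  rec <- read_config(path)
  if (is.null(params)) {
    params <- score_params(
      Dst = if (!is.null(rec$Dst)) rec$Dst else 90,
      Sst = if (!is.null(rec$Sst)) rec$Sst else 60)
  }
  reference_pose(rec$movement, unlist(rec$angles), params)
}

#' Total angular deviation between observed and regulated angles
#'
#' The deviation sum `D`: per-angle absolute deviations `|theta_i -
#' theta'_i|` and their total. The observed and regulated vectors must carry
#' identical angle names in identical order. The signed variant
#' `sum(theta_i - theta'_i)` — under which opposite errors cancel — is
#' available with `signed = TRUE` for comparison experiments; the absolute
#' form is the default because a deviation metric that lets errors cancel
#' cannot flag large opposing deviations as errors.
#'
#' @param observed,reference Named numeric angle vectors (degrees), same
#'   names in the same order.
#' @param signed If `TRUE`, return the signed sum instead (per-angle
#'   deviations remain signed).
#' @return An object of class `deviation_result` with elements `D` (total,
#'   degrees) and `per_angle` (named per-angle deviations).
#' @export
total_deviation <- function(observed, reference, signed = FALSE) {
  if (is.null(names(observed)) || is.null(names(reference)) ||
      !identical(names(observed), names(reference))) {
    only_obs <- setdiff(names(observed), names(reference))
    only_ref <- setdiff(names(reference), names(observed))
    stop("angle sets differ between observed and reference",
         if (length(only_obs)) paste0("; only in observed: ",
                                      paste(only_obs, collapse = ", ")),
         if (length(only_ref)) paste0("; only in reference: ",
                                      paste(only_ref, collapse = ", ")),
         if (!length(only_obs) && !length(only_ref)) "; same names, different order",
         call. = FALSE)
  }
  dev <- observed - reference
  if (!signed) dev <- abs(dev)
  structure(list(D = sum(dev), per_angle = dev, signed = signed),
            class = "deviation_result")
}

#' Piecewise recognition score
#'
#' Maps a total angular deviation `D` to the recognition score
#' \deqn{S = \frac{D_{st} - D}{D_{st}} (100 - S_{st}) + S_{st}, \quad 0 \le D < D_{st}}
#' and `S = 0` for `D >= Dst`. A perfect match (`D = 0`) scores 100; as `D`
#' grows toward the threshold, the score falls linearly toward `Sst`; at and
#' beyond the threshold the pose is flagged as an error and scores 0. The
#' boundary `D = Dst` belongs to the zero branch, so a passing score never
#' drops below `Sst`.
#'
#' @param D Total deviation in degrees (vectorized, non-negative).
#' @param params A [score_params()].
#' @return Score(s) in `{0}` union `(Sst, 100]`.
#' @examples
#' recognition_score(45, score_params(Dst = 90, Sst = 60))  # 80
#' @export
recognition_score <- function(D, params = score_params()) {
  if (any(!is.finite(D)) || any(D < 0)) {
    stop("D must be finite and non-negative", call. = FALSE)
  }
  S <- (params$Dst - D) / params$Dst * (100 - params$Sst) + params$Sst
  S[D >= params$Dst] <- 0
  S
}

#' Score a single frame against a reference pose
#'
#' Composition of [extract_angle_vector()], [total_deviation()] and
#' [recognition_score()]. No smoothing is applied (a single frame has no
#' temporal context); see [score_movement()] for windowed scoring.
#'
#' @param frame A [pose_frame()].
#' @param ref A [reference_pose()] with a static (vector) angle reference.
#' @param angles Angle set; default [default_angle_set()].
#' @return List with `deviation` (a `deviation_result`) and `S` (the score).
#' @export
score_frame <- function(frame, ref, angles = default_angle_set()) {
  if (is.matrix(ref$angles)) {
    stop("score_frame requires a static reference; use score_movement for a tracking reference",
         call. = FALSE)
  }
  obs <- extract_angle_vector(frame, angles)
  if (!setequal(names(obs), names(ref$angles))) {
    dev <- total_deviation(obs, ref$angles)  # errors, listing the difference
  } else {
    dev <- total_deviation(obs, ref$angles[names(obs)])
  }
  list(deviation = dev, S = recognition_score(dev$D, ref$params))
}

#' Score a movement window
#'
#' Scores every frame of a sequence against a reference pose and aggregates.
#' Landmark trajectories are first passed through the default smoothing
#' pipeline ([smooth_sequence()]); per-frame deviations and scores are then
#' computed, and the aggregate is the mean (default) or median of the
#' per-frame scores. The pass fraction is the share of frames scoring above
#' zero (i.e. with `D < Dst`).
#'
#' For a tracking reference (matrix `angles`), the number of reference rows
#' must equal the number of frames.
#'
#' @param seq A non-empty [motion_sequence()].
#' @param ref A [reference_pose()].
#' @param angles Angle set; default [default_angle_set()].
#' @param aggregate `"mean"` or `"median"`.
#' @param smooth If `TRUE` (default) apply [smooth_sequence()] before
#'   extraction.
#' @return An object of class `movement_score`: movement id, per-frame
#'   scores `S_t`, per-frame deviations `D_t`, `aggregate`, and
#'   `pass_fraction`.
#' @export
score_movement <- function(seq, ref, angles = default_angle_set(),
                           aggregate = c("mean", "median"), smooth = TRUE) {
  aggregate <- match.arg(aggregate)
  if (length(seq$frames) == 0L) stop("empty sequence", call. = FALSE)
  if (inherits(ref, "tracking_reference")) {
    times <- frame_times(seq)
    ref <- materialize_reference(ref, times - times[1])
  }
  arr <- seq_to_array(seq)
  if (smooth) arr <- smooth_array(arr)
  obs <- angles_from_array(arr, angles)
  nm <- angle_set_names(angles)
  if (is.matrix(ref$angles)) {
    if (nrow(ref$angles) != nrow(obs)) {
      stop(sprintf("tracking reference has %d rows but sequence has %d frames",
                   nrow(ref$angles), nrow(obs)), call. = FALSE)
    }
    refm <- ref$angles[, nm, drop = FALSE]
  } else {
    if (!all(nm %in% names(ref$angles))) {
      stop("angle sets differ between reference and angle set: missing ",
           paste(setdiff(nm, names(ref$angles)), collapse = ", "),
           call. = FALSE)
    }
    refm <- matrix(rep(ref$angles[nm], each = nrow(obs)), nrow(obs),
                   dimnames = list(NULL, nm))
  }
  D_t <- rowSums(abs(obs - refm))
  S_t <- recognition_score(D_t, ref$params)
  agg <- if (aggregate == "mean") mean(S_t) else stats::median(S_t)
  structure(list(movement = ref$movement, S_t = S_t, D_t = D_t,
                 aggregate = agg, aggregate_rule = aggregate,
                 pass_fraction = mean(S_t > 0)),
            class = "movement_score")
}

#' @export
print.movement_score <- function(x, ...) {
  cat(sprintf("<movement_score> %s: %s S = %.2f over %d frames (pass %.0f%%)\n",
              x$movement, x$aggregate_rule, x$aggregate, length(x$S_t),
              100 * x$pass_fraction))
  invisible(x)
}
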