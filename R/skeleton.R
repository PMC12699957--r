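#' Canonical landmark names
#'
#' The skeleton model is fixed at ten anatomical landmarks tracked by the
#' pose-estimation front end: head, waist, and the left/right wrists, elbows,
#' knees and ankles. All pose frames must carry exactly this set.
#'
#' @return Character vector of the 10 canonical landmark names, in canonical
#'   order.
#' @examples
#' landmark_names()
#' @export
landmark_names <- function() {
  c("head", "waist",
    "left_wrist", "right_wrist",
    "left_elbow", "right_elbow",
    "left_knee", "right_knee",
    "left_ankle", "right_ankle")
}

#' Construct a pose frame
#'
#' A pose frame is one time-stamped skeleton observation: a 3D position in
#' meters for each of the 10 canonical landmarks, with an optional
#' per-landmark confidence in \[0, 1\]. Coordinates use a right-handed, y-up
#' frame in meters; the subject nominally faces +z. Joint angles are invariant
#' to rigid motion, so the convention only matters for axis-referenced angles
#' (see [default_angle_set()]).
#'
#' @param time Non-negative time in seconds.
#' @param positions 10 x 3 numeric matrix of landmark positions (meters), with
#'   rownames covering [landmark_names()]; or a named list of length-3
#'   vectors.
#' @param confidence Optional named numeric vector of per-landmark confidences
#'   in \[0, 1\].
#' @return An object of class `pose_frame`.
#' @seealso [validate_frame()] for the validation rules.
#' @export
pose_frame <- function(time, positions, confidence = NULL) {
  if (is.list(positions)) {
    positions <- do.call(rbind, lapply(positions, as.numeric))
  }
  positions <- as.matrix(positions)
  if (is.null(rownames(positions))) {
    if (nrow(positions) == 10L) rownames(positions) <- landmark_names()
  }
  frame <- structure(
    list(time = as.numeric(time), positions = positions,
         confidence = confidence),
    class = "pose_frame")
  findings <- validate_frame(frame)
  if (length(findings) > 0L) {
    stop("invalid pose frame: ", paste(findings, collapse = "; "),
         call. = FALSE)
  }
  frame
}

#' Validate a pose frame
#'
#' Checks a frame against the skeleton invariants and returns findings rather
#' than raising: all 10 canonical landmarks present, all coordinates finite,
#' time non-negative and finite, and confidence (when present) within
#' \[0, 1\]. An empty result means the frame is valid. A missing landmark is a
#' finding (the skeleton is fixed at 10 points); a low confidence is not —
#' confidence thresholding is left to callers.
#'
#' @param frame A `pose_frame` (or a bare list with the same fields).
#' @return Character vector of findings, each naming the offending landmark
#'   and rule; `character(0)` if the frame is valid.
#' @examples
#' f <- neutral_pose()
#' validate_frame(f)  # character(0)
#' @export
validate_frame <- function(frame) {
  findings <- character(0)
  pos <- frame$positions
  if (!is.matrix(pos) || ncol(pos) != 3L) {
    return("positions: expected a landmark x 3 coordinate matrix")
  }
  canon <- landmark_names()
  missing <- setdiff(canon, rownames(pos))
  for (lm in missing) findings <- c(findings, paste0(lm, ": landmark missing"))
  extra <- setdiff(rownames(pos), canon)
  for (lm in extra) findings <- c(findings, paste0(lm, ": unknown landmark"))
  for (lm in intersect(canon, rownames(pos))) {
    if (!all(is.finite(pos[lm, ]))) {
      findings <- c(findings, paste0(lm, ": non-finite coordinate"))
    }
  }
  if (!is.numeric(frame$time) || !is.finite(frame$time) || frame$time < 0) {
    findings <- c(findings, "time: must be a finite non-negative number")
  }
  conf <- frame$confidence
  if (!is.null(conf)) {
    for (lm in names(conf)) {
      if (!is.finite(conf[[lm]]) || conf[[lm]] < 0 || conf[[lm]] > 1) {
        findings <- c(findings, paste0(lm, ": confidence outside [0, 1]"))
      }
    }
  }
  findings
}

#' Construct a motion sequence
#'
#' An ordered series of pose frames with a nominal frame rate and free-form
#' metadata (subject id, movement id, generator seed, ...). Frame times must
#' be strictly increasing and all frames must share the canonical landmark
#' set. The stated `fps` is cross-checked against the median frame spacing
#' and a warning is issued if they disagree by more than 5%.
#'
#' @param frames List of `pose_frame` objects with strictly increasing times.
#' @param fps Nominal frames per second (positive).
#' @param metadata Named list of free-form metadata.
#' @return An object of class `motion_sequence`.
#' @export
motion_sequence <- function(frames, fps, metadata = list()) {
  stopifnot(is.list(frames), is.numeric(fps), fps > 0)
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing", call. = FALSE)
  }
  if (length(times) > 1L) {
    implied <- 1 / stats::median(diff(times))
    if (abs(implied - fps) / fps > 0.05) {
      warning(sprintf(
        "stated fps (%.3f) differs from median frame spacing (%.3f fps) by >5%%",
        fps, implied), call. = FALSE)
    }
  }
  structure(list(frames = frames, fps = as.numeric(fps), metadata = metadata),
            class = "motion_sequence")
}

#' @export
length.motion_sequence <- function(x) length(x$frames)

#' @export
print.motion_sequence <- function(x, ...) {
  times <- frame_times(x)
  cat(sprintf("<motion_sequence> %d frames @ %.6g fps", length(x$frames), x$fps))
  if (length(times)) cat(sprintf(", t = [%.3f, %.3f] s", min(times), max(times)))
  cat("\n")
  if (length(x$metadata)) {
    cat("  metadata:", paste(names(x$metadata),
                             vapply(x$metadata, format, character(1)),
                             sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.pose_frame <- function(x, ...) {
  cat(sprintf("<pose_frame> t = %.6g s\n", x$time))
  print(round(x$positions, 4))
  invisible(x)
}

#' Frame times of a motion sequence
#'
#' @param seq A `motion_sequence`.
#' @return Numeric vector of frame times in seconds.
#' @export
frame_times <- function(seq) {
  vapply(seq$frames, function(f) f$time, numeric(1))
}

# Internal dense representation: T x 10 x 3 array (frame, landmark, axis).
# Filters and vectorized angle extraction work on this form.
seq_to_array <- function(seq) {
  canon <- landmark_names()
  nT <- length(seq$frames)
  arr <- array(NA_real_, dim = c(nT, 10L, 3L),
               dimnames = list(NULL, canon, c("x", "y", "z")))
  for (i in seq_len(nT)) arr[i, , ] <- seq$frames[[i]]$positions[canon, ]
  arr
}

array_to_seq <- function(arr, times, fps, metadata = list(), confidence = NULL) {
  canon <- landmark_names()
  frames <- vector("list", dim(arr)[1])
  for (i in seq_along(frames)) {
    pos <- matrix(arr[i, , ], nrow = 10L, ncol = 3L,
                  dimnames = list(canon, c("x", "y", "z")))
    frames[[i]] <- structure(
      list(time = times[i], positions = pos,
           confidence = if (is.null(confidence)) NULL else confidence[[i]]),
      class = "pose_frame")
  }
  motion_sequence(frames, fps = fps, metadata = metadata)
}
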