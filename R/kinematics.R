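#' Angle between two rays at a vertex
#'
#' The basic geometric primitive of pose comparison: the angle at vertex `b`
#' between the rays `b -> a` and `b -> c`, in degrees. Computed as the
#' arccosine of the normalized dot product, with the cosine clamped to
#' \[-1, 1\] so floating-point round-off never produces `NaN`.
#'
#' @param a,b,c Numeric 3-vectors. `b` is the vertex.
#' @param eps Degeneracy tolerance in meters: an endpoint closer than `eps`
#'   to the vertex is an error.
#' @return Angle in degrees, in \[0, 180\].
#' @examples
#' joint_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))  # 90
#' @export
joint_angle <- function(a, b, c, eps = 1e-9) {
  u <- as.numeric(a) - as.numeric(b)
  v <- as.numeric(c) - as.numeric(b)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu <= eps || nv <= eps) {
    stop("degenerate geometry: ray endpoint coincides with vertex",
         call. = FALSE)
  }
  cosang <- sum(u * v) / (nu * nv)
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

#' Define a named joint angle
#'
#' Two kinds of angle are supported. A *three-point* angle is measured at a
#' vertex landmark between rays to two endpoint landmarks; it is invariant
#' under any rigid motion of the skeleton. An *axis-referenced* angle is
#' measured between the ray vertex -> endpoint and a fixed world axis; it is
#' translation- but not rotation-invariant (used for trunk tilt against the
#' vertical).
#'
#' @param name Identifier for the angle.
#' @param kind `"three_point"` or `"axis"`.
#' @param vertex Vertex landmark name.
#' @param a,c Endpoint landmark names (three-point only); `a`, `vertex`, `c`
#'   must be pairwise distinct.
#' @param endpoint Endpoint landmark name (axis kind only).
#' @param axis Unit reference 3-vector (axis kind only).
#' @return An object of class `angle_definition`.
#' @export
angle_definition <- function(name, kind = c("three_point", "axis"),
                             vertex, a = NULL, c = NULL,
                             endpoint = NULL, axis = NULL) {
  kind <- match.arg(kind)
  canon <- landmark_names()
  if (kind == "three_point") {
    stopifnot(!is.null(a), !is.null(c))
    if (anyDuplicated(c(a, vertex, c)) > 0L) {
      stop("three-point angle requires pairwise distinct landmarks",
           call. = FALSE)
    }
    refs <- c(a, vertex, c)
  } else {
    stopifnot(!is.null(endpoint), !is.null(axis))
    axis <- as.numeric(axis)
    if (abs(sqrt(sum(axis^2)) - 1) > 1e-9) {
      stop("reference axis must have unit norm", call. = FALSE)
    }
    refs <- c(vertex, endpoint)
  }
  bad <- setdiff(refs, canon)
  if (length(bad) > 0L) {
    stop("unknown landmark(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(name = name, kind = kind, vertex = vertex, a = a, c = c,
                 endpoint = endpoint, axis = axis),
            class = "angle_definition")
}

#' Canonical angle set
#'
#' The default set of 9 named angles compared between the observed and the
#' regulated posture. The skeleton has no shoulder or hip landmarks, so
#' elbow and knee flexion use the waist as the proximal reference, and limb
#' elevation is measured at the waist against the head direction:
#' \itemize{
#'   \item `left_elbow`, `right_elbow`: wrist–elbow–waist
#'   \item `left_knee`, `right_knee`: ankle–knee–waist
#'   \item `left_arm_elevation`, `right_arm_elevation`: elbow–waist–head
#'   \item `left_leg_elevation`, `right_leg_elevation`: knee–waist–head
#'   \item `trunk_tilt`: waist -> head ray against the world y-axis
#'     (axis-referenced; 0 when standing upright)
#' }
#' The set is a documented convention, not a biomechanical necessity; any
#' list of [angle_definition()]s can be passed wherever an angle set is
#' accepted, or loaded from file with [read_angle_set()].
#'
#' @return List of 9 `angle_definition`s, classed `angle_set`.
#' @export
default_angle_set <- function() {
  defs <- list(
    angle_definition("left_elbow", "three_point", vertex = "left_elbow",
                     a = "left_wrist", c = "waist"),
    angle_definition("right_elbow", "three_point", vertex = "right_elbow",
                     a = "right_wrist", c = "waist"),
    angle_definition("left_knee", "three_point", vertex = "left_knee",
                     a = "left_ankle", c = "waist"),
    angle_definition("right_knee", "three_point", vertex = "right_knee",
                     a = "right_ankle", c = "waist"),
    angle_definition("left_arm_elevation", "three_point", vertex = "waist",
                     a = "left_elbow", c = "head"),
    angle_definition("right_arm_elevation", "three_point", vertex = "waist",
                     a = "right_elbow", c = "head"),
    angle_definition("left_leg_elevation", "three_point", vertex = "waist",
                     a = "left_knee", c = "head"),
    angle_definition("right_leg_elevation", "three_point", vertex = "waist",
                     a = "right_knee", c = "head"),
    angle_definition("trunk_tilt", "axis", vertex = "waist",
                     endpoint = "head", axis = c(0, 1, 0))
  )
  names(defs) <- vapply(defs, `[[`, character(1), "name")
  structure(defs, class = c("angle_set", "list"))
}

#' Names of an angle set
#' @param angles A list of [angle_definition()]s.
#' @return Character vector of angle names in set order.
#' @export
angle_set_names <- function(angles) {
  vapply(angles, `[[`, character(1), "name")
}

#' Read an angle set from a JSON or YAML file
#'
#' The file holds a list of records `{name, kind, vertex, endpoints | axis}`;
#' `kind` is `"three_point"` (endpoints = \[a, c\]) or `"axis"`
#' (endpoint + axis).
#'
#' @param path Path to a `.json` or `.yaml`/`.yml` file.
#' @return An `angle_set`.
#' @export
read_angle_set <- function(path) {
  recs <- read_config(path)
  defs <- lapply(recs, function(r) {
    if (identical(r$kind, "axis")) {
      angle_definition(r$name, "axis", vertex = r$vertex,
                       endpoint = r$endpoint, axis = as.numeric(r$axis))
    } else {
      angle_definition(r$name, "three_point", vertex = r$vertex,
                       a = r$endpoints[[1]], c = r$endpoints[[2]])
    }
  })
  names(defs) <- vapply(defs, `[[`, character(1), "name")
  structure(defs, class = c("angle_set", "list"))
}

# shared JSON/YAML config loader (YAML requires the suggested 'yaml' package)
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML config requires the 'yaml' package", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
}

#' Extract a named angle vector from one frame
#'
#' Evaluates every definition in the angle set on a single frame, in set
#' order. Degenerate geometry (an endpoint coinciding with its vertex) is an
#' error tagged with the angle's name.
#'
#' @param frame A [pose_frame()].
#' @param angles A list of [angle_definition()]s; default
#'   [default_angle_set()].
#' @return Named numeric vector of angles in degrees, in set order.
#' @export
extract_angle_vector <- function(frame, angles = default_angle_set()) {
  pos <- frame$positions
  vals <- vapply(angles, function(d) {
    tryCatch({
      if (d$kind == "three_point") {
        joint_angle(pos[d$a, ], pos[d$vertex, ], pos[d$c, ])
      } else {
        joint_angle(pos[d$vertex, ] + d$axis, pos[d$vertex, ], pos[d$endpoint, ])
      }
    }, error = function(e) {
      stop(sprintf("angle '%s': %s", d$name, conditionMessage(e)),
           call. = FALSE)
    })
  }, numeric(1))
  names(vals) <- angle_set_names(angles)
  vals
}

# Vectorized extraction over a T x 10 x 3 array -> T x n_angles matrix.
angles_from_array <- function(arr, angles) {
  nT <- dim(arr)[1]
  out <- matrix(NA_real_, nT, length(angles),
                dimnames = list(NULL, angle_set_names(angles)))
  for (j in seq_along(angles)) {
    d <- angles[[j]]
    if (d$kind == "three_point") {
      u <- arr[, d$a, , drop = FALSE] - arr[, d$vertex, , drop = FALSE]
      v <- arr[, d$c, , drop = FALSE] - arr[, d$vertex, , drop = FALSE]
    } else {
      u <- arr[, d$endpoint, , drop = FALSE] - arr[, d$vertex, , drop = FALSE]
      v <- array(rep(d$axis, each = nT), dim = c(nT, 1L, 3L))
    }
    u <- matrix(u, nT, 3L); v <- matrix(v, nT, 3L)
    cosang <- rowSums(u * v) /
      (sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)))
    out[, j] <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  }
  out
}

#' Extract per-frame angle vectors from a sequence
#'
#' @param seq A [motion_sequence()].
#' @param angles Angle set; default [default_angle_set()].
#' @return Numeric matrix, one row per frame, one column per angle (degrees).
#' @export
extract_angle_matrix <- function(seq, angles = default_angle_set()) {
  angles_from_array(seq_to_array(seq), angles)
}

#' Exponential moving average filter
#'
#' Per-landmark, per-axis first-order smoothing of landmark trajectories:
#' `y[1] = x[1]`, `y[t] = alpha * x[t] + (1 - alpha) * y[t-1]`. Timestamps
#' and metadata are unchanged; `alpha = 1` is the identity.
#'
#' @param seq A [motion_sequence()] with at least one frame.
#' @param alpha Smoothing weight in (0, 1\].
#' @return A smoothed `motion_sequence`.
#' @export
ema_filter <- function(seq, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    stop("alpha must lie in (0, 1]", call. = FALSE)
  }
  if (length(seq$frames) == 0L) stop("empty sequence", call. = FALSE)
  arr <- smooth_array(seq_to_array(seq), median_window = NULL, alpha = alpha)
  array_to_seq(arr, frame_times(seq), seq$fps, seq$metadata)
}

running_median <- function(x, window) {
  n <- length(x)
  if (window == 3L) {
    if (n < 3L) return(x)
    a <- x[1:(n - 2L)]; b <- x[2:(n - 1L)]; d <- x[3:n]
    c(x[1L], pmax(pmin(a, b), pmin(pmax(a, b), d)), x[n])
  } else {
    half <- (window - 1L) %/% 2L
    out <- numeric(n)
    for (i in seq_len(n)) {
      # shrink the window symmetrically at the edges
      h <- min(half, i - 1L, n - i)
      out[i] <- stats::median(x[(i - h):(i + h)])
    }
    out
  }
}

# array-space smoothing fast path shared by the filters and the scorers
smooth_array <- function(arr, median_window = 3L, alpha = 0.3) {
  if (!is.null(median_window)) {
    for (l in seq_len(dim(arr)[2])) {
      for (ax in 1:3) arr[, l, ax] <- running_median(arr[, l, ax], median_window)
    }
  }
  if (!is.null(alpha)) {
    nT <- dim(arr)[1]
    if (nT > 1L) {
      for (t in 2:nT) {
        arr[t, , ] <- alpha * arr[t, , ] + (1 - alpha) * arr[t - 1L, , ]
      }
    }
  }
  arr
}

#' Running-median prefilter
#'
#' Per-landmark, per-axis sliding median over an odd window; removes
#' isolated single-frame spikes before the EMA stage. At the sequence edges
#' the window shrinks symmetrically, so the first and last frames pass
#' through unchanged.
#'
#' @param seq A [motion_sequence()].
#' @param window Odd integer window length, at least 3.
#' @return A filtered `motion_sequence`.
#' @export
median_prefilter <- function(seq, window = 3L) {
  window <- as.integer(window)
  if (is.na(window) || window < 3L || window %% 2L == 0L) {
    stop("window must be an odd integer >= 3", call. = FALSE)
  }
  if (length(seq$frames) == 0L) stop("empty sequence", call. = FALSE)
  arr <- smooth_array(seq_to_array(seq), median_window = window, alpha = NULL)
  array_to_seq(arr, frame_times(seq), seq$fps, seq$metadata)
}

#' Default temporal smoothing pipeline
#'
#' The smoothing applied to landmark trajectories before angle extraction in
#' [score_movement()] and [run_session()]: a running median (window 3) to
#' reject single-frame spikes, then an EMA with `alpha = 0.3` to attenuate
#' jitter. Both constants are exposed; pass `median_window = NULL` or
#' `alpha = NULL` to skip a stage.
#'
#' @param seq A [motion_sequence()].
#' @param median_window Odd window for [median_prefilter()], or `NULL`.
#' @param alpha EMA weight for [ema_filter()], or `NULL`.
#' @return A smoothed `motion_sequence`.
#' @export
smooth_sequence <- function(seq, median_window = 3L, alpha = 0.3) {
  if (!is.null(median_window)) seq <- median_prefilter(seq, median_window)
  if (!is.null(alpha)) seq <- ema_filter(seq, alpha)
  seq
}
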