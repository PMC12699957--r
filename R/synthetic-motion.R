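#' Skeleton segment lengths of the synthetic subject
#'
#' Fixed proportions of the generated skeleton (meters): waist->head 0.60,
#' waist->elbow 0.35, elbow->wrist 0.30, waist->knee 0.45, knee->ankle 0.45
#' — roughly a 1.7 m adult. The generator is a test fixture, not a
#' biomechanical model; angles, not lengths, carry all the signal.
#'
#' @return Named numeric vector of segment lengths in meters.
#' @export
segment_lengths <- function() {
  c(head = 0.60, upper_arm = 0.35, forearm = 0.30, thigh = 0.45,
    shank = 0.45)
}

#' Neutral standing angle vector
#'
#' The canonical 9 angles of a relaxed upright stance: arms hanging slightly
#' away from the trunk, legs extended, trunk vertical (tilt 0).
#'
#' @return Named numeric vector over the [default_angle_set()] names.
#' @export
neutral_angles <- function() {
  c(left_elbow = 160, right_elbow = 160,
    left_knee = 170, right_knee = 170,
    left_arm_elevation = 160, right_arm_elevation = 160,
    left_leg_elevation = 170, right_leg_elevation = 170,
    trunk_tilt = 0)
}

# lateral half-planes used to disambiguate limb placement; forward bias in z
# keeps left/right limbs off the trunk plane
.limb_axes <- list(
  arm_left  = c(1, 0, 0.25) / sqrt(1 + 0.25^2),
  arm_right = c(-1, 0, 0.25) / sqrt(1 + 0.25^2),
  leg_left  = c(1, 0, -0.25) / sqrt(1 + 0.25^2),
  leg_right = c(-1, 0, -0.25) / sqrt(1 + 0.25^2))

# Rotate unit rows `u` (T x 3) by theta (deg) toward the component of the
# fixed axis `s` orthogonal to u; rows where s is (nearly) parallel to u fall
# back to `s_alt`. Returns unit rows at angle theta from u.
rot_plane <- function(u, s, theta_deg, s_alt = c(0, 0, 1)) {
  nT <- nrow(u)
  srep <- matrix(s, nT, 3L, byrow = TRUE)
  w <- srep - rowSums(srep * u) * u
  nw <- sqrt(rowSums(w^2))
  bad <- nw < 1e-8
  if (any(bad)) {
    arep <- matrix(s_alt, sum(bad), 3L, byrow = TRUE)
    ub <- u[bad, , drop = FALSE]
    wb <- arep - rowSums(arep * ub) * ub
    w[bad, ] <- wb
    nw[bad] <- sqrt(rowSums(wb^2))
  }
  w <- w / nw
  th <- theta_deg * pi / 180
  cos(th) * u + sin(th) * w
}

# Forward placement: theta (T x 9, canonical names) -> T x 10 x 3 array.
# Construction guarantees every canonical angle is realized exactly:
# head direction encodes trunk tilt against +y; each limb's proximal segment
# is placed at the elevation angle from the head direction within a fixed
# lateral half-plane; each distal segment at the flexion angle from the ray
# back to the waist.
place_from_angles <- function(theta) {
  nm <- names(neutral_angles())
  stopifnot(all(nm %in% colnames(theta)))
  if (any(!is.finite(theta)) || any(theta < -1e-9) || any(theta > 180 + 1e-9)) {
    stop("angle trajectories must stay within [0, 180] degrees", call. = FALSE)
  }
  L <- segment_lengths()
  nT <- nrow(theta)
  canon <- landmark_names()
  arr <- array(NA_real_, dim = c(nT, 10L, 3L),
               dimnames = list(NULL, canon, c("x", "y", "z")))
  waist <- matrix(c(0, 1, 0), nT, 3L, byrow = TRUE)
  arr[, "waist", ] <- waist
  tau <- theta[, "trunk_tilt"] * pi / 180
  u_h <- cbind(sin(tau), cos(tau), 0)
  arr[, "head", ] <- waist + L[["head"]] * u_h
  place_limb <- function(side, elev_name, flex_name, prox, dist, axis,
                         L_prox, L_dist) {
    d_prox <- rot_plane(u_h, axis, theta[, elev_name])
    p_prox <- waist + L_prox * d_prox
    v <- -d_prox  # unit ray proximal joint -> waist
    d_dist <- rot_plane(v, axis, theta[, flex_name])
    arr[, prox, ] <<- p_prox
    arr[, dist, ] <<- p_prox + L_dist * d_dist
  }
  place_limb("left", "left_arm_elevation", "left_elbow", "left_elbow",
             "left_wrist", .limb_axes$arm_left, L[["upper_arm"]],
             L[["forearm"]])
  place_limb("right", "right_arm_elevation", "right_elbow", "right_elbow",
             "right_wrist", .limb_axes$arm_right, L[["upper_arm"]],
             L[["forearm"]])
  place_limb("left", "left_leg_elevation", "left_knee", "left_knee",
             "left_ankle", .limb_axes$leg_left, L[["thigh"]], L[["shank"]])
  place_limb("right", "right_leg_elevation", "right_knee", "right_knee",
             "right_ankle", .limb_axes$leg_right, L[["thigh"]], L[["shank"]])
  arr
}

#' Realize a pose frame from canonical angles
#'
#' Places the 10 landmarks by forward construction from the waist with fixed
#' segment lengths so that extracting the [default_angle_set()] recovers the
#' requested angles exactly (to floating-point precision).
#'
#' @param angles Named numeric vector over the canonical 9 angle names
#'   (degrees in \[0, 180\]); defaults filled from [neutral_angles()].
#' @param time Frame timestamp in seconds.
#' @return A [pose_frame()].
#' @export
pose_from_angles <- function(angles = neutral_angles(), time = 0) {
  full <- neutral_angles()
  full[names(angles)] <- angles
  arr <- place_from_angles(matrix(full, 1L, dimnames = list(NULL, names(full))))
  pos <- matrix(arr[1L, , ], 10L, 3L,
                dimnames = list(landmark_names(), c("x", "y", "z")))
  pose_frame(time, pos)
}

#' Neutral standing pose
#'
#' @param time Frame timestamp in seconds.
#' @return A [pose_frame()] realizing [neutral_angles()].
#' @export
neutral_pose <- function(time = 0) pose_from_angles(neutral_angles(), time)

#' Static hold of a pose as a motion sequence
#'
#' Repeats one canonical-angle pose over a time window — a subject holding a
#' regulated posture perfectly.
#'
#' @param angles Named canonical angle vector; see [pose_from_angles()].
#' @param duration Duration in seconds.
#' @param fps Frames per second.
#' @return A [motion_sequence()].
#' @export
static_pose_sequence <- function(angles = neutral_angles(), duration = 1,
                                 fps = 30) {
  n <- max(1L, round(duration * fps))
  full <- neutral_angles()
  full[names(angles)] <- angles
  theta <- matrix(full, n, length(full), byrow = TRUE,
                  dimnames = list(NULL, names(full)))
  arr <- place_from_angles(theta)
  array_to_seq(arr, (seq_len(n) - 1L) / fps, fps,
               metadata = list(movement = "static"))
}

# --- movement templates ------------------------------------------------

# Each template: loop period (s) and per-angle keyframes (phase in [0,1],
# value in degrees), linearly interpolated and periodic. Angles not listed
# hold their neutral value. Stylized, physiologically plausible loops for
# the six prescribed aerobic movements; authored fixtures, not biomechanics.
.kf <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  colnames(m) <- c("phase", "value")
  m
}

.movement_templates <- list(
  toe_stretch = list(period = 4, keyframes = list(
    left_arm_elevation  = .kf(0, 160, 0.5, 30, 1, 160),
    right_arm_elevation = .kf(0, 160, 0.5, 30, 1, 160),
    left_elbow  = .kf(0, 160, 0.5, 172, 1, 160),
    right_elbow = .kf(0, 160, 0.5, 172, 1, 160),
    left_knee   = .kf(0, 170, 0.5, 165, 1, 170),
    right_knee  = .kf(0, 170, 0.5, 165, 1, 170))),
  high_knees = list(period = 1.2, keyframes = list(
    left_leg_elevation  = .kf(0, 170, 0.25, 95, 0.5, 170, 1, 170),
    left_knee           = .kf(0, 170, 0.25, 90, 0.5, 170, 1, 170),
    right_leg_elevation = .kf(0, 170, 0.5, 170, 0.75, 95, 1, 170),
    right_knee          = .kf(0, 170, 0.5, 170, 0.75, 90, 1, 170),
    left_elbow  = .kf(0, 120, 0.25, 90, 0.5, 120, 0.75, 150, 1, 120),
    right_elbow = .kf(0, 120, 0.25, 150, 0.5, 120, 0.75, 90, 1, 120))),
  side_arm_raise = list(period = 3, keyframes = list(
    left_arm_elevation  = .kf(0, 160, 0.5, 85, 1, 160),
    right_arm_elevation = .kf(0, 160, 0.5, 85, 1, 160),
    left_elbow  = .kf(0, 160, 0.5, 172, 1, 160),
    right_elbow = .kf(0, 160, 0.5, 172, 1, 160))),
  punching = list(period = 1.6, keyframes = list(
    left_elbow  = .kf(0, 70, 0.25, 165, 0.5, 70, 1, 70),
    right_elbow = .kf(0, 70, 0.5, 70, 0.75, 165, 1, 70),
    left_arm_elevation  = .kf(0, 95, 1, 95),
    right_arm_elevation = .kf(0, 95, 1, 95))),
  arm_stretch_hip_extension = list(period = 4, keyframes = list(
    left_arm_elevation  = .kf(0, 160, 0.5, 35, 1, 160),
    right_arm_elevation = .kf(0, 160, 0.5, 35, 1, 160),
    trunk_tilt          = .kf(0, 0, 0.5, 15, 1, 0),
    left_leg_elevation  = .kf(0, 170, 0.5, 160, 1, 170),
    right_leg_elevation = .kf(0, 170, 0.5, 160, 1, 170))),
  elbow_to_chest = list(period = 2.5, keyframes = list(
    left_elbow  = .kf(0, 160, 0.5, 45, 1, 160),
    right_elbow = .kf(0, 160, 0.5, 45, 1, 160),
    left_arm_elevation  = .kf(0, 160, 0.5, 100, 1, 160),
    right_arm_elevation = .kf(0, 160, 0.5, 100, 1, 160))))

#' Movement template
#'
#' The keyframe loop that defines a synthetic movement: period in seconds
#' and per-angle `(phase, value)` keyframes, linearly interpolated and
#' periodic; angles without keyframes hold their [neutral_angles()] value.
#'
#' @param id One of [movement_ids()].
#' @return List with `id`, `period` and `keyframes`.
#' @export
movement_template <- function(id) {
  if (!id %in% names(.movement_templates)) {
    stop("unknown movement id: ", id, "; known: ",
         paste(names(.movement_templates), collapse = ", "), call. = FALSE)
  }
  c(list(id = id), .movement_templates[[id]])
}

#' Evaluate a movement template's angle trajectories
#'
#' @param id One of [movement_ids()].
#' @param t Numeric vector of times in seconds (wrapped into the loop's
#'   period).
#' @return Matrix `length(t)` x 9 of canonical angles in degrees.
#' @export
template_angles <- function(id, t) {
  tpl <- movement_template(id)
  phase <- (t / tpl$period) %% 1
  nm <- names(neutral_angles())
  out <- matrix(rep(neutral_angles(), each = length(t)), length(t),
                length(nm), dimnames = list(NULL, nm))
  for (an in names(tpl$keyframes)) {
    kf <- tpl$keyframes[[an]]
    out[, an] <- stats::approx(kf[, "phase"], kf[, "value"], xout = phase,
                               rule = 2)$y
  }
  out
}

#' Noise specification for the motion generator
#'
#' @param angular_sd Per-frame, per-angle Gaussian jitter SD in degrees
#'   (>= 0).
#' @param temporal_sd Gaussian jitter SD on the template sampling time in
#'   seconds (>= 0).
#' @param seed Integer RNG seed (required; the generator has a single RNG
#'   stream per call and is fully reproducible).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(angular_sd = 0, temporal_sd = 0, seed) {
  if (missing(seed)) stop("noise_spec requires an explicit seed", call. = FALSE)
  if (angular_sd < 0 || temporal_sd < 0) {
    stop("noise SDs must be non-negative", call. = FALSE)
  }
  structure(list(angular_sd = angular_sd, temporal_sd = temporal_sd,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

# evaluate code under a local RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# core generator: angles at jittered template times + angular jitter,
# clamped to the valid range, then realized as landmark positions
generate_theta <- function(id, rel_times, noise) {
  t_sample <- rel_times
  if (noise$temporal_sd > 0) {
    t_sample <- t_sample + stats::rnorm(length(rel_times), 0, noise$temporal_sd)
  }
  theta <- template_angles(id, t_sample)
  if (noise$angular_sd > 0) {
    theta <- theta + matrix(stats::rnorm(length(theta), 0, noise$angular_sd),
                            nrow(theta), ncol(theta))
  }
  pmax(pmin(theta, 180), 0)
}

#' Generate a synthetic movement recording
#'
#' Produces a seeded skeleton recording of a subject performing one of the
#' six aerobic movements: the movement template's angle trajectories are
#' sampled at the frame times (optionally jittered in time), perturbed by
#' Gaussian angular noise, clamped to \[0, 180\] degrees, and realized as
#' landmark positions by forward placement from the waist. With zero noise
#' the extracted angle trajectories reproduce the template to floating-point
#' precision. Deterministic for a fixed seed; the caller's RNG state is left
#' untouched.
#'
#' @param id One of [movement_ids()].
#' @param duration Recording length in seconds (> 0); the prescribed
#'   per-movement duration is 50 s.
#' @param fps Frames per second (> 0); default 30.
#' @param noise A [noise_spec()].
#' @return A [motion_sequence()] with metadata `movement` and `seed`.
#' @export
generate_movement <- function(id, duration = 50, fps = 30,
                              noise = noise_spec(seed = 1)) {
  stopifnot(duration > 0, fps > 0)
  tpl <- movement_template(id)  # validates the id
  n <- round(duration * fps)
  times <- (seq_len(n) - 1L) / fps
  theta <- with_seed(noise$seed, generate_theta(id, times, noise))
  arr <- place_from_angles(theta)
  array_to_seq(arr, times, fps,
               metadata = list(movement = id, seed = noise$seed))
}

# Rodrigues rotation of vector v about unit axis k by deg degrees
rodrigues <- function(v, k, deg) {
  th <- deg * pi / 180
  v * cos(th) + cross3(k, v) * sin(th) + k * sum(k * v) * (1 - cos(th))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# unit normal of the plane spanned by two unit rays; fallback when collinear
plane_normal <- function(u_ref, u_mov, fallback = c(0, 0, 1)) {
  n <- cross3(u_ref, u_mov)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) {
    n <- cross3(u_ref, fallback)
    nn <- sqrt(sum(n^2))
    if (nn < 1e-12) {
      n <- cross3(u_ref, c(1, 0, 0))
      nn <- sqrt(sum(n^2))
    }
  }
  n / nn
}

#' Inject a known angular deviation into a sequence
#'
#' Re-poses the relevant landmark(s) in every frame so that the named
#' canonical angle changes by exactly `delta` degrees while the other
#' canonical angles are untouched (limb segments are rotated rigidly about
#' their parent joint, and trunk tilt rotates the whole skeleton about the
#' waist). Used to close the scoring loop: inject a known deviation, verify
#' the measured deviation sum recovers it.
#'
#' @param seq A [motion_sequence()].
#' @param angle One of the [default_angle_set()] names.
#' @param delta Deviation in degrees; every frame's resulting angle must
#'   stay within \[0, 180\].
#' @return The modified `motion_sequence`.
#' @export
inject_deviation <- function(seq, angle, delta) {
  nm <- names(neutral_angles())
  if (!angle %in% nm) {
    stop("angle must be one of the canonical set: ",
         paste(nm, collapse = ", "), call. = FALSE)
  }
  if (delta == 0) return(seq)
  side <- if (startsWith(angle, "left_")) "left" else "right"
  kind <- sub("^(left|right)_", "", angle)
  frames <- seq$frames
  for (i in seq_along(frames)) {
    pos <- frames[[i]]$positions
    W <- pos["waist", ]
    moved <- switch(
      kind,
      elbow = {
        E <- pos[paste0(side, "_elbow"), ]
        Wr <- pos[paste0(side, "_wrist"), ]
        rot_about(pos, vertex = E, ref = W - E, mov = Wr - E, delta = delta,
                  targets = paste0(side, "_wrist"), angle = angle)
      },
      knee = {
        K <- pos[paste0(side, "_knee"), ]
        A <- pos[paste0(side, "_ankle"), ]
        rot_about(pos, vertex = K, ref = W - K, mov = A - K, delta = delta,
                  targets = paste0(side, "_ankle"), angle = angle)
      },
      arm_elevation = {
        E <- pos[paste0(side, "_elbow"), ]
        rot_about(pos, vertex = W, ref = pos["head", ] - W, mov = E - W,
                  delta = delta,
                  targets = paste0(side, c("_elbow", "_wrist")), angle = angle)
      },
      leg_elevation = {
        K <- pos[paste0(side, "_knee"), ]
        rot_about(pos, vertex = W, ref = pos["head", ] - W, mov = K - W,
                  delta = delta,
                  targets = paste0(side, c("_knee", "_ankle")), angle = angle)
      },
      trunk_tilt = {
        rot_about(pos, vertex = W, ref = c(0, 1, 0), mov = pos["head", ] - W,
                  delta = delta,
                  targets = setdiff(landmark_names(), "waist"),
                  angle = angle)
      },
      stop("unsupported angle: ", angle, call. = FALSE))
    frames[[i]]$positions <- moved
  }
  motion_sequence(frames, seq$fps, seq$metadata)
}

# rotate the target landmarks about `vertex` in the (ref, mov) plane so the
# angle between ref and mov grows by delta; errors if the result leaves
# [0, 180]
rot_about <- function(pos, vertex, ref, mov, delta, targets, angle) {
  u_ref <- ref / sqrt(sum(ref^2))
  u_mov <- mov / sqrt(sum(mov^2))
  cur <- acos(min(1, max(-1, sum(u_ref * u_mov)))) * 180 / pi
  if (cur + delta < -1e-9 || cur + delta > 180 + 1e-9) {
    stop(sprintf("deviation of %+g deg would push %s (currently %.2f deg) outside [0, 180]",
                 delta, angle, cur), call. = FALSE)
  }
  n <- plane_normal(u_ref, u_mov)
  for (lm in targets) {
    pos[lm, ] <- vertex + rodrigues(pos[lm, ] - vertex, n, delta)
  }
  pos
}

#' Generate a full aerobic session stream
#'
#' Concatenates [generate_movement()] outputs for the plan's six scheduled
#' windows into one continuous 300 s recording: window `i` runs
#' `[50(i-1), 50i)` seconds with the movement's template phase restarting at
#' the window boundary (mirroring the on-screen demonstration). A single RNG
#' stream seeded from `noise$seed` drives all windows.
#'
#' @param plan A [build_session()] plan.
#' @param noise A [noise_spec()].
#' @param fps Frames per second; default 30.
#' @return A [motion_sequence()] spanning the aerobic block.
#' @export
generate_session_stream <- function(plan, noise = noise_spec(seed = 1),
                                    fps = 30) {
  win <- session_windows(plan)
  n_win <- round(plan$movement_duration * fps)
  rel <- (seq_len(n_win) - 1L) / fps
  thetas <- with_seed(noise$seed, {
    lapply(win$movement, function(id) generate_theta(id, rel, noise))
  })
  theta <- do.call(rbind, thetas)
  arr <- place_from_angles(theta)
  times <- as.vector(vapply(win$start, function(s) s + rel, numeric(n_win)))
  array_to_seq(arr, times, fps,
               metadata = list(plan = paste(win$movement, collapse = ","),
                               seed = noise$seed))
}

#' Tracking reference for a movement template
#'
#' A reference that follows the movement's demonstration instead of holding
#' a single static posture: when scored inside [run_session()], the
#' regulated angles are the template's trajectories evaluated at the
#' window-relative frame times and passed through the same smoothing
#' pipeline as the observed stream, so a noiseless performance has exactly
#' zero deviation in every frame.
#'
#' @param movement One of [movement_ids()].
#' @param params A [score_params()].
#' @param angles Angle set the reference is expressed in; default
#'   [default_angle_set()].
#' @param median_window,alpha Smoothing-pipeline settings, matching
#'   [smooth_sequence()] defaults.
#' @return An object of class `tracking_reference`.
#' @export
tracking_reference <- function(movement, params = score_params(),
                               angles = default_angle_set(),
                               median_window = 3L, alpha = 0.3) {
  movement_template(movement)  # validates
  structure(list(movement = movement, params = params, angles = angles,
                 median_window = median_window, alpha = alpha),
            class = "tracking_reference")
}

# realize a tracking reference at specific window-relative times
materialize_reference <- function(ref, rel_times) {
  theta <- template_angles(ref$movement, rel_times)
  arr <- smooth_array(place_from_angles(theta), ref$median_window, ref$alpha)
  reference_pose(ref$movement, angles_from_array(arr, ref$angles),
                 ref$params)
}

#' Tracking references for a whole plan
#'
#' @param plan A [build_session()] plan.
#' @param params A [score_params()] shared by all movements.
#' @return Named list of [tracking_reference()]s keyed by movement id.
#' @export
session_references <- function(plan, params = score_params()) {
  refs <- lapply(plan$movements, tracking_reference, params = params)
  names(refs) <- plan$movements
  refs
}
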