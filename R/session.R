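#' The six aerobic movements
#'
#' Identifiers of the six prescribed aerobic movements performed in every
#' session: toe stretches, high knees, side arm raises, punching, arm
#' stretches with hip extension, and elbow-to-chest expansions.
#'
#' @return Character vector of 6 movement ids.
#' @export
movement_ids <- function() {
  c("toe_stretch", "high_knees", "side_arm_raise", "punching",
    "arm_stretch_hip_extension", "elbow_to_chest")
}

#' Allowed resistance-band levels
#'
#' Resistance levels offered for the resistance block, in 0.25 kg steps from
#' 0.25 to 1.5 kg.
#'
#' @return Numeric vector of allowed levels in kilograms.
#' @export
resistance_levels <- function() seq(0.25, 1.5, by = 0.25)

#' Build a 10-minute session plan
#'
#' A session is 10 minutes: a 5-minute aerobic block of six movements at
#' 50 seconds each, followed by a 5-minute resistance block at a chosen band
#' level. The resistance block is scheduled but not pose-scored (band
#' exercises are performed under supervision, outside the camera loop).
#'
#' @param movements Character vector of exactly 6 movement ids; default
#'   [movement_ids()].
#' @param resistance_kg Band level in kilograms, one of
#'   [resistance_levels()].
#' @return An object of class `session_plan` with `movements`,
#'   `movement_duration` (50), `aerobic_seconds` (300), `resistance_seconds`
#'   (300), `total_seconds` (600) and `resistance_kg`.
#' @export
build_session <- function(movements = movement_ids(), resistance_kg = 0.5) {
  movements <- as.character(movements)
  if (length(movements) != 6L) {
    stop("a session plan requires exactly 6 aerobic movements, got ",
         length(movements), call. = FALSE)
  }
  if (!isTRUE(any(abs(resistance_kg - resistance_levels()) < 1e-9))) {
    stop("resistance_kg must be one of ",
         paste(format(resistance_levels()), collapse = ", "), " kg",
         call. = FALSE)
  }
  structure(list(movements = movements, movement_duration = 50,
                 aerobic_seconds = 300, resistance_seconds = 300,
                 total_seconds = 600,
                 resistance_kg = as.numeric(resistance_kg)),
            class = "session_plan")
}

#' @export
print.session_plan <- function(x, ...) {
  cat(sprintf("<session_plan> %d s aerobic (6 x %d s) + %d s resistance @ %.2f kg\n",
              x$aerobic_seconds, x$movement_duration, x$resistance_seconds,
              x$resistance_kg))
  cat("  movements:", paste(x$movements, collapse = ", "), "\n")
  invisible(x)
}

#' Aerobic schedule windows of a plan
#'
#' The six half-open windows `[start, end)` in seconds, relative to session
#' start, that tile the aerobic block with no gaps or overlaps.
#'
#' @param plan A [build_session()] plan.
#' @return Data frame with `movement`, `start`, `end`.
#' @export
session_windows <- function(plan) {
  starts <- (seq_along(plan$movements) - 1L) * plan$movement_duration
  data.frame(movement = plan$movements, start = starts,
             end = starts + plan$movement_duration,
             stringsAsFactors = FALSE)
}

#' Score a full aerobic block
#'
#' Partitions a captured pose stream by the plan's schedule (six 50 s
#' half-open windows relative to the stream's first timestamp) and scores
#' each window with [score_movement()] against that movement's reference.
#' Points per movement are `round(aggregate S)` (half away from zero), so a
#' perfect session earns 600 points.
#'
#' References may be static [reference_pose()]s or [tracking_reference()]s;
#' a tracking reference is materialized per window at the window-relative
#' frame times, so the regulated posture follows the on-screen
#' demonstration.
#'
#' @param seq A [motion_sequence()] spanning the aerobic block.
#' @param plan A [build_session()] plan.
#' @param refs Named list mapping each scheduled movement id to its
#'   reference.
#' @param angles Angle set; default [default_angle_set()].
#' @param aggregate Aggregation rule passed to [score_movement()].
#' @return An object of class `session_result`: list of `movement_score`s,
#'   `points` per movement, `total_points`, and the plan.
#' @export
run_session <- function(seq, plan, refs, angles = default_angle_set(),
                        aggregate = "mean") {
  win <- session_windows(plan)
  missing <- setdiff(win$movement, names(refs))
  if (length(missing) > 0L) {
    stop("missing reference pose(s) for scheduled movement(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  times <- frame_times(seq)
  t0 <- times[1]
  rel <- times - t0
  span <- rel[length(rel)] + 1 / seq$fps
  if (span < plan$aerobic_seconds - 1e-9) {
    stop(sprintf("sequence covers %.2f s but the aerobic block is %d s",
                 span, plan$aerobic_seconds), call. = FALSE)
  }
  scores <- vector("list", nrow(win))
  for (i in seq_len(nrow(win))) {
    idx <- which(rel >= win$start[i] - 1e-9 & rel < win$end[i] - 1e-9)
    if (length(idx) == 0L) {
      stop(sprintf("no frames in the %s window [%g, %g) s",
                   win$movement[i], win$start[i], win$end[i]), call. = FALSE)
    }
    sub <- motion_sequence(seq$frames[idx], fps = seq$fps,
                           metadata = seq$metadata)
    ref <- refs[[win$movement[i]]]
    if (inherits(ref, "tracking_reference")) {
      ref <- materialize_reference(ref, rel[idx] - win$start[i])
    }
    scores[[i]] <- score_movement(sub, ref, angles, aggregate = aggregate)
  }
  points <- vapply(scores, function(s) floor(s$aggregate + 0.5), numeric(1))
  structure(list(scores = scores, points = points,
                 total_points = sum(points), plan = plan,
                 timestamp = t0),
            class = "session_result")
}

#' @export
print.session_result <- function(x, ...) {
  cat("<session_result>\n")
  for (i in seq_along(x$scores)) {
    s <- x$scores[[i]]
    cat(sprintf("  %-26s S = %6.2f  points = %d\n", s$movement, s$aggregate,
                as.integer(x$points[i])))
  }
  cat(sprintf("  total points: %d\n", as.integer(x$total_points)))
  invisible(x)
}

#' Default reward catalog
#'
#' In-game items redeemable with points earned through accurate execution.
#' Items and prices are engine conventions (configurable); the catalog
#' covers background music, avatar customization and new virtual
#' environments.
#'
#' @return Named numeric vector of point costs.
#' @export
reward_catalog <- function() {
  c(background_music = 300, avatar_customization = 600,
    virtual_environment = 900)
}

#' Create a reward ledger
#'
#' @param points Initial non-negative point balance.
#' @param unlocked Character vector of already-unlocked item ids.
#' @param catalog Named cost vector; default [reward_catalog()].
#' @return An object of class `reward_ledger`.
#' @export
reward_ledger <- function(points = 0, unlocked = character(0),
                          catalog = reward_catalog()) {
  points <- as.numeric(points)
  if (!is.finite(points) || points < 0) {
    stop("points must be non-negative", call. = FALSE)
  }
  if (anyDuplicated(unlocked) > 0L) {
    stop("an item can be unlocked at most once", call. = FALSE)
  }
  structure(list(points = points, unlocked = as.character(unlocked),
                 catalog = catalog),
            class = "reward_ledger")
}

#' Credit a session's points to a ledger
#'
#' @param result A [run_session()] result.
#' @param ledger A [reward_ledger()].
#' @return The updated ledger (unlocks unchanged).
#' @export
award_points <- function(result, ledger) {
  ledger$points <- ledger$points + result$total_points
  ledger
}

#' Redeem a catalog item
#'
#' Deducts the item's cost and adds it to the unlocked set. Redeeming an
#' unknown or already-unlocked item, or redeeming with insufficient points,
#' is an error and leaves the ledger unchanged.
#'
#' @param ledger A [reward_ledger()].
#' @param item Catalog item id.
#' @return The updated ledger.
#' @export
redeem <- function(ledger, item) {
  if (!item %in% names(ledger$catalog)) {
    stop("unknown catalog item: ", item, call. = FALSE)
  }
  if (item %in% ledger$unlocked) {
    stop("item already unlocked: ", item, call. = FALSE)
  }
  cost <- ledger$catalog[[item]]
  if (ledger$points < cost) {
    stop(sprintf("insufficient points: have %g, %s costs %g",
                 ledger$points, item, cost), call. = FALSE)
  }
  ledger$points <- ledger$points - cost
  ledger$unlocked <- c(ledger$unlocked, item)
  ledger
}

#' @export
print.reward_ledger <- function(x, ...) {
  cat(sprintf("<reward_ledger> %g points; unlocked: %s\n", x$points,
              if (length(x$unlocked)) paste(x$unlocked, collapse = ", ")
              else "(none)"))
  invisible(x)
}
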