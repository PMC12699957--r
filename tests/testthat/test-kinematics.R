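test_that("joint_angle reproduces elementary geometry", {
  expect_equal(joint_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  expect_equal(joint_angle(c(1, 0, 0), c(0, 0, 0), c(-2, 0, 0)), 180)
  expect_equal(joint_angle(c(1, 0, 0), c(0, 0, 0), c(1, 1, 0)), 45)
  expect_error(joint_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)), "degenerate")
})

test_that("joint_angle matches an independent arccos oracle on random triples", {
  set.seed(7)
  for (i in 1:100) {
    a <- rnorm(3); b <- rnorm(3); c <- rnorm(3)
    u <- a - b; v <- c - b
    oracle <- acos(max(-1, min(1, (u %*% v) / sqrt(sum(u^2) * sum(v^2))))) *
      180 / pi
    expect_equal(joint_angle(a, b, c), as.numeric(oracle), tolerance = 1e-9)
  }
})

test_that("joint_angle clamps round-off without producing NaN", {
  # parallel rays whose dot product can round above 1
  v <- c(0.1, 0.2, 0.3)
  expect_equal(joint_angle(v, c(0, 0, 0), 7 * v), 0, tolerance = 1e-5)
  expect_false(is.nan(joint_angle(v, c(0, 0, 0), v * (1 + 1e-15))))
})

test_that("the canonical angle set has 9 angles over the 10 landmarks", {
  ang <- default_angle_set()
  expect_length(ang, 9L)
  refs <- unlist(lapply(ang, function(d) c(d$vertex, d$a, d$c, d$endpoint)))
  expect_true(all(refs %in% landmark_names()))
  kinds <- vapply(ang, `[[`, character(1), "kind")
  expect_identical(sum(kinds == "axis"), 1L)
  av <- extract_angle_vector(neutral_pose(), ang)
  expect_equal(unname(av[["trunk_tilt"]]), 0)
  expect_true(all(is.finite(av)))
})

test_that("three-point angles are rigid-motion invariant", {
  set.seed(11)
  f <- pose_from_angles(random_canonical_angles())
  base <- extract_angle_vector(f)
  th <- 40 * pi / 180
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  pos <- t(R %*% t(f$positions)) + matrix(c(3, 1, -2), 10, 3, byrow = TRUE)
  rownames(pos) <- rownames(f$positions)
  moved <- extract_angle_vector(pose_frame(0, pos))
  # rotation about y preserves the y-axis-referenced trunk tilt too
  expect_equal(moved, base, tolerance = 1e-6)
})

test_that("extract_angle_vector equals hand-composed joint_angle calls", {
  set.seed(21)
  f <- pose_from_angles(random_canonical_angles())
  av <- extract_angle_vector(f)
  p <- f$positions
  expect_equal(unname(av[["left_elbow"]]),
               joint_angle(p["left_wrist", ], p["left_elbow", ], p["waist", ]))
  expect_equal(unname(av[["right_knee"]]),
               joint_angle(p["right_ankle", ], p["right_knee", ], p["waist", ]))
  expect_equal(unname(av[["left_arm_elevation"]]),
               joint_angle(p["left_elbow", ], p["waist", ], p["head", ]))
  expect_equal(unname(av[["trunk_tilt"]]),
               joint_angle(p["waist", ] + c(0, 1, 0), p["waist", ], p["head", ]))
})

test_that("ema_filter follows the first-order recurrence", {
  static <- static_pose_sequence(duration = 0.5, fps = 10)
  smoothed <- ema_filter(static, 0.4)
  expect_equal(seq_to_arr(smoothed), seq_to_arr(static), tolerance = 1e-12)

  seq <- noisy_sequence(seed = 5)
  expect_equal(seq_to_arr(ema_filter(seq, 1)), seq_to_arr(seq),
               tolerance = 1e-12)

  # unit step in head x at frame 3 of 5, alpha = 0.5
  frames <- lapply(0:4, function(i) {
    f <- neutral_pose(i / 30)
    if (i >= 2) f$positions["head", 1] <- f$positions["head", 1] + 1
    f
  })
  step <- motion_sequence(frames, 30)
  out <- ema_filter(step, 0.5)
  base <- neutral_pose()$positions["head", 1]
  trace <- vapply(out$frames, function(f) f$positions["head", 1] - base,
                  numeric(1))
  expect_equal(trace, c(0, 0, 0.5, 0.75, 0.875))

  expect_error(ema_filter(seq, 0), "alpha")
  expect_error(ema_filter(seq, 1.2), "alpha")
})

test_that("median_prefilter rejects spikes and matches a brute-force oracle", {
  static <- static_pose_sequence(duration = 0.5, fps = 10)
  expect_equal(seq_to_arr(median_prefilter(static, 3)), seq_to_arr(static),
               tolerance = 1e-12)

  # single-frame spike of +10 m in waist y, window 3
  frames <- lapply(0:6, function(i) {
    f <- neutral_pose(i / 30)
    if (i == 3) f$positions["waist", 2] <- f$positions["waist", 2] + 10
    f
  })
  spiky <- motion_sequence(frames, 30)
  clean <- median_prefilter(spiky, 3)
  waist_y <- vapply(clean$frames, function(f) f$positions["waist", 2],
                    numeric(1))
  expect_equal(waist_y, rep(1, 7))

  brute <- function(x, w) {
    n <- length(x); h <- (w - 1) %/% 2
    vapply(seq_len(n), function(i) {
      hh <- min(h, i - 1, n - i)
      stats::median(x[(i - hh):(i + hh)])
    }, numeric(1))
  }
  seq <- noisy_sequence(seed = 13, sd = 6)
  arr <- seq_to_arr(seq)
  out5 <- seq_to_arr(median_prefilter(seq, 5))
  out3 <- seq_to_arr(median_prefilter(seq, 3))
  for (lm in c(2, 5, 9)) {
    for (ax in 1:3) {
      expect_equal(out5[, lm, ax], brute(arr[, lm, ax], 5))
      expect_equal(out3[, lm, ax], brute(arr[, lm, ax], 3))
    }
  }
  expect_error(median_prefilter(seq, 4), "odd")
  expect_error(median_prefilter(seq, 1), "odd")
})

test_that("filtering commutes with global translation", {
  seq <- noisy_sequence(seed = 17, sd = 4)
  shift <- c(2, -1, 0.5)
  shifted <- seq
  shifted$frames <- lapply(seq$frames, function(f) {
    f$positions <- f$positions + matrix(shift, 10, 3, byrow = TRUE)
    f
  })
  a <- seq_to_arr(smooth_sequence(shifted))
  b <- seq_to_arr(smooth_sequence(seq))
  for (ax in 1:3) b[, , ax] <- b[, , ax] + shift[ax]
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("angle sets round-trip through a JSON config file", {
  p <- withr::local_tempfile(fileext = ".json")
  recs <- lapply(default_angle_set(), function(d) {
    if (d$kind == "axis") {
      list(name = d$name, kind = "axis", vertex = d$vertex,
           endpoint = d$endpoint, axis = d$axis)
    } else {
      list(name = d$name, kind = "three_point", vertex = d$vertex,
           endpoints = c(d$a, d$c))
    }
  })
  jsonlite::write_json(unname(recs), p, auto_unbox = TRUE, digits = NA)
  back <- read_angle_set(p)
  expect_identical(angle_set_names(back), angle_set_names(default_angle_set()))
  f <- pose_from_angles(random_canonical_angles())
  expect_equal(extract_angle_vector(f, back), extract_angle_vector(f))
})
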