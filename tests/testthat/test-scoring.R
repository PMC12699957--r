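test_that("total_deviation sums per-angle absolute deviations", {
  ref <- random_canonical_angles()
  same <- total_deviation(ref, ref)
  expect_equal(same$D, 0)
  expect_equal(unname(same$per_angle), rep(0, 9))

  obs <- ref
  obs[["left_knee"]] <- obs[["left_knee"]] + 30
  expect_equal(total_deviation(obs, ref)$D, 30)
  expect_equal(total_deviation(ref, obs)$D, 30)  # symmetric

  set.seed(31)
  for (i in 1:20) {
    a <- random_canonical_angles()
    b <- random_canonical_angles()
    expect_equal(total_deviation(a, b)$D, sum(abs(a - b)), tolerance = 1e-12)
  }
})

test_that("signed deviation is available but cancels opposite errors", {
  ref <- neutral_angles()
  obs <- ref
  obs[["left_elbow"]] <- ref[["left_elbow"]] - 20
  obs[["right_elbow"]] <- ref[["right_elbow"]] + 20
  expect_equal(total_deviation(obs, ref, signed = TRUE)$D, 0)
  expect_equal(total_deviation(obs, ref)$D, 40)
})

test_that("mismatched angle sets raise a configuration error naming them", {
  a <- random_canonical_angles()
  b <- a[-1]
  expect_error(total_deviation(a, b), "left_elbow")
  expect_error(total_deviation(a, rev(a)), "order")
})

test_that("total_deviation is a metric on fixed angle sets", {
  set.seed(41)
  for (i in 1:25) {
    x <- random_canonical_angles()
    y <- random_canonical_angles()
    z <- random_canonical_angles()
    dxy <- total_deviation(x, y)$D
    dyx <- total_deviation(y, x)$D
    expect_equal(dxy, dyx)
    expect_true(dxy > 0 || identical(x, y))
    expect_lte(total_deviation(x, z)$D,
               dxy + total_deviation(y, z)$D + 1e-12)
  }
})

test_that("recognition_score follows the piecewise formula", {
  p <- score_params(Dst = 90, Sst = 60)
  expect_equal(recognition_score(0, p), 100)
  expect_equal(recognition_score(45, p), 80)  # (90-45)/90*40 + 60
  expect_equal(recognition_score(120, p), 0)
  expect_equal(recognition_score(90, p), 0)   # boundary -> error branch
  expect_equal(recognition_score(90, score_params(90, 0)), 0)
  expect_error(recognition_score(-1, p), "non-negative")
})

test_that("recognition_score is monotone, bounded and scale-invariant", {
  set.seed(51)
  for (i in 1:30) {
    Dst <- runif(1, 10, 150)
    Sst <- runif(1, 0, 99)
    p <- score_params(Dst, Sst)
    D <- sort(runif(50, 0, 2 * Dst))
    S <- recognition_score(D, p)
    expect_true(all(diff(S) <= 1e-12))              # non-increasing
    pass <- S[D < Dst]
    expect_true(all(diff(pass) < 0))                # strictly decreasing
    expect_true(all(S == 0 | (S > Sst & S <= 100)))
    expect_true(all(S[D >= Dst] == 0))
    expect_equal(recognition_score(2 * D, score_params(2 * Dst, Sst)), S,
                 tolerance = 1e-12)
  }
  expect_equal(recognition_score(0, score_params(12, 37)), 100)
})

test_that("score_frame composes extraction, deviation and scoring", {
  set.seed(61)
  theta <- random_canonical_angles()
  theta[["left_knee"]] <- 150
  ref <- reference_pose("hold", theta, score_params(90, 60))
  exact <- score_frame(pose_from_angles(theta), ref)
  expect_equal(exact$S, 100)
  expect_equal(exact$deviation$D, 0, tolerance = 1e-9)

  # push one angle past Dst on its own
  theta2 <- theta
  theta2[["left_knee"]] <- theta[["left_knee"]] - 95  # 95 deg > Dst alone
  off <- score_frame(pose_from_angles(theta2), ref)
  expect_equal(off$S, 0)

  # compositional equality on a noisy frame
  f <- noisy_sequence(seed = 9)$frames[[10]]
  manual_obs <- extract_angle_vector(f)
  manual_D <- total_deviation(manual_obs, ref$angles[names(manual_obs)])$D
  got <- score_frame(f, ref)
  expect_equal(got$deviation$D, manual_D)
  expect_equal(got$S, recognition_score(manual_D, ref$params))
})

test_that("score_movement aggregates per-frame scores over the window", {
  theta <- neutral_angles()
  ref <- reference_pose("hold", theta, score_params(90, 60))
  clean <- static_pose_sequence(theta, duration = 1, fps = 30)
  ms <- score_movement(clean, ref)
  expect_equal(ms$aggregate, 100)
  expect_equal(ms$pass_fraction, 1)

  far <- theta
  far[c("left_elbow", "right_elbow")] <- far[c("left_elbow", "right_elbow")] - 60
  beyond <- static_pose_sequence(far, duration = 1, fps = 30)
  ms0 <- score_movement(beyond, ref)
  expect_equal(ms0$aggregate, 0)
  expect_equal(ms0$pass_fraction, 0)

  # half clean, half beyond threshold; mean aggregate = 50, pass 0.5
  both <- motion_sequence(c(clean$frames,
                            lapply(beyond$frames, function(f) {
                              f$time <- f$time + 1
                              f
                            })), fps = 30)
  half <- score_movement(both, ref, smooth = FALSE)
  expect_equal(half$aggregate, 50)
  expect_equal(half$pass_fraction, 0.5)
  med <- score_movement(both, ref, aggregate = "median", smooth = FALSE)
  expect_equal(med$aggregate, 50)

  expect_true(ms$aggregate >= min(ms$S_t) && ms$aggregate <= max(ms$S_t))
  expect_error(score_movement(motion_sequence(list(), 30), ref), "empty")
})

test_that("deviation recovery: an injected angular error is measured back", {
  seq <- generate_movement("high_knees", duration = 2, fps = 30,
                           noise = noise_spec(seed = 19))
  ref <- tracking_reference("high_knees")
  for (delta in c(10, 30, 60)) {
    injected <- inject_deviation(seq, "trunk_tilt", delta)
    ms <- score_movement(injected, ref)
    expect_equal(stats::median(ms$D_t), delta, tolerance = 2)
  }
})

test_that("reference poses load from JSON files", {
  p <- withr::local_tempfile(fileext = ".json")
  theta <- neutral_angles()
  jsonlite::write_json(list(movement = "hold", angles = as.list(theta),
                            Dst = 75, Sst = 50),
                       p, auto_unbox = TRUE, digits = NA)
  ref <- read_reference_pose(p)
  expect_identical(ref$movement, "hold")
  expect_equal(ref$params$Dst, 75)
  expect_equal(ref$params$Sst, 50)
  expect_equal(ref$angles[names(theta)], theta)
  expect_error(reference_pose("x", c(left_elbow = 190)), "180")
  expect_error(score_params(Dst = 0), "Dst")
  expect_error(score_params(Sst = 100), "Sst")
})
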