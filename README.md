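# exerscore

Camera-based exercise games ("exergames") guide a player through prescribed
movements, estimate their body pose from video, and score how closely each
posture matches a regulated reference. `exerscore` is the scoring and trial
analysis engine for such a system built around an ordinary monocular camera:
it consumes 3D keypoint streams (pose estimation itself is out of scope),
compares joint angles against regulated postures, runs the 10-minute
session/reward protocol, computes heart-rate training zones, and reproduces
the summary-statistics inference used to evaluate a three-arm trial of the
game in adults at high risk of type 2 diabetes. A seeded synthetic
skeleton-motion generator makes the whole pipeline testable without any
recorded data.

## The model

The skeleton is fixed at 10 landmarks (head, waist, left/right wrists,
elbows, knees, ankles), each with a 3D position per frame. Nine named joint
angles θ are extracted per frame (elbow and knee flexion, arm and leg
elevation, trunk tilt; see `default_angle_set()`), and compared against the
regulated angles θ′ of the reference posture by the deviation sum

    D = Σᵢ |θᵢ − θ′ᵢ|   (degrees)

which feeds the piecewise recognition score with threshold *Dst* and
baseline rate *Sst*:

    S = (Dst − D)/Dst · (100 − Sst) + Sst    for 0 ≤ D < Dst
    S = 0                                    for D ≥ Dst

A perfect match scores 100; scores fall linearly toward *Sst* as the
deviation approaches the threshold, and a pose at or beyond *Dst* is flagged
as an error (score 0). Landmark trajectories are smoothed (running median +
exponential moving average) before extraction. Sessions are 5 minutes of
aerobic work — six movements at 50 s each — plus 5 minutes of resistance
training (0.25–1.5 kg bands); per-movement points are `round(S)` and points
unlock in-game rewards. Exercise intensity targets 50–80% of
`HRmax = 208 − 0.7 · age`. The trial-statistics module performs one-way
ANOVA, pooled t tests, and rank tests from group `(n, mean, SD)` summaries,
with Cohen *f* effect sizes (cutpoints 0.1 / 0.40 / 0.80) and noncentral-F
power/sample-size calculation.

## Worked example

```r
library(exerscore)

# three seconds of synthetic high-knees with 4 degrees of angular jitter
seq <- generate_movement("high_knees", duration = 3, fps = 30,
                         noise = noise_spec(angular_sd = 4, seed = 7))
score_movement(seq, tracking_reference("high_knees"))
#> <movement_score> high_knees: mean S = 94.22 over 90 frames (pass 100%)

# a full aerobic block, scored window by window
plan <- build_session()
stream <- generate_session_stream(plan, noise_spec(angular_sd = 4, seed = 7))
res <- run_session(stream, plan, session_references(plan))
res
#> <session_result>
#>   toe_stretch                S =  94.04  points = 94
#>   high_knees                 S =  94.10  points = 94
#>   side_arm_raise             S =  94.25  points = 94
#>   punching                   S =  90.23  points = 90
#>   arm_stretch_hip_extension  S =  93.72  points = 94
#>   elbow_to_chest             S =  94.49  points = 94
#>   total points: 560

redeem(award_points(res, reward_ledger()), "background_music")
#> <reward_ledger> 260 points; unlocked: background_music

target_zone(47.12)
#> <heart_rate_zone> age 47.12: HRmax 175 bpm, target 87.51-140 bpm (50-80%)

# trial inference from printed group summaries (n, mean, SD per arm)
anova_from_summary(trial_groups(trial_outcome_summary(), "inner_motivation"))
#> One-way ANOVA from summaries: F(2, 42) = 33.13, p = 2.315e-09
#>   eta^2 = 0.612, Cohen f = 1.256 (large)

sample_size_anova(f = 0.48, k = 3, alpha = 0.05, power = 0.80)
#> [1] 45
```

The scores read as: with 4° of per-angle jitter spread over 9 angles the
typical frame deviates ~29° in total, well inside the default threshold
(*Dst* = 90°), so every frame passes and the linear band maps the residual
deviation to scores in the mid-90s. The ANOVA line recomputes the trial's
intrinsic-motivation contrast from its published per-arm summaries; the
sample-size line recovers the trial's 45-participant design from its stated
effect size, power, and alpha.

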