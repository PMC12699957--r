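---
title: "Methods: pose-comparison scoring, session protocol, and trial statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pose-comparison scoring, session protocol, and trial statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exerscore)
```

## The scoring model

The engine consumes a stream of skeleton observations: ten named landmarks
(head, waist, and the left/right wrists, elbows, knees, ankles), each a 3D
position in meters, at a nominal frame rate around 30 fps. How those
positions were obtained — which pose estimator, which camera — is outside
the model; the skeleton is taken at face value, and a frame missing any
landmark is rejected rather than imputed, because every downstream angle is
defined on the full set.

Posture is compared in joint-angle space. An angle vector
$\theta = (\theta_1,\dots,\theta_9)$ is extracted per frame and compared
against the regulated vector $\theta'$ of the reference posture through the
deviation sum

$$D = \sum_i |\theta_i - \theta'_i| \quad \text{(degrees)},$$

which is mapped to the recognition score by the piecewise function

$$S(D) = \begin{cases}
\dfrac{D_{st}-D}{D_{st}}\,(100 - S_{st}) + S_{st}, & 0 \le D < D_{st},\\[4pt]
0, & D \ge D_{st}.
\end{cases}$$

$D_{st}$ (the recognition threshold, degrees) is the total deviation at
which a pose stops being a recognizable attempt and is flagged as an error;
$S_{st}$ (the baseline recognition rate) is the score floor of the passing
band, so a recognized pose always scores in $(S_{st}, 100]$ and a perfect
match scores exactly 100.

Two conventions here deserve emphasis because the underlying formula leaves
them open:

* **Absolute deviations.** A signed sum $\sum_i (\theta_i - \theta'_i)$
  lets a $+40°$ error on one joint cancel a $-40°$ error on another,
  producing $D = 0$ for a badly wrong pose — which contradicts the whole
  point of flagging significant deviations as errors. The engine therefore
  sums absolute deviations by default; the signed variant remains available
  (`total_deviation(..., signed = TRUE)`) for comparison experiments.
* **The boundary $D = D_{st}$.** The two branches ($D < D_{st}$ passing,
  $D > D_{st}$ error) leave the boundary itself undefined. It is assigned to
  the error branch: the passing band is half-open, so a passing score never
  sits at its discontinuous edge and $S = S_{st}$ is never attained.

Defaults are $D_{st} = 90°$ and $S_{st} = 60$. These are engine
conventions, not measured constants: $90°$ total across nine angles means
an average per-angle error of $10°$ ends the passing band, which matches
the granularity at which a human coach would call a pose wrong; $60$ keeps
the passing band's floor well above zero so that recognized-but-sloppy
attempts remain visibly distinct from failures. Both are exposed in
`score_params()` and in every file format and CLI flag that carries them.

## The canonical angle set

The skeleton has no shoulder or hip landmarks, so classical shoulder/hip
angles are not measurable. The default set (`default_angle_set()`) is the
maximal natural set computable from the ten landmarks:

| angle | definition | kind |
|---|---|---|
| left/right elbow | wrist–elbow–waist | three-point |
| left/right knee | ankle–knee–waist | three-point |
| left/right arm elevation | elbow–waist–head | three-point |
| left/right leg elevation | knee–waist–head | three-point |
| trunk tilt | waist→head vs. world y-axis | axis-referenced |

Three-point angles are invariant under any rigid motion of the subject, so
camera placement and facing direction do not matter for them. Trunk tilt is
referenced to the world vertical and is therefore translation- but not
rotation-invariant about non-vertical axes; this is intentional (leaning is
defined against gravity) and documented. The set is a convention, not a
biomechanical claim — any list of `angle_definition()`s can replace it, and
angle sets load from JSON/YAML config files.

Coordinates are right-handed, y-up, in meters, subject nominally facing +z.
Because only the axis-referenced angle sees the world frame, the convention
is almost entirely cosmetic, but it is fixed so that serialized streams are
interchangeable.

## Temporal smoothing

Keypoint streams from monocular estimators jitter and occasionally spike.
The default pipeline applied before scoring is a running median (window 3)
followed by an exponential moving average with $\alpha = 0.3$:

* the median stage removes isolated single-frame spikes exactly (a window-3
  median passes any monotone trace through unchanged and annihilates
  singleton outliers), shrinking its window symmetrically at the edges so
  the first and last frames pass through;
* the EMA stage ($y_t = \alpha x_t + (1-\alpha) y_{t-1}$, $y_1 = x_1$)
  attenuates high-frequency jitter at the cost of a group delay of roughly
  $(1-\alpha)/\alpha \approx 2.3$ frames — about 78 ms at 30 fps, short
  relative to movements with periods of 1–4 s.

The filter family and constants are engine choices; only the smoothing
contract (spike rejection and jitter attenuation, identity on constants,
commuting with translation) is load-bearing, and all constants are
arguments of `smooth_sequence()`.

## Static versus tracking references

A reference pose may be a single regulated angle vector (a held posture) or
a *tracking reference* that follows the on-screen demonstration. Inside
`run_session()` each 50 s window is scored against its movement's template
evaluated at the window-relative frame times and passed through the *same*
smoothing pipeline as the observed stream. Smoothing both sides identically
is what makes "zero deviation" exact: a noiseless performance produces
literally the reference trajectory, smoothing lag and all, so $D = 0$ in
every frame and the window scores 100. Scoring a moving performance against
a single static vector would instead conflate the movement itself with
error.

## Session protocol, points and rewards

A session is 10 minutes: a 300 s aerobic block of six movements (toe
stretches, high knees, side arm raises, punching, arm stretch with hip
extension, elbow-to-chest expansion) at 50 s each, then a 300 s resistance
block with a band level from {0.25, 0.5, …, 1.5} kg. The aerobic windows
tile the block exactly — half-open intervals, no gaps or overlaps — and
each window is scored only from its own frames. The resistance block is
scheduled but not pose-scored: band exercises happen under supervision,
outside the camera loop.

Points per movement are `round(aggregate S)` (half away from zero), so a
perfect session earns 600. The aggregate is the mean of per-frame scores by
default (median available); the points rule and the reward catalog
(background music 300, avatar customization 600, virtual environment 900)
are deliberately simple conventions — any monotone rule would do — and are
pluggable. The ledger maintains the invariant *points = awarded − spent*,
never negative, each item unlocked at most once.

## Heart-rate physiology

Exercise intensity is anchored to the age-predicted maximum heart rate
$\mathrm{HR}_{max} = 208 - 0.7 \cdot \mathrm{age}$ (bpm), with the target
zone at 50–80% of it — appropriate for middle-aged adults at elevated
metabolic risk. Zone boundaries are inclusive (a heart rate exactly at a
bound is in-zone); ages outside [35, 80] warn, outside [18, 100] error.
Perceived exertion uses the Borg 6–20 scale, validated as a plain integer
range. Post-exercise heart-rate sampling windows are a data-collection
convention on the input, not something the engine simulates.

## The synthetic motion generator

The generator exists so every scoring and session path is testable without
recorded data. Each movement is a stylized keyframe loop in angle space
(piecewise-linear, periodic, periods 1.2–4 s) staying comfortably inside
$[0°, 180°]$; a skeleton with fixed segment lengths (waist→head 0.60 m,
waist→elbow 0.35 m, elbow→wrist 0.30 m, waist→knee 0.45 m, knee→ankle
0.45 m — roughly a 1.7 m adult) realizes the angles by forward placement
from the waist. The placement is constructed so that extraction is the
exact inverse: the head direction encodes trunk tilt, each proximal limb
segment is placed at its elevation angle from the head direction within a
fixed lateral half-plane, each distal segment at its flexion angle from the
ray back to the waist. Noiseless generation therefore reproduces the
template to floating-point precision, which turns scoring tests into exact
identities rather than tolerance games.

Noise is applied in angle space — Gaussian jitter per angle per frame
(degrees), plus optional Gaussian jitter on the template sampling time
(seconds) — then clamped to $[0°, 180°]$ and realized geometrically. A
single RNG stream per call, seeded explicitly in `noise_spec()`, gives
byte-identical streams per seed while leaving the caller's RNG state
untouched.

`inject_deviation()` perturbs exactly one named angle by rotating the
affected landmark(s) rigidly in the plane of the current angle: a wrist for
an elbow angle, a whole forearm about the waist for arm elevation, the
whole skeleton about the waist for trunk tilt. Because each rotation is
rigid about the relevant vertex, the other eight canonical angles are
exactly preserved — the injected deviation is pure, making
deviation-recovery tests sharp.

What the generator deliberately does **not** emulate: bone-length
variation, balance and ground contact, occlusion and depth ambiguity of
monocular estimation, estimator-specific noise spectra (which are neither
Gaussian nor white), or multi-person scenes. Passing tests therefore
demonstrate the correctness of the scoring pipeline's mathematics on
well-formed skeleton streams, not the field robustness of any particular
pose estimator.

## Trial statistics from group summaries

The trial that motivates the stats module reported only group-level
summaries — mean (SD) per arm, n = 15 each — so the module works from
`(n, mean, sd)` triplets directly:

* `anova_from_summary()`: $SS_B = \sum n_i(\bar x_i - \bar x)^2$ about the
  n-weighted grand mean, $SS_W = \sum (n_i - 1) s_i^2$, the usual F ratio,
  $\eta^2 = SS_B/(SS_B + SS_W)$ and Cohen $f = \sqrt{\eta^2/(1-\eta^2)}$.
  This is algebraically identical to a raw-data ANOVA on any samples
  matching the summaries, which is exactly how it is tested (affine
  rescaling of random draws to hit each mean and SD, then `stats::aov`).
* `t_from_summary()`: pooled-variance t by default — matching a plain
  "independent-samples t test" with no stated correction — with Welch
  available by option. Zero pooled variance with equal means defines
  $t = 0$; with unequal means it is an error rather than an infinity.
* `kruskal_wallis()` delegates to `stats::kruskal.test` (tie-corrected H,
  chi-square upper tail at all sample sizes — the documented large-sample
  policy), with the all-values-equal degenerate case defined as $H = 0$.
* `mann_whitney()`: $U$ counts pairs $a > b$ plus half the ties. For pooled
  sizes $\le 12$ the two-sided p is exact by enumerating all
  $\binom{n_1+n_2}{n_1}$ labelings of the pooled data — valid under ties,
  which the usual exact algorithms refuse — and for larger samples the
  tie-corrected normal approximation without continuity correction. The
  switch is purely size-based.
* `sample_size_anova()`: smallest total N divisible by k whose
  noncentral-F power ($\lambda = f^2 N$, $df = (k-1, N-k)$) meets the
  target. For the design parameters $f = 0.48$, $k = 3$, $\alpha = .05$,
  power $0.80$ this search returns N = 45 — the acceptance suite
  cross-checks the noncentral-F computation against a 50,000-replicate
  Monte-Carlo simulation of the design at N and N − 3.
* Cohen f classification uses left-closed bands at 0.1 / 0.40 / 0.80
  (negligible/small/medium/large). Note an f of 0.265 classifies as
  *small* under these cutpoints even though verbal labels elsewhere
  sometimes call that range moderate; the printed cutpoints win.

Within-group pre/post comparisons are out of scope by design: a paired t
test from summaries requires the pre/post correlation, which summary tables
do not carry. The bundled `trial_*_summary()` tables expose the trial's
printed group summaries as plain data frames for the worked examples; some
of the trial's own printed test statistics are not algebraically consistent
with its printed summaries, so the package asserts equality only against
its own raw-data oracles, never against printed F or t values.

## Numerical choices and degenerate inputs

* `joint_angle` clamps the normalized dot product to $[-1, 1]$ before
  `acos`, so collinear rays never produce NaN; rays shorter than $10^{-9}$ m
  are a degeneracy error, named after the offending angle.
* Serialization is canonical — fixed key order, fixed 6-decimal precision —
  so write/read round-trips are byte-stable and test comparisons are exact
  at serialization precision.
* Frame rate is stored explicitly and cross-checked against median frame
  spacing (warning beyond 5% discrepancy); on read it is inferred from the
  timestamps.
* Empty sequences error in filters and scorers; a sequence shorter than the
  aerobic block is a coverage error in `run_session`.
* Injection deltas that would push an angle outside $[0°, 180°]$ in any
  frame are an error, not a clamp, so recovery tests measure exactly what
  was injected.

## Problem sizes in the test suite

The suite exercises full-scale objects where the contract demands it (a
300 s, 30 fps session stream is 9,000 frames; the jitter-moment check uses
10,000 frames; the summary-vs-raw ANOVA oracle runs 200 random designs; the
power cross-check runs 50,000 Monte-Carlo replicates) and short 1–5 s
clips everywhere a property is local to a few frames. These sizes were
chosen as the smallest that make each statistical check sharp.

## Known limitations

* Elevation and flexion angles use the waist as the proximal reference in
  lieu of shoulder/hip landmarks; they are correlated with, but not equal
  to, anatomical joint angles.
* The recognition score weights all angles equally; no per-joint weighting
  is provided because the underlying formula has none.
* The deviation sum grows with the number of angles in the active set, so
  $D_{st}$ must be recalibrated if the angle set changes.
* Rank-test p-values use the chi-square / normal approximations outside the
  exact-enumeration regime; for very small heavily-tied samples beyond
  pooled size 12 they are approximate.
* The synthetic generator's noise model is Gaussian in angle space;
  real monocular-estimator error is structured (depth-dominant,
  occlusion-correlated) and will degrade scores differently.
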