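---
title: "Quantifying ciliate locomotion: endpoints, models, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ciliate locomotion: endpoints, models, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliotrack)
library(dplyr)
```

## The measurement problem

Free-swimming ciliates such as *Tetrahymena* are attractive sentinels for
behavioural toxicology: locomotion responds to stressors within minutes, at
doses well below those affecting growth or survival, and a single short video
of a depression slide captures hundreds of cells at once. Machine-vision
trackers turn such a video into one coordinate file per cell: the centroid
position, in pixels, at every frame where the cell was resolved. ciliotrack
takes over from there. It consolidates the per-cell exports, screens out
broken tracks, reduces each trajectory to six locomotor endpoints, and runs
the downstream statistics a screening assay needs: rank-based group
comparisons, dose–response EC50 estimation, and multivariate summaries of
treatment profiles.

Everything operates on tidy tables: trajectories are long tibbles (one row
per cell per frame), endpoints are one row per cell, statistics are one row
per comparison, so the whole pipeline composes with dplyr verbs and the
pipe.

## From coordinates to endpoints

A trajectory is a sequence of valid positions $(x_t, y_t)$ in micrometres at
frame times $t$ (pixels times the `um_per_px` calibration). Consecutive valid
positions define steps with length
$\ell_t = \lVert (x_{t+1}, y_{t+1}) - (x_t, y_t) \rVert$, instantaneous speed
$v_t = \ell_t \cdot \mathrm{fps} / \Delta t$ (with $\Delta t$ the frames
spanned, so a step across a short tracker dropout is not inflated), heading
$\theta_t = \operatorname{atan2}(\Delta y, \Delta x)$, and signed turning
angle $\tau_t = \operatorname{wrap}(\theta_{t+1} - \theta_t) \in
(-180^\circ, 180^\circ]$. The six endpoints are:

| endpoint | definition | units |
|---|---|---|
| total distance | $\sum_t \ell_t$ | mm |
| average speed | total distance / observed time | mm/s |
| burst count | #\{valid steps with $v_t >$ Q3 of reference speeds\} | count |
| angular velocity | $\mathrm{mean}_t \lvert \tau_t \rvert \cdot \mathrm{fps}$ | deg/s |
| meandering | $\sum_t \lvert \tau_t \rvert \,/\, \sum_t \ell_t$ | deg/um |
| rotation count | half-turn excursions of $\sum \tau_t$, by sign | count |

Observed time is the time the cell was actually tracked (frames spanned by
valid steps over fps), not the nominal video length, so a cell visible for
half the recording is not scored as half as fast.

Several small rules make these definitions total and reproducible:

* **Zero-length steps** inherit the previous heading and contribute a turn of
  zero, so a stationary cell has zero angular velocity rather than an
  undefined arctangent. A cell that never moves has zero distance and an
  *undefined* meandering (flagged, excluded from meandering summaries —
  never silently zero).
* **Rotation counting** accumulates signed turns and tallies one clockwise or
  counter-clockwise rotation each time the running sum reaches a half turn
  ($\pm 180^\circ$), keeping the overshoot. The trigger carries a
  $10^{-9}$-degree tolerance: turning angles recovered from coordinates via
  `atan2` differ from nominal values at rounding level, and a swimmer turning
  an exact multiple of $180^\circ$ must not lose its final excursion to that
  rounding. The accumulator restarts after every track gap.
* **Quartiles** everywhere (burst threshold, summary IQRs) use linear
  interpolation between order statistics (`stats::quantile` type 7), stated
  once and reused, so Q3 of $\{1,2,3,4\}$ is 3.25.
* **Burst pooling**: the "upper quartile of velocity" needs a reference
  population. The default pools all valid step speeds of the control set of
  the recording, so burst counts are comparable across treatments scored
  against the same threshold; a per-cell policy is available
  (`burst_policy = "per-cell"`), and an explicit threshold in um/s overrides
  both. This is exposed as a policy precisely because the verbal definition
  admits both readings.

## Track quality control

Identity loss is a fact of life for machine-vision tracking — cells collide,
leave the field, or swap labels; error rates in the low tens of percent are
typical for this kind of assay. `filter_tracks()` drops tracks with
valid-frame coverage below `min_coverage` (default 0.85) or fewer than
`min_frames` valid frames (default 30, one second at 30 fps), and returns an
accounting of every dropped cell. Within kept tracks, gaps up to
`max_gap_frames` (default 5 frames, 1/6 s) are bridged with time-correct
speeds; longer gaps split the track into segments whose endpoints are
aggregated (distances and counts summed, rates time-weighted), and no turning
angle is ever computed across a segment break. The I/O layer never
interpolates a missing position; gap policy belongs to kinematics where it
can be tested.

## The swimmer simulator

The simulator supplies ground truth the field cannot: every downstream
module is validated on trajectories whose endpoints are known by
construction. Three models share a heading-persistent stepping scheme
(per frame: heading plus deterministic turn plus Gaussian wobble; step
length equals the per-frame speed draw over fps):

* **straight** — constant heading, closed forms for every endpoint;
* **circular** — constant signed turn per frame, so angular velocity is
  exactly `turn_per_frame * fps` and rotation counts follow from the
  accumulated angle;
* **run_and_tumble** — heading wobble plus Bernoulli tumbles (wrapped-normal
  reorientation) and a Bernoulli burst speed mode, the statistical skeleton
  of ciliate swimming.

The default cohort conditions mirror the assay this package is built for:
10 s recordings at 30 fps (300 frames), 158 cells per group, and a wild-type
preset targeting an overall mean speed of 0.18 mm/s — with a 25% burst
fraction at twice base speed, the base speed is deflated accordingly — with
15% per-frame speed noise, 8°/frame heading wobble, and a 5%/frame tumble
probability. Simulated fixtures are written with a 1.62 um/px calibration, a
representative value for a 4x objective on a 4K sensor; real analyses must
supply their own measured calibration, which is why `recording_meta()` has
no default for it. Tumble angles are wrapped-normal by choice of convenience,
not biological fitting: only the mixture structure matters for testing.

What the simulator does *not* emulate: hydrodynamic wall effects, cell–cell
collisions, directional bias (chemotaxis), tracker mislabeling that stitches
two cells into one path, and body-posture features. Passing tests therefore
demonstrate that the *computations* are correct on data with known structure,
not that any biological effect size will reproduce.

Per-cell seeds are derived deterministically from the master seed and cell
index, so cohorts are bit-reproducible and insensitive to generation order.

## Statistics

Endpoint distributions are skewed, so group comparisons are rank-based
throughout, mirroring standard practice for this assay: Mann–Whitney for two
groups (exact permutation p when the pooled sample is at most 12 without
ties, otherwise normal approximation with tie and continuity corrections),
Kruskal–Wallis for dose series with Dunn's rank-based z tests of each
treatment against the control, Holm-adjusted. Control-referenced contrasts
(rather than all pairs) match how dose series are reported; the adjustment
method is a parameter. Summaries are medians with interquartile ranges, and
p values map to the conventional strict-threshold star codes
(0.05/0.01/0.001/0.0001).

## Dose–response

The EC50 stage fits the log-inhibitor vs normalized-response model
$Y = 100 / (1 + 10^{(x - \log_{10}\mathrm{EC50}) \cdot s})$ on
$x = \log_{10}$ concentration, slope fixed at $s = 1$ by default (the
"standard" named model; `slope_mode = "variable"` frees it). Responses are
per-cell endpoint values as percent of the control central value (mean by
default); zero-dose controls define 100% but contribute no finite $x$ and
are excluded from the fit. Per-cell fitting weights every cell equally;
aggregate to per-concentration means first if that is the design you want.

The 95% CI on logEC50 is t-based. Its standard error defaults to a
heteroscedasticity-consistent sandwich estimator rather than the classical
OLS formula: percent-of-control responses from individual cells have
variance that grows with the response level (cell-to-cell variability is
essentially multiplicative), and in Monte-Carlo checks the sandwich SE
tracks the empirical sampling SD closely while the classical SE
overestimates it by ~30% under 20% multiplicative noise. `ci_method =
"classical"` restores the textbook formula. A fit is flagged unidentifiable
when the estimated logEC50 falls outside the tested concentration range or
the CI spans it — the "all responses near 100%" failure mode — instead of
returning a confident extrapolation.

## Multivariate structure

For profile-level comparisons the package builds the endpoints × groups
matrix of group means, unit-variance scales each row (each endpoint has mean
0, sd 1 across groups — six quantities in incomparable units would otherwise
be dominated by whichever has the largest numbers), and then:

* **PCA** by singular value decomposition of the scaled matrix: groups get
  scores, endpoints get loadings, explained variance comes from squared
  singular values (summing to 100% over the non-null components — row
  centering leaves at most `n_groups - 1` of them). Component signs are
  canonicalised (largest-magnitude loading positive) so score plots do not
  flip between runs.
* **Hierarchical clustering** of both rows and columns with Pearson
  correlation distance ($1 - r$: 0 identical shape, 2 exact
  anti-correlation) and unweighted average linkage (UPGMA), which guarantees
  monotone merge heights. Cutting the column tree (`cut_cluster(x, k)`)
  partitions treatments into behaviour regimes.

On synthetic cohorts programmed with three regimes — normal,
slowed-but-straight, slow-and-tortuous — the k = 3 cut recovers the
programmed partition exactly (adjusted Rand index 1), the structural
behaviour this stage exists to detect.

## Numerical and validation choices

The test suite validates every endpoint against a brute-force oracle: an
independent frame-by-frame transcription of the endpoint definitions, run on
1,000 randomly generated short trajectories with dropouts and stationary
stretches, with agreement required to 1e-9 relative (exact for counts).
Geometric invariances are exercised as properties: translations and
rotations change nothing, reflection swaps the two rotation senses,
calibration scaling multiplies metric endpoints and divides meandering.
Statistical calibration uses 1,000 null pairs (n = 50 each) drawn as
disjoint random splits from a pool of 2,000 simulated wild-type cells —
exchangeable splits make the null hold exactly at a fraction of the cost of
fresh cohorts per replicate — requiring a rejection rate within [0.03, 0.07]
at $\alpha = 0.05$. EC50 recovery is checked exactly on noise-free responses
at the assay's five working concentrations (0.5–5000 uM) and under mean-one
lognormal multiplicative noise (20% CV, 129 cells per concentration,
200 replicates; mean-one because plain lognormal noise inflates the fixed
100% plateau and biases logEC50 by construction). Problem sizes throughout
(cells per cohort, frames per track, replicate counts) are chosen so the
full validation runs in about a minute on one core while keeping every check
statistically meaningful.

## Limitations

* Endpoints are centroid-based; body orientation, ciliary beat and posture
  are out of scope.
* The burst and rotation definitions are operationalizations of verbal
  definitions; both are policy-configurable and documented rather than
  presented as the single truth.
* Angular velocity is averaged per step and scaled by fps; for tracks that
  are mostly gaps this rate is dominated by the surviving segments.
* The EC50 CI is asymptotic (t-based on one parameter); for designs with few
  concentrations and strong curvature a profile or bootstrap interval would
  be more faithful, and is not implemented.
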