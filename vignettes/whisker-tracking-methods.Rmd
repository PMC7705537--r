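---
title: "Tracking individual whiskers: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking individual whiskers: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(whisktrace)
```

Mice sweep their facial whiskers back and forth at 5--30 Hz. Following every
individual whisker of an untrimmed animal through a high-speed video is hard:
whiskers are thin (a few pixels), fast, visually identical, and they cross
and occlude each other. `whisktrace` decomposes the problem into pixel-level
detection, per-frame abstraction into a four-parameter whisker description,
and temporal tracking with appearance-based recognition. This vignette
explains each model, the tunable parameters, and the choices made where the
design was genuinely open.

## Imaging model and preprocessing

The expected input is backlit high-speed video: whiskers dark against a
bright, static background, with a dark snout silhouette and fur at the snout
edge. The background is estimated as the per-pixel **maximum** over frames
sampled evenly across the video (default `background$n_samples = 20`);
anything that moves reveals the backlight in some sample, so moving
structures vanish from the model while static ones remain. Subtracting the
frame from this background (clamped to `[0, 1]`) leaves whiskers as bright
curvilinear ridges on a near-zero background. Residual blobby content --
snout edge and fur -- is removed by binarizing (Otsu by default), deleting
thin structures with a morphological opening (disc radius
`silhouette$open_radius = 2` px, chosen to be wider than a whisker cross
section but smaller than fur tufts), and padding the remaining blob with a
dilation (radius `silhouette$dilate_radius = 3` px). The operator radii are
package choices; only the operator sequence is canonical. Intensities are
processed as floating point throughout and clamped on write-out. Polarity is
fixed (dark whiskers on bright backlight); a `source$invert` flag flips the
input first when needed.

## Sub-pixel centerline detection

A whisker is far longer than it is wide, so its image abstraction is its
centerline. The cleaned image is treated as a height map and ridge crests
are found by second-order analysis: five Gaussian partial derivatives
($r_x, r_y, r_{xx}, r_{xy}, r_{yy}$) are computed by separable convolution
at scale `centerline$sigma` (default 1.5 px; the scale should satisfy
$\sigma \ge w/\sqrt 3$ for a ridge of profile sd $w$). At each pixel, the
eigenvector of the most negative Hessian eigenvalue gives the ridge normal;
the zero of the first directional derivative of the local second-order
Taylor model along that normal gives the sub-pixel crest position. A point
is accepted only when that zero lies within the pixel (normal offset at most
0.5 px) and the eigenvalue magnitude ("ridge strength") reaches a threshold.
Each pixel is processed independently, so the result is order-independent by
construction. The discrete derivative kernels are normalized so constant,
linear and quadratic inputs give exact responses, which is what makes the
localization exact on noiseless straight ridges.

The strength threshold default is calibrated on the first frame as 0.4 times
the 99.5th percentile of positive strengths. Whisker crests form a narrow
band at the top of the strength distribution, so a *fraction of a high
quantile* lands reliably below the band and above fur/noise. A plain high
quantile -- the obvious alternative -- fails whenever whiskers dominate the
nonzero pixels, because after background subtraction the background is
mostly exactly zero and the quantile lands *inside* the whisker band,
deleting whisker segments. Both alternatives (`"otsu"`, `"quantile"`) remain
available via `centerline$threshold_method`.

## Clustering centerline points into whiskers

Two initial clustering algorithms are provided, selectable per run
(`cluster$method`), because their failure modes are complementary:

* **`dbscan`** -- density-based clustering on the sub-pixel positions
  (`dbscan_eps = 2.5` px, `dbscan_min_pts = 3`). Robust to rough or
  interrupted centerlines, but merges whiskers where they cross.
* **`steger`** -- each point proposes at most one neighbor forward and one
  backward along its local tangent, searching the 8-neighborhood plus the
  ring one pixel further (so one missing point cannot break a chain), within
  a 45 degree angular tolerance; links require mutual proposal. Directions
  separate crossing whiskers, but the method needs smooth, well-detected
  centerlines. Because every point carries at most two mutual links, each
  component is a path; components are ordered by walking that path, and the
  path is cut wherever its windowed direction turns by more than 60 degrees
  over +-4 points. The cut guards against a failure mode of shallow
  crossings: where two whiskers approach within a pixel or two, a mutual
  link can bridge them, producing a path that runs up one whisker and folds
  back down the other -- a turn no real whisker (a few milliradians of
  curvature per pixel) can make.

Fragments of one whisker are then **stitched**: for each cluster at least
`stitch_fit_len = 20` px long, a total-least-squares line through its tip
section is extended tip-ward; candidate clusters must have their base point
within `stitch_max_dist = 3` px of that line, within `stitch_max_gap = 30`
px along it, *and* have their own basal direction within
`stitch_max_angle = 30` degrees of the line. Among passing candidates, the
merge partner minimizes the combined normalized deviation (perpendicular
distance, angular deviation and gap, each scaled by its gate; ties by
lowest index), and the scan repeats to a fixpoint (merges strictly reduce
the cluster count, so termination is guaranteed). The angular gate and the
combined score are package additions: at an X-crossing the two
post-junction fragments' bases can sit sub-pixel apart, so base-point
distance alone cannot choose the true continuation, while the angular
deviation can.

Whiskers that overlap near the snout and diverge distally leave the lower
whisker's cluster floating in mid-air; its basal direction is extrapolated
toward the snout and, when a snout-connected cluster lies along that line,
the donor's base segment -- from the junction down to the snout -- is
*copied* (and flagged) so both whiskers reach the snout. Three gates keep
this from fabricating whiskers: the floating cluster must itself be
whisker-sized (at least `min_whisker_len`; copying a base onto a short fur
chain would duplicate a whisker), the junction must lie within
`stitch_max_gap` of the floating base (a donor approached only far away is
not a shared base), and the donor's local direction at the junction must
agree with the extrapolated line within `stitch_max_angle` (a shared base
means near-parallel curves; an X-crossing has divergent ones and is
excluded). Finally clusters shorter than `min_whisker_len = 40` px are discarded
as fur, and a cluster is "snout-connected" when its base is within
`snout_attach_dist = 10` px of the snout line. All defaults were chosen for
480 x 512 px recordings and are exposed in the configuration.

## The four-parameter whisker description

Relative to a user-supplied snout line (two endpoints in the configuration;
automatic estimation is out of scope), a whisker in one frame is the tuple
$(\rho, \theta, b, L)$: base position along the line, base angle, bending
coefficient of the quadratic deviation model $d = b x^2$, and straight
base-to-tip length. $x$ is measured along the whisker's **chord** from the
snout line (not arclength) -- the two readings are equivalent for the sketch
that motivates the model, and the chord admits closed-form evaluation. $L$
is definitional (the cluster's base-to-tip distance) and is not fitted. The
remaining parameters are fit by Levenberg-Marquardt least squares on the
residual $d_i - b x_i^2$ at matched chord coordinate -- an approximation of
perpendicular point-to-curve distance that avoids nested projection solves
-- initialized from a straight-line fit of the basal section ($\theta_0$,
snout intercept $\rho_0$, $b_0 = 0$), with at most `fit$max_iter = 100`
iterations and relative tolerance `fit$tol = 1e-8`. Fits whose RMS residual
exceeds `fit$max_rms = 1` px are rejected as garbage (typically a cluster
that merged two crossing whiskers). Angles are radians internally; degree
values in the configuration are converted on load.

## Tracking, recognition and the experts

Identities are fixed at frame 1 (one per detected whisker, numbered by base
position; whiskers appearing later are not given new identities). Tracking
combines three cooperating parts:

1. **Kalman tracker.** Per identity, a linear filter over
   $(\rho, \theta, \dot\rho, \dot\theta, b, L)$: constant velocity on
   position/angle, random walk on bending and length. The noise scales
   (`process_noise`, `measurement_noise`) were tuned once on synthetic data
   and are configuration-exposed; the state/noise model itself is a package
   choice. Matching predictions to detections is an optimal (Hungarian-type)
   assignment on the normalized parameter distance over
   $(\rho, \cot\theta, b, L)$, each scaled by its running standard deviation
   over the training window; pairs costlier than `assign_max_cost = 3` are
   rejected. Optimal rather than greedy assignment costs nothing at
   $N \le 15$ and avoids order artifacts.
2. **Recognizer.** After a bootstrap period (`bootstrap_len = 50` frames of
   pure Kalman tracking that seeds the training set -- best while whisking
   is slow), a one-vs-one ensemble of $N(N-1)/2$ linear soft-margin SVMs
   (cost 1.0; six nearly linearly separable features make a linear kernel
   sufficient) classifies each detection: features are $L$, $b$, $\rho$,
   $\cot\theta$, and the offsets of $\rho$ and $\cot\theta$ from the
   *previous* frame's means (the current frame's means are unknown until
   all whiskers are identified). $\cot\theta$ appears because rotation
   about a fixed pivot behind the snout makes $\rho = L_f \cot\theta +
   \rho_f$ exactly -- whiskers are lines in $(\cot\theta, \rho)$ space, and
   `estimate_pivot()` recovers $(L_f, \rho_f)$ by ordinary least squares.
   The ensemble is retrained every `s = 25` frames on the window of
   accepted detections from the last `W = 2000` frames, standardized to
   mean 0 / sd 1; each retrain caps the design matrix at the most recent
   `max_train_per_class = 200` samples per identity so a retrain stays
   cheap regardless of window length. Whether raw $\theta$ should be a
   seventh feature was an open question; the six-feature form was chosen
   because $\cot\theta$ already carries the angle.
3. **Experts.** Per post-bootstrap frame, in this order: the classifier
   runs first; the **N-expert** then rejects any classified detection whose
   $|\Delta\theta| > 10^\circ$ or $|\Delta\rho| > 15$ px against the same
   identity's accepted parameters in the immediately preceding frame
   (strict inequality; such jumps within 1 ms are physically impossible).
   Rejected detections are barred from the output and the training window
   for that identity but return to the orphan pool, since the underlying
   detection may belong to another whisker. The tracker then acts as
   **P-expert**: lost identities' Kalman predictions are matched against
   the remaining orphans under the same cost rule, and recovered matches
   re-enter output and training. An identity found by neither keeps its
   Kalman estimate, flagged `estimated` and excluded from the valid output;
   lost tracks coast for at most `max_coast = 100` frames, then freeze
   (their prediction variance would otherwise diverge). The N-expert check
   deliberately applies only to consecutive-frame pairs: a whisker
   reappearing after a 20-frame occlusion could never satisfy a per-frame
   jump bound against its pre-occlusion angle, and recovery after occlusion
   is precisely the behavior the recognizer exists to provide. After a gap
   longer than 3 frames the Kalman state is re-initialized from the new
   measurement rather than updated, since the coasted velocity estimate is
   stale.

## Evaluation metrics

Four metrics score any trace table (this pipeline's or an external
tracker's, via the documented CSV schema): whiskers per frame; per-identity
detection ratio (percent of frames with a valid entry); the signal-to-noise
ratio of each angle trace; and, when ground truth exists, identity
consistency. SNR separates whisking (below ~30 Hz) from tracker noise by
Savitzky-Golay smoothing (quadratic). The canonical window of 10 frames is
even, which a symmetric Savitzky-Golay filter cannot use, so the package
uses the centered 11-frame window -- the documented deviation of at most one
sample. Signal power is taken on the mean-removed smoothed trace and noise
power on the residual; mean removal makes the metric exactly invariant to
constant angle offsets, which is also what a sinusoid-plus-noise power
ratio oracle expects. A local polynomial fit also absorbs part of any white
noise into the smooth (about `sum(w^2)` of the noise variance, with `w` the
filter's center row) while the residual under-reports it; both powers are
corrected with these known white-noise gains, so the reported ratio matches
the true component powers to within about 0.1 dB from 15 to 60 dB instead
of being biased upward by more than 1 dB at the noisy end. Missing frames
split a trace into segments; segments shorter than the window are
excluded. Identity consistency maps each
accepted entry to the nearest ground-truth whisker in normalized parameter
space; a switch is a change of that mapping between an identity's
consecutive frames, and consistency is the fraction of frames carrying the
identity's modal mapping.

## The synthetic scene generator

Real reference recordings are not redistributable, so the package ships a
seeded generator that emulates the imaging model the tracker assumes: a
bright static background with mild texture, a dark snout with short
low-contrast fur fragments that jitter by ~0.4 px per frame (static fur
would be absorbed into the background model; the jitter is what lets fur
exercise the length filter), and $N$ whiskers rendered as dark ridges with
an analytic Gaussian cross-section (the `width` parameter is the profile's
FWHM), evaluated from exact curve distances so the sub-pixel ground truth
is exact rather than rasterized. Each whisker rotates about a fixed hidden
pivot with $\theta(t) = \text{rest} + A \sin(2\pi f t + \phi)$ and
$\rho = L_f\cot\theta + \rho_f$, so the pivot relation holds exactly in the
ground truth; sinusoidal whisking is a simplification of real whisking, but
the tracker only assumes smoothness. Occlusions are scripted per whisker
and frame range. Per-frame RNG streams are derived from the scene seed and
the frame index, making every frame bit-reproducible in isolation.

The default benchmark ("benchmark-B") is 10 whiskers on 480 x 512 px frames
at a 1,000 fps-equivalent rate for 2,000 frames, seed 42, with one 20-frame
occlusion and two whiskers phase-offset by 0.45 rad so each briefly crosses
its nearest neighbor once per whisk cycle (relative angle amplitude ~5
degrees against ~3.3 degrees of rest-angle spacing). An earlier candidate
design with phase-opposed whiskers was discarded: counter-whisking by
+/-22 degrees sweeps a whisker across six neighbors every cycle, which is a
different (and unrealistically adversarial) scenario than transient
crossings.

What passing on this generator does *not* show: robustness to non-sinusoidal
whisking kinematics, object contact (which deforms the whisker beyond the
one-coefficient bending model), moving backgrounds, photorealistic fur, or
3D out-of-plane motion. Those are out of scope by design.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` compute: sub-pixel accuracy over
18 orientations x 3 widths of noiseless ridges; clustering accuracy over
500 generated frames each without and with a persistent X-crossing (the
crossing case uses the direction-based method, the clean case the
density-based one); 1,000 jittered parameter-recovery fits; 1,000 noisy
pivot regressions; the full 2,000-frame benchmark-B tracking run; SNR
metric error across 20--60 dB; and 50 injected identity jumps for expert
hygiene. Bit-identical reproducibility is asserted on a 300-frame prefix of
benchmark-B run twice end to end (every random draw is seeded per frame and
the SVM and assignment steps are deterministic, so prefix identity is the
structural property being checked; the full benchmark additionally runs
once in the tests and once in the acceptance script).

## Known limitations

* Identities are fixed at the first frame; a whisker invisible at frame 1
  is never tracked.
* The parameter model covers free whisking only; touching an object bends a
  whisker beyond $d = bx^2$.
* The background must be static; the silhouette step assumes the snout is
  the dominant blob.
* Three-way overlaps in a single frame are not resolved; the affected
  frames surface as dropouts rather than errors, by design (the N-expert
  prefers "undetected" over contaminating the training data).
* AVI input is not supported; convert to multi-page TIFF or an image
  sequence.
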