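---
title: "Methods: breath-resolved chest morphometry from depth-camera point clouds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: breath-resolved chest morphometry from depth-camera point clouds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Chest-wall deformities and reduced chest mobility are common companions of
spastic cerebral palsy, and progress under physical therapy is usually judged
with tape measures or, at much greater cost and radiation burden, with
cross-sectional imaging. An overhead RGB-D camera offers a contact-free
alternative: a supine child breathing quietly on a treatment table produces a
sequence of colorized point clouds in which the torso surface rises and falls
a few millimetres to centimetres per breath. `chestmorph` turns such a
sequence into a small set of reproducible morphological parameters:

* transverse **cross-sections (CS1, CS2, CS3)** of the chest at three
  anatomical levels between the nipple line and the navel, extracted
  separately at the inspiration and expiration moments of every retained
  breath;
* their **dispersion** (coefficient of variation per location and of the CS
  area), the package's reliability measure;
* **chest mobility** `Dsess = 100 (A_insp - A_exp) / A_exp`, the percentage
  excess of the representative inspiration CS area over the expiration one;
* **morphology change** `D = 100 (A_sess2 - A_sess1) / A_sess1` between two
  sessions, per level and phase.

## Processing chain

1. **ROI crop and table plane.** Every frame of a trial is cropped with a box
   chosen on the first frame. The table plane is fitted by least squares to
   operator-marked table patches of the first frame and held fixed for the
   trial (the table does not move). We require patches on *both* sides of the
   patient: a one-sided patch leaves the plane free to pivot about it, and the
   lever arm turns a milliradian of fit noise into millimetre-scale depth bias
   across the torso.
2. **Marker tracking.** Three 1 cm circular matte markers (nipples, navel)
   are detected on the saturation channel (hexcone `S = (max-min)/max`) of
   the point cloud projected to the x-y plane at 0.1 cm/px. Detection is a
   two-stage circular Hough transform: saturation-gradient edge pixels vote
   along their gradient direction for all candidate radii (nominal ±50 %),
   and the peak is refined by an iterated least-squares circle fit to the rim
   pixels. The operator clicks the three markers once on frame 1; the
   corrected center of frame *k* seeds frame *k + 1*, which narrows the
   search window (2 cm default) without ever integrating error — seeding is
   stabilizing, so tracking error does not grow with sequence length. The
   final 3-D marker center is the centroid of the cloud points inside the
   detected circle.
3. **Rigid alignment.** Each frame is rotated so the table normal becomes
   (0, 0, 1) and the nipple-to-nipple line runs along +y. Both conditions are
   imposed by construction, so aligned nipple x-coordinates agree to machine
   precision and the table sits at a constant z = d.
4. **Grid of channels.** A 7 × 7 grid of 2 cm square ROIs spans the nipple
   line (row 1) to the navel (row 7) and the left (column 1) to the right
   nipple; it is rebuilt per frame from that frame's tracked markers, so the
   channels follow the breathing motion of the chest landmarks. The channel
   signal is the ROI mean of `d - z`. Rows 1, 3, 5 are the channels of
   interest (21 signals); the central location is channel (3, 4), the middle
   of that 3 × 7 block — approximately equidistant from the three markers
   and over the abdomen, where breathing excursions are largest.
5. **Breath separation.** The central signal is smoothed with a 4th-order
   Butterworth low-pass at 1 Hz, applied forward and backward (zero phase,
   so extrema timing — which indexes everything downstream — is preserved).
   Local minima/maxima of the smoothed central signal, repaired to strict
   alternation, segment *every* channel identically, which guarantees an
   equal breath count on all channels.
6. **Artifact rejection.** Patient motion shows up as sudden, large-amplitude
   events. Each channel's unsmoothed signal (mean-removed) is wavelet
   transformed with the real Morlet wavelet
   `psi(t) = exp(-t^2) cos(pi sqrt(2/ln 2) t)` over 64 log-spaced scales with
   pseudo-frequencies 0.05–5 Hz; the scalogram magnitudes summed across
   scales form a 1-D criterion whose values above the 99th percentile
   (linear-interpolation estimator) are flagged. A breath containing a
   flagged sample on *any* channel is removed.
7. **Breath-pattern gating.** Breaths are summarized by (period, amplitude);
   a Gaussian is fitted per session and a breath is kept iff its membership
   probability is at least 5 % under both sessions' models. Membership is
   `1 - F(D^2)` with `D^2` the squared Mahalanobis distance and `F` the
   chi-square CDF with 2 df — the probability mass outside the point's
   density contour, a scale-free quantity compatible with a 5 % floor.
8. **Cross-sections.** For each retained breath, the 7 channel values of a
   row at the breath's maximum (inspiration) or end minimum (expiration)
   form a CS; intermediate positions are linearly interpolated and the area
   is the trapezoidal integral (exact for a piecewise-linear curve), with the
   table plane (depth 0) as baseline. Outliers are removed with a single-pass
   1.5-IQR fence per location; a flagged CS drags the same-time-sample CSs of
   the other levels with it (the quartiles are not refitted after removal).
   The representative triplet is the medoid in (A1, A2, A3) area space, ties
   broken by the earliest time sample.
9. **Session statistics.** Paired cohort comparisons use Shapiro–Wilk on each
   group at α = 0.05; if both pass, a paired t-test, otherwise the Wilcoxon
   signed-rank test, two-sided throughout.

## Key parameters

| parameter | default | unit | why |
|---|---|---|---|
| ROI size | 2 | cm | averages out lattice noise and small marker shifts |
| pixel pitch | 0.1 | cm/px | a 1 cm marker spans ~20 px, enough for circle voting |
| search radius | 2 | cm | covers inter-frame marker motion at 30 fps with margin |
| Hough radii | nominal ± 50 % | cm | tolerates projection distortion |
| filter | 4th order, 1 Hz | – | passes breathing (≈ 0.2–0.5 Hz), rejects sensor noise |
| CWT scales | 64, 0.05–5 Hz | – | brackets the breathing band and artifact transients |
| artifact percentile | 99 | % | the largest 1 % of criterion values mark artifact onsets |
| membership floor | 5 | % | gate on the intersection of the two session models |
| IQR factor | 1.5 | – | conventional boxplot fence |

## The phantom

Patient recordings are not distributable, so the package ships a synthetic
phantom that generates what the camera would see and, alongside it, the
ground truth every stage can be checked against. It emulates: a planar table
at a configurable camera distance (53 cm default, exposed in the config); a
smooth torso dome whose static depth and breathing amplitude are cubic
splines through per-row values (amplitude grows toward the abdomen); three
saturated circular markers on the surface; a per-cycle raised-cosine
breathing waveform whose period (2 ± 0.2 s, matching roughly 30 breaths/min
in young children) and depth (± 5 % per cycle) jitter breath to breath;
i.i.d. Gaussian depth noise (0.1 cm, a plausible sensor figure at ~0.5 m);
small camera tilt/yaw/offset; and injectable step, spike or drift artifacts
with per-channel contamination masks. Points sit on a 0.25 cm x-y lattice
offset by half a pitch so that ROI boundaries never coincide with lattice
points (a knife-edge where sub-milliradian alignment noise would flip
boundary points in and out of a ROI).

The phantom deliberately does **not** model photorealistic skin texture,
non-rigid rib-cage kinematics, asymmetric or paradoxical breathing, sensor
distortion fields, or motion blur. Passing the phantom suite therefore
demonstrates that the *processing chain* is correct and self-consistent —
not that the method is clinically accurate on real anatomy.

Two generator choices deserve a note. First, breath-to-breath tidal
variability (the ± 5 % depth jitter) is what makes cross-session Gaussian
gating meaningful: with a strictly repeating waveform the amplitude variance
collapses to sensor noise and any real inter-session change would lie many
standard deviations out, so every breath would be rejected. Second,
experiments that check *deterministic* recovery (an exactly configured
amplitude, or the zero-dispersion degeneracy) disable the period and depth
jitter for that run, since those check the transfer of a fixed waveform
through the chain, not the statistics of breathing.

## Numerical choices and degenerate inputs

* **Zero-phase filtering** pads the signal with an odd (point-symmetric)
  reflection and primes both filter delay lines with the boundary value, so
  a constant signal passes through bit-exactly and edge transients are
  suppressed.
* **Plateau ties** in extrema detection resolve to the leftmost sample of a
  flat run; consecutive same-type extrema keep the more extreme member.
* **Percentile estimator**: linear interpolation between order statistics
  (`quantile` type 7). On 1000 distinct values, exactly 10 exceed the 99th
  percentile.
* **CWT edges**: signals are mean-removed and mirror-extended before
  convolution, so trial boundaries do not masquerade as artifacts.
* **Degenerate feature covariance**: a deterministic phantom produces
  identical breath features. Rather than failing on the singular covariance,
  Mahalanobis distances are computed per eigen-direction; a zero-variance
  direction contributes nothing when the point lies within numerical
  tolerance of the mean (and infinity otherwise). Fewer than 5 breaths is
  still an error.
* **Half-open crop intervals** avoid double-counting points on shared ROI
  boundaries; crop is idempotent.
* **Expiration CSs use the breath's end minimum.** Consecutive breaths share
  their boundary minima, so the start/end choice only affects the first and
  last breath of a trial; a fixed convention keeps the bookkeeping exact.
* **Breath features are 2-D** (period, amplitude). The density surface over
  that plane is what one would plot in 3-D; a third feature could be added,
  but none is needed to separate breathing patterns on the phantom.
* **Outlier propagation runs within a phase**: inspiration and expiration
  CSs live at different time samples, so a flag propagates across the three
  levels of its own triplet only.

## Problem sizes used in the validation suite

The test suite and `scripts/acceptance.R` use 30–90 s trials at 30 fps
(900–2700 frames of ~20 000 points), 10–20 random poses for the alignment
invariants, 100 random groups of up to 200 triplets for the medoid oracle,
and 2000 replicates for the type-I calibration of the paired test — sizes at
which every oracle (direct CWT sums, exhaustive medoid search, quartile
fences) can be recomputed independently. The full marker-tracking chain is
exercised on the 60 s recovery experiment and on the random-pose set; the
remaining experiments feed the pipeline the phantom's ground-truth marker
tracks, which isolates the stage under study from detection noise that the
tracking experiments already bound.

## Known limitations

* Sagittal cross-sections are out of scope; only transverse CSs are derived.
* The 99th-percentile artifact rule flags a fixed 1 % of samples per channel.
  It concentrates on the strongest events: with one dominant artifact, a
  weaker simultaneous one can go unflagged, and on an artifact-free trial 1 %
  of samples are still flagged (typically removing the one or two most
  irregular breaths). Both behaviors are inherent to the rule.
* `Dsess` and `D` are ratios of single representative areas; their run-to-run
  spread is set by the tidal variability of the medoid breath, not by sensor
  noise.
* The detector assumes markers remain visible; occlusion raises an error
  rather than extrapolating through it.
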