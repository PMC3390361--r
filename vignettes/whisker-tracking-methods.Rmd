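---
title: "Whisker tracking: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whisker tracking: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

whiskr analyses high-speed (hundreds of Hz) grayscale videos of head-fixed
rodents trimmed to a single row of whiskers: thin, dark, tapered hairs
silhouetted on a bright background, swept rhythmically ("whisking") at up
to thousands of degrees per second, occasionally occluding one another or
a thin stimulus pole. The pipeline is *trace* (every frame independently),
then *link* (assign persistent identities), then *measure* (kinematics).
This vignette explains the models and the choices made where the design
was genuinely open. Every empirical number quoted here is computed by the
package's test suite or by `scripts/acceptance.R`; none are asserted from
elsewhere.

## 1. Seeding: where tracing starts

A 7×7 box is centred on a candidate pixel and split into two partitions:
its 7 one-pixel columns and its 7 rows. Each strip contributes the
position of its intensity minimum; when a dark line crosses the box, one
partition's minima fall on the backbone and are therefore collinear. With
covariance eigenvalues λ₁ ≥ λ₂ of the minima positions, the line-likeness
score is the ellipse eccentricity √(1 − λ₂/λ₁) and the orientation is the
major axis. Sites above an eccentricity threshold (default 0.95) on a
sparse grid (default 50 px; whiskers span hundreds of pixels, so the grid
crosses each whisker) become seeds, consumed in decreasing eccentricity;
seeds falling within 1 px of an already-traced curve are discarded.

Three practical rules were needed beyond the textbook description:

* **Constant boxes score 0.** On an exactly uniform box the per-strip
  argmin tie rule (first pixel in scan order) makes both partitions'
  minima collinear, which would give eccentricity 1 everywhere on a blank
  frame.
* **Edge-hugging minima are degenerate.** If ≥ 6 of a partition's 7
  minima lie on the same box-edge line, the dark structure lies *outside*
  the box (the box sees only a monotone intensity tail). Without this
  rule, boxes floating 2–4 px beside a whisker produce confident seeds
  whose traces lock onto the whisker's flank and produce phantom
  parallel curves.
* **Ties between partitions go to the darker minima.** On noiseless
  axis-aligned lines both partitions can reach eccentricity 1, but only
  the backbone partition collects whisker-core (dark) pixels.
* **The seed position is the minima centroid**, a point on the backbone,
  not the box centre (which can be 3 px off the line — too far for the
  detector's ±0.5 px offset range to recover).

## 2. The line detector

A whisker cross-section is modelled as a rectangular intensity valley of
width *w*. The detector is the discrete Laplacian of that model: two
parallel step-edge elements of length 20 px (the distance over which even
strongly curved whiskers stay nearly straight) separated by *w*, each
element a +1 band (1 px thick, outside the line) adjacent to a −1 band
(inside). Pixel stencils are the exact area integral of this
piecewise-constant field over each pixel square (computed by polygon
clipping; verified against a supersampled numerical integral to 1e−3),
pre-tabulated on a lattice of sub-pixel offset (0.1 px), width (0.2 px in
[0.4, 6]) and angle (2.5°), and memoized.

**Normalization.** Stencils are normalized to zero sum (intensity-offset
invariance), and scaled so the positive and negative masses are each 1.
The response is then contrast-linear and approximately equals the valley
depth when matched. We deliberately did *not* normalize to unit L2: an
L2-normalized bank systematically rewards stencils that straddle pixel
boundaries (their norm is smaller), and on a pixel-integrated width-2
valley the lattice argmax then lands at width 2.6–2.8 with an ~8% score
advantage over the true parameters. With the mass normalization the
full-lattice argmax recovers width, angle and perpendicular offset at
lattice resolution (see `test-detector.R`).

**Known limitation.** For *crisp* (rectangular-profile) lines exactly
aligned with the pixel grid, the pixel-integrated image is invariant
under a family of (offset, width) detector parameters, so the sub-pixel
estimate there is defined only up to ~0.4 px and odd widths alias badly.
Oblique lines, and the smooth tapered profiles of real (and generated)
whiskers, are unaffected.

**Per-step optimization.** From the previous step's parameters, the
optimizer searches angles within ±10°, widths within ±0.4 px, and
sub-pixel offsets, taking the maximum response; ties break toward the
smallest change (angle, then width, then offset — so on a uniform image
the previous parameters are returned unchanged). The exported
`optimize_step()` searches all 100 offsets. The tracer's internal step
restricts offsets to the ~10 lattice points along the step's
perpendicular: the along-track offset component of a matched line
detector is unidentifiable on a locally straight ridge (sliding the
detector along the line changes nothing), and the restriction makes the
2000-frame benchmark tractable. The stored point keeps the 1 px
along-track advance and applies only the perpendicular refinement, which
also guarantees monotone ~1 px point spacing.

## 3. Tracing, stop tests and gap jumping

Initialization alternates a 1-D scan over all lattice widths with a
perpendicular re-centring step (up to 8 rounds, abandoned early if the
response stays below threshold), so seeds landing a pixel or two off the
backbone converge onto it rather than locking a wide detector onto the
flank of the line. Curves then grow bidirectionally in 1 px steps.

Four tests guard every step; each has a user-adjustable threshold:

| test | default | what it catches |
|---|---|---|
| minimum response | 0.2 × frame intensity range | crossings, occlusions, ends |
| left–right asymmetry | 0.25 | a second structure under one side |
| mean intensity about the detector | 0.5 × frame mean | large dark objects (the pole, the snout) |
| angular change per step | 25° | implausible bends, junction hopping |

Two of these needed design decisions the original description leaves
open. The *asymmetry* bands are the spans of the detector's own step-edge
elements (perpendicular ±[w/2 − 1, w/2 + 1]): bands placed outside the
detector cannot see a line riding under one element. The *minimum
response* default matters most: a matched detector responds at roughly
the line's full contrast, while the degenerate configurations the
optimizer can wander into — straddling a crossing, riding a flank —
respond at 0.2–0.4 of it. A near-zero threshold (rejecting only empty
background) lets traces power straight through whisker crossings and
emerge as parallel "ghost" duplicates ~2 px off the backbone, which the
2 px redundancy rule cannot remove; 0.2 × range places the distrust
threshold between the matched and degenerate regimes, so crossings
trigger the tests and are handled by gap jumping as intended. The cost is
that tracing stops where a whisker's taper drops its contrast below 20%
of the frame range — the physically invisible tail.

On a failed test, up to `max_gap_px` (default 8) single-pixel probes
continue along the last trusted direction; if all four tests pass at a
probe, the gap is bridged with a straight segment (bridge points carry
score 0) and tracing resumes; otherwise the curve is truncated at the
last trusted point. Duplicate traces are resolved by the redundancy rule:
if a contiguous interval of one curve within 2 px of another covers more
than half its arc length, the shorter is discarded, repeated to a fixed
point. Candidate pairs are found by shared rasterized pixels, dilated by
one 4-neighbourhood so near-parallel duplicates offset ~1 px still
collide.

## 4. Linking: the ordered-label HMM

Whiskers are long, and they keep a fixed anterior–posterior order along
the snout. Both facts are exploited.

**Training from the video itself.** For a length threshold λ, let F_n(λ)
be the frames with exactly *n* curves longer than λ. Given the whisker
count N, λ̂ maximizes |F_N(λ)|; those frames form the training set and
their long curves are, by construction, true whiskers (heuristically
labeled W1…WN posterior→anterior, everything else F_i). With N unknown,
|F_n(λ)| is maximized jointly; among tied counts we prefer the *n* whose
maximizing λ-interval — the plateau between consecutive observed lengths
— is widest, i.e. the most robust length gap (this tie rule is not in the
original description but is forced by simple cases where several (n, λ)
reach the same count). Candidate λ are midpoints between consecutive
distinct observed lengths, quantized to ~1 px when more than 1200
distinct lengths are observed.

**Shape and motion statistics.** Six features per curve — angle near the
face, mean |curvature| (both from a degree-3 parametric fit), mean trace
score, arc length, and the anterior–posterior positions of the two
endpoints — are histogrammed (32 uniform bins over the training range,
one count added to every bin before normalizing so nothing has zero
likelihood; out-of-range queries clamp to the edge bins) separately for
whiskers and false positives. Frame-to-frame *changes* of the same
features are histogrammed the same way, using the shape-only labeling of
consecutive training frames as the correspondence; false positives are
zipped by shared F_i label in anterior–posterior order. Labels without a
unique correspondent (an absent whisker, any F label) use a neutral
constant: the mean log bin mass of the change histograms.

**Per-frame decoding.** Curves sorted posterior→anterior are labeled
from the 2N+1 alphabet {W1…WN, F0…FN} under the ordering rules (label
indices never decrease along the sequence; at most one W_i; F_i may not
precede W_i). Start and transition probabilities are label-pair
frequencies from the heuristic training labelings, add-one smoothed over
*legal* transitions only — illegal ones stay at probability zero. The
optimal sequence maximizes transitions × per-curve likelihoods (shape,
plus change terms relative to a neighbouring frame's labeling when
available) by the Viterbi recursion; it is verified against brute-force
enumeration on hundreds of random instances in the test suite.

**Confidence-ordered propagation.** Every frame is first labeled with
shape features alone and scored by its per-curve mean log probability.
Repeatedly, the highest-scoring unvisited frame is visited and its
unvisited neighbours are relabeled with the full model conditioned on it
(change terms oriented later-minus-earlier), updating their scores; the
most confident frames thus influence their neighbours transitively until
all frames are visited — an error in one frame cannot propagate through
the whole video the way frame-sequential tracking lets it.

## 5. Measurement

The traced midline is fit with a degree-5 parametric polynomial in
normalized cumulative chord length (arc-length parameterization keeps
curvature well-conditioned). The face mask — an image-edge half-plane or
a circle — gives a reference point where the curve crosses it (or the
linear extrapolation of the face-side end); the follicle, which is not
imaged, is placed a configured distance past the mask along the tangent.
The angle at base is the tangent angle at the reference, 0° on the
lateral axis, protraction positive. Curvature is measured at an interest
point a configured arc distance from the reference (default 5 mm, for
signal-to-noise) as the curvature of a *degree-2 re-fit over a 1–2.5 mm
window* (default 2 mm) about it, so whisker shape outside the window
cannot bias the measurement; the reference point, arc positions and
window membership are computed from the raw polyline (the global fit
would leak distal perturbations into the window at the 1e−9 level the
invariance test demands). Pole contact is the closest point to the pole
centre on the curve or on the tangent line extrapolated from its nearest
end. Contact episodes are maximal runs of frames with contact distance
below the pole radius plus a margin; each reports its peak curvature
change from the resting (median non-contact) curvature.

## 6. The synthetic world

The generator is first-class, tested code; all validation rests on it.
Its default scene is a scaled-down analog of a head-fixed rig: 256×176 px
at 40 µm/px, face on the left edge behind a 24 px dark snout silhouette
(wider than the detector so the mean-intensity test engages at the base,
as on a real snout), four whiskers with quadratic-Bézier backbones
(closed-form tangents and curvature for oracles) anchored at the face,
bases 2–3.5 px wide tapering to 0.05 px (~2 µm — physically right, and
the smooth fade is what terminates traces gracefully at the tip),
correlated 15 Hz sinusoidal whisking of 12° amplitude at 500 fps, six
short facial hairs emerging from the silhouette at steep angles, Gaussian
sensor noise (sd 2), a 10-unit illumination gradient, an odd-line gain of
0.9, and 8-bit quantization. Whisker chord lengths (152, 158, 155, 149 px)
give overlapping *imaged* lengths, as cropped fields of view do; with
cleanly separated lengths the unknown-N threshold heuristic prefers a
smaller N — its documented failure mode. The benchmark adds a
single-frame 35° transient (≈17.5°/ms at 500 fps, the flick-past event),
a 30-frame episode in which whisker 4 leaves the field, and a 2.5 px
(0.2 mm) pole on whisker 2's sweep.

What a green benchmark does *not* establish: robustness to fur texture,
motion blur, defocus, multi-row geometry, or whisker-pole *bending*
(contact here is purely occlusive). Rendered whiskers rotate rigidly;
real whiskers bend under contact and inertia.

Noise is drawn per frame from a stream derived from the scene seed and
the frame index, so any frame renders identically regardless of order.

## 7. Numerical choices

* Patch intensities are centred on the frame mean before the float dot
  products, so responses on uniform images are exactly zero and
  tie-breaking is exact.
* Out-of-image stencil pixels read the frame mean (neutral under
  zero-sum weights); traces additionally stop at the image border.
* Angles are folded mod 180° where only orientation matters; the tracer
  keeps a 0–360° heading so the two growth directions stay distinct.
* `fit_parametric` reduces the degree on rank deficiency with a message;
  `curvature_at` raises an error when the parameterization speed
  vanishes.
* All probability arithmetic is in log space; frame confidence is the
  mean per-curve log probability so frames with different curve counts
  are comparable.

## 8. Known limitations

* Sub-pixel estimates on crisp axis-aligned rectangular lines alias with
  the pixel grid (§2); smooth or oblique structures are unaffected.
* Two whiskers osculating tangentially over tens of pixels are
  ill-posed for the tracer (and for human annotators); transversal
  crossings are handled by the stop tests and gap jumping.
* The linking model assumes a single row: anterior–posterior ordering is
  a hard constraint, so multi-row or bilateral fields will trace but not
  link correctly.
* The length-threshold heuristic mis-estimates N when one whisker's
  imaged length is separated from the others by a persistent gap, or
  when a whisker is absent for a large fraction of the video; N can
  always be supplied.
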