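---
title: "Quantifying local contour cues and validating the analyses by simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying local contour cues and validating the analyses by simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contourcues)
```

# The problem

A contour fragment cut from a natural scene carries several local Gestalt
cues that can pull figure–ground assignment one way or the other: the
bulge of the contour (convexity), how enclosed each side is (closure),
and whether a mirror-symmetry axis runs through one side (symmetry). This
package quantifies the three cues on 69 × 69-pixel binary contour
patches centred on a contour pixel, and implements two analyses that use
them: a similarity-rating experiment analysed by nonmetric MDS and
Procrustes configuration comparison, and a two-alternative forced-choice
(2AFC) figure-direction experiment analysed by convex-choice rates and a
six-term linear regression.

The human response data such designs produce are not publicly deposited,
and the natural-contour corpus behind them has no machine-readable
accession. The package therefore treats synthetic data as first-class:
contour generators plant known curvature, enclosure and mirror-axis
structure, simulated observers rate and choose as noisy functions of the
indices, and every analysis stage is validated by recovering what was
planted. Passing tests demonstrate that the pipeline measures what it
claims on contours with known ground truth; they do not certify
behaviour on natural images, whose statistics (junction density, texture,
multi-contour clutter) the generators deliberately do not emulate.

# The local frame

All three indices hinge on the geometry at the patch centre, estimated
from the 41 chain pixels centred there (20 to each side; closed chains
wrap around; shorter chains are an error).

* **Tangent** — principal direction of the window (total-least-squares
  line fit); reported as an angle in [0°, 180°) with 0° vertical.
* **Curvature** — reciprocal radius of a least-squares circle fit to the
  same window. We use the Taubin algebraic fit rather than the naive
  (Kasa) algebraic fit: on a near-straight rasterized window the Kasa
  normal equations trade the true, nearly infinite radius against the
  spread of the points along the line and collapse to a circle of radius
  ≈ 11 px, an error of several orders of magnitude; the Taubin
  normalization removes this bias and recovers planted radii 15–30 px
  within ~2%.
* **Convex side** — the unit perpendicular of the tangent, signed toward
  the fitted circle centre. Tying the normal to the tangent (rather than
  using the raw centre-to-centre direction) keeps the two exactly
  orthogonal even when rasterization tilts the window.
* **Degenerate frames** — when the fitted |curvature| falls below
  `rho_tol = 1e-3` per pixel the contour is treated as straight; the
  convex side then defaults to the left of the chain's traversal
  direction, purely for determinism, and the patch carries a `degenerate`
  flag that downstream analyses use to exclude it.

The window covers a fixed *pixel count*, not a fixed arc length, so on
tightly curved contours it spans a large turn angle; the circle fit is
exact for arcs of any extent, but the tangent of a long asymmetric
window can tilt a few degrees. This only moves patches near orientation
bin edges.

# The three indices

**Convexity** is `log(1 + |rho|)` (natural logarithm; the base is a
convention — only monotonicity matters downstream). It is zero for a
straight contour and about 0.26 at the tightest curvature the
stratification covers (radius ≈ 4 px).

**Closure** places probe points at ±5 px from the centre along the convex
normal and casts 16 rays at 22.5° increments from each, the first ray
along the normal. A ray counts at most once, if it meets any contour
pixel inside the patch; crossing is decided by an exact ray/axis-aligned
pixel-square (slab) test, so there is no step-size parameter. The index
is `N_convex − N_concave`, where `N_convex` comes from the probe
displaced toward the convex side: a closed region around the convex-side
probe forces all 16 of its rays to cross, making the index positive when
the convex side is the enclosed one, which is the orientation of the sign
convention adopted here. Rays from *both* probes use the full 360° fan
(16 × 22.5°). The test suite checks the implementation against an
independent ray–edge-intersection oracle, exactly, on 50 random patches.

**Symmetry** is built on the degree of symmetry `dos(θ, x)`: rotate the
patch by θ about its centre and translate it by x columns
(nearest-neighbour resampling of the sparse pixel coordinates), then
count contour pixels that coincide with their mirror image about the
central column, divided by the pre-dilation contour length. By default
both images are dilated by a radius-1 disc (the 5-point cross) before
the overlap, because single-pixel curves barely overlap on an integer
grid under rotation; a `dilate = FALSE` flag restores exact arithmetic
for tests. The optimal axis is an exhaustive search over θ = 0…179° × x
= −34…34 px, ties broken toward the smallest θ, then smallest x. For
speed, each rotation's full x-profile is accumulated at once: a pair of
same-row pixels with columns c₁, c₂ is mirror-matched at exactly one
shift, x = (70 − c₁ − c₂)/2, so tabulating ordered pair sums row by row
replaces 69 independent overlap evaluations; the result is identical to
the direct evaluation, which the tests assert at 1000 random grid
points.

The Symmetry index of patch k is `max dos(k) / m`, where m is the
largest maximal dos in the corpus actually analysed, so exactly one
patch in any corpus scores magnitude 1 and the index is independent of
patch size. The sign is negative when the optimal axis runs mainly
through the concave side. Operationally, the axis clipped to the patch
square is sampled at 0.25 px; samples within 0.75 px of a contour pixel
count as axis–contour contacts and are dropped; each remaining sample is
labelled convex or concave by the side of its *nearest* contour pixel
(sign of the dot product with the convex normal), and the sign is
negative iff the convex-side total length is strictly shorter.
Nearest-contour labelling, rather than the half-plane of the centre
tangent, is what makes the shallow-arc case work: the optimal axis of a
nearly straight arc hugs the contour itself, where the centre half-plane
labels are all ambiguous but every axis point clearly lies on the
concave (outer) side of the curve. Two consequences are worth knowing:
a small closed symmetric blob gets a *negative* sign, because most of
the clipped 69-px axis lies outside the region; and contours that
inflect inside the window have no well-defined convex side to begin
with — one circle is fitted to the whole window and the ambiguity is
inherited, not resolved.

# Stimulus stratification

Patches are classified by five convexity bins, five closure bins and
eight orientation bins (200 classes). Only the outer bin edges of the
first two are prescribed — convexity [0, 0.018) and [0.222, 0.258],
closure [−8, −6) and (6, 8] — so the three interior bins are equal-width,
the simplest partition consistent with those edges; all interior
boundaries are half-open, lower-inclusive (closure is integer-valued, so
only the printed edges matter). Orientation bins are the unequal widths
0–15–30–60–90–120–150–165–180° with 0° vertical. `stratified_select()`
draws one member uniformly per non-empty class under a seed; empty
classes are simply skipped, as natural corpora never fill all 200.

X-junction screening uses the crossing number: a contour pixel whose
8-neighbourhood ring contains ≥ 4 connected runs of contour pixels marks
a crossing; T-junctions (3 runs) pass. This assumes thin contours, which
the tracers and generators produce. Two further screens in the original
protocol were human visual inspections; `patch_exclusion_flags()`
provides documented geometric stand-ins (contour-density threshold,
enclosed-area fraction of a closed chain), off by default because they
approximate a judgement, not a computation. Display stimuli are the
binary patch multiplied by an isotropic Gaussian window (σ = 17 px, peak
1 at the centre).

# Similarity analysis

Ratings on the 5-point scale (5 = most similar) become dissimilarities
as `5 − mean(rating)` per unordered pair. The map is linear and
order-preserving; since the embedding is nonmetric, only its ranks
matter. `nonmetric_mds()` minimizes Kruskal stress (via `MASS::isoMDS`,
the standard implementation of that optimization) from a
classical-scaling start plus 9 seeded random restarts, and returns the
solution with the lowest in-package stress-1. Zero dissimilarities are
lifted to a tiny epsilon only for the optimizer, which requires positive
input. `kruskal_stress()` itself fits the monotone transform by isotonic
regression of configuration distances on the dissimilarity order, with
the primary approach to ties (tied dissimilarities unconstrained among
themselves), and reports the square-root (stress-1) form; the squared
ratio is trivially its square, and all comparisons here use stress-1.

Topographic configurations place each stimulus at its selected cue
values, each factor z-standardized across the stimulus set: Procrustes
alignment removes global scale but not per-axis anisotropy, so the axes
must be made commensurate before comparison. Alignment uses
`vegan::procrustes` (translation, rotation, reflection, uniform scale —
reflections are allowed because MDS solutions are chiral-ambiguous), and
the raw Error is the squared-sum of aligned pairwise distances, checked
in the tests against an independent brute-force optimizer.

The Error is normalized by its scrambling null: stimulus labels of the
dissimilarity matrix are permuted (permutation preserves the value
distribution and keeps the matrix valid, unlike cell-level shuffling,
which was considered and rejected), the permuted matrix is re-embedded,
and the Procrustes residual against the perceptual configuration is
recorded; the normalized Error divides the observed raw Error by the
*mean* of `n_random = 100` such null Errors (dividing by the mean, not
each draw, was the reading adopted where both are defensible). Null
embeddings use 2 random restarts instead of 10 — the null needs the
location of a chance Error, not a globally optimal embedding — and the
p-value is a one-sided one-sample t-test of the null distribution
against the observed value, since the observed Error is a single number
per participant. Group-level analysis is per-observer first, then
paired t-tests across observers per factor-set pair
(`compare_factor_sets()`).

# Figure–ground analysis

A 2AFC answer (left/right for near-vertical contours, top/bottom
otherwise) counts as convex-chosen iff its direction has positive dot
product with the patch's convex normal. Degenerate (straight) patches
are excluded with a logged count, since their convex side is a
tie-break, not a measurement. Rates are pooled over observers per patch
for the headline regression (a per-observer option is retained), and
`mlra()` fits ordinary least squares of rate on the three raw indices
and their three pairwise products. Predictors stay unstandardized so
coefficients live on the natural cue scales, and a linear probability
model is used despite bounded rates — that is the analysis the design
prescribes, and it matches the simulated observer exactly. Adjusted R²
is reported, flagged undefined when the response is constant.

The simulated 2AFC observer is clipped-linear: P(choose convex) is the
same seven-term linear predictor clipped to [0, 1], Bernoulli-sampled
per repetition. Because generator and analysis share a functional form,
exact recovery is a meaningful test. The recovery simulations therefore
restrict stimuli to the interior regime where no clipping occurs — with
the default planted weights (intercept 0.490, closure 0.0755, the other
five terms small) that means |closure| ≤ 6, keeping the planted
probability inside (0, 1); at |closure| = 8 the predictor exceeds 1 and
OLS recovery would be attenuated by construction, which is a property of
the linear probability model, not a defect of the fit.

# Synthetic generators and observers

* `generate_arc(radius, arc_extent, orientation, center_offset)` —
  rasterized circular arc through the patch centre; plants curvature
  1/radius and tangent orientation. The closed-circle variant encloses
  the convex-side probe, the planted positive-closure fixture.
* `generate_blob(harmonic_amplitudes, mirror_symmetric, seed, axis_deg,
  base_radius)` — closed radial-harmonic contour
  `r(φ) = r₀ + Σ A_k cos(kφ + ψ_k)` arranged to pass through the patch
  centre with the planted axis through it. `mirror_symmetric` zeroes the
  phases; a vertical planted axis is rasterized half-and-mirrored so the
  pixel grid (and hence its dilation) is *exactly* symmetric, which is
  what makes the corpus-maximum Symmetry magnitude exactly 1 rather than
  approximately so. The default amplitudes (3, 2, 1.5 on base radius 12)
  give distinct lobes: with weaker shape (2, 1) the planted oblique axis
  is beaten by spurious near-symmetries of a nearly elliptical outline
  under dilation, so lobedness is a requirement of axis identifiability,
  not an aesthetic choice.
* `generate_open_curve(smoothness, seed)` — the workhorse emulating
  single open natural contours: a unit-step walk whose heading integrates
  a per-draw base curvature, drawn signed-uniform on [0, 1.8/smoothness],
  plus smoothed Gaussian wiggle (sd 1.2/smoothness, 5-step moving
  average), laid through the centre both ways and clipped at the patch
  border. The default smoothness 6 lets the base curvature reach ≈ 0.3
  per pixel, covering all five convexity bins, and produces loops that
  enclose one probe or the other, covering the closure bins; these
  constants were fixed once from a single calibration run of the bin
  coverage (2000 draws populate ≥ 60% of the 25 convexity × closure
  bins) and are the package's standing emulation of a varied contour
  corpus. About 3% of draws curl too tightly for the 41-pixel frame
  window and are rejected by the same screen that drops X-junctions.
* `observer_model()` — per-observer latent parameters. Similarity:
  latent dissimilarity is the weighted Euclidean distance in
  z-standardized cue space plus Gaussian noise (sd 0.3 by default), cut
  at fixed thresholds (0.5, 1.25, 2.0, 3.0) into the 5-point scale; the
  distance-plus-thresholds form is the simplest model whose ranks
  reflect the planted structure. Figure–ground: the clipped-linear model
  above, with default weights planting a closure-dominated pattern
  (intercept 0.490, convexity −0.334, closure 0.0755, symmetry 0.0383,
  and small interactions) so that end-to-end runs have a known dominant
  cue.

All generators and simulators are bit-reproducible under their seeds,
and every seeded routine saves and restores the caller's RNG state. A
single run seed expands into per-stage seeds via `split_seed()` (one
`sample.int` draw per stage under the run seed).

# Numerical choices and problem sizes

* Coordinates are 1-based (row, col) with rows increasing downward, the
  native R convention; angles measure from vertical. All intervals are
  half-open, lower-inclusive.
* Chain tracing splits branch points by largest unvisited continuation,
  with ties broken toward 4-connected neighbours (this keeps staircase
  corner pixels inside the chain instead of orphaning them) and then
  lexicographic pixel order — fully deterministic.
* The dos search grid is 1° × 1 px; planted oblique axes are recovered
  to the grid step for well-lobed blobs. Rotations by multiples of 90°
  are exact lattice maps, so the rotation invariance of dos is exact,
  and the tests assert it exactly.
* Simulation sizes used by the test suite were chosen for a desk-scale
  run and fixed before the suite was finalized: factor-dominance
  replicates use 18 stimuli, 20 null configurations and 50 replicates;
  the null self-consistency check uses 12 stimuli and 15 nulls over 50
  replicates; regression recovery uses 50 patches, 100 repetitions and
  100 replicates. The full design sizes (54 stimuli → 1431 pairs × 4
  repetitions; 100 nulls; 100 2AFC repetitions) remain the function
  defaults.

# Limitations

* The generators emulate controllable cue structure, not natural-image
  statistics; results on them validate the measurement and analysis
  chain, nothing about natural scenes.
* The Symmetry sign rule is an operationalization of an informally
  stated convention; alternatives (half-plane labelling, parity
  propagation across contacts) disagree on closed blobs and
  axis-tangent cases, and the nearest-contour rule was chosen for
  robustness on the constructed test cases.
* Closure assumes thin contours; thick input must be thinned before
  tracing.
* The linear probability model can plant probabilities outside [0, 1]
  for extreme cue values; recovery guarantees hold in the interior
  regime only.
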