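# contourcues

Local contour-shape cues for figure–ground perception, with the two
psychophysical analyses they drive.

When people look at a fragment of a natural contour, which side of it
looks like the *figure*? Three local Gestalt cues are candidates:

- **Convexity** — `log(1 + |ρ|)`, where ρ is the curvature at the patch
  centre estimated over a 41-pixel chain window. The *convex side* is the
  side toward the osculating-circle centre.
- **Closure** — `N_convex − N_concave`: from two probe points placed ±5 px
  from the centre along the contour normal, 16 radial rays (22.5°
  increments) are cast, and a ray counts once if it crosses the contour
  inside the 69 × 69 patch. Positive when the convex side is the more
  enclosed one; range −16 … 16.
- **Symmetry** — the degree of symmetry `dos(θ, x)` is the number of
  contour pixels coinciding with their mirror image about a candidate
  axis (patch rotated by θ, translated by x columns), divided by contour
  length. An exhaustive grid search (θ = 0…179°, x = −34…34 px) finds the
  optimal axis; the index is `max dos / m`, normalized by the largest dos
  `m` in the working corpus (so the corpus maximum scores 1), with a
  negative sign when the optimal axis runs mainly through the concave
  side.

The package computes these indices on binary contour maps, stratifies
patches into the 5 (convexity) × 5 (closure) × 8 (orientation) = 200
stimulus classes with one-per-class random selection, and implements the
two analyses:

1. **Perceptual similarity** — 5-point similarity ratings are aggregated
   into dissimilarities (`5 − mean rating`), embedded by nonmetric MDS
   (Kruskal stress-1), and compared with *topographic* configurations
   built from cue subsets via Procrustes alignment. Agreement is the
   **Error** statistic: the squared-sum of aligned point distances,
   normalized by its mean over 100 configurations re-fitted after
   scrambling the stimulus labels of the dissimilarity matrix (0 =
   perfect, ≈1 = chance).
2. **Figure–ground choices** — 2AFC figure-direction responses are scored
   against each patch's convex normal, and the per-patch convex-choice
   rate is regressed on the three indices and their pairwise products
   (six terms plus intercept, ordinary least squares, adjusted R²).

Human data for these designs are not deposited anywhere, so the package
ships synthetic generators for both sides: contour patches with planted
curvature, closure and mirror-axis structure (`generate_arc()`,
`generate_blob()`, `generate_open_curve()`), and simulated observers
(`observer_model()`, `simulate_similarity()`, `simulate_fg()`) whose
ratings and choices are noisy functions of the indices. Every analysis
stage is validated by parameter recovery against these planted truths.

## Worked example

```r
library(contourcues)

# a synthetic corpus: one exactly mirror-symmetric blob + screened open curves
gen <- function(s) {
  p <- generate_open_curve(seed = s)
  ok <- !has_x_junction(p) &&
    !inherits(tryCatch(local_frame(p), error = identity), "error")
  if (ok) p else NULL
}
curves <- Filter(Negate(is.null), lapply(1:45, gen))
patches <- c(list(blob = generate_blob(mirror_symmetric = TRUE, axis_deg = 30)),
             setNames(curves, sprintf("curve%02d", seq_along(curves))))

cues <- compute_cues(patches)   # frames, Convexity, Closure, axis search, Symmetry
cues[, 1:6]
#> # A tibble: 37 × 6
#>   patch_id convexity closure symmetry orientation_deg orientation_bin
#>   <chr>        <dbl>   <int>    <dbl>           <dbl>           <int>
#> 1 blob        0.0877      11   -0.990         118.                  5
#> 2 curve01     0.211        0    0.764          32.6                 3
#> 3 curve02     0.173        0    0.760           0.603               1
#> 4 curve03     0.0478       5    0.762          41.9                 3
#> # i 33 more rows
```

The blob is closed around its convex side (closure 11) and is the most
symmetric patch in the corpus (|symmetry| ≈ 1; the sign is negative
because the clipped optimal axis runs mostly outside the small closed
region).

Simulated similarity experiment, driven by closure + convexity only:

```r
obs <- observer_model(similarity_weights = c(convexity = 1, closure = 1,
                                             symmetry = 0),
                      noise_sd = 0.3, seed = 2)
D <- aggregate_dissimilarity(simulate_similarity(cues[1:14, ], obs))
P <- nonmetric_mds(D, dims = 2, seed = 3)
glance(P)
#>   stress  dims     n  seed
#> 1 0.0431     2    14     3
normalized_error(P, topographic_config(cues[1:14, ], c("convexity", "closure")),
                 n_random = 20, seed = 4)
#> <error_stat> raw 3.118, normalized 0.006 (null mean 502.1, n = 20), p = 1.64e-21
```

A normalized Error of 0.006 means the convexity–closure configuration
sits essentially on top of the perceptual one; label-scrambled null
configurations are ~170× farther away.

Simulated 2AFC experiment with the default (closure-dominated) observer,
100 repetitions per patch:

```r
resp <- simulate_fg(cues, observer_model(seed = 5), n_reps = 100)
reg <- mlra(convex_choice_rate(resp, cues), cues)
tidy(reg)
#>   term                 estimate std_error statistic  p_value
#> 1 (Intercept)         0.517       0.0311    16.6    1.06e-16
#> 2 convexity          -0.531       0.236     -2.25   3.20e- 2
#> 3 closure             0.0581      0.00514   11.3    2.40e-12
#> 4 symmetry            0.0424      0.0355     1.19   2.42e- 1
#> 5 convexity:closure  -0.0149      0.0333    -0.448  6.57e- 1
#> 6 convexity:symmetry -0.0235      0.250     -0.0943 9.25e- 1
#> 7 closure:symmetry    0.0000421   0.00365    0.0115 9.91e- 1
glance(reg)
#>   adj_r_squared r_squared n_patches constant_response
#> 1         0.939     0.949        37 FALSE
```

Closure carries the choices (t ≈ 11), the other cues and interactions do
not — the planted observer pattern, recovered from the simulated trials.

`run_pipeline(run_config(seed = 1))` chains all stages (simulate →
features → select → similarity → fg) into a run directory with manifests,
logs and CSV/JSON outputs; `validate_io()` checks the artifact schemas.

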