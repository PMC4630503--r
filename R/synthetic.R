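# Rasterisation helpers
# ---------------------

# math (x, y) points -> rounded (row, col), consecutive duplicates removed
.rasterise_path <- function(xy) {
  rc <- cbind(round(-xy[, 2]), round(xy[, 1]))
  keep <- c(TRUE, rowSums(abs(diff(rc))) > 0)
  rc[keep, , drop = FALSE]
}

# trim an ordered pixel path to the maximal in-bounds run containing the
# centre pixel, and build the patch
.path_to_patch <- function(rc, provenance) {
  ctr <- which(rc[, 1] == PATCH_CENTER & rc[, 2] == PATCH_CENTER)
  if (length(ctr) == 0) abort("path does not pass through the patch centre")
  idx <- ctr[1]
  inside <- rc[, 1] >= 1 & rc[, 1] <= PATCH_N & rc[, 2] >= 1 & rc[, 2] <= PATCH_N
  lo <- idx; while (lo > 1 && inside[lo - 1]) lo <- lo - 1
  hi <- idx; while (hi < nrow(rc) && inside[hi + 1]) hi <- hi + 1
  chain <- rc[lo:hi, , drop = FALSE]
  grid <- matrix(0L, PATCH_N, PATCH_N)
  grid[chain] <- 1L
  contour_patch(grid, chain, provenance = provenance)
}

# unit tangent/axis direction (math coords) for an angle from vertical
.dir_from_vertical <- function(deg) {
  a <- deg * pi / 180
  c(sin(a), cos(a))
}

#' Generate a circular-arc patch
#'
#' Rasterises a circular arc through the patch centre with a prescribed
#' tangent orientation there, planting curvature `1/radius`. The convex
#' side (toward the circle centre) is the left of the tangent direction.
#'
#' @param radius Circle radius in pixels (> 2).
#' @param arc_extent Swept angle in degrees; `NULL` (default) spans about
#'   120 px of arc length, capped at a full circle. 360 gives a closed
#'   circle through the centre.
#' @param orientation Tangent angle at the centre, degrees from vertical.
#' @param center_offset Arc-length offset (px) of the arc midpoint from the
#'   patch centre; the centre must remain on the arc.
#' @return A `contour_patch`.
#' @examples
#' p <- generate_arc(20, 150, 0)
#' local_frame(p)$rho
#' @export
generate_arc <- function(radius, arc_extent = NULL, orientation = 0,
                         center_offset = 0) {
  if (radius <= 2) abort("radius must exceed 2 px")
  if (is.null(arc_extent))
    arc_extent <- min(360, 120 / radius * 180 / pi)
  ext <- arc_extent * pi / 180
  co <- center_offset / radius
  e1 <- ext / 2 + co; e2 <- ext / 2 - co
  if (e1 < 0 || e2 < 0) abort("arc not passing through center")

  tangent <- .dir_from_vertical(orientation)
  nrm <- c(-tangent[2], tangent[1])  # left of tangent
  ctr <- c(PATCH_CENTER, -PATCH_CENTER)  # (x, y)
  C <- ctr + radius * nrm
  phi0 <- atan2(ctr[2] - C[2], ctr[1] - C[1])

  dphi <- 0.3 / radius
  left <- seq(phi0, phi0 - e1, by = -dphi)
  right <- seq(phi0, phi0 + e2, by = dphi)
  phi <- c(rev(left), right[-1])
  xy <- cbind(C[1] + radius * cos(phi), C[2] + radius * sin(phi))
  rc <- .rasterise_path(xy)
  # closed sweep: drop duplicated seam pixel
  if (nrow(rc) > 1 && all(rc[1, ] == rc[nrow(rc), ]))
    rc <- rc[-nrow(rc), , drop = FALSE]
  .path_to_patch(rc, sprintf("arc r=%g ext=%g ori=%g off=%g",
                             radius, arc_extent, orientation, center_offset))
}

#' Generate a closed blob from radial harmonics
#'
#' Builds a closed contour `r(phi) = base_radius + sum_k A_k cos(k phi +
#' psi_k)` around a centre placed so the contour passes through the patch
#' centre and the planted axis runs through it. With
#' `mirror_symmetric = TRUE` all phases are zero, giving an exact mirror
#' axis at `axis_deg`; a vertical planted axis (`axis_deg = 0`) is
#' rasterised half-and-mirrored so the pixel grid itself is exactly
#' mirror-symmetric.
#'
#' @param harmonic_amplitudes Amplitudes `A_k` for harmonics k = 1, 2, ...
#' @param mirror_symmetric Plant an exact mirror axis (zero phases).
#' @param seed Integer seed for the random phases (ignored when
#'   `mirror_symmetric`).
#' @param axis_deg Planted axis angle, degrees from vertical.
#' @param base_radius Mean radius in pixels.
#' @return A `contour_patch`.
#' @examples
#' p <- generate_blob(mirror_symmetric = TRUE, axis_deg = 0)
#' @export
generate_blob <- function(harmonic_amplitudes = c(3, 2, 1.5),
                          mirror_symmetric = FALSE, seed = 1,
                          axis_deg = 0, base_radius = 12) {
  A <- harmonic_amplitudes
  psi <- if (mirror_symmetric) rep(0, length(A)) else
    runif_seeded(length(A), 0, 2 * pi, seed)
  rfun <- function(phi) {
    r <- rep(base_radius, length(phi))
    for (k in seq_along(A)) r <- r + A[k] * cos(k * phi + psi[k])
    r
  }
  probe <- rfun(seq(0, 2 * pi, length.out = 720))
  if (min(probe) <= 2) abort("self-intersecting parameterization: radius collapses")

  a <- .dir_from_vertical(axis_deg)
  aperp <- c(-a[2], a[1])
  ctr <- c(PATCH_CENTER, -PATCH_CENTER)
  B <- ctr + rfun(pi) * a
  point <- function(phi) {
    r <- rfun(phi)
    cbind(B[1] + r * (cos(phi) * a[1] + sin(phi) * aperp[1]),
          B[2] + r * (cos(phi) * a[2] + sin(phi) * aperp[2]))
  }
  dphi <- 0.3 / max(probe)

  exact_vertical <- mirror_symmetric && axis_deg == 0
  if (exact_vertical) {
    # rasterise phi in [0, pi] and mirror the pixels about the centre
    # column: the grid is then exactly symmetric, dilation included
    phi <- seq(0, pi, by = dphi)
    half <- .rasterise_path(point(phi))
    other <- cbind(half[, 1], 2L * PATCH_CENTER - half[, 2])
    rc <- rbind(half, other[rev(seq_len(nrow(other))), , drop = FALSE])
    keep <- c(TRUE, rowSums(abs(diff(rc))) > 0)
    rc <- rc[keep, , drop = FALSE]
  } else {
    # start the sweep at phi = pi so the path runs through the centre pixel
    phi <- seq(pi, pi + 2 * pi, by = dphi)
    rc <- .rasterise_path(point(phi))
  }
  if (nrow(rc) > 1 && all(rc[1, ] == rc[nrow(rc), ]))
    rc <- rc[-nrow(rc), , drop = FALSE]
  if (any(rc < 1 | rc > PATCH_N))
    abort("blob exceeds patch; reduce base_radius or amplitudes")
  .path_to_patch(rc, sprintf("blob base=%g axis=%g sym=%s seed=%d",
                             base_radius, axis_deg, mirror_symmetric, seed))
}

runif_seeded <- function(n, lo, hi, seed) {
  restore <- .preserve_rng_state()
  on.exit(restore())
  set.seed(as.integer(seed %% .Machine$integer.max))
  runif(n, lo, hi)
}

#' Generate a smoothed random open curve through the patch centre
#'
#' Emulates a single open natural contour: the heading of a unit-step walk
#' integrates a per-draw base curvature (signed, uniform on
#' `[0, 1.8/smoothness]`) plus smoothed Gaussian wiggle, and the walk is
#' laid through the patch centre in both directions, then clipped at the
#' patch border. Low `smoothness` gives tightly curved, often
#' self-enclosing curves; high `smoothness` approaches a straight line.
#' Cue indices vary widely over seeds, populating many stimulus classes.
#'
#' @param smoothness Positive scalar; default 6 spans the full convexity
#'   range used for stratification.
#' @param seed Integer seed; a fixed seed reproduces the patch exactly.
#' @param half_length Steps walked on each side of the centre.
#' @return A `contour_patch`.
#' @export
generate_open_curve <- function(smoothness = 6, seed = 1, half_length = 80) {
  if (smoothness <= 0) abort("smoothness must be positive")
  restore <- .preserve_rng_state()
  on.exit(restore())
  set.seed(as.integer(seed %% .Machine$integer.max))

  n <- 2 * half_length + 1
  kappa0 <- sample(c(-1, 1), 1) * runif(1, 0, 1.8 / smoothness)
  wig <- rnorm(n + 10, 0, 1.2 / smoothness)
  k <- 5L
  wig <- as.numeric(stats::filter(wig, rep(1 / k, k), sides = 2))
  wig <- wig[!is.na(wig)][seq_len(n)]
  heading <- runif(1, 0, 2 * pi) + cumsum(kappa0 + wig)

  dx <- cos(heading); dy <- sin(heading)
  x <- cumsum(dx); y <- cumsum(dy)
  # place step `half_length + 1` at the continuous patch centre
  x <- x - x[half_length + 1] + PATCH_CENTER
  y <- y - y[half_length + 1] - PATCH_CENTER
  rc <- .rasterise_path(cbind(x, y))
  .path_to_patch(rc, sprintf("open_curve smooth=%g seed=%d", smoothness, seed))
}

#' Simulated observer model
#'
#' Bundles the latent parameters of a simulated participant: feature
#' weights of the perceptual distance, the four cut points mapping latent
#' dissimilarity to the 5-point similarity scale (rating 5 = below the
#' first cut), the seven linear coefficients of the figure-ground choice
#' model, the latent Gaussian noise, and the seed.
#'
#' Default figure-ground weights plant the published regression pattern
#' (closure-dominated choices) so end-to-end recovery runs against a known
#' ground truth.
#'
#' @param similarity_weights Named non-negative weights on `convexity`,
#'   `closure`, `symmetry` distance components.
#' @param rating_thresholds Four strictly increasing cut points on latent
#'   dissimilarity.
#' @param fg_weights Seven named coefficients: `intercept`, `convexity`,
#'   `closure`, `symmetry`, `convexity_closure`, `convexity_symmetry`,
#'   `closure_symmetry`.
#' @param noise_sd Standard deviation of the latent per-trial noise.
#' @param seed Integer seed.
#' @param observer_id Label carried into simulated trial tables.
#' @return An `observer_model`.
#' @export
observer_model <- function(similarity_weights = c(convexity = 1, closure = 1,
                                                  symmetry = 1),
                           rating_thresholds = c(0.5, 1.25, 2.0, 3.0),
                           fg_weights = c(intercept = 0.490,
                                          convexity = -0.334,
                                          closure = 0.0755,
                                          symmetry = 0.0383,
                                          convexity_closure = -0.0200,
                                          convexity_symmetry = 0.282,
                                          closure_symmetry = 0.00557),
                           noise_sd = 0.3, seed = 1,
                           observer_id = "obs1") {
  if (length(rating_thresholds) != 4 || any(diff(rating_thresholds) <= 0))
    abort("rating_thresholds must be 4 strictly increasing cut points")
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  need <- c("intercept", "convexity", "closure", "symmetry",
            "convexity_closure", "convexity_symmetry", "closure_symmetry")
  if (!all(need %in% names(fg_weights)))
    abort(paste("fg_weights must name:", paste(need, collapse = ", ")))
  structure(list(similarity_weights = similarity_weights,
                 rating_thresholds = rating_thresholds,
                 fg_weights = fg_weights[need],
                 noise_sd = noise_sd,
                 seed = as.integer(seed),
                 observer_id = observer_id),
            class = "observer_model")
}

# z-scores that tolerate zero variance (all-equal column -> zeros)
.safe_z <- function(v) {
  s <- sd(v)
  if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
}

#' Simulate similarity-rating trials
#'
#' Latent dissimilarity of a stimulus pair is the weighted Euclidean
#' distance between their standardized cue vectors; per trial, Gaussian
#' noise is added and the result is cut at the observer's thresholds into
#' a 1-5 similarity rating (5 = most similar). All unordered pairs are
#' rated `n_repetitions` times.
#'
#' @param stimuli Cue tibble with `patch_id`, `convexity`, `closure`,
#'   `symmetry`.
#' @param model An [observer_model()].
#' @param n_repetitions Ratings per pair (design default 4).
#' @return Tibble: `observer_id`, `stimulus_a`, `stimulus_b`,
#'   `repetition`, `rating`.
#' @export
simulate_similarity <- function(stimuli, model, n_repetitions = 4) {
  stopifnot(inherits(model, "observer_model"))
  w <- model$similarity_weights
  z <- sapply(c("convexity", "closure", "symmetry"),
              function(f) .safe_z(stimuli[[f]]))
  pairs <- utils::combn(seq_len(nrow(stimuli)), 2)
  diff2 <- (z[pairs[1, ], , drop = FALSE] - z[pairs[2, ], , drop = FALSE])^2
  latent <- sqrt(as.numeric(
    diff2 %*% w[c("convexity", "closure", "symmetry")]))
  np <- ncol(pairs)
  restore <- .preserve_rng_state()
  on.exit(restore())
  set.seed(model$seed)
  out <- tidyr::expand_grid(pair = seq_len(np),
                            repetition = seq_len(n_repetitions))
  lat <- latent[out$pair] + rnorm(nrow(out), 0, model$noise_sd)
  tibble::tibble(observer_id = model$observer_id,
                 stimulus_a = stimuli$patch_id[pairs[1, out$pair]],
                 stimulus_b = stimuli$patch_id[pairs[2, out$pair]],
                 repetition = out$repetition,
                 rating = as.integer(5 - pmin(pmax(findInterval(
                   lat, model$rating_thresholds), 0), 4)))
}

# linear predictor of the clipped-linear figure-ground observer
.fg_linear_predictor <- function(stimuli, fg_weights) {
  with(stimuli,
       fg_weights[["intercept"]] +
         fg_weights[["convexity"]] * convexity +
         fg_weights[["closure"]] * closure +
         fg_weights[["symmetry"]] * symmetry +
         fg_weights[["convexity_closure"]] * convexity * closure +
         fg_weights[["convexity_symmetry"]] * convexity * symmetry +
         fg_weights[["closure_symmetry"]] * closure * symmetry)
}

#' Simulate 2AFC figure-direction trials
#'
#' The probability of choosing the convex side is the observer's linear
#' predictor on the cue vector (and pairwise products), clipped to
#' `[0, 1]`; each repetition is a Bernoulli draw. Answers are emitted in
#' the direction vocabulary of the patch's group: stimuli with tangents
#' within 30 degrees of vertical (orientation bins 1, 2, 7, 8) belong to
#' the vertical group and are answered left/right; the rest top/bottom.
#'
#' @param stimuli Cue tibble with `patch_id`, the three indices,
#'   `orientation_bin`, `normal_row`, `normal_col`, `degenerate`.
#' @param model An [observer_model()].
#' @param n_reps Repetitions per patch (design default 100); 0 gives an
#'   empty table.
#' @return Tibble: `observer_id`, `patch_id`, `repetition`, `group`,
#'   `answer`.
#' @export
simulate_fg <- function(stimuli, model, n_reps = 100) {
  stopifnot(inherits(model, "observer_model"))
  cols <- c("observer_id", "patch_id", "repetition", "group", "answer")
  if (n_reps == 0)
    return(tibble::as_tibble(setNames(
      list(character(), character(), integer(), character(), character()),
      cols)))
  st <- dplyr::filter(stimuli, !.data$degenerate)
  p <- pmin(pmax(.fg_linear_predictor(st, model$fg_weights), 0), 1)

  vertical <- st$orientation_bin %in% c(1L, 2L, 7L, 8L)
  group <- ifelse(vertical, "vertical", "horizontal")
  comp <- ifelse(vertical, st$normal_col, -st$normal_row)
  if (any(comp == 0)) abort("convex normal orthogonal to the answer axis")
  convex_word <- ifelse(vertical,
                        ifelse(comp > 0, "right", "left"),
                        ifelse(comp > 0, "top", "bottom"))
  other_word <- ifelse(vertical,
                       ifelse(comp > 0, "left", "right"),
                       ifelse(comp > 0, "bottom", "top"))

  restore <- .preserve_rng_state()
  on.exit(restore())
  set.seed(.sub_seed(model$seed, 1))
  out <- tidyr::expand_grid(i = seq_len(nrow(st)), repetition = seq_len(n_reps))
  chose <- rbinom(nrow(out), 1, p[out$i]) == 1
  tibble::tibble(observer_id = model$observer_id,
                 patch_id = st$patch_id[out$i],
                 repetition = out$repetition,
                 group = group[out$i],
                 answer = ifelse(chose, convex_word[out$i], other_word[out$i]))
}
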