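# Mirror-overlap machinery
# ------------------------
# The degree of symmetry (dos) of a patch about a candidate axis is the
# number of contour pixels that coincide with their mirror image about the
# axis, divided by the contour length. Candidate axes are generated by
# rotating the patch raster by theta about its centre and translating it by
# x columns, after which the axis is the central vertical column. Rotation
# is nearest-neighbour on the sparse pixel coordinates; to absorb
# rasterisation jitter both images are (optionally) dilated by a radius-1
# disc (the 5-point cross) before the overlap; the normalising length is
# always the pre-dilation contour pixel count.

# Rotated, rounded, deduplicated, canvas-clipped pixel set for one theta.
# Returns integer matrix (row, col); dilation applied when requested.
.rotated_set <- function(px, theta, dilate) {
  a <- theta * pi / 180
  u <- px[, 1] - PATCH_CENTER
  v <- px[, 2] - PATCH_CENTER
  rr <- round(u * cos(a) - v * sin(a)) + PATCH_CENTER
  cc <- round(u * sin(a) + v * cos(a)) + PATCH_CENTER
  keep <- rr >= 1 & rr <= PATCH_N & cc >= 1 & cc <= PATCH_N
  rr <- rr[keep]; cc <- cc[keep]
  id <- unique((cc - 1) * PATCH_N + rr)
  if (dilate && length(id)) {
    rr0 <- ((id - 1) %% PATCH_N) + 1
    cc0 <- ((id - 1) %/% PATCH_N) + 1
    dr <- c(0, 1, -1, 0, 0); dc <- c(0, 0, 0, 1, -1)
    rr1 <- rep(rr0, each = 5) + dr
    cc1 <- rep(cc0, each = 5) + dc
    keep <- rr1 >= 1 & rr1 <= PATCH_N & cc1 >= 1 & cc1 <= PATCH_N
    id <- unique((cc1[keep] - 1) * PATCH_N + rr1[keep])
  }
  cbind(row = ((id - 1) %% PATCH_N) + 1, col = ((id - 1) %/% PATCH_N) + 1)
}

# Mirror-overlap count of a pixel set shifted by x columns: number of
# pixels (r, c + x) inside the canvas whose mirror (r, 70 - c - x) is also
# present.
.overlap_at_shift <- function(set, x) {
  cc <- set[, 2] + x
  keep <- cc >= 1 & cc <= PATCH_N
  r <- set[keep, 1]; c <- cc[keep]
  id <- (c - 1) * PATCH_N + r
  mid <- (PATCH_N - c) * PATCH_N + r  # mirror column is 70 - c
  sum(mid %in% id)
}

#' Degree of symmetry about one candidate axis
#'
#' Evaluates the mirror overlap of a patch for the axis obtained by
#' rotating the patch by `theta` about its centre and translating by `x`
#' columns (the axis is then the central vertical column). The overlap
#' count is divided by the contour length of the patch.
#'
#' @param patch A `contour_patch` with at least one contour pixel.
#' @param theta Axis rotation in degrees.
#' @param x Axis translation in pixels (columns).
#' @param dilate Dilate both images by a radius-1 disc before the overlap
#'   (default); disable for exact-arithmetic checks.
#' @return Non-negative scalar.
#' @export
dos <- function(patch, theta, x, dilate = TRUE) {
  stopifnot(inherits(patch, "contour_patch"))
  len <- sum(patch$grid)
  if (len == 0) abort("no contour")
  px <- which(patch$grid == 1L, arr.ind = TRUE)
  set <- .rotated_set(px, theta, dilate)
  .overlap_at_shift(set, as.integer(x)) / len
}

#' Exhaustive search for the optimal symmetry axis
#'
#' Evaluates [dos()] over the full grid `theta = 0, 1, ..., 179` degrees
#' and `x = -34, ..., 34` pixels and returns the argmax. Ties are broken by
#' the smallest `theta`, then the smallest `x`, so the search is
#' deterministic.
#'
#' For each `theta` the overlap is accumulated for all shifts at once: a
#' pair of same-row pixels with columns `c1, c2` is mirror-matched exactly
#' at the shift `x = (70 - c1 - c2) / 2`, so tabulating ordered pair sums
#' row by row yields the whole `x` profile of one rotation.
#'
#' @inheritParams dos
#' @return A `symmetry_search` object: list with `theta_star`, `x_star`,
#'   `dos_star`, `length` (contour pixel count).
#' @export
optimal_axis <- function(patch, dilate = TRUE) {
  stopifnot(inherits(patch, "contour_patch"))
  len <- sum(patch$grid)
  if (len == 0) abort("no contour")
  px <- which(patch$grid == 1L, arr.ind = TRUE)

  best <- c(theta = 0, x = -PATCH_HALF, count = -1)
  xs <- (-PATCH_HALF):PATCH_HALF
  for (theta in 0:179) {
    set <- .rotated_set(px, theta, dilate)
    counts <- integer(PATCH_N)  # index = x + 35
    for (w in split(set[, 2], set[, 1])) {
      s <- outer(w, w, "+")
      cmin <- outer(w, w, pmin)
      cmax <- outer(w, w, pmax)
      even <- s %% 2 == 0
      xv <- (2 * PATCH_CENTER - s) / 2
      ok <- even & xv >= -PATCH_HALF & xv <= PATCH_HALF &
        (cmin + xv) >= 1 & (cmax + xv) <= PATCH_N
      if (any(ok)) {
        add <- tabulate(xv[ok] + PATCH_CENTER, nbins = PATCH_N)
        counts <- counts + add
      }
    }
    # earliest (theta, x) wins on ties: strict improvement only
    mx <- max(counts)
    if (mx > best[["count"]]) {
      best <- c(theta = theta, x = xs[which.max(counts)], count = mx)
    }
  }
  structure(list(theta_star = as.numeric(best[["theta"]]),
                 x_star = as.numeric(best[["x"]]),
                 dos_star = best[["count"]] / len,
                 length = len),
            class = "symmetry_search")
}

#' @export
print.symmetry_search <- function(x, ...) {
  cat(sprintf("<symmetry_search> theta* = %g deg, x* = %g px, dos* = %.4f (length %d)\n",
              x$theta_star, x$x_star, x$dos_star, x$length))
  invisible(x)
}

# Sample the optimal axis inside the patch square and split its length into
# convex-side and concave-side totals. Samples closer than `contact` px to
# the contour are treated as axis/contour intersections and dropped; each
# remaining sample is labelled by the side of the nearest contour pixel it
# lies on (sign of the dot product with the convex normal).
.axis_side_lengths <- function(patch, frame, theta, x, step = 0.25,
                               contact = 0.75) {
  a <- theta * pi / 180
  nvec <- c(sin(a), cos(a))        # axis normal in centred (row, col) space
  dvec <- c(cos(a), -sin(a))       # axis direction
  p0 <- -x * nvec                  # point on axis (centred coords)
  # clip the line p0 + t * dvec to the square [-34.5, 34.5]^2
  tr <- c(-Inf, Inf)
  for (k in 1:2) {
    if (abs(dvec[k]) < 1e-12) {
      if (abs(p0[k]) > PATCH_HALF + 0.5) return(c(convex = 0, concave = 0))
    } else {
      t1 <- (-(PATCH_HALF + 0.5) - p0[k]) / dvec[k]
      t2 <- ((PATCH_HALF + 0.5) - p0[k]) / dvec[k]
      tr <- c(max(tr[1], min(t1, t2)), min(tr[2], max(t1, t2)))
    }
  }
  if (tr[1] >= tr[2]) return(c(convex = 0, concave = 0))
  t <- seq(tr[1], tr[2], by = step)
  pts <- cbind(p0[1] + t * dvec[1], p0[2] + t * dvec[2])

  px <- which(patch$grid == 1L, arr.ind = TRUE)
  pc <- cbind(px[, 1] - PATCH_CENTER, px[, 2] - PATCH_CENTER)
  d2 <- outer(pts[, 1], pc[, 1], "-")^2 + outer(pts[, 2], pc[, 2], "-")^2
  nearest <- max.col(-d2, ties.method = "first")
  mind <- sqrt(d2[cbind(seq_len(nrow(pts)), nearest)])
  keep <- mind > contact
  if (!any(keep)) return(c(convex = 0, concave = 0))
  rel <- pts[keep, , drop = FALSE] - pc[nearest[keep], , drop = FALSE]
  side <- rel[, 1] * frame$convex_normal[["row"]] +
    rel[, 2] * frame$convex_normal[["col"]]
  c(convex = step * sum(side > 0), concave = step * sum(side < 0))
}

#' Signed, corpus-normalised symmetry index
#'
#' The magnitude is the patch's maximal dos divided by the largest dos in
#' the working corpus, so the corpus-maximum patch scores 1. The sign is
#' negative when the optimal axis runs mainly through the concave side:
#' the axis clipped to the patch square is split at its contacts with the
#' contour and each piece is labelled convex or concave by the side of the
#' contour it lies on; the index is negated iff the convex-side total
#' length is strictly shorter.
#'
#' @param patch A `contour_patch`.
#' @param frame Its `local_frame` (supplies the convex normal).
#' @param corpus_max_dos Largest `dos_star` over the corpus being analysed;
#'   must be positive.
#' @param search Optional precomputed [optimal_axis()] result.
#' @param dilate Passed to [optimal_axis()] when `search` is missing.
#' @return Signed scalar in `[-1, 1]`.
#' @export
symmetry_index <- function(patch, frame, corpus_max_dos, search = NULL,
                           dilate = TRUE) {
  if (!is.numeric(corpus_max_dos) || corpus_max_dos <= 0)
    abort("corpus_max_dos must be positive")
  if (is.null(search)) search <- optimal_axis(patch, dilate = dilate)
  magnitude <- search$dos_star / corpus_max_dos
  sides <- .axis_side_lengths(patch, frame, search$theta_star, search$x_star)
  if (sides[["convex"]] < sides[["concave"]]) -magnitude else magnitude
}
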