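#' Convexity index
#'
#' Convexity of a patch is `log(1 + |rho|)` (natural log), where `rho` is
#' the curvature magnitude at the patch centre estimated over the 41-pixel
#' chain window. Always non-negative; zero for a straight contour.
#'
#' @param frame A `local_frame` from [local_frame()].
#' @return Non-negative scalar.
#' @examples
#' log1p(0.05)  # value for a circle of radius 20 px
#' @export
convexity <- function(frame) {
  stopifnot(inherits(frame, "local_frame"))
  log1p(abs(frame$rho))
}

# Ray/axis-aligned-box crossing test, vectorised over pixel squares.
# p = c(x, y) ray origin, d = c(dx, dy) unit direction, sq = matrix with
# columns xlo, xhi, ylo, yhi. Returns TRUE if the ray (t >= 0) meets any
# square.
.ray_hits_any <- function(p, d, sq) {
  slab <- function(lo, hi, p1, d1) {
    if (abs(d1) < 1e-12) {
      inside <- p1 >= lo & p1 <= hi
      cbind(ifelse(inside, -Inf, Inf), ifelse(inside, Inf, -Inf))
    } else {
      t1 <- (lo - p1) / d1; t2 <- (hi - p1) / d1
      cbind(pmin(t1, t2), pmax(t1, t2))
    }
  }
  tx <- slab(sq[, 1], sq[, 2], p[1], d[1])
  ty <- slab(sq[, 3], sq[, 4], p[2], d[2])
  tenter <- pmax(tx[, 1], ty[, 1], 0)
  texit <- pmin(tx[, 2], ty[, 2])
  any(tenter <= texit)
}

# Count, among 16 radial rays from probe point p (math coords), how many
# cross at least one contour pixel of the patch. Directions are
# phi0 + k * 22.5 deg, k = 0..15; each ray counts at most once.
.ray_crossings <- function(p, phi0, sq) {
  ang <- (phi0 + (0:(CLOSURE_N_RAYS - 1)) * CLOSURE_STEP_DEG) * pi / 180
  sum(vapply(ang, function(a) .ray_hits_any(p, c(cos(a), sin(a)), sq),
             logical(1)))
}

# Pixel squares (math coords) for all contour pixels of a patch grid.
.pixel_squares <- function(grid) {
  px <- which(grid == 1L, arr.ind = TRUE)
  cbind(xlo = px[, 2] - 0.5, xhi = px[, 2] + 0.5,
        ylo = -px[, 1] - 0.5, yhi = -px[, 1] + 0.5)
}

#' Closure index
#'
#' Places two probe points 5 px from the patch centre along the contour
#' normal, one on the convex side and one on the concave side, casts 16
#' radial rays (22.5-degree increments, the first along the convex normal)
#' from each probe, and counts for each probe how many rays cross the
#' contour anywhere inside the patch (each ray at most once). Closure is
#' `N_convex - N_concave`, positive when the convex side is the more
#' enclosed one. Range is `-16 ... 16`.
#'
#' @param patch A `contour_patch`.
#' @param frame Its `local_frame`. For a degenerate (straight) frame the
#'   default left-of-traversal normal labels the sides.
#' @return Integer in `[-16, 16]`.
#' @export
closure <- function(patch, frame) {
  stopifnot(inherits(patch, "contour_patch"), inherits(frame, "local_frame"))
  sq <- .pixel_squares(patch$grid)
  nx <- frame$convex_normal[["col"]]
  ny <- -frame$convex_normal[["row"]]
  ctr <- c(PATCH_CENTER, -PATCH_CENTER)
  p_convex <- ctr + CLOSURE_OFFSET * c(nx, ny)
  p_concave <- ctr - CLOSURE_OFFSET * c(nx, ny)
  half <- PATCH_HALF + 0.5
  if (any(abs(p_convex - ctr) > half) || any(abs(p_concave - ctr) > half))
    abort("probe point outside patch")
  phi0 <- atan2(ny, nx) * 180 / pi
  n_convex <- .ray_crossings(p_convex, phi0, sq)
  n_concave <- .ray_crossings(p_concave, phi0, sq)
  as.integer(n_convex - n_concave)
}
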