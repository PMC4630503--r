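# Internal coordinate conventions
# -------------------------------
# Pixels are (row, col), 1-based, row increasing downward. For angles and
# vector geometry we use a math frame x = col, y = -row (y up), so that
# 0 deg = vertical matches the tangent-angle convention of the cue measures.

# (row, col) matrix -> (x, y) math coordinates
.to_xy <- function(rc) cbind(x = rc[, 2], y = -rc[, 1])

# math direction (dx, dy) -> tangent angle from vertical in [0, 180)
.tangent_angle <- function(dx, dy) {
  (90 - atan2(dy, dx) * 180 / pi) %% 180
}

# Extract the m-pixel chain window centred on the centre pixel, wrapping
# around for closed chains (first and last pixel 8-adjacent).
.chain_window <- function(chain, half = FRAME_HALF) {
  idx <- which(chain[, 1] == PATCH_CENTER & chain[, 2] == PATCH_CENTER)[1]
  n <- nrow(chain)
  closed <- n >= 3 &&
    max(abs(chain[1, ] - chain[n, ])) <= 1 &&
    !all(chain[1, ] == chain[n, ])
  want <- (idx - half):(idx + half)
  if (closed && n >= 2 * half + 1) {
    want <- ((want - 1) %% n) + 1
  } else if (min(want) < 1 || max(want) > n) {
    abort("insufficient contour support")
  }
  chain[want, , drop = FALSE]
}

# Taubin algebraic least-squares circle fit. The naive (Kasa) algebraic fit
# collapses to a tiny circle on near-straight rasterized windows, so the
# Taubin normalization is required here. Returns list(center = c(x, y),
# radius) in math coordinates, or NULL in the straight-line limit.
.fit_circle <- function(xy) {
  mu <- colMeans(xy)
  X <- xy[, 1] - mu[1]; Y <- xy[, 2] - mu[2]
  Z <- X^2 + Y^2
  Zm <- mean(Z)
  if (Zm <= 0) return(NULL)
  Z0 <- (Z - Zm) / (2 * sqrt(Zm))
  sv <- svd(cbind(Z0, X, Y))
  A <- sv$v[, 3]
  A1 <- A[1] / (2 * sqrt(Zm))
  A4 <- -Zm * A1
  if (abs(A1) < 1e-12) return(NULL)  # straight line: infinite radius
  ctr <- -A[2:3] / A1 / 2 + mu
  r2 <- (A[2]^2 + A[3]^2 - 4 * A1 * A4) / (4 * A1^2)
  if (!is.finite(r2) || r2 <= 0) return(NULL)
  list(center = c(ctr[1], ctr[2]), radius = sqrt(r2))
}

#' Local frame at the centre of a patch
#'
#' Estimates the tangent angle, the magnitude of curvature, and the convex
#' side at the patch centre from the 41 chain pixels centred there. The
#' tangent comes from a total-least-squares line fit (principal direction of
#' the window); curvature is the reciprocal radius of a least-squares circle
#' fit to the same window. The convex side is the side of the tangent on
#' which the fitted (osculating) circle centre lies: `convex_normal` is the
#' unit perpendicular of the tangent, signed toward that circle centre. When the window
#' is straight (`rho < rho_tol`) the frame is flagged degenerate and the
#' convex normal defaults to the left of the chain's traversal direction.
#'
#' @param patch A `contour_patch` whose chain extends at least 20 pixels to
#'   each side of the centre (closed chains wrap around).
#' @param rho_tol Curvature magnitude (1/px) below which the frame is
#'   treated as straight.
#' @return A `local_frame`: list with `tangent_deg` in `[0, 180)`
#'   (0 = vertical), `rho` (1/px, non-negative), `convex_normal` (unit
#'   `(row, col)` vector) and `degenerate` flag.
#' @examples
#' p <- generate_arc(radius = 20, arc_extent = 150, orientation = 0)
#' f <- local_frame(p)
#' abs(f$rho - 1 / 20) < 0.01
#' @export
local_frame <- function(patch, rho_tol = RHO_TOL) {
  stopifnot(inherits(patch, "contour_patch"))
  win <- .chain_window(patch$chain)
  xy <- .to_xy(win)
  ctr_xy <- c(x = PATCH_CENTER, y = -PATCH_CENTER)

  # tangent: principal direction of the centred window (TLS line fit)
  mu <- colMeans(xy)
  cen <- sweep(xy, 2, mu)
  ev <- eigen(crossprod(cen), symmetric = TRUE)
  dirv <- ev$vectors[, 1]
  tangent_deg <- .tangent_angle(dirv[1], dirv[2])

  # traversal direction at the centre (for the degenerate default)
  m <- nrow(win)
  trav <- .to_xy(win[m, , drop = FALSE]) - .to_xy(win[1, , drop = FALSE])
  trav <- trav / sqrt(sum(trav^2))

  fit <- .fit_circle(xy)
  rho <- if (is.null(fit)) 0 else 1 / fit$radius
  degenerate <- rho < rho_tol

  if (degenerate) {
    # left of traversal: rotate traversal direction +90 deg in math frame
    nx <- -trav[2]; ny <- trav[1]
  } else {
    # unit perpendicular of the fitted tangent, signed toward the
    # osculating-circle centre (keeps the normal exactly orthogonal to the
    # tangent even when rasterization tilts the window)
    n0 <- c(-dirv[2], dirv[1])
    v <- fit$center - c(ctr_xy[["x"]], ctr_xy[["y"]])
    s <- sign(sum(n0 * v))
    if (s == 0) s <- 1
    nx <- s * n0[1]; ny <- s * n0[2]
  }
  # back to (row, col): drow = -dy, dcol = dx
  structure(list(tangent_deg = as.numeric(tangent_deg),
                 rho = as.numeric(rho),
                 convex_normal = c(row = as.numeric(-ny), col = as.numeric(nx)),
                 degenerate = degenerate),
            class = "local_frame")
}

#' @export
print.local_frame <- function(x, ...) {
  cat(sprintf("<local_frame> tangent %.1f deg, rho %.4f /px%s\n",
              x$tangent_deg, x$rho, if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Orientation bin of a tangent angle
#'
#' Classifies a tangent angle (0 = vertical) into the eight unequal-width
#' orientation bins used for stimulus stratification: 0-15, 15-30, 30-60,
#' 60-90, 90-120, 120-150, 150-165 and 165-180 degrees. Intervals are
#' half-open, lower-inclusive.
#'
#' @param tangent_deg Angle(s) in `[0, 180)`.
#' @return Integer bin index in `1..8` (vectorised).
#' @examples
#' orientation_bin(c(0, 10, 100))
#' @export
orientation_bin <- function(tangent_deg) {
  if (any(tangent_deg < 0 | tangent_deg >= 180))
    abort("tangent angle outside [0, 180)")
  breaks <- c(0, 15, 30, 60, 90, 120, 150, 165, 180)
  as.integer(findInterval(tangent_deg, breaks, left.open = FALSE))
}
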