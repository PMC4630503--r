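# Independent oracles and fixture builders for the test suite. These
# deliberately use different algorithms from the package internals.

# --- connected-component pixel counts (BFS flood fill, 8-connectivity) ----
component_sizes <- function(grid) {
  nr <- nrow(grid); nc <- ncol(grid)
  lab <- matrix(0L, nr, nc)
  sizes <- integer(0)
  nxt <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (grid[r0, c0] == 1L && lab[r0, c0] == 0L) {
      nxt <- nxt + 1L
      queue <- list(c(r0, c0)); lab[r0, c0] <- nxt; n <- 0L
      while (length(queue)) {
        p <- queue[[1]]; queue[[1]] <- NULL; n <- n + 1L
        for (dr in -1:1) for (dc in -1:1) {
          rr <- p[1] + dr; cc <- p[2] + dc
          if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
              grid[rr, cc] == 1L && lab[rr, cc] == 0L) {
            lab[rr, cc] <- nxt
            queue[[length(queue) + 1L]] <- c(rr, cc)
          }
        }
      }
      sizes[nxt] <- n
    }
  }
  sizes
}

# --- ray-casting oracle for Closure ---------------------------------------
# A ray from p (math coords x, y) in direction d crosses a pixel square iff
# p lies inside the square or the ray intersects one of its four edges.
# Ray-segment intersections are computed with cross products, a different
# route from the package's slab test.
.ray_seg_hit <- function(p, d, q1, q2) {
  s <- q2 - q1
  denom <- d[1] * s[2] - d[2] * s[1]
  w <- q1 - p
  if (abs(denom) < 1e-14) return(FALSE)  # parallel: grazing is measure-zero
  t <- (w[1] * s[2] - w[2] * s[1]) / denom
  u <- (w[1] * d[2] - w[2] * d[1]) / denom
  t >= 0 && u >= 0 && u <= 1
}

.ray_square_hit_oracle <- function(p, d, xlo, xhi, ylo, yhi) {
  if (p[1] >= xlo && p[1] <= xhi && p[2] >= ylo && p[2] <= yhi) return(TRUE)
  corners <- list(c(xlo, ylo), c(xhi, ylo), c(xhi, yhi), c(xlo, yhi))
  edges <- list(c(1, 2), c(2, 3), c(3, 4), c(4, 1))
  for (e in edges) {
    if (.ray_seg_hit(p, d, corners[[e[1]]], corners[[e[2]]])) return(TRUE)
  }
  FALSE
}

closure_oracle <- function(patch, frame) {
  px <- which(patch$grid == 1L, arr.ind = TRUE)
  nx <- frame$convex_normal[["col"]]; ny <- -frame$convex_normal[["row"]]
  ctr <- c(35, -35)
  probes <- list(convex = ctr + 5 * c(nx, ny), concave = ctr - 5 * c(nx, ny))
  phi0 <- atan2(ny, nx)
  counts <- vapply(probes, function(p) {
    hits <- 0L
    for (k in 0:15) {
      a <- phi0 + k * 22.5 * pi / 180
      d <- c(cos(a), sin(a))
      crossed <- FALSE
      for (i in seq_len(nrow(px))) {
        if (.ray_square_hit_oracle(p, d,
                                   px[i, 2] - 0.5, px[i, 2] + 0.5,
                                   -px[i, 1] - 0.5, -px[i, 1] + 0.5)) {
          crossed <- TRUE; break
        }
      }
      if (crossed) hits <- hits + 1L
    }
    hits
  }, integer(1))
  as.integer(counts[["convex"]] - counts[["concave"]])
}

# --- brute-force Procrustes by numerical optimization ----------------------
# Aligns T onto P over translation, rotation angle, scale and both
# reflection branches by general-purpose optimization (2D only).
procrustes_error_oracle <- function(P, T_) {
  P <- as.matrix(P); T_ <- as.matrix(T_)
  obj <- function(par, refl) {
    th <- par[1]; s <- exp(par[2]); tr <- par[3:4]
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    if (refl) R <- R %*% diag(c(-1, 1))
    A <- s * T_ %*% R
    sum((P - sweep(A, 2, -tr))^2)
  }
  best <- Inf
  for (refl in c(FALSE, TRUE)) {
    for (th0 in c(0, pi / 2, pi, 3 * pi / 2)) {
      o <- optim(c(th0, 0, 0, 0), obj, refl = refl,
                 method = "BFGS", control = list(maxit = 500, reltol = 1e-14))
      best <- min(best, o$value)
    }
  }
  best
}

# --- misc fixtures ---------------------------------------------------------
vertical_line_map <- function(nr = 101, nc = 101, col = 51) {
  g <- matrix(0L, nr, nc); g[, col] <- 1L
  contour_map(g, "vline fixture")
}

# a pool of valid random open-curve patches (frame computable, no X-junction)
random_patch_pool <- function(n, seed0) {
  out <- list(); s <- 0
  while (length(out) < n) {
    s <- s + 1
    p <- generate_open_curve(seed = seed0 + s)
    f <- tryCatch(local_frame(p), error = function(e) NULL)
    if (is.null(f) || has_x_junction(p)) next
    out[[sprintf("p%03d", length(out) + 1)]] <- p
  }
  out
}

# random in-range cue tibble for analysis-level tests
random_cue_table <- function(n, seed, closure_max = 8L) {
  withr::with_seed(seed, {
    ang <- runif(n, 0, 2 * pi)
    tibble::tibble(
      patch_id = sprintf("p%02d", seq_len(n)),
      convexity = runif(n, 0, 0.25),
      closure = as.integer(sample(seq(-closure_max, closure_max), n, TRUE)),
      symmetry = runif(n, -1, 1),
      orientation_bin = sample(1:8, n, TRUE),
      normal_row = sin(ang),
      normal_col = cos(ang),
      degenerate = FALSE
    )
  })
}
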