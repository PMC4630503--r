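#' Construct a contour patch
#'
#' A patch is a 69 x 69 binary window cut from a contour map, centred on a
#' contour pixel (row 35, column 35, 1-based), together with the ordered
#' chain of contour pixels passing through the centre.
#'
#' @param grid 69 x 69 binary matrix with `grid[35, 35] == 1`.
#' @param chain Integer `m x 2` matrix of (row, col) patch coordinates,
#'   8-connected and containing the centre.
#' @param provenance Free-text origin tag.
#' @return A `contour_patch` object.
#' @export
contour_patch <- function(grid, chain, provenance = "unspecified") {
  grid <- matrix(as.integer(grid != 0), nrow(grid), ncol(grid))
  if (nrow(grid) != PATCH_N || ncol(grid) != PATCH_N)
    abort(sprintf("patch grid must be %d x %d", PATCH_N, PATCH_N))
  if (grid[PATCH_CENTER, PATCH_CENTER] != 1L)
    abort("centre pixel is not on a contour")
  chain <- matrix(as.integer(chain), ncol = 2,
                  dimnames = list(NULL, c("row", "col")))
  if (!any(chain[, 1] == PATCH_CENTER & chain[, 2] == PATCH_CENTER))
    abort("chain does not contain the centre pixel")
  structure(list(grid = grid,
                 center = c(row = PATCH_CENTER, col = PATCH_CENTER),
                 chain = chain,
                 provenance = as.character(provenance)[1]),
            class = "contour_patch")
}

#' @export
print.contour_patch <- function(x, ...) {
  cat(sprintf("<contour_patch> %d contour px, chain length %d, provenance: %s\n",
              sum(x$grid), nrow(x$chain), x$provenance))
  invisible(x)
}

#' Extract a 69 x 69 patch around a contour pixel
#'
#' Cuts the window `center_row - 34 ... center_row + 34` (and likewise for
#' columns) out of a contour map. The chain stored with the patch is the
#' maximal contiguous run, inside the window, of the traced chain passing
#' through the centre pixel.
#'
#' @param map A `contour_map`.
#' @param center Length-2 integer vector `(row, col)`, 1-based; must be a
#'   contour pixel, and the window must fit inside the map.
#' @param chains Optional pre-traced chain list from [trace_contours()]
#'   (re-traced if missing).
#' @return A `contour_patch`.
#' @export
extract_patch <- function(map, center, chains = NULL) {
  stopifnot(inherits(map, "contour_map"))
  r <- as.integer(center[1]); c <- as.integer(center[2])
  nr <- nrow(map$grid); nc <- ncol(map$grid)
  if (r < 1 || r > nr || c < 1 || c > nc || map$grid[r, c] != 1L)
    abort("center not on contour")
  if (r - PATCH_HALF < 1 || r + PATCH_HALF > nr ||
      c - PATCH_HALF < 1 || c + PATCH_HALF > nc)
    abort("patch exceeds map")
  rows <- (r - PATCH_HALF):(r + PATCH_HALF)
  cols <- (c - PATCH_HALF):(c + PATCH_HALF)
  grid <- map$grid[rows, cols]

  if (is.null(chains)) chains <- trace_contours(map)
  hit <- which(vapply(chains, function(ch) any(ch[, 1] == r & ch[, 2] == c),
                      logical(1)))
  if (length(hit) == 0) abort("center pixel not reached by any traced chain")
  ch <- chains[[hit[1]]]
  # to patch coordinates
  pr <- ch[, 1] - r + PATCH_CENTER
  pc <- ch[, 2] - c + PATCH_CENTER
  inside <- pr >= 1 & pr <= PATCH_N & pc >= 1 & pc <= PATCH_N
  idx <- which(pr == PATCH_CENTER & pc == PATCH_CENTER)[1]
  # maximal contiguous inside-run containing the centre index
  lo <- idx; while (lo > 1 && inside[lo - 1]) lo <- lo - 1
  hi <- idx; while (hi < length(inside) && inside[hi + 1]) hi <- hi + 1
  chain <- cbind(row = pr[lo:hi], col = pc[lo:hi])
  contour_patch(grid, chain,
                provenance = sprintf("%s @(%d,%d)", map$provenance, r, c))
}

#' Rotate a patch by a multiple of 90 degrees
#'
#' Exact lattice rotation about the patch centre (used mainly to check the
#' rotation invariances of the cue measures).
#'
#' @param patch A `contour_patch`.
#' @param k Number of counterclockwise quarter turns (0-3).
#' @return A `contour_patch`.
#' @export
rotate_patch_90 <- function(patch, k = 1L) {
  k <- as.integer(k) %% 4L
  g <- patch$grid; ch <- patch$chain
  for (i in seq_len(k)) {
    # counterclockwise: new(row, col) = (N + 1 - col, row)
    g <- t(g)[PATCH_N:1, , drop = FALSE]
    ch <- cbind(row = PATCH_N + 1L - ch[, 2], col = ch[, 1])
  }
  contour_patch(g, ch, provenance = paste0(patch$provenance, sprintf(" rot%d", 90L * k)))
}

#' Mirror a patch left-right
#'
#' Reflects grid and chain about the central column.
#'
#' @param patch A `contour_patch`.
#' @return A `contour_patch`.
#' @export
mirror_patch <- function(patch) {
  g <- patch$grid[, PATCH_N:1, drop = FALSE]
  ch <- cbind(row = patch$chain[, 1], col = PATCH_N + 1L - patch$chain[, 2])
  contour_patch(g, ch, provenance = paste0(patch$provenance, " mirrored"))
}

#' Export a patch as PNG with a JSON sidecar
#'
#' Writes the binary patch raster as an 8-bit PNG and a `.json` sidecar
#' recording the centre, chain length and provenance.
#'
#' @param patch A `contour_patch`.
#' @param path PNG path; the sidecar replaces the extension with `.json`.
#' @return `path`, invisibly.
#' @export
write_patch <- function(patch, path) {
  png::writePNG(patch$grid + 0, path)
  side <- sub("\\.png$", ".json", path, ignore.case = TRUE)
  jsonlite::write_json(
    list(center = unname(patch$center), chain_length = nrow(patch$chain),
         provenance = patch$provenance),
    side, auto_unbox = TRUE)
  invisible(path)
}
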