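#' Detect X-junctions in a patch
#'
#' A patch contains an X-junction when two contours cross, i.e. some
#' contour pixel has four or more chain branches leaving it. Branches are
#' counted as connected runs of contour pixels around the 8-neighbourhood
#' ring, so T-junctions (three branches) and simple curves (two) do not
#' count. Assumes thin (1-pixel) contours, as produced by the tracers and
#' generators here; thicker input should be thinned upstream.
#'
#' @param patch A `contour_patch` (or a bare binary matrix).
#' @return Logical scalar.
#' @examples
#' g <- matrix(0L, 69, 69); g[35, ] <- 1L; g[, 35] <- 1L
#' has_x_junction(g)
#' @export
has_x_junction <- function(patch) {
  g <- if (inherits(patch, "contour_patch")) patch$grid else patch
  px <- which(g == 1L, arr.ind = TRUE)
  if (nrow(px) == 0) return(FALSE)
  nr <- nrow(g); nc <- ncol(g)
  # ring of 8 neighbours in circular order
  ring <- cbind(dr = c(-1, -1, -1, 0, 1, 1, 1, 0),
                dc = c(-1, 0, 1, 1, 1, 0, -1, -1))
  for (i in seq_len(nrow(px))) {
    r <- px[i, 1]; c <- px[i, 2]
    rr <- r + ring[, 1]; cc <- c + ring[, 2]
    on <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    v <- integer(8)
    v[on] <- g[cbind(rr[on], cc[on])]
    if (sum(v) < 4) next
    # number of connected runs of 1s around the circular ring
    runs <- sum(v == 1 & c(v[8], v[1:7]) == 0)
    if (runs >= 4) return(TRUE)
  }
  FALSE
}

# Bin edges printed for the stratification: outer convexity bins
# [0, 0.018) and [0.222, 0.258], three equal-width interior bins between;
# closure bins [-8,-6), [-6,-2), [-2,2], (2,6], (6,8].
.convexity_edges <- function() {
  inner <- seq(0.018, 0.222, length.out = 4)
  c(0, inner, 0.258)
}

.closure_bin <- function(cl) {
  dplyr::case_when(
    cl < -8 | cl > 8 ~ NA_integer_,
    cl < -6 ~ 1L,
    cl < -2 ~ 2L,
    cl <= 2 ~ 3L,
    cl <= 6 ~ 4L,
    TRUE ~ 5L
  )
}

.convexity_bin <- function(cv) {
  e <- .convexity_edges()
  out <- rep(NA_integer_, length(cv))
  inr <- !is.na(cv) & cv >= 0 & cv <= 0.258
  # half-open lower-inclusive, top bin closed at 0.258
  b <- findInterval(cv[inr], e, rightmost.closed = TRUE)
  out[inr] <- as.integer(pmin(b, 5L))
  out
}

#' Assign stimulus classes
#'
#' Maps each cue vector to one of the 200 stratification classes (5
#' convexity bins x 5 closure bins x 8 orientation bins). Convexity values
#' outside `[0, 0.258]` or closure outside `[-8, 8]` are unbinned (`NA`
#' class).
#'
#' @param cues Tibble with columns `convexity`, `closure`,
#'   `orientation_bin` (e.g. from [compute_cues()]).
#' @return The input with columns `convexity_bin`, `closure_bin` and
#'   `class_id` (string `"cv-cl-or"`, `NA` when unbinned) appended.
#' @examples
#' assign_class(tibble::tibble(convexity = 0.01, closure = -7L,
#'                             orientation_bin = 1L))
#' @export
assign_class <- function(cues) {
  stopifnot(all(c("convexity", "closure", "orientation_bin") %in% names(cues)))
  out <- dplyr::mutate(
    cues,
    convexity_bin = .convexity_bin(.data$convexity),
    closure_bin = .closure_bin(.data$closure),
    class_id = dplyr::if_else(
      is.na(.data$convexity_bin) | is.na(.data$closure_bin),
      NA_character_,
      paste(.data$convexity_bin, .data$closure_bin, .data$orientation_bin,
            sep = "-"))
  )
  tibble::as_tibble(out)
}

#' Stratified one-per-class stimulus selection
#'
#' Draws exactly one member uniformly at random from every non-empty class
#' of a classified pool. Empty classes are skipped (natural contour corpora
#' rarely fill all 200). The draw is reproducible from `seed`.
#'
#' @param pool Classified tibble from [assign_class()]; unbinned rows are
#'   dropped with a message.
#' @param seed Integer RNG seed.
#' @return A tibble (one row per selected stimulus) with attribute `seed`.
#' @export
stratified_select <- function(pool, seed) {
  if (nrow(pool) == 0) abort("empty pool")
  if (!"class_id" %in% names(pool)) pool <- assign_class(pool)
  n_unbinned <- sum(is.na(pool$class_id))
  if (n_unbinned > 0)
    message(sprintf("dropping %d unbinned patches", n_unbinned))
  pool <- dplyr::filter(pool, !is.na(.data$class_id))
  if (nrow(pool) == 0) abort("empty pool after dropping unbinned patches")
  restore <- .preserve_rng_state()
  on.exit(restore())
  set.seed(seed)
  sel <- pool |>
    dplyr::group_by(.data$class_id) |>
    dplyr::slice_sample(n = 1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$class_id)
  attr(sel, "seed") <- seed
  sel
}

# Save and restore the global RNG state so seeded selections do not
# perturb the caller's stream.
.preserve_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    function() assign(".Random.seed", old, envir = globalenv())
  } else {
    function() if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

#' Render a display stimulus from a patch
#'
#' Multiplies the binary patch by an isotropic Gaussian window centred on
#' the patch centre (weight 1 at the centre), which fades the contour out
#' toward the patch border.
#'
#' @param patch A `contour_patch`.
#' @param sigma Gaussian standard deviation in pixels.
#' @return A 69 x 69 numeric matrix in `[0, 1]`.
#' @examples
#' s <- render_stimulus(generate_arc(20, 150, 0))
#' max(s) == 1
#' @export
render_stimulus <- function(patch, sigma = 17) {
  stopifnot(inherits(patch, "contour_patch"))
  idx <- seq_len(PATCH_N) - PATCH_CENTER
  d2 <- outer(idx^2, idx^2, "+")
  patch$grid * exp(-d2 / (2 * sigma^2))
}

#' Write a stimulus-set manifest
#'
#' Saves the selection as a manifest CSV whose header comment records the
#' selection seed, plus one PNG stimulus per row when `patches` is given.
#'
#' @param sel Selection tibble from [stratified_select()].
#' @param dir Output directory (created if needed).
#' @param patches Optional named list of patches to render as PNGs.
#' @param sigma Gaussian window width for rendering.
#' @return The manifest path, invisibly.
#' @export
write_stimulus_set <- function(sel, dir, patches = NULL, sigma = 17) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- file.path(dir, "manifest.csv")
  con <- file(manifest, "w")
  writeLines(sprintf("# selection seed: %s", attr(sel, "seed") %||% "NA"), con)
  sel$file <- file.path(dir, paste0(sel$patch_id, ".png"))
  keep <- c("patch_id", "convexity_bin", "closure_bin", "orientation_bin",
            "class_id", "file")
  write.csv(as.data.frame(sel)[, intersect(keep, names(sel))], con,
            row.names = FALSE)
  close(con)
  if (!is.null(patches)) {
    for (id in sel$patch_id) {
      if (!is.null(patches[[id]])) {
        png::writePNG(render_stimulus(patches[[id]], sigma = sigma),
                      file.path(dir, paste0(id, ".png")))
      }
    }
  }
  invisible(manifest)
}

#' Optional geometric exclusion heuristics
#'
#' The stimulus screen drops X-junction patches automatically; two further
#' exclusions in the original screening protocol (a whole object visible,
#' or contours too densely packed to judge figure direction) were human
#' judgements. These heuristics stand in for them, and are off by default
#' because they are documented approximations, not claims of fidelity:
#' `max_density` flags patches whose contour-pixel fraction exceeds the
#' threshold (packed contours), and `max_enclosed_frac` flags patches whose
#' chain is closed and encloses more than that fraction of the patch area
#' (a whole object filling the patch).
#'
#' @param patch A `contour_patch`.
#' @param max_density Contour-pixel fraction above which the patch is
#'   flagged, or `NULL` to skip the check.
#' @param max_enclosed_frac Enclosed-area fraction (shoelace area of a
#'   closed chain over the patch area) above which the patch is flagged,
#'   or `NULL` to skip.
#' @return Named logical vector `c(too_dense, whole_object)`.
#' @export
patch_exclusion_flags <- function(patch, max_density = NULL,
                                  max_enclosed_frac = NULL) {
  stopifnot(inherits(patch, "contour_patch"))
  too_dense <- FALSE
  if (!is.null(max_density))
    too_dense <- sum(patch$grid) / PATCH_N^2 > max_density
  whole_object <- FALSE
  if (!is.null(max_enclosed_frac)) {
    ch <- patch$chain
    n <- nrow(ch)
    closed <- n >= 8 && max(abs(ch[1, ] - ch[n, ])) <= 1
    if (closed) {
      x <- ch[, 2]; y <- ch[, 1]
      area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
      whole_object <- area / PATCH_N^2 > max_enclosed_frac
    }
  }
  c(too_dense = too_dense, whole_object = whole_object)
}
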