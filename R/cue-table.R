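#' Compute the three cue indices for a corpus of patches
#'
#' Runs the whole labelling stage: local frame, Convexity, Closure, the
#' exhaustive symmetry-axis search, and finally the corpus-wide
#' normalisation of the Symmetry index (the largest dos over the corpus
#' defines magnitude 1, mirroring normalisation over the full dataset a
#' study would analyse).
#'
#' @param patches Named list of `contour_patch` objects; names become
#'   `patch_id` (unnamed lists get `patch_001`, ...).
#' @param dilate Passed to the dos computation.
#' @param rho_tol Straightness tolerance for [local_frame()].
#' @return A tibble with one row per patch: `patch_id`, `convexity`,
#'   `closure`, `symmetry`, `orientation_deg`, `orientation_bin`,
#'   `theta_star`, `x_star`, `dos_star`, `length`, `degenerate`,
#'   `normal_row`, `normal_col`.
#' @examples
#' \donttest{
#' ps <- list(a = generate_arc(20, 150, 10), b = generate_arc(30, 120, 45))
#' compute_cues(ps)
#' }
#' @export
compute_cues <- function(patches, dilate = TRUE, rho_tol = RHO_TOL) {
  stopifnot(is.list(patches), length(patches) > 0)
  ids <- names(patches)
  if (is.null(ids)) ids <- sprintf("patch_%03d", seq_along(patches))

  rows <- purrr::map2(patches, ids, function(p, id) {
    fr <- local_frame(p, rho_tol = rho_tol)
    srch <- optimal_axis(p, dilate = dilate)
    tibble::tibble(
      patch_id = id,
      convexity = convexity(fr),
      closure = closure(p, fr),
      orientation_deg = fr$tangent_deg,
      orientation_bin = orientation_bin(fr$tangent_deg),
      theta_star = srch$theta_star,
      x_star = srch$x_star,
      dos_star = srch$dos_star,
      length = srch$length,
      degenerate = fr$degenerate,
      normal_row = fr$convex_normal[["row"]],
      normal_col = fr$convex_normal[["col"]],
      .frame = list(fr),
      .search = list(srch)
    )
  })
  out <- dplyr::bind_rows(rows)
  m <- max(out$dos_star)
  out$symmetry <- unname(purrr::pmap_dbl(
    list(patches, out$.frame, out$.search),
    function(p, fr, srch) symmetry_index(p, fr, m, search = srch)
  ))
  dplyr::select(out, "patch_id", "convexity", "closure", "symmetry",
                "orientation_deg", "orientation_bin", "theta_star",
                "x_star", "dos_star", "length", "degenerate",
                "normal_row", "normal_col")
}

#' Write / read a cue table as CSV
#'
#' @param cues Tibble from [compute_cues()].
#' @param path CSV path.
#' @return The path (write) or a tibble (read).
#' @export
write_cue_table <- function(cues, path) {
  write.csv(as.data.frame(cues), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cue_table
#' @export
read_cue_table <- function(path) {
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
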