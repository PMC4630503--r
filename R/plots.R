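#' Plot a patch or rendered stimulus
#'
#' @param patch A `contour_patch`.
#' @param sigma Optional Gaussian window width; `NULL` plots the raw
#'   binary patch.
#' @return A ggplot object.
#' @export
plot_patch <- function(patch, sigma = NULL) {
  g <- if (is.null(sigma)) patch$grid else render_stimulus(patch, sigma)
  df <- tidyr::expand_grid(col = seq_len(PATCH_N), row = seq_len(PATCH_N))
  df$value <- as.vector(g)  # column-major: row varies fastest
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "grey85", high = "black",
                                 guide = "none") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, title = patch$provenance) +
    ggplot2::theme_void()
}

#' Overlay a perceptual and an aligned topographic configuration
#'
#' Aligns the topographic configuration onto the perceptual one by
#' Procrustes and plots both point sets with stimulus labels, the
#' conventional display of configuration agreement.
#'
#' @param object A `perceptual_config`.
#' @param topo Optional topographic configuration (matrix from
#'   [topographic_config()]); omitted = perceptual points only.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.perceptual_config <- function(object, topo = NULL, ...) {
  pts <- object$points
  if (ncol(pts) == 1) pts <- cbind(pts, 0)
  df <- tibble::tibble(x = pts[, 1], y = pts[, 2],
                       label = rownames(object$points) %||%
                         as.character(seq_len(nrow(pts))),
                       which = "perceptual")
  if (!is.null(topo)) {
    fit <- vegan::procrustes(object$points, as.matrix(topo), scale = TRUE)
    tp <- fit$Yrot
    if (ncol(tp) == 1) tp <- cbind(tp, 0)
    df <- dplyr::bind_rows(df, tibble::tibble(
      x = tp[, 1], y = tp[, 2], label = df$label, which = "topographic"))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$which,
                                   label = .data$label)) +
    ggplot2::geom_text(size = 3) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "dimension 1", y = "dimension 2", colour = NULL,
                  subtitle = sprintf("stress-1 = %.3f", object$stress)) +
    ggplot2::theme_minimal()
}

#' Convex-choice rate against each cue index
#'
#' Reproduces the standard summary of the figure-ground experiment: the
#' per-patch rate of choosing the convex side plotted against Convexity,
#' Closure and Symmetry.
#'
#' @param table Choice table from [convex_choice_rate()].
#' @param cues Cue table with the three indices per `patch_id`.
#' @return A ggplot object (faceted by cue).
#' @export
plot_choice_rates <- function(table, cues) {
  d <- dplyr::inner_join(tibble::as_tibble(table),
                         dplyr::select(cues, "patch_id", "convexity",
                                       "closure", "symmetry"),
                         by = "patch_id") |>
    tidyr::pivot_longer(c("convexity", "closure", "symmetry"),
                        names_to = "cue", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value, y = .data$rate)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::facet_wrap(~cue, scales = "free_x") +
    ggplot2::labs(x = "cue index", y = "rate of choosing the convex side") +
    ggplot2::theme_minimal()
}
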