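# 2AFC answer words -> (row, col) direction vectors. Row increases
# downward, so "top" is (-1, 0).
.answer_dirs <- list(right = c(0, 1), left = c(0, -1),
                     top = c(-1, 0), bottom = c(1, 0))
.group_answers <- list(vertical = c("left", "right"),
                       horizontal = c("top", "bottom"))

#' Convex-side choice rates from 2AFC responses
#'
#' Scores each figure-direction answer against the patch's convex normal:
#' a response counts as convex-chosen iff the answered direction has a
#' positive dot product with the convex normal. Rates are pooled over
#' observers and repetitions per patch (set `by_observer = TRUE` for
#' per-observer rates). Patches with a degenerate (straight) frame are
#' flagged and excluded with a message.
#'
#' @param responses Tibble with columns `patch_id`, `group`
#'   (`"vertical"` or `"horizontal"`), `answer` (`"left"`/`"right"` for the
#'   vertical group, `"top"`/`"bottom"` for the horizontal group), and
#'   optionally `observer_id`, `repetition`.
#' @param cues Cue table from [compute_cues()] supplying `normal_row`,
#'   `normal_col` and `degenerate` per `patch_id`.
#' @param by_observer Keep observers separate instead of pooling.
#' @return A tibble (`choice_table`): `patch_id`, `group`, `n_convex`,
#'   `n_trials`, `rate`.
#' @export
convex_choice_rate <- function(responses, cues, by_observer = FALSE) {
  stopifnot(all(c("patch_id", "group", "answer") %in% names(responses)))
  stopifnot(all(c("patch_id", "normal_row", "normal_col", "degenerate") %in%
                  names(cues)))
  ok_group <- responses$group %in% names(.group_answers)
  if (!all(ok_group)) abort("group must be 'vertical' or 'horizontal'")
  legal <- purrr::map2_lgl(responses$answer, responses$group,
                           function(a, g) a %in% .group_answers[[g]])
  if (!all(legal))
    abort(sprintf("answer inconsistent with group in %d trial(s)", sum(!legal)))

  x <- dplyr::left_join(responses,
                        dplyr::select(cues, "patch_id", "normal_row",
                                      "normal_col", "degenerate"),
                        by = "patch_id")
  if (anyNA(x$normal_row)) abort("responses reference patches missing from cues")
  n_deg <- length(unique(x$patch_id[x$degenerate]))
  if (n_deg > 0)
    message(sprintf("excluding %d patch(es) with degenerate frames", n_deg))
  x <- dplyr::filter(x, !.data$degenerate)

  dirs <- do.call(rbind, .answer_dirs[x$answer])
  dot <- dirs[, 1] * x$normal_row + dirs[, 2] * x$normal_col
  if (any(dot == 0)) abort("answer axis orthogonal to convex normal")
  x$convex_chosen <- dot > 0

  keys <- c(if (by_observer) "observer_id", "patch_id", "group")
  out <- x |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(n_convex = sum(.data$convex_chosen),
                     n_trials = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(rate = .data$n_convex / .data$n_trials)
  class(out) <- c("choice_table", class(out))
  out
}

#' Six-term multiple linear regression of convex-choice rates
#'
#' Ordinary least squares of the per-patch convex-choice rate on the three
#' raw cue indices and their three pairwise products (seven coefficients
#' with the intercept). Predictors enter unstandardized so coefficients
#' are on the natural cue scales. A linear probability model is used even
#' though rates are bounded, matching the analysis design.
#'
#' @param table Choice table from [convex_choice_rate()].
#' @param cues Cue table with `convexity`, `closure`, `symmetry` per
#'   `patch_id`.
#' @return An `fg_regression`: the underlying `lm` fit plus `adj_r2`,
#'   `n_patches` and a `constant_response` flag (adjusted R-squared is
#'   meaningless when all rates are equal). Use [tidy()] / [glance()].
#' @export
mlra <- function(table, cues) {
  stopifnot(all(c("patch_id", "rate") %in% names(table)))
  d <- dplyr::inner_join(tibble::as_tibble(table)[, c("patch_id", "rate")],
                         dplyr::select(cues, "patch_id", "convexity",
                                       "closure", "symmetry",
                                       dplyr::any_of("degenerate")),
                         by = "patch_id")
  if ("degenerate" %in% names(d)) d <- dplyr::filter(d, !.data$degenerate)
  if (nrow(d) < 8) abort("need at least 8 patches with non-degenerate cues")
  for (v in c("convexity", "closure", "symmetry"))
    if (sd(d[[v]]) == 0) abort(sprintf("zero-variance predictor: %s", v))

  fit <- lm(rate ~ convexity + closure + symmetry +
              convexity:closure + convexity:symmetry + closure:symmetry,
            data = d)
  if (fit$rank < 7 || anyNA(coef(fit)))
    abort("rank-deficient design: interaction terms are collinear")
  constant <- sd(d$rate) == 0
  # a noiseless planted response gives a zero-residual fit; the summary
  # warning about it is expected there
  s <- suppressWarnings(summary(fit))
  structure(list(fit = fit,
                 adj_r2 = if (constant) NA_real_ else s$adj.r.squared,
                 constant_response = constant,
                 n_patches = nrow(d)),
            class = "fg_regression")
}

#' @export
print.fg_regression <- function(x, ...) {
  cat(sprintf("<fg_regression> %d patches, adjusted R^2 = %s\n",
              x$n_patches,
              if (is.na(x$adj_r2)) "undefined (constant response)"
              else sprintf("%.3f", x$adj_r2)))
  print(coef(x$fit))
  invisible(x)
}

#' @rdname mlra
#' @param x An `fg_regression`.
#' @param ... Unused.
#' @export
tidy.fg_regression <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(term = rownames(s),
                 estimate = s[, "Estimate"],
                 std_error = s[, "Std. Error"],
                 statistic = s[, "t value"],
                 p_value = s[, "Pr(>|t|)"])
}

#' @rdname mlra
#' @export
glance.fg_regression <- function(x, ...) {
  tibble::tibble(adj_r_squared = x$adj_r2,
                 r_squared = suppressWarnings(summary(x$fit))$r.squared,
                 n_patches = x$n_patches,
                 constant_response = x$constant_response)
}

#' Tidiers for perceptual configurations
#'
#' `tidy()` returns one row per stimulus with its embedding coordinates;
#' `glance()` returns the stress and embedding size.
#'
#' @param x A `perceptual_config` from [nonmetric_mds()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.perceptual_config <- function(x, ...) {
  pts <- x$points
  out <- tibble::as_tibble(pts, .name_repair = ~ paste0("dim", seq_along(.)))
  out$stimulus_id <- rownames(pts) %||% as.character(seq_len(nrow(pts)))
  dplyr::relocate(out, "stimulus_id")
}

#' @rdname tidy.perceptual_config
#' @export
glance.perceptual_config <- function(x, ...) {
  tibble::tibble(stress = x$stress, dims = x$dims, n = nrow(x$points),
                 seed = x$seed)
}
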