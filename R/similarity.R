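#' Aggregate similarity ratings into a dissimilarity matrix
#'
#' Converts per-trial 5-point similarity ratings (5 = most similar) of one
#' observer into a symmetric dissimilarity matrix with
#' `dissimilarity(i, j) = 5 - mean(rating)` over repetitions, zero
#' diagonal. Every unordered stimulus pair must be rated at least once.
#'
#' @param trials Tibble with columns `stimulus_a`, `stimulus_b`, `rating`
#'   (1-5) and optionally `observer_id` (must be unique if present) and
#'   `repetition`.
#' @return A `dissimilarity_matrix`: list with `values` (n x n matrix with
#'   stimulus ids as dimnames), `observer_id`, `n_repetitions` (minimum
#'   repetitions per pair).
#' @export
aggregate_dissimilarity <- function(trials) {
  stopifnot(all(c("stimulus_a", "stimulus_b", "rating") %in% names(trials)))
  if ("observer_id" %in% names(trials)) {
    obs <- unique(trials$observer_id)
    if (length(obs) > 1)
      abort("trials contain several observers; aggregate one observer at a time")
  } else obs <- NA_character_
  if (any(trials$rating < 1 | trials$rating > 5))
    abort("ratings must lie in 1..5")

  ids <- sort(unique(c(as.character(trials$stimulus_a),
                       as.character(trials$stimulus_b))))
  n <- length(ids)
  # canonical unordered pair key
  a <- pmin(as.character(trials$stimulus_a), as.character(trials$stimulus_b))
  b <- pmax(as.character(trials$stimulus_a), as.character(trials$stimulus_b))
  agg <- tibble::tibble(a = a, b = b, rating = trials$rating) |>
    dplyr::filter(a != b) |>
    dplyr::group_by(.data$a, .data$b) |>
    dplyr::summarise(d = 5 - mean(.data$rating), k = dplyr::n(),
                     .groups = "drop")

  need <- utils::combn(ids, 2)
  have <- paste(agg$a, agg$b)
  missing <- !(paste(need[1, ], need[2, ]) %in% have)
  if (any(missing)) {
    miss <- paste(need[1, missing], need[2, missing], sep = " / ")
    abort(paste0("missing rated pair(s): ",
                 paste(head(miss, 5), collapse = "; "),
                 if (sum(missing) > 5) sprintf(" (and %d more)", sum(missing) - 5)))
  }

  m <- matrix(0, n, n, dimnames = list(ids, ids))
  m[cbind(match(agg$a, ids), match(agg$b, ids))] <- agg$d
  m <- m + t(m)
  structure(list(values = m, observer_id = obs,
                 n_repetitions = min(agg$k)),
            class = "dissimilarity_matrix")
}

#' @export
print.dissimilarity_matrix <- function(x, ...) {
  cat(sprintf("<dissimilarity_matrix> %d stimuli, observer %s, >= %d repetitions/pair\n",
              nrow(x$values), x$observer_id, x$n_repetitions))
  invisible(x)
}

.as_dissim <- function(D) {
  if (inherits(D, "dissimilarity_matrix")) D$values
  else if (is.matrix(D)) D
  else abort("expected a dissimilarity matrix")
}

#' Kruskal stress-1 of a configuration against dissimilarities
#'
#' Measures how well the inter-point distances of a configuration preserve
#' the rank order of the dissimilarities. The monotone transform is fitted
#' by isotonic regression of configuration distances on the dissimilarity
#' order (primary approach to ties: tied dissimilarities are left
#' unconstrained against each other), and the statistic is
#' `sqrt(sum((d - dhat)^2) / sum(d^2))` over pairs, where `d` are the
#' configuration distances and `dhat` the fitted disparities. Zero means a
#' perfect rank-order match.
#'
#' @param config n x k matrix of point coordinates.
#' @param D Dissimilarity matrix (or [aggregate_dissimilarity()] result).
#' @return Scalar in `[0, 1]`.
#' @export
kruskal_stress <- function(config, D) {
  Dm <- .as_dissim(D)
  config <- as.matrix(config)
  if (nrow(config) != nrow(Dm)) abort("one point per stimulus required")
  d <- as.matrix(dist(config))
  iu <- upper.tri(Dm)
  dv <- d[iu]; Dv <- Dm[iu]
  if (all(dv == 0)) abort("degenerate configuration: all points identical")
  # primary ties: order by dissimilarity, then by configuration distance so
  # tied blocks impose no constraint among themselves
  o <- order(Dv, dv)
  fit <- isoreg(dv[o])$yf
  sqrt(sum((dv[o] - fit)^2) / sum(dv^2))
}

#' Nonmetric multidimensional scaling
#'
#' Embeds stimuli in `dims` dimensions so that inter-point distances
#' preserve the rank order of the dissimilarities as well as possible
#' (Kruskal's method). Optimization starts from the classical-scaling
#' solution plus `n_restarts` seeded random starts; the solution with the
#' lowest [kruskal_stress()] is returned, centred at the origin.
#'
#' @param D Dissimilarity matrix or [aggregate_dissimilarity()] result.
#' @param dims Embedding dimension (1, 2 or 3).
#' @param seed Integer seed controlling the random restarts.
#' @param n_restarts Number of random restarts added to the classical
#'   start.
#' @return A `perceptual_config`: list with `points` (n x dims, centred),
#'   `stress` (stress-1), `dims`, `seed`, and the input `D` retained for
#'   downstream null construction.
#' @export
nonmetric_mds <- function(D, dims = 2, seed = 1, n_restarts = 9) {
  Dm <- .as_dissim(D)
  if (!isSymmetric(unname(Dm), tol = 1e-8)) abort("dissimilarity matrix must be symmetric")
  n <- nrow(Dm)
  if (n < dims + 2) abort("need at least dims + 2 stimuli")
  # isoMDS requires positive off-diagonal dissimilarities
  eps <- min(Dm[Dm > 0], 1) * 1e-3
  Dpos <- Dm
  Dpos[Dpos <= 0] <- eps
  diag(Dpos) <- 0

  starts <- list()
  cs <- suppressWarnings(cmdscale(Dpos, k = dims))
  if (ncol(cs) < dims) cs <- cbind(cs, matrix(0, n, dims - ncol(cs)))
  starts[[1]] <- cs + matrix(rnorm_seeded(n * dims, seed) * 1e-4, n, dims)
  for (r in seq_len(n_restarts))
    starts[[r + 1]] <- matrix(rnorm_seeded(n * dims, .sub_seed(seed, r)),
                              n, dims)

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      suppressWarnings(MASS::isoMDS(Dpos, y = st, k = dims, trace = FALSE)),
      error = function(e) NULL)
    if (is.null(fit)) next
    s <- kruskal_stress(fit$points, Dm)
    if (is.null(best) || s < best$stress) best <- list(points = fit$points, stress = s)
  }
  if (is.null(best)) abort("MDS failed from every start")
  pts <- scale(best$points, scale = FALSE)
  attr(pts, "scaled:center") <- NULL
  rownames(pts) <- rownames(Dm)
  structure(list(points = pts, stress = best$stress, dims = dims,
                 seed = seed, D = Dm),
            class = "perceptual_config")
}

# Seeded N(0,1) draws that leave the caller's RNG stream untouched.
rnorm_seeded <- function(n, seed) {
  restore <- .preserve_rng_state()
  on.exit(restore())
  set.seed(as.integer(seed %% .Machine$integer.max))
  rnorm(n)
}

# derive a sub-seed without integer overflow (32-bit R integers)
.sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k) %% (.Machine$integer.max - 1) + 1)
}

#' @export
print.perceptual_config <- function(x, ...) {
  cat(sprintf("<perceptual_config> %d stimuli in %dD, stress-1 = %.4f\n",
              nrow(x$points), x$dims, x$stress))
  invisible(x)
}

#' Topographic configuration from cue indices
#'
#' Places each stimulus at the coordinates given by the selected cue
#' indices, each standardized to zero mean and unit variance across the
#' stimulus set so the axes are commensurate under Procrustes alignment.
#'
#' @param cues Tibble with one row per stimulus containing at least the
#'   selected factor columns (subset of `convexity`, `closure`,
#'   `symmetry`).
#' @param factors Non-empty character vector of factor names.
#' @return n x length(factors) matrix of standardized coordinates.
#' @export
topographic_config <- function(cues, factors) {
  if (length(factors) == 0) abort("empty factor set")
  bad <- setdiff(factors, c("convexity", "closure", "symmetry"))
  if (length(bad)) abort(paste("unknown factor(s):", paste(bad, collapse = ", ")))
  m <- as.matrix(dplyr::select(cues, dplyr::all_of(factors)))
  sds <- apply(m, 2, sd)
  if (any(sds == 0))
    abort(paste("zero variance in factor(s):",
                paste(factors[sds == 0], collapse = ", ")))
  z <- scale(m)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  if ("patch_id" %in% names(cues)) rownames(z) <- cues$patch_id
  z
}

#' Procrustes residual between two configurations
#'
#' Optimally translates, rotates, reflects and uniformly scales the second
#' configuration onto the first (least squares) and returns the squared
#' sum of the remaining pairwise point distances.
#'
#' @param P Target configuration (n x d matrix or `perceptual_config`).
#' @param T_ Configuration to align (same n and d).
#' @return Non-negative scalar.
#' @export
procrustes_error <- function(P, T_) {
  if (inherits(P, "perceptual_config")) P <- P$points
  if (inherits(T_, "perceptual_config")) T_ <- T_$points
  P <- as.matrix(P); T_ <- as.matrix(T_)
  if (nrow(P) != nrow(T_)) abort("configurations must have the same number of points")
  if (ncol(P) != ncol(T_)) abort("configurations must have the same dimension")
  fit <- vegan::procrustes(P, T_, scale = TRUE, symmetric = FALSE)
  sum(residuals(fit)^2)
}

#' Error statistic normalized by a scrambling null
#'
#' Quantifies the agreement between a perceptual configuration `P` and a
#' candidate (e.g. topographic) configuration `T_`. The raw Error is the
#' Procrustes residual [procrustes_error()]. The null distribution is
#' built by scrambling the similarities: the stimulus labels of the
#' retained dissimilarity matrix are permuted, the permuted matrix is
#' re-embedded by [nonmetric_mds()], and the Procrustes residual against
#' `P` is recorded, `n_random` times. The normalized Error is the raw
#' Error divided by the mean null Error (0 = perfect agreement, about 1 =
#' chance); the p-value is a one-sided one-sample t-test of the null
#' distribution against the observed raw Error (alternative: null mean
#' greater, i.e. observed smaller than chance).
#'
#' @param P A `perceptual_config` from [nonmetric_mds()] (its retained
#'   dissimilarity matrix feeds the null).
#' @param T_ Candidate configuration, same n and dims as `P`.
#' @param n_random Number of scrambled configurations (design default 100).
#' @param seed Integer seed for the permutations and null MDS restarts.
#' @param null_restarts Random restarts used for each null MDS fit (fewer
#'   than the headline fit; the null needs location, not a global optimum).
#' @return An `error_stat`: list with `raw_error`, `normalized_error`,
#'   `null_distribution`, `p_value`, `n_random`.
#' @export
normalized_error <- function(P, T_, n_random = 100, seed = 1,
                             null_restarts = 2) {
  stopifnot(inherits(P, "perceptual_config"))
  if (n_random < 2) abort("n_random must be at least 2")
  raw <- procrustes_error(P$points, T_)
  n <- nrow(P$D)
  restore <- .preserve_rng_state()
  on.exit(restore())
  set.seed(as.integer(seed %% .Machine$integer.max))
  null <- vapply(seq_len(n_random), function(r) {
    perm <- sample.int(n)
    Dr <- P$D[perm, perm]
    Cr <- nonmetric_mds(Dr, dims = P$dims, seed = .sub_seed(seed, r),
                        n_restarts = null_restarts)
    procrustes_error(P$points, Cr$points)
  }, numeric(1))
  pv <- tryCatch(t.test(null, mu = raw, alternative = "greater")$p.value,
                 error = function(e) NA_real_)
  structure(list(raw_error = raw,
                 normalized_error = raw / mean(null),
                 null_distribution = null,
                 p_value = pv,
                 n_random = n_random),
            class = "error_stat")
}

#' @export
print.error_stat <- function(x, ...) {
  cat(sprintf("<error_stat> raw %.4g, normalized %.3f (null mean %.4g, n = %d), p = %.3g\n",
              x$raw_error, x$normalized_error, mean(x$null_distribution),
              x$n_random, x$p_value))
  invisible(x)
}

#' Pairwise comparison of factor sets across participants
#'
#' Given per-participant normalized Errors for several factor sets, runs a
#' paired t-test for every pair of factor sets.
#'
#' @param errors Tibble with columns `observer_id`, `factor_set` and
#'   `normalized_error`; every observer must appear under every factor
#'   set.
#' @return Tibble with one row per factor-set pair: `set_a`, `set_b`,
#'   `mean_diff` (a minus b), `t`, `df`, `p_value`.
#' @export
compare_factor_sets <- function(errors) {
  stopifnot(all(c("observer_id", "factor_set", "normalized_error") %in%
                  names(errors)))
  wide <- tidyr::pivot_wider(errors, id_cols = "observer_id",
                             names_from = "factor_set",
                             values_from = "normalized_error")
  if (nrow(wide) < 2) abort("need at least 2 participants")
  sets <- setdiff(names(wide), "observer_id")
  if (anyNA(wide[sets])) abort("every observer must have every factor set")
  pairs <- utils::combn(sets, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- wide[[pairs[1, k]]]; b <- wide[[pairs[2, k]]]
    dd <- a - b
    if (sd(dd) == 0) {
      tibble::tibble(set_a = pairs[1, k], set_b = pairs[2, k],
                     mean_diff = mean(dd),
                     t = if (mean(dd) == 0) 0 else sign(mean(dd)) * Inf,
                     df = length(dd) - 1,
                     p_value = if (mean(dd) == 0) 1 else 0)
    } else {
      tt <- t.test(a, b, paired = TRUE)
      tibble::tibble(set_a = pairs[1, k], set_b = pairs[2, k],
                     mean_diff = unname(tt$estimate),
                     t = unname(tt$statistic), df = unname(tt$parameter),
                     p_value = tt$p.value)
    }
  })
}
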