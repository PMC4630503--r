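make_trials <- function(n_stim, rating_fun, reps = 1, observer = "o1") {
  ids <- sprintf("s%02d", seq_len(n_stim))
  pairs <- utils::combn(ids, 2)
  out <- tidyr::expand_grid(k = seq_len(ncol(pairs)), repetition = seq_len(reps))
  tibble::tibble(observer_id = observer,
                 stimulus_a = pairs[1, out$k],
                 stimulus_b = pairs[2, out$k],
                 repetition = out$repetition,
                 rating = rating_fun(out$k))
}

test_that("ratings aggregate to a symmetric zero-diagonal dissimilarity", {
  # all pairs rated 5: identical-looking stimuli, zero dissimilarity
  tr <- make_trials(6, function(k) rep(5L, length(k)), reps = 2)
  D <- aggregate_dissimilarity(tr)
  expect_true(all(D$values == 0))
  expect_equal(D$n_repetitions, 2)

  # four ratings of 1 for one pair give dissimilarity 4
  tr2 <- make_trials(3, function(k) ifelse(k == 1, 1L, 3L), reps = 4)
  D2 <- aggregate_dissimilarity(tr2)
  expect_equal(D2$values["s01", "s02"], 4)
  expect_equal(D2$values["s02", "s01"], 4)
  expect_true(all(diag(D2$values) == 0))

  # 54 stimuli produce the full 1431-pair design
  tr3 <- make_trials(54, function(k) rep(3L, length(k)))
  expect_equal(nrow(tr3), 1431)
  D3 <- aggregate_dissimilarity(tr3)
  expect_equal(dim(D3$values), c(54, 54))

  # a missing pair is reported by name
  expect_error(aggregate_dissimilarity(tr3[-1, ]), "s01 / s02")
})

test_that("Kruskal stress is zero iff ranks are preserved", {
  X <- withr::with_seed(1, matrix(rnorm(30), 15, 2))
  D <- as.matrix(dist(X))
  expect_lt(kruskal_stress(X, D), 1e-9)
  # any monotone transform of the dissimilarities leaves stress at zero
  expect_lt(kruskal_stress(X, D^2), 1e-9)
  expect_lt(kruskal_stress(X, log1p(D)), 1e-9)

  # a random 1D configuration against unrelated dissimilarities has
  # positive stress
  y <- withr::with_seed(2, matrix(rnorm(15), 15, 1))
  D2 <- withr::with_seed(3, {
    M <- matrix(runif(225), 15, 15); M <- M + t(M); diag(M) <- 0; M
  })
  expect_gt(kruskal_stress(y, D2), 0.05)

  expect_error(kruskal_stress(matrix(1, 15, 2), D), "degenerate")
})

test_that("stress is invariant under similarity transforms of the config", {
  X <- withr::with_seed(4, matrix(rnorm(24), 12, 2))
  D <- withr::with_seed(5, {
    M <- matrix(runif(144), 12, 12); M <- M + t(M); diag(M) <- 0; M
  })
  s0 <- kruskal_stress(X, D)
  th <- 0.8; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(kruskal_stress(3 * X %*% R + 2, D), s0, tolerance = 1e-9)
  expect_equal(kruskal_stress(X %*% diag(c(-1, 1)), D), s0, tolerance = 1e-9)
})

test_that("nonmetric MDS recovers a planted configuration", {
  X <- withr::with_seed(6, matrix(rnorm(40), 20, 2))
  D <- as.matrix(dist(X))
  P <- nonmetric_mds(D, dims = 2, seed = 1)
  expect_lt(P$stress, 0.01)
  scale2 <- sum(scale(X, scale = FALSE)^2)
  expect_lt(procrustes_error(P$points, X) / scale2, 1e-3)
  # centred output, deterministic under seed
  expect_equal(colMeans(P$points), c(0, 0), tolerance = 1e-9)
  expect_equal(nonmetric_mds(D, dims = 2, seed = 1)$points, P$points)

  # nested dimensions: stress decreases (within restart slack)
  s1 <- nonmetric_mds(D, dims = 1, seed = 1)$stress
  s3 <- nonmetric_mds(D, dims = 3, seed = 1)$stress
  expect_gte(s1, P$stress - 1e-3)
  expect_gte(P$stress, s3 - 1e-3)

  expect_error(nonmetric_mds(D[1:3, 1:3], dims = 2), "dims \\+ 2")
  expect_error(nonmetric_mds(matrix(1:16, 4, 4), dims = 1), "symmetric")
})

test_that("topographic configurations standardize the chosen factors", {
  cues <- random_cue_table(10, seed = 7)
  z <- topographic_config(cues, c("convexity", "closure"))
  expect_equal(dim(z), c(10, 2))
  expect_equal(colMeans(z), c(convexity = 0, closure = 0), tolerance = 1e-12)
  expect_equal(apply(z, 2, sd), c(convexity = 1, closure = 1), tolerance = 1e-12)
  expect_equal(rownames(z), cues$patch_id)

  z1 <- topographic_config(cues, "closure")
  expect_equal(ncol(z1), 1)

  expect_error(topographic_config(cues, character(0)), "empty")
  cues$symmetry <- 0.5
  expect_error(topographic_config(cues, "symmetry"), "zero variance")
})

test_that("the Procrustes residual matches an independent optimizer", {
  X <- withr::with_seed(8, matrix(rnorm(20), 10, 2))
  # exact alignment cases: similarity transform and reflection
  th <- 0.5; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_lt(procrustes_error(X, 2.5 * X %*% R + 1), 1e-18)
  expect_lt(procrustes_error(X, X %*% diag(c(-1, 1))), 1e-18)

  # general case agrees with brute-force optimization over all transforms
  for (s in 1:5) {
    T_ <- withr::with_seed(100 + s, matrix(rnorm(20), 10, 2))
    expect_equal(procrustes_error(X, T_), procrustes_error_oracle(X, T_),
                 tolerance = 1e-6)
  }

  expect_error(procrustes_error(X, T_[1:5, ]), "number of points")
})

test_that("the residual is symmetric after centering and unit scaling", {
  norm_cfg <- function(M) {
    M <- scale(M, scale = FALSE)
    M / sqrt(sum(M^2))
  }
  for (s in 1:20) {
    pq <- withr::with_seed(200 + s, list(matrix(rnorm(16), 8, 2),
                                         matrix(rnorm(16), 8, 2)))
    a <- procrustes_error(norm_cfg(pq[[1]]), norm_cfg(pq[[2]]))
    b <- procrustes_error(norm_cfg(pq[[2]]), norm_cfg(pq[[1]]))
    expect_equal(a, b, tolerance = 1e-9)
  }
})

test_that("the normalized Error is zero for self and about one under the null", {
  cues <- random_cue_table(12, seed = 9)
  model <- observer_model(noise_sd = 0.2, seed = 10)
  D <- aggregate_dissimilarity(simulate_similarity(cues, model))
  P <- nonmetric_mds(D, dims = 2, seed = 3)

  e0 <- normalized_error(P, P$points, n_random = 10, seed = 1)
  expect_lt(e0$normalized_error, 1e-6)
  expect_length(e0$null_distribution, 10)
  expect_error(normalized_error(P, P$points, n_random = 1), "at least 2")

  # configurations drawn by the null mechanism itself score about 1
  reps <- vapply(1:50, function(r) {
    perm <- withr::with_seed(400 + r, sample.int(nrow(P$D)))
    Tnull <- nonmetric_mds(P$D[perm, perm], dims = 2, seed = 500 + r,
                           n_restarts = 1)$points
    normalized_error(P, Tnull, n_random = 15, seed = 600 + r,
                     null_restarts = 1)$normalized_error
  }, numeric(1))
  expect_equal(mean(reps), 1, tolerance = 0.1)
})

test_that("planted similarity structure is detected against unrelated factors", {
  cues <- random_cue_table(15, seed = 12)
  model <- observer_model(similarity_weights = c(convexity = 1, closure = 1,
                                                 symmetry = 0),
                          noise_sd = 0.25, seed = 13)
  D <- aggregate_dissimilarity(simulate_similarity(cues, model))
  P2 <- nonmetric_mds(D, dims = 2, seed = 5)
  P1 <- nonmetric_mds(D, dims = 1, seed = 5)
  e_cc <- normalized_error(P2, topographic_config(cues, c("convexity", "closure")),
                           n_random = 20, seed = 6)
  e_sy <- normalized_error(P1, topographic_config(cues, "symmetry"),
                           n_random = 20, seed = 6)
  # the planted factor pair is far below chance, and below the unrelated one
  expect_lt(e_cc$normalized_error, 0.5)
  expect_lt(e_cc$p_value, 0.01)
  expect_lt(e_cc$normalized_error, e_sy$normalized_error)
})

test_that("factor sets are compared by paired t-tests across participants", {
  err <- tidyr::expand_grid(observer_id = sprintf("o%d", 1:6),
                            factor_set = c("A", "B"))
  err$normalized_error <- rep(c(0.5, 0.5), 6)
  res <- compare_factor_sets(err)
  expect_equal(res$mean_diff, 0)
  expect_equal(res$p_value, 1)

  # constant planted offset with zero variance: p collapses to zero
  err$normalized_error <- ifelse(err$factor_set == "A", 0.4, 0.5)
  res2 <- compare_factor_sets(err)
  expect_equal(res2$mean_diff, -0.1, tolerance = 1e-12)
  expect_equal(res2$p_value, 0)

  # planted effect direction recovered in >= 90 percent of replicates
  hits <- vapply(1:100, function(r) {
    withr::with_seed(700 + r, {
      a <- rnorm(6, 0.5, 0.05); b <- a + 0.1 + rnorm(6, 0, 0.03)
      d <- tibble::tibble(observer_id = rep(sprintf("o%d", 1:6), 2),
                          factor_set = rep(c("A", "B"), each = 6),
                          normalized_error = c(a, b))
      compare_factor_sets(d)$mean_diff < 0
    })
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  expect_error(compare_factor_sets(err[err$observer_id == "o1", ]),
               "at least 2")
})
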