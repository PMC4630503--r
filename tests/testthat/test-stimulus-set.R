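test_that("X-junction detection separates crossings from T-junctions", {
  # plus sign: two crossing lines
  g <- matrix(0L, 69, 69); g[35, 10:60] <- 1L; g[10:60, 35] <- 1L
  expect_true(has_x_junction(g))

  # a single arc has no junction
  expect_false(has_x_junction(generate_arc(20, 150, 10)))

  # T-junction: three branches only
  g2 <- matrix(0L, 69, 69); g2[35, 10:60] <- 1L; g2[35:60, 35] <- 1L
  expect_false(has_x_junction(g2))
})

test_that("class assignment uses the printed outer bins", {
  cues <- tibble::tibble(convexity = c(0.01, 0.25, 0.1, 0.05),
                         closure = c(-7L, 7L, 12L, 0L),
                         orientation_bin = c(1L, 5L, 1L, 3L))
  cl <- assign_class(cues)
  expect_equal(cl$class_id[1], "1-1-1")
  expect_equal(cl$class_id[2], "5-5-5")
  expect_true(is.na(cl$class_id[3]))  # closure 12 is outside [-8, 8]
  expect_equal(cl$convexity_bin[4], 2L)
  expect_equal(cl$closure_bin[4], 3L)

  # bin edge conventions: half-open lower-inclusive; closed top bins
  edges <- tibble::tibble(convexity = c(0, 0.018, 0.222, 0.258, 0.26),
                          closure = c(-8L, -6L, 2L, 6L, 8L),
                          orientation_bin = 1L)
  ecl <- assign_class(edges)
  expect_equal(ecl$convexity_bin, c(1L, 2L, 5L, 5L, NA))
  expect_equal(ecl$closure_bin, c(1L, 2L, 3L, 4L, 5L))
})

test_that("in-range cue space partitions into exactly 200 classes", {
  grid <- tidyr::expand_grid(
    convexity = c(0.009, 0.05, 0.12, 0.19, 0.24),
    closure = c(-7L, -4L, 0L, 4L, 7L),
    orientation_bin = 1:8)
  cl <- assign_class(grid)
  expect_false(anyNA(cl$class_id))
  expect_equal(length(unique(cl$class_id)), 200)

  # every in-range vector maps to exactly one class
  rnd <- tibble::tibble(convexity = withr::with_seed(1, runif(500, 0, 0.258)),
                        closure = withr::with_seed(2, sample(-8:8, 500, TRUE)),
                        orientation_bin = withr::with_seed(3, sample(1:8, 500, TRUE)))
  rcl <- assign_class(rnd)
  expect_false(anyNA(rcl$class_id))
  expect_true(all(rcl$class_id %in% cl$class_id))
})

test_that("stratified selection draws one member per class, reproducibly", {
  pool <- assign_class(random_cue_table(120, seed = 30))
  pool <- pool[!is.na(pool$class_id), ]
  sel <- stratified_select(pool, seed = 5)
  expect_equal(nrow(sel), length(unique(pool$class_id)))
  expect_equal(anyDuplicated(sel$class_id), 0)
  expect_identical(stratified_select(pool, seed = 5)$patch_id, sel$patch_id)

  expect_error(stratified_select(pool[0, ], seed = 1), "empty pool")
})

test_that("selection within a class is uniform over candidates", {
  pool <- tibble::tibble(patch_id = c("a", "b", "c"),
                         convexity = 0.05, closure = 0L,
                         orientation_bin = 1L)
  pool <- assign_class(pool)
  picks <- vapply(1:1000, function(s) stratified_select(pool, seed = s)$patch_id,
                  character(1))
  tab <- table(factor(picks, levels = c("a", "b", "c")))
  expect_gt(chisq.test(tab)$p.value, 0.01)
})

test_that("rendered stimuli are Gaussian-windowed patches", {
  p <- extract_patch(vertical_line_map(), c(51, 51))
  s <- render_stimulus(p, sigma = 17)
  expect_equal(s[35, 35], 1)                      # peak weight at the centre
  expect_equal(s[1, 35], exp(-34^2 / (2 * 17^2)))  # on-contour edge pixel
  # the corner weight formula (corner is off-contour here, so check the
  # window itself)
  w <- exp(-(34^2 + 34^2) / (2 * 17^2))
  expect_equal(w, 0.0183, tolerance = 1e-3)
  expect_true(all(s[p$grid == 0L] == 0))
  expect_true(all(s <= 1 & s >= 0))
})

test_that("stimulus sets are written with their selection seed", {
  pool <- assign_class(random_cue_table(60, seed = 31))
  sel <- stratified_select(pool[!is.na(pool$class_id), ], seed = 9)
  dir <- withr::local_tempdir()
  manifest <- write_stimulus_set(sel, dir)
  lines <- readLines(manifest)
  expect_match(lines[1], "selection seed: 9")
  body <- read.csv(manifest, comment.char = "#")
  expect_equal(nrow(body), nrow(sel))
})

test_that("optional exclusion heuristics flag packed and object-filling patches", {
  arc <- generate_arc(20, 150, 10)
  # off by default: nothing flagged
  expect_false(any(patch_exclusion_flags(arc)))
  # a sparse open arc passes both checks
  expect_false(any(patch_exclusion_flags(arc, max_density = 0.05,
                                         max_enclosed_frac = 0.5)))
  # a closed blob filling most of the patch triggers the area flag
  big <- generate_blob(harmonic_amplitudes = numeric(0),
                       mirror_symmetric = TRUE, base_radius = 16)
  flags <- patch_exclusion_flags(big, max_enclosed_frac = 0.10)
  expect_true(flags[["whole_object"]])
  expect_false(patch_exclusion_flags(big, max_enclosed_frac = 0.9)[["whole_object"]])
  # density flag
  expect_true(patch_exclusion_flags(big, max_density = 0.005)[["too_dense"]])
})
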