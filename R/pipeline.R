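#' Split a top-level seed into per-stage seeds
#'
#' One run seed expands deterministically into independent stage seeds:
#' the run seed initialises R's RNG once and the stage seeds are drawn as
#' `sample.int(2^31 - 2, n)`, named after the stages.
#'
#' @param seed Integer run seed.
#' @param stages Character vector of stage names.
#' @return Named integer vector of stage seeds.
#' @export
split_seed <- function(seed, stages = c("simulate", "features", "select",
                                        "similarity", "fg")) {
  restore <- .preserve_rng_state()
  on.exit(restore())
  set.seed(as.integer(seed %% .Machine$integer.max))
  setNames(sample.int(.Machine$integer.max - 1L, length(stages)), stages)
}

#' Default pipeline configuration
#'
#' Returns the configuration list consumed by [run_pipeline()]; every
#' stochastic stage gets its seed from [split_seed()]. The defaults are
#' sized for a desk-scale synthetic run.
#'
#' @param seed Run seed.
#' @param n_pool Open-curve pool size for the feature/selection stages.
#' @param out_dir Output directory.
#' @param n_repetitions Similarity ratings per pair.
#' @param n_fg_reps 2AFC repetitions per patch.
#' @param mds_dims Embedding dimension for the similarity stage.
#' @param n_random Scrambled configurations in the Error null.
#' @param dilate Dilation flag for the dos computation.
#' @return A named list (class `run_config`).
#' @export
run_config <- function(seed = 1, n_pool = 60, out_dir = tempfile("ccrun"),
                       n_repetitions = 4, n_fg_reps = 100, mds_dims = 2,
                       n_random = 20, dilate = TRUE) {
  cfg <- list(seed = as.integer(seed),
              stage_seeds = as.list(split_seed(seed)),
              n_pool = n_pool, out_dir = out_dir,
              n_repetitions = n_repetitions, n_fg_reps = n_fg_reps,
              mds_dims = mds_dims, n_random = n_random, dilate = dilate,
              version = as.character(utils::packageVersion("contourcues")))
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Read / write a pipeline configuration
#'
#' Configurations round-trip through JSON or YAML (chosen by extension)
#' unchanged.
#'
#' @param cfg A `run_config`.
#' @param path `.json` or `.yaml`/`.yml` file path.
#' @return `write_run_config()` the path; `read_run_config()` a
#'   `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(unclass(cfg), path)
  } else {
    jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("run_config", "list")
  cfg
}

.log_line <- function(con, ...) {
  writeLines(sprintf("%s %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                     sprintf(...)), con)
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the requested stages in order -- `simulate` (generate the
#' open-curve pool), `features` (cue indices), `select` (stratified
#' stimulus set), `similarity` (simulated ratings, MDS, Error statistics)
#' and `fg` (simulated 2AFC responses, choice rates, regression) -- and
#' writes each stage's outputs plus a parameter-echo log into
#' `config$out_dir`. Identical configurations produce identical outputs.
#'
#' @param config A [run_config()].
#' @param stages Stages to run, in pipeline order.
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("simulate", "features", "select",
                                    "similarity", "fg")) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- file(file.path(config$out_dir, "run.log"), "a")
  on.exit(close(log))
  .log_line(log, "run seed %d, stages: %s", config$seed,
            paste(stages, collapse = ", "))
  write_run_config(config, file.path(config$out_dir, "config.json"))
  sseed <- config$stage_seeds

  path <- function(f) file.path(config$out_dir, f)

  if ("simulate" %in% stages) {
    pool <- purrr::map(seq_len(config$n_pool), function(i)
      generate_open_curve(seed = sseed$simulate + i))
    names(pool) <- sprintf("patch_%03d", seq_along(pool))
    ok <- vapply(pool, function(p) {
      !has_x_junction(p) &&
        !inherits(tryCatch(local_frame(p), error = identity), "error")
    }, logical(1))
    pool <- pool[ok]
    # patches are regenerable from the seed; only the manifest is kept
    jsonlite::write_json(list(n_pool = config$n_pool,
                              kept = names(pool),
                              generator_seed = sseed$simulate),
                         path("pool_manifest.json"), auto_unbox = TRUE)
    .log_line(log, "simulate: %d/%d patches kept (X-junctions excluded)",
              length(pool), config$n_pool)
  } else pool <- NULL

  if ("features" %in% stages) {
    if (is.null(pool)) abort("missing upstream output for stage 'features': simulate")
    cues <- compute_cues(pool, dilate = config$dilate)
    write_cue_table(cues, path("cues.csv"))
    .log_line(log, "features: %d cue vectors", nrow(cues))
  } else cues <- NULL

  if ("select" %in% stages) {
    if (is.null(cues)) abort("missing upstream output for stage 'select': features")
    sel <- stratified_select(assign_class(cues), seed = sseed$select)
    write_stimulus_set(sel, path("stimuli"), patches = pool)
    .log_line(log, "select: %d stimuli from %d classes", nrow(sel),
              length(unique(sel$class_id)))
  } else sel <- NULL

  if ("similarity" %in% stages) {
    if (is.null(sel)) abort("missing upstream output for stage 'similarity': select")
    stim <- dplyr::semi_join(cues, sel, by = "patch_id")
    model <- observer_model(seed = sseed$similarity)
    trials <- simulate_similarity(stim, model,
                                  n_repetitions = config$n_repetitions)
    write.csv(as.data.frame(trials), path("ratings.csv"), row.names = FALSE)
    D <- aggregate_dissimilarity(trials)
    P <- nonmetric_mds(D, dims = config$mds_dims, seed = sseed$similarity)
    Tc <- topographic_config(stim, c("convexity", "closure")[seq_len(
      min(2, config$mds_dims))])
    es <- normalized_error(P, Tc, n_random = config$n_random,
                           seed = sseed$similarity)
    write.csv(data.frame(stimulus_id = rownames(P$points), P$points),
              path("configuration.csv"), row.names = FALSE)
    jsonlite::write_json(list(stress = P$stress, dims = P$dims,
                              seed = P$seed), path("stress.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(list(raw_error = es$raw_error,
                              normalized_error = es$normalized_error,
                              p_value = es$p_value,
                              null = es$null_distribution,
                              seed = sseed$similarity),
                         path("error_stat.json"), auto_unbox = TRUE,
                         digits = NA)
    .log_line(log, "similarity: stress %.3f, normalized error %.3f",
              P$stress, es$normalized_error)
  }

  if ("fg" %in% stages) {
    if (is.null(sel)) abort("missing upstream output for stage 'fg': select")
    stim <- dplyr::semi_join(cues, sel, by = "patch_id")
    model <- observer_model(seed = sseed$fg)
    resp <- simulate_fg(stim, model, n_reps = config$n_fg_reps)
    write.csv(as.data.frame(resp), path("responses.csv"), row.names = FALSE)
    ct <- convex_choice_rate(resp, stim)
    write.csv(as.data.frame(ct), path("choice_table.csv"), row.names = FALSE)
    reg <- mlra(ct, stim)
    jsonlite::write_json(list(coefficients = as.list(coef(reg$fit)),
                              p_values = as.list(tidy(reg)$p_value),
                              adjusted_r2 = reg$adj_r2,
                              n_patches = reg$n_patches),
                         path("fg_regression.json"), auto_unbox = TRUE,
                         digits = NA)
    .log_line(log, "fg: %d patches, adjusted R^2 %.3f", reg$n_patches,
              reg$adj_r2)
  }

  invisible(config$out_dir)
}

# Column schemas for validate_io
.io_schemas <- list(
  ratings = list(cols = c("observer_id", "stimulus_a", "stimulus_b",
                          "repetition", "rating"),
                 check = function(d) {
                   v <- character()
                   if (any(d$rating < 1 | d$rating > 5))
                     v <- c(v, "rating out of 1-5")
                   v
                 }),
  responses = list(cols = c("observer_id", "patch_id", "repetition",
                            "group", "answer"),
                   check = function(d) {
                     v <- character()
                     if (!all(d$group %in% c("vertical", "horizontal")))
                       v <- c(v, "group not vertical/horizontal")
                     bad <- mapply(function(a, g)
                       !a %in% .group_answers[[g]], d$answer, d$group)
                     if (any(bad)) v <- c(v, "answer inconsistent with group")
                     v
                   }),
  cues = list(cols = c("patch_id", "convexity", "closure", "symmetry"),
              check = function(d) {
                v <- character()
                if (any(d$convexity < 0)) v <- c(v, "negative convexity")
                if (any(abs(d$closure) > 16)) v <- c(v, "closure out of [-16, 16]")
                if (any(abs(d$symmetry) > 1 + 1e-9))
                  v <- c(v, "symmetry out of [-1, 1]")
                v
              }),
  dissimilarity = list(cols = NULL,
                       check = function(m) {
                         v <- character()
                         if (!isSymmetric(unname(as.matrix(m)), tol = 1e-8))
                           v <- c(v, "matrix not symmetric")
                         if (any(diag(as.matrix(m)) != 0))
                           v <- c(v, "nonzero diagonal")
                         v
                       })
)

#' Validate a pipeline artifact against its schema
#'
#' Checks a CSV (or numeric matrix CSV for `"dissimilarity"`) against the
#' named schema and reports row counts and violations.
#'
#' @param path File path.
#' @param schema One of `"ratings"`, `"responses"`, `"cues"`,
#'   `"dissimilarity"`.
#' @return A list with `path`, `schema`, `n_rows`, `violations`
#'   (character vector, empty when clean).
#' @export
validate_io <- function(path, schema = c("ratings", "responses", "cues",
                                         "dissimilarity")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) abort(sprintf("unreadable file: %s", path))
  sc <- .io_schemas[[schema]]
  if (schema == "dissimilarity") {
    d <- as.matrix(read.csv(path, header = FALSE))
    violations <- sc$check(d)
    n <- nrow(d)
  } else {
    d <- read.csv(path, stringsAsFactors = FALSE)
    missing <- setdiff(sc$cols, names(d))
    violations <- if (length(missing))
      paste("missing column(s):", paste(missing, collapse = ", "))
    else sc$check(d)
    n <- nrow(d)
  }
  list(path = path, schema = schema, n_rows = n,
       violations = as.character(violations))
}
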