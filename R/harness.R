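#' Default pipeline configuration
#'
#' Returns the fully-defaulted configuration used by [run_pipeline()].
#' The `experiment` block sets the simulated study (subjects, runs, grid,
#' TR, implanted effect); `analysis` sets the decoding/RSA parameters
#' (radius 4 mm, 100 shuffle repetitions, 10000 permutations by default);
#' `seeds` holds the single master seed every stage fans out from.
#'
#' @return nested named list.
#' @export
default_pipeline_config <- function() {
  list(
    experiment = list(n_subjects = 4L, n_runs = 2L,
                      grid_shape = c(12L, 12L, 12L), spacing = 2.4,
                      tr = 0.85, n_trim = 10L, effect_scale = 1,
                      noise_sd = 1, dimension = "desirability"),
    analysis = list(dimension = "desirability",
                    scheme = "leave_one_run_out", radius_mm = 4,
                    n_reps = 100L, test_fraction = 0.2,
                    n_perm = 10000L, alpha = 0.05,
                    rsa_shuffles = 20L, run_rsa = TRUE,
                    run_encoding = TRUE),
    seeds = list(master = 1L),
    paths = list(out_dir = NULL)
  )
}

#' Validate a pipeline configuration
#'
#' Accepts a nested list or a path to a JSON file, fills in defaults,
#' rejects unknown keys, and reports every invalid value in one itemized
#' error.
#'
#' @param config nested list or JSON file path.
#' @return the fully-defaulted, validated configuration (class
#'   `pipeline_config`).
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  defaults <- default_pipeline_config()
  errors <- character(0)
  unknown_blocks <- setdiff(names(config), names(defaults))
  if (length(unknown_blocks))
    errors <- c(errors, paste0("unknown block(s): ",
                               paste(unknown_blocks, collapse = ", ")))
  merged <- defaults
  for (blk in intersect(names(config), names(defaults))) {
    unknown <- setdiff(names(config[[blk]]), names(defaults[[blk]]))
    if (length(unknown))
      errors <- c(errors, paste0("unknown key(s) in ", blk, ": ",
                                 paste(unknown, collapse = ", ")))
    for (key in intersect(names(config[[blk]]), names(defaults[[blk]])))
      merged[[blk]][[key]] <- config[[blk]][[key]]
  }
  chk <- function(cond, msg) if (!isTRUE(cond)) errors <<- c(errors, msg)
  e <- merged$experiment; a <- merged$analysis
  chk(e$n_subjects >= 1, "experiment$n_subjects must be >= 1")
  chk(e$n_runs >= 1, "experiment$n_runs must be >= 1")
  chk(length(e$grid_shape) == 3 && all(e$grid_shape >= 4),
      "experiment$grid_shape must be 3 values >= 4")
  chk(e$spacing > 0, "experiment$spacing must be positive")
  chk(e$tr > 0, "experiment$tr must be positive")
  chk(e$effect_scale >= 0, "experiment$effect_scale must be >= 0")
  chk(e$noise_sd >= 0, "experiment$noise_sd must be >= 0")
  chk(a$radius_mm > 0, "analysis$radius_mm must be positive")
  chk(a$n_reps >= 1, "analysis$n_reps must be >= 1")
  chk(a$n_perm >= 1, "analysis$n_perm must be >= 1")
  chk(a$alpha > 0 && a$alpha < 1, "analysis$alpha must be in (0, 1)")
  chk(a$dimension %in% c("affect", "desirability"),
      "analysis$dimension must be 'affect' or 'desirability'")
  chk(a$scheme %in% c("stratified_shuffle", "leave_one_run_out",
                      "leave_two_concepts_out"),
      "analysis$scheme is not a known CV scheme")
  chk(is.numeric(merged$seeds$master) && length(merged$seeds$master) == 1,
      "seeds$master must be a single number")
  if (length(errors))
    stop("invalid configuration:\n  - ",
         paste(errors, collapse = "\n  - "))
  merged$experiment$grid_shape <- as.integer(merged$experiment$grid_shape)
  # JSON round-trips encode NULL paths as empty containers
  if (!length(merged$paths$out_dir)) merged$paths["out_dir"] <- list(NULL)
  class(merged) <- c("pipeline_config", "list")
  merged
}

#' Run the end-to-end synthetic pipeline
#'
#' Simulates the configured experiment, prepares examples, runs the
#' searchlight decoder per subject, performs group TFCE sign-flip
#' inference, optionally adds model-based RSA and encoding-based RSA
#' maps, computes the behavioral report, and writes every product (NIfTI
#' maps with JSON sidecars, TSV tables, a provenance manifest) under
#' `out_dir`. Deterministic given `seeds$master`.
#'
#' @param config a `pipeline_config` (or list/path accepted by
#'   [validate_config()]).
#' @param out_dir output directory (overrides `paths$out_dir`).
#' @return invisibly, a list with the in-memory results (`subject_maps`,
#'   `group`, `rsa`, `encoding`, `behavior`, `manifest`).
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = NULL) {
  cfg <- validate_config(unclass(config))
  out_dir <- out_dir %||% cfg$paths$out_dir %||%
    stop("no output directory given")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  e <- cfg$experiment; a <- cfg$analysis
  master <- as.integer(cfg$seeds$master)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(err)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(err),
           " (partial results in ", out_dir, ")", call. = FALSE))
    message(sprintf("[%s] %.1f s", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  concept_set <- make_concept_set(seed = master)
  grid <- make_volume_grid(e$grid_shape, e$spacing)
  embeddings <- simulate_embeddings(concept_set, max_tokens = 4L,
                                    width = 16L, class_effect = 2,
                                    dimension = a$dimension,
                                    seed = substream_seed(master, 21L))
  model_rdm <- compute_rdm(embeddings)

  subjects <- stage("simulate+prepare", lapply(seq_len(e$n_subjects),
    function(s) {
      spec <- make_signal_spec(grid, dimension = e$dimension,
                               effect_scale = e$effect_scale,
                               noise_sd = e$noise_sd,
                               seed = substream_seed(master, 100L + s))
      sim <- simulate_subject(concept_set, grid, spec, n_runs = e$n_runs,
                              tr = e$tr,
                              seed = substream_seed(master, 200L + s))
      # leave room for the trimmed lead-in
      sim$runs <- lapply(sim$runs, function(r) {
        pad <- array(r$data[, , , 1], dim = c(grid$shape, e$n_trim))
        bold_run(array(c(pad, r$data),
                       dim = c(grid$shape, e$n_trim + dim(r$data)[4])),
                 grid, tr = r$tr, run_id = r$run_id)
      })
      sim$events <- lapply(sim$events, function(ev) {
        ev$onset <- ev$onset + e$n_trim * e$tr
        ev
      })
      es <- prepare_examples(sim$runs, sim$events, n_trim = e$n_trim)
      list(example_set = es, manifest = sim$manifest, roi = spec$roi)
    }))

  subject_maps <- stage("searchlight", lapply(seq_along(subjects),
    function(s) {
      m <- run_searchlight(subjects[[s]]$example_set,
                           dimension = a$dimension, scheme = a$scheme,
                           n_reps = a$n_reps,
                           test_fraction = a$test_fraction,
                           radius_mm = a$radius_mm,
                           seed = substream_seed(master, 300L + s))
      p <- file.path(out_dir, sprintf("sub-%02d_%s_%s.nii.gz", s,
                                      a$dimension, a$scheme))
      write_stat_map(m, p, sidecar = list(
        operation = "run_searchlight", subject = s,
        dimension = a$dimension, scheme = a$scheme,
        radius_mm = a$radius_mm, n_reps = a$n_reps,
        seed = substream_seed(master, 300L + s)))
      m
    }))

  group <- stage("groupstats", {
    g <- one_sample_signflip(subject_maps, n_perm = a$n_perm,
                             alpha = a$alpha,
                             seed = substream_seed(master, 400L))
    write_stat_map(g$tfce_map, file.path(out_dir, "group_tfce.nii.gz"),
                   sidecar = list(operation = "one_sample_signflip",
                                  n_perm = a$n_perm, alpha = a$alpha,
                                  seed = substream_seed(master, 400L)))
    write_stat_map(g$p_map, file.path(out_dir, "group_p.nii.gz"))
    jsonlite::write_json(cluster_table(g),
                         file.path(out_dir, "group_clusters.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    g
  })

  rsa_res <- NULL
  if (isTRUE(a$run_rsa)) rsa_res <- stage("rsa", {
    maps <- lapply(seq_along(subjects), function(s) {
      pat <- average_per_concept(subjects[[s]]$example_set)
      obs <- searchlight_rsa(pat, model_rdm, radius_mm = a$radius_mm)
      ch <- rsa_chance(pat, model_rdm, radius_mm = a$radius_mm,
                       n_shuffles = a$rsa_shuffles,
                       seed = substream_seed(master, 500L + s))
      diff <- stat_map(obs$values - ch$values, obs$grid, "z_minus_chance")
      write_stat_map(diff,
                     file.path(out_dir,
                               sprintf("sub-%02d_rsa.nii.gz", s)),
                     sidecar = list(operation = "searchlight_rsa",
                                    subject = s,
                                    n_shuffles = a$rsa_shuffles,
                                    radius_mm = a$radius_mm))
      diff
    })
    maps
  })

  enc_res <- NULL
  if (isTRUE(a$run_encoding) && e$n_subjects >= 3)
    enc_res <- stage("encoding", {
      pats <- lapply(subjects, function(s)
        average_per_concept(s$example_set))
      maps <- lapply(seq_along(pats), function(s) {
        enc <- fit_ridge_encoder(embeddings, pats, holdout_subject = s,
                                 n_chunks = 5L)
        pred <- chunked_predict(enc, embeddings)
        obs <- encoding_rsa_map(pred, pats[[s]], radius_mm = a$radius_mm)
        ch <- encoding_rsa_chance(pred, pats[[s]],
                                  radius_mm = a$radius_mm,
                                  n_shuffles = a$rsa_shuffles,
                                  seed = substream_seed(master, 600L + s))
        diff <- stat_map(obs$values - ch$values, obs$grid,
                         "z_minus_chance")
        write_stat_map(diff,
                       file.path(out_dir,
                                 sprintf("sub-%02d_encoding.nii.gz", s)),
                       sidecar = list(operation = "encoding_rsa_map",
                                      subject = s, lambda = enc$lambda))
        diff
      })
      maps
    })

  behavior <- stage("behavior", {
    ratings <- simulate_ratings(concept_set, n_subjects = e$n_subjects,
                                seed = substream_seed(master, 700L))
    rep <- behavioral_report(ratings, concept_set)
    write.table(ratings, file.path(out_dir, "ratings.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    flat <- lapply(rep, function(r) list(
      t = r$contrast$statistic, df = r$contrast$df,
      d = r$contrast$effect_size, ln_bf10 = r$contrast$ln_bf10,
      p = r$contrast$p_value, icc = r$retest$icc,
      icc_ci = c(r$retest$ci_lower, r$retest$ci_upper)))
    jsonlite::write_json(flat, file.path(out_dir, "behavior.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    rep
  })

  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- list(config_hash = unname(tools::md5sum(cfg_path)),
                   master_seed = master,
                   package_version =
                     as.character(utils::packageVersion("socialmap")),
                   ground_truth = lapply(subjects, `[[`, "manifest"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(subject_maps = subject_maps, group = group,
                 rsa = rsa_res, encoding = enc_res, behavior = behavior,
                 manifest = manifest,
                 roi = subjects[[1]]$roi))
}
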