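#' Build the 2x2 factorial set of social concepts
#'
#' The experimental design crosses two binary dimensions of social-trait
#' concepts — affect (whether the trait explicitly involves emotion) and
#' social desirability (how likable the trait is) — with nine concepts in
#' each of the four cells, 36 concepts in total. Definitions are synthetic
#' placeholder sentences; only the factorial label structure matters for
#' the analyses.
#'
#' @param seed integer seed (fixes the placeholder definitions).
#' @return A `data.frame` with columns `concept_id` (0-35), `affect`
#'   (`"high"`/`"low"`), `desirability` (`"high"`/`"low"`), `definition`.
#' @export
make_concept_set <- function(seed = 1L) {
  cells <- expand.grid(affect = c("high", "low"),
                       desirability = c("high", "low"),
                       stringsAsFactors = FALSE)
  cs <- cells[rep(seq_len(4), each = 9), ]
  cs$concept_id <- 0:35
  cs$definition <- sprintf(
    "She behaves in a way typical of trait %02d (%s affect, %s desirability).",
    cs$concept_id, cs$affect, cs$desirability)
  rownames(cs) <- NULL
  cs[, c("concept_id", "affect", "desirability", "definition")]
}

#' Default intertrial-interval distribution
#'
#' Jitter between the offset of one audio definition and the onset of the
#' next follows a pseudo-exponential distribution on 6-8 s in 0.5-s steps:
#' probabilities halve per step (50%, 25%, 12.5%, ...) and the remaining
#' mass is assigned to the final 8-s bin so the distribution sums to 1.
#'
#' @return `data.frame` with columns `iti` (seconds) and `prob`.
#' @export
default_iti_spec <- function() {
  iti <- c(6, 6.5, 7, 7.5, 8)
  prob <- c(0.5, 0.25, 0.125, 0.0625, 0)
  prob[length(prob)] <- 1 - sum(prob)
  data.frame(iti = iti, prob = prob)
}

#' Draw intertrial intervals from a jitter distribution
#'
#' @param n number of intervals.
#' @param iti_spec `data.frame(iti, prob)`; probabilities must sum to 1.
#' @param mode `"sample"` draws i.i.d. from the distribution;
#'   `"deterministic"` allocates counts by largest remainder (exact
#'   proportions whenever `n * prob` are integers) and shuffles the order.
#' @param seed integer seed.
#' @return numeric vector of `n` intervals in seconds.
#' @export
draw_itis <- function(n, iti_spec = default_iti_spec(),
                      mode = c("sample", "deterministic"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n >= 1, abs(sum(iti_spec$prob) - 1) < 1e-8,
            all(iti_spec$prob >= 0))
  with_seed(seed, {
    if (mode == "sample") {
      sample(iti_spec$iti, n, replace = TRUE, prob = iti_spec$prob)
    } else {
      exact <- n * iti_spec$prob
      cnt <- floor(exact)
      rem <- n - sum(cnt)
      if (rem > 0) {
        frac_order <- order(exact - cnt, decreasing = TRUE)
        cnt[frac_order[seq_len(rem)]] <- cnt[frac_order[seq_len(rem)]] + 1
      }
      sample(rep(iti_spec$iti, cnt))
    }
  })
}

#' Generate per-run event schedules
#'
#' Each run presents all 36 concepts once in a run-specific random order.
#' A trial consists of a 0.25-s fixation, a 0.5-s blank, a 3.5-s audio
#' definition and a 2-s mental-simulation period; the tabulated `onset` is
#' the audio onset and `duration` the audio length. The jittered interval
#' between audio offset and the next audio onset is drawn from `iti_spec`
#' (the simulation period and the next trial's fixation/blank fall inside
#' that gap).
#'
#' @param concept_set from [make_concept_set()].
#' @param n_runs number of runs (default 8).
#' @param trial_timing named list with `fixation`, `blank`, `audio`,
#'   `simulation` durations in seconds.
#' @param iti_spec jitter distribution, see [default_iti_spec()].
#' @param seed integer master seed; runs get deterministic sub-seeds.
#' @param first_onset audio onset of the first trial (seconds).
#' @param run_duration available run length in seconds (default
#'   537 volumes x 0.85 s); a schedule whose last trial (plus simulation
#'   period) would not fit is refused.
#' @param iti_mode passed to [draw_itis()].
#' @return list of per-run `data.frame`s with columns `onset`, `duration`,
#'   `concept_id`, `affect`, `desirability`, `run_id`.
#' @export
make_event_schedule <- function(concept_set, n_runs = 8L,
                                trial_timing = list(fixation = 0.25,
                                                    blank = 0.5,
                                                    audio = 3.5,
                                                    simulation = 2.0),
                                iti_spec = default_iti_spec(), seed = 1L,
                                first_onset = 10, run_duration = 537 * 0.85,
                                iti_mode = "sample") {
  stopifnot(n_runs >= 1, nrow(concept_set) >= 1)
  n_trials <- nrow(concept_set)
  lapply(seq_len(n_runs), function(r) {
    sub <- substream_seed(seed, r)
    ord <- with_seed(sub, sample(n_trials))
    itis <- if (n_trials > 1)
      draw_itis(n_trials - 1, iti_spec, mode = iti_mode,
                seed = substream_seed(seed, 1000L + r)) else numeric(0)
    onsets <- first_onset +
      cumsum(c(0, trial_timing$audio + itis))
    run_end <- onsets[n_trials] + trial_timing$audio +
      trial_timing$simulation
    if (run_end > run_duration)
      stop(sprintf(paste0("run %d schedule ends at %.2f s but only %.2f s",
                          " are available; reduce trials or ITIs"),
                   r, run_end, run_duration))
    ev <- concept_set[ord, c("concept_id", "affect", "desirability")]
    data.frame(onset = onsets, duration = trial_timing$audio,
               concept_id = ev$concept_id, affect = ev$affect,
               desirability = ev$desirability, run_id = r,
               row.names = NULL)
  })
}

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities with response delay 6 s, undershoot
#' delay 16 s, unit dispersions and a 1/6 undershoot ratio — the standard
#' shape used for event-related BOLD modelling. Needed only for synthesis;
#' the analysis side works on raw (simulated) BOLD.
#'
#' @param t time in seconds (vector).
#' @param peak_delay,undershoot_delay gamma shape parameters (s).
#' @param ratio peak-to-undershoot amplitude ratio.
#' @return HRF values, peak normalized to 1.
#' @export
hrf_double_gamma <- function(t, peak_delay = 6, undershoot_delay = 16,
                             ratio = 6) {
  h <- stats::dgamma(t, shape = peak_delay, rate = 1) -
    stats::dgamma(t, shape = undershoot_delay, rate = 1) / ratio
  h[t < 0] <- 0
  pk <- stats::dgamma(peak_delay - 1, shape = peak_delay, rate = 1) -
    stats::dgamma(peak_delay - 1, shape = undershoot_delay, rate = 1) / ratio
  h / pk
}

#' Specify the ground-truth signal implanted in simulated BOLD
#'
#' Defines where (an ROI inside the brain mask) and how strongly simulated
#' trials evoke condition-specific multivoxel patterns. Patterns are fixed
#' per simulated subject — consistent across runs — since cross-run decoding
#' presumes stable patterns. With `pattern_by = "class"` each level of
#' `dimension` has its own pattern vector; with `"concept"` each of the 36
#' concepts does (used for representational-structure recovery).
#'
#' @param grid a `volume_grid`.
#' @param roi logical array (ROI must lie inside the grid mask) or `NULL`
#'   for a default 3x3x3 block at the mask centre.
#' @param pattern_by `"class"` or `"concept"`.
#' @param dimension which label drives class patterns (`"affect"` or
#'   `"desirability"`); ignored for `"concept"`.
#' @param patterns optional matrix (classes or concepts) x ROI-voxels of
#'   pattern amplitudes; drawn standard normal if `NULL`.
#' @param n_patterns number of pattern rows when `patterns` is `NULL`
#'   (2 for class mode, 36 for concept mode).
#' @param effect_scale multiplies the pattern amplitudes (>= 0).
#' @param noise_sd i.i.d. Gaussian noise SD in signal units (>= 0).
#' @param drift_amplitude max absolute linear drift over a run.
#' @param smooth_fwhm optional Gaussian smoothing FWHM in mm (0 = none).
#' @param baseline constant baseline level.
#' @param seed seed for drawing default patterns.
#' @return A `signal_spec` object.
#' @export
make_signal_spec <- function(grid, roi = NULL,
                             pattern_by = c("class", "concept"),
                             dimension = "desirability", patterns = NULL,
                             n_patterns = NULL, effect_scale = 1,
                             noise_sd = 1, drift_amplitude = 0,
                             smooth_fwhm = 0, baseline = 100, seed = 1L) {
  pattern_by <- match.arg(pattern_by)
  stopifnot(effect_scale >= 0, noise_sd >= 0, drift_amplitude >= 0,
            smooth_fwhm >= 0)
  if (is.null(roi)) {
    roi <- array(FALSE, dim = grid$shape)
    ctr <- round((grid$shape + 1) / 2)
    rng <- lapply(ctr, function(c) pmax(1, c - 1):pmin(grid$shape[1], c + 1))
    roi[rng[[1]], rng[[2]], rng[[3]]] <- TRUE
    roi <- roi & grid$mask
  }
  stopifnot(all(dim(roi) == grid$shape))
  if (any(roi & !grid$mask)) stop("ROI extends outside the grid mask")
  if (!any(roi)) stop("ROI is empty")
  n_roi <- sum(roi)
  if (is.null(n_patterns))
    n_patterns <- if (pattern_by == "class") 2L else 36L
  if (is.null(patterns))
    patterns <- with_seed(seed,
                          matrix(rnorm(n_patterns * n_roi), n_patterns, n_roi))
  stopifnot(ncol(patterns) == n_roi)
  structure(list(roi = roi, pattern_by = pattern_by, dimension = dimension,
                 patterns = patterns, effect_scale = effect_scale,
                 noise_sd = noise_sd, drift_amplitude = drift_amplitude,
                 smooth_fwhm = smooth_fwhm, baseline = baseline),
            class = "signal_spec")
}

# Separable 3D Gaussian smoothing (kernel truncated at 3 sigma per axis).
gaussian_smooth_3d <- function(arr, fwhm_mm, spacing) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / spacing
  out <- arr
  for (axis in 1:3) {
    s <- sigma[axis]
    if (s < 1e-6) next
    half <- max(1L, ceiling(3 * s))
    k <- exp(-(seq(-half, half))^2 / (2 * s^2))
    k <- k / sum(k)
    out <- .smooth_along(out, k, axis)
  }
  out
}

.smooth_along <- function(arr, kernel, axis) {
  d <- dim(arr)
  half <- (length(kernel) - 1L) / 2L
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[axis])
  n <- nrow(m)
  res <- matrix(0, n, ncol(m))
  for (o in seq_along(kernel)) {
    shift <- o - half - 1L
    src <- pmin(pmax(seq_len(n) + shift, 1L), n)  # replicate edges
    res <- res + kernel[o] * m[src, , drop = FALSE]
  }
  aperm(array(res, dim = d[perm]), order(perm))
}

#' Simulate one run of event-related BOLD data
#'
#' The voxel time series is baseline + HRF-convolved stimulus boxcars
#' scaled by condition-specific ROI patterns + a per-voxel linear drift +
#' i.i.d. Gaussian noise, optionally followed by Gaussian smoothing. The
#' stimulus boxcar spans each event's `onset` to `onset + duration`,
#' sampled at TR resolution, convolved with [hrf_double_gamma()].
#'
#' @param events one run's event table (see [make_event_schedule()]).
#' @param grid a `volume_grid`.
#' @param signal_spec a [make_signal_spec()] object.
#' @param n_volumes number of volumes (default 537).
#' @param tr repetition time in seconds (default 0.85).
#' @param seed integer seed for noise and drift.
#' @return A `bold_run`.
#' @export
simulate_bold <- function(events, grid, signal_spec, n_volumes = 537L,
                          tr = 0.85, seed = 1L) {
  stopifnot(inherits(signal_spec, "signal_spec"), n_volumes >= 1, tr > 0)
  if (nrow(events) &&
      max(events$onset + events$duration) > n_volumes * tr)
    stop("event schedule does not fit within n_volumes * tr")
  sp <- signal_spec
  shp <- grid$shape
  n_vox <- prod(shp)
  t_grid <- (seq_len(n_volumes) - 1) * tr
  hrf <- hrf_double_gamma(seq(0, 32, by = tr))

  # one HRF-convolved regressor per pattern row
  if (sp$pattern_by == "class") {
    lev <- sort(unique(events[[sp$dimension]]))
    if (nrow(sp$patterns) < length(lev))
      stop("signal_spec has fewer patterns than classes")
    cond_of <- match(events[[sp$dimension]], lev)
  } else {
    cond_of <- events$concept_id + 1L
  }
  n_cond <- nrow(sp$patterns)
  design <- matrix(0, n_volumes, n_cond)
  for (i in seq_len(nrow(events))) {
    box <- as.numeric(t_grid >= events$onset[i] &
                      t_grid < events$onset[i] + events$duration[i])
    reg <- stats::convolve(box, rev(hrf), type = "open")[seq_len(n_volumes)]
    design[, cond_of[i]] <- design[, cond_of[i]] + reg
  }

  data <- array(sp$baseline, dim = c(shp, n_volumes))
  dim(data) <- c(n_vox, n_volumes)
  roi_idx <- which(sp$roi)
  if (sp$effect_scale > 0 && length(roi_idx)) {
    sig <- design %*% (sp$effect_scale * sp$patterns)  # t x roi voxels
    data[roi_idx, ] <- data[roi_idx, ] + t(sig)
  }
  with_seed(seed, {
    if (sp$drift_amplitude > 0) {
      slopes <- runif(n_vox, -1, 1) * sp$drift_amplitude
      tt <- seq(-0.5, 0.5, length.out = n_volumes)
      data <- data + outer(slopes, tt)
    }
    if (sp$noise_sd > 0)
      data <- data + matrix(rnorm(n_vox * n_volumes, sd = sp$noise_sd),
                            n_vox, n_volumes)
  })
  dim(data) <- c(shp, n_volumes)
  if (sp$smooth_fwhm > 0) {
    spc <- voxel_spacing(grid)
    for (v in seq_len(n_volumes))
      data[, , , v] <- gaussian_smooth_3d(data[, , , v], sp$smooth_fwhm, spc)
  }
  bold_run(data, grid, tr = tr,
           run_id = if (nrow(events)) events$run_id[1] else 1L)
}

#' Simulate sentence-embedding matrices with class structure
#'
#' Emulates flattened per-token hidden states of a language model: each of
#' the 36 sentences gets `token_count x width` standard-normal features,
#' zero-padded to `max_tokens` tokens and flattened token-major (defaults
#' 21 x 768 = 16128 elements). A class-dependent mean shift of magnitude
#' `class_effect` is applied along a random unit direction within the
#' first-token block (always present regardless of sentence length).
#'
#' @param concept_set from [make_concept_set()].
#' @param max_tokens,width embedding geometry (defaults 21, 768).
#' @param class_effect separation (distance between class means) along the
#'   shifted direction; 0 gives pure null embeddings.
#' @param dimension which label carries the shift.
#' @param seed integer seed.
#' @return numeric matrix `36 x (max_tokens*width)` with attributes
#'   `token_counts`, `max_tokens`, `width`, `padding` (`"zero_tail"`).
#' @export
simulate_embeddings <- function(concept_set, max_tokens = 21L, width = 768L,
                                class_effect = 0, dimension = "affect",
                                seed = 1L) {
  stopifnot(max_tokens >= 1, width >= 1)
  n <- nrow(concept_set)
  n_feat <- max_tokens * width
  with_seed(seed, {
    token_counts <- sample(seq(max(1L, min(5L, max_tokens)), max_tokens),
                           n, replace = TRUE)
    E <- matrix(0, n, n_feat)
    for (i in seq_len(n)) {
      k <- token_counts[i] * width
      E[i, seq_len(k)] <- rnorm(k)
    }
    if (class_effect > 0) {
      u <- rnorm(width)
      u <- u / sqrt(sum(u^2))
      hi <- concept_set[[dimension]] == "high"
      E[hi, seq_len(width)] <- E[hi, seq_len(width)] +
        matrix(class_effect / 2 * u, sum(hi), width, byrow = TRUE)
      E[!hi, seq_len(width)] <- E[!hi, seq_len(width)] -
        matrix(class_effect / 2 * u, sum(!hi), width, byrow = TRUE)
    }
    structure(E, token_counts = token_counts, max_tokens = max_tokens,
              width = width, padding = "zero_tail")
  })
}

#' Simulate pre/post behavioral ratings
#'
#' Each subject rates every concept on both dimensions (0-100 scale) before
#' and after scanning. Sessions share a subject-by-concept true score
#' (cell mean + subject-level deviation) and differ only by independent
#' session noise, so the expected test-retest reliability is
#' `between_subject_sd^2 / (between_subject_sd^2 + noise_sd^2)` (before
#' clipping). Values are clipped to \[0, 100\]; the clipped count is
#' recorded in attribute `n_clipped`.
#'
#' @param concept_set from [make_concept_set()].
#' @param n_subjects number of subjects (default 30).
#' @param mean_by_cell named list: for each dimension, `c(high=, low=)`
#'   population mean rating of concepts whose label on that dimension is
#'   high/low. Defaults follow the study conditions.
#' @param between_subject_sd SD of subject-by-concept true-score deviations.
#' @param noise_sd SD of per-session measurement noise.
#' @param seed integer seed.
#' @return long `data.frame(subject_id, concept_id, dimension, session,
#'   rating)` with the complete crossing.
#' @export
simulate_ratings <- function(concept_set, n_subjects = 30L,
                             mean_by_cell = list(
                               affect = c(high = 68.5, low = 45.8),
                               desirability = c(high = 84.5, low = 15.4)),
                             between_subject_sd = 10, noise_sd = 5,
                             seed = 1L) {
  stopifnot(n_subjects >= 1, between_subject_sd >= 0, noise_sd >= 0)
  for (d in names(mean_by_cell))
    stopifnot(all(mean_by_cell[[d]] >= 0 & mean_by_cell[[d]] <= 100))
  n_c <- nrow(concept_set)
  dims <- names(mean_by_cell)
  with_seed(seed, {
    out <- vector("list", length(dims))
    for (di in seq_along(dims)) {
      d <- dims[di]
      mu <- mean_by_cell[[d]][concept_set[[d]]]
      base <- expand.grid(subject_id = seq_len(n_subjects),
                          concept_id = concept_set$concept_id)
      truth <- rep(mu, each = n_subjects) +
        rnorm(nrow(base), sd = between_subject_sd)
      pre <- truth + rnorm(nrow(base), sd = noise_sd)
      post <- truth + rnorm(nrow(base), sd = noise_sd)
      out[[di]] <- rbind(
        data.frame(base, dimension = d, session = "pre", rating = pre),
        data.frame(base, dimension = d, session = "post", rating = post))
    }
    res <- do.call(rbind, out)
    n_clipped <- sum(res$rating < 0 | res$rating > 100)
    res$rating <- pmin(pmax(res$rating, 0), 100)
    rownames(res) <- NULL
    structure(res, n_clipped = n_clipped)
  })
}

#' Simulate a full subject (events, BOLD runs, ground-truth manifest)
#'
#' Convenience wrapper tying the design, schedule and BOLD generators
#' together. The returned manifest records the ground truth (ROI, pattern
#' mode, effect scale, seeds) so downstream recovery tests can score
#' themselves against what was implanted.
#'
#' @param concept_set from [make_concept_set()].
#' @param grid a `volume_grid`.
#' @param signal_spec a `signal_spec`.
#' @param n_runs,tr,n_volumes acquisition parameters; `n_volumes = NULL`
#'   sizes each run to fit its schedule plus a 15-s tail.
#' @param seed master seed; per-run noise seeds are derived from it.
#' @param iti_mode passed to [make_event_schedule()].
#' @param first_onset,run_duration passed to [make_event_schedule()].
#' @return list with `events` (list per run), `runs` (list of `bold_run`),
#'   `manifest` (named list of ground truth).
#' @export
simulate_subject <- function(concept_set, grid, signal_spec, n_runs = 8L,
                             tr = 0.85, n_volumes = NULL, seed = 1L,
                             iti_mode = "sample", first_onset = 10,
                             run_duration = NULL) {
  if (is.null(run_duration))
    run_duration <- if (is.null(n_volumes)) Inf else n_volumes * tr
  events <- make_event_schedule(concept_set, n_runs = n_runs, seed = seed,
                                iti_mode = iti_mode,
                                first_onset = first_onset,
                                run_duration = run_duration)
  runs <- lapply(seq_len(n_runs), function(r) {
    nv <- n_volumes %||%
      ceiling((max(events[[r]]$onset + events[[r]]$duration) + 15) / tr)
    simulate_bold(events[[r]], grid, signal_spec, n_volumes = nv, tr = tr,
                  seed = substream_seed(seed, 5000L + r))
  })
  manifest <- list(seed = seed, n_runs = n_runs, tr = tr,
                   grid_shape = grid$shape,
                   roi_voxels = which(signal_spec$roi),
                   pattern_by = signal_spec$pattern_by,
                   dimension = signal_spec$dimension,
                   effect_scale = signal_spec$effect_scale,
                   noise_sd = signal_spec$noise_sd)
  list(events = events, runs = runs, manifest = manifest)
}

#' Write an event table as BIDS-style TSV
#' @param events one run's event table.
#' @param path output `.tsv` path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  out <- data.frame(onset = events$onset, duration = events$duration,
                    trial_type = paste(events$affect, events$desirability,
                                       sep = "_"),
                    concept_id = events$concept_id, affect = events$affect,
                    desirability = events$desirability)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BIDS-style events TSV
#' @param path `.tsv` path written by [write_events_tsv()].
#' @param run_id run identifier to attach.
#' @return event table `data.frame`.
#' @export
read_events_tsv <- function(path, run_id = 1L) {
  ev <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  ev$run_id <- run_id
  ev
}
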