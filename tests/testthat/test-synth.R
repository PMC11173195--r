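test_that("concept set is a balanced 2x2 factorial of 36 concepts", {
  cs <- fx_concepts
  expect_equal(nrow(cs), 36L)
  expect_equal(length(unique(cs$concept_id)), 36L)
  tab <- table(cs$affect, cs$desirability)
  expect_true(all(tab == 9L))
  expect_equal(sum(tab), 36L)
  # orthogonal factors: 18/18 marginal split on each
  expect_equal(as.vector(table(cs$affect)), c(18L, 18L))
  expect_equal(as.vector(table(cs$desirability)), c(18L, 18L))
})

test_that("event schedules respect ordering, jitter bounds and counts", {
  sched <- make_event_schedule(fx_concepts, n_runs = 8, seed = 4)
  expect_length(sched, 8L)
  expect_equal(sum(vapply(sched, nrow, integer(1))), 288L)
  for (ev in sched) {
    expect_true(all(diff(ev$onset) > 0))
    gaps <- diff(ev$onset)
    # spacing >= stimulus length + 6 s, <= stimulus + 8 s
    expect_true(all(gaps >= ev$duration[1] + 6 - 1e-9))
    expect_true(all(gaps <= ev$duration[1] + 8 + 1e-9))
    expect_equal(sort(ev$concept_id), 0:35)
  }
  # orders differ between runs
  expect_false(identical(sched[[1]]$concept_id, sched[[2]]$concept_id))
  # schedule that cannot fit is refused with a diagnostic
  expect_error(make_event_schedule(fx_concepts, n_runs = 1,
                                   run_duration = 100),
               "schedule ends")
})

test_that("ITI distribution follows the halving pseudo-exponential", {
  spec <- default_iti_spec()
  expect_equal(spec$prob, c(0.5, 0.25, 0.125, 0.0625, 0.0625))
  expect_equal(sum(spec$prob), 1)
  # deterministic allocation is exact when n * prob are integers
  itis <- draw_itis(1600, spec, mode = "deterministic", seed = 2)
  expect_equal(as.vector(table(itis)[as.character(c(6, 6.5, 7))]),
               c(800L, 400L, 200L))
  # sampled mode approximates the proportions
  itis <- draw_itis(10000, spec, mode = "sample", seed = 3)
  props <- table(itis) / 10000
  expect_equal(as.vector(props[c("6", "6.5", "7")]),
               c(0.5, 0.25, 0.125), tolerance = 0.05)
})

test_that("simulated BOLD matches a direct-convolution oracle", {
  grid <- make_volume_grid(c(3L, 3L, 3L), mask = "full")
  roi <- array(FALSE, dim = grid$shape); roi[2, 2, 2] <- TRUE
  tr <- 0.85; nvol <- 80L
  spec <- make_signal_spec(grid, roi = roi, patterns = matrix(1, 1, 1),
                           n_patterns = 1, effect_scale = 1, noise_sd = 0,
                           baseline = 0, pattern_by = "concept")
  ev <- data.frame(onset = 10, duration = 3.5, concept_id = 0,
                   affect = "high", desirability = "high", run_id = 1)
  run <- simulate_bold(ev, grid, spec, n_volumes = nvol, tr = tr, seed = 1)
  ts <- run$data[2, 2, 2, ]
  # independent oracle: brute-force discrete convolution at TR resolution
  tgrid <- (seq_len(nvol) - 1) * tr
  box <- as.numeric(tgrid >= 10 & tgrid < 13.5)
  hrf <- hrf_double_gamma(seq(0, 32, by = tr))
  oracle <- vapply(seq_len(nvol), function(i) {
    acc <- 0
    for (k in seq_len(i)) {
      lag <- i - k + 1
      if (lag <= length(hrf)) acc <- acc + box[k] * hrf[lag]
    }
    acc
  }, numeric(1))
  expect_equal(ts, oracle, tolerance = 1e-10)
  # peak lands a hemodynamic delay after onset
  expect_gt(tgrid[which.max(ts)], 13)
  expect_lt(tgrid[which.max(ts)], 20)
  # voxels outside the ROI carry no signal
  expect_true(all(run$data[1, 1, 1, ] == 0))
})

test_that("zero-signal, zero-noise simulation is constant baseline", {
  grid <- make_volume_grid(c(4L, 4L, 4L))
  spec <- make_signal_spec(grid, effect_scale = 0, noise_sd = 0,
                           drift_amplitude = 0, baseline = 7)
  ev <- make_event_schedule(fx_concepts[1:6, ], n_runs = 1, seed = 1)[[1]]
  run <- simulate_bold(ev, grid, spec, n_volumes = 120, tr = 0.85)
  expect_true(all(run$data == 7))
})

test_that("simulation refuses an ROI outside the mask", {
  grid <- make_volume_grid(c(6L, 6L, 6L))  # ellipsoid mask
  roi <- array(FALSE, dim = grid$shape); roi[1, 1, 1] <- TRUE
  expect_error(make_signal_spec(grid, roi = roi), "outside")
})

test_that("embedding matrices satisfy the padding and null contracts", {
  E <- simulate_embeddings(fx_concepts, max_tokens = 21, width = 768,
                           class_effect = 0, seed = 5)
  expect_equal(dim(E), c(36L, 16128L))
  tc <- attr(E, "token_counts")
  for (i in c(1, 12, 36)) {
    tail_start <- tc[i] * 768 + 1
    if (tail_start <= 16128)
      expect_true(all(E[i, tail_start:16128] == 0))
  }
  # strong class effect is recovered by an independent nearest-centroid
  # oracle under pair holdout
  Es <- simulate_embeddings(fx_concepts, max_tokens = 3, width = 8,
                            class_effect = 12, dimension = "affect",
                            seed = 6)
  y <- fx_concepts$affect
  centroid_auc <- local({
    lo <- which(y == "low"); hi <- which(y == "high")
    total <- 0
    for (a in lo) for (b in hi) {
      keep <- setdiff(seq_len(36), c(a, b))
      mu_hi <- colMeans(Es[intersect(keep, hi), ])
      mu_lo <- colMeans(Es[intersect(keep, lo), ])
      sa <- sum(Es[a, ] * (mu_hi - mu_lo))
      sb <- sum(Es[b, ] * (mu_hi - mu_lo))
      total <- total + (if (sb > sa) 1 else if (sb == sa) 0.5 else 0)
    }
    total / (length(lo) * length(hi))
  })
  expect_equal(centroid_auc, 1)
  expect_equal(pair_holdout_decode(Es, y), 1)
})

test_that("simulated ratings are bounded, complete and reliable as designed", {
  r <- simulate_ratings(fx_concepts, n_subjects = 5, seed = 8)
  expect_true(all(r$rating >= 0 & r$rating <= 100))
  expect_equal(nrow(r), 5 * 36 * 2 * 2)   # subject x concept x dim x session
  expect_true(is.numeric(attr(r, "n_clipped")))
  # noise-free sessions agree perfectly
  r0 <- simulate_ratings(fx_concepts, n_subjects = 3, noise_sd = 0,
                         seed = 9)
  w <- merge(r0[r0$session == "pre", ], r0[r0$session == "post", ],
             by = c("subject_id", "concept_id", "dimension"))
  expect_equal(w$rating.x, w$rating.y)
  icc <- icc_testretest(w$rating.x[w$dimension == "affect"],
                        w$rating.y[w$dimension == "affect"])
  expect_equal(icc$icc, 1)
})

test_that("ratings generator hits a targeted reliability", {
  # variance-component arithmetic: with flat cell means the true-score
  # variance is sd_b^2, so ICC = sd_b^2 / (sd_b^2 + sd_e^2);
  # sd_b = 12, sd_e = 4 gives 144/160 = 0.9
  r <- simulate_ratings(fx_concepts, n_subjects = 12,
                        mean_by_cell = list(
                          affect = c(high = 50, low = 50),
                          desirability = c(high = 50, low = 50)),
                        between_subject_sd = 12, noise_sd = 4, seed = 10)
  sub <- r[r$dimension == "desirability", ]
  w <- merge(sub[sub$session == "pre", ], sub[sub$session == "post", ],
             by = c("subject_id", "concept_id"))
  expect_gt(nrow(w), 200)
  icc <- icc_testretest(w$rating.x, w$rating.y)
  expect_equal(icc$icc, 0.9, tolerance = 0.056)  # +/- 0.05 on the value
})

test_that("identical seed and configuration reproduce outputs exactly", {
  s1 <- make_event_schedule(fx_concepts, n_runs = 2, seed = 42)
  s2 <- make_event_schedule(fx_concepts, n_runs = 2, seed = 42)
  expect_identical(s1, s2)
  grid <- make_volume_grid(c(5L, 5L, 5L))
  spec <- make_signal_spec(grid, effect_scale = 1, noise_sd = 1, seed = 3)
  b1 <- simulate_bold(s1[[1]], grid, spec, n_volumes = 500, tr = 0.85,
                      seed = 42)
  b2 <- simulate_bold(s1[[1]], grid, spec, n_volumes = 500, tr = 0.85,
                      seed = 42)
  expect_identical(b1$data, b2$data)
  expect_identical(simulate_ratings(fx_concepts, 3, seed = 5),
                   simulate_ratings(fx_concepts, 3, seed = 5))
})

test_that("subject manifests carry the implanted ground truth", {
  fx <- fx_small_subject
  man <- fx$sim$manifest
  expect_equal(man$roi_voxels, which(fx$spec$roi))
  expect_equal(man$effect_scale, 3)
  expect_equal(man$pattern_by, "class")
})
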