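test_that("sphere membership matches brute-force enumeration", {
  grid <- make_volume_grid(c(9L, 9L, 9L), mask = "full")
  sm <- sphere_members(c(5, 5, 5), grid, radius_mm = 4)
  # oracle: all integer offsets with ||2.4 * (i,j,k)|| <= 4
  offs <- as.matrix(expand.grid(-2:2, -2:2, -2:2))
  inside <- sqrt(rowSums((2.4 * offs)^2)) <= 4 + 1e-9
  expect_equal(nrow(sm$members), sum(inside))
  expect_equal(nrow(sm$members), 19L)
  # radius below the voxel spacing keeps only the centre
  expect_equal(nrow(sphere_members(c(5, 5, 5), grid, radius_mm = 1)$members),
               1L)
  # boundary centres lose out-of-mask members
  corner <- sphere_members(c(1, 1, 1), grid, radius_mm = 4)
  expect_lt(nrow(corner$members), 19L)
  # anisotropic spacing goes through the affine
  ga <- make_volume_grid(c(9L, 9L, 9L), spacing = c(1, 2, 4), mask = "full")
  sma <- sphere_members(c(5, 5, 5), ga, radius_mm = 2.5)
  offs_a <- as.matrix(expand.grid(-3:3, -3:3, -3:3))
  inside_a <- sqrt((offs_a[, 1] * 1)^2 + (offs_a[, 2] * 2)^2 +
                   (offs_a[, 3] * 4)^2) <= 2.5 + 1e-9
  expect_equal(nrow(sma$members), sum(inside_a))
})

test_that("cross-validation schemes produce the expected folds", {
  # metadata for a full 8-run design
  run_ids <- rep(1:8, each = 36)
  concept_ids <- rep(0:35, times = 8)
  labels <- rep(rep(c("high", "low"), each = 18), times = 8)

  loro <- make_cv_splits("leave_one_run_out", labels, run_ids = run_ids)
  expect_length(loro, 8L)
  expect_true(all(vapply(loro, function(f) length(f$test), integer(1)) ==
                  36L))

  l2co <- make_cv_splits("leave_two_concepts_out", labels,
                         concept_ids = concept_ids)
  expect_length(l2co, 18L * 18L)
  expect_true(all(vapply(l2co, function(f) length(f$test), integer(1)) ==
                  16L))

  strat <- make_cv_splits("stratified_shuffle", labels, n_reps = 25,
                          seed = 3)
  expect_length(strat, 25L)
  for (f in c(loro[1:2], l2co[1:2], strat[1:2])) {
    expect_length(intersect(f$train, f$test), 0L)
    expect_setequal(union(f$train, f$test), seq_along(labels))
    expect_equal(length(unique(labels[f$test])), 2L)
  }
  # stratified test sets keep the 80/20 class balance
  expect_true(all(vapply(strat, function(f)
    sum(labels[f$test] == "high"), integer(1)) == round(144 * 0.2)))
  expect_error(make_cv_splits("leave_one_run_out", labels), "run_ids")
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  for (i in 1:5) {
    y <- sample(c("a", "b"), 40, replace = TRUE, prob = c(0.4, 0.6))
    sc <- round(rnorm(40), 1)   # rounding forces ties
    ours <- roc_auc(sc, y, positive = "b")
    ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(
      response = y, predictor = sc, levels = c("a", "b"),
      direction = "<"))))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("decoding scores behave at the separable and null extremes", {
  set.seed(5)
  n <- 60
  y <- rep(c("high", "low"), each = n / 2)
  X_sep <- cbind(ifelse(y == "high", 1, -1) + rnorm(n, sd = 0.05),
                 rnorm(n))
  folds <- make_cv_splits("stratified_shuffle", y, n_reps = 10, seed = 2)
  expect_equal(decode_auc(X_sep, y, folds, seed = 1), 1)
  # labels independent of features: mean over many reps near 0.5
  X_null <- matrix(rnorm(n * 4), n)
  folds50 <- make_cv_splits("stratified_shuffle", y, n_reps = 50, seed = 3)
  expect_lt(abs(decode_auc(X_null, y, folds50, seed = 1) - 0.5), 0.12)
})

test_that("dummy chance ignores features and is centred on 0.5", {
  set.seed(6)
  y <- rep(c("high", "low"), each = 20)
  folds <- make_cv_splits("stratified_shuffle", y, n_reps = 40, seed = 4)
  X1 <- matrix(rnorm(40 * 3), 40)
  X2 <- matrix(rnorm(40 * 3) * 100, 40)
  expect_identical(chance_auc(X1, y, folds, seed = 9),
                   chance_auc(X2, y, folds, seed = 9))
  draws <- vapply(1:40, function(s) chance_auc(X1, y, folds, seed = s),
                  numeric(1))
  expect_lt(abs(mean(draws) - 0.5), 0.03)
  # fold-mean variance shrinks roughly as 1/n_reps
  f10 <- make_cv_splits("stratified_shuffle", y, n_reps = 10, seed = 4)
  f90 <- make_cv_splits("stratified_shuffle", y, n_reps = 90, seed = 4)
  v10 <- var(vapply(1:60, function(s) chance_auc(X1, y, f10, seed = s),
                    numeric(1)))
  v90 <- var(vapply(1:60, function(s) chance_auc(X1, y, f90, seed = s),
                    numeric(1)))
  expect_lt(v90, v10)          # monte-carlo: 9x fewer reps, larger var
  expect_gt(v10 / v90, 3)      # coarse 1/n scaling check
})

test_that("searchlight values compose from standalone decode minus chance", {
  es <- fx_small_subject$example_set
  grid <- es$grid
  ctr <- matrix(c(5L, 5L, 5L), 1)
  map <- run_searchlight(es, dimension = "desirability",
                         scheme = "leave_one_run_out", radius_mm = 4,
                         seed = 20, centers = ctr)
  # rebuild the same sphere features and sub-seed by hand
  lookup <- array(NA_integer_, dim = grid$shape)
  lookup[es$voxel_coords] <- seq_len(ncol(es$X))
  sm <- sphere_members(c(5, 5, 5), grid, mask = !is.na(lookup),
                       radius_mm = 4)
  cols <- lookup[sm$members]
  folds <- make_cv_splits("leave_one_run_out", es$desirability,
                          run_ids = es$run_id,
                          concept_ids = es$concept_id, seed = 20)
  sub_seed <- socialmap:::substream_seed(20, 5 + grid$shape[1] *
                                           (5 + grid$shape[2] * 5))
  a <- decode_auc(es$X[, cols], es$desirability, folds, seed = sub_seed)
  ch <- chance_auc(es$X[, cols], es$desirability, folds, seed = sub_seed)
  expect_equal(map$values[5, 5, 5], a - ch, tolerance = 1e-12)
  expect_true(abs(map$values[5, 5, 5]) <= 1)
})

test_that("searchlight is invariant to traversal restriction and recovers signal", {
  es <- fx_small_subject$example_set
  roi <- fx_small_subject$spec$roi
  roi_centers <- which(roi, arr.ind = TRUE)
  far <- which(!roi & es$grid$mask, arr.ind = TRUE)
  far <- far[order(-rowSums(sweep(far, 2, c(5, 5, 5))^2))[1:6], ]
  map <- run_searchlight(es, dimension = "desirability",
                         scheme = "leave_one_run_out", radius_mm = 4,
                         seed = 33, centers = rbind(roi_centers, far))
  roi_vals <- map$values[roi_centers]
  far_vals <- map$values[far]
  expect_gt(median(roi_vals), 0.3)   # strong implanted effect
  expect_lt(abs(median(far_vals)), 0.15)
  # per-sphere sub-seeding: computing a subset reproduces the same values
  map2 <- run_searchlight(es, dimension = "desirability",
                          scheme = "leave_one_run_out", radius_mm = 4,
                          seed = 33, centers = roi_centers[1:3, ,
                                                           drop = FALSE])
  expect_equal(map2$values[roi_centers[1:3, , drop = FALSE]],
               map$values[roi_centers[1:3, , drop = FALSE]])
})
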