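test_that("per-concept averaging matches hand-computed means", {
  es <- fx_small_subject$example_set
  pat <- average_per_concept(es)
  expect_equal(dim(pat), c(36L, ncol(es$X)))
  id7 <- which(es$concept_id == 7)
  expect_equal(unname(pat["7", ]), unname(colMeans(es$X[id7, ])))
  # identical examples average to themselves
  toy <- es
  toy$X <- matrix(rep(c(1, 2, 3, 4), each = 2), 4, 2)
  toy$concept_id <- c(0L, 0L, 1L, 1L)
  toy_pat <- average_per_concept(toy)
  # X columns are c(1,1,2,2) and c(3,3,4,4); concept 0 = rows 1-2
  expect_equal(unname(unclass(toy_pat)),
               matrix(c(1, 3, 2, 4), 2, 2, byrow = TRUE),
               ignore_attr = TRUE)
})

test_that("RDM entries follow the 1 - Pearson definition", {
  p <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(-1, -2, -3, -4))
  rdm <- compute_rdm(p)
  expect_equal(rdm[1, 2], 0)
  expect_equal(rdm[1, 3], 2)
  expect_true(isSymmetric(unclass(rdm)))
  expect_equal(diag(rdm), rep(0, 3))
  # direct covariance/sigma oracle on a random 3x4 matrix
  set.seed(4)
  q <- matrix(rnorm(12), 3, 4)
  rdm_q <- compute_rdm(q)
  for (i in 1:2) for (j in (i + 1):3) {
    xi <- q[i, ] - mean(q[i, ]); xj <- q[j, ] - mean(q[j, ])
    oracle <- 1 - sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
    expect_equal(rdm_q[i, j], oracle, tolerance = 1e-12)
  }
  expect_error(compute_rdm(rbind(c(1, 1, 1), c(1, 2, 3))), "constant")
  # invariant under per-item affine rescaling
  q2 <- q * c(2, 0.5, 7) + c(10, -3, 0)
  expect_equal(unclass(compute_rdm(q2)), unclass(rdm_q),
               tolerance = 1e-12)
})

make_rsa_fixture <- function(n_items = 8, seed = 14, effect = 1.5) {
  # concept patterns whose ROI similarity structure follows a model RDM
  set.seed(seed)
  grid <- make_volume_grid(c(8L, 8L, 8L))
  feats <- matrix(rnorm(n_items * 5), n_items)
  model_rdm <- compute_rdm(feats)
  coords <- which(grid$mask, arr.ind = TRUE)
  nv <- nrow(coords)
  pat <- matrix(rnorm(n_items * nv, sd = 0.2), n_items, nv)
  roi <- array(FALSE, grid$shape); roi[4:6, 4:6, 4:6] <- TRUE
  roi_cols <- which(roi[coords])
  W <- matrix(rnorm(5 * length(roi_cols)), 5)
  pat[, roi_cols] <- pat[, roi_cols] + effect * feats %*% W
  list(grid = grid, coords = coords, patterns = pat,
       model_rdm = model_rdm, roi = roi, roi_cols = roi_cols)
}

test_that("searchlight RSA matches a rank-then-Pearson Spearman oracle", {
  fx <- make_rsa_fixture()
  map <- searchlight_rsa(fx$patterns, fx$model_rdm, fx$grid, fx$coords,
                         radius_mm = 4)
  # oracle at one centre: build the sphere RDM by hand
  ctr <- c(5L, 5L, 5L)
  lookup <- array(NA_integer_, dim = fx$grid$shape)
  lookup[fx$coords] <- seq_len(nrow(fx$coords))
  sm <- sphere_members(ctr, fx$grid, mask = !is.na(lookup), radius_mm = 4)
  cols <- lookup[sm$members]
  rdm <- 1 - cor(t(fx$patterns[, cols]))
  a <- rdm[upper.tri(rdm)]; b <- fx$model_rdm[upper.tri(fx$model_rdm)]
  rho_oracle <- cor(rank(a), rank(b))   # rank-then-Pearson, average ties
  expect_equal(map$values[5, 5, 5], atanh(rho_oracle), tolerance = 1e-10)
  # perfect rank agreement: model correlated with itself
  self_map <- searchlight_rsa(fx$patterns, rdm_self <- local({
    # model rdm equal to the sphere rdm at the test centre
    rdm
  }), fx$grid, fx$coords, radius_mm = 4)
  expect_equal(tanh(self_map$values[5, 5, 5]), 1, tolerance = 1e-6)
  # implanted structure recovered in the ROI
  expect_gt(map$values[5, 5, 5], 0.5)
})

test_that("tied dissimilarities use average ranks", {
  set.seed(2)
  a <- c(1, 1, 2, 3, 3, 4)   # ties in both vectors
  b <- c(2, 2, 1, 5, 5, 5)
  expect_equal(cor(a, b, method = "spearman"),
               cor(rank(a), rank(b)), tolerance = 1e-12)
})

test_that("shuffle-based chance matches exhaustive enumeration at n = 4", {
  # 4 items: compare the sampled chance with all 4! joint shuffles of the
  # centre sphere's RDM
  set.seed(15)
  grid1 <- make_volume_grid(c(3L, 3L, 3L), mask = "full")
  coords <- which(grid1$mask, arr.ind = TRUE)
  patterns <- matrix(rnorm(4 * nrow(coords)), 4)
  model <- compute_rdm(matrix(rnorm(4 * 5), 4))
  lookup <- array(NA_integer_, dim = grid1$shape)
  lookup[coords] <- seq_len(nrow(coords))
  cols <- lookup[sphere_members(c(2L, 2L, 2L), grid1,
                                radius_mm = 2.5)$members]
  rdm <- compute_rdm(patterns[, cols])
  perms <- as.matrix(expand.grid(rep(list(1:4), 4)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  zs <- apply(perms, 1, function(p) {
    r <- rdm[p, p]
    atanh(min(max(cor(r[upper.tri(r)], model[upper.tri(model)],
                      method = "spearman"), -(1 - 1e-7)), 1 - 1e-7))
  })
  exhaustive_mean <- mean(zs)
  ch <- rsa_chance(patterns, model, grid1, coords, radius_mm = 2.5,
                   n_shuffles = 600, seed = 44)
  expect_equal(ch$values[2, 2, 2], exhaustive_mean, tolerance = 0.05)
})

test_that("observed-minus-chance RSA is calibrated on null data", {
  set.seed(16)
  grid <- make_volume_grid(c(6L, 6L, 6L))
  coords <- which(grid$mask, arr.ind = TRUE)
  pat <- matrix(rnorm(8 * nrow(coords)), 8)
  model <- compute_rdm(matrix(rnorm(8 * 4), 8))
  obs <- searchlight_rsa(pat, model, grid, coords, radius_mm = 4)
  ch <- rsa_chance(pat, model, grid, coords, radius_mm = 4,
                   n_shuffles = 100, seed = 3)
  d <- obs$values - ch$values
  expect_lt(abs(mean(d, na.rm = TRUE)), 0.08)
  expect_lt(abs(mean(ch$values, na.rm = TRUE)), 0.08)
})

test_that("RSA is invariant to a common reordering of items", {
  fx <- make_rsa_fixture(n_items = 6)
  map1 <- searchlight_rsa(fx$patterns, fx$model_rdm, fx$grid, fx$coords)
  p <- c(4, 2, 6, 1, 3, 5)
  map2 <- searchlight_rsa(fx$patterns[p, ], fx$model_rdm[p, p],
                          fx$grid, fx$coords)
  expect_equal(map1$values, map2$values, tolerance = 1e-10)
})

test_that("noise ceilings bound subject agreement correctly", {
  fx <- make_rsa_fixture()
  # identical subjects: lower = upper = 1 wherever defined
  same <- lapply(1:4, function(s) fx$patterns)
  nc <- noise_ceiling(same, fx$grid, fx$coords, radius_mm = 4)
  ok <- !is.na(nc$lower$values)
  expect_true(all(abs(nc$lower$values[ok] - 1) < 1e-10))
  expect_true(all(abs(nc$upper$values[ok] - 1) < 1e-10))
  # noisy subjects sharing structure: lower <= upper everywhere
  set.seed(17)
  subs <- lapply(1:5, function(s)
    fx$patterns + matrix(rnorm(length(fx$patterns), sd = 0.6),
                         nrow(fx$patterns)))
  nc2 <- noise_ceiling(subs, fx$grid, fx$coords, radius_mm = 4)
  ok2 <- !is.na(nc2$lower$values) & !is.na(nc2$upper$values)
  expect_true(all(nc2$lower$values[ok2] <= nc2$upper$values[ok2] + 1e-10))
  expect_error(noise_ceiling(subs[1:2], fx$grid, fx$coords), "3 subjects")
})

test_that("noise ceiling matches a hand-rolled leave-one-out oracle", {
  set.seed(18)
  grid <- make_volume_grid(c(3L, 3L, 3L), mask = "full")
  coords <- which(grid$mask, arr.ind = TRUE)
  subs <- lapply(1:3, function(s) matrix(rnorm(5 * nrow(coords)), 5))
  nc <- noise_ceiling(subs, grid, coords, radius_mm = 2.5)
  ctr <- c(2L, 2L, 2L)
  lookup <- array(NA_integer_, dim = grid$shape)
  lookup[coords] <- seq_len(nrow(coords))
  cols <- lookup[sphere_members(ctr, grid, radius_mm = 2.5)$members]
  rdms <- lapply(subs, function(p) {
    r <- 1 - cor(t(p[, cols]))
    r[upper.tri(r)]
  })
  lo <- up <- numeric(3)
  for (s in 1:3) {
    others <- Reduce(`+`, rdms[-s]) / 2
    all_m <- Reduce(`+`, rdms) / 3
    lo[s] <- cor(rdms[[s]], others, method = "spearman")
    up[s] <- cor(rdms[[s]], all_m, method = "spearman")
  }
  expect_equal(nc$lower$values[2, 2, 2], mean(lo), tolerance = 1e-10)
  expect_equal(nc$upper$values[2, 2, 2], mean(up), tolerance = 1e-10)
})

test_that("model RDMs round-trip through TSV", {
  rdm <- compute_rdm(matrix(rnorm(6 * 4), 6))
  f <- tempfile(fileext = ".tsv")
  write_rdm_tsv(rdm, f)
  back <- read_rdm_tsv(f)
  expect_equal(back, unclass(rdm), tolerance = 1e-6,
               ignore_attr = TRUE)
})
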