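#' Closed-form ridge regression solve
#'
#' Solves `argmin ||Y - X W||^2 + lambda ||W||^2` column-wise. Uses the
#' primal normal equations when features <= samples and the dual (kernel)
#' form otherwise, which keeps the solve cheap for wide feature matrices.
#'
#' @param X samples x features (already standardized/centred as desired).
#' @param Y samples x targets.
#' @param lambda ridge penalty (>= 0).
#' @return weight matrix features x targets.
#' @export
ridge_solve <- function(X, Y, lambda) {
  stopifnot(lambda >= 0, nrow(X) == nrow(Y))
  n <- nrow(X); p <- ncol(X)
  Y <- as.matrix(Y)
  if (p <= n) {
    solve(crossprod(X) + diag(lambda, p), crossprod(X, Y))
  } else {
    t(X) %*% solve(tcrossprod(X) + diag(lambda, n), Y)
  }
}

# feature standardization parameters from a training feature matrix
.feature_scaler <- function(features) {
  mu <- colMeans(features)
  s <- apply(features, 2, sd)
  s[s < 1e-12] <- 1
  list(mu = mu, s = s)
}
.apply_scaler <- function(features, scaler) {
  sweep(sweep(features, 2, scaler$mu), 2, scaler$s, `/`)
}

# contiguous equal chunks over 1..n_voxels
.chunk_bounds <- function(n_voxels, n_chunks) {
  n_chunks <- min(n_chunks, n_voxels)
  sizes <- rep(n_voxels %/% n_chunks, n_chunks)
  extra <- n_voxels %% n_chunks
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  ends <- cumsum(sizes)
  cbind(start = c(1L, head(ends, -1) + 1L), end = ends)
}

#' Fit a leave-one-subject-out ridge encoder
#'
#' Trains a linear mapping from sentence features to voxel responses on
#' all subjects except `holdout_subject` (stacking concepts x training
#' subjects as samples). The L2 penalty is selected by an inner
#' leave-one-subject-out grid search within the training set, scored by
#' the mean per-voxel Pearson correlation between predicted and held-out
#' responses. Voxels are split into `n_chunks` contiguous sets fitted
#' independently (a memory device; ridge is column-separable, so chunked
#' and unchunked predictions agree exactly).
#'
#' @param features concepts x features matrix (shared across subjects).
#' @param patterns_by_subject list of concepts x voxels matrices, one per
#'   subject, common voxel order.
#' @param holdout_subject index of the held-out subject (its data never
#'   touches fitting or lambda selection).
#' @param lambda_grid candidate L2 penalties (default
#'   `c(0.01, 0.1, 1, 10, 100, 1000)`).
#' @param n_chunks number of voxel chunks (default 20).
#' @return An `encoder_spec`: list with `weights` (features x voxels),
#'   `intercept` (per-voxel), `lambda`, `lambda_scores`, `scaler`,
#'   `chunks`, `train_subjects`.
#' @export
fit_ridge_encoder <- function(features, patterns_by_subject,
                              holdout_subject,
                              lambda_grid = c(0.01, 0.1, 1, 10, 100, 1000),
                              n_chunks = 20L) {
  if (!length(lambda_grid)) stop("lambda_grid must not be empty")
  n_sub <- length(patterns_by_subject)
  stopifnot(n_sub >= 3, holdout_subject >= 1, holdout_subject <= n_sub)
  train_subjects <- setdiff(seq_len(n_sub), holdout_subject)
  n_vox <- ncol(patterns_by_subject[[1]])
  scaler <- .feature_scaler(features)
  Xs <- .apply_scaler(features, scaler)

  stack <- function(subjects)
    list(X = Xs[rep(seq_len(nrow(Xs)), length(subjects)), , drop = FALSE],
         Y = do.call(rbind, patterns_by_subject[subjects]))

  # inner leave-one-subject-out grid search for lambda
  score_lambda <- function(lambda) {
    sc <- vapply(train_subjects, function(inner) {
      tr <- setdiff(train_subjects, inner)
      d <- stack(tr)
      ymu <- colMeans(d$Y)
      W <- ridge_solve(d$X, sweep(d$Y, 2, ymu), lambda)
      pred <- Xs %*% W + matrix(ymu, nrow(Xs), n_vox, byrow = TRUE)
      obs <- patterns_by_subject[[inner]]
      r <- vapply(seq_len(n_vox), function(v) {
        if (sd(pred[, v]) < 1e-12 || sd(obs[, v]) < 1e-12) return(NA_real_)
        cor(pred[, v], obs[, v])
      }, numeric(1))
      mean(r, na.rm = TRUE)
    }, numeric(1))
    mean(sc, na.rm = TRUE)
  }
  lambda_scores <- vapply(lambda_grid, score_lambda, numeric(1))
  best <- lambda_grid[which.max(lambda_scores)]

  chunks <- .chunk_bounds(n_vox, n_chunks)
  d <- stack(train_subjects)
  ymu <- colMeans(d$Y)
  W <- matrix(0, ncol(Xs), n_vox)
  for (ch in seq_len(nrow(chunks))) {
    cols <- chunks[ch, "start"]:chunks[ch, "end"]
    W[, cols] <- ridge_solve(d$X, sweep(d$Y[, cols, drop = FALSE], 2,
                                        ymu[cols]), best)
  }
  structure(list(weights = W, intercept = ymu, lambda = best,
                 lambda_scores = stats::setNames(lambda_scores,
                                                 lambda_grid),
                 scaler = scaler, chunks = chunks,
                 train_subjects = train_subjects),
            class = "encoder_spec")
}

#' Predict voxel patterns from an encoder, chunk by chunk
#'
#' Per-chunk predictions are concatenated in the original voxel order;
#' the result is numerically identical to an unchunked fit with the same
#' penalty.
#'
#' @param encoder an `encoder_spec`.
#' @param features concepts x features matrix (same feature space as
#'   training).
#' @return predicted concepts x voxels matrix.
#' @export
chunked_predict <- function(encoder, features) {
  stopifnot(inherits(encoder, "encoder_spec"))
  if (ncol(features) != nrow(encoder$weights))
    stop("feature dimension mismatch: encoder expects ",
         nrow(encoder$weights), " features, got ", ncol(features))
  Xs <- .apply_scaler(features, encoder$scaler)
  n_vox <- ncol(encoder$weights)
  pred <- matrix(0, nrow(features), n_vox)
  for (ch in seq_len(nrow(encoder$chunks))) {
    cols <- encoder$chunks[ch, "start"]:encoder$chunks[ch, "end"]
    pred[, cols] <- Xs %*% encoder$weights[, cols, drop = FALSE] +
      matrix(encoder$intercept[cols], nrow(features), length(cols),
             byrow = TRUE)
  }
  pred
}

#' Encoding-based RSA map for one held-out subject
#'
#' Within each sphere, the RDM of the encoder-predicted patterns is
#' rank-correlated (Spearman) with the RDM of the held-out subject's
#' observed patterns over strict upper triangles and Fisher-z
#' transformed.
#'
#' @param predicted,observed concepts x voxels matrices on the same grid
#'   and voxel order.
#' @param grid a `volume_grid`.
#' @param voxel_coords voxels x 3 coordinate map.
#' @param radius_mm sphere radius in mm.
#' @return a `stat_map` with semantic `"z"`.
#' @export
encoding_rsa_map <- function(predicted, observed, grid = NULL,
                             voxel_coords = NULL, radius_mm = 4) {
  grid <- grid %||% attr(observed, "grid")
  voxel_coords <- voxel_coords %||% attr(observed, "voxel_coords")
  stopifnot(all(dim(predicted) == dim(observed)))
  res <- .searchlight_rdm(observed, grid, voxel_coords, radius_mm,
    function(rdm_obs, rdm_pred)
      .fisher_z(.spearman(upper_tri_vec(rdm_obs),
                          upper_tri_vec(rdm_pred))),
    patterns_b = predicted)
  stat_map(res$vals, res$grid, semantic = "z")
}

#' Shuffle-based chance map for encoding RSA
#'
#' Shuffles the observed concept rows before the RDM comparison (joint
#' row/column permutation of the observed sphere RDM) and averages the
#' Fisher-z over shuffles.
#'
#' @inheritParams encoding_rsa_map
#' @param n_shuffles number of shuffles.
#' @param seed integer seed.
#' @return a `stat_map` with semantic `"z_chance"`.
#' @export
encoding_rsa_chance <- function(predicted, observed, grid = NULL,
                                voxel_coords = NULL, radius_mm = 4,
                                n_shuffles = 100L, seed = 1L) {
  grid <- grid %||% attr(observed, "grid")
  voxel_coords <- voxel_coords %||% attr(observed, "voxel_coords")
  n <- nrow(observed)
  perms <- with_seed(seed, replicate(n_shuffles, sample(n),
                                     simplify = FALSE))
  res <- .searchlight_rdm(observed, grid, voxel_coords, radius_mm,
    function(rdm_obs, rdm_pred) {
      pv <- upper_tri_vec(rdm_pred)
      zs <- vapply(perms, function(p)
        .fisher_z(.spearman(upper_tri_vec(rdm_obs[p, p]), pv)),
        numeric(1))
      mean(zs, na.rm = TRUE)
    },
    patterns_b = predicted)
  stat_map(res$vals, res$grid, semantic = "z_chance")
}
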