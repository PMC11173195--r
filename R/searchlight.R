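#' Integer voxel offsets within a radius
#'
#' Enumerates all integer offsets `(i, j, k)` whose centre-to-centre
#' distance in mm (given the voxel spacing) is at most `radius_mm`.
#'
#' @param radius_mm sphere radius in mm (default 4).
#' @param spacing voxel spacing in mm (length 3 or scalar).
#' @return integer matrix with columns `i, j, k`.
#' @export
sphere_offsets <- function(radius_mm = 4, spacing = 2.4) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  rng <- lapply(spacing, function(s) seq(-floor(radius_mm / s),
                                         floor(radius_mm / s)))
  off <- as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]]))
  d2 <- (off[, 1] * spacing[1])^2 + (off[, 2] * spacing[2])^2 +
        (off[, 3] * spacing[3])^2
  off[d2 <= radius_mm^2 + 1e-9, , drop = FALSE]
}

#' Voxels belonging to a searchlight sphere
#'
#' All in-mask voxels whose centre lies within `radius_mm` of the centre
#' voxel, with distances measured in mm through the grid affine (so
#' anisotropic grids are handled).
#'
#' @param center integer length-3 voxel coordinate (1-based).
#' @param grid a `volume_grid`.
#' @param mask logical array (defaults to the grid mask).
#' @param radius_mm sphere radius in mm.
#' @return list with `center` and `members` (voxel coordinates, one row
#'   per member).
#' @export
sphere_members <- function(center, grid, mask = NULL, radius_mm = 4) {
  if (is.null(mask)) mask <- grid$mask
  stopifnot(mask[matrix(center, 1)])
  off <- sphere_offsets(radius_mm, voxel_spacing(grid))
  cand <- sweep(off, 2, as.integer(center), `+`)
  ok <- cand[, 1] >= 1 & cand[, 1] <= grid$shape[1] &
        cand[, 2] >= 1 & cand[, 2] <= grid$shape[2] &
        cand[, 3] >= 1 & cand[, 3] <= grid$shape[3]
  cand <- cand[ok, , drop = FALSE]
  cand <- cand[mask[cand], , drop = FALSE]
  list(center = as.integer(center), members = cand)
}

#' Build cross-validation folds
#'
#' Three schemes are supported. `stratified_shuffle` repeats `n_reps`
#' random stratified 80/20 splits and deliberately ignores run structure.
#' `leave_one_run_out` holds out one run per fold. `leave_two_concepts_out`
#' builds one fold per (low-class concept, high-class concept) pair,
#' testing on every trial of those two concepts.
#'
#' @param scheme `"stratified_shuffle"`, `"leave_one_run_out"` or
#'   `"leave_two_concepts_out"`.
#' @param labels binary label vector (character or factor, 2 levels).
#' @param run_ids run id per example (required for leave-one-run-out).
#' @param concept_ids concept id per example (required for
#'   leave-two-concepts-out).
#' @param n_reps number of shuffle repetitions (default 100).
#' @param test_fraction test proportion for the shuffle scheme (default
#'   0.2).
#' @param seed integer seed for the shuffle scheme.
#' @return list of folds, each `list(train, test)` of row indices.
#' @export
make_cv_splits <- function(scheme = c("stratified_shuffle",
                                      "leave_one_run_out",
                                      "leave_two_concepts_out"),
                           labels, run_ids = NULL, concept_ids = NULL,
                           n_reps = 100L, test_fraction = 0.2, seed = 1L) {
  scheme <- match.arg(scheme)
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2) stop("labels must have exactly two classes")
  n <- length(labels)
  if (scheme == "stratified_shuffle") {
    idx_by_class <- split(seq_len(n), labels)
    with_seed(seed, {
      lapply(seq_len(n_reps), function(rep) {
        test <- unlist(lapply(idx_by_class, function(ix) {
          k <- max(1L, round(length(ix) * test_fraction))
          sample(ix, k)
        }), use.names = FALSE)
        list(train = setdiff(seq_len(n), test), test = sort(test))
      })
    })
  } else if (scheme == "leave_one_run_out") {
    if (is.null(run_ids)) stop("leave_one_run_out requires run_ids")
    lapply(sort(unique(run_ids)), function(r) {
      test <- which(run_ids == r)
      list(train = which(run_ids != r), test = test)
    })
  } else {
    if (is.null(concept_ids)) stop("leave_two_concepts_out requires concept_ids")
    c_lo <- sort(unique(concept_ids[labels == lev[1]]))
    c_hi <- sort(unique(concept_ids[labels == lev[2]]))
    folds <- list()
    for (a in c_lo) for (b in c_hi) {
      test <- which(concept_ids %in% c(a, b))
      folds[[length(folds) + 1L]] <- list(train = setdiff(seq_len(n), test),
                                          test = test)
    }
    folds
  }
}

# Rank-based ROC AUC (equivalent to the Mann-Whitney U statistic with
# average ranks for ties).
roc_auc <- function(scores, labels, positive = NULL) {
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (is.null(positive)) positive <- lev[length(lev)]
  pos <- labels == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Standardize train columns, apply to test; zero-variance columns pass
# through centred only.
.standardize_pair <- function(Xtr, Xte) {
  mu <- colMeans(Xtr)
  s <- apply(Xtr, 2, sd)
  s[s < 1e-12] <- 1
  list(train = sweep(sweep(Xtr, 2, mu), 2, s, `/`),
       test = sweep(sweep(Xte, 2, mu), 2, s, `/`))
}

# Linear SVC decision values with a Platt-style sigmoid calibration stage:
# out-of-fold decision values from a small internal CV fit the sigmoid,
# which is then applied to the full-train model's test decision values.
.calibrated_svc_probs <- function(Xtr, ytr, Xte, cost = 1, calib_folds = 3L,
                                  seed = 1L) {
  ytr <- factor(ytr)
  positive <- levels(ytr)[2]
  fit <- e1071::svm(Xtr, ytr, kernel = "linear", cost = cost, scale = FALSE)
  dv_te <- .oriented_dv(fit, Xte, Xtr, ytr, positive)
  # internal CV for the calibration map
  folds <- with_seed(seed, sample(rep_len(seq_len(calib_folds),
                                          length(ytr))))
  dv_oof <- rep(NA_real_, length(ytr))
  for (f in seq_len(calib_folds)) {
    tr <- folds != f
    if (length(unique(ytr[tr])) < 2) next
    sub <- e1071::svm(Xtr[tr, , drop = FALSE], droplevels(ytr[tr]),
                      kernel = "linear", cost = cost, scale = FALSE)
    dv_oof[!tr] <- .oriented_dv(sub, Xtr[!tr, , drop = FALSE],
                                Xtr[tr, , drop = FALSE], ytr[tr], positive)
  }
  ok <- !is.na(dv_oof)
  if (sum(ok) >= 4 && length(unique(ytr[ok])) == 2) {
    df <- data.frame(dv = dv_oof[ok], pos = ytr[ok] == positive)
    cal <- suppressWarnings(glm(pos ~ dv, binomial, data = df))
    slope <- coef(cal)[2]
    if (is.finite(slope) && slope > 0) {
      return(as.numeric(predict(cal, data.frame(dv = dv_te),
                                type = "response")))
    }
  }
  # degenerate calibration: fall back to a fixed-scale sigmoid (monotone,
  # so ranking metrics are unaffected)
  1 / (1 + exp(-dv_te))
}

# decision values oriented so larger = more evidence for `positive`
.oriented_dv <- function(fit, Xte, Xtr, ytr, positive) {
  dv <- attr(predict(fit, Xte, decision.values = TRUE),
             "decision.values")[, 1]
  dv_tr <- attr(predict(fit, Xtr, decision.values = TRUE),
                "decision.values")[, 1]
  m_pos <- mean(dv_tr[ytr == positive])
  m_neg <- mean(dv_tr[ytr != positive])
  if (m_pos < m_neg) dv <- -dv
  dv
}

#' Cross-validated decoding score (mean ROC AUC)
#'
#' For each fold: standardize features on the training set and apply those
#' parameters to the test set, fit a linear max-margin classifier (cost
#' 1) wrapped in a sigmoid probability-calibration stage, and score the
#' test-set probabilities with ROC AUC. Folds whose training set contains
#' a single class are skipped with a warning.
#'
#' @param X examples x features matrix.
#' @param y binary labels.
#' @param folds from [make_cv_splits()].
#' @param seed seed for the internal calibration folds.
#' @param cost margin penalty of the linear SVC.
#' @param calib_folds internal calibration CV folds (default 3).
#' @return mean ROC AUC over folds.
#' @export
decode_auc <- function(X, y, folds, seed = 1L, cost = 1, calib_folds = 3L) {
  y <- factor(as.character(y))
  positive <- levels(y)[2]
  aucs <- rep(NA_real_, length(folds))
  for (f in seq_along(folds)) {
    tr <- folds[[f]]$train; te <- folds[[f]]$test
    if (length(unique(y[tr])) < 2) {
      warning("fold with single-class training set skipped")
      next
    }
    std <- .standardize_pair(X[tr, , drop = FALSE], X[te, , drop = FALSE])
    p <- .calibrated_svc_probs(std$train, y[tr], std$test, cost = cost,
                               calib_folds = calib_folds,
                               seed = substream_seed(seed, f))
    aucs[f] <- roc_auc(p, y[te], positive = positive)
  }
  mean(aucs, na.rm = TRUE)
}

#' Chance-level decoding score via a dummy classifier
#'
#' Identical protocol to [decode_auc()] but the classifier ignores the
#' features and emits label-independent uniform-random probabilities, so
#' the returned fold-mean AUC is centred on 0.5. Used to estimate the
#' empirical chance level that is subtracted from the real decoding score.
#'
#' @inheritParams decode_auc
#' @return mean ROC AUC of the dummy classifier over folds.
#' @export
chance_auc <- function(X, y, folds, seed = 1L) {
  y <- factor(as.character(y))
  positive <- levels(y)[2]
  aucs <- rep(NA_real_, length(folds))
  with_seed(seed, {
    for (f in seq_along(folds)) {
      tr <- folds[[f]]$train; te <- folds[[f]]$test
      if (length(unique(y[tr])) < 2) {
        warning("fold with single-class training set skipped")
        next
      }
      aucs[f] <- roc_auc(runif(length(te)), y[te], positive = positive)
    }
  })
  mean(aucs, na.rm = TRUE)
}

#' Whole-brain searchlight decoding map
#'
#' Slides a sphere of `radius_mm` over every in-mask voxel; within each
#' sphere the retained voxels' examples are decoded with [decode_auc()]
#' and the paired dummy-chance score ([chance_auc()], same folds and
#' per-sphere seed) is subtracted. The difference is assigned to the
#' sphere centre. Spheres with no retained voxels are left `NA`.
#'
#' @param example_set an `example_set` from [prepare_examples()].
#' @param dimension `"affect"` or `"desirability"`.
#' @param scheme,n_reps,test_fraction see [make_cv_splits()].
#' @param radius_mm sphere radius in mm (default 4).
#' @param seed master seed; each sphere gets a deterministic sub-seed so
#'   traversal order cannot change results.
#' @param cost linear SVC margin penalty.
#' @param centers optional integer matrix of sphere centres (voxel
#'   coordinates) to restrict the map.
#' @return a `stat_map` with semantic `"auc_minus_chance"`.
#' @export
run_searchlight <- function(example_set, dimension = "desirability",
                            scheme = "stratified_shuffle", n_reps = 100L,
                            test_fraction = 0.2, radius_mm = 4, seed = 1L,
                            cost = 1, centers = NULL) {
  es <- example_set
  stopifnot(dimension %in% c("affect", "desirability"))
  y <- es[[dimension]]
  folds <- make_cv_splits(scheme, y, run_ids = es$run_id,
                          concept_ids = es$concept_id, n_reps = n_reps,
                          test_fraction = test_fraction, seed = seed)
  grid <- es$grid
  # map voxel coordinates -> column index of X
  lookup <- array(NA_integer_, dim = grid$shape)
  lookup[es$voxel_coords] <- seq_len(ncol(es$X))
  vox_mask <- !is.na(lookup)
  if (is.null(centers)) centers <- which(vox_mask, arr.ind = TRUE)
  off <- sphere_offsets(radius_mm, voxel_spacing(grid))
  vals <- array(NA_real_, dim = grid$shape)
  for (ci in seq_len(nrow(centers))) {
    ctr <- centers[ci, ]
    cand <- sweep(off, 2, as.integer(ctr), `+`)
    ok <- cand[, 1] >= 1 & cand[, 1] <= grid$shape[1] &
          cand[, 2] >= 1 & cand[, 2] <= grid$shape[2] &
          cand[, 3] >= 1 & cand[, 3] <= grid$shape[3]
    cols <- lookup[cand[ok, , drop = FALSE]]
    cols <- cols[!is.na(cols)]
    if (!length(cols)) next
    sub_seed <- substream_seed(seed, ctr[1] + grid$shape[1] *
                                 (ctr[2] + grid$shape[2] * ctr[3]))
    Xs <- es$X[, cols, drop = FALSE]
    auc <- decode_auc(Xs, y, folds, seed = sub_seed, cost = cost)
    ch <- chance_auc(Xs, y, folds, seed = sub_seed)
    vals[ctr[1], ctr[2], ctr[3]] <- auc - ch
  }
  grid_out <- grid
  grid_out$mask <- vox_mask
  stat_map(vals, grid_out, semantic = "auc_minus_chance")
}
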