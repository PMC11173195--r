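#' Average examples per concept
#'
#' Collapses an example set to one mean pattern per concept (rows ordered
#' by concept id), the input for representational similarity analyses.
#'
#' @param example_set an `example_set`.
#' @return numeric matrix `n_concepts x n_voxels` with rownames the
#'   concept ids; attribute `voxel_coords` carries the column-coordinate
#'   map, `grid` the volume grid.
#' @export
average_per_concept <- function(example_set) {
  es <- example_set
  ids <- sort(unique(es$concept_id))
  out <- t(vapply(ids, function(id) {
    colMeans(es$X[es$concept_id == id, , drop = FALSE])
  }, numeric(ncol(es$X))))
  rownames(out) <- ids
  attr(out, "voxel_coords") <- es$voxel_coords
  attr(out, "grid") <- es$grid
  out
}

#' Representational dissimilarity matrix (1 - Pearson)
#'
#' @param patterns items x features matrix; every row must vary.
#' @return symmetric `n x n` matrix with zero diagonal and attribute
#'   `metric = "one_minus_pearson"`.
#' @export
compute_rdm <- function(patterns) {
  stopifnot(nrow(patterns) >= 2)
  sds <- apply(patterns, 1, sd)
  if (any(sds < 1e-12))
    stop("constant pattern row(s): correlation undefined for item(s) ",
         paste(which(sds < 1e-12), collapse = ", "))
  rdm <- 1 - cor(t(patterns))
  diag(rdm) <- 0
  attr(rdm, "metric") <- "one_minus_pearson"
  rdm
}

#' Strict upper-triangle vectorization of an RDM
#' @param m square matrix.
#' @return numeric vector (no diagonal).
#' @export
upper_tri_vec <- function(m) m[upper.tri(m)]

# Spearman correlation of two dissimilarity vectors; NA if either is
# constant (rank correlation undefined).
.spearman <- function(a, b) {
  if (sd(a) < 1e-15 || sd(b) < 1e-15) return(NA_real_)
  cor(a, b, method = "spearman")
}

# Fisher z with |rho| clipped so the transform stays finite.
.fisher_z <- function(rho, clip = 1 - 1e-7) {
  atanh(pmin(pmax(rho, -clip), clip))
}

# Shared searchlight driver over sphere RDM correlations.
# For every in-mask centre it computes the sphere RDM(s) and calls
# `corr_fun(rdm_obs, rdm_pred)` (rdm_pred NULL for model-based RSA).
.searchlight_rdm <- function(patterns, grid, voxel_coords, radius_mm,
                             corr_fun, patterns_b = NULL, min_voxels = 2L) {
  lookup <- array(NA_integer_, dim = grid$shape)
  lookup[voxel_coords] <- seq_len(ncol(patterns))
  vox_mask <- !is.na(lookup)
  centers <- which(vox_mask, arr.ind = TRUE)
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
    if (length(cols) < min_voxels) next
    sub <- patterns[, cols, drop = FALSE]
    if (any(apply(sub, 1, sd) < 1e-12)) next
    rdm_a <- 1 - cor(t(sub))
    rdm_b <- NULL
    if (!is.null(patterns_b)) {
      sub_b <- patterns_b[, cols, drop = FALSE]
      if (any(apply(sub_b, 1, sd) < 1e-12)) next
      rdm_b <- 1 - cor(t(sub_b))
    }
    vals[ctr[1], ctr[2], ctr[3]] <- corr_fun(rdm_a, rdm_b)
  }
  grid_out <- grid
  grid_out$mask <- vox_mask
  list(vals = vals, grid = grid_out)
}

#' Searchlight model-based RSA map
#'
#' Within each sphere the brain RDM (1 - Pearson over the sphere's voxel
#' patterns) is rank-correlated (Spearman, average ranks for ties) with
#' the model RDM over strict upper triangles, Fisher-z transformed
#' (arctanh, |rho| clipped at `1 - 1e-7`), and assigned to the sphere
#' centre. Spheres with fewer than 2 retained voxels, or with a constant
#' pattern row, are left `NA`.
#'
#' @param concept_patterns concepts x voxels matrix (e.g. from
#'   [average_per_concept()]).
#' @param model_rdm square model RDM matching the concept count.
#' @param grid a `volume_grid`.
#' @param voxel_coords voxels x 3 coordinates mapping pattern columns to
#'   the grid (defaults to the matrix's `voxel_coords` attribute).
#' @param radius_mm sphere radius in mm (default 4).
#' @return a `stat_map` with semantic `"z"`.
#' @export
searchlight_rsa <- function(concept_patterns, model_rdm, grid = NULL,
                            voxel_coords = NULL, radius_mm = 4) {
  grid <- grid %||% attr(concept_patterns, "grid")
  voxel_coords <- voxel_coords %||% attr(concept_patterns, "voxel_coords")
  stopifnot(nrow(model_rdm) == nrow(concept_patterns))
  model_vec <- upper_tri_vec(model_rdm)
  res <- .searchlight_rdm(concept_patterns, grid, voxel_coords, radius_mm,
                          function(rdm, ...)
                            .fisher_z(.spearman(upper_tri_vec(rdm),
                                                model_vec)))
  stat_map(res$vals, res$grid, semantic = "z")
}

#' Shuffle-based chance map for searchlight RSA
#'
#' Destroys the brain-model correspondence by shuffling the assignment of
#' concept rows before the RDM comparison; the chance map is the mean
#' Fisher-z over `n_shuffles` shuffles. Shuffling rows of the patterns is
#' equivalent to jointly permuting rows and columns of the sphere RDM, so
#' each sphere's RDM is computed once and re-indexed per shuffle. The
#' inference input is `observed - chance`.
#'
#' @inheritParams searchlight_rsa
#' @param n_shuffles number of shuffles (default 100).
#' @param seed integer seed; shuffles are shared across spheres.
#' @return a `stat_map` with semantic `"z_chance"`.
#' @export
rsa_chance <- function(concept_patterns, model_rdm, grid = NULL,
                       voxel_coords = NULL, radius_mm = 4,
                       n_shuffles = 100L, seed = 1L) {
  stopifnot(n_shuffles >= 1)
  grid <- grid %||% attr(concept_patterns, "grid")
  voxel_coords <- voxel_coords %||% attr(concept_patterns, "voxel_coords")
  n <- nrow(concept_patterns)
  model_vec <- upper_tri_vec(model_rdm)
  perms <- with_seed(seed, replicate(n_shuffles, sample(n),
                                     simplify = FALSE))
  res <- .searchlight_rdm(concept_patterns, grid, voxel_coords, radius_mm,
    function(rdm, ...) {
      zs <- vapply(perms, function(p)
        .fisher_z(.spearman(upper_tri_vec(rdm[p, p]), model_vec)),
        numeric(1))
      mean(zs, na.rm = TRUE)
    })
  stat_map(res$vals, res$grid, semantic = "z_chance")
}

#' Searchlight noise-ceiling maps
#'
#' Bounds the sphere-level RSA performance attainable given
#' between-subject variability. Per sphere: the lower ceiling is the mean
#' over subjects of the Spearman correlation between the subject's RDM
#' and the mean RDM of the remaining subjects; the upper ceiling
#' correlates against the mean RDM of all subjects (including the subject
#' itself, which inflates agreement).
#'
#' @param patterns_by_subject list (>= 3) of concepts x voxels matrices on
#'   a common grid and voxel order.
#' @param grid a `volume_grid`.
#' @param voxel_coords voxels x 3 coordinate map for the pattern columns.
#' @param radius_mm sphere radius in mm.
#' @return list of class `noise_ceiling_map` with `lower` and `upper`
#'   `stat_map`s.
#' @export
noise_ceiling <- function(patterns_by_subject, grid = NULL,
                          voxel_coords = NULL, radius_mm = 4) {
  if (length(patterns_by_subject) < 3)
    stop("noise ceiling requires at least 3 subjects")
  grid <- grid %||% attr(patterns_by_subject[[1]], "grid")
  voxel_coords <- voxel_coords %||%
    attr(patterns_by_subject[[1]], "voxel_coords")
  n_sub <- length(patterns_by_subject)
  lookup <- array(NA_integer_, dim = grid$shape)
  lookup[voxel_coords] <- seq_len(ncol(patterns_by_subject[[1]]))
  vox_mask <- !is.na(lookup)
  centers <- which(vox_mask, arr.ind = TRUE)
  off <- sphere_offsets(radius_mm, voxel_spacing(grid))
  lower <- array(NA_real_, dim = grid$shape)
  upper <- array(NA_real_, dim = grid$shape)
  for (ci in seq_len(nrow(centers))) {
    ctr <- centers[ci, ]
    cand <- sweep(off, 2, as.integer(ctr), `+`)
    ok <- cand[, 1] >= 1 & cand[, 1] <= grid$shape[1] &
          cand[, 2] >= 1 & cand[, 2] <= grid$shape[2] &
          cand[, 3] >= 1 & cand[, 3] <= grid$shape[3]
    cols <- lookup[cand[ok, , drop = FALSE]]
    cols <- cols[!is.na(cols)]
    if (length(cols) < 2) next
    rdms <- lapply(patterns_by_subject, function(p) {
      sub <- p[, cols, drop = FALSE]
      if (any(apply(sub, 1, sd) < 1e-12)) return(NULL)
      upper_tri_vec(1 - cor(t(sub)))
    })
    if (any(vapply(rdms, is.null, logical(1)))) next
    R <- do.call(cbind, rdms)           # pairs x subjects
    tot <- rowSums(R)
    lo <- up <- numeric(n_sub)
    for (s in seq_len(n_sub)) {
      lo[s] <- .spearman(R[, s], (tot - R[, s]) / (n_sub - 1))
      up[s] <- .spearman(R[, s], tot / n_sub)
    }
    lower[ctr[1], ctr[2], ctr[3]] <- mean(lo, na.rm = TRUE)
    upper[ctr[1], ctr[2], ctr[3]] <- mean(up, na.rm = TRUE)
  }
  grid_out <- grid
  grid_out$mask <- vox_mask
  structure(list(lower = stat_map(lower, grid_out, "noise_ceiling_lower"),
                 upper = stat_map(upper, grid_out, "noise_ceiling_upper")),
            class = "noise_ceiling_map")
}

#' Read / write a model RDM as TSV
#' @param rdm square matrix.
#' @param path `.tsv` path.
#' @return `path` (write) or the matrix (read).
#' @export
write_rdm_tsv <- function(rdm, path) {
  write.table(unclass(rdm), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_rdm_tsv
#' @export
read_rdm_tsv <- function(path) {
  m <- as.matrix(read.table(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  stopifnot(nrow(m) == ncol(m))
  attr(m, "metric") <- "one_minus_pearson"
  m
}
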