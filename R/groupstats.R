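#' Threshold-free cluster enhancement
#'
#' Integrates cluster extent and height across all thresholds: each voxel
#' receives `sum over h = dh, 2dh, ... <= value of e(h)^E * h^H * dh`,
#' where `e(h)` is the size of the supra-threshold (`value >= h`)
#' connected component containing the voxel. Defaults are the standard
#' published parameters `E = 0.5`, `H = 2` with 26-connectivity and
#' `dh = max/100`. Only positive values are enhanced (one-sided,
#' greater-than-zero inference).
#'
#' @param map numeric 3D array or `stat_map`.
#' @param mask logical array; defaults to the map's mask or finite voxels.
#' @param E,H extent and height exponents.
#' @param dh threshold step; `NULL` for `max(map)/100`.
#' @param connectivity 6 or 26 (or 18) neighbourhood.
#' @return `stat_map` (if input was one) or 3D array of TFCE scores, zero
#'   where nothing is supra-threshold.
#' @export
tfce <- function(map, mask = NULL, E = 0.5, H = 2, dh = NULL,
                 connectivity = 26L) {
  is_map <- inherits(map, "stat_map")
  arr <- if (is_map) map$values else map
  stopifnot(length(dim(arr)) == 3L)
  if (is.null(mask)) {
    mask <- if (is_map) map$grid$mask else array(is.finite(arr),
                                                 dim = dim(arr))
  }
  arr2 <- arr
  arr2[!mask | !is.finite(arr2)] <- 0
  mx <- max(arr2)
  if (is.null(dh)) dh <- if (mx > 0) mx / 100 else 1
  stopifnot(dh > 0)
  out <- .tfce_cpp(as.numeric(arr2), as.integer(dim(arr2)),
                   as.logical(mask), E, H, dh, as.integer(connectivity))
  out <- array(out, dim = dim(arr2))
  if (is_map) stat_map(out, map$grid, semantic = "tfce") else out
}

#' Label connected components of a 3D mask
#' @param keep logical 3D array.
#' @param connectivity 6, 18 or 26.
#' @return integer array of component labels (0 = background).
#' @export
label_components <- function(keep, connectivity = 26L) {
  stopifnot(is.logical(keep), length(dim(keep)) == 3L)
  array(.label_components_cpp(as.logical(keep), as.integer(dim(keep)),
                              as.integer(connectivity)),
        dim = dim(keep))
}

.maps_to_matrix <- function(maps, mask) {
  vapply(maps, function(m) {
    arr <- if (inherits(m, "stat_map")) m$values else m
    v <- arr[mask]
    v[!is.finite(v)] <- 0
    v
  }, numeric(sum(mask)))
}

#' One-sample group inference with TFCE and sign-flip permutations
#'
#' The observed statistic is the TFCE of the across-subject mean map
#' (optionally of the one-sample t map when `variance_normalize = TRUE`).
#' The null distribution is the maximum TFCE score over the brain under
#' random per-subject sign flips; corrected p-values follow the
#' max-statistic convention `p = (1 + #\{perm max >= observed\}) /
#' (1 + n_perm)`, giving family-wise error control for the one-sided
#' (greater-than-zero) test.
#'
#' @param maps list of subject maps (`stat_map`s or 3D arrays on one grid).
#' @param n_perm number of sign-flip permutations (default 10000).
#' @param alpha significance level for the cluster mask.
#' @param seed integer seed; the sign-flip matrix is a deterministic
#'   function of it.
#' @param mask logical array; defaults to the first map's mask.
#' @param E,H,dh,connectivity TFCE parameters, see [tfce()].
#' @param variance_normalize use the one-sample t map instead of the mean
#'   map before TFCE (off by default).
#' @return A `group_result`: list with `mean_map`, `tfce_map`, `p_map`
#'   (corrected), `sig_mask`, `max_null`, `n_perm`, `alpha`, `seed`.
#' @export
one_sample_signflip <- function(maps, n_perm = 10000L, alpha = 0.05,
                                seed = 1L, mask = NULL, E = 0.5, H = 2,
                                dh = NULL, connectivity = 26L,
                                variance_normalize = FALSE) {
  stopifnot(length(maps) >= 2)
  if (n_perm < 1) stop("n_perm must be at least 1")
  grid <- if (inherits(maps[[1]], "stat_map")) maps[[1]]$grid else NULL
  shape <- if (is.null(grid)) dim(maps[[1]]) else grid$shape
  if (is.null(mask))
    mask <- if (is.null(grid)) array(TRUE, dim = shape) else grid$mask
  M <- .maps_to_matrix(maps, mask)   # voxels x subjects
  n_sub <- ncol(M)

  stat_3d <- function(v) {
    arr <- array(0, dim = shape)
    arr[mask] <- v
    arr
  }
  group_stat <- function(signs) {
    Ms <- sweep(M, 2, signs, `*`)
    mu <- rowMeans(Ms)
    if (variance_normalize) {
      s <- sqrt(pmax(matrixStats_rowVars(Ms), 1e-24) / n_sub)
      mu <- mu / s
    }
    mu
  }
  obs <- group_stat(rep(1, n_sub))
  tf_obs <- tfce(stat_3d(obs), mask = mask, E = E, H = H, dh = dh,
                 connectivity = connectivity)
  max_null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      signs <- sample(c(-1, 1), n_sub, replace = TRUE)
      tf <- tfce(stat_3d(group_stat(signs)), mask = mask, E = E, H = H,
                 dh = dh, connectivity = connectivity)
      max(tf)
    }, numeric(1))
  })
  exceed <- vapply(tf_obs[mask], function(v) sum(max_null >= v),
                   numeric(1))
  p <- array(NA_real_, dim = shape)
  p[mask] <- (1 + exceed) / (1 + n_perm)
  sig <- array(FALSE, dim = shape)
  sig[mask] <- p[mask] <= alpha & tf_obs[mask] > 0
  vgrid <- grid %||% structure(list(shape = shape, affine = diag(4),
                                    mask = mask), class = "volume_grid")
  structure(list(mean_map = stat_map(stat_3d(rowMeans(M)), vgrid, "mean"),
                 tfce_map = stat_map(tf_obs, vgrid, "tfce"),
                 p_map = stat_map(p, vgrid, "p"),
                 sig_mask = sig, max_null = max_null, n_perm = n_perm,
                 alpha = alpha, seed = seed,
                 connectivity = connectivity),
            class = "group_result")
}

#' @export
print.group_result <- function(x, ...) {
  cat("<group_result> ", x$n_perm, " permutations, alpha ", x$alpha,
      ", ", sum(x$sig_mask), " significant voxel(s)\n", sep = "")
  invisible(x)
}

#' Paired-difference group inference
#'
#' Computes per-subject difference maps `a - b` and performs the
#' one-sample sign-flip TFCE test on them (same subjects in both lists,
#' matched by position).
#'
#' @param maps_a,maps_b lists of subject maps, same length and grid.
#' @param ... passed to [one_sample_signflip()].
#' @return a `group_result` for the `a - b` contrast.
#' @export
paired_difference_inference <- function(maps_a, maps_b, ...) {
  if (length(maps_a) != length(maps_b))
    stop("maps_a and maps_b must contain the same subjects")
  diffs <- lapply(seq_along(maps_a), function(i) {
    a <- if (inherits(maps_a[[i]], "stat_map")) maps_a[[i]]$values
         else maps_a[[i]]
    b <- if (inherits(maps_b[[i]], "stat_map")) maps_b[[i]]$values
         else maps_b[[i]]
    stopifnot(all(dim(a) == dim(b)))
    d <- a - b
    if (inherits(maps_a[[i]], "stat_map"))
      stat_map(d, maps_a[[i]]$grid, "difference") else d
  })
  one_sample_signflip(diffs, ...)
}

#' Tabulate significant clusters of a group result
#'
#' @param result a `group_result`.
#' @return `data.frame` with one row per connected significant cluster:
#'   peak voxel coordinate, extent (voxels), peak TFCE score and minimum
#'   corrected p.
#' @export
cluster_table <- function(result) {
  stopifnot(inherits(result, "group_result"))
  lab <- label_components(result$sig_mask, result$connectivity)
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  if (!length(ids))
    return(data.frame(cluster = integer(0), peak_x = integer(0),
                      peak_y = integer(0), peak_z = integer(0),
                      extent = integer(0), peak_tfce = numeric(0),
                      min_p = numeric(0)))
  tf <- result$tfce_map$values
  p <- result$p_map$values
  do.call(rbind, lapply(ids, function(id) {
    vox <- which(lab == id, arr.ind = TRUE)
    tv <- tf[lab == id]
    peak <- vox[which.max(tv), ]
    data.frame(cluster = id, peak_x = peak[1], peak_y = peak[2],
               peak_z = peak[3], extent = nrow(vox),
               peak_tfce = max(tv), min_p = min(p[lab == id]),
               row.names = NULL)
  }))
}
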