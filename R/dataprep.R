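#' Drop initial volumes of a run
#'
#' The first volumes of each run are discarded to ensure steady-state
#' magnetization (default 10). Event onsets referenced to the original run
#' start must be re-referenced by `-n * TR`; see [rereference_onsets()].
#'
#' @param run a `bold_run`.
#' @param n number of leading volumes to drop.
#' @return the trimmed `bold_run`.
#' @export
trim_initial_volumes <- function(run, n = 10L) {
  stopifnot(inherits(run, "bold_run"), n >= 0)
  nt <- dim(run$data)[4]
  if (n >= nt)
    stop(sprintf("cannot drop %d volumes from a %d-volume run", n, nt))
  if (n == 0L) return(run)
  bold_run(run$data[, , , (n + 1L):nt, drop = FALSE], run$grid,
           tr = run$tr, run_id = run$run_id)
}

#' Re-reference event onsets after trimming
#' @param events an event table.
#' @param n number of trimmed volumes.
#' @param tr repetition time in seconds.
#' @return event table with shifted onsets.
#' @export
rereference_onsets <- function(events, n, tr) {
  events$onset <- events$onset - n * tr
  events
}

#' Identify voxels that vary in every run
#'
#' Invariant features — voxels whose BOLD activity does not vary over a
#' run — carry no pattern information and break z-scoring; a voxel is kept
#' only if its temporal variance exceeds `tol` in every run.
#'
#' @param runs list of `bold_run`s (>= 1).
#' @param tol variance tolerance.
#' @return logical 3D array: `TRUE` where the voxel is retained (also
#'   restricted to the grid mask).
#' @export
remove_invariant_voxels <- function(runs, tol = 1e-12) {
  stopifnot(length(runs) >= 1)
  grid <- runs[[1]]$grid
  keep <- grid$mask
  for (run in runs) {
    d <- run$data
    dim(d) <- c(prod(grid$shape), dim(run$data)[4])
    v <- matrixStats_rowVars(d)
    keep <- keep & array(v > tol, dim = grid$shape)
  }
  if (!any(keep)) stop("all voxels are invariant in at least one run")
  keep
}

# row variances without extra dependencies
matrixStats_rowVars <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

#' Detrend and z-score a run voxel-wise
#'
#' Removes a least-squares linear trend from each voxel time series and
#' scales the residual to zero mean, unit variance (a single combined
#' linear model: intercept + slope, then residual standardization).
#' Voxels whose residual variance is zero are set to all-zeros and counted
#' in attribute `n_flagged`.
#'
#' @param run a `bold_run` with >= 3 volumes.
#' @return normalized `bold_run`.
#' @export
normalize_run <- function(run) {
  stopifnot(inherits(run, "bold_run"))
  nt <- dim(run$data)[4]
  if (nt < 3) stop("need at least 3 time points to detrend")
  d <- run$data
  nv <- prod(dim(d)[1:3])
  dim(d) <- c(nv, nt)
  tt <- seq_len(nt) - (nt + 1) / 2      # centered time regressor
  slope <- (d %*% tt) / sum(tt^2)
  resid <- d - rowMeans(d) - slope %*% rbind(tt)
  s <- sqrt(rowSums(resid^2) / (nt - 1))
  flagged <- s <= 1e-12
  s[flagged] <- 1
  resid <- resid / s
  resid[flagged, ] <- 0
  dim(resid) <- dim(run$data)
  out <- bold_run(resid, run$grid, tr = run$tr, run_id = run$run_id)
  attr(out, "n_flagged") <- sum(flagged)
  out
}

#' Extract trial-wise classification examples
#'
#' For each trial, all volumes whose acquisition midpoint `t = (i - 0.5) *
#' TR` falls in the half-open window `[onset + window[1], onset +
#' window[2])` are averaged into one example; examples from all runs are
#' stacked. The default 5.5-10.5 s window captures the hemodynamic peak
#' following each 3.5-s definition. Trials whose window extends past the
#' run end are dropped with a warning.
#'
#' @param runs list of normalized `bold_run`s.
#' @param events list of matching event tables (onsets re-referenced if
#'   runs were trimmed).
#' @param mask logical array of voxels to retain (e.g. from
#'   [remove_invariant_voxels()]); defaults to the grid mask.
#' @param window two-element window in seconds after stimulus onset.
#' @return An `example_set`: list with `X` (examples x voxels), `affect`,
#'   `desirability`, `run_id`, `concept_id`, `voxel_coords` (voxels x 3
#'   array indices mapping columns to grid coordinates), `grid`.
#' @export
extract_examples <- function(runs, events, mask = NULL,
                             window = c(5.5, 10.5)) {
  stopifnot(length(runs) == length(events), length(runs) >= 1,
            length(window) == 2, window[2] > window[1])
  grid <- runs[[1]]$grid
  if (is.null(mask)) mask <- grid$mask
  stopifnot(all(dim(mask) == grid$shape))
  coords <- which(mask, arr.ind = TRUE)
  vox_idx <- which(mask)
  rows <- list()
  meta <- list()
  for (r in seq_along(runs)) {
    run <- runs[[r]]
    ev <- events[[r]]
    nt <- dim(run$data)[4]
    mid <- (seq_len(nt) - 0.5) * run$tr
    d <- run$data
    dim(d) <- c(prod(grid$shape), nt)
    d <- d[vox_idx, , drop = FALSE]
    for (i in seq_len(nrow(ev))) {
      lo <- ev$onset[i] + window[1]
      hi <- ev$onset[i] + window[2]
      if (hi > nt * run$tr + run$tr / 2) {
        warning(sprintf("run %d trial %d window extends past run end; dropped",
                        ev$run_id[i], i))
        next
      }
      sel <- which(mid >= lo & mid < hi)
      if (!length(sel)) {
        warning(sprintf("run %d trial %d has no volumes in window; dropped",
                        ev$run_id[i], i))
        next
      }
      rows[[length(rows) + 1L]] <- rowMeans(d[, sel, drop = FALSE])
      meta[[length(meta) + 1L]] <- ev[i, c("run_id", "concept_id", "affect",
                                           "desirability")]
    }
  }
  if (!length(rows)) stop("no examples could be extracted")
  X <- do.call(rbind, rows)
  m <- do.call(rbind, meta)
  structure(list(X = X, affect = m$affect, desirability = m$desirability,
                 run_id = m$run_id, concept_id = m$concept_id,
                 voxel_coords = coords, grid = grid),
            class = "example_set")
}

#' @export
print.example_set <- function(x, ...) {
  cat("<example_set> ", nrow(x$X), " examples x ", ncol(x$X), " voxels, ",
      length(unique(x$run_id)), " run(s)\n", sep = "")
  invisible(x)
}

#' Full preparation pipeline: trim, mask, normalize, extract
#'
#' Applies the preparation stages in order: drop the first `n_trim`
#' volumes (re-referencing onsets), remove voxels invariant in any run,
#' z-score + detrend each run, then average the peri-peak window into one
#' example per trial and stack runs.
#'
#' @param runs list of `bold_run`s.
#' @param events list of matching event tables.
#' @param n_trim leading volumes to drop (default 10).
#' @param window averaging window in seconds (default `c(5.5, 10.5)`).
#' @return an `example_set`.
#' @export
prepare_examples <- function(runs, events, n_trim = 10L,
                             window = c(5.5, 10.5)) {
  runs <- lapply(runs, trim_initial_volumes, n = n_trim)
  events <- lapply(events, rereference_onsets, n = n_trim,
                   tr = runs[[1]]$tr)
  keep <- remove_invariant_voxels(runs)
  runs <- lapply(runs, normalize_run)
  extract_examples(runs, events, mask = keep, window = window)
}

#' Write / read an example set as a plain-text directory
#'
#' The matrix is stored as TSV alongside a JSON header documenting labels,
#' run and concept ids, and the voxel-coordinate map.
#'
#' @param es an `example_set`.
#' @param dir output directory (created if needed).
#' @return `dir` (write) or an `example_set` (read).
#' @export
write_example_set <- function(es, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(es$X, file.path(dir, "examples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  hdr <- list(affect = es$affect, desirability = es$desirability,
              run_id = es$run_id, concept_id = es$concept_id,
              voxel_coords = unname(apply(es$voxel_coords, 1, c,
                                          simplify = FALSE)),
              grid_shape = es$grid$shape,
              affine = as.vector(es$grid$affine))
  jsonlite::write_json(hdr, file.path(dir, "header.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(dir)
}

#' @rdname write_example_set
#' @export
read_example_set <- function(dir) {
  X <- as.matrix(read.table(file.path(dir, "examples.tsv"), sep = "\t",
                            header = FALSE))
  dimnames(X) <- NULL
  hdr <- jsonlite::read_json(file.path(dir, "header.json"),
                             simplifyVector = TRUE)
  shape <- as.integer(hdr$grid_shape)
  affine <- matrix(hdr$affine, 4, 4)
  coords <- matrix(as.integer(t(hdr$voxel_coords)), ncol = 3, byrow = TRUE)
  mask <- array(FALSE, dim = shape)
  mask[coords] <- TRUE
  grid <- structure(list(shape = shape, affine = affine, mask = mask),
                    class = "volume_grid")
  colnames(coords) <- c("dim1", "dim2", "dim3")
  structure(list(X = X, affect = hdr$affect,
                 desirability = hdr$desirability,
                 run_id = as.integer(hdr$run_id),
                 concept_id = as.integer(hdr$concept_id),
                 voxel_coords = coords, grid = grid),
            class = "example_set")
}
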