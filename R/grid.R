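#' Define a volume grid
#'
#' A volume grid bundles the 3D array shape, the voxel-to-mm affine and a
#' brain mask, and is shared by all simulated subjects (no between-subject
#' spatial normalization is modelled). The default is a 24^3 grid of
#' 2.4 mm isotropic voxels with an ellipsoidal "brain" mask, large enough
#' for 4-mm searchlight sphere geometry while staying desk-scale.
#'
#' @param shape integer length-3 array dimensions.
#' @param spacing voxel size in mm (scalar or length 3).
#' @param mask `"ellipsoid"` (default), `"full"`, or a logical array of
#'   dimension `shape`.
#' @return An object of class `volume_grid` with fields `shape`,
#'   `affine` (4x4 voxel-to-mm), and `mask` (logical array).
#' @export
make_volume_grid <- function(shape = c(24L, 24L, 24L), spacing = 2.4,
                             mask = c("ellipsoid", "full")) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stopifnot(all(spacing > 0))
  affine <- diag(c(spacing, 1))
  # centre the grid on the origin
  affine[1:3, 4] <- -spacing * (shape - 1) / 2
  if (is.character(mask)) {
    mask <- match.arg(mask)
    if (mask == "full") {
      m <- array(TRUE, dim = shape)
    } else {
      idx <- as.matrix(expand.grid(x = seq_len(shape[1]),
                                   y = seq_len(shape[2]),
                                   z = seq_len(shape[3])))
      ctr <- (shape + 1) / 2
      semi <- pmax(shape / 2 - 0.5, 0.5)
      r2 <- ((idx[, 1] - ctr[1]) / semi[1])^2 +
            ((idx[, 2] - ctr[2]) / semi[2])^2 +
            ((idx[, 3] - ctr[3]) / semi[3])^2
      m <- array(r2 <= 1, dim = shape)
    }
  } else {
    stopifnot(is.logical(mask), all(dim(mask) == shape))
    m <- mask
  }
  if (!any(m)) stop("volume grid mask is empty")
  structure(list(shape = shape, affine = affine, mask = m),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> ", paste(x$shape, collapse = "x"),
      " voxels, spacing ", paste(signif(voxel_spacing(x), 4), collapse = "x"),
      " mm, ", sum(x$mask), " in-mask voxels\n", sep = "")
  invisible(x)
}

#' Voxel spacing (mm) implied by a grid's affine
#' @param grid a `volume_grid`.
#' @return numeric length 3.
#' @export
voxel_spacing <- function(grid) {
  A <- grid$affine[1:3, 1:3]
  sqrt(colSums(A^2))
}

#' Construct a per-voxel statistic map
#'
#' A `stat_map` is a scalar brain map on a [make_volume_grid()] grid with a
#' semantic tag saying what the values are (`"auc_minus_chance"`, `"z"`,
#' `"tfce"`, `"p"`, ...). Values outside the mask are set to `NA`.
#'
#' @param values numeric 3D array matching `grid$shape`.
#' @param grid a `volume_grid`.
#' @param semantic character tag for the value semantics.
#' @return A `stat_map` object.
#' @export
stat_map <- function(values, grid, semantic = "stat") {
  stopifnot(inherits(grid, "volume_grid"), all(dim(values) == grid$shape))
  values[!grid$mask] <- NA_real_
  if (any(!is.finite(values[grid$mask]) & !is.na(values[grid$mask])))
    stop("stat_map values must be finite (or NA) inside the mask")
  structure(list(values = values, grid = grid, semantic = semantic),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  v <- x$values[x$grid$mask]
  cat("<stat_map:", x$semantic, "> ",
      paste(x$grid$shape, collapse = "x"),
      sprintf(", range [%.4g, %.4g], %d NA\n",
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))),
      sep = "")
  invisible(x)
}

.as_nifti_with_affine <- function(arr, affine, tr = 1) {
  img <- RNifti::asNifti(arr)
  sp <- sqrt(colSums(affine[1:3, 1:3]^2))
  img$pixdim <- c(0, sp, tr, 0, 0, 0)
  xf <- structure(affine, code = 2L)
  RNifti::qform(img) <- xf
  RNifti::sform(img) <- xf
  img
}

#' Write / read a statistic map as NIfTI-1
#'
#' Values outside the mask are stored as NaN. A JSON sidecar describing the
#' producing operation can be attached with `sidecar`.
#'
#' @param map a `stat_map`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param sidecar optional named list written as `<path>.json`.
#' @return `write_stat_map` returns `path` invisibly; `read_stat_map`
#'   returns a `stat_map`.
#' @export
write_stat_map <- function(map, path, sidecar = NULL) {
  stopifnot(inherits(map, "stat_map"))
  img <- .as_nifti_with_affine(map$values, map$grid$affine)
  RNifti::writeNifti(img, path)
  if (!is.null(sidecar)) write_sidecar(path, sidecar)
  invisible(path)
}

#' @rdname write_stat_map
#' @param mask optional logical array; defaults to finite voxels.
#' @param semantic semantic tag for the reconstructed map.
#' @export
read_stat_map <- function(path, mask = NULL, semantic = "stat") {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  affine <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  if (is.null(mask)) mask <- array(is.finite(arr), dim = dim(arr))
  grid <- structure(list(shape = dim(arr), affine = affine, mask = mask),
                    class = "volume_grid")
  stat_map(arr, grid, semantic = semantic)
}

#' Write / read a 4D BOLD run as NIfTI-1
#'
#' @param run a `bold_run` (see [simulate_bold()]).
#' @param path output path.
#' @param sidecar optional named list written as `<path>.json`.
#' @return `write_bold_run` returns `path` invisibly; `read_bold_run` a
#'   `bold_run`.
#' @export
write_bold_run <- function(run, path, sidecar = NULL) {
  stopifnot(inherits(run, "bold_run"))
  img <- .as_nifti_with_affine(run$data, run$grid$affine, tr = run$tr)
  RNifti::writeNifti(img, path)
  if (!is.null(sidecar)) write_sidecar(path, sidecar)
  invisible(path)
}

#' @rdname write_bold_run
#' @param grid optional `volume_grid`; reconstructed from the header if
#'   missing (full mask).
#' @param run_id run identifier to attach.
#' @export
read_bold_run <- function(path, grid = NULL, run_id = 1L) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  stopifnot(length(dim(arr)) == 4L)
  tr <- RNifti::pixdim(img)[4]
  if (is.null(grid)) {
    affine <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
    grid <- structure(list(shape = dim(arr)[1:3], affine = affine,
                           mask = array(TRUE, dim = dim(arr)[1:3])),
                      class = "volume_grid")
  }
  bold_run(arr, grid, tr = tr, run_id = run_id)
}

#' Assemble a BOLD run object
#'
#' @param data numeric 4D array `(x, y, z, t)`, finite.
#' @param grid a `volume_grid` matching the first three dimensions.
#' @param tr repetition time in seconds (default 0.85).
#' @param run_id integer run identifier.
#' @return A `bold_run` object.
#' @export
bold_run <- function(data, grid, tr = 0.85, run_id = 1L) {
  stopifnot(inherits(grid, "volume_grid"), length(dim(data)) == 4L,
            all(dim(data)[1:3] == grid$shape), tr > 0)
  if (!all(is.finite(data))) stop("BOLD data must be finite")
  structure(list(run_id = as.integer(run_id), data = data, tr = tr,
                 grid = grid),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  cat("<bold_run ", x$run_id, "> ", paste(dim(x$data), collapse = "x"),
      ", TR ", x$tr, " s\n", sep = "")
  invisible(x)
}

#' Write a JSON sidecar next to an output file
#' @param path path of the data file; sidecar written at `<path>.json`.
#' @param info named list of provenance fields.
#' @return sidecar path, invisibly.
#' @export
write_sidecar <- function(path, info) {
  side <- paste0(path, ".json")
  jsonlite::write_json(info, side, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(side)
}

#' NIfTI round-trip of a map or run
#'
#' Writes the object to disk and reads it back, checking that shape and
#' affine survive. Used to validate I/O fidelity.
#'
#' @param x a `stat_map` or `bold_run`.
#' @param path optional path; a temporary file by default.
#' @return the re-read object.
#' @export
nifti_roundtrip <- function(x, path = tempfile(fileext = ".nii.gz")) {
  if (inherits(x, "stat_map")) {
    write_stat_map(x, path)
    out <- read_stat_map(path, mask = x$grid$mask, semantic = x$semantic)
  } else if (inherits(x, "bold_run")) {
    write_bold_run(x, path)
    out <- read_bold_run(path, grid = x$grid, run_id = x$run_id)
  } else stop("nifti_roundtrip() expects a stat_map or bold_run")
  stopifnot(all(dim(out$values %||% out$data) ==
                dim(x$values %||% x$data)))
  if (max(abs(out$grid$affine - x$grid$affine)) > 1e-4)
    stop("affine not preserved in NIfTI round-trip")
  out
}
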