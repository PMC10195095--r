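#' Voxel grid specification
#'
#' Describes the regular, isotropic voxel grid shared by all volumes in a
#' reconstruction. Axis roles are fixed: the x axis is the sheet-normal
#' direction, y the myocyte longitudinal direction, z the transverse
#' direction (the imaging convention in which the field of view is rotated so
#' that myocyte long axes align with y).
#'
#' @param shape integer vector of length 3, voxels along (x, y, z); all >= 1.
#' @param spacing voxel edge length in meters (isotropic, > 0).
#' @return An object of class `grid_spec` with fields `shape`, `spacing`, and
#'   the fixed `axis_roles` mapping.
#' @examples
#' grid_spec(c(64, 128, 64), 200e-9)
#' @export
grid_spec <- function(shape, spacing) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("`shape` must be three integers >= 1", call. = FALSE)
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) ||
      spacing <= 0)
    stop("`spacing` must be a single positive length in meters", call. = FALSE)
  structure(
    list(shape = shape, spacing = as.numeric(spacing),
         axis_roles = c(normal = "x", longitudinal = "y", transverse = "z")),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d x %d voxels, spacing %g nm\n",
              x$shape[1], x$shape[2], x$shape[3], x$spacing * 1e9))
  invisible(x)
}

check_array <- function(grid, a, what) {
  if (!is.array(a) || length(dim(a)) != 3L)
    stop(sprintf("`%s` must be a 3D array", what), call. = FALSE)
  if (!identical(as.integer(dim(a)), grid$shape))
    stop(sprintf("`%s` shape does not match the grid", what), call. = FALSE)
  invisible(a)
}

#' Myocyte instance segmentation volume
#'
#' @param grid a [grid_spec()].
#' @param ids 3D array of non-negative integer myocyte IDs; 0 is background
#'   (non-myocyte), k > 0 labels myocyte k.
#' @return An object of class `segment_volume`.
#' @export
segment_volume <- function(grid, ids) {
  stopifnot(inherits(grid, "grid_spec"))
  check_array(grid, ids, "ids")
  storage.mode(ids) <- "integer"
  if (anyNA(ids) || any(ids < 0L))
    stop("myocyte IDs must be non-negative integers", call. = FALSE)
  structure(list(grid = grid, ids = ids), class = "segment_volume")
}

#' @export
print.segment_volume <- function(x, ...) {
  n <- length(setdiff(unique(as.vector(x$ids)), 0L))
  cat(sprintf("<segment_volume> %d myocytes on a %d x %d x %d grid\n",
              n, x$grid$shape[1], x$grid$shape[2], x$grid$shape[3]))
  invisible(x)
}

#' Co-registered tissue class masks
#'
#' Boolean masks for vessels, fibroblasts, myofibroblasts and interlaminar
#' clefts on the same grid as the myocyte segmentation. The three cell-class
#' masks must be pairwise disjoint; clefts are part of the extracellular
#' space and must not overlap any cell mask.
#'
#' @param grid a [grid_spec()].
#' @param vessel,fibroblast,myofibroblast,cleft 3D logical arrays.
#' @return An object of class `tissue_labels`.
#' @export
tissue_labels <- function(grid, vessel = NULL, fibroblast = NULL,
                          myofibroblast = NULL, cleft = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  empty <- array(FALSE, grid$shape)
  take <- function(m, what) {
    if (is.null(m)) return(empty)
    check_array(grid, m, what)
    storage.mode(m) <- "logical"
    m
  }
  vessel <- take(vessel, "vessel")
  fibroblast <- take(fibroblast, "fibroblast")
  myofibroblast <- take(myofibroblast, "myofibroblast")
  cleft <- take(cleft, "cleft")
  if (any((vessel & fibroblast) | (vessel & myofibroblast) |
          (fibroblast & myofibroblast)))
    stop("vessel/fibroblast/myofibroblast masks must be pairwise disjoint",
         call. = FALSE)
  if (any(cleft & (vessel | fibroblast | myofibroblast)))
    stop("cleft mask must be disjoint from all cell masks", call. = FALSE)
  structure(list(grid = grid, vessel = vessel, fibroblast = fibroblast,
                 myofibroblast = myofibroblast, cleft = cleft),
            class = "tissue_labels")
}

#' Fluorescence intensity volume (e.g. the Cx43 channel)
#'
#' @param grid a [grid_spec()].
#' @param values 3D numeric array of non-negative finite intensities
#'   (arbitrary fluorescence units).
#' @return An object of class `intensity_volume`.
#' @export
intensity_volume <- function(grid, values) {
  stopifnot(inherits(grid, "grid_spec"))
  check_array(grid, values, "values")
  storage.mode(values) <- "double"
  if (!all(is.finite(values)) || any(values < 0))
    stop("intensities must be finite and non-negative", call. = FALSE)
  structure(list(grid = grid, values = values), class = "intensity_volume")
}

volume_data <- function(vol) {
  if (inherits(vol, "segment_volume")) vol$ids else vol$values
}

myoconduct_error <- function(class, msg) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Write a volume to a multi-page TIFF with a YAML sidecar
#'
#' One TIFF page per z slice (page rows = y, columns = x). Integer data
#' (segmentations, masks) are stored as 16-bit samples and round-trip
#' bit-exactly; intensity data are stored as 32-bit floats. Grid spacing and
#' the volume kind are recorded in `<path>.yaml`.
#'
#' @param vol a `segment_volume`, `intensity_volume`, or a single logical
#'   mask wrapped in a `segment_volume`-like array via [segment_volume()].
#' @param path output file path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  grid <- vol$grid
  a <- volume_data(vol)
  kind <- if (inherits(vol, "segment_volume")) "segments" else "intensity"
  scale <- 1
  if (kind == "segments") {
    if (max(a) > 65535L)
      stop("integer volumes above 65535 are not supported by the TIFF writer",
           call. = FALSE)
    pages <- lapply(seq_len(grid$shape[3]),
                    function(k) t(a[, , k]) / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else {
    # float TIFF samples are defined on [0, 1]: store normalized intensities
    # and keep the scale factor in the sidecar
    scale <- max(a, 1e-300)
    pages <- lapply(seq_len(grid$shape[3]), function(k) t(a[, , k]) / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  }
  yaml::write_yaml(list(spacing = grid$spacing, kind = kind,
                        shape = as.integer(grid$shape), scale = scale),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Read a volume from a multi-page TIFF written by [write_volume()]
#'
#' The `<path>.yaml` sidecar supplies the voxel spacing and the volume kind;
#' integer-typed data yield a [segment_volume()], float-typed data an
#' [intensity_volume()]. Anisotropic spacing and HDF5 containers are
#' rejected with named errors.
#'
#' @param path TIFF file path.
#' @param dataset optional dataset name; only meaningful for HDF5 input,
#'   which this build does not support (raises
#'   `myoconduct_unsupported_format`).
#' @param spacing optional spacing override in meters (used when no sidecar
#'   is present).
#' @return A `segment_volume` or `intensity_volume`.
#' @export
read_volume <- function(path, dataset = NULL, spacing = NULL) {
  if (!file.exists(path))
    myoconduct_error("myoconduct_missing_file",
                     sprintf("volume file not found: %s", path))
  if (grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE))
    myoconduct_error("myoconduct_unsupported_format",
                     "HDF5 volumes are not supported; use multi-page TIFF")
  meta_path <- paste0(path, ".yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  if (is.null(spacing)) spacing <- meta$spacing
  if (is.null(spacing))
    myoconduct_error("myoconduct_missing_spacing",
                     "voxel spacing not found in sidecar metadata and not supplied")
  if (length(spacing) > 1L) {
    if (length(unique(spacing)) > 1L)
      myoconduct_error("myoconduct_anisotropic_spacing",
                       "anisotropic voxel spacing is not supported")
    spacing <- spacing[1]
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(dim(pages[[1]])) != 2L)
    myoconduct_error("myoconduct_bad_dataset", "dataset is not a stack of 2D slices")
  nz <- length(pages)
  ny <- nrow(pages[[1]])
  nx <- ncol(pages[[1]])
  a <- array(0, c(nx, ny, nz))
  for (k in seq_len(nz)) a[, , k] <- t(pages[[k]])
  grid <- grid_spec(c(nx, ny, nz), spacing)
  kind <- if (!is.null(meta$kind)) meta$kind else "intensity"
  if (kind == "segments") {
    segment_volume(grid, array(as.integer(round(a * 65535)), dim(a)))
  } else {
    scale <- if (!is.null(meta$scale)) meta$scale else 1
    intensity_volume(grid, a * scale)
  }
}

#' Extract non-overlapping substacks
#'
#' Tiles the x-y plane with non-overlapping square windows of physical side
#' `extent_xy`, each spanning the full z depth, starting at index 0 in x and
#' y; trailing remainder voxels are discarded. Myocyte IDs are preserved.
#'
#' @param volume a `segment_volume`, `intensity_volume`, or `tissue_labels`.
#' @param extent_xy window side length in meters (must not exceed the
#'   physical x and y extents of `volume`).
#' @return A list of volumes of the same class as the input, with attributes
#'   `tile_x`/`tile_y` (0-based tile indices) on each element.
#' @export
extract_substacks <- function(volume, extent_xy) {
  grid <- volume$grid
  nvox <- extent_xy / grid$spacing
  nvox <- as.integer(round(nvox))
  if (nvox < 1L || nvox > grid$shape[1] || nvox > grid$shape[2])
    myoconduct_error("myoconduct_extent_too_large",
                     "substack extent exceeds the volume in x or y")
  tx <- grid$shape[1] %/% nvox
  ty <- grid$shape[2] %/% nvox
  sub_grid <- grid_spec(c(nvox, nvox, grid$shape[3]), grid$spacing)
  out <- vector("list", tx * ty)
  k <- 0L
  for (iy in seq_len(ty) - 1L) {
    for (ix in seq_len(tx) - 1L) {
      xs <- ix * nvox + seq_len(nvox)
      ys <- iy * nvox + seq_len(nvox)
      sub <- if (inherits(volume, "segment_volume")) {
        segment_volume(sub_grid, volume$ids[xs, ys, , drop = FALSE])
      } else if (inherits(volume, "intensity_volume")) {
        intensity_volume(sub_grid, volume$values[xs, ys, , drop = FALSE])
      } else if (inherits(volume, "tissue_labels")) {
        tissue_labels(sub_grid,
                      vessel = volume$vessel[xs, ys, , drop = FALSE],
                      fibroblast = volume$fibroblast[xs, ys, , drop = FALSE],
                      myofibroblast = volume$myofibroblast[xs, ys, , drop = FALSE],
                      cleft = volume$cleft[xs, ys, , drop = FALSE])
      } else stop("unsupported volume class", call. = FALSE)
      k <- k + 1L
      attr(sub, "tile_x") <- ix
      attr(sub, "tile_y") <- iy
      out[[k]] <- sub
    }
  }
  out
}
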