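#' Threshold the Cx43 channel
#'
#' Histogram-based thresholding of the connexin43 fluorescence signal: a
#' voxel is kept when its intensity exceeds the image mode plus `k_sd`
#' standard deviations, both computed over all voxels of the stack. The mode
#' uses integer intensity bins (width 1) for integer-valued data and 256
#' equal-width bins over the intensity range otherwise, with ties broken
#' toward the lowest bin.
#'
#' @param cx43 an [intensity_volume()].
#' @param k_sd threshold multiplier (default 4.5).
#' @return 3D logical array of supra-threshold voxels.
#' @export
threshold_cx43 <- function(cx43, k_sd = 4.5) {
  v <- cx43$values
  s <- stats::sd(v)
  integerish <- all(v == round(v))
  if (integerish) {
    tab <- table(as.vector(v))
    mode_val <- as.numeric(names(tab)[which.max(tab)])  # which.max: first = lowest
  } else {
    rng <- range(v)
    if (diff(rng) == 0) {
      mode_val <- rng[1]
    } else {
      h <- graphics::hist(as.vector(v), breaks = seq(rng[1], rng[2],
                                                     length.out = 257L),
                          plot = FALSE)
      mode_val <- h$mids[which.max(h$counts)]
    }
  }
  if (s == 0) {
    warning("constant Cx43 image: threshold mask is empty", call. = FALSE)
    return(array(v > mode_val, dim(v)))
  }
  array(v > mode_val + k_sd * s, dim(v))
}

#' Isolate myocytes and build the membrane boundary layer
#'
#' Reproduces the membrane-candidate construction used for gap-junction
#' assignment: (1) myocyte labels are dilated three times with the
#' 26-neighbourhood so adjacent myocytes come into close contact — the
#' dilation is conflict-barrier dilation, in which a background voxel adopts
#' the unique label in its neighbourhood and voxels reached by two or more
#' labels stay background, so an existing one-voxel wall is never
#' swallowed; (2) myocytes are isolated with exactly one separating voxel
#' layer by clearing any labelled voxel whose 26-neighbourhood holds a
#' smaller nonzero label (a deterministic single pass); (3) the boundary is
#' the 26-neighbourhood dilation of the isolated myocytes minus the
#' myocytes themselves — a one-voxel shell holding all candidate
#' gap-junction locations.
#'
#' @param segments a [segment_volume()].
#' @return List with `isolated_segments` (a [segment_volume()]) and
#'   `boundary` (3D logical array).
#' @export
build_boundary <- function(segments) {
  dim3 <- segments$grid$shape
  dil <- cpp_dilate_labels_barrier(as.vector(segments$ids), dim3, 3L)
  iso <- cpp_carve_touching(dil, dim3)
  shell <- cpp_boundary_shell(iso, dim3)
  list(isolated_segments = segment_volume(segments$grid, array(iso, dim3)),
       boundary = array(shell, dim3))
}

#' Project thresholded Cx43 voxels onto the membrane boundary
#'
#' Every supra-threshold Cx43 voxel within Euclidean distance `max_dist` of
#' the boundary is assigned to its nearest boundary voxel (ties broken by
#' smallest linear voxel index, x fastest); voxels farther away are
#' dropped. A boundary voxel that receives at least one projected voxel and
#' is 26-adjacent to two or more distinct myocyte IDs becomes a
#' gap-junction-containing voxel, attributed to the lexicographically
#' smallest adjacent ID pair.
#'
#' @param mask 3D logical array from [threshold_cx43()].
#' @param boundary 3D logical boundary array from [build_boundary()].
#' @param isolated_segments the isolated [segment_volume()] from
#'   [build_boundary()].
#' @param max_dist maximum projection distance in meters (default 1e-6).
#' @return An object of class `gap_junction_map`: `grid`, `gj_mask` (3D
#'   logical), `pair_counts` (data.frame `id_a`, `id_b`, `count` with
#'   `id_a < id_b`), and `v_gj` (volume fraction, %).
#' @export
project_cx43 <- function(mask, boundary, isolated_segments, max_dist = 1e-6) {
  grid <- isolated_segments$grid
  dim3 <- grid$shape
  queries <- which(mask)
  gj_mask <- array(FALSE, dim3)
  pair_counts <- data.frame(id_a = integer(0), id_b = integer(0),
                            count = integer(0))
  if (length(queries)) {
    tgt <- cpp_project_to_boundary(queries, as.vector(boundary), dim3,
                                   max_dist / grid$spacing)
    hits <- sort(unique(tgt[!is.na(tgt)]))
    if (length(hits)) {
      pr <- cpp_adjacent_pair(as.vector(isolated_segments$ids), dim3, hits)
      shared <- pr[, 2] > 0L
      gj_vox <- hits[shared]
      gj_mask[gj_vox] <- TRUE
      if (length(gj_vox)) {
        key <- paste(pr[shared, 1], pr[shared, 2], sep = "-")
        tab <- table(key)
        ab <- do.call(rbind, strsplit(names(tab), "-", fixed = TRUE))
        pair_counts <- data.frame(id_a = as.integer(ab[, 1]),
                                  id_b = as.integer(ab[, 2]),
                                  count = as.integer(tab))
        pair_counts <- pair_counts[order(pair_counts$id_a, pair_counts$id_b), ]
        rownames(pair_counts) <- NULL
      }
    }
  }
  structure(list(grid = grid, gj_mask = gj_mask, pair_counts = pair_counts,
                 v_gj = 100 * sum(gj_mask) / prod(dim3)),
            class = "gap_junction_map")
}

#' @export
print.gap_junction_map <- function(x, ...) {
  cat(sprintf("<gap_junction_map> %d gj voxels, %d coupled pairs, Vgj %.4f%%\n",
              sum(x$gj_mask), nrow(x$pair_counts), x$v_gj))
  invisible(x)
}

#' Calibrate the gap-junction voxel conductivity
#'
#' Maps the mean number of coupled Cx43 voxels per myocyte pair in control
#' stacks onto a reference whole-pair conductance (1.24 uS for normal
#' ventricular myocyte pairs), giving the conductivity assigned to a single
#' gap-junction voxel of edge length l and face area A:
#' `sigma_gj = pair_conductance / N_gj_control * l / A`.
#'
#' @param pair_counts a `pair_counts` data.frame (or a list of them, pooled
#'   across control stacks) as produced by [project_cx43()].
#' @param pair_conductance reference myocyte-pair conductance in Siemens.
#' @param grid a [grid_spec()] supplying the voxel length.
#' @param n_pairs optional total number of myocyte pairs to average over;
#'   by default the mean is taken over coupled pairs only (count >= 1).
#' @return An object of class `gj_conductivity` with fields `sigma_gj`
#'   (S/m), `pair_conductance`, `n_gj_control`, `l`, `A`.
#' @export
calibrate_sigma_gj <- function(pair_counts, pair_conductance = 1.24e-6,
                               grid, n_pairs = NULL) {
  if (is.data.frame(pair_counts)) pair_counts <- list(pair_counts)
  counts <- unlist(lapply(pair_counts, function(p) p$count))
  counts <- counts[counts >= 1L]
  if (length(counts) == 0L)
    myoconduct_error("myoconduct_no_coupled_pairs",
                     "no coupled myocyte pairs available for calibration")
  n_gj_control <- if (is.null(n_pairs)) mean(counts) else sum(counts) / n_pairs
  l <- grid$spacing
  A <- grid$spacing^2
  structure(list(sigma_gj = pair_conductance / n_gj_control * l / A,
                 pair_conductance = pair_conductance,
                 n_gj_control = n_gj_control, l = l, A = A),
            class = "gj_conductivity")
}

#' @export
print.gj_conductivity <- function(x, ...) {
  cat(sprintf(paste0("<gj_conductivity> sigma_gj %.4g S/m ",
                     "(pair conductance %.3g uS, N_gj %.2f, l %g nm)\n"),
              x$sigma_gj, x$pair_conductance * 1e6, x$n_gj_control, x$l * 1e9))
  invisible(x)
}

#' Gap-junction-coupled neighbours per myocyte
#'
#' For each myocyte, the number of distinct partner myocytes with which it
#' shares at least one gap-junction voxel.
#'
#' @param gj a `gap_junction_map`.
#' @param ids optional vector of all myocyte IDs in the stack; myocytes
#'   without partners then report a count of 0. Defaults to the IDs present
#'   in the pair table.
#' @return List with `per_myocyte` (named integer vector), `mean`, and `sd`.
#' @export
coupled_neighbor_count <- function(gj, ids = NULL) {
  p <- gj$pair_counts[gj$pair_counts$count >= 1L, , drop = FALSE]
  if (is.null(ids)) ids <- sort(unique(c(p$id_a, p$id_b)))
  ids <- sort(unique(as.integer(ids)))
  counts <- vapply(ids, function(i)
    length(unique(c(p$id_b[p$id_a == i], p$id_a[p$id_b == i]))), integer(1))
  names(counts) <- ids
  list(per_myocyte = counts,
       mean = if (length(counts)) mean(counts) else NA_real_,
       sd = if (length(counts) > 1L) stats::sd(counts) else NA_real_)
}

#' Derive the gap-junction map from segmentation and Cx43 channel
#'
#' Convenience wrapper chaining [threshold_cx43()], [build_boundary()] and
#' [project_cx43()].
#'
#' @param segments a [segment_volume()].
#' @param cx43 an [intensity_volume()] on the same grid.
#' @param k_sd threshold multiplier (see [threshold_cx43()]).
#' @param max_dist projection distance in meters (see [project_cx43()]).
#' @return List with `gj` (a `gap_junction_map`), `isolated_segments`, and
#'   `boundary`.
#' @export
derive_gap_junctions <- function(segments, cx43, k_sd = 4.5, max_dist = 1e-6) {
  bb <- build_boundary(segments)
  m <- threshold_cx43(cx43, k_sd)
  gj <- project_cx43(m, bb$boundary, bb$isolated_segments, max_dist)
  list(gj = gj, isolated_segments = bb$isolated_segments,
       boundary = bb$boundary)
}
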