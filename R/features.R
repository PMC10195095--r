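#' Extracellular volume fraction identity
#'
#' The extracellular space is the residual volume not segmented as
#' myocyte, vessel, fibroblast or myofibroblast:
#' `Ve = 100% - (Vmyo + Vfibro + Vmyofibro + Vvessels)`.
#'
#' @param v_myo,v_vessels,v_fibro,v_myofibro volume fractions in percent.
#' @return Ve in percent.
#' @export
extracellular_fraction <- function(v_myo, v_vessels, v_fibro, v_myofibro) {
  100 - (v_myo + v_fibro + v_myofibro + v_vessels)
}

#' Tissue composition volume fractions
#'
#' Each class fraction is 100 times its voxel count over the stack voxel
#' count; the extracellular fraction follows from
#' [extracellular_fraction()]. The cleft fraction is reported separately but
#' counted inside Ve. Orientation fields are left unset (see
#' [myocyte_orientation()] and [cleft_normal()], or use [quantify_stack()]).
#'
#' @param segments a [segment_volume()].
#' @param labels a [tissue_labels()] on the same grid.
#' @param gj optional `gap_junction_map` supplying `v_gj`.
#' @return An object of class `tissue_features`.
#' @export
volume_fractions <- function(segments, labels, gj = NULL) {
  if (!identical(segments$grid$shape, labels$grid$shape))
    stop("segments and labels are not co-registered", call. = FALSE)
  myo <- segments$ids > 0L
  cells <- labels$vessel | labels$fibroblast | labels$myofibroblast
  if (any(myo & cells))
    myoconduct_error("myoconduct_overlapping_masks",
                     "tissue class masks overlap the myocyte segmentation")
  if (any(myo & labels$cleft))
    myoconduct_error("myoconduct_overlapping_masks",
                     "cleft mask overlaps the myocyte segmentation")
  total <- prod(segments$grid$shape)
  v_myo <- 100 * sum(myo) / total
  v_vessels <- 100 * sum(labels$vessel) / total
  v_fibro <- 100 * sum(labels$fibroblast) / total
  v_myofibro <- 100 * sum(labels$myofibroblast) / total
  structure(list(v_myo = v_myo, v_vessels = v_vessels, v_fibro = v_fibro,
                 v_myofibro = v_myofibro,
                 v_e = extracellular_fraction(v_myo, v_vessels, v_fibro,
                                              v_myofibro),
                 v_clefts = 100 * sum(labels$cleft) / total,
                 v_gj = if (!is.null(gj)) gj$v_gj else NA_real_,
                 v_fibrosis = NA_real_,
                 delta_l = NA_real_, delta_n = NA_real_,
                 excluded = FALSE, exclusion_reason = ""),
            class = "tissue_features")
}

#' @export
print.tissue_features <- function(x, ...) {
  cat(sprintf(paste0("<tissue_features> Vmyo %.2f%% Vvessels %.2f%% ",
                     "Vfibro %.2f%% Vmyofibro %.2f%% Ve %.2f%%\n"),
              x$v_myo, x$v_vessels, x$v_fibro, x$v_myofibro, x$v_e))
  if (!is.na(x$v_gj)) cat(sprintf("  Vgj %.4f%%", x$v_gj))
  if (!is.na(x$delta_l)) cat(sprintf("  dl %.1f deg", x$delta_l))
  if (!is.na(x$delta_n)) cat(sprintf("  dn %.1f deg", x$delta_n))
  if (x$excluded) cat(sprintf("  EXCLUDED (%s)", x$exclusion_reason))
  cat("\n")
  invisible(x)
}

fibrosis_sum <- function(f) f$v_e + f$v_fibro + f$v_myofibro

#' Fibrosis volume fraction relative to the control group
#'
#' Fibrosis is quantified through its extracellular and cellular
#' constituents: the sample's `Ve + Vfibro + Vmyofibro` minus the mean of
#' that sum over the control group. By construction the control-group mean
#' of this quantity is exactly zero; individual control values may be
#' negative.
#'
#' @param sample a `tissue_features` object.
#' @param control_group non-empty list of `tissue_features` for the control
#'   stacks.
#' @return Vfibrosis in percent.
#' @export
fibrosis_fraction <- function(sample, control_group) {
  if (length(control_group) == 0L)
    myoconduct_error("myoconduct_empty_control", "control group is empty")
  ref <- mean(vapply(control_group, fibrosis_sum, numeric(1)))
  fibrosis_sum(sample) - ref
}

segment_axis <- function(coords) {
  # principal axis of one myocyte from its second-order central moments
  centered <- sweep(coords, 2, colMeans(coords))
  m <- crossprod(centered) / nrow(centered)
  e <- eigen(m, symmetric = TRUE)
  v <- e$vectors[, 1]  # largest eigenvalue first; deterministic LAPACK order
  # sign convention: non-negative y component; fall back to first nonzero
  if (v[2] < 0 || (v[2] == 0 && (v[1] < 0 || (v[1] == 0 && v[3] < 0)))) v <- -v
  v
}

#' Mean myocyte long-axis deviation from the longitudinal axis
#'
#' Computes the principal axis of each of the `n_largest` myocytes by voxel
#' count from the eigenvectors of its second-order central moments, flips
#' each axis into the non-negative-y hemisphere (axes are directionless),
#' averages the unit vectors, and returns the angle between the mean axis
#' and the y axis in degrees.
#'
#' @param segments a [segment_volume()].
#' @param n_largest number of myocytes to average (default 10); if fewer
#'   exist, all are used with a warning.
#' @return `delta_l` in degrees, in `[0, 90]`.
#' @export
myocyte_orientation <- function(segments, n_largest = 10L) {
  ids <- segments$ids
  tab <- table(ids[ids > 0L])
  if (length(tab) == 0L) stop("no myocytes in segmentation", call. = FALSE)
  if (length(tab) < n_largest) {
    warning(sprintf("only %d myocytes present; using all", length(tab)),
            call. = FALSE)
    n_largest <- length(tab)
  }
  top <- as.integer(names(sort(tab, decreasing = TRUE)[seq_len(n_largest)]))
  axes <- vapply(top, function(id) {
    w <- which(ids == id, arr.ind = TRUE)
    segment_axis(w)
  }, numeric(3))
  v <- rowMeans(axes)
  v <- v / sqrt(sum(v^2))
  acos(pmin(1, abs(v[2]))) * 180 / pi
}

#' Deviation of the largest interlaminar cleft-plane normal from x
#'
#' The largest 26-connected component of the cleft mask is fit by a plane
#' (least squares on voxel centers: the plane normal is the eigenvector of
#' the smallest eigenvalue of the component's second-order central
#' moments); `delta_n` is the angle between that normal and the x axis. An
#' empty cleft mask yields 0 with the `no_cleft` flag set.
#'
#' @param labels a [tissue_labels()].
#' @return List with `delta_n` (degrees) and `no_cleft` (logical).
#' @export
cleft_normal <- function(labels) {
  m <- labels$cleft
  if (!any(m)) return(list(delta_n = 0, no_cleft = TRUE))
  comp <- array(cpp_label_components(as.vector(m), labels$grid$shape, 26L),
                dim(m))
  tab <- tabulate(comp[comp > 0L])
  largest <- which.max(tab)
  w <- which(comp == largest, arr.ind = TRUE)
  centered <- sweep(w, 2, colMeans(w))
  mom <- crossprod(centered) / nrow(centered)
  e <- eigen(mom, symmetric = TRUE)
  nrm <- e$vectors[, 3]  # smallest eigenvalue last
  list(delta_n = acos(pmin(1, abs(nrm[1]))) * 180 / pi, no_cleft = FALSE)
}

#' Apply the stack exclusion criteria
#'
#' Stacks with weak alignment of the microstructure are excluded from
#' analysis: deviation of the myocyte long axis from y above 10 degrees, or
#' deviation of the cleft normal from x above 30 degrees (both strict
#' inequalities).
#'
#' @param features a `tissue_features` with `delta_l` and `delta_n` set.
#' @return The features object with `excluded` and `exclusion_reason`
#'   filled in.
#' @export
qc_exclude <- function(features) {
  reasons <- character(0)
  if (!is.na(features$delta_l) && features$delta_l > 10)
    reasons <- c(reasons, "delta_l > 10 deg")
  if (!is.na(features$delta_n) && features$delta_n > 30)
    reasons <- c(reasons, "delta_n > 30 deg")
  features$excluded <- length(reasons) > 0L
  features$exclusion_reason <- paste(reasons, collapse = "; ")
  features
}

#' Quantify all tissue features of one stack
#'
#' Convenience wrapper: volume fractions, myocyte orientation, cleft-plane
#' normal, and the exclusion rule in one call.
#'
#' @inheritParams volume_fractions
#' @param n_largest passed to [myocyte_orientation()].
#' @return A complete `tissue_features` object.
#' @export
quantify_stack <- function(segments, labels, gj = NULL, n_largest = 10L) {
  f <- volume_fractions(segments, labels, gj)
  f$delta_l <- myocyte_orientation(segments, n_largest)
  cn <- cleft_normal(labels)
  f$delta_n <- cn$delta_n
  qc_exclude(f)
}
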