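#' Specification of a synthetic brick-myocyte tissue
#'
#' Describes a lattice of brick-shaped myocytes separated by thin
#' extracellular walls, with gap-junction patches on end-to-end and
#' side-to-side faces, optional interlaminar cleft planes normal to x,
#' optional vessel/fibroblast/myofibroblast block inclusions, and an optional
#' in-plane rotation of the myocyte long axis. Used as the test bed with
#' known ground truth in place of microscopy data.
#'
#' @param grid a [grid_spec()].
#' @param myocyte_dims numeric length 3, myocyte (length_y, width_x,
#'   height_z) in meters; each must span at least 3 voxels.
#' @param wall_thickness inter-myocyte wall thickness in voxels (>= 1).
#' @param stagger_fraction longitudinal offset between adjacent myocyte
#'   columns as a fraction of the longitudinal period, in `[0, 1)`.
#' @param n_gj_end coupled gap-junction voxels per end-to-end junction face.
#' @param n_gj_side coupled voxels per lateral (side-to-side) junction face.
#' @param cleft_period_x spacing of interlaminar cleft planes in meters
#'   (0 = no clefts). Cleft planes are carved along existing x walls.
#' @param cleft_thickness cleft slab thickness in voxels.
#' @param inclusion_fractions named numeric vector with entries `vessel`,
#'   `fibroblast`, `myofibroblast`: target volume fractions (0-1 scale) to be
#'   met within one percentage point by random non-overlapping blocks.
#' @param rotation_deg in-plane (about z) rotation of the myocyte long axis
#'   away from y, degrees.
#' @param seed integer RNG seed; generation is bit-reproducible given the
#'   spec.
#' @return An object of class `brick_tissue_spec`.
#' @export
brick_tissue_spec <- function(grid, myocyte_dims, wall_thickness = 1L,
                              stagger_fraction = 0, n_gj_end = 0L,
                              n_gj_side = 0L, cleft_period_x = 0,
                              cleft_thickness = 1L,
                              inclusion_fractions = c(vessel = 0,
                                                      fibroblast = 0,
                                                      myofibroblast = 0),
                              rotation_deg = 0, seed = 1L) {
  stopifnot(inherits(grid, "grid_spec"))
  vox <- function(len) as.integer(round(len / grid$spacing))
  my <- vox(myocyte_dims[1]); mx <- vox(myocyte_dims[2]); mz <- vox(myocyte_dims[3])
  if (min(mx, my, mz) < 3L)
    stop("myocyte dimensions must each span >= 3 voxels", call. = FALSE)
  wall_thickness <- as.integer(wall_thickness)
  if (wall_thickness < 1L) stop("wall_thickness must be >= 1", call. = FALSE)
  if (stagger_fraction < 0 || stagger_fraction >= 1)
    stop("stagger_fraction must lie in [0, 1)", call. = FALSE)
  if (n_gj_end > mx * mz)
    myoconduct_error("myoconduct_gj_overflow",
                     "n_gj_end exceeds the end-face area in voxels")
  if (n_gj_side > max(my * mz, my * mx))
    myoconduct_error("myoconduct_gj_overflow",
                     "n_gj_side exceeds the lateral face area in voxels")
  inc <- c(vessel = 0, fibroblast = 0, myofibroblast = 0)
  inc[names(inclusion_fractions)] <- inclusion_fractions
  if (any(inc < 0) || sum(inc) > 0.5)
    stop("inclusion fractions must be small non-negative fractions", call. = FALSE)
  structure(list(grid = grid,
                 myocyte_dims = as.numeric(myocyte_dims),
                 myocyte_vox = c(x = mx, y = my, z = mz),
                 wall_thickness = wall_thickness,
                 stagger_fraction = stagger_fraction,
                 n_gj_end = as.integer(n_gj_end),
                 n_gj_side = as.integer(n_gj_side),
                 cleft_period_x = cleft_period_x,
                 cleft_thickness = as.integer(cleft_thickness),
                 inclusion_fractions = inc,
                 rotation_deg = rotation_deg,
                 seed = as.integer(seed)),
            class = "brick_tissue_spec")
}

#' Control and infarct border-zone tissue presets
#'
#' Configuration defaults emulating the two study groups: the infarct (MI)
#' preset has wider walls (lower myocyte volume fraction), gap-junction
#' counts scaled by 0.4 (mirroring the roughly 0.03 vs 0.07% gap-junction
#' volume fractions of the two groups), denser and thicker cleft planes, and
#' added fibroblast/myofibroblast inclusions.
#'
#' @param group `"control"` or `"mi"`.
#' @param grid a [grid_spec()]; defaults to a 63 x 120 x 63 voxel stack at
#'   1 um spacing.
#' @param seed integer RNG seed.
#' @return A [brick_tissue_spec()].
#' @export
brick_preset <- function(group = c("control", "mi"), grid = NULL, seed = 1L) {
  group <- match.arg(group)
  if (is.null(grid)) grid <- grid_spec(c(63L, 120L, 63L), 1e-6)
  if (group == "control") {
    brick_tissue_spec(grid,
                      myocyte_dims = c(80e-6, 18e-6, 18e-6),
                      wall_thickness = max(1L, as.integer(round(3e-6 / grid$spacing))),
                      stagger_fraction = 0.4,
                      n_gj_end = 25L, n_gj_side = 8L,
                      cleft_period_x = 42e-6, cleft_thickness = 2L,
                      inclusion_fractions = c(vessel = 0.05, fibroblast = 0.03,
                                              myofibroblast = 0.001),
                      seed = seed)
  } else {
    brick_tissue_spec(grid,
                      myocyte_dims = c(70e-6, 20e-6, 20e-6),
                      wall_thickness = max(1L, as.integer(round(5e-6 / grid$spacing))),
                      stagger_fraction = 0.4,
                      n_gj_end = 10L, n_gj_side = 3L,
                      cleft_period_x = 25e-6, cleft_thickness = 4L,
                      inclusion_fractions = c(vessel = 0.033, fibroblast = 0.02,
                                              myofibroblast = 0.01),
                      seed = seed)
  }
}

# offset of column (ix, iz) in voxels along y
column_offset <- function(spec, ix, iz) {
  py <- spec$myocyte_vox["y"] + spec$wall_thickness
  frac <- ((ix + iz) * spec$stagger_fraction) %% 1
  as.integer(round(frac * py)) %% py
}

# realized bricks of one column: data.frame(k, y0, y1) (0-based, clipped)
column_bricks <- function(spec, offset) {
  my <- spec$myocyte_vox["y"]; t <- spec$wall_thickness
  py <- my + t
  ny <- spec$grid$shape[2]
  ks <- seq(floor((-offset - my) / py) - 1L, ceiling((ny - offset) / py) + 1L)
  y0 <- offset + ks * py
  y1 <- y0 + my - 1L
  keep <- y1 >= 0L & y0 <= ny - 1L
  data.frame(k = ks[keep], y0 = pmax(y0[keep], 0L), y1 = pmin(y1[keep], ny - 1L),
             y0_full = y0[keep], y1_full = y1[keep])
}

# myocyte span of column ic along a lateral axis of n voxels (0-based, clipped)
column_span <- function(ic, m, t, n) {
  m <- unname(m); t <- unname(t)
  p <- m + t
  c(lo = ic * p, hi = min(ic * p + m - 1L, n - 1L))
}

#' Generate a synthetic brick-myocyte tissue
#'
#' Rasterizes the lattice described by a [brick_tissue_spec()]: staggered
#' brick myocytes with distinct instance IDs (truncated bricks at the stack
#' border keep their IDs), a bright Cx43 intensity patch of exactly
#' `n_gj_end` / `n_gj_side` voxels per realized junction face (positions
#' sampled uniformly without replacement from the face interior), cleft
#' planes carved along selected x walls, and randomly placed non-overlapping
#' inclusion blocks meeting the target volume fractions within one
#' percentage point. The returned `truth` record carries the spec and the
#' exact per-pair coupled-voxel counts realized in the Cx43 channel.
#'
#' @param spec a [brick_tissue_spec()].
#' @return An object of class `synthetic_tissue`: list with `segments`
#'   ([segment_volume()]), `labels` ([tissue_labels()]), `cx43`
#'   ([intensity_volume()]), and `truth`.
#' @export
generate_brick_tissue <- function(spec) {
  grid <- spec$grid
  nx <- grid$shape[1]; ny <- grid$shape[2]; nz <- grid$shape[3]
  mx <- spec$myocyte_vox["x"]; my <- spec$myocyte_vox["y"]; mz <- spec$myocyte_vox["z"]
  t <- spec$wall_thickness
  px <- mx + t; pz <- mz + t
  if (nx < mx || ny < my || nz < mz)
    stop("grid too small for a single myocyte", call. = FALSE)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  ids <- array(0L, c(nx, ny, nz))
  cx <- array(0, c(nx, ny, nz))
  pair_of_voxel <- array(0L, c(nx, ny, nz))
  cleft <- array(FALSE, c(nx, ny, nz))

  ncol_x <- length(seq(0L, nx - 1L, by = px))
  ncol_z <- length(seq(0L, nz - 1L, by = pz))

  # --- bricks ---------------------------------------------------------------
  brick_id <- new.env(parent = emptyenv())  # key "ix,iz,k" -> id
  next_id <- 0L
  columns <- expand.grid(ix = seq_len(ncol_x) - 1L, iz = seq_len(ncol_z) - 1L)
  col_info <- vector("list", nrow(columns))
  for (ci in seq_len(nrow(columns))) {
    ix <- columns$ix[ci]; iz <- columns$iz[ci]
    xs <- column_span(ix, mx, t, nx); zs <- column_span(iz, mz, t, nz)
    off <- column_offset(spec, ix, iz)
    br <- column_bricks(spec, off)
    br$id <- NA_integer_
    for (bi in seq_len(nrow(br))) {
      next_id <- next_id + 1L
      br$id[bi] <- next_id
      assign(sprintf("%d,%d,%d", ix, iz, br$k[bi]), next_id, envir = brick_id)
      ids[(xs["lo"]:xs["hi"]) + 1L, (br$y0[bi]:br$y1[bi]) + 1L,
          (zs["lo"]:zs["hi"]) + 1L] <- next_id
    }
    col_info[[ci]] <- list(ix = ix, iz = iz, xs = xs, zs = zs, off = off,
                           bricks = br)
  }

  # --- cleft planes along selected x walls ----------------------------------
  cleft_walls <- integer(0)
  if (spec$cleft_period_x > 0 && ncol_x > 1L) {
    period_vox <- round(spec$cleft_period_x / grid$spacing)
    every <- max(1L, as.integer(round(period_vox / px)))
    cleft_walls <- if (every - 1L <= ncol_x - 2L)
      seq(every - 1L, ncol_x - 2L, by = every) else integer(0)
    for (ix in cleft_walls) {
      x0 <- ix * px + mx
      x1 <- min(x0 + max(spec$cleft_thickness, t) - 1L, nx - 1L)
      if (x0 > nx - 1L) next
      ids[(x0:x1) + 1L, , ] <- 0L
      cleft[(x0:x1) + 1L, , ] <- TRUE
    }
  }

  # --- gap junctions --------------------------------------------------------
  pairs <- list()
  place_patch <- function(face_x, face_y, face_z, n_target, ida, idb, type) {
    # face_* are 0-based coordinate vectors of the full wall patch (the wall
    # axis has length 1). Face-interior positions are sampled first so that
    # neighbouring patches stay separated; edge positions are only used when
    # the requested count exceeds the interior (e.g. full-face junctions).
    if (n_target < 1L) return(invisible(NULL))
    shrink <- function(r) if (length(r) >= 3L) r[-c(1L, length(r))] else r
    pos_all <- expand.grid(x = face_x, y = face_y, z = face_z)
    pos_int <- expand.grid(x = shrink(face_x), y = shrink(face_y),
                           z = shrink(face_z))
    if (nrow(pos_all) == 0L) return(invisible(NULL))
    pick <- function(pos, n) {
      if (n >= nrow(pos)) seq_len(nrow(pos)) else sample.int(nrow(pos), n)
    }
    sel <- pos_int[pick(pos_int, min(n_target, nrow(pos_int))), , drop = FALSE]
    if (n_target > nrow(pos_int)) {
      key_all <- paste(pos_all$x, pos_all$y, pos_all$z)
      key_int <- paste(pos_int$x, pos_int$y, pos_int$z)
      edge <- pos_all[!(key_all %in% key_int), , drop = FALSE]
      extra <- min(n_target - nrow(pos_int), nrow(edge))
      if (extra > 0L) sel <- rbind(sel, edge[pick(edge, extra), , drop = FALSE])
    }
    a <- min(ida, idb); b <- max(ida, idb)
    key <- length(pairs) + 1L
    for (j in seq_len(nrow(sel))) {
      xi <- sel$x[j] + 1L; yi <- sel$y[j] + 1L; zi <- sel$z[j] + 1L
      if (cleft[xi, yi, zi] || ids[xi, yi, zi] != 0L) next
      cx[xi, yi, zi] <<- 1000
      pair_of_voxel[xi, yi, zi] <<- key
    }
    cnt <- sum(pair_of_voxel == key)
    if (cnt > 0L)
      pairs[[key]] <<- data.frame(id_a = a, id_b = b, count = cnt, type = type)
    invisible(NULL)
  }
  rng <- function(lo, hi) unname(lo):unname(hi)

  for (ci in seq_along(col_info)) {
    info <- col_info[[ci]]
    br <- info$bricks
    # end-to-end junctions within the column
    if (nrow(br) >= 2L) {
      for (bi in seq_len(nrow(br) - 1L)) {
        wall_y <- br$y1_full[bi] + 1L + (t - 1L) %/% 2L
        if (wall_y < 0L || wall_y > ny - 1L) next
        place_patch(rng(info$xs["lo"], info$xs["hi"]), wall_y,
                    rng(info$zs["lo"], info$zs["hi"]),
                    spec$n_gj_end, br$id[bi], br$id[bi + 1L], "end")
      }
    }
    # lateral junctions to the +x and +z neighbour columns
    for (lateral in c("x", "z")) {
      if (lateral == "x") {
        if (info$ix >= ncol_x - 1L || info$ix %in% cleft_walls) next
        wall_c <- info$ix * px + mx + (t - 1L) %/% 2L
        if (wall_c > nx - 1L) next
        nb <- Filter(function(o) o$ix == info$ix + 1L && o$iz == info$iz, col_info)
      } else {
        if (info$iz >= ncol_z - 1L) next
        wall_c <- info$iz * pz + mz + (t - 1L) %/% 2L
        if (wall_c > nz - 1L) next
        nb <- Filter(function(o) o$ix == info$ix && o$iz == info$iz + 1L, col_info)
      }
      if (length(nb) == 0L) next
      nb <- nb[[1L]]
      for (bi in seq_len(nrow(br))) {
        for (bj in seq_len(nrow(nb$bricks))) {
          ylo <- max(br$y0[bi], nb$bricks$y0[bj])
          yhi <- min(br$y1[bi], nb$bricks$y1[bj])
          if (yhi - ylo < 2L) next  # need an interior for the patch
          if (lateral == "x") {
            place_patch(wall_c, rng(ylo, yhi),
                        rng(info$zs["lo"], info$zs["hi"]),
                        spec$n_gj_side, br$id[bi], nb$bricks$id[bj], "side")
          } else {
            place_patch(rng(info$xs["lo"], info$xs["hi"]),
                        rng(ylo, yhi), wall_c,
                        spec$n_gj_side, br$id[bi], nb$bricks$id[bj], "side")
          }
        }
      }
    }
  }

  # --- inclusions -----------------------------------------------------------
  vessel <- array(FALSE, c(nx, ny, nz))
  fibro <- array(FALSE, c(nx, ny, nz))
  myofibro <- array(FALSE, c(nx, ny, nz))
  blocked <- cx > 0
  total <- nx * ny * nz
  bdim <- list(
    vessel = pmax(1L, as.integer(round(c(2e-6, 10e-6, 2e-6) / grid$spacing))),
    fibroblast = pmax(1L, as.integer(round(c(3e-6, 3e-6, 3e-6) / grid$spacing))),
    myofibroblast = pmax(1L, as.integer(round(c(3e-6, 3e-6, 3e-6) / grid$spacing))))
  for (cls in names(spec$inclusion_fractions)) {
    f <- spec$inclusion_fractions[[cls]]
    if (f <= 0) next
    d <- bdim[[cls]]
    mask <- array(FALSE, c(nx, ny, nz))
    placed <- 0L
    attempts <- 0L
    while (placed / total < f) {
      if ((placed + prod(d)) / total > f + 0.01) break
      attempts <- attempts + 1L
      if (attempts > 20000L)
        myoconduct_error("myoconduct_inclusion_unsatisfiable",
                         sprintf("could not reach the %s volume fraction", cls))
      x0 <- sample.int(nx - d[1] + 1L, 1L)
      y0 <- sample.int(ny - d[2] + 1L, 1L)
      z0 <- sample.int(nz - d[3] + 1L, 1L)
      xs <- x0:(x0 + d[1] - 1L); ys <- y0:(y0 + d[2] - 1L); zs <- z0:(z0 + d[3] - 1L)
      if (any(vessel[xs, ys, zs] | fibro[xs, ys, zs] | myofibro[xs, ys, zs] |
              cleft[xs, ys, zs])) next
      # keep a clear margin around Cx43 voxels so truth counts stay realized
      xe <- max(1L, x0 - 1L):min(nx, x0 + d[1]); ye <- max(1L, y0 - 1L):min(ny, y0 + d[2])
      ze <- max(1L, z0 - 1L):min(nz, z0 + d[3])
      if (any(blocked[xe, ye, ze])) next
      mask[xs, ys, zs] <- TRUE
      ids[xs, ys, zs] <- 0L
      placed <- placed + prod(d)
    }
    if (abs(placed / total - f) > 0.01)
      myoconduct_error("myoconduct_inclusion_unsatisfiable",
                       sprintf("could not reach the %s volume fraction", cls))
    if (cls == "vessel") vessel <- mask
    else if (cls == "fibroblast") fibro <- mask
    else myofibro <- mask
  }

  # --- optional in-plane rotation -------------------------------------------
  if (spec$rotation_deg != 0) {
    rot <- function(a, theta, background) {
      d <- dim(a)
      cxy <- (d[1:2] + 1) / 2
      xo <- rep(seq_len(d[1]), times = d[2]) - cxy[1]
      yo <- rep(seq_len(d[2]), each = d[1]) - cxy[2]
      ct <- cos(-theta); st <- sin(-theta)
      xs <- round(ct * xo - st * yo + cxy[1])
      ys <- round(st * xo + ct * yo + cxy[2])
      ok <- xs >= 1 & xs <= d[1] & ys >= 1 & ys <= d[2]
      out <- array(background, d)
      src <- cbind(xs[ok], ys[ok])
      dst_idx <- which(ok)
      for (k in seq_len(d[3])) {
        slice <- a[, , k]
        new <- matrix(background, d[1], d[2])
        new[dst_idx] <- slice[src]
        out[, , k] <- new
      }
      out
    }
    th <- spec$rotation_deg * pi / 180
    ids <- rot(ids, th, 0L)
    cx <- rot(cx, th, 0)
    pair_of_voxel <- rot(pair_of_voxel, th, 0L)
    cleft <- rot(cleft, th, FALSE)
    vessel <- rot(vessel, th, FALSE)
    fibro <- rot(fibro, th, FALSE)
    myofibro <- rot(myofibro, th, FALSE)
    # recount realized pair counts after resampling
    for (key in seq_along(pairs)) {
      if (!is.null(pairs[[key]])) pairs[[key]]$count <- sum(pair_of_voxel == key)
    }
  }

  pair_df <- if (length(pairs)) do.call(rbind, pairs[!vapply(pairs, is.null, TRUE)])
  else data.frame(id_a = integer(0), id_b = integer(0), count = integer(0),
                  type = character(0))
  pair_df <- pair_df[pair_df$count > 0L, , drop = FALSE]
  rownames(pair_df) <- NULL

  segments <- segment_volume(grid, ids)
  labels <- tissue_labels(grid, vessel = vessel, fibroblast = fibro,
                          myofibroblast = myofibro, cleft = cleft)
  structure(list(segments = segments, labels = labels,
                 cx43 = intensity_volume(grid, cx),
                 truth = list(spec = spec, pairs = pair_df,
                              n_myocytes = next_id)),
            class = "synthetic_tissue")
}

#' @export
print.synthetic_tissue <- function(x, ...) {
  cat(sprintf("<synthetic_tissue> %d myocytes, %d coupled pairs, %d gj voxels\n",
              x$truth$n_myocytes, nrow(x$truth$pairs), sum(x$truth$pairs$count)))
  print(x$segments$grid)
  invisible(x)
}

#' Closed-form directional conductivity of an untruncated brick lattice
#'
#' Series/parallel resistor reduction of the periodic brick-myocyte lattice
#' under the same discretization geometry as the numerical solver (one-voxel
#' junction layers, harmonic series composition, ghost-face electrodes).
#' Along the chosen direction one period is the myocyte span at `sigma_cyto`
#' in series with one junction layer whose conducting area is the
#' gap-junction voxel count at `sigma_gj` (smeared over the face), the whole
#' scaled by the conducting cross-sectional area fraction. The reduction is
#' exact — and agrees with the finite-volume solution to solver precision —
#' when junction patches cover the full shared face; for partial coverage it
#' neglects constriction (current-spreading) resistance and is an upper
#' bound on the numerical value. Returns 0 when the direction has no
#' junctions, when walls thicker than one voxel block it, or when a cleft
#' plane fully interrupts it.
#'
#' @param spec a [brick_tissue_spec()] describing an untruncated periodic
#'   lattice: `stagger_fraction = 0`, no inclusions, no rotation, and grid
#'   dimensions that start and end with a full myocyte along each axis.
#' @param direction `"normal"` (x), `"longitudinal"` (y) or `"transverse"`
#'   (z).
#' @param sigma_cyto cytoplasmic conductivity, S/m.
#' @param sigma_gj gap-junction voxel conductivity, S/m (`Inf` treats the
#'   junction layer as lossless).
#' @return Effective conductivity in S/m.
#' @export
analytic_conductivity <- function(spec, direction = c("normal", "longitudinal",
                                                      "transverse"),
                                  sigma_cyto = 0.86, sigma_gj) {
  direction <- match.arg(direction)
  if (spec$stagger_fraction != 0 || spec$rotation_deg != 0 ||
      any(spec$inclusion_fractions > 0))
    myoconduct_error("myoconduct_analytic_domain",
                     "closed form requires stagger 0, no inclusions, no rotation")
  n <- spec$grid$shape
  m <- c(spec$myocyte_vox["x"], spec$myocyte_vox["y"], spec$myocyte_vox["z"])
  t <- spec$wall_thickness
  p <- m + t
  ax <- match(direction, c("normal", "longitudinal", "transverse"))
  for (a in 1:3) {
    if ((n[a] + t) %% p[a] != 0L)
      myoconduct_error("myoconduct_analytic_domain",
                       "grid must start and end with a full myocyte on every axis")
  }
  nb <- (n + t) %/% p            # bricks per axis
  njunc <- nb[ax] - 1L           # junction layers along the direction
  n_gj <- if (ax == 2L) spec$n_gj_end else spec$n_gj_side
  face <- prod(m[-ax])
  # conducting cross-section: myocyte footprint columns, less cleft slabs
  cols_perp <- prod(m[-ax] * nb[-ax])
  area_perp <- prod(n[-ax])
  if (spec$cleft_period_x > 0 && ax != 1L) {
    # cleft slabs remove x layers (walls widened into the +x myocyte)
    period_vox <- round(spec$cleft_period_x / spec$grid$spacing)
    every <- max(1L, as.integer(round(period_vox / p[1])))
    walls <- if (every - 1L <= nb[1] - 2L)
      seq(every - 1L, nb[1] - 2L, by = every) else integer(0)
    eaten <- max(spec$cleft_thickness - t, 0L)  # myocyte layers consumed
    mx_lost <- length(walls) * eaten
    cols_perp <- cols_perp - mx_lost * (if (ax == 2L) m[3] * nb[3] else m[2] * nb[2])
  }
  if (njunc > 0L) {
    if (n_gj == 0L || t > 1L) return(0)
    if (ax == 1L && spec$cleft_period_x > 0) return(0)
  }
  if (ax == 1L && spec$cleft_period_x > 0 && nb[1] > 1L) return(0)
  sigma_layer <- if (is.infinite(sigma_gj)) Inf else sigma_gj * n_gj / face
  n_myo_vox <- n[ax] - njunc * t
  series <- n_myo_vox / sigma_cyto +
    if (njunc > 0L && is.finite(sigma_layer)) njunc / sigma_layer else 0
  unname((cols_perp / area_perp) * n[ax] / series)
}
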