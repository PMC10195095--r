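grid9 <- function(shape = c(9, 9, 9), spacing = 200e-9) grid_spec(shape, spacing)

test_that("threshold is mode + k_sd standard deviations", {
  g <- grid9(c(10, 10, 10), 1e-6)
  # engineered integer image: mode 10, values 19 and 20 straddle the cut
  v <- array(10, c(10, 10, 10))
  v[1:200] <- rep(c(8, 12), 100)       # symmetric spread, mode stays 10
  v[c(501, 502)] <- c(19, 20)
  iv <- intensity_volume(g, v)
  s <- sd(v)
  k <- (20 - 10) / s - 0.01            # threshold just below 20
  m <- threshold_cx43(iv, k_sd = k)
  expect_true(m[arrayInd(502, dim(v))])
  k2 <- (19 - 10) / s + 0.01           # threshold just above 19
  m2 <- threshold_cx43(iv, k_sd = k2)
  expect_false(m2[arrayInd(501, dim(v))])
  expect_true(m2[arrayInd(502, dim(v))])
})

test_that("constant image yields an empty mask with a warning", {
  iv <- intensity_volume(grid9(), array(7, c(9, 9, 9)))
  expect_warning(m <- threshold_cx43(iv), "constant")
  expect_false(any(m))
})

test_that("thresholding matches a brute-force histogram oracle", {
  g <- grid9(c(12, 12, 12), 1e-6)
  set.seed(42)
  v <- array(sample(0:5, 12^3, replace = TRUE), c(12, 12, 12))
  bright <- sample(12^3, 50)
  v[bright] <- 1000
  iv <- intensity_volume(g, v)
  # brute-force: scan all observed integer values for the most frequent
  vals <- sort(unique(as.vector(v)))
  counts <- vapply(vals, function(u) sum(v == u), integer(1))
  mode_bf <- vals[which.max(counts)]
  sd_bf <- sqrt(sum((v - mean(v))^2) / (length(v) - 1))
  m <- threshold_cx43(iv, 4.5)
  expect_identical(which(m), sort(bright))
  expect_identical(m, array(v > mode_bf + 4.5 * sd_bf, dim(v)))
})

test_that("dilation closes gaps and isolation leaves one separating layer", {
  # two bricks separated by a 3-voxel gap along y
  g <- grid9(c(5, 13, 5), 1e-6)
  ids <- array(0L, g$shape)
  ids[, 1:5, ] <- 1L
  ids[, 9:13, ] <- 2L
  bb <- build_boundary(segment_volume(g, ids))
  iso <- bb$isolated_segments$ids
  profile <- iso[3, , 3]
  # 1D profile oracle: dilation meets in the middle; exactly one zero layer
  expect_identical(profile, c(rep(1L, 6), 0L, rep(2L, 6)))
  expect_true(all(bb$boundary[, 7, ]))
  # bricks already touching face-to-face: a one-voxel gap is carved
  ids2 <- array(0L, g$shape)
  ids2[, 1:6, ] <- 1L
  ids2[, 7:13, ] <- 2L
  bb2 <- build_boundary(segment_volume(g, ids2))
  prof2 <- bb2$isolated_segments$ids[3, , 3]
  expect_identical(sum(prof2 == 0L), 1L)
  gap <- which(prof2 == 0L)
  expect_setequal(unique(prof2[-gap]), c(1L, 2L))
  # voxel-by-voxel: the carved layer is the smaller-ID side of the contact
  expect_identical(gap, 7L)
  # single myocyte: nothing is carved; it grows by the three dilation steps
  # (clipped at the grid) and the boundary is the dilated brick's outer shell
  ids3 <- array(0L, g$shape)
  ids3[2:4, 2:6, 2:4] <- 1L
  bb3 <- build_boundary(segment_volume(g, ids3))
  dilated <- array(0L, g$shape)
  dilated[, 1:9, ] <- 1L               # Chebyshev-3 ball, clipped
  expect_identical(bb3$isolated_segments$ids, dilated)
  shell <- bb3$boundary
  expected_shell <- array(FALSE, g$shape)
  expected_shell[, 10, ] <- TRUE
  expect_identical(shell, expected_shell)
  expect_false(any(shell & dilated > 0L))
})

test_that("projection assigns Cx43 to nearest shared-membrane voxels", {
  g <- grid9(c(5, 11, 5), 1e-6)
  ids <- array(0L, g$shape)
  ids[, 1:5, ] <- 1L
  ids[, 7:11, ] <- 2L
  bb <- build_boundary(segment_volume(g, ids))
  # zero-distance: a Cx43 voxel on a shared boundary voxel becomes a gj voxel
  m <- array(FALSE, g$shape); m[3, 6, 3] <- TRUE
  gj <- project_cx43(m, bb$boundary, bb$isolated_segments)
  expect_true(gj$gj_mask[3, 6, 3])
  expect_identical(gj$pair_counts$count, 1L)
  expect_equal(gj$v_gj, 100 / prod(g$shape))
  # beyond max_dist: dropped (1.2 um away with a 1 um cutoff)
  # use a far Cx43 voxel: distance from (3,1,3) to wall y=6 is 5 um
  m2 <- array(FALSE, g$shape); m2[3, 1, 3] <- TRUE
  ids_gap <- ids; ids_gap[, 1:2, ] <- 0L   # strip myocyte under the voxel
  bbg <- build_boundary(segment_volume(g, ids_gap))
  gj2 <- project_cx43(m2, bbg$boundary, bbg$isolated_segments, max_dist = 1e-6)
  expect_false(any(gj2$gj_mask))
  # a colinear cluster collapsing onto one shared voxel counts once, and
  # voxels nearest to a single-myocyte boundary voxel are not gap junctions
  g13 <- grid9(c(5, 13, 5), 1e-6)
  ids13 <- array(0L, g13$shape)
  ids13[, 1:5, ] <- 1L
  ids13[, 7:11, ] <- 2L                    # y = 12:13 left as background
  iso13 <- segment_volume(g13, ids13)
  bnd13 <- array(FALSE, g13$shape)
  bnd13[, 6, ] <- TRUE                     # shared wall
  bnd13[, 12, ] <- TRUE                    # outer shell of myocyte 2 only
  m3 <- array(FALSE, g13$shape)
  m3[3, 4:6, 3] <- TRUE                    # all nearest to (3, 6, 3)
  m3[3, 13, 3] <- TRUE                     # nearest to non-shared (3, 12, 3)
  gj3 <- project_cx43(m3, bnd13, iso13, max_dist = 3e-6)
  expect_true(gj3$gj_mask[3, 6, 3])
  expect_identical(sum(gj3$gj_mask), 1L)
  expect_identical(gj3$pair_counts,
                   data.frame(id_a = 1L, id_b = 2L, count = 1L))
  # max_dist = 0 keeps only Cx43 voxels lying exactly on boundary voxels
  gj0 <- project_cx43(m3, bnd13, iso13, max_dist = 0)
  expect_identical(which(gj0$gj_mask), which(m3 & bnd13))
})

test_that("gj maps are equivariant under myocyte ID relabeling", {
  spec <- brick_tissue_spec(grid_spec(c(9, 23, 9), 200e-9),
                            myocyte_dims = c(7, 4, 4) * 200e-9,
                            n_gj_end = 6L, n_gj_side = 3L, seed = 9L)
  tis <- generate_brick_tissue(spec)
  bb <- build_boundary(tis$segments)
  m <- tis$cx43$values > 0
  gj <- project_cx43(m, bb$boundary, bb$isolated_segments)
  # apply a random permutation to the IDs
  ids <- tis$segments$ids
  n <- max(ids)
  set.seed(1)
  perm <- sample(n)
  ids2 <- array(0L, dim(ids))
  ids2[ids > 0L] <- perm[ids[ids > 0L]]
  bb2 <- build_boundary(segment_volume(tis$segments$grid, ids2))
  gj2 <- project_cx43(m, bb2$boundary, bb2$isolated_segments)
  expect_identical(gj$gj_mask, gj2$gj_mask)
  expect_equal(gj$v_gj, gj2$v_gj)
  expect_equal(sum(gj$pair_counts$count), sum(gj2$pair_counts$count))
})

test_that("pipeline recovers the generator's pair counts exactly", {
  spec <- brick_tissue_spec(grid_spec(c(9, 23, 9), 200e-9),
                            myocyte_dims = c(7, 4, 4) * 200e-9,
                            n_gj_end = 4L, n_gj_side = 2L, seed = 21L)
  tis <- generate_brick_tissue(spec)
  bb <- build_boundary(tis$segments)
  gj <- project_cx43(tis$cx43$values > 0, bb$boundary, bb$isolated_segments)
  truth <- tis$truth$pairs[order(tis$truth$pairs$id_a, tis$truth$pairs$id_b), ]
  got <- gj$pair_counts
  expect_identical(got$id_a, truth$id_a)
  expect_identical(got$id_b, truth$id_b)
  expect_identical(got$count, as.integer(truth$count))
  # v_gj scales linearly with the number of placed junction voxels
  spec2 <- brick_tissue_spec(grid_spec(c(9, 23, 9), 200e-9),
                             myocyte_dims = c(7, 4, 4) * 200e-9,
                             n_gj_end = 8L, n_gj_side = 4L, seed = 21L)
  tis2 <- generate_brick_tissue(spec2)
  bb2 <- build_boundary(tis2$segments)
  gj2 <- project_cx43(tis2$cx43$values > 0, bb2$boundary, bb2$isolated_segments)
  expect_equal(gj2$v_gj / gj$v_gj,
               sum(tis2$truth$pairs$count) / sum(tis$truth$pairs$count))
})

test_that("sigma_gj calibration follows the pair-conductance relation", {
  g <- grid_spec(c(4, 4, 4), 200e-9)
  p1 <- data.frame(id_a = 1L, id_b = 2L, count = 1L)
  cal <- calibrate_sigma_gj(p1, grid = g)
  # 1.24 uS / 1 * l / A with l = 200 nm: 1.24e-6 * 5e6 = 6.2 S/m
  expect_equal(cal$sigma_gj, 6.2)
  p62 <- data.frame(id_a = 1:2, id_b = 3:4, count = c(62L, 62L))
  expect_equal(calibrate_sigma_gj(p62, grid = g)$sigma_gj, 0.1)
  # doubling every count halves sigma_gj
  p2 <- data.frame(id_a = 1:3, id_b = 4:6, count = c(2L, 6L, 10L))
  pd <- transform(p2, count = count * 2L)
  expect_equal(calibrate_sigma_gj(p2, grid = g)$sigma_gj /
                 calibrate_sigma_gj(pd, grid = g)$sigma_gj, 2)
  # pooling across stacks and the all-pairs alternative
  pooled <- calibrate_sigma_gj(list(p1, p62), grid = g)
  expect_equal(pooled$n_gj_control, mean(c(1, 62, 62)))
  allp <- calibrate_sigma_gj(p1, grid = g, n_pairs = 4L)
  expect_equal(allp$n_gj_control, 0.25)
  empty <- data.frame(id_a = integer(0), id_b = integer(0), count = integer(0))
  expect_error(calibrate_sigma_gj(empty, grid = g),
               class = "myoconduct_no_coupled_pairs")
})

test_that("coupled-neighbour counts follow the junction wiring", {
  g <- grid_spec(c(4, 4, 4), 200e-9)
  chain <- data.frame(id_a = c(1L, 2L), id_b = c(2L, 3L), count = c(3L, 5L))
  gj <- structure(list(grid = g, gj_mask = array(FALSE, g$shape),
                       pair_counts = chain, v_gj = 0),
                  class = "gap_junction_map")
  cn <- coupled_neighbor_count(gj)
  expect_identical(unname(cn$per_myocyte), c(1L, 2L, 1L))
  expect_equal(cn$mean, 4 / 3)
  # empty map: all counts zero given the ID universe
  gj0 <- structure(list(grid = g, gj_mask = array(FALSE, g$shape),
                        pair_counts = chain[0, ], v_gj = 0),
                   class = "gap_junction_map")
  cn0 <- coupled_neighbor_count(gj0, ids = 1:5)
  expect_identical(unname(cn0$per_myocyte), rep(0L, 5))
  # synthetic lattice wiring equals the generator truth
  spec <- brick_tissue_spec(grid_spec(c(9, 23, 9), 200e-9),
                            myocyte_dims = c(7, 4, 4) * 200e-9,
                            n_gj_end = 4L, n_gj_side = 2L, seed = 2L)
  tis <- generate_brick_tissue(spec)
  bb <- build_boundary(tis$segments)
  gjs <- project_cx43(tis$cx43$values > 0, bb$boundary, bb$isolated_segments)
  cns <- coupled_neighbor_count(gjs, ids = seq_len(tis$truth$n_myocytes))
  truth_partners <- vapply(seq_len(tis$truth$n_myocytes), function(i)
    length(unique(c(tis$truth$pairs$id_b[tis$truth$pairs$id_a == i],
                    tis$truth$pairs$id_a[tis$truth$pairs$id_b == i]))),
    integer(1))
  expect_identical(unname(cns$per_myocyte), truth_partners)
})
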