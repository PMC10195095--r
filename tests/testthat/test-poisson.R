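test_that("conductivity models map tissue classes to conductivities", {
  g <- grid_spec(c(6, 8, 6), 1e-6)
  ids <- array(0L, g$shape); ids[, 1:3, ] <- 1L; ids[, 5:8, ] <- 2L
  seg <- segment_volume(g, ids)
  gj_mask <- array(FALSE, g$shape); gj_mask[2:3, 4, 2:3] <- TRUE
  gj <- structure(list(grid = g, gj_mask = gj_mask,
                       pair_counts = data.frame(id_a = 1L, id_b = 2L,
                                                count = 4L),
                       v_gj = 100 * 4 / prod(g$shape)),
                  class = "gap_junction_map")
  mod <- build_model(seg, gj, sigma_cyto = 0.86, sigma_gj = 0.1)
  expect_equal(sum(mod$sigma == 0.86), sum(ids > 0L))
  expect_equal(sum(mod$sigma == 0.1), 4L)
  expect_equal(sum(mod$sigma == 0),
               prod(g$shape) - sum(ids > 0L) - 4L)
  # gap-junction voxels on myocyte voxels are a contract violation
  bad <- gj; bad$gj_mask[1, 1, 1] <- TRUE
  expect_error(build_model(seg, bad, 0.86, 0.1),
               class = "myoconduct_gj_overlap")
  # empty gj map: isolated conducting islands only
  mod0 <- build_model(seg, NULL, 0.86)
  expect_identical(sort(unique(as.vector(mod0$sigma))), c(0, 0.86))
  # generator truth predicts the sigma histogram
  spec <- brick_tissue_spec(grid_spec(c(9, 23, 9), 200e-9),
                            myocyte_dims = c(7, 4, 4) * 200e-9,
                            n_gj_end = 4L, n_gj_side = 2L, seed = 3L)
  tis <- generate_brick_tissue(spec)
  bb <- build_boundary(tis$segments)
  gjt <- project_cx43(tis$cx43$values > 0, bb$boundary, bb$isolated_segments)
  modt <- build_model(bb$isolated_segments, gjt, 0.86, 0.1)
  expect_equal(sum(modt$sigma == 0.1), sum(tis$truth$pairs$count))
  expect_equal(sum(modt$sigma == 0.86), sum(tis$segments$ids > 0L))
})

test_that("region growing removes only electrode-unreachable voxels", {
  g <- grid_spec(c(10, 5, 5), 1e-6)
  sig <- array(0, g$shape)
  sig[1:3, , ] <- 0.5                 # slab touching the + electrode (x = 1)
  sig[6:7, 2:3, 2:3] <- 0.5           # floating cube
  mod <- make_model(sig)
  out <- exclude_isolated(mod, "normal")
  expect_equal(attr(out, "excluded_voxels"), 8L)
  expect_true(all(out$sigma[6:7, 2:3, 2:3] == 0))
  expect_true(all(out$sigma[1:3, , ] == 0.5))
  # fully connected domain: nothing removed
  full <- make_model(array(0.5, g$shape))
  expect_equal(attr(exclude_isolated(full, "normal"), "excluded_voxels"), 0L)
  # one component per electrode: both kept (flood-fill oracle agreement)
  two <- array(0, g$shape)
  two[1:2, , ] <- 0.5                 # touches + electrode only
  two[1:10, 5, 5] <- 0.7              # spans both electrodes
  mod2 <- make_model(two)
  out2 <- exclude_isolated(mod2, "normal")
  expect_equal(attr(out2, "excluded_voxels"), 0L)
  # all-unreachable: everything excluded, with a warning
  mid <- array(0, g$shape); mid[4:6, 2:3, 2:3] <- 0.5
  expect_warning(out3 <- exclude_isolated(make_model(mid), "normal"),
                 "electrode")
  expect_true(all(out3$sigma == 0))
})

test_that("uniform bars give linear potentials and exact conductivity", {
  g <- grid_spec(c(6, 12, 5), 1e-6)
  mod <- make_model(array(0.86, g$shape))
  for (m in c("direct", "cg")) {
    ps <- solve_potential(mod, "longitudinal", tol = 1e-12, method = m)
    phi <- ps$phi
    n <- 12
    expected <- 1 - 2 * (seq_len(n) - 0.5) / n
    for (k in seq_len(n))
      expect_equal(unname(phi[3, k, 2]), expected[k], tolerance = 1e-10)
    expect_lt(max(abs(sweep(phi, 2, phi[1, , 1]))), 1e-10)  # flat cross-section
    sol <- current_and_conductivity(mod, phi, "longitudinal")
    expect_equal(sol$sigma_dir, 0.86, tolerance = 1e-12)
  }
})

test_that("two-slab series model reproduces the resistor-divider potential", {
  g <- grid_spec(c(3, 10, 3), 1e-6)
  sigma <- array(0, g$shape)
  sigma[, 1:5, ] <- 2; sigma[, 6:10, ] <- 1
  mod <- make_model(sigma)
  ps <- solve_potential(mod, "longitudinal", tol = 1e-13)
  phi <- unname(ps$phi[2, , 2])
  # exact discrete solution from the 1D resistor chain (scaled units):
  # ghost half-faces at the electrodes, harmonic-mean interior faces
  r_face <- c(0.5 / 2, rep(1 / 2, 4), 1 / (2 * 2 * 1 / (2 + 1)), rep(1, 4),
              0.5 / 1)
  I <- 2 / sum(r_face)
  phi_expected <- 1 - I * cumsum(r_face)[1:10]
  expect_equal(phi, phi_expected, tolerance = 1e-12)
  # interface potential (half a cell past cell 5): (s1 - s2) / (s1 + s2)
  iface <- phi[5] - I * 0.5 / 2
  expect_equal(iface, (2 - 1) / (2 + 1), tolerance = 1e-12)
})

test_that("zero-conductivity planes disconnect the domain", {
  g <- grid_spec(c(3, 9, 3), 1e-6)
  sigma <- array(0.5, g$shape)
  sigma[, 5, ] <- 0
  mod <- exclude_isolated(make_model(sigma), "longitudinal")
  ps <- solve_potential(mod, "longitudinal", tol = 1e-12)
  expect_true(all(abs(ps$phi[, 1:4, ] - 1) < 1e-12))
  expect_true(all(abs(ps$phi[, 6:9, ] + 1) < 1e-12))
  expect_true(all(is.na(ps$phi[, 5, ])))
  sol <- current_and_conductivity(mod, ps$phi, "longitudinal")
  expect_equal(sol$sigma_dir, 0, tolerance = 1e-14)
})

test_that("solver agrees with the dense Kirchhoff oracle on random media", {
  set.seed(11)
  for (rep in 1:3) {
    sigma <- array(stats::runif(6 * 7 * 5, 0.05, 1), c(6, 7, 5))
    sigma[sample(210, 40)] <- 0
    mod <- exclude_isolated(make_model(sigma), "longitudinal")
    ps <- solve_potential(mod, "longitudinal", tol = 1e-12)
    sol <- current_and_conductivity(mod, ps$phi, "longitudinal")
    orc <- oracle_sigma_dir(mod$sigma, 2)
    expect_equal(sol$sigma_dir, orc$sigma_dir, tolerance = 1e-9)
    # discrete maximum principle
    expect_true(all(ps$phi >= -1 - 1e-12, na.rm = TRUE))
    expect_true(all(ps$phi <= 1 + 1e-12, na.rm = TRUE))
  }
})

test_that("conjugate-gradient and direct paths agree", {
  spec <- brick_tissue_spec(grid_spec(c(9, 23, 9), 200e-9),
                            myocyte_dims = c(7, 4, 4) * 200e-9,
                            n_gj_end = 8L, n_gj_side = 4L, seed = 5L)
  tis <- generate_brick_tissue(spec)
  bb <- build_boundary(tis$segments)
  gj <- project_cx43(tis$cx43$values > 0, bb$boundary, bb$isolated_segments)
  mod <- build_model(bb$isolated_segments, gj, 0.86, 0.1)
  teD <- estimate_tensor(mod, tol = 1e-12, method = "direct")
  teC <- estimate_tensor(mod, tol = 1e-12, method = "cg")
  expect_equal(coef(teC), coef(teD), tolerance = 1e-10)
})

test_that("total axial current is conserved plane by plane", {
  spec <- brick_tissue_spec(grid_spec(c(9, 23, 9), 200e-9),
                            myocyte_dims = c(7, 4, 4) * 200e-9,
                            n_gj_end = 8L, n_gj_side = 4L, seed = 6L)
  tis <- generate_brick_tissue(spec)
  bb <- build_boundary(tis$segments)
  gj <- project_cx43(tis$cx43$values > 0, bb$boundary, bb$isolated_segments)
  mod <- build_model(bb$isolated_segments, gj, 0.86, 0.1)
  for (d in c("normal", "longitudinal", "transverse")) {
    md <- exclude_isolated(mod, d)
    ps <- solve_potential(md, d, tol = 1e-12)
    sol <- current_and_conductivity(md, ps$phi, d, ps$residual)
    I <- sol$plane_mean_J
    expect_lt(max(abs(I - mean(I))), 1e-8 * max(1, abs(mean(I))))
  }
})

test_that("sigma_dir is monotone in any voxel's conductivity", {
  set.seed(23)
  sigma <- array(stats::runif(5 * 6 * 5, 0.1, 1), c(5, 6, 5))
  sigma[sample(150, 20)] <- 0
  base_mod <- exclude_isolated(make_model(sigma), "longitudinal")
  base <- oracle_sigma_dir(base_mod$sigma, 2)$sigma_dir
  ps <- solve_potential(base_mod, "longitudinal", tol = 1e-12)
  base_pkg <- current_and_conductivity(base_mod, ps$phi, "longitudinal")$sigma_dir
  expect_equal(base_pkg, base, tolerance = 1e-9)
  for (v in sample(which(sigma > 0), 4)) {
    s2 <- sigma
    s2[v] <- s2[v] * 2
    m2 <- exclude_isolated(make_model(s2), "longitudinal")
    up_orc <- oracle_sigma_dir(m2$sigma, 2)$sigma_dir
    ps2 <- solve_potential(m2, "longitudinal", tol = 1e-12)
    up_pkg <- current_and_conductivity(m2, ps2$phi, "longitudinal")$sigma_dir
    expect_gte(up_pkg + 1e-12, base_pkg)
    expect_equal(up_pkg, up_orc, tolerance = 1e-9)
  }
})

test_that("sigma_dir scales linearly with a global conductivity factor", {
  set.seed(31)
  sigma <- array(stats::runif(5 * 5 * 5, 0.1, 1), c(5, 5, 5))
  mod <- exclude_isolated(make_model(sigma), "transverse")
  ps <- solve_potential(mod, "transverse", tol = 1e-13)
  s1 <- current_and_conductivity(mod, ps$phi, "transverse")$sigma_dir
  mod3 <- exclude_isolated(make_model(3 * sigma), "transverse")
  ps3 <- solve_potential(mod3, "transverse", tol = 1e-13)
  s3 <- current_and_conductivity(mod3, ps3$phi, "transverse")$sigma_dir
  expect_equal(s3, 3 * s1, tolerance = 1e-10)
})

test_that("tensor estimation handles isotropy and open circuits", {
  g <- grid_spec(c(8, 8, 8), 1e-6)
  te <- estimate_tensor(make_model(array(0.86, g$shape)))
  expect_equal(unname(coef(te)), rep(0.86, 3), tolerance = 1e-12)
  # end junctions only: transverse and normal circuits are open
  spec <- brick_tissue_spec(grid_spec(c(9, 23, 9), 200e-9),
                            myocyte_dims = c(7, 4, 4) * 200e-9,
                            n_gj_end = 16L, n_gj_side = 0L, seed = 7L)
  tis <- generate_brick_tissue(spec)
  bb <- build_boundary(tis$segments)
  gj <- project_cx43(tis$cx43$values > 0, bb$boundary, bb$isolated_segments)
  mod <- build_model(bb$isolated_segments, gj, 0.86, 0.3)
  te2 <- estimate_tensor(mod, tol = 1e-12)
  expect_equal(te2$sigma_myo_n, 0, tolerance = 1e-12)
  expect_equal(te2$sigma_myo_t, 0, tolerance = 1e-12)
  expect_gt(te2$sigma_myo_l, 0.1)
  # full-face junctions: all three estimates match the closed form
  an <- analytic_conductivity(spec, "longitudinal", 0.86, 0.3)
  expect_equal(te2$sigma_myo_l, an, tolerance = 1e-11)
})
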