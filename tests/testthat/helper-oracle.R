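# Independent dense Kirchhoff oracle for the 7-point conductance network.
# Deliberately written as a plain dense-matrix solve over all conducting
# voxels, sharing no code with the package solver: harmonic-mean face
# conductances, ghost-face Dirichlet electrodes (+1 / -1 V), zero-flux
# elsewhere. Only for fixtures of up to ~10^3 voxels.
oracle_sigma_dir <- function(sigma, axis) {
  d <- dim(sigma)
  act <- which(sigma > 0)
  if (length(act) == 0) return(list(sigma_dir = 0, phi = array(NA_real_, d)))
  idx <- array(seq_len(prod(d)), d)
  row_of <- integer(prod(d))
  row_of[act] <- seq_along(act)
  n <- length(act)
  A <- matrix(0, n, n)
  b <- numeric(n)
  hm <- function(a, s) if (a > 0 && s > 0) 2 * a * s / (a + s) else 0
  coords <- arrayInd(act, d)
  for (q in seq_len(n)) {
    v <- act[q]
    xyz <- coords[q, ]
    for (ax in 1:3) {
      for (dir in c(-1L, 1L)) {
        nb <- xyz
        nb[ax] <- nb[ax] + dir
        if (nb[ax] < 1L || nb[ax] > d[ax]) next
        w <- idx[nb[1], nb[2], nb[3]]
        g <- hm(sigma[v], sigma[w])
        if (g == 0) next
        A[q, q] <- A[q, q] + g
        A[q, row_of[w]] <- A[q, row_of[w]] - g
      }
    }
    if (xyz[axis] == 1L) {
      A[q, q] <- A[q, q] + 2 * sigma[v]
      b[q] <- b[q] + 2 * sigma[v]
    }
    if (xyz[axis] == d[axis]) {
      A[q, q] <- A[q, q] + 2 * sigma[v]
      b[q] <- b[q] - 2 * sigma[v]
    }
  }
  x <- solve(A, b)
  phi <- array(NA_real_, d)
  phi[act] <- x
  # plane currents including electrode ghost planes
  m <- d[axis]
  perp <- prod(d[-axis])
  p0 <- phi
  p0[is.na(p0)] <- 0
  take <- function(a, k) {
    if (axis == 1) a[k, , ] else if (axis == 2) a[, k, ] else a[, , k]
  }
  plane_I <- numeric(m + 1)
  plane_I[1] <- sum(2 * take(sigma, 1) * (1 - take(p0, 1)))
  plane_I[m + 1] <- sum(2 * take(sigma, m) * (take(p0, m) + 1))
  if (m > 1) {
    for (k in 1:(m - 1)) {
      s1 <- take(sigma, k)
      s2 <- take(sigma, k + 1)
      g <- ifelse(s1 > 0 & s2 > 0, 2 * s1 * s2 / (s1 + s2), 0)
      plane_I[k + 1] <- sum(g * (take(p0, k) - take(p0, k + 1)))
    }
  }
  list(sigma_dir = mean(plane_I) * m / (2 * perp), phi = phi,
       plane_I = plane_I)
}

# small two-brick column fixture: bricks of (mx x my x mz) voxels separated
# by a one-voxel wall along y, with a gap-junction patch of n_gj voxels
two_brick_model <- function(mx = 4, my = 4, mz = 4, n_gj = 4,
                            sigma_cyto = 0.86, sigma_gj = 0.1) {
  d <- c(mx, 2 * my + 1, mz)
  sigma <- array(0, d)
  sigma[, 1:my, ] <- sigma_cyto
  sigma[, (my + 2):(2 * my + 1), ] <- sigma_cyto
  pos <- expand.grid(x = seq_len(mx), z = seq_len(mz))
  take <- pos[seq_len(n_gj), , drop = FALSE]
  for (j in seq_len(nrow(take))) sigma[take$x[j], my + 1, take$z[j]] <- sigma_gj
  g <- grid_spec(d, 1e-6)
  structure(list(grid = g, sigma = sigma,
                 provenance = list(sigma_cyto = sigma_cyto,
                                   sigma_gj = sigma_gj)),
            class = "conductivity_model")
}

make_model <- function(sigma, spacing = 1e-6) {
  structure(list(grid = grid_spec(dim(sigma), spacing), sigma = sigma,
                 provenance = list(sigma_cyto = NA, sigma_gj = NA)),
            class = "conductivity_model")
}

# closed-form OLS on a tiny table, written independently of lm()
ols_closed_form <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - sum(res^2) / sst
  fstat <- (sst - sum(res^2)) / (sum(res^2) / (n - 2))
  p <- stats::pf(fstat, 1, n - 2, lower.tail = FALSE)
  list(slope = slope, intercept = intercept, r_squared = r2, p_value = p)
}

# closed-form pooled-variance two-sample t-test
ttest_closed_form <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  p <- 2 * stats::pt(-abs(tstat), na + nb - 2)
  list(t = tstat, p = p)
}
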