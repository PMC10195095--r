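#' Build the intracellular conductivity model
#'
#' Assigns the cytoplasmic conductivity to (isolated) myocyte voxels and the
#' calibrated gap-junction conductivity to gap-junction voxels; everything
#' else — extracellular space, vessels, fibroblasts, myofibroblasts, clefts,
#' and uncoupled boundary voxels — is non-conducting (0 S/m).
#'
#' @param segments the isolated [segment_volume()] (one-voxel separation,
#'   see [build_boundary()]).
#' @param gj a `gap_junction_map` whose mask lies in the separating
#'   boundary layer.
#' @param sigma_cyto cytoplasmic conductivity, S/m (default 0.86).
#' @param sigma_gj gap-junction voxel conductivity, S/m (see
#'   [calibrate_sigma_gj()]); a `gj_conductivity` object is also accepted.
#' @return An object of class `conductivity_model` with fields `grid`,
#'   `sigma` (3D array, S/m) and `provenance`.
#' @export
build_model <- function(segments, gj = NULL, sigma_cyto = 0.86, sigma_gj = 0) {
  if (inherits(sigma_gj, "gj_conductivity")) sigma_gj <- sigma_gj$sigma_gj
  sigma <- array(0, segments$grid$shape)
  sigma[segments$ids > 0L] <- sigma_cyto
  if (!is.null(gj) && any(gj$gj_mask)) {
    if (any(gj$gj_mask & segments$ids > 0L))
      myoconduct_error("myoconduct_gj_overlap",
                       "gap-junction voxels overlap myocyte voxels")
    sigma[gj$gj_mask] <- sigma_gj
  }
  structure(list(grid = segments$grid, sigma = sigma,
                 provenance = list(sigma_cyto = sigma_cyto,
                                   sigma_gj = sigma_gj)),
            class = "conductivity_model")
}

#' @export
print.conductivity_model <- function(x, ...) {
  n <- prod(x$grid$shape)
  cat(sprintf("<conductivity_model> %.1f%% conducting (sigma_cyto %g, sigma_gj %g S/m)\n",
              100 * sum(x$sigma > 0) / n, x$provenance$sigma_cyto,
              x$provenance$sigma_gj))
  invisible(x)
}

direction_axis <- function(direction) {
  match(match.arg(direction, c("normal", "longitudinal", "transverse")),
        c("normal", "longitudinal", "transverse"))
}

#' Remove conducting voxels unreachable from the electrodes
#'
#' Region growing over face-connected (6-neighbourhood) conducting voxels,
#' seeded at all conducting voxels touching either electrode plane of the
#' chosen direction. Voxels in no reached component are set to 0 S/m so the
#' linear system stays non-singular; face connectivity matches the 7-point
#' stencil, through which all current flows.
#'
#' @param model a `conductivity_model`.
#' @param direction `"normal"`, `"longitudinal"` or `"transverse"`.
#' @return The model with unreachable voxels zeroed; the number of removed
#'   voxels is in `attr(, "excluded_voxels")`.
#' @export
exclude_isolated <- function(model, direction) {
  ax <- direction_axis(direction)
  active <- model$sigma > 0
  if (!any(active)) {
    attr(model, "excluded_voxels") <- 0L
    return(model)
  }
  comp <- array(cpp_label_components(as.vector(active), model$grid$shape, 6L),
                dim(active))
  first <- slice_index(model$grid$shape, ax, 1L)
  last <- slice_index(model$grid$shape, ax, model$grid$shape[ax])
  keep <- setdiff(unique(c(comp[first], comp[last])), 0L)
  if (length(keep) == 0L)
    warning("no conducting voxel touches either electrode; all excluded",
            call. = FALSE)
  drop <- active & !(comp %in% keep)
  model$sigma[drop] <- 0
  attr(model, "excluded_voxels") <- sum(drop)
  model
}

# linear indices of one slice perpendicular to axis `ax`
slice_index <- function(shape, ax, pos) {
  idx <- array(seq_len(prod(shape)), shape)
  as.vector(if (ax == 1L) idx[pos, , ]
            else if (ax == 2L) idx[, pos, ]
            else idx[, , pos])
}

harm_mean <- function(a, b) ifelse(a > 0 & b > 0, 2 * a * b / (a + b), 0)

# sparse assembly of the 7-point system over active voxels (direct path)
assemble_system <- function(sigma, ax) {
  shape <- dim(sigma)
  n <- prod(shape)
  act <- sigma > 0
  map <- integer(n)
  map[act] <- seq_len(sum(act))
  na <- sum(act)
  ii <- list(); jj <- list(); xx <- list()
  dia <- numeric(na)
  b <- numeric(na)
  idx <- array(seq_len(n), shape)
  for (a in 1:3) {
    m <- shape[a]
    if (m < 2L) next
    take <- function(arr, r) {
      if (a == 1L) arr[r, , , drop = FALSE]
      else if (a == 2L) arr[, r, , drop = FALSE]
      else arr[, , r, drop = FALSE]
    }
    i1 <- as.vector(take(idx, 1:(m - 1)))
    i2 <- as.vector(take(idx, 2:m))
    g <- harm_mean(sigma[i1], sigma[i2])
    keep <- g > 0
    i1 <- i1[keep]; i2 <- i2[keep]; g <- g[keep]
    r1 <- map[i1]; r2 <- map[i2]
    ii[[length(ii) + 1L]] <- c(r1, r2)
    jj[[length(jj) + 1L]] <- c(r2, r1)
    xx[[length(xx) + 1L]] <- c(-g, -g)
    dia <- dia + rowsum_vec(g, r1, na) + rowsum_vec(g, r2, na)
  }
  # electrode ghost faces along the field axis
  for (side in c(1L, 2L)) {
    pos <- if (side == 1L) 1L else shape[ax]
    sl <- slice_index(shape, ax, pos)
    sl <- sl[act[sl]]
    ge <- 2 * sigma[sl]
    rows <- map[sl]
    dia <- dia + rowsum_vec(ge, rows, na)
    b <- b + rowsum_vec(ge * (if (side == 1L) 1 else -1), rows, na)
  }
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(na, na), repr = "C") +
    Matrix::Diagonal(na, dia)
  list(A = Matrix::forceSymmetric(A), b = b, map = map, act = act)
}

rowsum_vec <- function(val, idx, n) {
  out <- numeric(n)
  if (length(idx)) {
    s <- rowsum(val, idx)
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}

#' Solve Poisson's equation for the stationary potential
#'
#' Solves `div(sigma grad phi) = 0` with Dirichlet electrodes of +1 V on the
#' low-index face and -1 V on the high-index face of the chosen axis and
#' zero-flux conditions on all other boundary faces, using a
#' flux-conservative 7-point finite-volume discretization with
#' harmonic-mean face conductances (electrode values act on ghost faces at
#' half-cell distance). Small systems are solved by sparse Cholesky
#' factorization, large ones by conjugate gradients with a symmetric
#' Gauss-Seidel preconditioner; in both cases the reported residual norm is
#' computed against the identical stencil (conductances scaled by the
#' common factor A/l).
#'
#' @param model a `conductivity_model` that has passed [exclude_isolated()]
#'   for this direction.
#' @param direction `"normal"`, `"longitudinal"` or `"transverse"`.
#' @param tol residual-norm convergence criterion (default 1e-10).
#' @param method `"auto"`, `"direct"` or `"cg"`.
#' @param maxit iteration cap for the conjugate-gradient path.
#' @param direct_limit largest active-voxel count for the direct path under
#'   `method = "auto"`.
#' @return List with `phi` (3D array, volts; `NA` on non-conducting
#'   voxels), `residual`, `iterations`, and `method`.
#' @export
solve_potential <- function(model, direction, tol = 1e-10,
                            method = c("auto", "direct", "cg"),
                            maxit = 30000L, direct_limit = 150000L) {
  method <- match.arg(method)
  ax <- direction_axis(direction)
  shape <- model$grid$shape
  na <- sum(model$sigma > 0)
  if (na == 0L) {
    return(list(phi = array(NA_real_, shape), residual = 0,
                iterations = 0L, method = "none"))
  }
  if (method == "auto") method <- if (na <= direct_limit) "direct" else "cg"
  if (method == "direct") {
    sys <- assemble_system(model$sigma, ax)
    x <- as.vector(Matrix::solve(sys$A, sys$b))
    phi <- array(NA_real_, shape)
    phi[sys$act] <- x
    res <- cpp_residual_norm(as.vector(model$sigma), shape, ax - 1L,
                             as.vector(phi))
    if (res >= tol) {  # one step of iterative refinement
      r <- sys$b - as.vector(sys$A %*% x)
      x <- x + as.vector(Matrix::solve(sys$A, r))
      phi[sys$act] <- x
      res <- cpp_residual_norm(as.vector(model$sigma), shape, ax - 1L,
                               as.vector(phi))
    }
    if (res >= tol)
      myoconduct_error("myoconduct_solver",
                       sprintf("direct solve residual %.3g above tolerance %.3g",
                               res, tol))
    list(phi = phi, residual = res, iterations = 1L, method = "direct")
  } else {
    out <- cpp_pcg_solve(as.vector(model$sigma), shape, ax - 1L, tol,
                         as.integer(maxit))
    if (!out$converged)
      myoconduct_error("myoconduct_solver",
                       sprintf(paste0("conjugate gradients did not reach ",
                                      "residual %.3g (reached %.3g after %d ",
                                      "iterations)"),
                               tol, out$residual, out$iterations))
    list(phi = array(out$phi, shape), residual = out$residual,
         iterations = out$iterations, method = "cg")
  }
}

# permute so the field axis comes first
axis_first <- function(a, ax) {
  perm <- switch(ax, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  aperm(a, perm)
}

#' Current density and directional conductivity
#'
#' Evaluates the axial current density on voxel faces perpendicular to the
#' field axis (`J = sigma_face * dphi / l`, harmonic-mean face
#' conductivities, electrode ghost faces included), averages it over each
#' full face plane (non-conducting area contributes zero current), and
#' divides the across-plane mean by the applied field
#' `E = 2 V / (n_axis * spacing)`.
#'
#' @param model a `conductivity_model`.
#' @param phi converged potential array from [solve_potential()].
#' @param direction `"normal"`, `"longitudinal"` or `"transverse"`.
#' @param residual_norm,excluded_voxels,iterations optional solver
#'   diagnostics carried into the result.
#' @return An object of class `field_solution`: `direction`, `phi`,
#'   `plane_mean_J` (A/m^2 per face plane), `E` (V/m), `sigma_dir` (S/m),
#'   `residual_norm`, `excluded_voxels`, `iterations`.
#' @export
current_and_conductivity <- function(model, phi, direction,
                                     residual_norm = NA_real_,
                                     excluded_voxels = NA_integer_,
                                     iterations = NA_integer_) {
  ax <- direction_axis(direction)
  l <- model$grid$spacing
  s <- axis_first(model$sigma, ax)
  p <- axis_first(phi, ax)
  p[is.na(p)] <- 0
  p[s <= 0] <- 0
  m <- dim(s)[1]
  area_vox <- dim(s)[2] * dim(s)[3]
  # scaled plane currents: I_p = sum over faces of g * dphi (units sigma * V)
  plane_I <- numeric(m + 1L)
  plane_I[1] <- sum(2 * s[1, , ] * (1 - p[1, , ]))
  plane_I[m + 1L] <- sum(2 * s[m, , ] * (p[m, , ] - (-1)))
  if (m > 1L) {
    for (k in 1:(m - 1L)) {
      g <- harm_mean(s[k, , ], s[k + 1L, , ])
      plane_I[k + 1L] <- sum(g * (p[k, , ] - p[k + 1L, , ]))
    }
  }
  E <- 2 / (m * l)                       # V/m
  plane_mean_J <- plane_I / (area_vox * l)  # A/m^2 (factor A/l * 1/(A_tot))
  sigma_dir <- mean(plane_mean_J) / E
  structure(list(direction = direction, phi = phi,
                 plane_mean_J = plane_mean_J, E = E, sigma_dir = sigma_dir,
                 residual_norm = residual_norm,
                 excluded_voxels = excluded_voxels, iterations = iterations),
            class = "field_solution")
}

#' @export
print.field_solution <- function(x, ...) {
  cat(sprintf("<field_solution> %s: sigma_dir %.6g S/m (residual %.2g, %s excluded)\n",
              x$direction, x$sigma_dir, x$residual_norm,
              format(x$excluded_voxels)))
  invisible(x)
}

#' Estimate the intracellular conductivity tensor
#'
#' Runs the exclusion of unreachable voxels, the Poisson solve, and the
#' current-density reduction for electrode pairs along all three axes
#' (normal = x, longitudinal = y, transverse = z) and collects the
#' directional conductivities.
#'
#' @param model a `conductivity_model`.
#' @inheritParams solve_potential
#' @param keep_fields keep the per-direction potential arrays in the result
#'   (memory-heavy for large stacks; default `FALSE` stores diagnostics
#'   only).
#' @return An object of class `tensor_estimate` with fields `sigma_myo_n`,
#'   `sigma_myo_l`, `sigma_myo_t` (S/m) and per-direction `solutions`.
#' @export
estimate_tensor <- function(model, tol = 1e-10, method = "auto",
                            maxit = 30000L, direct_limit = 150000L,
                            keep_fields = FALSE) {
  dirs <- c("normal", "longitudinal", "transverse")
  sols <- list()
  sig <- c(normal = 0, longitudinal = 0, transverse = 0)
  for (d in dirs) {
    md <- exclude_isolated(model, d)
    excl <- attr(md, "excluded_voxels")
    if (sum(md$sigma > 0) == 0L) {
      sol <- structure(list(direction = d, phi = NULL,
                            plane_mean_J = NULL, E = 2 / (model$grid$shape[direction_axis(d)] * model$grid$spacing),
                            sigma_dir = 0, residual_norm = 0,
                            excluded_voxels = excl, iterations = 0L),
                       class = "field_solution")
    } else {
      ps <- solve_potential(md, d, tol = tol, method = method, maxit = maxit,
                            direct_limit = direct_limit)
      sol <- current_and_conductivity(md, ps$phi, d,
                                      residual_norm = ps$residual,
                                      excluded_voxels = excl,
                                      iterations = ps$iterations)
      if (!keep_fields) sol$phi <- NULL
    }
    sols[[d]] <- sol
    sig[d] <- sol$sigma_dir
  }
  structure(list(sigma_myo_n = sig[["normal"]],
                 sigma_myo_l = sig[["longitudinal"]],
                 sigma_myo_t = sig[["transverse"]],
                 solutions = sols),
            class = "tensor_estimate")
}

#' @export
print.tensor_estimate <- function(x, ...) {
  cat("Intracellular conductivity tensor estimate (S/m)\n")
  cat(sprintf("  longitudinal (y): %.6g\n", x$sigma_myo_l))
  cat(sprintf("  transverse   (z): %.6g\n", x$sigma_myo_t))
  cat(sprintf("  normal       (x): %.6g\n", x$sigma_myo_n))
  invisible(x)
}

#' @export
coef.tensor_estimate <- function(object, ...) {
  c(sigma_myo_n = object$sigma_myo_n, sigma_myo_l = object$sigma_myo_l,
    sigma_myo_t = object$sigma_myo_t)
}

#' @export
summary.tensor_estimate <- function(object, ...) {
  out <- data.frame(
    direction = c("normal", "longitudinal", "transverse"),
    axis = c("x", "y", "z"),
    sigma = c(object$sigma_myo_n, object$sigma_myo_l, object$sigma_myo_t),
    residual = vapply(object$solutions, function(s) s$residual_norm, 0),
    excluded = vapply(object$solutions, function(s) as.numeric(s$excluded_voxels), 0),
    iterations = vapply(object$solutions, function(s) as.numeric(s$iterations), 0))
  rownames(out) <- NULL
  structure(list(table = out), class = "summary.tensor_estimate")
}

#' @export
print.summary.tensor_estimate <- function(x, ...) {
  cat("Directional intracellular conductivities:\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
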