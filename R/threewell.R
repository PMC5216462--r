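#' Three-well diffusion parameters
#'
#' Defines a 2-D potential with (up to) three metastable wells along a
#' reaction coordinate — two deep end basins (ion bound / ion released)
#' separated by a shallower intermediate basin — the continuous analogue of
#' the free-energy landscape the Markov model discretizes. The potential is
#' a sum of inverted Gaussian wells, Gaussian barrier ridges across the
#' channel at the midpoints between adjacent wells (ridges depend on the
#' release coordinate x only, so they cannot be bypassed laterally), and a
#' soft harmonic wall confining the particle to the region of the wells:
#' \deqn{U(r) = -\sum_i d_i e^{-|r-c_i|^2 / 2w^2}
#'            + \sum_j b_j e^{-(x-m_j)^2 / 2w_b^2}
#'            + \frac{\kappa}{2}\max(0, |r-\bar c| - R_0)^2}
#' Wells are laid out in order along the first coordinate (the release
#' coordinate).
#'
#' @param well_centers Numeric matrix with one 2-D point per row (1 or 3
#'   rows), ordered along the release coordinate.
#' @param well_depths Depth of each well in kT (positive).
#' @param barrier_heights Barrier bump heights in kT between adjacent wells
#'   (length `nrow(well_centers) - 1`); must be > 0 when wells > 1.
#' @param well_width,barrier_width Gaussian widths (length units).
#' @param diffusion_coeff Diffusion coefficient, length^2 / time.
#' @param timestep Integration time step.
#' @param temperature_factor kT scale (dimensionless; energies are in kT).
#' @param labels State tag per well; defaults to
#'   `c("bound", "intermediate", "released")` for three wells.
#' @return An object of class `three_well_params`.
#' @examples
#' p <- three_well_params()
#' three_well_potential(p, cbind(0, 0)) # intermediate well bottom
#' @export
three_well_params <- function(well_centers = rbind(c(-1.5, 0), c(0, 0), c(1.5, 0)),
                              well_depths = c(3, 1.5, 3),
                              barrier_heights = c(2.5, 2.5),
                              well_width = 0.35,
                              barrier_width = 0.3,
                              diffusion_coeff = 1,
                              timestep = 0.002,
                              temperature_factor = 1,
                              labels = NULL) {
  well_centers <- as.matrix(well_centers)
  if (ncol(well_centers) != 2) abort("`well_centers` must have 2 columns.")
  nw <- nrow(well_centers)
  if (!nw %in% c(1L, 3L)) abort("Provide 1 (test limit) or 3 well centers.")
  if (length(well_depths) != nw) abort("`well_depths` length must match wells.")
  if (any(well_depths <= 0)) abort("`well_depths` must be positive (kT).")
  if (nw > 1) {
    if (length(barrier_heights) != nw - 1) {
      abort("`barrier_heights` must have one entry per adjacent well pair.")
    }
    if (any(barrier_heights <= 0)) abort("`barrier_heights` must be > 0.")
    mid <- which(seq_len(nw) %in% 2L)
    if (well_depths[2] >= min(well_depths[c(1, nw)])) {
      abort("The intermediate well must be shallower than both end wells.")
    }
  } else {
    barrier_heights <- numeric(0)
  }
  assert_scalar_number(well_width, "well_width", lower = 1e-9)
  assert_scalar_number(barrier_width, "barrier_width", lower = 1e-9)
  assert_scalar_number(diffusion_coeff, "diffusion_coeff", lower = 0)
  assert_scalar_number(timestep, "timestep", lower = 1e-15)
  assert_scalar_number(temperature_factor, "temperature_factor", lower = 1e-9)
  if (is.null(labels)) {
    labels <- if (nw == 3) c("bound", "intermediate", "released") else "bound"
  }
  labels <- rep_len(labels, nw)
  centroid <- colMeans(well_centers)
  r0 <- if (nw > 1) {
    max(row_norms(sweep(well_centers, 2, centroid))) + 2 * well_width
  } else {
    4 * well_width
  }
  structure(
    list(
      well_centers = well_centers, well_depths = well_depths,
      barrier_heights = barrier_heights, well_width = well_width,
      barrier_width = barrier_width, diffusion_coeff = diffusion_coeff,
      timestep = timestep, temperature_factor = temperature_factor,
      labels = labels, confine_center = centroid, confine_radius = r0,
      confine_k = 25
    ),
    class = "three_well_params"
  )
}

barrier_midpoints <- function(params) {
  nw <- nrow(params$well_centers)
  if (nw < 2) return(matrix(numeric(0), 0, 2))
  (params$well_centers[-nw, , drop = FALSE] +
     params$well_centers[-1, , drop = FALSE]) / 2
}

#' Evaluate the three-well potential
#'
#' @param params A [three_well_params()].
#' @param xy Numeric matrix of positions (n x 2).
#' @return Numeric vector of energies in kT.
#' @export
three_well_potential <- function(params, xy) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  u <- numeric(nrow(xy))
  w2 <- 2 * params$well_width^2
  for (i in seq_len(nrow(params$well_centers))) {
    d2 <- (xy[, 1] - params$well_centers[i, 1])^2 +
      (xy[, 2] - params$well_centers[i, 2])^2
    u <- u - params$well_depths[i] * exp(-d2 / w2)
  }
  mids <- barrier_midpoints(params)
  wb2 <- 2 * params$barrier_width^2
  for (j in seq_len(nrow(mids))) {
    u <- u + params$barrier_heights[j] * exp(-(xy[, 1] - mids[j, 1])^2 / wb2)
  }
  r <- sqrt((xy[, 1] - params$confine_center[1])^2 +
              (xy[, 2] - params$confine_center[2])^2)
  excess <- pmax(0, r - params$confine_radius)
  u + 0.5 * params$confine_k * excess^2
}

# Analytic gradient of the potential, vectorized over rows of xy.
three_well_gradient <- function(params, xy) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  g <- matrix(0, nrow(xy), 2)
  w2 <- 2 * params$well_width^2
  for (i in seq_len(nrow(params$well_centers))) {
    dx <- xy[, 1] - params$well_centers[i, 1]
    dy <- xy[, 2] - params$well_centers[i, 2]
    e <- exp(-(dx * dx + dy * dy) / w2)
    s <- params$well_depths[i] * e * (2 / w2)
    g[, 1] <- g[, 1] + s * dx
    g[, 2] <- g[, 2] + s * dy
  }
  mids <- barrier_midpoints(params)
  wb2 <- 2 * params$barrier_width^2
  for (j in seq_len(nrow(mids))) {
    dx <- xy[, 1] - mids[j, 1]
    e <- exp(-dx * dx / wb2)
    g[, 1] <- g[, 1] - params$barrier_heights[j] * e * (2 / wb2) * dx
  }
  dx <- xy[, 1] - params$confine_center[1]
  dy <- xy[, 2] - params$confine_center[2]
  r <- sqrt(dx * dx + dy * dy)
  excess <- pmax(0, r - params$confine_radius)
  nz <- r > 0
  s <- ifelse(nz, params$confine_k * excess / pmax(r, 1e-300), 0)
  g[, 1] <- g[, 1] + s * dx
  g[, 2] <- g[, 2] + s * dy
  g
}

min_well_separation <- function(params) {
  nc <- nrow(params$well_centers)
  if (nc < 2) return(Inf)
  d <- as.matrix(stats::dist(params$well_centers))
  min(d[upper.tri(d)])
}

#' Simulate overdamped Langevin diffusion on the three-well potential
#'
#' Euler–Maruyama integration of
#' \eqn{dr = -(D/kT)\,\nabla U\,dt + \sqrt{2D\,dt}\,\xi}.
#' The step size is validated so the per-step RMS displacement stays well
#' below the well separation; an unstable step raises an error with a
#' suggested bound.
#'
#' @param params A [three_well_params()].
#' @param n_steps Number of recorded steps per trajectory.
#' @param seed Integer seed or `NULL`.
#' @param n_traj Number of independent trajectories (integrated jointly,
#'   vectorized).
#' @param start Starting point(s): a 2-vector recycled to all trajectories,
#'   an `n_traj x 2` matrix, or `"wells"` to cycle trajectories through the
#'   well centers (reduces initialization bias in ensemble runs).
#'   Default: the first well center.
#' @param thin Record every `thin`-th integrator step (default 1).
#' @param burn_in Integrator steps discarded before recording (default 0).
#' @return A tibble with columns `trajectory`, `frame`, `x`, `y`; the
#'   frame stride in time units is `timestep * thin` (stored in attribute
#'   `"stride"`).
#' @export
simulate_three_well <- function(params, n_steps, seed = NULL, n_traj = 1,
                                start = NULL, thin = 1, burn_in = 0) {
  if (!inherits(params, "three_well_params")) {
    abort("`params` must be a `three_well_params`.")
  }
  n_steps <- assert_count(n_steps, "n_steps")
  n_traj <- assert_count(n_traj, "n_traj")
  thin <- assert_count(thin, "thin")
  D <- params$diffusion_coeff
  dt <- params$timestep
  kT <- params$temperature_factor
  sep <- min_well_separation(params)
  noise_sd <- sqrt(2 * D * dt)
  if (is.finite(sep) && noise_sd > sep / 8) {
    abort(sprintf(
      "Timestep too large: per-step noise %.3g exceeds %.3g (well separation / 8). Use timestep < %.3g.",
      noise_sd, sep / 8, (sep / 8)^2 / (2 * D)
    ))
  }
  if (is.null(start)) start <- params$well_centers[1, ]
  pos <- if (is.character(start) && identical(start, "wells")) {
    nw <- nrow(params$well_centers)
    params$well_centers[((seq_len(n_traj) - 1L) %% nw) + 1L, , drop = FALSE]
  } else if (is.matrix(start)) {
    if (nrow(start) != n_traj) abort("`start` matrix must have n_traj rows.")
    start
  } else {
    matrix(rep(as.numeric(start), each = n_traj), n_traj, 2)
  }
  burn_in <- if (burn_in > 0) assert_count(burn_in, "burn_in") else 0L
  total <- n_steps * thin + burn_in
  out <- array(NA_real_, dim = c(n_steps, n_traj, 2))
  with_seed(seed, {
    for (t in seq_len(total)) {
      if (D > 0) {
        grad <- three_well_gradient(params, pos)
        pos <- pos - (D / kT) * grad * dt +
          noise_sd * matrix(rnorm(2 * n_traj), n_traj, 2)
      }
      rec <- t - burn_in
      if (rec > 0 && rec %% thin == 0) out[rec %/% thin, , ] <- pos
    }
  })
  res <- tibble(
    trajectory = rep(seq_len(n_traj), each = n_steps),
    frame = rep(seq_len(n_steps), times = n_traj),
    x = as.vector(out[, , 1]),
    y = as.vector(out[, , 2])
  )
  attr(res, "stride") <- dt * thin
  res
}

#' Basin assignment by nearest well center
#'
#' Ground-truth labeling used to validate clustering and lumping stages:
#' each point is assigned to the nearest well center.
#'
#' @param params A [three_well_params()].
#' @param xy Positions (n x 2 matrix or a tibble with `x`, `y`).
#' @return Integer vector of well indices (1-based, in the order of
#'   `params$well_centers`).
#' @export
assign_basin <- function(params, xy) {
  if (is.data.frame(xy)) xy <- cbind(xy$x, xy$y)
  xy <- matrix(as.numeric(xy), ncol = 2)
  d2 <- sapply(seq_len(nrow(params$well_centers)), function(i) {
    (xy[, 1] - params$well_centers[i, 1])^2 +
      (xy[, 2] - params$well_centers[i, 2])^2
  })
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1)
  max.col(-d2, ties.method = "first")
}

#' Boltzmann weights of the basins by numerical quadrature
#'
#' Integrates \eqn{e^{-U/kT}} over the partition of the plane induced by
#' nearest-well-center assignment, on a regular grid covering the confined
#' region. This is the generator-side ground truth against which sampled
#' basin occupancies and free-energy differences are compared.
#'
#' @param params A [three_well_params()].
#' @param n_grid Grid points per axis.
#' @return A tibble with `basin`, `label`, `weight` (normalized to 1) and
#'   `free_energy` (kT, min-shifted).
#' @export
boltzmann_basin_weights <- function(params, n_grid = 400) {
  r0 <- params$confine_radius + 1.5
  cx <- params$confine_center[1]
  cy <- params$confine_center[2]
  gx <- seq(cx - r0, cx + r0, length.out = n_grid)
  gy <- seq(cy - r0, cy + r0, length.out = n_grid)
  grid <- cbind(rep(gx, times = n_grid), rep(gy, each = n_grid))
  w <- exp(-three_well_potential(params, grid) / params$temperature_factor)
  basin <- assign_basin(params, grid)
  tot <- tapply(w, basin, sum)
  weight <- as.numeric(tot / sum(tot))
  fe <- -log(weight)
  tibble(
    basin = as.integer(names(tot)),
    label = params$labels[as.integer(names(tot))],
    weight = weight,
    free_energy = fe - min(fe)
  )
}
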