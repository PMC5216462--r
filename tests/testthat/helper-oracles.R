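# Independent brute-force oracles. These deliberately re-derive every
# quantity with plain loops and no shared code with the implementation.

brute_dist <- function(p, q) sqrt(sum((p - q)^2))

frame_pos <- function(frame, label) {
  r <- frame[frame$label == label, ][1, ]
  c(r$x, r$y, r$z)
}

# per-frame pair distance by explicit double loop over frames
brute_pair_distances <- function(frames, a, b) {
  df <- as.data.frame(frames)
  keys <- unique(df[c("trajectory", "frame")])
  out <- numeric(nrow(keys))
  for (i in seq_len(nrow(keys))) {
    fr <- df[df$trajectory == keys$trajectory[i] & df$frame == keys$frame[i], ]
    out[i] <- brute_dist(frame_pos(fr, a), frame_pos(fr, b))
  }
  cbind(keys, dist = out)
}

brute_coordination <- function(frame, ion_label, cutoff) {
  ion <- frame_pos(frame, ion_label)
  wat <- frame[frame$role == "water", ]
  n <- 0L
  for (i in seq_len(nrow(wat))) {
    if (brute_dist(c(wat$x[i], wat$y[i], wat$z[i]), ion) <= cutoff) n <- n + 1L
  }
  n
}

brute_ec_vestibule <- function(frame) {
  f326 <- frame_pos(frame, "F326_CB")
  wat <- frame[frame$role == "water", ]
  lip <- frame[frame$role == "lipid", ]
  keep <- character(0)
  for (i in seq_len(nrow(wat))) {
    w <- c(wat$x[i], wat$y[i], wat$z[i])
    if (brute_dist(w, f326) > 26) next
    if (w[3] - f326[3] > 23) next
    near_lip <- FALSE
    for (j in seq_len(nrow(lip))) {
      if (brute_dist(w, c(lip$x[j], lip$y[j], lip$z[j])) <= 5) {
        near_lip <- TRUE
        break
      }
    }
    if (!near_lip) keep <- c(keep, wat$label[i])
  }
  keep
}

brute_ec_cavity <- function(frame) {
  da <- frame_pos(frame, "DA")
  vest <- brute_ec_vestibule(frame)
  wat <- frame[frame$role == "water" & frame$label %in% vest, ]
  keep <- character(0)
  for (i in seq_len(nrow(wat))) {
    if (brute_dist(c(wat$x[i], wat$y[i], wat$z[i]), da) <= 10) {
      keep <- c(keep, wat$label[i])
    }
  }
  keep
}

brute_ic_split <- function(frame) {
  da <- frame_pos(frame, "DA")
  d436 <- frame_pos(frame, "D436_CB")
  t269 <- frame[grepl("^T269", frame$label), ]
  wat <- frame[frame$role == "water", ]
  lip <- frame[frame$role == "lipid", ]
  vest <- chan <- cav <- character(0)
  for (i in seq_len(nrow(wat))) {
    w <- c(wat$x[i], wat$y[i], wat$z[i])
    if (brute_dist(w, da) > 15) next
    if (abs(w[3] - d436[3]) > 15.5) next
    near_lip <- FALSE
    for (j in seq_len(nrow(lip))) {
      if (brute_dist(w, c(lip$x[j], lip$y[j], lip$z[j])) <= 5) {
        near_lip <- TRUE
        break
      }
    }
    if (near_lip) next
    vest <- c(vest, wat$label[i])
    in_chan <- FALSE
    for (j in seq_len(nrow(t269))) {
      if (brute_dist(w, c(t269$x[j], t269$y[j], t269$z[j])) <= 12) {
        in_chan <- TRUE
        break
      }
    }
    if (in_chan) chan <- c(chan, wat$label[i]) else cav <- c(cav, wat$label[i])
  }
  list(IC_vestibule = vest, IC_channel = chan, IC_cavity = cav)
}

brute_mediated <- function(frame, a_labels, b_label, m_labels, cutoff) {
  b <- frame_pos(frame, b_label)
  med <- frame[frame$label %in% m_labels, ]
  par_a <- frame[frame$label %in% a_labels, ]
  for (i in seq_len(nrow(med))) {
    m <- c(med$x[i], med$y[i], med$z[i])
    if (brute_dist(m, b) > cutoff) next
    for (j in seq_len(nrow(par_a))) {
      if (brute_dist(m, c(par_a$x[j], par_a$y[j], par_a$z[j])) <= cutoff) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# A fully randomized single frame carrying the standard marker set plus
# uniformly scattered waters / lipids / ions, for oracle comparisons.
random_frame <- function(seed, n_waters = 30, n_lipids = 6) {
  set.seed(seed)
  mk <- ionrelease:::synthetic_marker_layout()
  rows <- list(data.frame(
    trajectory = 1L, frame = 1L, label = mk$label, role = mk$role,
    x = mk$x + rnorm(nrow(mk)), y = mk$y + rnorm(nrow(mk)),
    z = mk$z + rnorm(nrow(mk))
  ))
  add <- function(label, role, n, spread = 30) {
    data.frame(
      trajectory = 1L, frame = 1L,
      label = if (n == 1) label else sprintf("%s%02d", label, seq_len(n)),
      role = role,
      x = runif(n, -spread, spread), y = runif(n, -spread, spread),
      z = runif(n, -spread, spread)
    )
  }
  rows <- c(rows, list(
    add("W", "water", n_waters),
    add("LIP", "lipid", n_lipids),
    add("Na2", "ion", 1),
    add("K", "ion", 3)
  ))
  out <- do.call(rbind, rows)
  out[!duplicated(out$label), ]
}

# --- path decomposition oracle ----------------------------------------------

# All simple paths from any source to any target on the positive-edge graph.
all_paths <- function(F, source, target) {
  res <- list()
  recurse <- function(path) {
    u <- path[length(path)]
    if (u %in% target) {
      res[[length(res) + 1L]] <<- path
      return()
    }
    for (v in which(F[u, ] > 0)) {
      if (!v %in% path) recurse(c(path, v))
    }
  }
  for (s in source) recurse(s)
  res
}

path_bottleneck <- function(F, path) {
  m <- Inf
  for (i in seq_len(length(path) - 1)) m <- min(m, F[path[i], path[i + 1]])
  m
}

# Exhaustive greedy bottleneck decomposition: enumerate every remaining
# simple path, take the one with maximal bottleneck (ties: shortest path,
# then lexicographically smallest), subtract, repeat.
brute_path_decomposition <- function(F, source, target, n_paths) {
  out <- list()
  for (r in seq_len(n_paths)) {
    ps <- all_paths(F, source, target)
    if (!length(ps)) break
    bn <- vapply(ps, function(p) path_bottleneck(F, p), numeric(1))
    if (max(bn) <= 1e-14) break
    f <- max(bn)
    cand <- ps[bn == f]
    lens <- lengths(cand)
    cand <- cand[lens == min(lens)]
    if (length(cand) > 1) {
      key <- vapply(cand, function(p) paste(sprintf("%04d", p),
                                            collapse = ","), character(1))
      cand <- cand[order(key)]
    }
    best <- cand[[1]]
    out[[r]] <- list(path = best, flux = f)
    for (i in seq_len(length(best) - 1)) {
      F[best[i], best[i + 1]] <- max(0, F[best[i], best[i + 1]] - f)
    }
  }
  out
}

random_dag_flux <- function(seed, n_nodes) {
  set.seed(seed)
  F <- matrix(0, n_nodes, n_nodes)
  for (i in seq_len(n_nodes - 1)) {
    for (j in seq(i + 1, n_nodes)) {
      if (runif(1) < 0.5) F[i, j] <- runif(1, 0.05, 1)
    }
  }
  # guarantee at least one source -> target route
  F[1, n_nodes] <- max(F[1, n_nodes], runif(1, 0.05, 1))
  F
}

# Dense nonsymmetric generalized-eigen oracle: eigen of C^{-1} C_TL.
dense_geigen <- function(C, Ctl) {
  e <- eigen(solve(C) %*% Ctl)
  ord <- order(Re(e$values), decreasing = TRUE)
  list(values = Re(e$values)[ord],
       vectors = Re(e$vectors)[, ord, drop = FALSE])
}

# Weighted Boltzmann free-energy profile along a fitted tICA coordinate:
# quadrature on an (x, y) grid pushed through the model's projection.
boltzmann_tic1_profile <- function(params, model, breaks, n_grid = 350) {
  r0 <- params$confine_radius + 1.5
  gx <- seq(params$confine_center[1] - r0, params$confine_center[1] + r0,
            length.out = n_grid)
  gy <- seq(params$confine_center[2] - r0, params$confine_center[2] + r0,
            length.out = n_grid)
  grid <- expand.grid(x = gx, y = gy)
  w <- exp(-three_well_potential(params, as.matrix(grid)) /
             params$temperature_factor)
  proj <- tica_project(tibble::as_tibble(grid), model, n_components = 1)
  t1 <- proj$tic_1
  bin <- cut(t1, breaks = breaks, include.lowest = TRUE)
  p <- tapply(w, bin, sum)
  p[is.na(p)] <- 0
  p <- p / sum(p)
  fe <- ifelse(p > 0, -log(p), NA_real_)
  as.numeric(fe - min(fe, na.rm = TRUE))
}
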