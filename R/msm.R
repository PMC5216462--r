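# Microstate Markov state models: k-means discretization of the reduced
# space, transition counting, reversible (transpose-symmetrized) TPM
# estimation, eigendecomposition and implied timescales.

projection_matrix <- function(projections) {
  cols <- setdiff(names(projections), c("trajectory", "frame"))
  as.matrix(projections[cols])
}

# k-means++ seeding: centers drawn with probability proportional to the
# squared distance from the nearest already-chosen center.
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  for (j in seq_len(k - 1)) {
    probs <- d2 / sum(d2)
    centers[j + 1, ] <- X[sample.int(n, 1, prob = probs), ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j + 1, ])^2))
  }
  centers
}

#' Cluster projected frames into microstates
#'
#' k-means++-seeded Lloyd clustering of the projected frames; every frame
#' is assigned to its nearest center (Euclidean). On an empty cluster the
#' clustering is re-seeded once before failing.
#'
#' @param projections Projection tibble from [tica_project()] (or any tidy
#'   table whose non-id columns are coordinates).
#' @param k Number of microstates (>= 2).
#' @param seed Integer seed or `NULL`.
#' @param iter_max Lloyd iteration cap.
#' @return A list with `centers` (k x d), `assignments` (tibble
#'   `trajectory`, `frame`, `state`).
#' @export
cluster_microstates <- function(projections, k, seed = NULL, iter_max = 100) {
  k <- assert_count(k, "k", lower = 2L)
  X <- projection_matrix(projections)
  if (nrow(X) < k) abort("Need at least `k` frames to form `k` microstates.")
  fit <- with_seed(seed, {
    run <- function() {
      init <- kmeanspp_init(X, k)
      suppressWarnings(
        stats::kmeans(X, centers = init, iter.max = iter_max,
                      algorithm = "Lloyd")
      )
    }
    f <- tryCatch(run(), error = function(e) NULL)
    if (is.null(f) || any(f$size == 0)) f <- run() # one re-seed
    if (is.null(f) || any(f$size == 0)) {
      abort("k-means produced an empty cluster even after re-seeding.")
    }
    f
  })
  assignments <- projections %>%
    select(dplyr::any_of(c("trajectory", "frame"))) %>%
    mutate(state = as.integer(fit$cluster))
  if (!"trajectory" %in% names(assignments)) {
    assignments <- mutate(assignments, trajectory = 1L, .before = 1)
  }
  list(centers = fit$centers, assignments = assignments)
}

#' Count microstate transitions at a lag
#'
#' `C[i, j]` counts the frame pairs `(t, t + lag)` assigned to states
#' `(i, j)`, pooled over trajectories, never spanning trajectory
#' boundaries. Sliding-window counting uses every pair; strided counting
#' uses pairs starting at multiples of the lag.
#'
#' @param assignments Tibble with `trajectory`, `state` in frame order, or
#'   a list of integer state vectors.
#' @param lag Lag in frames (>= 1).
#' @param n_states State-space size (default: max observed state).
#' @param mode `"sliding"` (default) or `"strided"`.
#' @return A `n_states x n_states` count matrix.
#' @export
count_transitions <- function(assignments, lag, n_states = NULL,
                              mode = c("sliding", "strided")) {
  mode <- match.arg(mode)
  lag <- assert_count(lag, "lag")
  seqs <- if (is.data.frame(assignments)) {
    split(assignments$state, assignments$trajectory)
  } else if (is.list(assignments)) {
    assignments
  } else {
    list(as.integer(assignments))
  }
  n_states <- n_states %||% max(unlist(seqs))
  C <- matrix(0, n_states, n_states)
  usable <- FALSE
  for (s in seqs) {
    if (length(s) <= lag) next
    usable <- TRUE
    starts <- if (mode == "sliding") {
      seq_len(length(s) - lag)
    } else {
      seq(1L, length(s) - lag, by = lag)
    }
    from <- s[starts]
    to <- s[starts + lag]
    tab <- table(factor(from, levels = seq_len(n_states)),
                 factor(to, levels = seq_len(n_states)))
    C <- C + unclass(tab)
  }
  if (!usable) abort("All trajectories are shorter than `lag + 1` frames.")
  unname(C)
}

# Largest connected component of the symmetrized count graph.
largest_connected_set <- function(C) {
  A <- (C + t(C)) > 0
  diag(A) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  comp <- igraph::components(g)
  # weight components by total counts, not node number
  wt <- tapply(rowSums(C) + colSums(C), comp$membership, sum)
  keep <- as.integer(names(wt)[which.max(wt)])
  sort(which(comp$membership == keep))
}

#' Estimate a reversible transition probability matrix
#'
#' Symmetrizes the count matrix with its transpose,
#' `C_sym = (C + C') / 2`, restricts to the largest connected set of the
#' count graph, and row-normalizes. The stationary distribution is the
#' normalized row-sum vector of `C_sym`; detailed balance
#' `pi_i T_ij = pi_j T_ji` holds by construction.
#'
#' @param count_matrix Square non-negative count matrix.
#' @return A list with `T` (row-stochastic), `pi`, and `active` — the
#'   indices of the original states retained.
#' @export
estimate_tpm <- function(count_matrix) {
  C <- as.matrix(count_matrix)
  if (nrow(C) != ncol(C) || any(C < 0)) {
    abort("`count_matrix` must be square and non-negative.")
  }
  if (sum(C) == 0) abort("Count matrix is empty.")
  active <- largest_connected_set(C)
  if (length(active) < nrow(C)) {
    inform(sprintf(
      "Restricting to largest connected set: %d of %d states kept.",
      length(active), nrow(C)
    ))
  }
  Cs <- (C + t(C))[active, active, drop = FALSE] / 2
  rs <- rowSums(Cs)
  if (any(rs == 0)) abort("Connected set contains an unvisited state.")
  T <- Cs / rs
  list(T = T, pi = rs / sum(rs), active = active)
}

#' Eigendecomposition of a reversible TPM
#'
#' Exploits detailed balance: in the pi-weighted inner product the TPM is
#' self-adjoint, so `D^{1/2} T D^{-1/2}` (with `D = diag(pi)`) is
#' symmetric and the spectrum is real. Returns eigenvalues in descending
#' order with right and left eigenvectors (`left[, 1]` is `pi`).
#'
#' @param T Row-stochastic reversible matrix.
#' @param pi Stationary distribution (computed if `NULL`).
#' @param tol Tolerance on the detailed-balance / realness check.
#' @return A list with `values`, `right`, `left`.
#' @export
msm_eigensystem <- function(T, pi = NULL, tol = 1e-8) {
  assert_stochastic(T)
  pi <- pi %||% stationary_distribution(T)
  if (any(pi <= 1e-14)) {
    # reducible chains have non-unique stationary vectors; fall back to
    # the uniform one when it is stationary (e.g. the identity matrix)
    k <- nrow(T)
    unif <- rep(1 / k, k)
    if (max(abs(unif %*% T - unif)) < tol) {
      pi <- unif
    } else {
      abort("Stationary distribution has zero entries; restrict the chain to its recurrent communicating class first.")
    }
  }
  db <- max(abs(pi * T - t(pi * T)))
  if (db > tol) {
    abort(sprintf(
      "Detailed balance violated (max |pi_i T_ij - pi_j T_ji| = %.3g); the symmetric solve would be invalid.",
      db
    ))
  }
  s <- sqrt(pi)
  M <- (s %o% (1 / s)) * T
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  ord <- order(e$values, decreasing = TRUE)
  vals <- e$values[ord]
  phi <- e$vectors[, ord, drop = FALSE]
  right <- phi / s
  left <- phi * s
  # normalize: right[,1] constant +1, left[,1] = pi
  for (j in seq_along(vals)) {
    nrm <- sqrt(sum(pi * right[, j]^2)) # pi-weighted norm 1
    right[, j] <- right[, j] / nrm
    left[, j] <- left[, j] * nrm
    i <- which.max(abs(right[, j]))
    if (right[i, j] < 0) {
      right[, j] <- -right[, j]
      left[, j] <- -left[, j]
    }
  }
  list(values = vals, right = right, left = left)
}

#' Implied timescales from TPM eigenvalues
#'
#' `tau_i = -tau' / log(lambda_i)` for `0 < lambda_i < 1`. The Perron
#' eigenvalue (1) maps to `Inf`; numerically `>= 1` maps to `Inf`;
#' `lambda <= 0` has no timescale interpretation and is returned as `NA`.
#'
#' @param values Eigenvalues sorted descending (Perron included or not).
#' @param lag Lag time tau' (any time unit; output shares it).
#' @return Numeric vector of timescales.
#' @examples
#' implied_timescales(exp(-1), 48) # 48
#' @export
implied_timescales <- function(values, lag) {
  assert_scalar_number(lag, "lag", lower = 1e-300)
  vapply(values, function(l) {
    if (!is.finite(l)) return(NA_real_)
    if (l >= 1) return(Inf)
    if (l <= 0) return(NA_real_)
    -lag / log(l)
  }, numeric(1))
}

#' Fit a microstate Markov model at a single lag
#'
#' Bundles counting, reversible TPM estimation and spectral analysis.
#'
#' @param assignments Tibble (`trajectory`, `frame`, `state`) or list of
#'   state vectors.
#' @param lag Lag in frames.
#' @param stride ns per frame (for reporting timescales in ns).
#' @param n_states State-space size override.
#' @param centers Optional microstate centers to attach.
#' @param mode Counting mode, see [count_transitions()].
#' @return An object of class `markov_model`.
#' @export
markov_model <- function(assignments, lag, stride = 1, n_states = NULL,
                         centers = NULL, mode = "sliding") {
  C <- count_transitions(assignments, lag, n_states = n_states, mode = mode)
  est <- estimate_tpm(C)
  eig <- msm_eigensystem(est$T, est$pi)
  lag_ns <- lag * stride
  structure(
    list(
      count_matrix = C, T = est$T, pi = est$pi, active = est$active,
      values = eig$values, right = eig$right, left = eig$left,
      lag_frames = as.integer(lag), lag_ns = lag_ns, stride = stride,
      timescales_ns = implied_timescales(eig$values[-1], lag_ns),
      centers = centers
    ),
    class = "markov_model"
  )
}

#' @export
print.markov_model <- function(x, ...) {
  cat(sprintf(
    "<markov_model> %d states, lag %d frames (%g ns), slowest timescale %s ns\n",
    nrow(x$T), x$lag_frames, x$lag_ns,
    format(signif(x$timescales_ns[1], 4))
  ))
  invisible(x)
}

#' @export
tidy.markov_model <- function(x, ...) {
  tibble(
    mode = seq_along(x$values),
    eigenvalue = x$values,
    implied_timescale_ns = c(Inf, x$timescales_ns)
  )
}

#' @export
glance.markov_model <- function(x, ...) {
  tibble(
    n_states = nrow(x$T),
    lag_frames = x$lag_frames,
    lag_ns = x$lag_ns,
    slowest_timescale_ns = x$timescales_ns[1],
    total_counts = sum(x$count_matrix)
  )
}

#' Implied-timescale scan over a lag ladder with trajectory bootstrap
#'
#' Re-estimates the model at each lag and reports the leading implied
#' timescales, with spread obtained by resampling whole trajectories with
#' replacement. Lag-independence (a flat curve) diagnoses Markovian
#' behavior; the flatness diagnostic is the maximum relative change of the
#' slowest timescale over the upper half of the ladder.
#'
#' @param assignments Tibble (`trajectory`, `frame`, `state`).
#' @param lags Integer lags in frames, ascending.
#' @param n_modes Number of relaxation modes reported.
#' @param n_boot Bootstrap subsamples (0 to skip).
#' @param seed Integer seed or `NULL`.
#' @param stride ns per frame.
#' @return An object of class `its_scan`: tibble `scan` (`lag_frames`,
#'   `lag_ns`, `mode`, `timescale_ns`, `ci_lo`, `ci_hi`) plus the
#'   flatness diagnostic.
#' @export
implied_timescale_scan <- function(assignments, lags, n_modes = 10,
                                   n_boot = 10, seed = NULL, stride = 1) {
  lags <- sort(unique(as.integer(lags)))
  seqs <- split(assignments$state, assignments$trajectory)
  n_states <- max(assignments$state)
  max_len <- max(vapply(seqs, length, integer(1)))
  drop <- lags >= max_len
  if (any(drop)) {
    warn(sprintf("%d lag(s) exceeding every trajectory length dropped.",
                 sum(drop)))
    lags <- lags[!drop]
  }
  if (!length(lags)) abort("No usable lags remain.")
  ts_at <- function(seq_list, lag) {
    ok <- tryCatch({
      C <- count_transitions(seq_list, lag, n_states = n_states)
      est <- estimate_tpm(C)
      eig <- msm_eigensystem(est$T, est$pi)
      implied_timescales(eig$values[-1], lag * stride)
    }, error = function(e) rep(NA_real_, n_states - 1))
    out <- rep(NA_real_, n_modes)
    out[seq_len(min(n_modes, length(ok)))] <- head(ok, n_modes)
    out
  }
  seeds <- derive_seeds(seed, max(n_boot, 1L))
  rows <- purrr::map_dfr(lags, function(lg) {
    full <- ts_at(seqs, lg)
    boot <- NULL
    if (n_boot > 0) {
      boot <- sapply(seq_len(n_boot), function(b) {
        pick <- with_seed(seeds[[b]],
                          sample(length(seqs), length(seqs), replace = TRUE))
        ts_at(seqs[pick], lg)
      })
      if (is.null(dim(boot))) boot <- matrix(boot, nrow = n_modes)
    }
    tibble(
      lag_frames = lg, lag_ns = lg * stride, mode = seq_len(n_modes),
      timescale_ns = full,
      ci_lo = if (is.null(boot)) NA_real_ else
        apply(boot, 1, quantile, 0.025, na.rm = TRUE, names = FALSE),
      ci_hi = if (is.null(boot)) NA_real_ else
        apply(boot, 1, quantile, 0.975, na.rm = TRUE, names = FALSE)
    )
  })
  upper <- lags[lags >= stats::median(lags)]
  t1 <- rows$timescale_ns[rows$mode == 1 & rows$lag_frames %in% upper]
  t1 <- t1[is.finite(t1)]
  flatness <- if (length(t1) > 1) diff(range(t1)) / mean(t1) else 0
  structure(list(scan = rows, flatness = flatness, stride = stride),
            class = "its_scan")
}

#' @export
print.its_scan <- function(x, ...) {
  cat(sprintf("<its_scan> %d lags, flatness diagnostic %.3f\n",
              length(unique(x$scan$lag_frames)), x$flatness))
  invisible(x)
}

#' @export
tidy.its_scan <- function(x, ...) x$scan

#' @export
autoplot.its_scan <- function(object, modes = 1:3, ...) {
  df <- object$scan %>% filter(.data$mode %in% modes,
                               is.finite(.data$timescale_ns))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lag_ns, y = .data$timescale_ns,
                                   color = factor(.data$mode))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi,
                   fill = factor(.data$mode)),
      alpha = 0.2, color = NA
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "lag (ns)", y = "implied timescale (ns)",
                  color = "mode", fill = "mode") +
    ggplot2::theme_minimal()
}

#' Serialize / restore a Markov model (JSON)
#'
#' @param model A `markov_model`.
#' @param path JSON file path.
#' @return `path` / the restored model.
#' @export
write_msm_json <- function(model, path) {
  payload <- model[c("count_matrix", "T", "pi", "active", "values",
                     "right", "left", "lag_frames", "lag_ns", "stride",
                     "timescales_ns", "centers")]
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' @rdname write_msm_json
#' @export
read_msm_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      count_matrix = as.matrix(p$count_matrix), T = as.matrix(p$T),
      pi = as.numeric(p$pi), active = as.integer(p$active),
      values = as.numeric(p$values), right = as.matrix(p$right),
      left = as.matrix(p$left), lag_frames = p$lag_frames,
      lag_ns = p$lag_ns, stride = p$stride,
      timescales_ns = as.numeric(p$timescales_ns),
      centers = if (is.null(p$centers)) NULL else as.matrix(p$centers)
    ),
    class = "markov_model"
  )
}
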