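# Free-energy profiles from state populations, block-bootstrap errors,
# basin identification, and ensemble release-event bookkeeping.

#' One-dimensional free-energy profile from populations
#'
#' Histograms the reaction-coordinate values and takes
#' `F_b = -ln(p_b)`, shifted so the minimum is 0 (units of kT). Empty
#' bins are reported as missing (`NA`), not zero or infinity, so error
#' propagation stays finite.
#'
#' @param values Reaction-coordinate samples (e.g. the first tICA
#'   coordinate of the trajectories with a release event).
#' @param n_bins Number of bins (>= 10).
#' @param limits Optional c(min, max) histogram range.
#' @param min_frames Minimum sample size accepted.
#' @return An object of class `free_energy_profile`: tibble `profile`
#'   (`bin_center`, `count`, `probability`, `free_energy`, `error`) plus
#'   `breaks`.
#' @export
free_energy_1d <- function(values, n_bins = 50, limits = NULL,
                           min_frames = 1000) {
  values <- values[is.finite(values)]
  if (!length(values)) abort("`values` is empty.")
  if (length(values) < min_frames) {
    abort(sprintf("Need >= %d frames for a stable profile (got %d).",
                  min_frames, length(values)))
  }
  n_bins <- assert_count(n_bins, "n_bins", lower = 10L)
  limits <- limits %||% range(values)
  breaks <- seq(limits[1], limits[2], length.out = n_bins + 1)
  # samples beyond explicit limits accumulate in the edge bins
  values <- pmin(pmax(values, limits[1]), limits[2])
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  p <- h$counts / sum(h$counts)
  fe <- ifelse(p > 0, -log(p), NA_real_)
  fe <- fe - min(fe, na.rm = TRUE)
  structure(
    list(
      profile = tibble(
        bin_center = h$mids, count = h$counts, probability = p,
        free_energy = fe, error = NA_real_
      ),
      breaks = breaks,
      n_samples = length(values)
    ),
    class = "free_energy_profile"
  )
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat(sprintf(
    "<free_energy_profile> %d bins, %d samples, relief %.2f kT\n",
    nrow(x$profile), x$n_samples,
    max(x$profile$free_energy, na.rm = TRUE)
  ))
  invisible(x)
}

#' Block-bootstrap errors for a free-energy profile
#'
#' Resamples contiguous blocks of frames (block length drawn uniformly in
#' `block_range`, expressed in ns) with replacement from the per-trajectory
#' series until the original sample size is reached, recomputes the
#' profile on the same bins, and reports the per-bin standard deviation
#' across replicates. Block resampling respects the autocorrelation of
#' the data; an iid bootstrap would understate the error.
#'
#' @param profile A [free_energy_1d()] result.
#' @param series_by_traj A list of numeric vectors (one reaction
#'   coordinate series per trajectory) or a tibble with `trajectory` and a
#'   value column.
#' @param block_range c(min, max) block length in ns (default 110-250,
#'   i.e. 180 +/- 70).
#' @param stride ns per frame.
#' @param n_boot Number of replicates.
#' @param seed Integer seed or `NULL`.
#' @return The profile with its `error` column filled (kT per bin), and a
#'   `replicates` attribute (bins x n_boot matrix of free energies).
#' @export
block_bootstrap_errors <- function(profile, series_by_traj,
                                   block_range = c(110, 250), stride = 1,
                                   n_boot = 50, seed = NULL) {
  if (!inherits(profile, "free_energy_profile")) {
    abort("`profile` must come from free_energy_1d().")
  }
  if (is.data.frame(series_by_traj)) {
    vc <- setdiff(names(series_by_traj), c("trajectory", "frame"))[1]
    series_by_traj <- split(series_by_traj[[vc]], series_by_traj$trajectory)
  }
  lens <- vapply(series_by_traj, length, integer(1))
  blk_frames <- pmax(1L, round(block_range / stride))
  if (blk_frames[1] > max(lens)) {
    abort("Minimum block length exceeds every trajectory length.")
  }
  total <- sum(lens)
  breaks <- profile$breaks
  nb <- nrow(profile$profile)
  reps <- with_seed(seed, {
    sapply(seq_len(n_boot), function(b) {
      got <- 0L
      acc <- vector("list", 0)
      while (got < total) {
        ti <- sample.int(length(series_by_traj), 1)
        s <- series_by_traj[[ti]]
        L <- sample(seq(blk_frames[1], blk_frames[2]), 1)
        L <- min(L, length(s))
        st <- sample.int(length(s) - L + 1L, 1)
        acc[[length(acc) + 1L]] <- s[st:(st + L - 1L)]
        got <- got + L
      }
      v <- unlist(acc)[seq_len(total)]
      cnt <- graphics::hist(pmin(pmax(v, breaks[1]), breaks[nb + 1]),
                            breaks = breaks, plot = FALSE)$counts
      p <- cnt / sum(cnt)
      fe <- ifelse(p > 0, -log(p), NA_real_)
      fe - min(fe, na.rm = TRUE)
    })
  })
  if (is.null(dim(reps))) reps <- matrix(reps, nrow = nb)
  err <- if (ncol(reps) < 2) rep(0, nb) else apply(reps, 1, sd, na.rm = TRUE)
  err[!is.finite(err)] <- NA_real_
  profile$profile$error <- err
  attr(profile, "replicates") <- reps
  profile
}

#' Identify basins in a free-energy profile
#'
#' Finds local minima separated by barriers of at least `min_depth` kT:
#' minima are merged (the shallower into the deeper) while the barrier
#' between them is below the threshold, so the basin count is
#' non-increasing in `min_depth`. Extents run to the barrier tops.
#'
#' @param profile A [free_energy_1d()] result.
#' @param min_depth Minimum barrier depth in kT.
#' @return A tibble: `basin`, `minimum` (coordinate), `min_free_energy`,
#'   `left`, `right` (extent bounds), `depth` (smaller flanking barrier).
#' @export
find_basins <- function(profile, min_depth = 1) {
  assert_scalar_number(min_depth, "min_depth", lower = 0)
  df <- profile$profile[!is.na(profile$profile$free_energy), , drop = FALSE]
  fe <- df$free_energy
  xs <- df$bin_center
  n <- length(fe)
  if (n < 3) return(empty_basin_table())
  # candidate minima: strictly lower than flat-run neighbors
  is_min <- vapply(seq_len(n), function(i) {
    l <- if (i > 1) fe[i - 1] else Inf
    r <- if (i < n) fe[i + 1] else Inf
    fe[i] < l && fe[i] <= r
  }, logical(1))
  mins <- which(is_min)
  if (!length(mins)) return(empty_basin_table())
  # merge adjacent minima while the separating barrier is too shallow
  repeat {
    if (length(mins) < 2) break
    barrier <- vapply(seq_len(length(mins) - 1), function(j) {
      seg <- fe[mins[j]:mins[j + 1]]
      max(seg) - max(fe[mins[j]], fe[mins[j + 1]])
    }, numeric(1))
    weak <- which(barrier < min_depth)
    if (!length(weak)) break
    j <- weak[which.min(barrier[weak])]
    drop_idx <- if (fe[mins[j]] <= fe[mins[j + 1]]) j + 1 else j
    mins <- mins[-drop_idx]
  }
  # basin boundaries at the barrier tops between surviving minima
  bounds <- c(1, vapply(seq_len(length(mins) - 1), function(j) {
    seg <- mins[j]:mins[j + 1]
    seg[which.max(fe[seg])]
  }, numeric(1)), n)
  purrr::map_dfr(seq_along(mins), function(b) {
    lo <- bounds[b]; hi <- bounds[b + 1]
    seg <- lo:hi
    left_bar <- if (b == 1) max(fe[1:mins[b]]) else fe[bounds[b]]
    right_bar <- if (b == length(mins)) max(fe[mins[b]:n]) else fe[bounds[b + 1]]
    tibble(
      basin = b, minimum = xs[mins[b]], min_free_energy = fe[mins[b]],
      left = xs[lo], right = xs[hi],
      depth = min(left_bar, right_bar) - fe[mins[b]]
    )
  })
}

empty_basin_table <- function() {
  tibble(basin = integer(), minimum = numeric(),
         min_free_energy = numeric(), left = numeric(), right = numeric(),
         depth = numeric())
}

#' @export
tidy.free_energy_profile <- function(x, ...) x$profile

#' @export
glance.free_energy_profile <- function(x, ...) {
  b <- find_basins(x)
  tibble(n_bins = nrow(x$profile), n_samples = x$n_samples,
         relief_kt = max(x$profile$free_energy, na.rm = TRUE),
         n_basins_1kt = nrow(b))
}

#' @export
autoplot.free_energy_profile <- function(object, ...) {
  df <- object$profile
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_center,
                                        y = .data$free_energy)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "reaction coordinate (tIC 1)", y = "free energy (kT)") +
    ggplot2::theme_minimal()
  if (any(is.finite(df$error))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$free_energy - .data$error,
                   ymax = .data$free_energy + .data$error),
      alpha = 0.25, na.rm = TRUE
    )
  }
  p
}

#' Release-event summary of a feature ensemble
#'
#' Applies the sustained-threshold release criterion to the ion-pair
#' distance of every trajectory: a release is called at the first frame
#' opening a run of at least `persistence` consecutive frames above
#' `threshold` Å (the persistence guard suppresses flicker). Reports the
#' per-trajectory call, the release time in ns, and the ensemble counts.
#'
#' @param features Feature tibble containing `trajectory`, `frame` and the
#'   distance column.
#' @param distance_col Name of the ion-pair distance column.
#' @param threshold Release threshold in Å (default 10).
#' @param persistence Minimum run length in frames (default 10).
#' @param stride ns per frame; taken from the features attribute if
#'   present.
#' @return An object of class `release_summary`: tibble `per_trajectory`
#'   (`trajectory`, `released`, `release_time_ns`), plus counts and
#'   min/max release times.
#' @export
release_summary <- function(features, distance_col = "na2_na1",
                            threshold = 10, persistence = 10,
                            stride = NULL) {
  if (!distance_col %in% names(features)) {
    abort(paste0("Distance feature column missing: ", distance_col))
  }
  stride <- stride %||% attr(features, "stride") %||% 1
  per <- features %>%
    arrange(.data$trajectory, .data$frame) %>%
    group_by(.data$trajectory) %>%
    summarise(
      first_frame = first_sustained_crossing(
        .data[[distance_col]], threshold, persistence
      ),
      .groups = "drop"
    ) %>%
    mutate(
      released = !is.na(.data$first_frame),
      release_time_ns = .data$first_frame * stride
    ) %>%
    select("trajectory", "released", "release_time_ns")
  rt <- per$release_time_ns[per$released]
  structure(
    list(
      per_trajectory = per,
      n_released = sum(per$released),
      n_not_released = sum(!per$released),
      fastest_ns = if (length(rt)) min(rt) else NA_real_,
      slowest_ns = if (length(rt)) max(rt) else NA_real_,
      threshold = threshold, persistence = persistence, stride = stride
    ),
    class = "release_summary"
  )
}

# Frame index (1-based) of the first frame opening a sustained
# above-threshold run, or NA.
first_sustained_crossing <- function(x, threshold, persistence) {
  above <- x > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values & r$lengths >= persistence
  if (!any(ok)) return(NA_integer_)
  as.integer(starts[which(ok)[1]])
}

#' @export
print.release_summary <- function(x, ...) {
  cat(sprintf(
    "<release_summary> released %d / %d trajectories (fastest %s ns, slowest %s ns)\n",
    x$n_released, x$n_released + x$n_not_released,
    format(x$fastest_ns), format(x$slowest_ns)
  ))
  invisible(x)
}

#' @export
tidy.release_summary <- function(x, ...) x$per_trajectory

#' @export
glance.release_summary <- function(x, ...) {
  tibble(n_released = x$n_released, n_not_released = x$n_not_released,
         fastest_ns = x$fastest_ns, slowest_ns = x$slowest_ns,
         threshold = x$threshold, persistence = x$persistence)
}
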