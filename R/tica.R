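# Time-structure-based independent component analysis.
#
# tICA finds the linear combinations of input features with the slowest
# autocorrelation by solving the generalized eigenvalue problem
#   C_TL V = C V Lambda
# between the time-lagged covariance C_TL(tau) = <X(t) X'(t+tau)> and the
# instantaneous covariance C = <X(t) X'(t)> of the mean-centered features.

# Split a feature tibble (trajectory, frame, features...) into a list of
# per-trajectory numeric matrices in frame order.
feature_matrices <- function(features, feature_cols = NULL) {
  if (is.data.frame(features)) {
    id <- intersect(c("trajectory", "frame"), names(features))
    if (!"trajectory" %in% id) {
      mats <- list(as.matrix(features))
      return(mats)
    }
    if (is.null(feature_cols)) feature_cols <- setdiff(names(features), id)
    features <- features %>% arrange(.data$trajectory, .data$frame)
    split_idx <- split(seq_len(nrow(features)), features$trajectory)
    lapply(split_idx, function(ix) {
      as.matrix(features[ix, feature_cols, drop = FALSE])
    })
  } else if (is.list(features)) {
    lapply(features, as.matrix)
  } else {
    list(as.matrix(features))
  }
}

#' Pooled instantaneous and time-lagged covariances
#'
#' Estimates the pooled mean, covariance `C` and (symmetrized on request by
#' the solver, raw here) time-lagged covariance `C_TL` across an ensemble
#' of feature trajectories. Lagged pairs `(t, t + lag)` never span a
#' trajectory boundary; trajectories shorter than `lag + 1` are skipped
#' with a warning.
#'
#' @param features A tidy feature tibble (`trajectory`, `frame`, feature
#'   columns) or a list of numeric matrices (frames x features).
#' @param lag Lag in frames (>= 1).
#' @return A list with `mean`, `C`, `C_TL`, `lag`, `n_frames`,
#'   `feature_names`.
#' @export
estimate_covariances <- function(features, lag) {
  lag <- assert_count(lag, "lag")
  mats <- feature_matrices(features)
  keep <- vapply(mats, nrow, integer(1)) >= lag + 1L
  if (!any(keep)) abort("All trajectories are shorter than `lag + 1`.")
  if (any(!keep)) {
    warn(sprintf("%d trajectorie(s) shorter than lag + 1 skipped.", sum(!keep)))
  }
  mats <- mats[keep]
  d <- ncol(mats[[1]])
  total <- sum(vapply(mats, nrow, integer(1)))
  mu <- Reduce(`+`, lapply(mats, colSums)) / total
  C <- matrix(0, d, d)
  Ctl <- matrix(0, d, d)
  n_pairs <- 0
  for (m in mats) {
    mc <- sweep(m, 2, mu)
    C <- C + crossprod(mc)
    t0 <- mc[seq_len(nrow(m) - lag), , drop = FALSE]
    t1 <- mc[seq_len(nrow(m) - lag) + lag, , drop = FALSE]
    Ctl <- Ctl + crossprod(t0, t1)
    n_pairs <- n_pairs + nrow(t0)
  }
  C <- C / total
  Ctl <- Ctl / n_pairs
  list(mean = mu, C = C, C_TL = Ctl, lag = lag, n_frames = total,
       feature_names = colnames(mats[[1]]))
}

#' Solve the tICA generalized eigenvalue problem
#'
#' Solves `C_TL V = C V Lambda` after symmetrizing `C_TL` (an asymmetric
#' estimate would yield complex pairs) and ridge-regularizing `C` with
#' `epsilon = 1e-10 * trace(C)/d`. Eigenvalues are returned in descending
#' order; eigenvectors are normalized to `v' C v = 1` and sign-fixed so
#' each vector's largest-magnitude entry is positive.
#'
#' @param C Instantaneous covariance (d x d, symmetric PSD).
#' @param C_TL Time-lagged covariance (d x d).
#' @param ridge Regularization scale (multiplied by `trace(C)/d`).
#' @return A list with `values` (descending) and `vectors` (columns).
#' @export
solve_tica <- function(C, C_TL, ridge = 1e-10) {
  d <- nrow(C)
  Csym <- (C + t(C)) / 2
  eps <- ridge * sum(diag(Csym)) / d
  Creg <- Csym + diag(eps + .Machine$double.xmin, d)
  Ctl_sym <- (C_TL + t(C_TL)) / 2
  ch <- tryCatch(chol(Creg), error = function(e) NULL)
  if (is.null(ch)) {
    abort(paste0(
      "Covariance matrix is singular even after regularization; ",
      "prune constant or perfectly collinear features."
    ))
  }
  # whiten: W = L^-T Ctl_sym L^-1 is symmetric; eigenpairs map back via L^-1
  Linv <- backsolve(ch, diag(d))
  W <- t(Linv) %*% Ctl_sym %*% Linv
  W <- (W + t(W)) / 2
  e <- eigen(W, symmetric = TRUE)
  V <- Linv %*% e$vectors
  ord <- order(e$values, decreasing = TRUE)
  vals <- e$values[ord]
  V <- V[, ord, drop = FALSE]
  # v' C v = 1 holds by construction (orthonormal in whitened space)
  for (j in seq_len(d)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  list(values = vals, vectors = V)
}

#' Fit a tICA model to an ensemble of feature trajectories
#'
#' @param features Tidy feature tibble or list of matrices (see
#'   [estimate_covariances()]).
#' @param lag Lag in frames.
#' @param n_components Number of components retained for projection
#'   (defaults to all).
#' @param stride ns per frame; taken from `attr(features, "stride")` when
#'   absent.
#' @return An object of class `tica_model`: covariances, eigenpairs,
#'   `lag_frames`, `lag_ns`, `n_components`, `feature_names`.
#' @export
tica <- function(features, lag, n_components = NULL, stride = NULL) {
  cov <- estimate_covariances(features, lag)
  sol <- solve_tica(cov$C, cov$C_TL)
  stride <- stride %||% attr(features, "stride") %||% 1
  d <- length(sol$values)
  n_components <- n_components %||% d
  n_components <- assert_count(n_components, "n_components")
  if (n_components > d) abort("`n_components` cannot exceed feature count.")
  structure(
    list(
      mean = cov$mean, C = cov$C, C_TL = cov$C_TL,
      values = sol$values, vectors = sol$vectors,
      lag_frames = cov$lag, lag_ns = cov$lag * stride,
      n_components = n_components,
      feature_names = cov$feature_names %||% paste0("f", seq_len(d)),
      n_frames = cov$n_frames
    ),
    class = "tica_model"
  )
}

#' @export
print.tica_model <- function(x, ...) {
  cat(sprintf(
    "<tica_model> %d features, lag %d frames (%g ns), top eigenvalues: %s\n",
    length(x$values), x$lag_frames, x$lag_ns,
    paste(signif(head(x$values, 4), 4), collapse = ", ")
  ))
  invisible(x)
}

#' Project features onto tICA components
#'
#' Computes `(X - mean) V[, 1:n]` per frame, preserving the trajectory
#' structure of the input.
#'
#' @param features Tidy feature tibble or list of matrices; feature
#'   columns must match the model's.
#' @param model A [tica()] model.
#' @param n_components Number of components (default: the model's).
#' @return A tibble `trajectory`, `frame`, `tic_1`, ..., `tic_n`, with the
#'   stride attribute carried over.
#' @export
tica_project <- function(features, model, n_components = NULL) {
  n <- n_components %||% model$n_components
  d <- length(model$values)
  n <- assert_count(n, "n_components")
  if (n > d) abort("`n_components` cannot exceed feature count.")
  tidy_input <- is.data.frame(features) && "trajectory" %in% names(features)
  mats <- feature_matrices(features)
  if (ncol(mats[[1]]) != d) {
    abort(sprintf("Feature dimension %d does not match model dimension %d.",
                  ncol(mats[[1]]), d))
  }
  V <- model$vectors[, seq_len(n), drop = FALSE]
  proj <- lapply(mats, function(m) sweep(m, 2, model$mean) %*% V)
  ids <- if (tidy_input) {
    features %>% arrange(.data$trajectory, .data$frame) %>%
      select("trajectory", "frame")
  } else {
    tibble(
      trajectory = rep(seq_along(proj), vapply(proj, nrow, integer(1))),
      frame = unlist(lapply(proj, function(p) seq_len(nrow(p))))
    )
  }
  pm <- do.call(rbind, proj)
  colnames(pm) <- paste0("tic_", seq_len(n))
  out <- bind_cols(ids, as_tibble(pm))
  attr(out, "stride") <- attr(features, "stride") %||% 1
  out
}

#' Per-component non-Gaussianity screen
#'
#' Components that merely mix fast degrees of freedom project the data to
#' near-Gaussian distributions; slow, mechanistically meaningful components
#' are typically multimodal. This screen applies a D'Agostino–Pearson-style
#' omnibus test (skewness + kurtosis chi-square) to each projected
#' component and recommends keeping the leading run of flagged components.
#'
#' @param projections Projection tibble from [tica_project()] (or any
#'   tibble whose non-id numeric columns are components).
#' @param alpha Flagging level.
#' @return A tibble per component: `component`, `statistic`, `p_value`,
#'   `non_gaussian`, `degenerate`; attribute `"recommended_n"` holds the
#'   suggested component count.
#' @export
screen_components <- function(projections, alpha = 0.01) {
  cols <- setdiff(names(projections), c("trajectory", "frame"))
  n <- nrow(projections)
  if (n < 100) abort("Need at least 100 frames to screen components.")
  rows <- purrr::map_dfr(cols, function(cl) {
    x <- projections[[cl]]
    if (sd(x) < 1e-12) {
      return(tibble(component = cl, statistic = NA_real_,
                    p_value = NA_real_, non_gaussian = TRUE,
                    degenerate = TRUE))
    }
    k2 <- dagostino_k2(x)
    tibble(component = cl, statistic = k2$statistic, p_value = k2$p_value,
           non_gaussian = k2$p_value < alpha, degenerate = FALSE)
  })
  flags <- rows$non_gaussian & !rows$degenerate
  rec <- if (any(!flags)) which(!flags)[1] - 1L else length(flags)
  attr(rows, "recommended_n") <- as.integer(rec)
  rows
}

# D'Agostino-Pearson omnibus normality statistic: transforms sample skewness
# and excess kurtosis to approximate normal deviates and sums their squares
# (chi-square, 2 df).
dagostino_k2 <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  m2 <- mean(x^2); m3 <- mean(x^3); m4 <- mean(x^4)
  b1 <- m3 / m2^1.5
  b2 <- m4 / m2^2
  # skewness transform
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  a <- sqrt(2 / (w2 - 1))
  zs <- delta * log(y / a + sqrt((y / a)^2 + 1))
  # kurtosis transform
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  aa <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  cbrt <- function(v) sign(v) * abs(v)^(1 / 3) # real cube root
  zk <- ((1 - 2 / (9 * aa)) -
           cbrt((1 - 2 / aa) / (1 + xk * sqrt(2 / (aa - 4))))) /
    sqrt(2 / (9 * aa))
  k2 <- zs^2 + zk^2
  list(statistic = k2, p_value = stats::pchisq(k2, df = 2, lower.tail = FALSE))
}

#' @export
tidy.tica_model <- function(x, ...) {
  tibble(
    component = seq_along(x$values),
    eigenvalue = x$values,
    timescale_frames = ifelse(x$values > 0 & x$values < 1,
                              -x$lag_frames / log(x$values), NA_real_),
    timescale_ns = ifelse(x$values > 0 & x$values < 1,
                          -x$lag_ns / log(x$values), NA_real_)
  )
}

#' @export
glance.tica_model <- function(x, ...) {
  tibble(
    n_features = length(x$values),
    lag_frames = x$lag_frames,
    lag_ns = x$lag_ns,
    n_components = x$n_components,
    n_frames = x$n_frames,
    lambda_1 = x$values[1]
  )
}

#' @export
autoplot.tica_model <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$eigenvalue)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "tICA component", y = "eigenvalue",
                  title = sprintf("tICA spectrum (lag %g ns)", object$lag_ns)) +
    ggplot2::theme_minimal()
}

#' Serialize / restore a tICA model (JSON)
#'
#' @param model A `tica_model`.
#' @param path Path of the JSON file.
#' @return `path` / the restored model.
#' @export
write_tica_json <- function(model, path) {
  payload <- list(
    mean = model$mean, C = model$C, C_TL = model$C_TL,
    values = model$values, vectors = model$vectors,
    lag_frames = model$lag_frames, lag_ns = model$lag_ns,
    n_components = model$n_components, feature_names = model$feature_names,
    n_frames = model$n_frames
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_tica_json
#' @export
read_tica_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      mean = as.numeric(p$mean), C = as.matrix(p$C), C_TL = as.matrix(p$C_TL),
      values = as.numeric(p$values), vectors = as.matrix(p$vectors),
      lag_frames = p$lag_frames, lag_ns = p$lag_ns,
      n_components = p$n_components, feature_names = p$feature_names,
      n_frames = p$n_frames
    ),
    class = "tica_model"
  )
}
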