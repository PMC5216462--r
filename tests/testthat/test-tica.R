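make_ar1 <- function(n, rho, seed, d = 1) {
  set.seed(seed)
  x <- matrix(0, n, d)
  for (j in seq_len(d)) {
    x[, j] <- as.numeric(stats::filter(rnorm(n, sd = sqrt(1 - rho^2)),
                                       rho, "recursive"))
  }
  x
}

test_that("constant features give zero covariances", {
  f <- tibble::tibble(trajectory = 1L, frame = 1:50, a = 2, b = -1)
  cov <- estimate_covariances(f, lag = 2)
  expect_equal(cov$C, matrix(0, 2, 2), ignore_attr = TRUE)
  expect_equal(cov$C_TL, matrix(0, 2, 2), ignore_attr = TRUE)
})

test_that("white noise decorrelates at any lag", {
  set.seed(4)
  n <- 20000
  f <- tibble::tibble(trajectory = 1L, frame = 1:n,
                      a = rnorm(n, sd = 2), b = rnorm(n))
  cov <- estimate_covariances(f, lag = 3)
  sigma <- 3 / sqrt(n)
  expect_lt(max(abs(cov$C_TL)), 4 * sigma * 2) # scaled by sd(a) bound
  expect_equal(cov$C[1, 1], 4, tolerance = 0.15)
  expect_equal(cov$C[2, 2], 1, tolerance = 0.1)
  expect_lt(abs(cov$C[1, 2]), 3 * sigma * 2)
})

test_that("AR(1) autocorrelation is recovered at lag one", {
  rho <- 0.8
  x <- make_ar1(30000, rho, seed = 5)
  f <- tibble::tibble(trajectory = 1L, frame = seq_len(nrow(x)), a = x[, 1])
  cov <- estimate_covariances(f, lag = 1)
  expect_equal(cov$C_TL[1, 1] / cov$C[1, 1], rho, tolerance = 0.03)
})

test_that("short trajectories are skipped with a warning", {
  f <- dplyr::bind_rows(
    tibble::tibble(trajectory = 1L, frame = 1:3, a = rnorm(3)),
    tibble::tibble(trajectory = 2L, frame = 1:50, a = rnorm(50))
  )
  expect_warning(estimate_covariances(f, lag = 10), "skipped")
  expect_error(estimate_covariances(f[f$trajectory == 1, ], lag = 10),
               "shorter")
})

test_that("the generalized eigensolve handles the diagonal case exactly", {
  sol <- solve_tica(diag(2), diag(c(0.9, 0.5)))
  expect_equal(sol$values, c(0.9, 0.5), tolerance = 1e-8)
  expect_equal(abs(sol$vectors), diag(2), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("eigenpairs match an independent dense solver", {
  for (seed in 1:10) {
    set.seed(seed)
    d <- sample(2:12, 1)
    A <- matrix(rnorm(d * d), d)
    C <- crossprod(A) / d + diag(d) * 0.1
    B <- matrix(rnorm(d * d), d)
    Ctl <- (B + t(B)) / 8
    sol <- solve_tica(C, Ctl)
    Cs <- (Ctl + t(Ctl)) / 2
    oracle <- dense_geigen(C, Cs)
    expect_equal(sol$values, oracle$values, tolerance = 1e-8)
    # residuals of the generalized problem
    for (j in seq_len(d)) {
      r <- Cs %*% sol$vectors[, j] -
        sol$values[j] * (C %*% sol$vectors[, j])
      expect_lt(sqrt(sum(r^2)), 1e-8 * sqrt(sum(sol$vectors[, j]^2)) +
                  1e-10)
      # normalization v' C v = 1
      expect_equal(as.numeric(t(sol$vectors[, j]) %*% C %*%
                                sol$vectors[, j]), 1, tolerance = 1e-8)
    }
  }
})

test_that("the dominant tIC aligns with the slow axis of a mixed process", {
  # two AR(1) processes (slow/fast) observed through a random mixing matrix
  slow <- make_ar1(40000, 0.98, seed = 6)
  fast <- make_ar1(40000, 0.2, seed = 7)
  set.seed(8)
  M <- matrix(rnorm(4), 2)
  obs <- cbind(slow, fast) %*% t(M)
  f <- tibble::tibble(trajectory = 1L, frame = seq_len(nrow(obs)),
                      a = obs[, 1], b = obs[, 2])
  model <- tica(f, lag = 5)
  # the slow source is recovered by the unmixing direction M^-T e1
  true_dir <- solve(t(M))[, 1]
  v <- model$vectors[, 1]
  cosine <- abs(sum(v * true_dir)) /
    sqrt(sum(v^2) * sum(true_dir^2))
  expect_gt(cosine, 0.99)
})

test_that("projection honors the trajectory structure and the mean", {
  f <- tibble::tibble(trajectory = rep(1:2, each = 200),
                      frame = rep(1:200, 2),
                      a = rnorm(400), b = rnorm(400))
  model <- tica(f, lag = 2)
  proj <- tica_project(f, model)
  expect_equal(nrow(proj), 400)
  expect_named(proj, c("trajectory", "frame", "tic_1", "tic_2"))
  # the mean projects to the origin
  mu <- tibble::tibble(trajectory = 1L, frame = 1L,
                       a = model$mean[1], b = model$mean[2])
  p0 <- tica_project(mu, model)
  expect_equal(as.numeric(p0[1, c("tic_1", "tic_2")]), c(0, 0),
               tolerance = 1e-12)
  # full-rank projection round-trips
  X <- as.matrix(f[c("a", "b")])
  P <- as.matrix(proj[c("tic_1", "tic_2")])
  back <- P %*% solve(model$vectors) # V is invertible for d = n
  expect_equal(back + matrix(model$mean, 400, 2, byrow = TRUE), X,
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("hand-computed projections match", {
  model <- structure(
    list(mean = c(1, 2), vectors = matrix(c(1, 0, 1, 1), 2), values = c(1, 1),
         n_components = 2, lag_frames = 1, lag_ns = 1,
         feature_names = c("a", "b"), n_frames = 1),
    class = "tica_model"
  )
  f <- tibble::tibble(trajectory = 1L, frame = 1:2, a = c(2, 0), b = c(4, 2))
  p <- tica_project(f, model)
  # (x - mean) %*% V with V = [[1,1],[0,1]]
  expect_equal(p$tic_1, c(1, -1))
  expect_equal(p$tic_2, c(3, -1))
})

test_that("tICs are invariant to affine rescaling of inputs (up to sign)", {
  set.seed(9)
  x <- make_ar1(8000, 0.9, seed = 10, d = 3)
  f <- tibble::tibble(trajectory = 1L, frame = seq_len(nrow(x)),
                      a = x[, 1], b = x[, 2], c = x[, 3])
  g <- dplyr::mutate(f, a = 3 * a + 5, b = -0.5 * b, c = c / 7 - 2)
  p1 <- tica_project(f, tica(f, lag = 4), n_components = 2)
  p2 <- tica_project(g, tica(g, lag = 4), n_components = 2)
  for (cl in c("tic_1", "tic_2")) {
    agreement <- abs(cor(p1[[cl]], p2[[cl]]))
    expect_gt(agreement, 1 - 1e-8)
  }
})

test_that("projected components are mutually uncorrelated at the lag", {
  x <- make_ar1(20000, 0.9, seed = 11, d = 3)
  f <- tibble::tibble(trajectory = 1L, frame = seq_len(nrow(x)),
                      a = x[, 1], b = x[, 2], c = x[, 3])
  model <- tica(f, lag = 5)
  proj <- tica_project(f, model)
  P <- as.matrix(proj[c("tic_1", "tic_2", "tic_3")])
  n <- nrow(P)
  lagged <- crossprod(P[1:(n - 5), ], P[6:n, ]) / (n - 5)
  off <- lagged[upper.tri(lagged)]
  expect_lt(max(abs(off)), 3 / sqrt(n) * 3)
})

test_that("non-Gaussianity screening flags multimodality, not noise", {
  # type-I error: standard normal flagged in few seeds
  flagged <- vapply(1:20, function(s) {
    set.seed(s)
    p <- tibble::tibble(trajectory = 1L, frame = 1:2000, tic_1 = rnorm(2000))
    screen_components(p)$non_gaussian[1]
  }, logical(1))
  expect_lte(mean(flagged), 0.05)
  # power: well-separated bimodal mixture is always flagged
  set.seed(30)
  bim <- c(rnorm(1000, -3), rnorm(1000, 3))
  p <- tibble::tibble(trajectory = 1L, frame = seq_along(bim), tic_1 = bim)
  expect_true(screen_components(p)$non_gaussian[1])
  # degenerate constant component reported separately
  p$tic_2 <- 1
  sc <- screen_components(p)
  expect_true(sc$degenerate[sc$component == "tic_2"])
  expect_error(screen_components(p[1:50, ]), "100")
})

test_that("tICA models serialize losslessly to JSON", {
  x <- make_ar1(2000, 0.8, seed = 12, d = 2)
  f <- tibble::tibble(trajectory = 1L, frame = seq_len(nrow(x)),
                      a = x[, 1], b = x[, 2])
  model <- tica(f, lag = 3)
  path <- file.path(tempdir(), "tica.json")
  write_tica_json(model, path)
  back <- read_tica_json(path)
  expect_equal(back$values, model$values, tolerance = 1e-12)
  expect_equal(back$vectors, model$vectors, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$mean, model$mean, tolerance = 1e-12,
               ignore_attr = TRUE)
  p1 <- tica_project(f, model)
  p2 <- tica_project(f, back)
  expect_equal(p2$tic_1, p1$tic_1, tolerance = 1e-10)
  unlink(path)
})
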