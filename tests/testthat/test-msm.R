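test_that("transition counting enumerates pairs by hand", {
  expect_equal(count_transitions(c(1, 2, 1, 2, 2), lag = 1),
               matrix(c(0, 1, 2, 1), 2), ignore_attr = TRUE)
  # lag-2 pairs of 1,1,2,2: (s1,s3) = (1,2), (s2,s4) = (1,2)
  expect_equal(count_transitions(c(1, 1, 2, 2), lag = 2),
               matrix(c(0, 0, 2, 0), 2), ignore_attr = TRUE)
  # conservation at lag 1: total = frames - trajectories
  seqs <- list(sample(1:3, 40, TRUE), sample(1:3, 25, TRUE))
  C <- count_transitions(seqs, lag = 1, n_states = 3)
  expect_equal(sum(C), 40 + 25 - 2)
  # strided counting uses non-overlapping pairs
  Cs <- count_transitions(c(1, 1, 2, 2, 1), lag = 2, mode = "strided")
  expect_equal(sum(Cs), 2)
  expect_error(count_transitions(c(1, 2), lag = 5), "shorter")
})

test_that("TPM estimation matches hand arithmetic and detailed balance", {
  C <- matrix(c(0, 1, 2, 1), 2) # rows: [0,2; 1,1]
  est <- estimate_tpm(C)
  expect_equal(est$T, matrix(c(0, 0.6, 1, 0.4), 2), ignore_attr = TRUE)
  expect_equal(est$pi, c(0.375, 0.625))
  expect_equal(as.numeric(est$pi %*% est$T), est$pi, tolerance = 1e-12)
  expect_lt(max(abs(est$pi * est$T - t(est$pi * est$T))), 1e-12)
  # symmetric counts: T is the row-normalized counts
  Cs <- matrix(c(4, 2, 2, 6), 2)
  est2 <- estimate_tpm(Cs)
  expect_equal(est2$T, Cs / rowSums(Cs), ignore_attr = TRUE)
  # block-diagonal counts: only the heavier block is kept
  Cb <- matrix(0, 4, 4)
  Cb[1:2, 1:2] <- 10
  Cb[3:4, 3:4] <- 1
  est3 <- suppressMessages(estimate_tpm(Cb))
  expect_equal(est3$active, 1:2)
  expect_error(estimate_tpm(matrix(0, 2, 2)), "empty")
})

test_that("the eigensystem matches closed forms and a dense solver", {
  T <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)
  es <- msm_eigensystem(T)
  expect_equal(es$values, c(1, 0.7), tolerance = 1e-12)
  expect_equal(es$left[, 1], c(2 / 3, 1 / 3), tolerance = 1e-10)
  expect_equal(msm_eigensystem(diag(3))$values, rep(1, 3))
  for (seed in 1:5) {
    Tr <- random_reversible_tpm(12, seed = seed)
    es <- msm_eigensystem(Tr)
    oracle <- sort(Re(eigen(Tr)$values), decreasing = TRUE)
    expect_equal(es$values, oracle, tolerance = 1e-8)
    # right eigenvectors satisfy T r = lambda r
    for (j in 1:12) {
      expect_lt(max(abs(Tr %*% es$right[, j] -
                          es$values[j] * es$right[, j])), 1e-8)
    }
  }
  # a clearly non-reversible matrix is rejected
  Tnr <- matrix(c(0, 1, 0, 0, 0, 1, 1, 0, 0), 3, byrow = TRUE)
  expect_error(msm_eigensystem(Tnr), "Detailed balance")
})

test_that("implied timescales follow the defining relation", {
  expect_equal(implied_timescales(exp(-1), 48), 48, tolerance = 1e-12)
  expect_equal(implied_timescales(0.7, 1), 2.803673, tolerance = 1e-6)
  # monotone increasing in lambda, diverging toward 1
  ls <- c(0.2, 0.5, 0.9, 0.99, 0.999)
  ts <- implied_timescales(ls, 10)
  expect_true(all(diff(ts) > 0))
  expect_identical(implied_timescales(1, 10), Inf)
  expect_true(is.na(implied_timescales(-0.1, 10)))
})

test_that("pi from row sums equals the left Perron eigenvector", {
  ch <- ground_truth_chain(random_reversible_tpm(5, seed = 3))
  seqs <- simulate_chain_ensemble(ch, 5, 3000, seed = 4)
  C <- count_transitions(seqs, lag = 1, n_states = 5)
  est <- estimate_tpm(C)
  perron <- ionrelease:::stationary_distribution(est$T)
  expect_equal(est$pi, perron, tolerance = 1e-10)
})

test_that("Chapman-Kolmogorov holds for Markovian data", {
  T <- matrix(c(0.95, 0.05, 0, 0.05, 0.9, 0.05, 0, 0.1, 0.9), 3,
              byrow = TRUE)
  ch <- ground_truth_chain(T)
  seqs <- simulate_chain_ensemble(ch, 20, 5000, seed = 6)
  C1 <- count_transitions(seqs, lag = 4, n_states = 3)
  C2 <- count_transitions(seqs, lag = 8, n_states = 3)
  T1 <- estimate_tpm(C1)$T
  T2 <- estimate_tpm(C2)$T
  expect_lt(max(abs(T2 - T1 %*% T1)), 0.02)
})

test_that("the timescale of a known chain is recovered across lags", {
  T <- matrix(c(0.98, 0.02, 0, 0.03, 0.94, 0.03, 0, 0.02, 0.98), 3,
              byrow = TRUE)
  ch <- ground_truth_chain(T)
  tau_true <- -1 / log(sort(eigen(T)$values, decreasing = TRUE)[2])
  seqs <- simulate_chain_ensemble(ch, 20, 8000, seed = 8)
  asg <- tibble::tibble(
    trajectory = rep(seq_along(seqs), lengths(seqs)),
    frame = unlist(lapply(seqs, seq_along)),
    state = unlist(seqs)
  )
  scan <- implied_timescale_scan(asg, lags = c(1, 2, 5, 10), n_modes = 2,
                                 n_boot = 5, seed = 9)
  t1 <- scan$scan$timescale_ns[scan$scan$mode == 1]
  expect_true(all(abs(t1 - tau_true) / tau_true < 0.2))
  expect_lt(scan$flatness, 0.25)
})

test_that("hidden-state lumping inflates timescales with lag", {
  # 3-state chain observed through a 2-state lumping is non-Markovian:
  # the apparent slowest timescale grows with lag toward the true one
  T <- matrix(c(0.9, 0.1, 0, 0.1, 0.8, 0.1, 0, 0.1, 0.9), 3, byrow = TRUE)
  ch <- ground_truth_chain(T)
  seqs <- simulate_chain_ensemble(ch, 20, 6000, seed = 10)
  lump <- function(s) ifelse(s <= 2, 1L, 2L)
  asg <- tibble::tibble(
    trajectory = rep(seq_along(seqs), lengths(seqs)),
    frame = unlist(lapply(seqs, seq_along)),
    state = unlist(lapply(seqs, lump))
  )
  scan <- implied_timescale_scan(asg, lags = c(1, 4, 16), n_modes = 1,
                                 n_boot = 0, seed = NULL)
  t1 <- scan$scan$timescale_ns[scan$scan$mode == 1]
  expect_gt(t1[2], t1[1])
  expect_gt(t1[3], t1[2])
})

test_that("k-means microstates recover well-separated clouds", {
  set.seed(12)
  proj <- tibble::tibble(
    trajectory = 1L, frame = 1:400,
    tic_1 = c(rnorm(200, -4, 0.3), rnorm(200, 4, 0.3)),
    tic_2 = rnorm(400, 0, 0.3)
  )
  cl <- cluster_microstates(proj, k = 2, seed = 13)
  centers <- sort(cl$centers[, 1])
  expect_equal(unname(centers), c(-4, 4), tolerance = 0.1)
  lab <- cl$assignments$state[1:200]
  expect_equal(length(unique(lab)), 1) # pure labels per cloud
  # determinism
  cl2 <- cluster_microstates(proj, k = 2, seed = 13)
  expect_identical(cl$assignments$state, cl2$assignments$state)
  # k = number of distinct points -> zero inertia
  pts <- tibble::tibble(trajectory = 1L, frame = 1:3,
                        tic_1 = c(0, 1, 2), tic_2 = c(0, 1, 0))
  cl3 <- cluster_microstates(pts, k = 3, seed = 1)
  d <- sqrt(rowSums((as.matrix(pts[c("tic_1", "tic_2")]) -
                       cl3$centers[cl3$assignments$state, ])^2))
  expect_equal(max(d), 0, tolerance = 1e-12)
})

test_that("bootstrap error bars vanish when resampling the full data once", {
  ch <- ground_truth_chain(matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE))
  s <- simulate_chain(ch, 4000, seed = 14)
  asg <- tibble::tibble(trajectory = 1L, frame = seq_along(s), state = s)
  scan <- implied_timescale_scan(asg, lags = c(1, 2), n_modes = 1,
                                 n_boot = 1, seed = 15)
  # with a single trajectory, resampling returns the same data
  expect_equal(scan$scan$ci_lo, scan$scan$timescale_ns, tolerance = 1e-10)
  expect_equal(scan$scan$ci_hi, scan$scan$timescale_ns, tolerance = 1e-10)
})

test_that("markov models serialize losslessly to JSON", {
  ch <- ground_truth_chain(random_reversible_tpm(4, seed = 16))
  seqs <- simulate_chain_ensemble(ch, 3, 2000, seed = 17)
  asg <- tibble::tibble(
    trajectory = rep(seq_along(seqs), lengths(seqs)),
    frame = unlist(lapply(seqs, seq_along)),
    state = unlist(seqs)
  )
  m <- markov_model(asg, lag = 2, stride = 0.5)
  path <- file.path(tempdir(), "msm.json")
  write_msm_json(m, path)
  back <- read_msm_json(path)
  expect_equal(back$T, m$T, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$pi, m$pi, tolerance = 1e-12)
  expect_equal(back$timescales_ns, m$timescales_ns, tolerance = 1e-12)
  unlink(path)
})
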