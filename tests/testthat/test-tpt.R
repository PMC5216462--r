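nearest_neighbor_walk <- function(k) {
  T <- matrix(0, k, k)
  for (i in 2:(k - 1)) T[i, c(i - 1, i + 1)] <- 0.5
  T[1, 2] <- 1
  T[k, k - 1] <- 1
  T
}

test_that("the committor solves the gambler's-ruin walk exactly", {
  T <- nearest_neighbor_walk(5)
  q <- committor(T, 1, 5)
  expect_equal(q, c(0, 0.25, 0.5, 0.75, 1), tolerance = 1e-12)
  expect_equal(q[1], 0)
  expect_equal(q[5], 1)
})

test_that("committor input validation and dead ends are caught", {
  T <- nearest_neighbor_walk(4)
  expect_error(committor(T, 1, 1), "disjoint")
  expect_error(committor(T, integer(0), 2), "non-empty")
  Tb <- diag(4) # no state can move
  expect_error(committor(Tb, 1, 4), "no path")
})

test_that("committor matches Monte-Carlo first-visit estimates", {
  Tr <- random_reversible_tpm(6, seed = 5)
  q <- committor(Tr, 1, 6)
  cum <- t(apply(Tr, 1, cumsum))
  set.seed(6)
  n_rep <- 3000
  for (s0 in 2:5) {
    hits <- 0
    for (r in seq_len(n_rep)) {
      s <- s0
      repeat {
        s <- 1L + findInterval(runif(1), cum[s, ], left.open = TRUE)
        if (s == 1L) break
        if (s == 6L) {
          hits <- hits + 1
          break
        }
      }
    }
    phat <- hits / n_rep
    sigma <- sqrt(q[s0] * (1 - q[s0]) / n_rep)
    expect_lt(abs(phat - q[s0]), 3.5 * sigma + 1e-3)
  }
})

test_that("the 3-state chain flux matches the hand-solved oracle", {
  T <- matrix(c(0.5, 0.5, 0, 0.25, 0.5, 0.25, 0, 0.5, 0.5), 3,
              byrow = TRUE)
  fd <- flux_matrix(T, 1, 3)
  expect_equal(fd$pi, c(0.25, 0.5, 0.25), tolerance = 1e-12)
  expect_equal(fd$committor, c(0, 0.5, 1), tolerance = 1e-12)
  expect_equal(fd$net_flux[1, 2], 0.0625, tolerance = 1e-12)
  expect_equal(fd$net_flux[2, 3], 0.0625, tolerance = 1e-12)
  expect_equal(fd$total_flux, 0.0625, tolerance = 1e-12)
})

test_that("flux conservation and two-cycle freeness hold generally", {
  for (seed in 1:10) {
    k <- sample(5:15, 1)
    Tr <- random_reversible_tpm(k, seed = seed)
    src <- 1:2
    tgt <- (k - 1):k
    fd <- flux_matrix(Tr, src, tgt)
    expect_true(all(fd$committor >= 0 & fd$committor <= 1))
    expect_equal(fd$committor[src], rep(0, 2))
    expect_equal(fd$committor[tgt], rep(1, 2))
    # no two-cycles in the net flux
    expect_equal(max(fd$net_flux * t(fd$net_flux)), 0)
    # Kirchhoff balance at interior nodes
    interior <- setdiff(seq_len(k), c(src, tgt))
    for (i in interior) {
      expect_lt(abs(sum(fd$net_flux[, i]) - sum(fd$net_flux[i, ])), 1e-10)
    }
    # flux out of the source equals flux into the target
    out_src <- sum(fd$net_flux[src, setdiff(seq_len(k), src)])
    in_tgt <- sum(fd$net_flux[setdiff(seq_len(k), tgt), tgt])
    expect_equal(out_src, in_tgt, tolerance = 1e-10)
    expect_equal(fd$total_flux, out_src, tolerance = 1e-12)
  }
})

test_that("an unreachable target propagates a committor error", {
  T <- matrix(0, 4, 4)
  T[1:2, 1:2] <- 0.5
  T[3:4, 3:4] <- 0.5
  expect_error(flux_matrix(T, 1, 4), "no path")
})

test_that("a single linear chain carries all flux on one path", {
  T <- nearest_neighbor_walk(4)
  fd <- flux_pathways(T, 1, 4, n_paths = 3)
  expect_equal(nrow(fd$paths), 1)
  expect_equal(fd$paths$path[[1]], 1:4)
  expect_equal(fd$paths$cumulative_fraction, 1, tolerance = 1e-10)
})

test_that("parallel branches rank by their net flux", {
  F <- matrix(0, 4, 4)
  F[1, 2] <- 0.6
  F[2, 4] <- 0.6
  F[1, 3] <- 0.4
  F[3, 4] <- 0.4
  paths <- top_paths(F, 1, 4, n_paths = 5, total_flux = 1)
  expect_equal(paths$flux, c(0.6, 0.4))
  expect_equal(paths$path[[1]], c(1, 2, 4))
  expect_equal(paths$path[[2]], c(1, 3, 4))
  expect_equal(paths$cumulative_fraction[2], 1, tolerance = 1e-12)
  # non-increasing path fluxes is a structural invariant
  expect_true(all(diff(paths$flux) <= 1e-12))
})

test_that("path decomposition equals exhaustive enumeration on DAGs", {
  for (seed in 1:30) {
    n <- sample(4:8, 1)
    F <- random_dag_flux(seed, n)
    total <- sum(F[1, ])
    got <- top_paths(F, 1, n, n_paths = 6, total_flux = total)
    want <- brute_path_decomposition(F, 1, n, 6)
    expect_equal(nrow(got), length(want))
    for (i in seq_along(want)) {
      expect_equal(got$flux[i], want[[i]]$flux, tolerance = 1e-12)
      expect_equal(got$path[[i]], want[[i]]$path)
    }
  }
})

test_that("sign-based lumping splits a two-block metastable chain", {
  blocks <- matrix(0.001, 6, 6)
  blocks[1:3, 1:3] <- 1
  blocks[4:6, 4:6] <- 1
  T <- (blocks + t(blocks)) / 2
  T <- T / rowSums(T)
  es <- msm_eigensystem(T)
  lump <- pcca_lump(es, n_macro = 2,
                    pi = ionrelease:::stationary_distribution(T))
  expect_equal(length(unique(lump$labels)), 2)
  expect_equal(length(unique(lump$labels[1:3])), 1)
  expect_equal(length(unique(lump$labels[4:6])), 1)
  expect_false(lump$labels[1] == lump$labels[4])
})

test_that("lumping degenerates gracefully", {
  Tr <- random_reversible_tpm(5, seed = 12)
  es <- msm_eigensystem(Tr)
  # one macrostate per microstate is the identity map
  lump <- pcca_lump(es, n_macro = 5,
                    pi = ionrelease:::stationary_distribution(Tr))
  expect_equal(sort(unique(lump$labels)), 1:5)
  expect_equal(length(unique(lump$labels)), 5)
})

test_that("macro aggregation conserves the total flux", {
  Tr <- random_reversible_tpm(9, seed = 13)
  fd <- flux_pathways(Tr, 1:2, 8:9, n_paths = 5)
  # identity map reproduces the micro table
  ident <- macro_flux_report(fd, 1:9, n_paths = 5)
  expect_equal(ident$macro_flux, unname(fd$net_flux), tolerance = 1e-12)
  # a coarse partition conserves total flux across the source cut
  labels <- c(1, 1, 2, 2, 2, 3, 3, 4, 4)
  mac <- macro_flux_report(fd, labels, n_paths = 5)
  out_src <- sum(mac$macro_flux[1, -1])
  micro_out <- sum(fd$net_flux[1:2, 3:9])
  expect_equal(out_src, micro_out, tolerance = 1e-12)
})

test_that("flux reports serialize to JSON", {
  T <- nearest_neighbor_walk(5)
  fd <- flux_pathways(T, 1, 5, n_paths = 2)
  path <- file.path(tempdir(), "flux.json")
  write_flux_json(fd, path)
  got <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(got$total_flux, fd$total_flux, tolerance = 1e-12)
  expect_equal(got$paths$nodes[[1]], 1:5)
  unlink(path)
})
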