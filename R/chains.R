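#' Ground-truth discrete Markov chain
#'
#' Bundles a row-stochastic transition matrix with its stationary
#' distribution, the physical time represented by one step, and a
#' mechanistic tag per state (`"bound"`, `"intermediate"`, `"released"`).
#' Chains built this way stand in for trajectory ensembles whose kinetics
#' are known exactly, so every downstream estimator can be checked against
#' closed-form answers.
#'
#' @param transition_matrix Square numeric matrix; rows must sum to 1.
#' @param lag_unit Physical time per step in nanoseconds.
#' @param labels Character vector, one tag per state, from
#'   `c("bound", "intermediate", "released")`. Recycled if length 1.
#' @return An object of class `gt_chain` with elements
#'   `transition_matrix`, `stationary_dist`, `lag_unit`, `labels`.
#' @examples
#' ch <- ground_truth_chain(matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE))
#' ch$stationary_dist
#' @export
ground_truth_chain <- function(transition_matrix, lag_unit = 1,
                               labels = "bound") {
  assert_stochastic(transition_matrix)
  assert_scalar_number(lag_unit, "lag_unit", lower = 1e-12)
  k <- nrow(transition_matrix)
  labels <- rep_len(as.character(labels), k)
  bad <- setdiff(unique(labels), c("bound", "intermediate", "released"))
  if (length(bad)) {
    abort(paste0("Unknown state labels: ", paste(bad, collapse = ", ")))
  }
  # Exact renormalization so invariants hold to 1e-12, not just input tol.
  T <- transition_matrix / rowSums(transition_matrix)
  structure(
    list(
      transition_matrix = T,
      stationary_dist = stationary_distribution(T),
      lag_unit = lag_unit,
      labels = labels
    ),
    class = "gt_chain"
  )
}

#' @export
print.gt_chain <- function(x, ...) {
  cat(sprintf(
    "<gt_chain> %d states, lag unit %g ns, labels: %s\n",
    nrow(x$transition_matrix), x$lag_unit,
    paste(unique(x$labels), collapse = "/")
  ))
  invisible(x)
}

#' Simulate a state sequence from a ground-truth chain
#'
#' Draws a realization of the Markov chain. With a fixed seed the result is
#' bit-reproducible; the empirical transition frequencies converge to the
#' chain's transition matrix at the usual `1/sqrt(n)` rate.
#'
#' @param chain A [ground_truth_chain()].
#' @param n_steps Number of states in the returned sequence (>= 1).
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param start Starting state index (1-based). Default: drawn from the
#'   stationary distribution.
#' @return Integer vector of length `n_steps` with values in `1:k`.
#' @examples
#' ch <- ground_truth_chain(matrix(c(0, 1, 1, 0), 2, byrow = TRUE))
#' simulate_chain(ch, 4, seed = 1, start = 1) # alternates 1,2,1,2
#' @export
simulate_chain <- function(chain, n_steps, seed = NULL, start = NULL) {
  if (!inherits(chain, "gt_chain")) abort("`chain` must be a `gt_chain`.")
  n_steps <- assert_count(n_steps, "n_steps")
  T <- chain$transition_matrix
  k <- nrow(T)
  cum <- t(apply(T, 1, cumsum))
  cum[, k] <- 1 # guard against rounding at the top end
  with_seed(seed, {
    s <- integer(n_steps)
    s[1] <- if (is.null(start)) {
      sample.int(k, 1, prob = chain$stationary_dist)
    } else {
      assert_count(start, "start")
    }
    if (n_steps > 1) {
      u <- runif(n_steps - 1)
      for (t in seq_len(n_steps - 1)) {
        s[t + 1] <- 1L + findInterval(u[t], cum[s[t], ], left.open = TRUE)
      }
    }
    s
  })
}

#' Simulate an ensemble of chain trajectories
#'
#' Convenience wrapper drawing `n_traj` independent realizations; each
#' trajectory gets its own sub-seed derived deterministically from `seed`.
#'
#' @inheritParams simulate_chain
#' @param n_traj Number of trajectories.
#' @return A list of integer vectors, one per trajectory.
#' @export
simulate_chain_ensemble <- function(chain, n_traj, n_steps, seed = NULL,
                                    start = NULL) {
  n_traj <- assert_count(n_traj, "n_traj")
  seeds <- derive_seeds(seed, n_traj)
  lapply(seq_len(n_traj), function(i) {
    simulate_chain(chain, n_steps, seed = seeds[i], start = start)
  })
}

# Deterministic stream of sub-seeds below 2^31.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

#' Random reversible transition matrix
#'
#' Builds a row-stochastic matrix satisfying detailed balance by
#' symmetrizing a random positive count matrix — useful as a test bed for
#' estimators whose guarantees assume reversibility.
#'
#' @param k Number of states.
#' @param seed Integer seed or `NULL`.
#' @param sparsity Fraction of off-diagonal entries forced to zero
#'   (kept connected).
#' @return A `k x k` row-stochastic reversible matrix.
#' @export
random_reversible_tpm <- function(k, seed = NULL, sparsity = 0) {
  k <- assert_count(k, "k", lower = 2L)
  assert_scalar_number(sparsity, "sparsity", 0, 0.9)
  with_seed(seed, {
    C <- matrix(runif(k * k, 0.05, 1), k, k)
    if (sparsity > 0) {
      mask <- matrix(runif(k * k) < sparsity, k, k)
      mask[cbind(seq_len(k), seq_len(k))] <- FALSE
      # keep a connected backbone
      mask[cbind(seq_len(k - 1), seq_len(k - 1) + 1L)] <- FALSE
      C[mask] <- 0
    }
    S <- (C + t(C)) / 2
    S / rowSums(S)
  })
}
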