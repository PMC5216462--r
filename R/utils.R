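# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name, lower, upper, x))
  }
  invisible(x)
}

assert_count <- function(x, name, lower = 1L) {
  assert_scalar_number(x, name, lower = lower)
  if (x != round(x)) abort(sprintf("`%s` must be an integer.", name))
  invisible(as.integer(x))
}

# Validate that `T` is a square row-stochastic matrix.
assert_stochastic <- function(T, name = "transition_matrix", tol = 1e-8) {
  if (!is.matrix(T) || nrow(T) != ncol(T)) {
    abort(sprintf("`%s` must be a square matrix.", name))
  }
  if (any(!is.finite(T)) || any(T < -tol)) {
    abort(sprintf("`%s` must have non-negative finite entries.", name))
  }
  rs <- rowSums(T)
  if (any(abs(rs - 1) > tol)) {
    abort(sprintf(
      "`%s` rows must sum to 1 (max deviation %.3g).", name, max(abs(rs - 1))
    ))
  }
  invisible(T)
}

# Stationary distribution of a row-stochastic matrix (left Perron vector).
stationary_distribution <- function(T) {
  assert_stochastic(T)
  e <- eigen(t(T))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  if (any(v < -1e-10)) abort("Perron vector has negative entries; matrix not irreducible?")
  pmax(v, 0) / sum(pmax(v, 0))
}

euclid <- function(a, b) sqrt(sum((a - b)^2))

# Row-wise Euclidean norms of a matrix.
row_norms <- function(m) sqrt(rowSums(m * m))
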