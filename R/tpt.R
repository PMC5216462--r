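# Transition path theory: committor, reactive flux, iterative
# bottleneck-path decomposition, and spectral (sign-based) lumping of
# microstates into macrostates.

#' Forward committor of a Markov chain
#'
#' Probability of visiting the target set before the source set, from each
#' state: `q = 0` on the source, `q = 1` on the target, and on interior
#' states `q_i = sum_j T_ij q_j` (a linear boundary-value system).
#'
#' @param T Row-stochastic transition matrix.
#' @param source,target Disjoint non-empty index sets.
#' @return Numeric committor vector in `[0, 1]`.
#' @examples
#' T <- matrix(0, 5, 5)
#' for (i in 2:4) T[i, i - 1] <- T[i, i + 1] <- 0.5
#' T[1, 2] <- 1; T[5, 4] <- 1
#' committor(T, 1, 5) # 0, 0.25, 0.5, 0.75, 1
#' @export
committor <- function(T, source, target) {
  assert_stochastic(T)
  k <- nrow(T)
  source <- unique(as.integer(source)); target <- unique(as.integer(target))
  if (!length(source) || !length(target)) {
    abort("`source` and `target` must be non-empty.")
  }
  if (length(intersect(source, target))) {
    abort("`source` and `target` must be disjoint.")
  }
  interior <- setdiff(seq_len(k), c(source, target))
  q <- numeric(k)
  q[target] <- 1
  g <- igraph::graph_from_adjacency_matrix(T > 0, mode = "directed")
  # a target no source can reach leaves zero reactive probability current
  src_reach <- igraph::distances(g, v = source, to = target, mode = "out")
  if (all(!is.finite(src_reach))) {
    abort("Target set has no path from the source set.")
  }
  if (length(interior)) {
    # states that cannot reach either boundary make the system singular
    reach <- igraph::distances(g, v = interior, to = c(source, target),
                               mode = "out")
    dead <- interior[apply(reach, 1, function(r) all(!is.finite(r)))]
    if (length(dead)) {
      abort(paste0("State(s) with no path to source or target: ",
                   paste(dead, collapse = ", ")))
    }
    A <- diag(length(interior)) - T[interior, interior, drop = FALSE]
    b <- T[interior, target, drop = FALSE] %*% rep(1, length(target))
    q[interior] <- as.numeric(solve(A, b))
  }
  pmin(pmax(q, 0), 1)
}

#' Reactive flux matrices
#'
#' Builds the gross reactive flux
#' `f_ij = pi_i (1 - q_i) T_ij q_j` (i != j), the net flux
#' `f+_ij = max(0, f_ij - f_ji)`, and the total reactive flux across the
#' source cut. Flux is conserved at every interior node.
#'
#' @param T Row-stochastic transition matrix.
#' @param pi Stationary distribution (computed if `NULL`).
#' @param source,target Index sets (as in [committor()]).
#' @return An object of class `flux_decomposition` (without paths; see
#'   [top_paths()] / [flux_pathways()]).
#' @export
flux_matrix <- function(T, source, target, pi = NULL) {
  q <- committor(T, source, target)
  pi <- pi %||% stationary_distribution(T)
  k <- nrow(T)
  f <- (pi * (1 - q)) %o% q * T
  diag(f) <- 0
  fnet <- pmax(f - t(f), 0)
  total <- sum(fnet[source, setdiff(seq_len(k), source), drop = FALSE])
  structure(
    list(source = sort(unique(as.integer(source))),
         target = sort(unique(as.integer(target))),
         committor = q, gross_flux = f, net_flux = fnet,
         total_flux = total, pi = pi, paths = NULL),
    class = "flux_decomposition"
  )
}

#' @export
print.flux_decomposition <- function(x, ...) {
  cat(sprintf(
    "<flux_decomposition> %d states, total flux %.4g%s\n",
    nrow(x$net_flux), x$total_flux,
    if (is.null(x$paths)) "" else sprintf(", %d paths", nrow(x$paths))
  ))
  invisible(x)
}

# Widest (maximum-bottleneck) path from any source to any target on a
# weighted graph, Dijkstra-style. Returns NULL when no path carries flux.
widest_path <- function(F, source, target) {
  k <- nrow(F)
  width <- rep(-Inf, k)
  prev <- rep(NA_integer_, k)
  width[source] <- Inf
  visited <- rep(FALSE, k)
  repeat {
    cand <- which(!visited & width > 0)
    if (!length(cand)) break
    u <- cand[which.max(width[cand])]
    visited[u] <- TRUE
    if (u %in% target) break
    for (v in which(F[u, ] > 0)) {
      w <- min(width[u], F[u, v])
      if (w > width[v]) {
        width[v] <- w
        prev[v] <- u
      }
    }
  }
  reached <- target[is.finite(width[target]) & width[target] > 0]
  if (!length(reached)) return(NULL)
  end <- reached[which.max(width[reached])]
  path <- end
  while (!path[1] %in% source) {
    path <- c(prev[path[1]], path)
  }
  list(path = path, flux = width[end])
}

# Canonical representative among all paths attaining the maximal
# bottleneck W: restrict to edges carrying >= W, take a shortest path,
# and break remaining ties lexicographically. Deterministic, so an
# exhaustive enumeration lands on the same decomposition.
canonical_bottleneck_path <- function(F, source, target, W) {
  k <- nrow(F)
  A <- F >= W & F > 0
  # reverse BFS: hop distance to the nearest target on the subgraph
  dist <- rep(Inf, k)
  dist[target] <- 0
  frontier <- target
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      for (u in which(A[, v])) {
        if (dist[u] > dist[v] + 1) {
          dist[u] <- dist[v] + 1
          nxt <- c(nxt, u)
        }
      }
    }
    frontier <- unique(nxt)
  }
  starts <- source[is.finite(dist[source])]
  if (!length(starts)) return(NULL)
  s <- min(starts[dist[starts] == min(dist[starts])])
  path <- s
  u <- s
  while (!u %in% target || dist[u] > 0) {
    nbr <- which(A[u, ] & dist[seq_len(k)] == dist[u] - 1)
    u <- min(nbr)
    path <- c(path, u)
  }
  path
}

#' Iterative bottleneck-path decomposition of a net flux matrix
#'
#' Repeatedly finds the source-to-target path whose bottleneck (minimum
#' edge flux) is maximal, records it with its bottleneck flux, subtracts
#' that flux from every edge on the path (zeroing the bottleneck edge),
#' and repeats — the standard iterative Dijkstra decomposition of the
#' reactive flux into ranked pathways. Equal-bottleneck ties (common
#' after subtraction) are resolved canonically: the shortest, then
#' lexicographically smallest, max-bottleneck path. Set
#' `remove = "edges"` to delete whole path edges instead of subtracting.
#'
#' @param net_flux Non-negative net flux matrix.
#' @param source,target Index sets.
#' @param n_paths Maximum number of paths.
#' @param total_flux Normalizer for cumulative fractions (default: flux
#'   across the source cut).
#' @param remove `"subtract"` (default) or `"edges"`.
#' @return A tibble: `rank`, `path` (list of integer vectors), `flux`,
#'   `fraction`, `cumulative_fraction`.
#' @export
top_paths <- function(net_flux, source, target, n_paths = 7,
                      total_flux = NULL, remove = c("subtract", "edges")) {
  remove <- match.arg(remove)
  n_paths <- assert_count(n_paths, "n_paths")
  F <- as.matrix(net_flux)
  k <- nrow(F)
  source <- unique(as.integer(source)); target <- unique(as.integer(target))
  total_flux <- total_flux %||%
    sum(F[source, setdiff(seq_len(k), source), drop = FALSE])
  rows <- list()
  tol <- max(total_flux, .Machine$double.eps) * 1e-12
  for (r in seq_len(n_paths)) {
    wp <- widest_path(F, source, target)
    if (is.null(wp) || wp$flux <= tol) {
      if (r <= n_paths) inform(sprintf(
        "Flux exhausted after %d path(s).", r - 1L
      ))
      break
    }
    # among equal-bottleneck paths pick the canonical (shortest, then
    # lexicographically smallest) representative
    pth <- canonical_bottleneck_path(F, source, target, wp$flux) %||%
      wp$path
    rows[[r]] <- tibble(rank = r, path = list(pth), flux = wp$flux)
    edges <- cbind(pth[-length(pth)], pth[-1])
    if (remove == "subtract") {
      F[edges] <- pmax(0, F[edges] - wp$flux)
    } else {
      F[edges] <- 0
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    return(tibble(rank = integer(), path = list(), flux = numeric(),
                  fraction = numeric(), cumulative_fraction = numeric()))
  }
  out$fraction <- out$flux / total_flux
  out$cumulative_fraction <- cumsum(out$fraction)
  out
}

#' Full TPT decomposition with ranked pathways
#'
#' @param T Row-stochastic TPM.
#' @param source,target Index sets.
#' @param pi Stationary distribution (optional).
#' @param n_paths Number of ranked pathways extracted.
#' @return A `flux_decomposition` whose `paths` field is the [top_paths()]
#'   table.
#' @export
flux_pathways <- function(T, source, target, pi = NULL, n_paths = 7) {
  fd <- flux_matrix(T, source, target, pi = pi)
  fd$paths <- top_paths(fd$net_flux, fd$source, fd$target,
                        n_paths = n_paths, total_flux = fd$total_flux)
  fd
}

#' @export
tidy.flux_decomposition <- function(x, ...) {
  if (is.null(x$paths) || !nrow(x$paths)) {
    return(tibble(rank = integer(), path = character(), flux = numeric(),
                  fraction = numeric(), cumulative_fraction = numeric()))
  }
  mutate(x$paths,
         path = vapply(.data$path, paste, character(1), collapse = " -> "))
}

#' @export
glance.flux_decomposition <- function(x, ...) {
  tibble(
    n_states = nrow(x$net_flux),
    total_flux = x$total_flux,
    n_paths = if (is.null(x$paths)) 0L else nrow(x$paths),
    flux_fraction_decomposed = if (is.null(x$paths) || !nrow(x$paths)) 0 else
      max(x$paths$cumulative_fraction)
  )
}

#' @export
autoplot.flux_decomposition <- function(object, ...) {
  df <- tibble(
    from = rep(seq_len(nrow(object$net_flux)), times = ncol(object$net_flux)),
    to = rep(seq_len(ncol(object$net_flux)), each = nrow(object$net_flux)),
    flux = as.vector(object$net_flux)
  ) %>% filter(.data$flux > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$to, y = .data$from,
                                   fill = .data$flux)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(trans = "log10") +
    ggplot2::labs(x = "to state", y = "from state", fill = "net flux") +
    ggplot2::theme_minimal()
}

#' Sign-based spectral lumping of microstates into macrostates
#'
#' Groups microstates by the sign pattern of the dominant (non-Perron)
#' right eigenvectors of the TPM — microstates sharing the signs of the
#' slow modes have similar kinetics. The smallest number of eigenvectors
#' giving at least `n_macro` distinct patterns is used; surplus patterns
#' are merged into exactly `n_macro` groups by agglomerating the
#' smallest-population pattern into its nearest (Hamming) neighbor, ties
#' broken by the Euclidean distance between the patterns'
#' population-weighted mean eigenvector coordinates (states straddling a
#' basin have a near-zero, hence noisy-signed, slow-mode entry; the
#' coordinate tie-break reunites them with their kinetic kin). This
#' deterministic sign rule is a deliberate simplification of
#' simplex-optimization PCCA+.
#'
#' @param eigensystem Result of [msm_eigensystem()] (or a `markov_model`).
#' @param n_macro Number of macrostates requested.
#' @param pi Stationary distribution for population weighting (taken from
#'   the model when available).
#' @return A list with `labels` (per-microstate macrostate index,
#'   `1..n_macro`) and `n_macro` (possibly reduced, with a message).
#' @export
pcca_lump <- function(eigensystem, n_macro, pi = NULL) {
  n_macro <- assert_count(n_macro, "n_macro", lower = 1L)
  if (inherits(eigensystem, "markov_model")) {
    pi <- pi %||% eigensystem$pi
    es <- list(values = eigensystem$values, right = eigensystem$right)
  } else {
    es <- eigensystem
  }
  R <- es$right
  k <- nrow(R)
  pi <- pi %||% rep(1 / k, k)
  if (n_macro >= k) {
    return(list(labels = seq_len(k), n_macro = k))
  }
  max_m <- ncol(R) - 1L
  signs_of <- function(m) {
    S <- sign(R[, 1L + seq_len(m), drop = FALSE])
    S[S == 0] <- 1
    S
  }
  m <- 1L
  while (m < max_m &&
         nrow(unique(signs_of(m))) < n_macro) {
    m <- m + 1L
  }
  S <- signs_of(m)
  key <- apply(S, 1, paste, collapse = ",")
  pats <- unique(key)
  if (length(pats) < n_macro) {
    inform(sprintf(
      "Only %d distinct sign patterns available; n_macro reduced from %d.",
      length(pats), n_macro
    ))
    n_macro <- length(pats)
  }
  # merge smallest-population patterns into their Hamming-nearest neighbor
  # (ties resolved by distance between pattern-mean eigenvector coordinates)
  coords <- R[, 1L + seq_len(m), drop = FALSE]
  pat_rows <- lapply(pats, function(p) which(key == p))
  pat_sign <- do.call(rbind, lapply(pat_rows, function(ix) S[ix[1], ]))
  pat_pop <- vapply(pat_rows, function(ix) sum(pi[ix]), numeric(1))
  pat_mean <- do.call(rbind, lapply(pat_rows, function(ix) {
    w <- pi[ix] / sum(pi[ix])
    colSums(coords[ix, , drop = FALSE] * w)
  }))
  while (length(pat_rows) > n_macro) {
    i <- which.min(pat_pop)
    hd <- rowSums(pat_sign != matrix(pat_sign[i, ], nrow(pat_sign),
                                     ncol(pat_sign), byrow = TRUE))
    hd[i] <- Inf
    cand <- which(hd == min(hd))
    if (length(cand) > 1) {
      dd <- rowSums((pat_mean[cand, , drop = FALSE] -
                       matrix(pat_mean[i, ], length(cand), ncol(pat_mean),
                              byrow = TRUE))^2)
      cand <- cand[which.min(dd)]
    }
    j <- cand[1]
    w_i <- pat_pop[i]; w_j <- pat_pop[j]
    pat_mean[j, ] <- (w_i * pat_mean[i, ] + w_j * pat_mean[j, ]) /
      (w_i + w_j)
    pat_rows[[j]] <- c(pat_rows[[j]], pat_rows[[i]])
    pat_pop[j] <- pat_pop[j] + pat_pop[i]
    pat_rows[[i]] <- NULL
    pat_sign <- pat_sign[-i, , drop = FALSE]
    pat_pop <- pat_pop[-i]
    pat_mean <- pat_mean[-i, , drop = FALSE]
  }
  labels <- integer(k)
  for (g in seq_along(pat_rows)) labels[pat_rows[[g]]] <- g
  list(labels = labels, n_macro = length(pat_rows))
}

#' Macrostate-level flux aggregation and pathway report
#'
#' Aggregates the microstate net flux over macrostate pairs (conserving
#' the total flux exactly) and re-runs the bottleneck-path decomposition
#' on the macrostate graph.
#'
#' @param flux A `flux_decomposition` (microstate level).
#' @param labels Per-microstate macrostate labels (e.g.
#'   `pcca_lump(...)$labels`).
#' @param n_paths Number of macro pathways.
#' @param macro_source,macro_target Explicit macrostate source/target
#'   sets; by default every macrostate containing source (target)
#'   microstates, which can blur the endpoints when a lump straddles the
#'   boundary — pass the dominant macrostates to pin them down.
#' @return A list with `macro_flux` (matrix), `macro_source`,
#'   `macro_target`, `paths` (tibble with per-path percent of total flux).
#' @export
macro_flux_report <- function(flux, labels, n_paths = 7,
                              macro_source = NULL, macro_target = NULL) {
  if (length(labels) != nrow(flux$net_flux)) {
    abort("`labels` must have one entry per microstate.")
  }
  n_macro <- max(labels)
  M <- matrix(0, n_macro, n_macro)
  for (a in seq_len(n_macro)) {
    for (b in seq_len(n_macro)) {
      if (a == b) next
      M[a, b] <- sum(flux$net_flux[labels == a, labels == b, drop = FALSE])
    }
  }
  macro_source <- macro_source %||% sort(unique(labels[flux$source]))
  macro_target <- macro_target %||% sort(unique(labels[flux$target]))
  macro_target <- setdiff(macro_target, macro_source)
  paths <- top_paths(M, macro_source, macro_target, n_paths = n_paths,
                     total_flux = flux$total_flux)
  if (nrow(paths)) {
    paths$percent <- 100 * paths$fraction
  } else {
    paths$percent <- numeric(0)
  }
  list(macro_flux = M, macro_source = macro_source,
       macro_target = macro_target, paths = paths)
}

#' Write a flux/pathway report as JSON
#'
#' @param flux A `flux_decomposition` (with paths) or the result of
#'   [macro_flux_report()].
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_flux_json <- function(flux, path) {
  pt <- if (inherits(flux, "flux_decomposition")) flux$paths else flux$paths
  payload <- list(
    total_flux = if (inherits(flux, "flux_decomposition")) flux$total_flux
                 else NULL,
    paths = lapply(seq_len(nrow(pt %||% tibble())), function(i) {
      list(rank = pt$rank[i], nodes = pt$path[[i]], flux = pt$flux[i],
           fraction = pt$fraction[i],
           cumulative_fraction = pt$cumulative_fraction[i])
    })
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}
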