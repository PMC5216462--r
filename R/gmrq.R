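# Generalized matrix Rayleigh quotient (GMRQ) cross-validation.
#
# The score measures how well the leading eigenvectors V learned on a
# training TPM diagonalize a held-out test TPM:
#   score = Tr[ (V' S V)^{-1} (V' C V) ],   S = diag(pi_test), C = S T_test.
# When train == test it equals the sum of the top-n eigenvalues, and for
# any reversible model it is bounded above by n (variational principle).

#' Split trajectories into train and test sets
#'
#' Disjoint covering split of trajectory ids, optionally stratified by a
#' binary outcome (e.g. release / no release) so both sets preserve the
#' outcome proportions as closely as integer counts allow.
#'
#' @param ids Vector of trajectory ids.
#' @param fraction Fraction assigned to the test set, in (0, 1).
#' @param seed Integer seed or `NULL`.
#' @param outcome Optional logical/factor vector parallel to `ids` used
#'   for stratification.
#' @return A list with `train` and `test` id vectors.
#' @examples
#' split_trajectories(1:4, 0.5, seed = 1)
#' @export
split_trajectories <- function(ids, fraction = 0.5, seed = NULL,
                               outcome = NULL) {
  if (length(ids) < 2) abort("Need at least 2 trajectories to split.")
  if (fraction <= 0 || fraction >= 1) abort("`fraction` must be in (0, 1).")
  if (!is.null(outcome) && length(outcome) != length(ids)) {
    abort("`outcome` must be parallel to `ids`.")
  }
  with_seed(seed, {
    test <- c()
    groups <- if (is.null(outcome)) {
      list(seq_along(ids))
    } else {
      split(seq_along(ids), outcome)
    }
    for (g in groups) {
      n_test <- round(fraction * length(g))
      n_test <- max(0L, min(length(g), n_test))
      test <- c(test, sample(g, n_test))
    }
    test <- sort(test)
    list(train = ids[-test], test = ids[test])
  })
}

#' GMRQ score of training eigenvectors against a test TPM
#'
#' @param V_train Matrix whose columns are the first `n` right
#'   eigenvectors of the training TPM, defined on the same state space as
#'   `T_test`.
#' @param T_test Row-stochastic test TPM.
#' @param pi_test Stationary distribution of the test TPM.
#' @param n Number of modes scored (defaults to `ncol(V_train)`).
#' @return Scalar score; invariant to invertible recombination of the
#'   columns of `V_train`.
#' @export
gmrq_score <- function(V_train, T_test, pi_test, n = ncol(V_train)) {
  n <- assert_count(n, "n")
  V <- as.matrix(V_train)[, seq_len(n), drop = FALSE]
  S <- diag(pi_test, nrow = length(pi_test))
  C <- S %*% T_test
  A <- t(V) %*% S %*% V
  B <- t(V) %*% C %*% V
  Ainv <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(Ainv)) {
    abort("V' S V is singular; score fewer modes or enlarge the test set.")
  }
  sum(diag(Ainv %*% B))
}

# Build a TPM from assignment sequences restricted to a state subset,
# returning NULL when the restriction disconnects or empties the chain.
tpm_on_subset <- function(seqs, lag, n_states, subset) {
  C <- tryCatch(count_transitions(seqs, lag, n_states = n_states),
                error = function(e) NULL)
  if (is.null(C)) return(NULL)
  C <- C[subset, subset, drop = FALSE]
  if (sum(C) == 0) return(NULL)
  est <- tryCatch(estimate_tpm(C), error = function(e) NULL)
  if (is.null(est)) return(NULL)
  list(T = est$T, pi = est$pi, states = subset[est$active])
}

#' Cross-validated GMRQ evaluation of one hyperparameter setting
#'
#' Splits the trajectory ensemble, builds train and test TPMs on the
#' intersection of their state spaces (both renormalized there), and
#' scores the training eigenvectors on the test TPM.
#'
#' @param assignments Tibble (`trajectory`, `frame`, `state`).
#' @param lag Lag in frames.
#' @param n_modes Modes scored.
#' @param fraction Test fraction.
#' @param seed Integer seed or `NULL`.
#' @param outcome Optional per-trajectory outcome for stratified splits
#'   (named by trajectory id, or parallel to the sorted unique ids).
#' @return A tibble row: `train_score`, `test_score`, `n_modes`, plus the
#'   split sizes; `NA` scores when a side failed to build.
#' @export
gmrq_crossval <- function(assignments, lag, n_modes = 10, fraction = 0.5,
                          seed = NULL, outcome = NULL) {
  ids <- sort(unique(assignments$trajectory))
  sp <- split_trajectories(ids, fraction, seed = seed, outcome = outcome)
  seqs <- split(assignments$state, assignments$trajectory)
  n_states <- max(assignments$state)
  seq_train <- seqs[as.character(sp$train)]
  seq_test <- seqs[as.character(sp$test)]
  visited <- function(sl) sort(unique(unlist(sl)))
  common <- intersect(visited(seq_train), visited(seq_test))
  fail <- tibble(train_score = NA_real_, test_score = NA_real_,
                 n_modes = n_modes, n_train = length(sp$train),
                 n_test = length(sp$test))
  if (length(common) < 2) return(fail)
  mtr <- tpm_on_subset(seq_train, lag, n_states, common)
  if (is.null(mtr)) return(fail)
  # re-restrict the test chain to the states the train model kept
  mte <- tpm_on_subset(seq_test, lag, n_states, mtr$states)
  if (is.null(mte)) return(fail)
  # align: keep only states present in both final models
  keep <- intersect(mtr$states, mte$states)
  if (length(keep) < 2) return(fail)
  itr <- match(keep, mtr$states)
  ite <- match(keep, mte$states)
  Ttr <- mtr$T[itr, itr, drop = FALSE]; Ttr <- Ttr / rowSums(Ttr)
  Tte <- mte$T[ite, ite, drop = FALSE]; Tte <- Tte / rowSums(Tte)
  pitr <- mtr$pi[itr] / sum(mtr$pi[itr])
  pite <- mte$pi[ite] / sum(mte$pi[ite])
  n <- min(n_modes, length(keep))
  eig_tr <- msm_eigensystem(Ttr, pitr)
  V <- eig_tr$right[, seq_len(n), drop = FALSE]
  tibble(
    train_score = gmrq_score(V, Ttr, pitr, n),
    test_score = gmrq_score(V, Tte, pite, n),
    n_modes = n, n_train = length(sp$train), n_test = length(sp$test)
  )
}

#' GMRQ hyperparameter scan
#'
#' Evaluates a grid of (number of tICA components, number of microstates)
#' settings by repeated random train/test splits, reporting the mean and
#' spread of the test score per grid point and the best setting.
#'
#' @param features Tidy feature table (see [tica()]).
#' @param tica_lag tICA lag in frames.
#' @param msm_lag MSM lag in frames.
#' @param n_tics_grid,k_grid Integer grids.
#' @param n_modes Modes scored.
#' @param n_splits Random splits per grid point.
#' @param seed Integer seed or `NULL`.
#' @param outcome Optional per-trajectory outcome for stratified splits.
#' @return An object of class `gmrq_scan`: `results` (per split),
#'   `summary` (per grid point), `best` (row of `summary`).
#' @export
gmrq_scan <- function(features, tica_lag, msm_lag, n_tics_grid = c(2, 3),
                      k_grid = c(50, 100), n_modes = 10, n_splits = 5,
                      seed = NULL, outcome = NULL) {
  if (!length(n_tics_grid) || !length(k_grid)) abort("Empty grid.")
  model <- tica(features, lag = tica_lag)
  block <- n_splits + 1L
  n_settings <- length(n_tics_grid) * length(k_grid)
  seeds <- derive_seeds(seed, n_settings * block)
  setting <- 0L
  results <- purrr::map_dfr(n_tics_grid, function(nt) {
    proj <- tica_project(features, model, n_components = nt)
    purrr::map_dfr(k_grid, function(k) {
      setting <<- setting + 1L
      base <- (setting - 1L) * block
      cl <- tryCatch(
        cluster_microstates(proj, k = k, seed = seeds[[base + 1L]]),
        error = function(e) NULL
      )
      purrr::map_dfr(seq_len(n_splits), function(s) {
        row <- if (is.null(cl)) {
          tibble(train_score = NA_real_, test_score = NA_real_,
                 n_modes = n_modes, n_train = NA_integer_,
                 n_test = NA_integer_)
        } else {
          gmrq_crossval(cl$assignments, lag = msm_lag, n_modes = n_modes,
                        seed = seeds[[base + 1L + s]], outcome = outcome)
        }
        mutate(row, n_tics = nt, k = k, split = s, .before = 1)
      })
    })
  })
  summary <- results %>%
    group_by(.data$n_tics, .data$k) %>%
    summarise(
      mean_test = mean(.data$test_score, na.rm = TRUE),
      sd_test = sd(.data$test_score, na.rm = TRUE),
      mean_train = mean(.data$train_score, na.rm = TRUE),
      n_ok = sum(!is.na(.data$test_score)),
      .groups = "drop"
    )
  best <- summary %>%
    filter(is.finite(.data$mean_test)) %>%
    arrange(dplyr::desc(.data$mean_test)) %>%
    head(1)
  structure(list(results = results, summary = summary, best = best),
            class = "gmrq_scan")
}

#' @export
print.gmrq_scan <- function(x, ...) {
  cat("<gmrq_scan>\n")
  print(x$summary)
  if (nrow(x$best)) {
    cat(sprintf("best: n_tics = %d, k = %d (mean test score %.4f)\n",
                x$best$n_tics, x$best$k, x$best$mean_test))
  }
  invisible(x)
}

#' @export
tidy.gmrq_scan <- function(x, ...) x$results

#' @export
glance.gmrq_scan <- function(x, ...) {
  tibble(n_settings = nrow(x$summary),
         best_n_tics = x$best$n_tics %||% NA_integer_,
         best_k = x$best$k %||% NA_integer_,
         best_mean_test = x$best$mean_test %||% NA_real_)
}

#' @export
autoplot.gmrq_scan <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = factor(.data$k), y = .data$mean_test,
                               fill = factor(.data$n_tics))) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_test - .data$sd_test,
                   ymax = .data$mean_test + .data$sd_test),
      position = ggplot2::position_dodge(width = 0.9), width = 0.25
    ) +
    ggplot2::labs(x = "microstates k", y = "mean test GMRQ",
                  fill = "tICs") +
    ggplot2::theme_minimal()
}
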