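# End-to-end orchestration: featurize -> tICA -> MSM -> (GMRQ) -> TPT ->
# free-energy statistics, from a single config, with stage artifacts
# persisted as delimited tables and JSON sidecars.

#' Default pipeline configuration
#'
#' Returns the configuration skeleton with the analysis defaults: tICA
#' lag 16 ns, MSM production lag 48 ns, about 100 microstates on the
#' first two tICA components, 15 macrostates and 7 ranked pathways.
#' All times are in ns and must be whole multiples of the frame stride.
#'
#' @param scenario `"three_well"` or `"release_ensemble"`.
#' @return A nested list; see fields in the source.
#' @export
default_config <- function(scenario = c("three_well", "release_ensemble")) {
  scenario <- match.arg(scenario)
  base <- list(
    scenario = scenario,
    seed = 1L,
    output_dir = NULL,
    tica = list(lag_ns = 16, n_components = 2),
    msm = list(lag_ns = 48, k = 100, lag_ladder_ns = NULL, n_boot = 5),
    gmrq = list(enabled = FALSE, n_tics_grid = c(2, 3),
                k_grid = c(50, 100), n_splits = 3),
    tpt = list(n_macro = 15, n_paths = 7,
               source_range = c(-Inf, -0.6), target_range = c(0.6, Inf)),
    thermo = list(n_bins = 50, min_depth = 1, n_boot = 30,
                  block_range_ns = c(110, 250))
  )
  if (scenario == "three_well") {
    base$generator <- list(n_traj = 10, n_steps = 20000, thin = 10)
    # diffusion time units double as "ns" for the synthetic landscape
    base$stride_ns <- NULL # derived from the generator
    base$tica$lag_ns <- NA  # set in frames below
    base$tica$lag_frames <- 5
    base$msm$lag_frames <- 25
    base$msm$lag_ladder <- c(2, 5, 10, 25, 50)
    base$msm$k <- 50
    base$tpt$n_macro <- 3
    # block lengths in the diffusion's time units (frames are 0.02 units)
    base$thermo$block_range_ns <- c(40, 120)
  } else {
    base$generator <- list(n_traj = 50, n_release = 12, n_frames = 150,
                           stride_ns = 5)
    base$stride_ns <- 5
    base$tica$lag_ns <- 15   # nearest whole-frame equivalent of the 16 ns default at a 5 ns stride
    base$msm$lag_ns <- 45
    base$msm$lag_ladder_ns <- c(5, 15, 30, 45, 60)
    base$msm$k <- 40
    base$tpt$source_range <- c(-Inf, -0.5)
    base$tpt$target_range <- c(0.5, Inf)
    base$tpt$n_macro <- 8
    base$release = list(threshold = 10, persistence = 10)
  }
  base
}

#' Read / write a pipeline config (YAML)
#'
#' @param path YAML file path.
#' @param config Config list.
#' @return The config list / `path`.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

ns_to_frames <- function(lag_ns, stride, what) {
  fr <- lag_ns / stride
  if (abs(fr - round(fr)) > 1e-9) {
    abort(sprintf(
      "%s (%g ns) is not a whole number of frames at stride %g ns.",
      what, lag_ns, stride
    ))
  }
  max(1L, as.integer(round(fr)))
}

#' Run the full analysis pipeline
#'
#' Executes every stage on the configured input and writes the artifacts
#' (feature table, tICA model, MSM, implied-timescale scan, flux report,
#' free-energy profile, summary JSON) into the output directory. With
#' fixed seeds two runs produce byte-identical summaries.
#'
#' @param config A config list (see [default_config()]) or path to a YAML
#'   file.
#' @param output_dir Overrides `config$output_dir`; defaults to a fresh
#'   temporary directory.
#' @return An object of class `pipeline_result`: list of stage results
#'   plus `summary` and `output_dir`.
#' @export
run_pipeline <- function(config = default_config(), output_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  out_dir <- output_dir %||% config$output_dir %||%
    file.path(tempfile("ionrelease_run_"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  seeds <- derive_seeds(seed, 8L)
  scen <- config$scenario %||% "three_well"

  # --- stage 1: input ------------------------------------------------------
  rel <- NULL
  truth <- NULL
  if (scen == "three_well") {
    params <- do.call(three_well_params, config$three_well %||% list())
    g <- config$generator
    traj <- simulate_three_well(
      params, n_steps = g$n_steps, seed = seeds[[1]],
      n_traj = g$n_traj, thin = g$thin %||% 1,
      start = g$start %||% "wells", burn_in = g$burn_in %||% 2000
    )
    features <- traj
    stride <- attr(traj, "stride")
    truth <- list(params = params)
    lag_tica <- config$tica$lag_frames %||%
      ns_to_frames(config$tica$lag_ns, stride, "tICA lag")
    lag_msm <- config$msm$lag_frames %||%
      ns_to_frames(config$msm$lag_ns, stride, "MSM lag")
    ladder <- config$msm$lag_ladder %||% c(1, 2, 5, 10, 20)
    inform(sprintf("[input] three-well diffusion: %d trajectories x %d frames",
                   g$n_traj, g$n_steps))
  } else if (scen == "release_ensemble") {
    g <- config$generator
    stride <- g$stride_ns %||% config$stride_ns %||% 5
    lag_tica <- ns_to_frames(config$tica$lag_ns, stride, "tICA lag")
    lag_msm <- ns_to_frames(config$msm$lag_ns, stride, "MSM lag")
    ladder <- vapply(config$msm$lag_ladder_ns,
                     function(l) ns_to_frames(l, stride, "ladder lag"),
                     integer(1))
    frames <- synthesize_release_ensemble(
      n_traj = g$n_traj, n_release = g$n_release, n_frames = g$n_frames,
      seed = seeds[[1]], stride = stride
    )
    truth <- list(released = attr(frames, "released"))
    inform(sprintf("[input] synthetic ensemble: %d trajectories (%d release)",
                   g$n_traj, g$n_release))
    features <- table_features(frames)
    rel <- release_summary(
      features,
      threshold = config$release$threshold %||% 10,
      persistence = config$release$persistence %||% 10
    )
    inform(sprintf("[release] %d released / %d not", rel$n_released,
                   rel$n_not_released))
  } else {
    abort(paste0("Unknown scenario: ", scen))
  }
  write_features_tsv(
    `attr<-`(as_tibble(features), "stride", stride),
    file.path(out_dir, "features.tsv")
  )

  # --- stage 2: tICA -------------------------------------------------------
  tmodel <- tica(features, lag = lag_tica,
                 n_components = config$tica$n_components, stride = stride)
  write_tica_json(tmodel, file.path(out_dir, "tica.json"))
  proj <- tica_project(features, tmodel)
  inform(sprintf("[tica] lag %d frames; lambda_1 = %.4f", lag_tica,
                 tmodel$values[1]))

  # --- stage 3: microstates + MSM -----------------------------------------
  cl <- cluster_microstates(proj, k = config$msm$k, seed = seeds[[2]])
  msm <- markov_model(cl$assignments, lag = lag_msm, stride = stride,
                      centers = cl$centers)
  write_msm_json(msm, file.path(out_dir, "msm.json"))
  scan <- implied_timescale_scan(
    cl$assignments, lags = ladder, n_modes = min(10, config$msm$k - 1),
    n_boot = config$msm$n_boot %||% 5, seed = seeds[[3]], stride = stride
  )
  utils::write.table(scan$scan, file.path(out_dir, "implied_timescales.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  inform(sprintf("[msm] %d/%d states kept; slowest timescale %.3g ns",
                 nrow(msm$T), config$msm$k, msm$timescales_ns[1]))

  # --- stage 4: GMRQ (optional) -------------------------------------------
  gm <- NULL
  if (isTRUE(config$gmrq$enabled)) {
    gm <- gmrq_scan(
      features, tica_lag = lag_tica, msm_lag = lag_msm,
      n_tics_grid = config$gmrq$n_tics_grid, k_grid = config$gmrq$k_grid,
      n_splits = config$gmrq$n_splits, seed = seeds[[4]],
      outcome = truth$released
    )
    utils::write.table(gm$results, file.path(out_dir, "gmrq.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  # --- stage 5: TPT --------------------------------------------------------
  centers1 <- msm$centers[msm$active, 1]
  sr <- config$tpt$source_range
  tr <- config$tpt$target_range
  source <- which(centers1 >= sr[1] & centers1 <= sr[2])
  target <- which(centers1 >= tr[1] & centers1 <= tr[2])
  if (!length(source) || !length(target)) {
    abort("Source/target tIC-1 ranges select no microstates.")
  }
  fd <- flux_pathways(msm$T, source, target, pi = msm$pi,
                      n_paths = config$tpt$n_paths)
  lump <- pcca_lump(msm, n_macro = min(config$tpt$n_macro, nrow(msm$T)))
  # endpoint macrostates = those carrying the bulk of the source/target
  # stationary weight
  dominant <- function(states) {
    w <- tapply(msm$pi[states], lump$labels[states], sum)
    as.integer(names(w)[which.max(w)])
  }
  macro <- macro_flux_report(fd, lump$labels, n_paths = config$tpt$n_paths,
                             macro_source = dominant(source),
                             macro_target = dominant(target))
  write_flux_json(fd, file.path(out_dir, "flux_micro.json"))
  write_flux_json(macro, file.path(out_dir, "flux_macro.json"))
  inform(sprintf("[tpt] total flux %.4g; %d micro paths, %d macro paths",
                 fd$total_flux, nrow(fd$paths), nrow(macro$paths)))

  # --- stage 6: free-energy profile ---------------------------------------
  tic1 <- proj
  if (scen == "release_ensemble" && !is.null(rel)) {
    keep <- rel$per_trajectory$trajectory[rel$per_trajectory$released]
    tic1 <- proj %>% filter(.data$trajectory %in% keep)
  }
  fep <- free_energy_1d(tic1$tic_1, n_bins = config$thermo$n_bins,
                        min_frames = min(1000, nrow(tic1)))
  fep <- block_bootstrap_errors(
    fep, tic1 %>% select("trajectory", "tic_1"),
    block_range = config$thermo$block_range_ns %||% c(110, 250),
    stride = stride, n_boot = config$thermo$n_boot, seed = seeds[[5]]
  )
  basins <- find_basins(fep, min_depth = config$thermo$min_depth)
  utils::write.table(fep$profile, file.path(out_dir, "free_energy.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  inform(sprintf("[thermo] %d basin(s) at min_depth %.2g kT", nrow(basins),
                 config$thermo$min_depth))

  # --- summary -------------------------------------------------------------
  summary <- list(
    scenario = scen,
    seed = seed,
    n_states = nrow(msm$T),
    lag_ns = msm$lag_ns,
    slowest_implied_timescale_ns = msm$timescales_ns[1],
    its_flatness = scan$flatness,
    total_flux = fd$total_flux,
    n_macrostates = lump$n_macro,
    top_macro_paths = lapply(seq_len(nrow(macro$paths)), function(i) {
      list(nodes = macro$paths$path[[i]], flux = macro$paths$flux[i],
           percent = macro$paths$percent[i])
    }),
    n_basins = nrow(basins),
    basin_minima = basins$minimum,
    basin_free_energy = basins$min_free_energy,
    released = if (is.null(rel)) NULL else rel$n_released,
    not_released = if (is.null(rel)) NULL else rel$n_not_released
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  structure(
    list(
      config = config, output_dir = out_dir, features = features,
      tica = tmodel, projections = proj, clustering = cl, msm = msm,
      its_scan = scan, gmrq = gm, flux = fd, lump = lump, macro = macro,
      fep = fep, basins = basins, release = rel, truth = truth,
      summary = summary
    ),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result> scenario %s: %d states, slowest timescale %.3g ns, %d basins, %d macro paths\n",
    x$summary$scenario, x$summary$n_states,
    x$summary$slowest_implied_timescale_ns, x$summary$n_basins,
    length(x$summary$top_macro_paths)
  ))
  cat("artifacts in:", x$output_dir, "\n")
  invisible(x)
}

#' Build small deterministic fixture datasets
#'
#' Writes a compact, reproducible fixture set — a discrete chain
#' ensemble, a short three-well diffusion, and a 20-frame coordinate toy —
#' for tests and documentation.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @return Named list of file paths, invisibly.
#' @export
make_fixtures <- function(dir = tempfile("fixtures_"), seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(seed, 3L)
  ch <- ground_truth_chain(
    matrix(c(0.95, 0.05, 0, 0.05, 0.9, 0.05, 0, 0.05, 0.95), 3,
           byrow = TRUE),
    labels = c("bound", "intermediate", "released")
  )
  chains <- simulate_chain_ensemble(ch, n_traj = 5, n_steps = 500,
                                    seed = seeds[[1]])
  chain_tbl <- tibble(
    trajectory = rep(seq_along(chains), lengths(chains)),
    frame = unlist(lapply(chains, seq_along)),
    state = unlist(chains)
  )
  p_chain <- file.path(dir, "chain_ensemble.tsv")
  utils::write.table(chain_tbl, p_chain, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  tw <- simulate_three_well(three_well_params(), n_steps = 2000,
                            seed = seeds[[2]], n_traj = 2, thin = 5)
  p_tw <- file.path(dir, "three_well.tsv")
  utils::write.table(tw, p_tw, sep = "\t", row.names = FALSE, quote = FALSE)
  toy <- synthesize_frames("release", n_frames = 20, seed = seeds[[3]],
                           release_frame = 8)
  p_toy <- file.path(dir, "coordinate_toy.tsv")
  write_frames_tsv(toy, p_toy)
  invisible(list(chain = p_chain, three_well = p_tw, frames = p_toy))
}
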