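#' Labeled coordinate frame ensembles
#'
#' A `frame_ensemble` is a tidy table of labeled pseudo-atom positions:
#' one row per particle per frame per trajectory, with columns
#' `trajectory`, `frame`, `label`, `role`, `x`, `y`, `z` (Å). The frame
#' stride (ns per frame) is carried as an attribute. The z axis is the
#' membrane normal with the positive direction toward the extracellular
#' side. Roles partition the particles into `ion`, `water` (oxygen
#' positions), `lipid`, `marker` (residue reference atoms) and `ligand`.
#'
#' @param data Data frame with the columns above.
#' @param stride Time per frame in ns (> 0).
#' @return A tibble of class `frame_ensemble`.
#' @export
frame_ensemble <- function(data, stride) {
  req <- c("trajectory", "frame", "label", "role", "x", "y", "z")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols)) {
    abort(paste0("Missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  assert_scalar_number(stride, "stride", lower = 1e-12)
  data <- as_tibble(data)
  # every frame of a trajectory must carry the same label set
  chk <- data %>%
    group_by(.data$trajectory, .data$frame) %>%
    summarise(sig = paste(sort(.data$label), collapse = "\r"), .groups = "drop_last") %>%
    summarise(ok = length(unique(.data$sig)) == 1L, .groups = "drop")
  if (!all(chk$ok)) {
    abort("All frames within a trajectory must share the same label set.")
  }
  structure(data, class = c("frame_ensemble", class(data)),
            stride = stride)
}

#' @export
print.frame_ensemble <- function(x, ...) {
  cat(sprintf(
    "<frame_ensemble> %d trajectories, %d frames total, %d particles/frame, stride %g ns\n",
    length(unique(x$trajectory)),
    nrow(dplyr::distinct(as_tibble(x)[c("trajectory", "frame")])),
    length(unique(x$label)), attr(x, "stride")
  ))
  NextMethod()
}

#' Stride (ns per frame) of a frame ensemble
#' @param frames A [frame_ensemble()].
#' @return Scalar stride in ns.
#' @export
frame_stride <- function(frames) attr(frames, "stride") %||% 1

#' Extract a single frame
#'
#' @param frames A [frame_ensemble()].
#' @param trajectory,frame Identifiers of the frame to extract.
#' @return A tibble with one row per particle.
#' @export
frame_at <- function(frames, trajectory, frame) {
  out <- as_tibble(frames)
  out[out$trajectory == trajectory & out$frame == frame, , drop = FALSE]
}

# Fixed marker scaffold of the synthetic transporter (Å). DA is the ligand
# center proxy at the origin; F326_CB sits on the extracellular side,
# the intracellular gate residues below; T269 backbone atoms ring the
# ion-permeation channel.
synthetic_marker_layout <- function() {
  tibble::tribble(
    ~label,      ~role,     ~x,    ~y,    ~z,
    "DA",        "ligand",   0,     0,     0,
    "F326_CB",   "marker",   0,     0,     6,
    "D436_CB",   "marker",   3,    -2,   -11,
    "T269_N",    "marker",   2.1,   0.5,  -4,
    "T269_CA",   "marker",   1.5,   1.1,  -4,
    "T269_C",    "marker",   0.9,   0.5,  -4,
    "T269_O",    "marker",   1.5,  -0.1,  -4,
    "Na1",       "ion",      1.5,   1,    -1,
    "D79",       "marker",   0.5,  -1.5,  -3,
    "D421",      "marker",   2,    -2,    -3,
    "E428",      "marker",   0,    -1,    -8,
    "R60",       "marker",   0,     2,   -12,
    "Y335",      "marker",   2,     0,   -10,
    "R445",      "marker",  -2,     1,    -9,
    "E446",      "marker",  -1,     3,   -11,
    "K66",       "marker",  -5,     3,   -13,
    "D345",      "marker",  -5,     5,   -13.5
  )
}

# Key reference positions reused when scripting particle motion.
.na2_site <- c(1, -1, -2.5)       # bound pose, ~2.6 Å from Na1
.na2_intermediate <- c(0, -1.3, -8.3)  # coordinated by E428
.na2_released <- c(0, -2, -14)    # intracellular solution

#' Synthesize a labeled coordinate trajectory
#'
#' Generates one pseudo-atom trajectory emulating the geometry of sodium
#' release through the intracellular vestibule of a transporter: a tagged
#' ion (`Na2`) either stays in its binding site next to `Na1`
#' (`scenario = "no_release"`) or escapes through a metastable intermediate
#' coordinated by the `E428` marker into the intracellular solution
#' (`scenario = "release"`). In the release scenario the intracellular
#' water count rises as the ion leaves, the ion's water coordination
#' number grows, and a K+ ion enters the emptied site (within 7 Å of
#' `D79`) only after the ion-to-`Na1` distance exceeds 10 Å.
#'
#' @param scenario `"release"` or `"no_release"`.
#' @param n_frames Number of frames (>= 1).
#' @param seed Integer seed or `NULL`.
#' @param stride Time per frame in ns.
#' @param release_frame Frame at which the ion reaches the released pose
#'   (release scenario only). Default: drawn uniformly in
#'   `[0.45, 0.7] * n_frames`. Release-time dispersion is a free
#'   parameter of the generator.
#' @param trajectory Integer id stamped on the output.
#' @return A [frame_ensemble()] with attributes `scenario` and
#'   `release_frame` (NA when not released).
#' @export
synthesize_frames <- function(scenario = c("release", "no_release"),
                              n_frames = 150, seed = NULL, stride = 5,
                              release_frame = NULL, trajectory = 1L) {
  scenario <- match.arg(scenario)
  n_frames <- assert_count(n_frames, "n_frames")
  with_seed(seed, {
    fr <- seq_len(n_frames)
    jit <- function(n, sd = 0.3) matrix(rnorm(3 * n, sd = sd), n, 3)

    markers <- synthetic_marker_layout()
    parts <- list()
    for (i in seq_len(nrow(markers))) {
      base <- c(markers$x[i], markers$y[i], markers$z[i])
      pos <- matrix(base, n_frames, 3, byrow = TRUE) + jit(n_frames, 0.25)
      if (scenario == "release" && markers$label[i] == "R60") {
        # intracellular gate opens as release proceeds
        drift <- cbind(0, 2.5 * fr / n_frames, -2 * fr / n_frames)
        pos <- pos + drift
      }
      parts[[markers$label[i]]] <- list(
        label = markers$label[i], role = markers$role[i], pos = pos
      )
    }

    # --- tagged ion path ---------------------------------------------------
    if (scenario == "release") {
      if (is.null(release_frame)) {
        release_frame <- max(12L, round(runif(1, 0.45, 0.7) * n_frames))
      }
      release_frame <- assert_count(release_frame, "release_frame")
      if (release_frame > n_frames - 10L) {
        abort("`release_frame` must leave >= 10 frames in the released pose.")
      }
      dwell <- max(4L, round(0.12 * n_frames))
      f_leave <- max(3L, release_frame - dwell)
      na2 <- matrix(NA_real_, n_frames, 3)
      ramp <- function(a, b, m) {
        s <- seq(0, 1, length.out = m)
        outer(1 - s, a) + outer(s, b)
      }
      n1 <- f_leave
      n2 <- release_frame - f_leave
      n3 <- n_frames - release_frame + 1L
      na2[seq_len(n1), ] <- matrix(.na2_site, n1, 3, byrow = TRUE)
      na2[f_leave + seq_len(n2) - 1L, ] <- ramp(.na2_site, .na2_intermediate, n2)
      # hold in the intermediate for most of the dwell, then drop out
      hold <- max(1L, round(0.6 * n2))
      na2[(f_leave + hold):(release_frame - 1L), ] <-
        matrix(.na2_intermediate, release_frame - f_leave - hold, 3, byrow = TRUE)
      na2[release_frame:n_frames, ] <- matrix(.na2_released, n3, 3, byrow = TRUE)
      na2 <- na2 + jit(n_frames, 0.25)
    } else {
      release_frame <- NA_integer_
      na2 <- matrix(.na2_site, n_frames, 3, byrow = TRUE) + jit(n_frames, 0.3)
    }
    parts[["Na2"]] <- list(label = "Na2", role = "ion", pos = na2)

    # --- waters ------------------------------------------------------------
    widx <- 0L
    add_water <- function(pos) {
      widx <<- widx + 1L
      parts[[sprintf("W%03d", widx)]] <<- list(
        label = sprintf("W%03d", widx), role = "water", pos = pos
      )
    }
    # extracellular vestibule waters (12): cylinder above the ligand
    for (i in 1:12) {
      ang <- runif(1, 0, 2 * pi); rad <- sqrt(runif(1)) * 9
      base <- c(rad * cos(ang), rad * sin(ang), runif(1, 3, 14))
      add_water(matrix(base, n_frames, 3, byrow = TRUE) + jit(n_frames, 0.4))
    }
    # bulk waters far outside every cavity (10)
    for (i in 1:10) {
      ang <- runif(1, 0, 2 * pi)
      base <- c(32 * cos(ang), 32 * sin(ang), runif(1, -25, 25))
      add_water(matrix(base, n_frames, 3, byrow = TRUE) + jit(n_frames, 0.4))
    }
    # intracellular waters: reservoir below, entering the IC vestibule over
    # time in the release scenario
    ic_sites <- rbind(
      c(1, 0, -5), c(0.5, 1, -6), c(-1, 0.5, -7), c(2, -1, -6),  # channel
      c(-9, 7, -8), c(-8, -7, -9), c(9, 7, -9)                   # cavity
    )
    n_ic <- 20L
    entries <- if (scenario == "release") {
      sort(round(runif(n_ic - 4L, 0.3, 0.92) * n_frames))
    } else {
      integer(0)
    }
    for (i in seq_len(n_ic)) {
      ang <- runif(1, 0, 2 * pi)
      reservoir <- c(19 * cos(ang), 19 * sin(ang), -18)
      entry <- if (i <= 4L) 1L else if (scenario == "release") entries[i - 4L] else NA_integer_
      site <- ic_sites[(i - 1L) %% nrow(ic_sites) + 1L, ]
      pos <- matrix(reservoir, n_frames, 3, byrow = TRUE)
      if (!is.na(entry)) {
        inside <- fr >= entry
        pos[inside, ] <- matrix(site, sum(inside), 3, byrow = TRUE)
      }
      add_water(pos + jit(n_frames, 0.4))
    }
    # hydration shell waters tracking the tagged ion once it leaves
    for (i in 1:5) {
      far <- c(20, 20, 10) + rnorm(3)
      pos <- matrix(far, n_frames, 3, byrow = TRUE)
      act_from <- if (i == 1L) 1L else if (scenario == "release") {
        max(1L, f_leave - 3L + i)
      } else {
        NA_integer_
      }
      if (!is.na(act_from)) {
        act <- fr >= act_from
        dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
        pos[act, ] <- na2[act, , drop = FALSE] +
          matrix(dir * runif(1, 1.9, 2.6), sum(act), 3, byrow = TRUE)
      }
      add_water(pos + jit(n_frames, 0.15))
    }

    # --- potassium ions ----------------------------------------------------
    for (i in 1:3) {
      ang <- runif(1, 0, 2 * pi)
      bulk <- c(16 * cos(ang), 16 * sin(ang), runif(1, -20, -16))
      pos <- matrix(bulk, n_frames, 3, byrow = TRUE)
      if (scenario == "release" && i == 1L) {
        after <- fr >= min(n_frames, release_frame + 3L)
        d79 <- c(0.5, -1.5, -3)
        pos[after, ] <- matrix(d79 + c(0.5, 0.5, -1.5), sum(after), 3, byrow = TRUE)
      }
      parts[[paste0("K", i)]] <- list(
        label = paste0("K", i), role = "ion", pos = pos + jit(n_frames, 0.4)
      )
    }

    # --- lipid markers -----------------------------------------------------
    lip_ang <- seq(0, 2 * pi, length.out = 9)[-9]
    for (i in seq_along(lip_ang)) {
      base <- c(28 * cos(lip_ang[i]), 28 * sin(lip_ang[i]),
                ifelse(i %% 2 == 0, 10, -12))
      parts[[sprintf("LIP%02d", i)]] <- list(
        label = sprintf("LIP%02d", i), role = "lipid",
        pos = matrix(base, n_frames, 3, byrow = TRUE) + jit(n_frames, 0.5)
      )
    }
    # one lipid poking into the EC rim to exercise the exclusion clause
    parts[["LIP09"]] <- list(
      label = "LIP09", role = "lipid",
      pos = matrix(c(12, 0, 8), n_frames, 3, byrow = TRUE) + jit(n_frames, 0.4)
    )

    df <- dplyr::bind_rows(lapply(parts, function(p) {
      tibble(
        trajectory = as.integer(trajectory), frame = fr,
        label = p$label, role = p$role,
        x = p$pos[, 1], y = p$pos[, 2], z = p$pos[, 3]
      )
    }))
    out <- frame_ensemble(df, stride = stride)
    attr(out, "scenario") <- scenario
    attr(out, "release_frame") <- release_frame
    out
  })
}

#' Synthesize a release/no-release trajectory ensemble
#'
#' Emulates the study design of an ensemble of independent trajectories in
#' which the tagged ion escapes in a minority: by default 50 trajectories
#' with release engineered in 12 of them.
#'
#' @param n_traj Total trajectories.
#' @param n_release Number with a release event.
#' @param n_frames Frames per trajectory.
#' @param seed Integer seed or `NULL`.
#' @param stride ns per frame.
#' @return A [frame_ensemble()] with attribute `released` — a logical
#'   vector of length `n_traj` (the ground truth).
#' @export
synthesize_release_ensemble <- function(n_traj = 50, n_release = 12,
                                        n_frames = 150, seed = NULL,
                                        stride = 5) {
  n_traj <- assert_count(n_traj, "n_traj")
  n_release <- assert_count(n_release, "n_release", lower = 0L)
  if (n_release > n_traj) abort("`n_release` cannot exceed `n_traj`.")
  seeds <- derive_seeds(seed, n_traj + 1L)
  released <- with_seed(seeds[[n_traj + 1L]], {
    sample(c(rep(TRUE, n_release), rep(FALSE, n_traj - n_release)))
  })
  pieces <- lapply(seq_len(n_traj), function(i) {
    synthesize_frames(
      scenario = if (released[i]) "release" else "no_release",
      n_frames = n_frames, seed = seeds[[i]], stride = stride,
      trajectory = i
    )
  })
  out <- frame_ensemble(dplyr::bind_rows(pieces), stride = stride)
  attr(out, "released") <- released
  attr(out, "release_frame") <- vapply(
    pieces, function(p) as.integer(attr(p, "release_frame")), integer(1)
  )
  out
}

#' Write / read a frame ensemble as a delimited archive
#'
#' The native interchange format is a plain TSV of the tidy particle table
#' plus a JSON sidecar holding the stride and provenance attributes.
#'
#' @param frames A [frame_ensemble()].
#' @param path Path of the `.tsv` file to write (sidecar gets `.json`).
#' @return `path`, invisibly.
#' @export
write_frames_tsv <- function(frames, path) {
  utils::write.table(as_tibble(frames), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  meta <- list(stride = frame_stride(frames),
               scenario = attr(frames, "scenario"),
               released = attr(frames, "released"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_frames_tsv
#' @export
read_frames_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  meta_path <- paste0(path, ".json")
  stride <- 1
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    stride <- meta$stride %||% 1
  }
  frame_ensemble(df, stride = stride)
}

#' Export a frame ensemble to multi-model PDB
#'
#' Writes one trajectory as a multi-MODEL PDB file (via the bio3d package)
#' so standard structure viewers and trajectory readers can consume the
#' synthetic data.
#'
#' @param frames A [frame_ensemble()].
#' @param path Output `.pdb` path.
#' @param trajectory Which trajectory to export.
#' @return `path`, invisibly.
#' @export
write_frames_pdb <- function(frames, path, trajectory = 1L) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    abort("PDB export requires the bio3d package.")
  }
  df <- as_tibble(frames)
  df <- df[df$trajectory == trajectory, , drop = FALSE]
  if (!nrow(df)) abort("No such trajectory in the ensemble.")
  df <- df[order(df$frame, df$label), , drop = FALSE]
  labs <- sort(unique(df$label))
  nat <- length(labs)
  xyz <- matrix(t(as.matrix(df[c("x", "y", "z")])), nrow = length(unique(df$frame)),
                byrow = TRUE)
  pdb <- bio3d::read.pdb
  # Build a minimal bio3d pdb object for the first frame, then write all
  # frames through write.pdb's multi-xyz support one MODEL at a time.
  first <- df[df$frame == min(df$frame), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  frames_ids <- sort(unique(df$frame))
  for (fi in seq_along(frames_ids)) {
    cur <- df[df$frame == frames_ids[fi], , drop = FALSE]
    writeLines(sprintf("MODEL     %4d", fi), con)
    for (a in seq_len(nrow(cur))) {
      writeLines(sprintf(
        "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        a, substr(cur$label[a], 1, 4), substr(toupper(cur$role[a]), 1, 3),
        a, cur$x[a], cur$y[a], cur$z[a]
      ), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
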