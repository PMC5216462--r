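#' Pairwise marker distances per frame
#'
#' Computes Euclidean distances (Å) between labeled particles, one column
#' per pair, preserving frame order — the building block of the tICA input
#' feature table.
#'
#' @param frames A [frame_ensemble()].
#' @param pairs A list of length-2 character vectors (`c(label_a, label_b)`).
#'   Names of the list become column names; unnamed pairs are named
#'   `a_b` (lower-case).
#' @return A tibble with `trajectory`, `frame` and one distance column per
#'   pair.
#' @examples
#' fr <- synthesize_frames("no_release", n_frames = 5, seed = 1)
#' pair_distances(fr, list(na2_na1 = c("Na2", "Na1")))
#' @export
pair_distances <- function(frames, pairs) {
  df <- as_tibble(frames)
  if (!length(pairs)) abort("`pairs` must be non-empty.")
  nms <- names(pairs) %||% rep("", length(pairs))
  have <- unique(df$label)
  out <- dplyr::distinct(df[c("trajectory", "frame")])
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    if (length(p) != 2) abort("Each pair must have exactly two labels.")
    miss <- setdiff(p, have)
    if (length(miss)) {
      abort(paste0("Label(s) not present in ensemble: ",
                   paste(miss, collapse = ", ")))
    }
    a <- df[df$label == p[1], c("trajectory", "frame", "x", "y", "z")]
    b <- df[df$label == p[2], c("trajectory", "frame", "x", "y", "z")]
    m <- dplyr::inner_join(a, b, by = c("trajectory", "frame"),
                           suffix = c("_a", "_b"))
    d <- sqrt((m$x_a - m$x_b)^2 + (m$y_a - m$y_b)^2 + (m$z_a - m$z_b)^2)
    nm <- if (nzchar(nms[i])) nms[i] else tolower(paste(p, collapse = "_"))
    out[[nm]] <- d[match(
      paste(out$trajectory, out$frame),
      paste(m$trajectory, m$frame)
    )]
  }
  out
}

#' Water coordination number of an ion
#'
#' Counts the water oxygens within `cutoff` Å of the tagged ion, per
#' frame. The 3.5 Å default is the conventional first-hydration-shell
#' cutoff for Na+ (the quantity itself does not fix a value; the choice is
#' configurable and recorded in pipeline configs).
#'
#' @param frames A [frame_ensemble()].
#' @param ion_label Label of the ion (default `"Na2"`).
#' @param water_role Role string identifying water particles.
#' @param cutoff Distance cutoff in Å (> 0).
#' @return A tibble `trajectory`, `frame`, `coordination` (integer).
#' @export
coordination_number <- function(frames, ion_label = "Na2",
                                water_role = "water", cutoff = 3.5) {
  assert_scalar_number(cutoff, "cutoff", lower = 1e-9)
  df <- as_tibble(frames)
  if (!ion_label %in% df$label) {
    abort(paste0("Label not present in ensemble: ", ion_label))
  }
  ion <- df[df$label == ion_label, c("trajectory", "frame", "x", "y", "z")]
  wat <- df[df$role == water_role, c("trajectory", "frame", "x", "y", "z")]
  out <- ion[c("trajectory", "frame")]
  if (!nrow(wat)) {
    out$coordination <- 0L
    return(out)
  }
  m <- dplyr::inner_join(wat, ion, by = c("trajectory", "frame"),
                         suffix = c("_w", "_i"))
  m$hit <- (m$x_w - m$x_i)^2 + (m$y_w - m$y_i)^2 + (m$z_w - m$z_i)^2 <=
    cutoff^2
  cnt <- m %>%
    group_by(.data$trajectory, .data$frame) %>%
    summarise(coordination = sum(.data$hit), .groups = "drop")
  out <- dplyr::left_join(out, cnt, by = c("trajectory", "frame"))
  out$coordination[is.na(out$coordination)] <- 0L
  out$coordination <- as.integer(out$coordination)
  out
}

# --- water cavity assignment -------------------------------------------------

marker_position <- function(frame, label) {
  row <- frame[frame$label == label, , drop = FALSE]
  if (!nrow(row)) abort(paste0("Required marker missing from frame: ", label))
  c(row$x[1], row$y[1], row$z[1])
}

water_table <- function(frame) frame[frame$role == "water", , drop = FALSE]

dist_to_point <- function(frame_rows, p) {
  sqrt((frame_rows$x - p[1])^2 + (frame_rows$y - p[2])^2 +
         (frame_rows$z - p[3])^2)
}

# Minimum distance of each row to any particle in `others`.
min_dist_to_set <- function(frame_rows, others) {
  if (!nrow(others)) return(rep(Inf, nrow(frame_rows)))
  apply(cbind(frame_rows$x, frame_rows$y, frame_rows$z), 1, function(p) {
    min(sqrt((others$x - p[1])^2 + (others$y - p[2])^2 +
               (others$z - p[3])^2))
  })
}

#' Extracellular vestibule water assignment
#'
#' A water oxygen belongs to the extracellular (EC) vestibule when it is
#' (a) within 26 Å of the `F326_CB` marker, (b) not within 5 Å of any
#' lipid particle, and (c) its z coordinate exceeds that of `F326_CB` by
#' no more than 23 Å. The z clause is one-sided, exactly as defined:
#' waters far below the marker are limited only by the 26 Å sphere.
#'
#' @param frame A single-frame tibble (see [frame_at()]).
#' @param sphere_cutoff,lipid_cutoff,z_max Clause cutoffs in Å.
#' @return Character vector of water labels in the EC vestibule.
#' @export
assign_ec_vestibule <- function(frame, sphere_cutoff = 26, lipid_cutoff = 5,
                                z_max = 23) {
  f326 <- marker_position(frame, "F326_CB")
  wat <- water_table(frame)
  if (!nrow(wat)) return(character(0))
  lip <- frame[frame$role == "lipid", , drop = FALSE]
  ok <- dist_to_point(wat, f326) <= sphere_cutoff &
    min_dist_to_set(wat, lip) > lipid_cutoff &
    (wat$z - f326[3]) <= z_max
  wat$label[ok]
}

#' Extracellular cavity water assignment
#'
#' The EC cavity is the part of the EC vestibule within 10 Å of the ligand
#' center of mass (the `DA` proxy point on synthetic frames).
#'
#' @param frame A single-frame tibble.
#' @param ec_vestibule_members Labels from [assign_ec_vestibule()];
#'   computed if `NULL`.
#' @param ligand_cutoff Cutoff in Å.
#' @return Character vector of water labels in the EC cavity.
#' @export
assign_ec_cavity <- function(frame, ec_vestibule_members = NULL,
                             ligand_cutoff = 10) {
  da <- marker_position(frame, "DA")
  if (is.null(ec_vestibule_members)) {
    ec_vestibule_members <- assign_ec_vestibule(frame)
  }
  wat <- water_table(frame)
  wat <- wat[wat$label %in% ec_vestibule_members, , drop = FALSE]
  if (!nrow(wat)) return(character(0))
  wat$label[dist_to_point(wat, da) <= ligand_cutoff]
}

#' Intracellular vestibule assignment and channel/cavity split
#'
#' A water belongs to the intracellular (IC) vestibule when it is within
#' 15 Å of the ligand center, not within 5 Å of any lipid, and its
#' |z distance| to the `D436_CB` marker does not exceed 15.5 Å. The
#' vestibule is partitioned into the IC channel — within 12 Å of any
#' particle of the T269 backbone — and the IC cavity (the remainder).
#'
#' @param frame A single-frame tibble.
#' @param ligand_cutoff,lipid_cutoff,z_max,channel_cutoff Clause cutoffs (Å).
#' @return A list with character vectors `IC_vestibule`, `IC_channel`,
#'   `IC_cavity` (the last two partition the first).
#' @export
assign_ic_vestibule <- function(frame, ligand_cutoff = 15, lipid_cutoff = 5,
                                z_max = 15.5, channel_cutoff = 12) {
  da <- marker_position(frame, "DA")
  d436 <- marker_position(frame, "D436_CB")
  t269 <- frame[grepl("^T269", frame$label), , drop = FALSE]
  if (!nrow(t269)) abort("Required marker missing from frame: T269 backbone")
  wat <- water_table(frame)
  lip <- frame[frame$role == "lipid", , drop = FALSE]
  if (!nrow(wat)) {
    return(list(IC_vestibule = character(0), IC_channel = character(0),
                IC_cavity = character(0)))
  }
  in_vest <- dist_to_point(wat, da) <= ligand_cutoff &
    min_dist_to_set(wat, lip) > lipid_cutoff &
    abs(wat$z - d436[3]) <= z_max
  vest <- wat[in_vest, , drop = FALSE]
  in_channel <- min_dist_to_set(vest, t269) <= channel_cutoff
  list(
    IC_vestibule = vest$label,
    IC_channel = vest$label[in_channel],
    IC_cavity = vest$label[!in_channel]
  )
}

#' Per-frame water counts of all defined cavities
#'
#' @param frames A [frame_ensemble()].
#' @return A tibble with per-frame integer counts `EC_vestibule`,
#'   `EC_cavity`, `IC_vestibule`, `IC_channel`, `IC_cavity`; the partition
#'   identities `EC_cavity <= EC_vestibule` and
#'   `IC_channel + IC_cavity = IC_vestibule` hold by construction.
#' @export
cavity_counts <- function(frames) {
  df <- as_tibble(frames)
  keys <- dplyr::distinct(df[c("trajectory", "frame")])
  res <- purrr::map_dfr(seq_len(nrow(keys)), function(i) {
    fr <- df[df$trajectory == keys$trajectory[i] & df$frame == keys$frame[i], ,
             drop = FALSE]
    ec <- assign_ec_vestibule(fr)
    ecc <- assign_ec_cavity(fr, ec)
    ic <- assign_ic_vestibule(fr)
    tibble(
      trajectory = keys$trajectory[i], frame = keys$frame[i],
      EC_vestibule = length(ec), EC_cavity = length(ecc),
      IC_vestibule = length(ic$IC_vestibule),
      IC_channel = length(ic$IC_channel),
      IC_cavity = length(ic$IC_cavity)
    )
  })
  res
}

#' Interaction frequency of a distance series
#'
#' Percent of frames in which the distance is at or below the cutoff —
#' the per-trajectory contact statistic (the conventional mediated-contact
#' cutoff is 6 Å).
#'
#' @param distance_series Numeric vector of distances (Å), non-empty.
#' @param cutoff Cutoff in Å.
#' @return Percent in `[0, 100]`.
#' @examples
#' interaction_frequency(c(3, 7, 5, 8), 6) # 50
#' @export
interaction_frequency <- function(distance_series, cutoff = 6) {
  if (!length(distance_series)) abort("`distance_series` must be non-empty.")
  assert_scalar_number(cutoff, "cutoff", lower = 0)
  100 * mean(distance_series <= cutoff)
}

#' Mediated contact between two partners
#'
#' TRUE when some mediator particle (e.g. a lipid headgroup) is
#' simultaneously within `cutoff` of the fixed partner and of at least one
#' particle of the other partner set — the definition of a lipid-bridged
#' residue contact.
#'
#' @param frame A single-frame tibble.
#' @param partnerA_labels Character vector of candidate partner labels.
#' @param partnerB_label Single fixed partner label.
#' @param mediator_labels Labels of mediator particles.
#' @param cutoff Cutoff in Å.
#' @return Logical scalar.
#' @export
mediated_contact <- function(frame, partnerA_labels, partnerB_label,
                             mediator_labels, cutoff = 6) {
  a <- frame[frame$label %in% partnerA_labels, , drop = FALSE]
  b <- frame[frame$label == partnerB_label, , drop = FALSE]
  m <- frame[frame$label %in% mediator_labels, , drop = FALSE]
  if (!nrow(b)) abort(paste0("Label not present in frame: ", partnerB_label))
  if (!nrow(a) || !nrow(m)) return(FALSE)
  pb <- c(b$x[1], b$y[1], b$z[1])
  near_b <- dist_to_point(m, pb) <= cutoff
  if (!any(near_b)) return(FALSE)
  m2 <- m[near_b, , drop = FALSE]
  any(min_dist_to_set(m2, a) <= cutoff)
}

#' Probability of a K+ ion at the emptied site, by release-progress bin
#'
#' Bins frames by the distance between the tagged ion and the reference
#' ion (`Na2`–`Na1`), and in each bin estimates the probability that at
#' least one K+ ion sits within `cutoff` Å of the site marker (`D79`).
#' Confidence intervals come from a trajectory-level bootstrap (resampling
#' a random number of trajectories per replicate, by default 26–38 out of
#' the ensemble, 100 times) and bin-to-bin significance from two-sample
#' t-tests on per-trajectory probabilities.
#'
#' @param frames A [frame_ensemble()].
#' @param site_label Site marker label.
#' @param k_labels Labels of the K+ ions (default: all labels matching
#'   `"^K[0-9]"`).
#' @param cutoff Site cutoff in Å.
#' @param breaks Bin breaks for the ion-pair distance (Å).
#' @param n_boot Bootstrap replicates.
#' @param boot_range Integer range for the number of trajectories drawn
#'   per replicate.
#' @param seed Integer seed or `NULL`.
#' @return A tibble per bin: `bin`, `n_frames`, `probability`, `ci_lo`,
#'   `ci_hi`; attribute `"p_values"` holds the pairwise t-test table.
#'   Bins with zero frames are flagged and excluded.
#' @export
kplus_site_probability <- function(frames, site_label = "D79",
                                   k_labels = NULL, cutoff = 7,
                                   breaks = c(0, 5, 10, Inf),
                                   n_boot = 100, boot_range = c(26, 38),
                                   seed = NULL) {
  df <- as_tibble(frames)
  if (is.null(k_labels)) {
    k_labels <- unique(df$label[df$role == "ion" & grepl("^K", df$label)])
  }
  dist_tbl <- pair_distances(frames, list(pairdist = c("Na2", "Na1")))
  site <- df[df$label == site_label, c("trajectory", "frame", "x", "y", "z")]
  if (!nrow(site)) abort(paste0("Label not present in ensemble: ", site_label))
  kion <- df[df$label %in% k_labels, c("trajectory", "frame", "x", "y", "z")]
  hit <- dist_tbl
  if (nrow(kion)) {
    m <- dplyr::inner_join(kion, site, by = c("trajectory", "frame"),
                           suffix = c("_k", "_s"))
    m$near <- (m$x_k - m$x_s)^2 + (m$y_k - m$y_s)^2 + (m$z_k - m$z_s)^2 <=
      cutoff^2
    anyk <- m %>%
      group_by(.data$trajectory, .data$frame) %>%
      summarise(k_present = any(.data$near), .groups = "drop")
    hit <- dplyr::left_join(hit, anyk, by = c("trajectory", "frame"))
    hit$k_present[is.na(hit$k_present)] <- FALSE
  } else {
    hit$k_present <- FALSE
  }
  hit$bin <- cut(hit$pairdist, breaks = breaks, include.lowest = TRUE)
  empty <- setdiff(levels(hit$bin), unique(as.character(hit$bin)))
  if (length(empty)) {
    warn(paste0("Empty distance bins excluded: ", paste(empty, collapse = ", ")))
  }
  per_bin <- hit %>%
    filter(!is.na(.data$bin)) %>%
    group_by(.data$bin) %>%
    summarise(n_frames = n(), probability = mean(.data$k_present),
              .groups = "drop") %>%
    filter(.data$n_frames > 0)

  trajs <- unique(hit$trajectory)
  boot <- with_seed(seed, {
    replicate(n_boot, {
      ns <- sample(seq(boot_range[1], boot_range[2]), 1)
      ns <- min(ns, length(trajs))
      pick <- sample(trajs, ns, replace = TRUE)
      sub <- dplyr::bind_rows(lapply(pick, function(tr) hit[hit$trajectory == tr, ]))
      v <- tapply(sub$k_present, sub$bin, mean)
      as.numeric(v[as.character(per_bin$bin)])
    })
  })
  if (is.null(dim(boot))) boot <- matrix(boot, nrow = nrow(per_bin))
  per_bin$ci_lo <- apply(boot, 1, quantile, probs = 0.025, na.rm = TRUE)
  per_bin$ci_hi <- apply(boot, 1, quantile, probs = 0.975, na.rm = TRUE)

  # pairwise t-tests on per-trajectory probabilities
  per_traj <- hit %>%
    filter(!is.na(.data$bin)) %>%
    group_by(.data$trajectory, .data$bin) %>%
    summarise(p = mean(.data$k_present), .groups = "drop")
  bins <- as.character(per_bin$bin)
  pv <- list()
  if (length(bins) > 1) {
    for (i in seq_len(length(bins) - 1)) {
      for (j in seq(i + 1, length(bins))) {
        a <- per_traj$p[per_traj$bin == bins[i]]
        b <- per_traj$p[per_traj$bin == bins[j]]
        pval <- if (length(a) > 1 && length(b) > 1 &&
                    (sd(a) > 0 || sd(b) > 0)) {
          stats::t.test(a, b)$p.value
        } else {
          NA_real_
        }
        pv[[length(pv) + 1]] <- tibble(bin_a = bins[i], bin_b = bins[j],
                                       p_value = pval)
      }
    }
  }
  attr(per_bin, "p_values") <- dplyr::bind_rows(pv)
  per_bin
}

#' Standard tICA feature table of an ensemble
#'
#' Computes the twelve canonical input parameters: four distances tracking
#' the tagged ion (to `Na1`, `E428`, `D421`, `D79`), seven intracellular
#' gate distances (`R60`–`Y335`, `R60`–`E446`, `R60`–`E428`, `R60`–`D436`,
#' `Y335`–`E428`, `D436`–`R445`, `E428`–`R445`) and the ion's water
#' coordination number.
#'
#' @param frames A [frame_ensemble()].
#' @param coord_cutoff Hydration-shell cutoff in Å for the coordination
#'   number.
#' @return A tibble `trajectory`, `frame` plus 12 feature columns; the
#'   stride is carried in attribute `"stride"`.
#' @export
table_features <- function(frames, coord_cutoff = 3.5) {
  pairs <- list(
    na2_na1   = c("Na2", "Na1"),
    na2_e428  = c("Na2", "E428"),
    na2_d421  = c("Na2", "D421"),
    na2_d79   = c("Na2", "D79"),
    r60_y335  = c("R60", "Y335"),
    r60_e446  = c("R60", "E446"),
    r60_e428  = c("R60", "E428"),
    r60_d436  = c("R60", "D436_CB"),
    y335_e428 = c("Y335", "E428"),
    d436_r445 = c("D436_CB", "R445"),
    e428_r445 = c("E428", "R445")
  )
  dists <- pair_distances(frames, pairs)
  coord <- coordination_number(frames, cutoff = coord_cutoff)
  out <- dplyr::left_join(dists, coord, by = c("trajectory", "frame")) %>%
    rename(na2_water_coord = "coordination") %>%
    arrange(.data$trajectory, .data$frame)
  attr(out, "stride") <- frame_stride(frames)
  out
}

#' Write / read a feature table as TSV
#'
#' @param features A feature tibble (e.g. from [table_features()]).
#' @param path Path of the TSV file.
#' @return `path` / the feature tibble.
#' @export
write_features_tsv <- function(features, path) {
  utils::write.table(features, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  meta <- list(stride = attr(features, "stride") %||% 1)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_features_tsv
#' @export
read_features_tsv <- function(path) {
  out <- as_tibble(utils::read.table(path, sep = "\t", header = TRUE))
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    attr(out, "stride") <-
      jsonlite::read_json(meta_path, simplifyVector = TRUE)$stride %||% 1
  }
  out
}
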