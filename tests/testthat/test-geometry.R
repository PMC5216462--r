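# A minimal hand-built frame for clause-level checks.
tiny_frame <- function(waters, lipids = NULL) {
  base <- data.frame(
    trajectory = 1L, frame = 1L,
    label = c("F326_CB", "DA", "D436_CB", "T269_N", "Na2", "Na1"),
    role = c("marker", "ligand", "marker", "marker", "ion", "ion"),
    x = c(0, 0, 0, 1, 0, 1), y = c(0, 0, 0, 0, 0, 1),
    z = c(0, -10, -11, -4, -3, -1)
  )
  wt <- data.frame(
    trajectory = 1L, frame = 1L,
    label = sprintf("W%02d", seq_len(nrow(waters))), role = "water",
    x = waters[, 1], y = waters[, 2], z = waters[, 3]
  )
  out <- rbind(base, wt)
  if (!is.null(lipids)) {
    lp <- data.frame(
      trajectory = 1L, frame = 1L,
      label = sprintf("L%02d", seq_len(nrow(lipids))), role = "lipid",
      x = lipids[, 1], y = lipids[, 2], z = lipids[, 3]
    )
    out <- rbind(out, lp)
  }
  out
}

test_that("pair distances match hand geometry", {
  fr <- frame_ensemble(tiny_frame(rbind(c(3, 4, 0))), stride = 1)
  d <- pair_distances(fr, list(p = c("F326_CB", "W01")))
  expect_equal(d$p, 5)
  d0 <- pair_distances(fr, list(p = c("F326_CB", "F326_CB")))
  expect_equal(d0$p, 0)
  expect_error(pair_distances(fr, list(c("F326_CB", "NOPE"))), "NOPE")
})

test_that("coordination number counts waters inside the cutoff", {
  w <- rbind(
    matrix(rep(c(0, 0, -3), 4), ncol = 3, byrow = TRUE) +
      cbind(c(2.3, -2.3, 0, 0), c(0, 0, 2.3, -2.3), 0),
    matrix(rep(c(5, 0, -3), 2), ncol = 3, byrow = TRUE)
  )
  fr <- frame_ensemble(tiny_frame(w), stride = 1)
  cn <- coordination_number(fr, cutoff = 3.5)
  expect_identical(cn$coordination, 4L)
  none <- frame_ensemble(tiny_frame(rbind(c(50, 50, 50))), stride = 1)
  expect_identical(coordination_number(none, cutoff = 3.5)$coordination, 0L)
})

test_that("EC vestibule clauses act independently and as written", {
  # all clauses slack
  fr1 <- tiny_frame(rbind(c(0, 0, 10)))
  expect_equal(assign_ec_vestibule(fr1), "W01")
  # outside the 26 A sphere
  fr2 <- tiny_frame(rbind(c(0, 0, 30)))
  expect_equal(assign_ec_vestibule(fr2), character(0))
  # z clause fires even though the sphere clause is satisfied:
  # dist = sqrt(100 + 576) = 26.0 <= 26 but dz = 24 > 23
  fr3 <- tiny_frame(rbind(c(10, 0, 24)))
  expect_equal(brute_ec_vestibule(fr3), character(0))
  expect_equal(assign_ec_vestibule(fr3), character(0))
  # one-sided z clause: a water far below passes z but the sphere limits it
  fr4 <- tiny_frame(rbind(c(0, 0, -24), c(0, 0, -27)))
  expect_equal(assign_ec_vestibule(fr4), "W01")
  # lipid exclusion
  fr5 <- tiny_frame(rbind(c(0, 0, 10)), lipids = rbind(c(0, 3, 10)))
  expect_equal(assign_ec_vestibule(fr5), character(0))
})

test_that("EC cavity is the vestibule subset near the ligand", {
  fr <- tiny_frame(rbind(c(0, 0, -1), c(0, 0, 12)))
  # W01: 9 A above DA (z=-10): in vestibule and within 10 of DA
  # W02: 22 A from DA: in vestibule only
  expect_setequal(assign_ec_vestibule(fr), c("W01", "W02"))
  expect_equal(assign_ec_cavity(fr), "W01")
  expect_equal(brute_ec_cavity(fr), "W01")
})

test_that("IC vestibule partition follows the three clauses", {
  fr <- tiny_frame(rbind(
    c(0, 5, -10),   # 5 A from DA, 6.7 A from T269_N -> channel
    c(0, 13, -14),  # 13.6 A from DA, 14.2 A from T269_N -> cavity
    c(0, 20, -10)   # 20 A from DA -> outside
  ))
  ic <- assign_ic_vestibule(fr)
  expect_setequal(ic$IC_vestibule, c("W01", "W02"))
  expect_equal(ic$IC_channel, "W01")
  expect_equal(ic$IC_cavity, "W02")
  br <- brute_ic_split(fr)
  expect_setequal(ic$IC_channel, br$IC_channel)
  expect_setequal(ic$IC_cavity, br$IC_cavity)
})

test_that("interaction frequency is the percent of close frames", {
  expect_equal(interaction_frequency(c(3, 7, 5, 8), 6), 50)
  expect_equal(interaction_frequency(c(1, 2, 3), 6), 100)
  expect_error(interaction_frequency(numeric(0), 6), "non-empty")
  set.seed(1)
  x <- runif(500, 0, 12)
  expect_equal(interaction_frequency(x, 6),
               100 * sum(x <= 6) / length(x))
})

test_that("mediated contacts require the mediator near both partners", {
  fr <- tiny_frame(rbind(c(0, 0, 5)))
  # mediator 4 A from both partners
  fr$label[fr$label == "W01"] <- "MED"
  fr$role[fr$label == "MED"] <- "lipid"
  fr <- rbind(fr, data.frame(trajectory = 1L, frame = 1L, label = "RA",
                             role = "marker", x = 0, y = 0, z = 9),
              data.frame(trajectory = 1L, frame = 1L, label = "RB",
                         role = "marker", x = 0, y = 0, z = 1))
  expect_true(mediated_contact(fr, "RA", "RB", "MED", cutoff = 6))
  expect_identical(mediated_contact(fr, "RA", "RB", "MED", cutoff = 6),
                   brute_mediated(fr, "RA", "RB", "MED", 6))
  # move mediator away from B
  fr$z[fr$label == "MED"] <- 9
  expect_false(mediated_contact(fr, "RA", "RB", "MED", cutoff = 3))
})

test_that("all geometric operators equal brute force on random frames", {
  for (seed in 1:100) {
    fr <- random_frame(seed)
    expect_setequal(assign_ec_vestibule(fr), brute_ec_vestibule(fr))
    expect_setequal(assign_ec_cavity(fr), brute_ec_cavity(fr))
    ic <- assign_ic_vestibule(fr)
    br <- brute_ic_split(fr)
    expect_setequal(ic$IC_vestibule, br$IC_vestibule)
    expect_setequal(ic$IC_channel, br$IC_channel)
    expect_setequal(ic$IC_cavity, br$IC_cavity)
    # partition invariant
    expect_setequal(c(ic$IC_channel, ic$IC_cavity), ic$IC_vestibule)
    expect_length(intersect(ic$IC_channel, ic$IC_cavity), 0)
    fe <- frame_ensemble(fr, stride = 1)
    cn <- coordination_number(fe, cutoff = 3.5)
    expect_identical(cn$coordination, brute_coordination(fr, "Na2", 3.5))
    expect_identical(
      mediated_contact(fr, c("R60", "K66"), "R445",
                       grep("^LIP", fr$label, value = TRUE), 6),
      brute_mediated(fr, c("R60", "K66"), "R445",
                     grep("^LIP", fr$label, value = TRUE), 6)
    )
  }
})

test_that("pair distances agree with the double-loop oracle on ensembles", {
  fr <- synthesize_frames("release", n_frames = 25, seed = 31,
                          release_frame = 14)
  fast <- pair_distances(fr, list(d = c("Na2", "E428")))
  slow <- brute_pair_distances(fr, "Na2", "E428")
  expect_equal(fast$d, slow$dist, tolerance = 1e-10)
})

test_that("K+ site probability separates known two-group proportions", {
  # two bins of 200 frames; K+ present near D79 in 10% vs 60% of frames,
  # spread over 20 trajectories so the t-test has trajectory replicates
  set.seed(99)
  mk <- function(traj, frame, d_na, k_near) {
    data.frame(
      trajectory = traj, frame = frame,
      label = c("Na2", "Na1", "D79", "K1"),
      role = c("ion", "ion", "marker", "ion"),
      x = c(0, d_na, 5, if (k_near) 6 else 40),
      y = c(0, 0, 0, 0), z = c(0, 0, 0, 0)
    )
  }
  rows <- list()
  idx <- 0
  for (tr in 1:20) {
    for (f in 1:20) {
      idx <- idx + 1
      near_bin <- f <= 10 # Na2-Na1 = 3 (bin 1) vs 15 (bin 2)
      p <- if (near_bin) 0.1 else 0.6
      rows[[idx]] <- mk(tr, f, if (near_bin) 3 else 15, runif(1) < p)
    }
  }
  fr <- frame_ensemble(do.call(rbind, rows), stride = 1)
  res <- kplus_site_probability(fr, breaks = c(0, 10, Inf), n_boot = 50,
                                boot_range = c(10, 15), seed = 2)
  expect_equal(nrow(res), 2)
  expect_lt(res$probability[1], res$probability[2])
  pv <- attr(res, "p_values")
  expect_lt(pv$p_value[1], 0.01)
  # closed-form two-proportion z-test agrees on rejection
  p1 <- res$probability[1]; p2 <- res$probability[2]
  pp <- (200 * p1 + 200 * p2) / 400
  z <- (p2 - p1) / sqrt(pp * (1 - pp) * (2 / 200))
  expect_gt(abs(z), qnorm(0.995))
})

test_that("feature tables carry the twelve canonical parameters", {
  fr <- synthesize_frames("release", n_frames = 30, seed = 12,
                          release_frame = 18)
  tf <- table_features(fr)
  expect_equal(ncol(tf) - 2, 12)
  expect_true(all(tf$na2_water_coord == as.integer(tf$na2_water_coord)))
  dist_cols <- setdiff(names(tf), c("trajectory", "frame",
                                    "na2_water_coord"))
  expect_true(all(as.matrix(tf[dist_cols]) >= 0))
  # TSV round trip
  path <- file.path(tempdir(), "features.tsv")
  write_features_tsv(tf, path)
  back <- read_features_tsv(path)
  expect_equal(attr(back, "stride"), attr(tf, "stride"))
  expect_equal(back$na2_na1, tf$na2_na1, tolerance = 1e-8)
  unlink(c(path, paste0(path, ".json")))
})
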