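test_that("dual-cutoff state machine follows the scripted distance series", {
  # 0.4 nm frames 10-19, 0.7 nm frames 20-24, 0.9 nm frame 25 (0-based)
  d <- c(rep(9, 10), rep(4, 10), rep(7, 5), 9, rep(9, 4))  # Angstrom
  ev <- dual_cutoff_events(scripted_series(d), r_on = 0.5, r_off = 0.8)
  expect_equal(nrow(ev), 1L)
  expect_equal(c(ev$start_frame, ev$end_frame), c(10L, 24L))

  # never reaches r_on: no events even though always within r_off
  expect_equal(nrow(dual_cutoff_events(scripted_series(rep(6, 50)))), 0L)

  # constant deep contact: one event spanning everything
  ev2 <- dual_cutoff_events(scripted_series(rep(3, 100)))
  expect_equal(c(ev2$start_frame, ev2$end_frame), c(0L, 99L))

  expect_error(dual_cutoff_events(scripted_series(rep(3, 5)),
                                  r_on = 0.9, r_off = 0.8), "r_on <= r_off")
})

test_that("events match the explicit per-frame oracle on random series", {
  set.seed(15)
  for (i in 1:40) {
    n <- sample(20:200, 1)
    # random walk wandering across both cutoffs
    d <- abs(4 + cumsum(stats::rnorm(n, 0, 1.5)))
    ev <- dual_cutoff_events(scripted_series(d))
    want <- oracle_dual_cutoff_series(d, 0.5, 0.8)
    expect_equal(nrow(ev), length(want))
    if (length(want)) {
      wm <- do.call(rbind, want)
      expect_equal(ev$start_frame, wm[, 1])
      expect_equal(ev$end_frame, wm[, 2])
      # event validity: starts at r_on, interior within r_off
      for (j in seq_len(nrow(ev))) {
        expect_lte(d[ev$start_frame[j] + 1], 5)
        expect_true(all(d[(ev$start_frame[j] + 1):(ev$end_frame[j] + 1)] <= 8))
      }
    }
  }
})

test_that("r_on = r_off reduces to plain single-cutoff thresholding", {
  set.seed(16)
  for (i in 1:20) {
    d <- abs(5 + cumsum(stats::rnorm(80, 0, 2)))
    ev <- dual_cutoff_events(scripted_series(d), r_on = 0.6, r_off = 0.6)
    r <- rle(d <= 6)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    runs <- cbind(starts, ends)[r$values, , drop = FALSE]
    expect_equal(nrow(ev), nrow(runs))
    if (nrow(runs)) {
      expect_equal(ev$start_frame, unname(runs[, 1] - 1L))
      expect_equal(ev$end_frame, unname(runs[, 2] - 1L))
    }
  }
})

test_that("occupancy counts frames with any lipid contact, once per frame", {
  d <- rep(9, 100); d[11:25] <- 3
  ev <- dual_cutoff_events(scripted_series(d))
  occ <- residue_occupancy(ev, 100)
  expect_equal(occ$occupancy_pct, 15)

  # two lipids parked on the same residue all frames: 100, not 200
  m <- rbind(rep(3, 60), rep(3, 60))
  ev2 <- dual_cutoff_events(scripted_multi_series(m))
  expect_equal(nrow(ev2), 2L)
  occ2 <- residue_occupancy(ev2, 60)
  expect_equal(nrow(occ2), 1L)
  expect_equal(occ2$occupancy_pct, 100)

  expect_equal(nrow(residue_occupancy(ev2[0, ], 60)), 0L)
  # matches the explicit frame-marking oracle on random event sets
  set.seed(17)
  for (i in 1:20) {
    m <- matrix(abs(5 + cumsum(stats::rnorm(3 * 120, 0, 2))), nrow = 3)
    ev3 <- dual_cutoff_events(scripted_multi_series(m))
    occ3 <- residue_occupancy(ev3, 120)
    if (nrow(ev3)) {
      want <- oracle_residue_occupancy(ev3, 120)
      expect_equal(stats::setNames(occ3$occupancy_pct, occ3$residue),
                   want[occ3$residue])
    }
  }
})

test_that("occupancy is monotone non-decreasing in the outer cutoff", {
  set.seed(18)
  for (i in 1:10) {
    d <- abs(5 + cumsum(stats::rnorm(150, 0, 2)))
    ts <- scripted_series(d)
    occ_of <- function(r_off) {
      ev <- dual_cutoff_events(ts, r_on = 0.5, r_off = r_off)
      if (nrow(ev) == 0L) 0 else residue_occupancy(ev, 150)$occupancy_pct
    }
    vals <- vapply(c(0.5, 0.6, 0.8, 1.0), occ_of, numeric(1L))
    expect_true(all(diff(vals) >= 0))
    expect_true(all(vals >= 0 & vals <= 100))
  }
})

test_that("residence times are event lengths times the frame stride", {
  d <- rep(9, 100); d[11:25] <- 3
  ev <- dual_cutoff_events(scripted_series(d))
  rt <- residence_times(ev, frame_stride_ps = 1000)
  expect_equal(rt$overall_mean_ps, 15000)
  expect_equal(rt$overall_max_ps, 15000)
  d2 <- rep(9, 100); d2[1:10] <- 3; d2[51:80] <- 3
  rt2 <- residence_times(dual_cutoff_events(scripted_series(d2)), 1)
  expect_equal(rt2$overall_mean_ps, 20)
  expect_equal(rt2$n_events, 2L)
})

test_that("binding sites split by lipid commonality and merge under one lipid", {
  # two residue groups visited by disjoint lipids -> two sites
  sites <- list(c("A:2", "A:4"), c("C:6", "C:8"))
  dt <- make_dwell_trajectory(toy4_sparse, sites, n_lipids = 2L,
                              n_frames = 300L, dwell_mean_frames = 40,
                              free_mean_frames = 20, seed = 19L)
  ev <- dual_cutoff_events(dt$traj)
  got <- cluster_binding_sites(ev, dt$traj$n_frames)
  expect_length(got$sites, 2L)
  expect_equal(lapply(got$sites, `[[`, "residues")[order(vapply(
    got$sites, function(s) s$residues[1], character(1L)))],
    list(c("A:2", "A:4"), c("C:6", "C:8")), ignore_attr = TRUE)

  # one lipid parked across all residues of one site -> single site
  dt2 <- make_dwell_trajectory(toy4_sparse, list(c("A:2", "A:4", "A:6")),
                               n_lipids = 1L, n_frames = 100L,
                               dwell_mean_frames = Inf, seed = 20L)
  ev2 <- dual_cutoff_events(dt2$traj)
  got2 <- cluster_binding_sites(ev2, 100L)
  expect_length(got2$sites, 1L)
  expect_equal(got2$sites[[1]]$residues, c("A:2", "A:4", "A:6"))
  expect_equal(got2$sites[[1]]$occupancy_pct, 100)
})

test_that("site occupancy uses union semantics over member residues", {
  # two residues occupied on disjoint halves -> site occupancy 100
  ev <- data.frame(lipid_id = c("L1", "L2"), residue = c("A:1", "A:2"),
                   chain_id = "A", residue_number = 1:2,
                   start_frame = c(0L, 50L), end_frame = c(49L, 99L),
                   n_frames_event = 50L, stringsAsFactors = FALSE)
  expect_equal(site_occupancy(c("A:1", "A:2"), ev, 100), 100)
  expect_equal(site_occupancy(c("A:9"), ev, 100), 0)
  occ <- residue_occupancy(ev, 100)
  expect_gte(site_occupancy(c("A:1", "A:2"), ev, 100),
             max(occ$occupancy_pct))
  # scripted 90-of-100-frames fixture
  d <- rep(9, 100); d[1:90] <- 3
  ev2 <- dual_cutoff_events(scripted_series(d))
  expect_equal(site_occupancy("A:1", ev2, 100), 90)
})

test_that("density map conserves mass and localizes a static lipid", {
  dt <- make_dwell_trajectory(toy4_sparse, list(c("A:2", "A:4")),
                              n_lipids = 1L, n_frames = 50L,
                              dwell_mean_frames = Inf, seed = 21L)
  dm <- density_map(dt$traj, grid_spacing = 2)
  expect_equal(sum(dm$density) * dm$n_frames, dm$n_observations)
  # static reference bead: all mass in one cell with value 1.0
  expect_equal(max(dm$density), 1.0)
  expect_equal(sum(dm$density > 0), 1L)

  # multinomial check: uniform positions fill cells near expectation
  set.seed(22)
  n_obs <- 10000L
  protein <- data.frame(atom_name = "CA", chain_id = "A",
                        residue_number = 1L, residue_name = "LYS")
  beads <- data.frame(lipid_id = sprintf("L%d", 1:10), bead_name = "B1",
                      species = "POP3")
  bxyz <- array(stats::runif(10 * 3 * 1000, 0, 40), dim = c(10, 3, 1000))
  bxyz[, 3, ] <- -abs(bxyz[, 3, ])  # inner leaflet
  ts <- frame_series(protein, beads, array(0, c(1, 3, 1000)), bxyz)
  dm2 <- density_map(ts, grid_spacing = 10, leaflet = "inner")
  counts <- dm2$density * dm2$n_frames
  expect_equal(sum(counts), n_obs)
  expected <- n_obs / length(counts)
  sigma <- sqrt(expected * (1 - 1 / length(counts)))
  expect_true(all(abs(counts - expected) < 4 * sigma))
  expect_error(density_map(ts, grid_spacing = 0), "positive")
})

test_that("trajectory analysis is invariant under rigid rotation about z", {
  sites <- list(c("A:2", "A:4"), c("B:6", "B:8"))
  dt <- make_dwell_trajectory(toy4_sparse, sites, n_lipids = 2L,
                              n_frames = 200L, dwell_mean_frames = 25,
                              free_mean_frames = 25, seed = 23L)
  base_ev <- dual_cutoff_events(dt$traj)
  rot <- dt$traj
  th <- 2 * pi / 4  # one C4 step
  rot_mat <- function(a) {
    out <- a
    out[, 1, ] <- cos(th) * a[, 1, ] - sin(th) * a[, 2, ]
    out[, 2, ] <- sin(th) * a[, 1, ] + cos(th) * a[, 2, ]
    out
  }
  rot$protein_xyz <- rot_mat(rot$protein_xyz)
  rot$bead_xyz <- rot_mat(rot$bead_xyz)
  rot_ev <- dual_cutoff_events(rot)
  expect_equal(rot_ev[, c("residue", "start_frame", "end_frame")],
               base_ev[, c("residue", "start_frame", "end_frame")])
  expect_equal(residue_occupancy(rot_ev, 200), residue_occupancy(base_ev, 200))
})
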