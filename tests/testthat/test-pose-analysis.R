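make_hexagon_pose <- function(center = c(0, 0, 0), c1 = c(0, 0, -3),
                              species = "PI45P2") {
  ring_ang <- 2 * pi * (0:5) / 6
  atoms <- data.frame(
    atom_name = c(paste0("C1", 1:6), "C1", "P4", "P5"),
    element = c(rep("C", 6L), "C", "P", "P"),
    x = c(cos(ring_ang) + center[1], c1[1], center[1] + 2.8, center[1] + 2.4),
    y = c(sin(ring_ang) + center[2], c1[2], center[2], center[2] - 1.6),
    z = c(rep(center[3], 6L), c1[3], center[3], center[3]),
    chain_id = "L", residue_number = 1L, residue_name = species,
    stringsAsFactors = FALSE)
  ligand_pose(1L, species, atoms)
}

test_that("pose vector centroids are unweighted group means", {
  p <- make_hexagon_pose()
  v <- compute_pose_vector(p)
  expect_equal(v$inositol, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(v$c1, c(0, 0, -3))
  expect_equal(v$wedge_rotation_k, 0L)

  # brute-force mean oracle on an arbitrary 6-atom ring
  set.seed(3)
  a <- p$atoms
  ring <- a$atom_name %in% paste0("C1", 1:6)
  a$x[ring] <- stats::rnorm(6); a$y[ring] <- stats::rnorm(6)
  a$z[ring] <- stats::rnorm(6)
  v2 <- compute_pose_vector(ligand_pose(1L, "PI45P2", a))
  manual <- c(sum(a$x[ring]) / 6, sum(a$y[ring]) / 6, sum(a$z[ring]) / 6)
  expect_equal(v2$inositol, manual, tolerance = 1e-12)
})

test_that("missing mapped atoms are reported by name and group", {
  p <- make_hexagon_pose()
  p$atoms <- p$atoms[p$atoms$atom_name != "P4", ]
  expect_error(compute_pose_vector(p), "P4.*anchor_phosphate")
})

test_that("orientation filter accepts membrane-facing and rejects cytoplasmic tails", {
  up <- orientation_filter(pv(1, c1 = c(0, 0, 3), ino = c(0, 0, 0)), mem)
  expect_true(up$accept)
  expect_equal(up$elevation_deg, 90)
  down <- orientation_filter(pv(1, c1 = c(0, 0, -3), ino = c(0, 0, 0)), mem)
  expect_false(down$accept)
  expect_equal(down$elevation_deg, -90)
  # slightly below parallel, within tolerance
  t_len <- 3
  phi <- -5 * pi / 180
  tilted <- pv(1, c1 = c(t_len * cos(phi), 0, t_len * sin(phi)),
               ino = c(0, 0, 0))
  f <- orientation_filter(tilted, mem, tolerance_deg = 15)
  expect_true(f$accept)
  expect_equal(f$elevation_deg, -5, tolerance = 1e-9)
  expect_false(orientation_filter(tilted, mem, tolerance_deg = 2)$accept)
})

test_that("acceptance is invariant under rigid rotation about z", {
  set.seed(4)
  for (i in 1:30) {
    ino <- stats::rnorm(3, sd = 10); c1 <- ino + stats::rnorm(3)
    base <- orientation_filter(pv(1, c1, ino), mem)
    k <- sample(0:5, 1); n <- 6L
    rot <- pv(1, rotate_about_z(c1, k, n), rotate_about_z(ino, k, n))
    f <- orientation_filter(rot, mem)
    expect_identical(f$accept, base$accept)
    expect_equal(f$elevation_deg, base$elevation_deg, tolerance = 1e-9)
  }
})

test_that("wedge reduction lands azimuths in [0, 360/n) and is idempotent", {
  sym <- symmetry_spec(4L, LETTERS[1:4])
  in_wedge <- pv(1, c(1, 1, 2), ino = c(cos(pi / 4), sin(pi / 4), -5) * 10)
  r <- reduce_to_reference_wedge(in_wedge, sym)
  expect_equal(r$wedge_rotation_k, 0L)
  expect_equal(r$inositol, in_wedge$inositol)

  az190 <- pv(2, c(0, 0, 0), ino = 12 * c(cos(190 * pi / 180),
                                          sin(190 * pi / 180), -1))
  r2 <- reduce_to_reference_wedge(az190, sym)
  expect_equal(r2$wedge_rotation_k, 2L)
  expect_equal(atan2(r2$inositol[2], r2$inositol[1]) * 180 / pi, 10,
               tolerance = 1e-9)
  expect_equal(reduce_to_reference_wedge(r2, sym), r2)

  # modular-arithmetic oracle over random azimuths and orders
  set.seed(5)
  for (i in 1:40) {
    n <- sample(1:8, 1)
    az <- stats::runif(1, 0, 360)
    v <- pv(i, c(0, 0, 1), ino = 8 * c(cos(az * pi / 180),
                                       sin(az * pi / 180), -1))
    red <- reduce_to_reference_wedge(v, symmetry_spec(n, LETTERS[1:n]))
    new_az <- (atan2(red$inositol[2], red$inositol[1]) * 180 / pi) %% 360
    expect_lt(new_az, 360 / n + 1e-9)
    expect_equal(red$wedge_rotation_k,
                 as.integer((-floor(az / (360 / n))) %% n))
  }
  expect_error(reduce_to_reference_wedge(pv(1, c(1, 1, 1), c(0, 0, -3)), sym),
               "symmetry axis")
})

test_that("contact cutoff boundary is inclusive at exactly 4 A", {
  m <- point_model(c(0, 0, 0))
  expect_equal(contact_residues(point_pose(c(3.9, 0, 0)), m, 4), "A:1")
  expect_equal(contact_residues(point_pose(c(4.0, 0, 0)), m, 4), "A:1")
  expect_length(contact_residues(point_pose(c(4.1, 0, 0)), m, 4), 0L)
})

test_that("contact sets match the all-pairs distance oracle and are monotone", {
  set.seed(6)
  for (i in 1:10) {
    atoms <- data.frame(
      atom_name = sprintf("X%d", 1:20), element = "C",
      x = stats::runif(20, -20, 20), y = stats::runif(20, -20, 20),
      z = stats::runif(20, -25, 25), chain_id = "L",
      residue_number = 1L, residue_name = "PI45P2",
      stringsAsFactors = FALSE)
    pose <- ligand_pose(i, "PI45P2", atoms)
    k <- sample(0:3, 1)
    got <- contact_residues(pose, toy4, 4, rotation_k = k)
    expect_identical(got, oracle_contact_residues(pose, toy4, 4, k))
    inner <- contact_residues(pose, toy4, 3)
    outer <- contact_residues(pose, toy4, 6)
    expect_true(all(inner %in% outer))
  }
})

test_that("hydrogens are excluded from contact detection on both sides", {
  m <- point_model(c(0, 0, 0))
  h_atoms <- data.frame(atom_name = "H1", element = "H", x = 1, y = 0, z = 0,
                        chain_id = "L", residue_number = 1L,
                        residue_name = "PI45P2", stringsAsFactors = FALSE)
  expect_error(contact_residues(ligand_pose(1L, "PI45P2", h_atoms), m, 4),
               "heavy atoms")
  both <- rbind(h_atoms,
                data.frame(atom_name = "C9", element = "C", x = 50, y = 0,
                           z = 0, chain_id = "L", residue_number = 1L,
                           residue_name = "PI45P2", stringsAsFactors = FALSE))
  expect_length(contact_residues(ligand_pose(1L, "PI45P2", both), m, 4), 0L)
})

test_that("contact frequencies recover planted per-residue probabilities", {
  probs <- c("A:2" = 0.8, "C:5" = 0.3)
  cp <- make_contact_pose_set(toy4_sparse, probs, n = 400L, seed = 9L)
  res <- residue_contact_frequencies(cp$poses, NULL, toy4_sparse, cutoff = 4)
  f <- res$frequencies
  expect_true(all(f$pct >= 0 & f$pct <= 100))
  got <- stats::setNames(f$pct, f$residue)
  expect_lt(abs(got[["A:2"]] - 80), 5)
  expect_lt(abs(got[["C:5"]] - 30), 5)
  # simple exact cases
  expect_equal(res$n_poses, 400L)
  expect_equal(res$n_distinct_residues, nrow(f))
})
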