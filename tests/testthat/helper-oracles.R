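# Independent brute-force oracles. These deliberately use the most naive
# formulation of each operation (double loops, explicit per-frame state
# walks, union-find over all pairs) so they share no code path with the
# package implementations they check.

oracle_contact_residues <- function(pose, model, cutoff, rotation_k = 0L) {
  lig <- pose$atoms[toupper(pose$atoms$element) != "H", , drop = FALSE]
  prot <- model$atoms[toupper(model$atoms$element) != "H", , drop = FALSE]
  theta <- 2 * pi * rotation_k / model$symmetry$order
  hits <- character()
  for (i in seq_len(nrow(lig))) {
    lx <- cos(theta) * lig$x[i] - sin(theta) * lig$y[i]
    ly <- sin(theta) * lig$x[i] + cos(theta) * lig$y[i]
    lz <- lig$z[i]
    for (j in seq_len(nrow(prot))) {
      d <- sqrt((lx - prot$x[j])^2 + (ly - prot$y[j])^2 + (lz - prot$z[j])^2)
      if (d <= cutoff)
        hits <- c(hits, paste(prot$chain_id[j], prot$residue_number[j],
                              sep = ":"))
    }
  }
  sort(unique(hits))
}

# single linkage at a fixed cutoff == connected components of the
# "directly linked" graph; grown by naive label propagation
oracle_single_linkage <- function(vectors, cutoff, mode = "all_centroids") {
  n <- length(vectors)
  linked <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    vi <- vectors[[i]]; vj <- vectors[[j]]
    d_ino <- sqrt(sum((vi$inositol - vj$inositol)^2))
    ok <- if (mode == "inositol_only") d_ino <= cutoff else
      d_ino <= cutoff &&
      sqrt(sum((vi$c1 - vj$c1)^2)) <= cutoff &&
      sqrt(sum((vi$phosphate - vj$phosphate)^2)) <= cutoff
    linked[i, j] <- ok
  }
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (linked[i, j] && lab[j] > lab[i]) { lab[j] <- lab[i]; changed <- TRUE }
      if (linked[i, j] && lab[i] > lab[j]) { lab[i] <- lab[j]; changed <- TRUE }
    }
    if (!changed) break
  }
  lab
}

oracle_medoid <- function(vectors) {
  n <- length(vectors)
  ids <- vapply(vectors, function(v) v$pose_id, integer(1L))
  tot <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n))
    tot[i] <- tot[i] + sqrt(sum((vectors[[i]]$inositol -
                                   vectors[[j]]$inositol)^2))
  cand <- ids[abs(tot - min(tot)) < 1e-9]
  min(cand)
}

# explicit per-frame state machine on one distance series (Angstrom in,
# cutoffs in nm); returns list of c(start, end) 0-based
oracle_dual_cutoff_series <- function(d, r_on_nm, r_off_nm) {
  on_A <- r_on_nm * 10; off_A <- r_off_nm * 10
  events <- list(); in_contact <- FALSE; start <- NA_integer_
  for (f in seq_along(d)) {
    if (!in_contact) {
      if (d[f] <= on_A) { in_contact <- TRUE; start <- f }
    } else if (d[f] > off_A) {
      events[[length(events) + 1L]] <- c(start - 1L, f - 2L)
      in_contact <- FALSE
      if (d[f] <= on_A) { in_contact <- TRUE; start <- f }
    }
  }
  if (in_contact)
    events[[length(events) + 1L]] <- c(start - 1L, length(d) - 1L)
  events
}

# occupancy by explicit frame marking from an event table
oracle_residue_occupancy <- function(events, n_frames) {
  res <- unique(events$residue)
  out <- stats::setNames(numeric(length(res)), res)
  for (rk in res) {
    marked <- rep(FALSE, n_frames)
    e <- events[events$residue == rk, , drop = FALSE]
    for (i in seq_len(nrow(e)))
      for (f in e$start_frame[i]:e$end_frame[i]) marked[f + 1L] <- TRUE
    out[rk] <- 100 * sum(marked) / n_frames
  }
  out
}

# frame_series with one protein atom at the origin and one single-bead
# lipid whose distance to it follows the scripted series (Angstrom)
scripted_series <- function(d, frame_stride_ps = 1) {
  n <- length(d)
  protein <- data.frame(atom_name = "CA", chain_id = "A",
                        residue_number = 1L, residue_name = "LYS")
  beads <- data.frame(lipid_id = "LIP_1", bead_name = "B1", species = "POP3")
  pxyz <- array(0, dim = c(1L, 3L, n))
  bxyz <- array(0, dim = c(1L, 3L, n))
  bxyz[1L, 1L, ] <- d
  frame_series(protein, beads, pxyz, bxyz, frame_stride_ps)
}

# multi-lipid scripted series: dists is a matrix n_lipids x n_frames of
# distances from each single-bead lipid to the one residue
scripted_multi_series <- function(dists) {
  nl <- nrow(dists); n <- ncol(dists)
  protein <- data.frame(atom_name = "CA", chain_id = "A",
                        residue_number = 1L, residue_name = "LYS")
  beads <- data.frame(lipid_id = sprintf("LIP_%d", seq_len(nl)),
                      bead_name = "B1", species = "POP3")
  pxyz <- array(0, dim = c(1L, 3L, n))
  bxyz <- array(0, dim = c(nl, 3L, n))
  for (li in seq_len(nl)) bxyz[li, 1L, ] <- dists[li, ]
  frame_series(protein, beads, pxyz, bxyz, 1)
}

random_pose_vectors <- function(n, spread = 30) {
  lapply(seq_len(n), function(i) {
    ino <- stats::runif(3, -spread, spread)
    structure(list(pose_id = i, c1 = ino + stats::rnorm(3),
                   inositol = ino, phosphate = ino + stats::rnorm(3),
                   wedge_rotation_k = 0L), class = "pose_vector")
  })
}

canonical_partition <- function(labels) {
  # relabel cluster ids by first appearance so partitions compare stably
  match(labels, unique(labels))
}
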