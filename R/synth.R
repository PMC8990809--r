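# Deterministic generators for toy symmetric proteins, planted pose sets
# and scripted lipid dwell trajectories. Geometry is idealized: only
# centroids and pair distances matter to the analyses under test, so
# residues are reduced to a CA + side-chain pair and headgroups to a
# regular hexagon with fixed bond lengths.

toy_residue_types <- data.frame(
  residue_name = c("LYS", "ARG", "SER", "LEU", "THR", "GLU"),
  tip_atom = c("NZ", "NH1", "OG", "CD1", "OG1", "OE1"),
  tip_element = c("N", "N", "O", "C", "O", "O"),
  stringsAsFactors = FALSE)

#' Generate a toy C_n-symmetric oligomer
#'
#' Builds \code{n_chains} idealized helical subunits placed with exact C_n
#' symmetry about z, spanning z in [-25, +25] \enc{Å}{Angstrom}. Each
#' residue carries a CA backbone atom, a CB and a side-chain tip atom, all
#' pointing radially outward, so the outer surface is solvent exposed.
#' The first chain gets a small seeded radial jitter which is then copied
#' to every symmetry image, keeping the symmetry exact while varying the
#' geometry between seeds.
#'
#' @param n_chains number of subunits (symmetry order).
#' @param residues_per_chain residues per subunit.
#' @param radius mean CA distance from the symmetry axis, \enc{Å}{Angstrom}.
#' @param seed integer seed.
#' @return a \code{\link{protein_model}} with \code{symmetry} of order
#'   \code{n_chains}.
#' @export
make_toy_oligomer <- function(n_chains = 4L, residues_per_chain = 20L,
                              radius = 15, seed = 1L) {
  if (n_chains < 1L || residues_per_chain < 1L || radius <= 0)
    stop("n_chains, residues_per_chain and radius must be positive")
  rng <- local({ set.seed(seed); stats::runif(residues_per_chain, -0.5, 0.5) })
  zs <- seq(-25, 25, length.out = residues_per_chain)
  # residues sweep a 60-degree arc so subunits do not interpenetrate
  angs <- seq(-pi / 6, pi / 6, length.out = residues_per_chain)
  types <- toy_residue_types[((seq_len(residues_per_chain) - 1L) %%
                                nrow(toy_residue_types)) + 1L, ]
  one_chain <- do.call(rbind, lapply(seq_len(residues_per_chain), function(i) {
    r_ca <- radius + rng[i]
    dir <- c(cos(angs[i]), sin(angs[i]))
    data.frame(
      atom_name = c("CA", "CB", types$tip_atom[i]),
      element = c("C", "C", types$tip_element[i]),
      x = dir[1L] * (r_ca + c(0, 1.5, 3.5)),
      y = dir[2L] * (r_ca + c(0, 1.5, 3.5)),
      z = zs[i],
      chain_id = "A",
      residue_number = i,
      residue_name = types$residue_name[i],
      stringsAsFactors = FALSE)
  }))
  chains <- LETTERS[seq_len(n_chains)]
  atoms <- do.call(rbind, lapply(seq_len(n_chains), function(k) {
    a <- one_chain
    xyz <- rotate_about_z(as.matrix(a[, c("x", "y", "z")]), k - 1L, n_chains)
    a$x <- xyz[, 1L]; a$y <- xyz[, 2L]; a$z <- xyz[, 3L]
    a$chain_id <- chains[k]
    a
  }))
  protein_model(atoms, symmetry = symmetry_spec(n_chains, chains))
}

# idealized headgroup template for one species, tail pointing up (+z);
# local frame: inositol ring centred on origin in the xy plane
headgroup_template <- function(species = "PI45P2") {
  ring_ang <- 2 * pi * (0:5) / 6
  atoms <- data.frame(
    atom_name = paste0("C1", 1:6), element = "C",
    x = 1.4 * cos(ring_ang), y = 1.4 * sin(ring_ang), z = 0,
    stringsAsFactors = FALSE)
  add <- function(a, name, el, x, y, z)
    rbind(a, data.frame(atom_name = name, element = el, x = x, y = y, z = z,
                        stringsAsFactors = FALSE))
  atoms <- add(atoms, "P1", "P", 0, -2.6, 1.2)
  atoms <- add(atoms, "C1", "C", 0, -3.0, 3.6)  # glycerol carbon, tail up
  pos_xy <- list(`3` = c(2.4, 1.6), `4` = c(2.8, 0), `5` = c(2.4, -1.6))
  phos <- switch(species,
                 PI = integer(), PI3P = 3L, PI4P = 4L, PI5P = 5L,
                 PI34P2 = c(3L, 4L), PI35P2 = c(3L, 5L),
                 PI45P2 = c(4L, 5L), PI345P3 = c(3L, 4L, 5L),
                 stop("unknown species ", species))
  for (p in 3:5) {
    xy <- pos_xy[[as.character(p)]]
    if (p %in% phos)
      atoms <- add(atoms, paste0("P", p), "P", xy[1L], xy[2L], 0.3)
    else
      atoms <- add(atoms, paste0("O", p), "O", 0.85 * xy[1L],
                   0.85 * xy[2L], 0.2)
  }
  atoms$chain_id <- "L"; atoms$residue_number <- 1L
  atoms$residue_name <- species
  atoms
}

#' Generate a planted pose set with known truth
#'
#' Places idealized phosphoinositide headgroup poses with Gaussian scatter
#' around planted centers on the intracellular side of a toy model. Each
#' pose is independently flipped tail-down (misoriented, rejected by the
#' orientation filter) with probability \code{frac_misoriented}, spun by a
#' random angle about its own axis, and optionally moved to a random
#' symmetry image of the assembly so the wedge reduction is exercised.
#'
#' @param model a \code{\link{protein_model}} (supplies the symmetry).
#' @param centers list of 3-vectors (\enc{Å}{Angstrom}), planted inositol
#'   positions; place them inside the reference wedge, on the
#'   intracellular side.
#' @param n_per_center poses per center.
#' @param scatter_sigma isotropic Gaussian scatter, \enc{Å}{Angstrom}.
#' @param frac_misoriented probability a pose is tail-flipped.
#' @param species headgroup species.
#' @param randomize_wedge move each pose to a random symmetry image
#'   (default TRUE).
#' @param seed integer seed.
#' @return list: \code{poses} (list of \code{\link{ligand_pose}}),
#'   \code{truth} data.frame (\code{pose_id}, \code{center},
#'   \code{misoriented}, \code{symmetry_k}) plus the planted centers as
#'   attribute \code{"centers"}.
#' @export
make_pose_set <- function(model, centers, n_per_center = 100L,
                          scatter_sigma = 2, frac_misoriented = 0,
                          species = "PI45P2", randomize_wedge = TRUE,
                          seed = 1L) {
  if (scatter_sigma < 0) stop("scatter_sigma must be >= 0")
  set.seed(seed)
  template <- headgroup_template(species)
  order <- model$symmetry$order
  rows <- list(); poses <- list(); pid <- 0L
  for (ci in seq_along(centers)) for (i in seq_len(n_per_center)) {
    pid <- pid + 1L
    a <- template
    mis <- stats::runif(1) < frac_misoriented
    if (mis) a$z <- -a$z  # flip tail through the ring plane
    spin <- stats::runif(1, 0, 2 * pi)
    xyz <- as.matrix(a[, c("x", "y", "z")])
    ct <- cos(spin); st <- sin(spin)
    xyz <- cbind(ct * xyz[, 1L] - st * xyz[, 2L],
                 st * xyz[, 1L] + ct * xyz[, 2L], xyz[, 3L])
    shift <- centers[[ci]] + stats::rnorm(3L, 0, scatter_sigma)
    xyz <- sweep(xyz, 2L, shift, "+")
    k <- if (randomize_wedge) sample.int(order, 1L) - 1L else 0L
    xyz <- rotate_about_z(xyz, k, order)
    a$x <- xyz[, 1L]; a$y <- xyz[, 2L]; a$z <- xyz[, 3L]
    poses[[pid]] <- ligand_pose(pid, species, a)
    rows[[pid]] <- data.frame(pose_id = pid, center = ci,
                              misoriented = mis, symmetry_k = k)
  }
  truth <- do.call(rbind, rows)
  attr(truth, "centers") <- centers
  list(poses = poses, truth = truth)
}

#' Generate poses with planted per-residue contact probabilities
#'
#' For each pose and each target residue, an extra probe atom is placed
#' within the contact cutoff of that residue's side-chain tip with the
#' planted probability, and far away otherwise. Supports binomial checks
#' of the contact-frequency tabulation.
#'
#' @param model a \code{\link{protein_model}}.
#' @param residue_probs named numeric vector: residue key
#'   (\code{"chain:resno"}) to contact probability in [0, 1].
#' @param n number of poses.
#' @param species headgroup species.
#' @param seed integer seed.
#' @return list \code{poses}, \code{truth} (the probability table).
#' @export
make_contact_pose_set <- function(model, residue_probs, n = 400L,
                                  species = "PI45P2", seed = 1L) {
  if (any(residue_probs < 0 | residue_probs > 1))
    stop("contact probabilities must lie in [0, 1]")
  set.seed(seed)
  template <- headgroup_template(species)
  far <- c(500, 500, -500)
  key_all <- residue_key(model$atoms$chain_id, model$atoms$residue_number)
  poses <- lapply(seq_len(n), function(pid) {
    a <- template
    base <- far + c(pid * 20, 0, 0)  # poses far from protein and each other
    a$x <- a$x + base[1L]; a$y <- a$y + base[2L]; a$z <- a$z + base[3L]
    probe <- 0L
    for (rk in names(residue_probs)) {
      probe <- probe + 1L
      if (stats::runif(1) < residue_probs[[rk]]) {
        at <- model$atoms[key_all == rk, , drop = FALSE]
        pos <- c(at$x[nrow(at)], at$y[nrow(at)], at$z[nrow(at)]) + c(1, 0, 0)
      } else pos <- far + c(pid * 20, probe * 10, -50)
      a <- rbind(a, data.frame(atom_name = paste0("XP", probe),
                               element = "C", x = pos[1L], y = pos[2L],
                               z = pos[3L], chain_id = "L",
                               residue_number = 1L, residue_name = species,
                               stringsAsFactors = FALSE))
    }
    ligand_pose(pid, species, a)
  })
  list(poses = poses, truth = residue_probs)
}

#' Generate a scripted lipid dwell trajectory with known truth
#'
#' Lipids alternate free diffusion far from the protein with scripted
#' dwells at planted binding sites. During a dwell every residue of the
#' site has one headgroup bead placed ~2 \enc{Å}{Angstrom} from its
#' side-chain tip (well inside the inner cutoff), so the dual-cutoff
#' detector sees the dwell exactly; between dwells all beads sit far
#' outside the outer cutoff. Dwell and free interval lengths are
#' geometrically distributed. A lipid whose \code{dwell_mean_frames} is
#' \code{Inf} stays parked at its site for the whole trajectory.
#'
#' @param model a \code{\link{protein_model}}.
#' @param site_defs list of character vectors of residue keys
#'   (\code{"chain:resno"}), one per planted site.
#' @param n_lipids number of lipid molecules; lipid i is assigned to site
#'   \code{(i - 1) \%\% length(site_defs) + 1}.
#' @param n_frames trajectory length.
#' @param dwell_mean_frames mean dwell length (scalar or per-lipid).
#' @param free_mean_frames mean free-interval length (scalar or per-lipid).
#' @param species lipid species label.
#' @param frame_stride_ps frame spacing metadata, ps.
#' @param periodic if TRUE, dwell and free intervals have the fixed
#'   lengths \code{dwell_mean_frames} / \code{free_mean_frames} instead of
#'   geometric draws, giving a deterministic duty cycle (e.g. 20 dwell /
#'   30 free plants a 40\% occupancy).
#' @param seed integer seed.
#' @return list: \code{traj} (a \code{\link{frame_series}}),
#'   \code{truth} with \code{schedule} data.frame (\code{lipid_id},
#'   \code{site}, \code{start_frame}, \code{end_frame}; 0-based inclusive),
#'   \code{site_defs}, and \code{residue_occupancy_pct} (named vector
#'   computed from the schedule).
#' @export
make_dwell_trajectory <- function(model, site_defs, n_lipids = 4L,
                                  n_frames = 1000L, dwell_mean_frames = 50,
                                  free_mean_frames = 50, species = "POP3",
                                  frame_stride_ps = 1000, periodic = FALSE,
                                  seed = 1L) {
  if (n_frames < 1L || n_lipids < 1L) stop("need >= 1 lipid and >= 1 frame")
  key_all <- residue_key(model$atoms$chain_id, model$atoms$residue_number)
  for (s in site_defs)
    if (!all(s %in% key_all)) stop("site residue not present in model: ",
                                   paste(setdiff(s, key_all), collapse = ", "))
  set.seed(seed)
  dwell_mean <- rep_len(dwell_mean_frames, n_lipids)
  free_mean <- rep_len(free_mean_frames, n_lipids)
  max_site <- max(lengths(site_defs))
  # anchor position for each site residue: side-chain tip + 2 A radially out
  anchor <- lapply(site_defs, function(res) t(vapply(res, function(rk) {
    at <- model$atoms[key_all == rk, , drop = FALSE]
    tip <- c(at$x[nrow(at)], at$y[nrow(at)], at$z[nrow(at)])
    out <- tip[1:2] / max(sqrt(sum(tip[1:2]^2)), 1e-9)
    c(tip[1L] + 2 * out[1L], tip[2L] + 2 * out[2L], tip[3L])
  }, numeric(3L))))

  beads <- do.call(rbind, lapply(seq_len(n_lipids), function(li)
    data.frame(lipid_id = sprintf("%s_%03d", species, li),
               bead_name = paste0("B", seq_len(max_site)),
               species = species, stringsAsFactors = FALSE)))
  bead_xyz <- array(0, dim = c(nrow(beads), 3L, n_frames))
  sched <- list()
  for (li in seq_len(n_lipids)) {
    site <- ((li - 1L) %% length(site_defs)) + 1L
    rows <- (li - 1L) * max_site + seq_len(max_site)
    free_pos <- c(200 + 40 * li, 200, -100)
    for (b in seq_len(max_site)) bead_xyz[rows[b], , ] <-
        free_pos + c(0, 3 * (b - 1L), 0)
    f <- 1L
    if (is.infinite(dwell_mean[li])) {
      dw <- c(1L, n_frames)
      sched[[length(sched) + 1L]] <- data.frame(
        lipid_id = beads$lipid_id[rows[1L]], site = site,
        start_frame = 0L, end_frame = n_frames - 1L)
      place_dwell(bead_xyz, rows, anchor[[site]], dw, free_pos) ->
        bead_xyz
      next
    }
    first <- TRUE
    while (f <= n_frames) {
      gap <- if (periodic) {
        # start dwelling immediately on the first cycle so the duty cycle
        # dwell/(dwell+free) is planted exactly up to end truncation
        if (first) 0L else as.integer(round(free_mean[li]))
      } else 1L + stats::rgeom(1L, 1 / max(free_mean[li], 1))
      first <- FALSE
      f <- f + gap
      if (f > n_frames) break
      len <- if (periodic) as.integer(round(dwell_mean[li])) else
        1L + stats::rgeom(1L, 1 / max(dwell_mean[li], 1))
      end <- min(f + len - 1L, n_frames)
      sched[[length(sched) + 1L]] <- data.frame(
        lipid_id = beads$lipid_id[rows[1L]], site = site,
        start_frame = f - 1L, end_frame = end - 1L)
      bead_xyz <- place_dwell(bead_xyz, rows, anchor[[site]],
                              c(f, end), free_pos)
      f <- end + 1L
    }
  }
  schedule <- if (length(sched)) do.call(rbind, sched) else
    data.frame(lipid_id = character(), site = integer(),
               start_frame = integer(), end_frame = integer())
  traj <- frame_series(
    protein = model$atoms[, c("atom_name", "chain_id", "residue_number",
                              "residue_name")],
    beads = beads,
    protein_xyz = replicate(n_frames,
                            as.matrix(model$atoms[, c("x", "y", "z")])),
    bead_xyz = bead_xyz,
    frame_stride_ps = frame_stride_ps)
  occ <- schedule_occupancy(schedule, site_defs, n_frames)
  list(traj = traj,
       truth = list(schedule = schedule, site_defs = site_defs,
                    residue_occupancy_pct = occ))
}

place_dwell <- function(bead_xyz, rows, site_anchor, frames, free_pos) {
  m <- nrow(site_anchor)
  for (b in seq_along(rows)) {
    tgt <- if (b <= m) site_anchor[b, ] else site_anchor[m, ] + c(0, 0, 2)
    for (ax in 1:3)
      bead_xyz[rows[b], ax, frames[1L]:frames[2L]] <- tgt[ax]
  }
  bead_xyz
}

# residue occupancy implied by a dwell schedule (independent of coordinates)
schedule_occupancy <- function(schedule, site_defs, n_frames) {
  res <- unique(unlist(site_defs))
  occ <- stats::setNames(numeric(length(res)), res)
  for (rk in res) {
    covered <- logical(n_frames)
    for (si in seq_along(site_defs)) {
      if (!(rk %in% site_defs[[si]])) next
      rows <- schedule[schedule$site == si, , drop = FALSE]
      for (i in seq_len(nrow(rows)))
        covered[(rows$start_frame[i] + 1L):(rows$end_frame[i] + 1L)] <- TRUE
    }
    occ[rk] <- 100 * sum(covered) / n_frames
  }
  occ
}
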