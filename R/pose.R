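pip_species <- c("PI", "PI3P", "PI4P", "PI5P", "PI34P2", "PI35P2",
                 "PI45P2", "PI345P3")

#' Default atom-group map for phosphoinositide headgroups
#'
#' Maps each phosphoinositide species to the three atom groups used for the
#' three-centroid pose reduction: the glycerol C1 carbon (where the
#' headgroup is truncated), the six inositol ring carbons, and an anchor
#' phosphate at the 3, 4 or 5 position. For the unphosphorylated parent
#' lipid PI, which has no 3/4/5 phosphate, the anchor falls back to the C4
#' hydroxyl oxygen. When a species carries several of the 3/4/5 phosphates
#' the lowest-numbered position is the anchor; edit the returned list to
#' choose another.
#'
#' Atom names follow a common headgroup convention: glycerol carbon
#' \code{C1}; inositol ring \code{C11}-\code{C16}; phosphate at position n
#' \code{Pn}; hydroxyl oxygen at position n \code{On}.
#'
#' @return named list; per species a list with \code{glycerol_c1},
#'   \code{inositol_ring}, \code{anchor_phosphate} atom-name vectors.
#' @export
default_atom_group_map <- function() {
  ring <- paste0("C1", 1:6)
  anchor <- list(PI = "O4", PI3P = "P3", PI4P = "P4", PI5P = "P5",
                 PI34P2 = "P3", PI35P2 = "P3", PI45P2 = "P4",
                 PI345P3 = "P3")
  out <- lapply(pip_species, function(sp)
    list(glycerol_c1 = "C1", inositol_ring = ring,
         anchor_phosphate = anchor[[sp]]))
  names(out) <- pip_species
  out
}

#' Construct a ligand pose
#'
#' One docked phosphoinositide headgroup pose (truncated at the glycerol C1
#' carbon). \code{docking_energy} is pass-through metadata.
#'
#' @param pose_id integer pose identifier.
#' @param species species label, one of \code{names(default_atom_group_map())}.
#' @param atoms atom table (same columns as \code{\link{protein_model}}).
#' @param docking_energy optional score, not used by any analysis.
#' @return object of class \code{ligand_pose}.
#' @export
ligand_pose <- function(pose_id, species, atoms, docking_energy = NA_real_) {
  if (!species %in% pip_species)
    stop("unknown species '", species, "'; expected one of: ",
         paste(pip_species, collapse = ", "))
  structure(list(pose_id = as.integer(pose_id), species = species,
                 atoms = atoms, docking_energy = docking_energy),
            class = "ligand_pose")
}

group_centroid <- function(atoms, names_wanted, group_label) {
  sel <- atoms$atom_name %in% names_wanted
  found <- unique(atoms$atom_name[sel])
  miss <- setdiff(names_wanted, found)
  if (length(miss))
    stop("pose is missing atom(s) ", paste(miss, collapse = ", "),
         " required for group '", group_label, "'")
  c(mean(atoms$x[sel]), mean(atoms$y[sel]), mean(atoms$z[sel]))
}

#' Reduce a pose to its three-centroid vector
#'
#' Computes the unweighted centroid of each of the three atom groups
#' (glycerol C1, inositol ring, anchor phosphate), giving the simplified
#' representative vector used by the orientation filter and clustering.
#'
#' @param pose a \code{\link{ligand_pose}}.
#' @param groups atom-group map, default \code{\link{default_atom_group_map}()}.
#' @return object of class \code{pose_vector}: centroids \code{c1},
#'   \code{inositol}, \code{phosphate} plus \code{wedge_rotation_k = 0}.
#' @export
compute_pose_vector <- function(pose, groups = default_atom_group_map()) {
  g <- groups[[pose$species]]
  if (is.null(g)) stop("no atom-group map for species ", pose$species)
  v <- structure(list(
    pose_id = pose$pose_id,
    c1 = group_centroid(pose$atoms, g$glycerol_c1, "glycerol_c1"),
    inositol = group_centroid(pose$atoms, g$inositol_ring, "inositol_ring"),
    phosphate = group_centroid(pose$atoms, g$anchor_phosphate,
                               "anchor_phosphate"),
    wedge_rotation_k = 0L), class = "pose_vector")
  if (sqrt(sum((v$c1 - v$inositol)^2)) == 0)
    stop("degenerate pose: glycerol C1 coincides with the inositol centroid")
  v
}

#' Membrane-orientation acceptance filter
#'
#' A pose is accepted when its lipid-tail direction (from the inositol ring
#' centroid toward the glycerol C1, where the acyl tails attach) is parallel
#' to the membrane plane or points toward the bilayer. With +z running from
#' the intracellular side toward the midplane, the tail elevation is
#' \code{phi = asin(t_z / |t|)}; the pose is accepted iff
#' \code{phi >= -tolerance_deg}.
#'
#' @param vec a \code{pose_vector}.
#' @param frame a \code{\link{membrane_frame}} (fixes the +z convention).
#' @param tolerance_deg slack below exactly parallel, degrees (default 15).
#' @return list with \code{accept} (logical) and \code{elevation_deg}.
#' @export
orientation_filter <- function(vec, frame, tolerance_deg = 15) {
  t <- vec$c1 - vec$inositol
  len <- sqrt(sum(t^2))
  if (len == 0) stop("zero-length tail vector; cannot orient pose")
  phi <- asin(t[3L] / len) * 180 / pi
  list(accept = phi >= -tolerance_deg, elevation_deg = phi)
}

#' Rotate a pose vector into the reference symmetry wedge
#'
#' Finds the unique symmetry step k for which the azimuth of the rotated
#' inositol centroid falls in [0, 360/order) degrees, applies that rotation
#' to all three centroids, and records it in \code{wedge_rotation_k}.
#' Idempotent: a vector already in the wedge is returned with k = 0.
#'
#' @param vec a \code{pose_vector}.
#' @param sym a \code{\link{symmetry_spec}}.
#' @return the wedge-reduced \code{pose_vector}.
#' @export
reduce_to_reference_wedge <- function(vec, sym) {
  ino <- vec$inositol
  if (ino[1L] == 0 && ino[2L] == 0)
    stop("inositol centroid lies on the symmetry axis; azimuth undefined")
  az <- atan2(ino[2L], ino[1L]) %% (2 * pi)
  wedge <- 2 * pi / sym$order
  k <- (-floor(az / wedge)) %% sym$order
  vec$c1 <- rotate_about_z(vec$c1, k, sym$order)
  vec$inositol <- rotate_about_z(vec$inositol, k, sym$order)
  vec$phosphate <- rotate_about_z(vec$phosphate, k, sym$order)
  # accumulate so k always records the total rotation from the original
  # pose frame and reduction is idempotent
  vec$wedge_rotation_k <- as.integer((vec$wedge_rotation_k + k) %% sym$order)
  vec
}

#' Residues contacting a ligand pose
#'
#' Returns every protein residue with at least one heavy atom within
#' \code{cutoff} (inclusive) of at least one ligand heavy atom. Hydrogens
#' are excluded on both sides. The pose is first rotated by
#' \code{rotation_k} symmetry steps about z (so wedge-reduced poses can be
#' matched against the unrotated model).
#'
#' @param pose a \code{\link{ligand_pose}}.
#' @param model a \code{\link{protein_model}}.
#' @param cutoff contact distance in \enc{Å}{Angstrom} (default 4.0).
#' @param rotation_k symmetry rotation applied to the pose atoms first.
#' @return character vector of residue keys \code{"chain:resno"}, sorted.
#' @export
contact_residues <- function(pose, model, cutoff = 4.0, rotation_k = 0L) {
  if (cutoff <= 0) stop("cutoff must be positive")
  lig <- pose$atoms[toupper(pose$atoms$element) != "H", , drop = FALSE]
  prot <- model$atoms[toupper(model$atoms$element) != "H", , drop = FALSE]
  if (nrow(lig) == 0L || nrow(prot) == 0L)
    stop("contact search needs heavy atoms on both the pose and the model")
  lxyz <- rotate_about_z(as.matrix(lig[, c("x", "y", "z")]),
                         rotation_k, model$symmetry$order)
  pxyz <- as.matrix(prot[, c("x", "y", "z")])
  # per protein atom, min squared distance to any ligand atom
  cut2 <- cutoff^2
  hit <- logical(nrow(pxyz))
  for (j in seq_len(nrow(lxyz))) {
    d2 <- (pxyz[, 1L] - lxyz[j, 1L])^2 + (pxyz[, 2L] - lxyz[j, 2L])^2 +
      (pxyz[, 3L] - lxyz[j, 3L])^2
    hit <- hit | d2 <= cut2
  }
  sort(unique(residue_key(prot$chain_id[hit], prot$residue_number[hit])))
}

#' Per-residue contact frequencies over accepted poses
#'
#' For each residue, the percentage of accepted poses whose 4-\enc{Å}{A}
#' contact set contains it, plus the total number of distinct residues
#' contacted by any accepted pose. Wedge rotations recorded on the pose
#' vectors are applied before the contact search.
#'
#' @param poses list of \code{\link{ligand_pose}} (the accepted ones).
#' @param vectors matching list of wedge-reduced \code{pose_vector}s (used
#'   for \code{wedge_rotation_k}); NULL means no rotation.
#' @param model a \code{\link{protein_model}}.
#' @param cutoff contact distance in \enc{Å}{Angstrom}.
#' @return list: \code{frequencies} data.frame (\code{residue},
#'   \code{chain_id}, \code{residue_number}, \code{n_poses}, \code{pct}),
#'   sorted by descending pct; \code{n_distinct_residues}; \code{n_poses}.
#' @export
residue_contact_frequencies <- function(poses, vectors = NULL, model,
                                        cutoff = 4.0) {
  if (length(poses) == 0L) stop("no accepted poses to tabulate")
  ks <- if (is.null(vectors)) rep(0L, length(poses)) else
    vapply(vectors, function(v) v$wedge_rotation_k, integer(1L))
  sets <- mapply(function(p, k) contact_residues(p, model, cutoff, k),
                 poses, ks, SIMPLIFY = FALSE)
  counts <- table(unlist(sets))
  n <- length(poses)
  if (length(counts) == 0L) {
    freq <- data.frame(residue = character(), chain_id = character(),
                       residue_number = integer(), n_poses = integer(),
                       pct = numeric(), stringsAsFactors = FALSE)
  } else {
    keys <- names(counts)
    parts <- strsplit(keys, ":", fixed = TRUE)
    freq <- data.frame(
      residue = keys,
      chain_id = vapply(parts, `[`, character(1L), 1L),
      residue_number = as.integer(vapply(parts, `[`, character(1L), 2L)),
      n_poses = as.integer(counts),
      pct = 100 * as.integer(counts) / n,
      stringsAsFactors = FALSE)
    freq <- freq[order(-freq$pct, freq$chain_id, freq$residue_number), ]
    rownames(freq) <- NULL
  }
  list(frequencies = freq, n_distinct_residues = nrow(freq), n_poses = n)
}
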