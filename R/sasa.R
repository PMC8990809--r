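# Shrake-Rupley solvent-accessible surface area on heavy atoms.
# Sphere points come from a Fibonacci lattice, fixed per point count, so
# results are deterministic.

vdw_radius <- function(element) {
  radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80,
             F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)
  r <- radii[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

#' Solvent-accessible surface area per atom
#'
#' Shrake-Rupley SASA over heavy atoms (hydrogens are ignored). Returns one
#' area per input atom; hydrogen rows get NA.
#'
#' @param atoms atom table with \code{element}, \code{x}, \code{y}, \code{z}.
#' @param probe_radius probe sphere radius in \enc{Å}{Angstrom} (water: 1.4).
#' @param n_points sphere sample points per atom; more is slower and more
#'   accurate.
#' @return numeric vector of per-atom areas in \enc{Å}{Angstrom}^2.
#' @export
atom_sasa <- function(atoms, probe_radius = 1.4, n_points = 192L) {
  heavy <- toupper(atoms$element) != "H"
  xyz <- as.matrix(atoms[heavy, c("x", "y", "z")])
  r <- vdw_radius(atoms$element[heavy]) + probe_radius
  n <- nrow(xyz)
  sph <- fibonacci_sphere(n_points)
  area <- numeric(n)
  if (n > 0L) {
    d2 <- as.matrix(stats::dist(xyz))^2
    for (i in seq_len(n)) {
      cut2 <- (r[i] + r)^2
      nb <- which(d2[i, ] < cut2)
      nb <- nb[nb != i]
      pts <- sweep(sph * r[i], 2L, xyz[i, ], "+")
      acc <- rep(TRUE, n_points)
      for (j in nb) {
        dj2 <- (pts[, 1L] - xyz[j, 1L])^2 + (pts[, 2L] - xyz[j, 2L])^2 +
          (pts[, 3L] - xyz[j, 3L])^2
        acc <- acc & dj2 > r[j]^2
        if (!any(acc)) break
      }
      area[i] <- 4 * pi * r[i]^2 * sum(acc) / n_points
    }
  }
  out <- rep(NA_real_, nrow(atoms))
  out[heavy] <- area
  out
}

backbone_names <- c("N", "CA", "C", "O", "OXT")

#' Lipid-accessible residues of the inner leaflet
#'
#' Identifies the residues forming the lipid-accessible protein surface of
#' the intracellular (inner) leaflet: a residue qualifies when (i) its
#' side-chain heavy-atom centroid lies in the z slab between the
#' intracellular headgroup boundary and the bilayer midplane, and (ii) its
#' side-chain relative solvent accessibility on the isolated protein is at
#' least \code{sasa_rel_threshold}. Relative accessibility is the residue's
#' side-chain SASA in the full model divided by the SASA of the same
#' side-chain atoms computed in isolation, which makes the measure
#' self-normalizing for any residue composition. Glycine-like residues
#' without side-chain atoms fall back to CA.
#'
#' @param model a \code{\link{protein_model}} oriented in the membrane frame.
#' @param frame a \code{\link{membrane_frame}}.
#' @param sasa_rel_threshold minimum relative side-chain accessibility
#'   (fraction, default 0.20).
#' @param probe_radius SASA probe radius in \enc{Å}{Angstrom}.
#' @return data.frame with \code{chain_id}, \code{residue_number},
#'   \code{residue_name}, \code{rel_sasa}, \code{centroid_z}, one row per
#'   accessible residue.
#' @export
accessible_leaflet_residues <- function(model, frame,
                                        sasa_rel_threshold = 0.20,
                                        probe_radius = 1.4) {
  if (!inherits(frame, "membrane_frame")) stop("frame must be a membrane_frame")
  atoms <- model$atoms
  heavy <- toupper(atoms$element) != "H"
  atoms_h <- atoms[heavy, , drop = FALSE]
  key <- residue_key(atoms_h$chain_id, atoms_h$residue_number)
  sc <- !(atoms_h$atom_name %in% backbone_names)
  # residues with no side-chain heavy atoms: use CA as proxy
  has_sc <- tapply(sc, key, any)
  use <- sc | (!has_sc[key] & atoms_h$atom_name == "CA")

  sasa_full <- atom_sasa(atoms_h, probe_radius = probe_radius)
  res_keys <- unique(key)
  out <- lapply(res_keys, function(k) {
    sel <- key == k & use
    if (!any(sel)) return(NULL)
    sub <- atoms_h[sel, , drop = FALSE]
    iso <- sum(atom_sasa(sub, probe_radius = probe_radius))
    rel <- if (iso > 0) sum(sasa_full[sel]) / iso else 0
    data.frame(chain_id = sub$chain_id[1L],
               residue_number = sub$residue_number[1L],
               residue_name = sub$residue_name[1L],
               rel_sasa = rel,
               centroid_z = mean(sub$z),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  keep <- out$rel_sasa >= sasa_rel_threshold &
    out$centroid_z >= frame$intracellular_boundary_z &
    out$centroid_z <= frame$midplane_z
  res <- out[keep, , drop = FALSE]
  res[order(res$chain_id, res$residue_number), , drop = FALSE]
}
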