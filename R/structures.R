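#' Construct a protein model
#'
#' A \code{protein_model} holds an atom table in a membrane frame (z is the
#' membrane normal) together with the rotational symmetry of the assembly.
#' Residue identity throughout the package is the pair
#' \code{(chain_id, residue_number)}.
#'
#' @param atoms data.frame with columns \code{atom_name}, \code{element},
#'   \code{x}, \code{y}, \code{z} (\enc{Å}{Angstrom}), \code{chain_id},
#'   \code{residue_number}, \code{residue_name}.
#' @param symmetry a \code{\link{symmetry_spec}}; defaults to C1 over the
#'   chains present.
#' @return object of class \code{protein_model}.
#' @export
protein_model <- function(atoms, symmetry = NULL) {
  req <- c("atom_name", "element", "x", "y", "z", "chain_id",
           "residue_number", "residue_name")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) == 0L) stop("protein model must contain at least one atom")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in atom table")
  if (any(!nzchar(atoms$atom_name))) stop("empty atom_name in atom table")
  chains <- unique(atoms$chain_id)
  if (is.null(symmetry)) symmetry <- symmetry_spec(1L, chains)
  if (!all(chains %in% symmetry$chain_cycle$chain))
    stop("chains in atom table not covered by the symmetry chain cycle")
  structure(list(atoms = atoms, chains = chains, symmetry = symmetry),
            class = "protein_model")
}

#' @export
print.protein_model <- function(x, ...) {
  cat(sprintf("protein_model: %d atoms, %d chains (%s), C%d symmetry\n",
              nrow(x$atoms), length(x$chains),
              paste(x$chains, collapse = ","), x$symmetry$order))
  invisible(x)
}

#' Rotational symmetry about the membrane normal
#'
#' Describes an exact C_n symmetry with the rotation axis fixed as z through
#' the origin. \code{chain_cycle} maps each chain to its image under one
#' n-fold rotation step (a rotation by 360/n degrees), so applying the step
#' \code{order} times is the identity permutation.
#'
#' @param order integer n >= 1.
#' @param chains ordered chain ids; the default cycle maps chain i to
#'   chain i+1 (wrapping), which matches subunits laid out counterclockwise.
#' @param image optional character vector: image[i] is the chain that
#'   chains[i] maps onto under one rotation step.
#' @return object of class \code{symmetry_spec} with a \code{chain_cycle}
#'   data.frame (columns \code{chain}, \code{image}).
#' @export
symmetry_spec <- function(order, chains, image = NULL) {
  order <- as.integer(order)
  if (is.na(order) || order < 1L) stop("symmetry order must be >= 1")
  chains <- as.character(chains)
  if (is.null(image)) {
    image <- c(chains[-1L], chains[1L])
    if (order == 1L) image <- chains
  }
  if (!setequal(image, chains) || length(image) != length(chains))
    stop("chain_cycle image must be a permutation of the chains")
  structure(list(order = order,
                 chain_cycle = data.frame(chain = chains, image = image,
                                          stringsAsFactors = FALSE)),
            class = "symmetry_spec")
}

#' Membrane frame
#'
#' Fixes the membrane geometry used by the orientation filter and the
#' leaflet slab: the membrane normal is +z, \code{midplane_z} is the bilayer
#' midplane and \code{intracellular_boundary_z} the inner-leaflet headgroup
#' plane. +z points from the intracellular side toward the midplane.
#'
#' @param midplane_z,intracellular_boundary_z heights in \enc{Å}{Angstrom};
#'   the boundary must lie below the midplane.
#' @return object of class \code{membrane_frame}.
#' @export
membrane_frame <- function(midplane_z = 0, intracellular_boundary_z = -20) {
  if (!is.finite(midplane_z) || !is.finite(intracellular_boundary_z))
    stop("membrane frame heights must be finite")
  if (intracellular_boundary_z >= midplane_z)
    stop("degenerate membrane frame: intracellular boundary must lie below the midplane")
  structure(list(midplane_z = midplane_z,
                 intracellular_boundary_z = intracellular_boundary_z),
            class = "membrane_frame")
}

#' Rotate coordinates about the z axis by a symmetry step
#'
#' Rotates by k * (360/order) degrees counterclockwise about z. Works on a
#' single 3-vector or an n x 3 matrix. The z component is untouched.
#'
#' @param coord numeric 3-vector or n x 3 matrix (\enc{Å}{Angstrom}).
#' @param k integer rotation step, 0 <= k < order.
#' @param order symmetry order, >= 1.
#' @return rotated coordinates, same shape as input.
#' @export
rotate_about_z <- function(coord, k, order) {
  order <- as.integer(order)
  if (is.na(order) || order < 1L) stop("symmetry order must be >= 1")
  k <- as.integer(k) %% order
  theta <- 2 * pi * k / order
  ct <- cos(theta); st <- sin(theta)
  if (is.matrix(coord)) {
    out <- coord
    out[, 1L] <- ct * coord[, 1L] - st * coord[, 2L]
    out[, 2L] <- st * coord[, 1L] + ct * coord[, 2L]
    out
  } else {
    c(ct * coord[1L] - st * coord[2L],
      st * coord[1L] + ct * coord[2L],
      coord[3L])
  }
}

#' Frame series (coarse-grained trajectory view)
#'
#' Holds, per frame, coordinates of a protein atom selection and of lipid
#' headgroup beads. Identities are fixed across frames: \code{protein}
#' describes the atom rows of \code{protein_xyz}, \code{beads} the rows of
#' \code{bead_xyz}. Coordinates are in \enc{Å}{Angstrom} (nm inputs are
#' converted at read time).
#'
#' @param protein data.frame: \code{atom_name}, \code{chain_id},
#'   \code{residue_number}, \code{residue_name}.
#' @param beads data.frame: \code{lipid_id}, \code{bead_name},
#'   \code{species}.
#' @param protein_xyz numeric array n_atoms x 3 x n_frames.
#' @param bead_xyz numeric array n_beads x 3 x n_frames.
#' @param frame_stride_ps time between stored frames, metadata only.
#' @return object of class \code{frame_series}.
#' @export
frame_series <- function(protein, beads, protein_xyz, bead_xyz,
                         frame_stride_ps = 1) {
  if (length(dim(protein_xyz)) != 3L || length(dim(bead_xyz)) != 3L)
    stop("coordinate arrays must be n x 3 x n_frames")
  n_frames <- dim(protein_xyz)[3L]
  if (n_frames < 1L) stop("frame series must contain at least one frame")
  if (dim(bead_xyz)[3L] != n_frames)
    stop("protein and bead arrays disagree on frame count")
  if (dim(protein_xyz)[1L] != nrow(protein) || dim(bead_xyz)[1L] != nrow(beads))
    stop("identity tables and coordinate arrays disagree on atom/bead count")
  structure(list(protein = protein, beads = beads,
                 protein_xyz = protein_xyz, bead_xyz = bead_xyz,
                 n_frames = n_frames, frame_stride_ps = frame_stride_ps),
            class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  cat(sprintf("frame_series: %d frames, %d protein atoms, %d lipid beads (%d lipids)\n",
              x$n_frames, nrow(x$protein), nrow(x$beads),
              length(unique(x$beads$lipid_id))))
  invisible(x)
}

# residue identity key "chain:resno" used internally for set operations
residue_key <- function(chain_id, residue_number) {
  paste(chain_id, residue_number, sep = ":")
}

# map residue keys to their image under k symmetry steps of the chain cycle
remap_residue_keys <- function(keys, sym, k = 1L) {
  k <- as.integer(k) %% sym$order
  if (k == 0L) return(keys)
  map <- sym$chain_cycle$image
  names(map) <- sym$chain_cycle$chain
  for (i in seq_len(k)) {
    parts <- strsplit(keys, ":", fixed = TRUE)
    keys <- vapply(parts, function(p)
      paste(map[[p[1L]]], p[2L], sep = ":"), character(1L))
  }
  keys
}
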