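# Shared fixtures, built once per test run.

toy4 <- make_toy_oligomer(n_chains = 4L, residues_per_chain = 20L,
                          radius = 15, seed = 42L)
# sparser variant: ~5.6 A between consecutive residues, so a bead parked
# at one residue's tip stays outside the 0.5 nm inner cutoff of neighbours
toy4_sparse <- make_toy_oligomer(n_chains = 4L, residues_per_chain = 10L,
                                 radius = 15, seed = 42L)
mem <- membrane_frame(midplane_z = 0, intracellular_boundary_z = -20)

# pose vector with explicit centroids
pv <- function(id, c1, ino, ph = ino + c(1, 0, 0)) {
  structure(list(pose_id = as.integer(id), c1 = c1, inositol = ino,
                 phosphate = ph, wedge_rotation_k = 0L),
            class = "pose_vector")
}

# minimal single-atom protein model at given coordinates
point_model <- function(xyz, order = 1L) {
  protein_model(data.frame(atom_name = "CA", element = "C",
                           x = xyz[1], y = xyz[2], z = xyz[3],
                           chain_id = "A", residue_number = 1L,
                           residue_name = "GLY", stringsAsFactors = FALSE),
                symmetry = symmetry_spec(order, "A"))
}

# minimal one-atom "pose" for distance boundary tests (uses PI with an O4
# anchor so the group map is satisfiable when needed)
point_pose <- function(xyz, id = 1L) {
  ligand_pose(id, "PI45P2",
              data.frame(atom_name = "C99", element = "C",
                         x = xyz[1], y = xyz[2], z = xyz[3],
                         chain_id = "L", residue_number = 1L,
                         residue_name = "PI45P2", stringsAsFactors = FALSE))
}
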