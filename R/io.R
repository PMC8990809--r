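# PDB / PDBQT reading is delegated to bio3d; PDBQT torsion-tree records
# (ROOT/BRANCH/TORSDOF) are stripped before parsing and its charge/type
# columns ignored. Elements missing from the file are inferred from the
# first alphabetic character of the atom name.

infer_element <- function(atom_name, elesy = NULL) {
  el <- if (is.null(elesy)) rep(NA_character_, length(atom_name)) else elesy
  el <- trimws(ifelse(is.na(el), "", el))
  # PDBQT atom types like OA/NA/HD are not elements; keep single letters only
  bad <- !(toupper(el) %in% c("H", "C", "N", "O", "P", "S", "F", "K",
                              "CL", "BR", "I", "MG", "NA", "ZN", "CA", "FE"))
  el[bad] <- ""
  need <- !nzchar(el)
  if (any(need)) {
    stripped <- gsub("[^A-Za-z]", "", atom_name[need])
    el[need] <- toupper(substr(stripped, 1L, 1L))
  }
  el
}

pdb_like_lines <- function(path, format) {
  lines <- readLines(path, warn = FALSE)
  if (format == "pdbqt") {
    keep <- grepl("^(ATOM|HETATM|MODEL|ENDMDL|TER|END)", lines)
    lines <- lines[keep]
    # PDBQT stores charge+type in the element columns; blank them out
    rec <- grepl("^(ATOM|HETATM)", lines)
    lines[rec] <- substr(lines[rec], 1L, 66L)
  }
  lines
}

read_pdb_via_bio3d <- function(path, format, multi) {
  lines <- pdb_like_lines(path, format)
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  suppressWarnings(bio3d::read.pdb(tmp, multi = multi, verbose = FALSE))
}

count_models <- function(path) {
  sum(grepl("^MODEL", readLines(path, warn = FALSE)))
}

atoms_from_bio3d <- function(pdb) {
  at <- pdb$atom
  if (any(!is.na(at$insert) & nzchar(trimws(at$insert))))
    stop("insertion codes are not supported; renumber residues first")
  chain <- ifelse(is.na(at$chain), "A", at$chain)
  data.frame(atom_name = at$elety,
             element = infer_element(at$elety, at$elesy),
             x = at$x, y = at$y, z = at$z,
             chain_id = chain,
             residue_number = as.integer(at$resno),
             residue_name = at$resid,
             stringsAsFactors = FALSE)
}

#' Read a single-model protein structure
#'
#' Parses ATOM/HETATM records of a PDB or PDBQT file into a
#' \code{\link{protein_model}}. Multi-model files are rejected here:
#' use \code{\link{read_pose_set}} for docked poses or
#' \code{\link{read_trajectory}} for trajectories.
#'
#' @param path file path.
#' @param format \code{"pdb"} or \code{"pdbqt"}.
#' @param symmetry optional \code{\link{symmetry_spec}}.
#' @return a \code{\link{protein_model}}.
#' @export
read_structure <- function(path, format = c("pdb", "pdbqt"), symmetry = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (count_models(path) > 1L)
    stop("multi-model input: use the pose/trajectory reader (read_pose_set or read_trajectory)")
  pdb <- read_pdb_via_bio3d(path, format, multi = FALSE)
  atoms <- atoms_from_bio3d(pdb)
  if (nrow(atoms) == 0L) stop("no atoms found in ", path)
  protein_model(atoms, symmetry = symmetry)
}

#' Read a docked pose set (one pose per MODEL)
#'
#' Reads a multi-model PDB or PDBQT file in the AutoDock output dialect
#' (one ligand pose per MODEL record) into a list of ligand poses. Docking
#' energies in \code{REMARK ... Binding Energy} style lines are carried
#' through as metadata when present.
#'
#' @inheritParams read_structure
#' @param species phosphoinositide species label attached to every pose
#'   (one of \code{names(default_atom_group_map())}).
#' @return list of \code{ligand_pose} objects.
#' @export
read_pose_set <- function(path, species, format = c("pdb", "pdbqt")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  n_models <- count_models(path)
  pdb <- read_pdb_via_bio3d(path, format, multi = n_models > 1L)
  atoms <- atoms_from_bio3d(pdb)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  lapply(seq_len(nrow(xyz)), function(i) {
    co <- matrix(xyz[i, ], ncol = 3L, byrow = TRUE)
    a <- atoms
    a$x <- co[, 1L]; a$y <- co[, 2L]; a$z <- co[, 3L]
    ligand_pose(pose_id = i, species = species, atoms = a)
  })
}

#' Read a multi-model PDB trajectory into a frame series
#'
#' Protein atoms are the ATOM records; lipid headgroup beads are the HETATM
#' records, identified per lipid molecule by (residue name, chain, residue
#' number). Coordinates are kept in \enc{Å}{Angstrom} (the PDB unit).
#'
#' @param path multi-model PDB file.
#' @param frame_stride_ps time between frames, metadata only.
#' @return a \code{\link{frame_series}}.
#' @export
read_trajectory <- function(path, frame_stride_ps = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  n_models <- count_models(path)
  pdb <- read_pdb_via_bio3d(path, "pdb", multi = n_models > 1L)
  atoms <- atoms_from_bio3d(pdb)
  is_het <- pdb$atom$type == "HETATM"
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  n_frames <- nrow(xyz)
  coords <- array(0, dim = c(nrow(atoms), 3L, n_frames))
  for (i in seq_len(n_frames))
    coords[, , i] <- matrix(xyz[i, ], ncol = 3L, byrow = TRUE)
  prot <- atoms[!is_het, c("atom_name", "chain_id", "residue_number",
                           "residue_name")]
  lip <- atoms[is_het, , drop = FALSE]
  beads <- data.frame(
    lipid_id = paste(lip$residue_name, lip$chain_id, lip$residue_number,
                     sep = "_"),
    bead_name = lip$atom_name,
    species = lip$residue_name,
    stringsAsFactors = FALSE)
  frame_series(protein = prot, beads = beads,
               protein_xyz = coords[!is_het, , , drop = FALSE],
               bead_xyz = coords[is_het, , , drop = FALSE],
               frame_stride_ps = frame_stride_ps)
}

format_pdb_line <- function(type, serial, name, resname, chain, resno,
                            x, y, z) {
  nm <- if (nchar(name) < 4L) sprintf(" %-3s", name) else substr(name, 1L, 4L)
  sprintf("%-6s%5d %4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial %% 100000L, nm, substr(resname, 1L, 4L), chain,
          resno %% 10000L, x, y, z, 1, 0,
          infer_element(name))
}

atom_table_pdb_lines <- function(atoms, type = "ATOM") {
  types <- if (length(type) == 1L) rep(type, nrow(atoms)) else type
  vapply(seq_len(nrow(atoms)), function(i)
    format_pdb_line(types[i], i, atoms$atom_name[i], atoms$residue_name[i],
                    atoms$chain_id[i], atoms$residue_number[i],
                    atoms$x[i], atoms$y[i], atoms$z[i]),
    character(1L))
}

#' Write a protein model as a PDB file
#' @param model a \code{\link{protein_model}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_structure <- function(model, path) {
  writeLines(c(atom_table_pdb_lines(model$atoms), "END"), path)
  invisible(path)
}

#' Write a pose set as a multi-model PDB file
#' @param poses list of \code{ligand_pose} objects.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_pose_set <- function(poses, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in poses) {
    writeLines(sprintf("MODEL     %4d", p$pose_id), con)
    writeLines(atom_table_pdb_lines(p$atoms, "HETATM"), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a frame series as a multi-model PDB trajectory
#'
#' Protein atoms become ATOM records and lipid beads HETATM records, one
#' MODEL per frame, so synthetic trajectories round-trip through
#' \code{\link{read_trajectory}}.
#'
#' @param traj a \code{\link{frame_series}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  bead_res <- as.integer(factor(traj$beads$lipid_id,
                                levels = unique(traj$beads$lipid_id)))
  for (f in seq_len(traj$n_frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    pa <- traj$protein
    pa$x <- traj$protein_xyz[, 1L, f]
    pa$y <- traj$protein_xyz[, 2L, f]
    pa$z <- traj$protein_xyz[, 3L, f]
    writeLines(atom_table_pdb_lines(pa), con)
    la <- data.frame(atom_name = traj$beads$bead_name,
                     residue_name = traj$beads$species,
                     chain_id = "X",
                     residue_number = bead_res,
                     x = traj$bead_xyz[, 1L, f],
                     y = traj$bead_xyz[, 2L, f],
                     z = traj$bead_xyz[, 3L, f],
                     stringsAsFactors = FALSE)
    writeLines(atom_table_pdb_lines(la, "HETATM"), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
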