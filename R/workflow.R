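# End-to-end workflows behind the command-line entry point (exec/pipsites).
# Defaults mirror the standard analysis parameters: 15 A cluster cutoff,
# 4 A contact cutoff, 0.5/0.8 nm dual cutoff, C4 symmetry.

default_run_config <- function() {
  list(symmetry_order = 4L,
       species = "PI45P2",
       state_label = "",
       midplane_z = 0,
       intracellular_boundary_z = -20,
       cluster_cutoff = 15,
       contact_cutoff = 4,
       tolerance_deg = 15,
       cluster_mode = "all_centroids",
       r_on = 0.5,
       r_off = 0.8,
       min_edge_pct = 5,
       grid_spacing = 2,
       frame_stride_ps = 1000,
       seed = 1L)
}

#' Read and validate a run configuration
#'
#' Loads a YAML configuration, fills unset keys with the package defaults
#' (cluster cutoff 15 \enc{Å}{A}, contact cutoff 4 \enc{Å}{A}, dual cutoff
#' 0.5/0.8 nm, symmetry order 4) and validates the cutoffs.
#'
#' @param path YAML file, or NULL for pure defaults.
#' @param overrides named list applied on top of the file.
#' @return validated config list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- utils::modifyList(cfg, yaml::read_yaml(path))
  }
  cfg <- utils::modifyList(cfg, overrides)
  stopifnot(cfg$cluster_cutoff > 0, cfg$contact_cutoff > 0,
            cfg$r_on > 0, cfg$r_on <= cfg$r_off,
            cfg$grid_spacing > 0, cfg$symmetry_order >= 1)
  if (cfg$intracellular_boundary_z >= cfg$midplane_z)
    stop("config error: intracellular_boundary_z must lie below midplane_z")
  cfg
}

config_log_block <- function(cfg) {
  flat <- cfg[!vapply(cfg, is.list, logical(1L))]
  hash <- sum(utf8ToInt(paste(names(flat), unlist(flat), collapse = "|"))) %%
    1000000L
  c(sprintf("pipsites %s", as.character(utils::packageVersion("pipsites"))),
    sprintf("seed: %s  config_hash: %06d", cfg$seed, hash),
    paste0("  ", names(flat), " = ", vapply(flat, function(v)
      paste(format(v), collapse = ","), character(1L))))
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full docking post-analysis workflow
#'
#' Reads a structure and a docked pose set (or takes them as objects),
#' runs \code{\link{summarize_docking}}, and writes the docking summary
#' (JSON), cluster table (CSV), residue contact-frequency table (CSV) and
#' a log with the configuration echo into \code{out_dir}.
#'
#' @param structure path to a PDB/PDBQT structure, or a
#'   \code{\link{protein_model}}.
#' @param poses path to a multi-MODEL pose file, or a list of
#'   \code{ligand_pose}.
#' @param out_dir output directory, created if missing.
#' @param config config list from \code{\link{read_run_config}}.
#' @return the \code{\link{summarize_docking}} result, invisibly, with
#'   \code{$files} listing the artifacts.
#' @export
run_dock_workflow <- function(structure, poses, out_dir,
                              config = read_run_config()) {
  model <- if (inherits(structure, "protein_model")) structure else
    read_structure(structure,
                   format = if (grepl("\\.pdbqt$", structure)) "pdbqt" else "pdb")
  if (model$symmetry$order != config$symmetry_order)
    model$symmetry <- symmetry_spec(config$symmetry_order, model$chains)
  if (is.character(poses))
    poses <- read_pose_set(poses, species = config$species,
                           format = if (grepl("\\.pdbqt$", poses)) "pdbqt" else "pdb")
  frame <- membrane_frame(config$midplane_z, config$intracellular_boundary_z)
  res <- summarize_docking(poses, model, frame, config)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(out_dir, c("docking_summary.json", "clusters.csv",
                                "contact_frequencies.csv", "run.log"))
  write_json_file(res$summary, files[1L])
  utils::write.csv(res$cluster_table, files[2L], row.names = FALSE)
  utils::write.csv(res$frequencies, files[3L], row.names = FALSE)
  log <- c(config_log_block(config), sprintf("n_poses_total: %d",
                                             res$summary$n_poses_total),
           sprintf("n_accepted: %d", res$summary$n_accepted))
  if (res$summary$n_accepted == 0L)
    log <- c(log, "WARNING: no pose passed the orientation filter")
  writeLines(log, files[4L])
  res$files <- files
  invisible(res)
}

#' Run the full trajectory contact workflow
#'
#' Reads a multi-model PDB trajectory (or takes a \code{frame_series}),
#' detects dual-cutoff contact events, computes per-residue occupancy and
#' residence times, clusters binding sites by residue co-contact, builds
#' an inner-leaflet density map, and writes all tables plus a log into
#' \code{out_dir}.
#'
#' @param trajectory path to a multi-model PDB, or a
#'   \code{\link{frame_series}}.
#' @param out_dir output directory, created if missing.
#' @param config config list from \code{\link{read_run_config}}.
#' @return list with \code{events}, \code{occupancy}, \code{residence},
#'   \code{sites}, \code{density}, \code{files}, invisibly.
#' @export
run_traj_workflow <- function(trajectory, out_dir,
                              config = read_run_config()) {
  traj <- if (inherits(trajectory, "frame_series")) trajectory else
    read_trajectory(trajectory, frame_stride_ps = config$frame_stride_ps)
  events <- dual_cutoff_events(traj, r_on = config$r_on, r_off = config$r_off)
  occ <- residue_occupancy(events, traj$n_frames)
  rt <- residence_times(events, traj$frame_stride_ps)
  sites <- cluster_binding_sites(events, traj$n_frames,
                                 min_edge_pct = config$min_edge_pct)
  dens <- density_map(traj, grid_spacing = config$grid_spacing,
                      leaflet = "both", midplane_z = config$midplane_z)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(out_dir, c("events.csv", "occupancy.csv",
                                "residence_times.csv", "sites.json",
                                "density.json", "density.txt", "run.log"))
  utils::write.csv(events, files[1L], row.names = FALSE)
  utils::write.csv(occ, files[2L], row.names = FALSE)
  utils::write.csv(rt$per_residue, files[3L], row.names = FALSE)
  site_json <- list(
    n_sites = length(sites$sites),
    sites = lapply(sites$sites, function(s)
      list(site_id = s$site_id, residues = s$residues,
           occupancy_pct = s$occupancy_pct)),
    singletons = sites$singletons)
  write_json_file(site_json, files[4L])
  write_json_file(list(origin = dens$origin, spacing = dens$spacing,
                       n_frames = dens$n_frames,
                       n_observations = dens$n_observations,
                       dim = dim(dens$density)), files[5L])
  utils::write.table(dens$density, files[6L], row.names = FALSE,
                     col.names = FALSE)
  writeLines(c(config_log_block(config),
               sprintf("n_frames: %d", traj$n_frames),
               sprintf("n_events: %d", nrow(events)),
               sprintf("n_sites: %d", length(sites$sites))), files[7L])
  invisible(list(events = events, occupancy = occ, residence = rt,
                 sites = sites, density = dens, files = files))
}
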