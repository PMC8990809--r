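pose_vector_matrix <- function(vectors) {
  t(vapply(vectors, function(v) c(v$c1, v$inositol, v$phosphate),
           numeric(9L)))
}

pairwise_group_dist <- function(vectors, mode) {
  m <- pose_vector_matrix(vectors)
  d_ino <- stats::dist(m[, 4:6, drop = FALSE])
  if (mode == "inositol_only") return(d_ino)
  d_c1 <- stats::dist(m[, 1:3, drop = FALSE])
  d_ph <- stats::dist(m[, 7:9, drop = FALSE])
  pmax(d_c1, d_ino, d_ph)
}

#' Cluster wedge-reduced pose vectors by centroid proximity
#'
#' Single-linkage agglomeration at a fixed distance cutoff. In mode
#' \code{all_centroids} (default, the strict reading of "centroids within
#' the cutoff") two poses are directly linked when each of the three
#' corresponding centroid pairs (glycerol C1, inositol, anchor phosphate)
#' is within the cutoff, i.e. the linkage distance is the maximum of the
#' three pairwise centroid distances. In mode \code{inositol_only} only the
#' inositol centroid pair is tested. Clusters are ordered by descending
#' size, ties broken by smallest member pose id, so output is deterministic
#' under permutation of the input.
#'
#' @param vectors list of wedge-reduced \code{pose_vector}s.
#' @param cutoff linkage cutoff in \enc{Å}{Angstrom} (default 15).
#' @param mode \code{"all_centroids"} or \code{"inositol_only"}.
#' @return list of \code{pose_cluster} objects: \code{cluster_id},
#'   \code{member_pose_ids}, \code{representative_pose_id},
#'   \code{mean_centroids} (3 x 3 matrix: rows c1, inositol, phosphate).
#' @export
cluster_poses <- function(vectors, cutoff = 15,
                          mode = c("all_centroids", "inositol_only")) {
  mode <- match.arg(mode)
  if (cutoff <= 0) stop("cluster cutoff must be positive")
  if (length(vectors) == 0L) return(list())
  ids <- vapply(vectors, function(v) v$pose_id, integer(1L))
  if (length(vectors) == 1L) {
    member <- 1L
  } else {
    d <- pairwise_group_dist(vectors, mode)
    hc <- stats::hclust(d, method = "single")
    member <- stats::cutree(hc, h = cutoff)
  }
  groups <- split(seq_along(vectors), member)
  sizes <- lengths(groups)
  min_id <- vapply(groups, function(g) min(ids[g]), numeric(1L))
  ord <- order(-sizes, min_id)
  groups <- groups[ord]
  m <- pose_vector_matrix(vectors)
  lapply(seq_along(groups), function(ci) {
    g <- groups[[ci]]
    mc <- matrix(colMeans(m[g, , drop = FALSE]), nrow = 3L, byrow = TRUE,
                 dimnames = list(c("c1", "inositol", "phosphate"),
                                 c("x", "y", "z")))
    structure(list(cluster_id = ci,
                   member_pose_ids = sort(ids[g]),
                   representative_pose_id =
                     select_representative(vectors[g]),
                   mean_centroids = mc,
                   size = length(g)),
              class = "pose_cluster")
  })
}

#' Medoid representative of a pose cluster
#'
#' The most representative pose of a cluster is its medoid on the inositol
#' centroid: the member minimizing the summed inositol-centroid distance to
#' all other members. Ties are broken by the smallest pose id; a singleton
#' returns itself.
#'
#' @param vectors list of \code{pose_vector}s belonging to one cluster.
#' @return the representative pose id.
#' @export
select_representative <- function(vectors) {
  if (length(vectors) == 0L) stop("empty cluster has no representative")
  ids <- vapply(vectors, function(v) v$pose_id, integer(1L))
  if (length(vectors) == 1L) return(ids)
  ino <- t(vapply(vectors, function(v) v$inositol, numeric(3L)))
  d <- as.matrix(stats::dist(ino))
  tot <- rowSums(d)
  best <- which(tot == min(tot))
  ids[best[which.min(ids[best])]]
}

#' Full docking post-analysis: filter, wedge-reduce, cluster, contacts
#'
#' Runs the complete post-docking chain on a pose set: three-centroid
#' vectorization, membrane-orientation acceptance, reduction into the
#' reference symmetry wedge, single-linkage centroid clustering, and
#' per-residue contact frequencies over the accepted poses.
#'
#' @param poses list of \code{\link{ligand_pose}}.
#' @param model a \code{\link{protein_model}}.
#' @param frame a \code{\link{membrane_frame}}.
#' @param config list of parameters; defaults are
#'   \code{cluster_cutoff = 15} \enc{Å}{A}, \code{contact_cutoff = 4}
#'   \enc{Å}{A}, \code{tolerance_deg = 15},
#'   \code{cluster_mode = "all_centroids"}, \code{state_label = ""},
#'   \code{groups = default_atom_group_map()}.
#' @return list with \code{summary} (species, state_label, n_poses_total,
#'   n_accepted, acceptance_fraction, n_clusters, n_distinct_residues),
#'   \code{clusters}, \code{cluster_table} data.frame, \code{frequencies}
#'   data.frame, \code{accepted} (pose indexes), \code{vectors},
#'   \code{elevations_deg}.
#' @export
summarize_docking <- function(poses, model, frame, config = list()) {
  cfg <- utils::modifyList(list(cluster_cutoff = 15, contact_cutoff = 4,
                                tolerance_deg = 15,
                                cluster_mode = "all_centroids",
                                state_label = "",
                                groups = default_atom_group_map()),
                           config)
  if (length(poses) == 0L) stop("no poses supplied")
  species <- poses[[1L]]$species
  vectors <- lapply(poses, compute_pose_vector, groups = cfg$groups)
  filt <- lapply(vectors, orientation_filter, frame = frame,
                 tolerance_deg = cfg$tolerance_deg)
  accepted <- which(vapply(filt, `[[`, logical(1L), "accept"))
  elev <- vapply(filt, `[[`, numeric(1L), "elevation_deg")

  n_total <- length(poses)
  if (length(accepted) == 0L) {
    summary <- list(species = species, state_label = cfg$state_label,
                    n_poses_total = n_total, n_accepted = 0L,
                    acceptance_fraction = 0, n_clusters = 0L,
                    n_distinct_residues = 0L)
    return(list(summary = summary, clusters = list(),
                cluster_table = empty_cluster_table(),
                frequencies = residue_contact_frequencies_empty(),
                accepted = integer(), vectors = vectors,
                elevations_deg = elev))
  }
  red <- lapply(vectors[accepted], reduce_to_reference_wedge,
                sym = model$symmetry)
  clusters <- cluster_poses(red, cutoff = cfg$cluster_cutoff,
                            mode = cfg$cluster_mode)
  freq <- residue_contact_frequencies(poses[accepted], red, model,
                                      cutoff = cfg$contact_cutoff)
  summary <- list(species = species, state_label = cfg$state_label,
                  n_poses_total = n_total, n_accepted = length(accepted),
                  acceptance_fraction = length(accepted) / n_total,
                  n_clusters = length(clusters),
                  n_distinct_residues = freq$n_distinct_residues)
  list(summary = summary, clusters = clusters,
       cluster_table = cluster_table(clusters),
       frequencies = freq$frequencies,
       accepted = accepted, vectors = vectors, elevations_deg = elev)
}

empty_cluster_table <- function() {
  data.frame(cluster_id = integer(), size = integer(),
             representative_pose_id = integer(),
             c1_x = numeric(), c1_y = numeric(), c1_z = numeric(),
             ino_x = numeric(), ino_y = numeric(), ino_z = numeric(),
             ph_x = numeric(), ph_y = numeric(), ph_z = numeric(),
             stringsAsFactors = FALSE)
}

residue_contact_frequencies_empty <- function() {
  data.frame(residue = character(), chain_id = character(),
             residue_number = integer(), n_poses = integer(),
             pct = numeric(), stringsAsFactors = FALSE)
}

#' Tabulate pose clusters
#' @param clusters list of \code{pose_cluster} objects.
#' @return data.frame, one row per cluster, with mean centroid coordinates.
#' @export
cluster_table <- function(clusters) {
  if (length(clusters) == 0L) return(empty_cluster_table())
  do.call(rbind, lapply(clusters, function(cl) {
    mc <- cl$mean_centroids
    data.frame(cluster_id = cl$cluster_id, size = cl$size,
               representative_pose_id = cl$representative_pose_id,
               c1_x = mc["c1", 1L], c1_y = mc["c1", 2L], c1_z = mc["c1", 3L],
               ino_x = mc["inositol", 1L], ino_y = mc["inositol", 2L],
               ino_z = mc["inositol", 3L],
               ph_x = mc["phosphate", 1L], ph_y = mc["phosphate", 2L],
               ph_z = mc["phosphate", 3L],
               stringsAsFactors = FALSE)
  }))
}
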