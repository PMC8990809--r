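# Lipid-residue distances: per frame, the minimum distance between any
# headgroup bead of a lipid and any particle of a residue. The dual-cutoff
# detector and all occupancy/site logic run on these series. Frames are
# 0-based in every exported table, matching trajectory-frame conventions.

#' Minimum lipid-residue distance series
#'
#' Computes, for every (lipid, residue) pair and frame, the minimum
#' distance between the lipid's headgroup beads and the residue's protein
#' particles.
#'
#' @param traj a \code{\link{frame_series}}.
#' @return list: \code{dist} array n_lipids x n_residues x n_frames in
#'   \enc{Å}{Angstrom}; \code{lipids}; \code{residues} (keys
#'   \code{"chain:resno"}).
#' @export
lipid_residue_distances <- function(traj) {
  res_key <- residue_key(traj$protein$chain_id, traj$protein$residue_number)
  residues <- unique(res_key)
  lipids <- unique(traj$beads$lipid_id)
  res_idx <- split(seq_len(nrow(traj$protein)),
                   factor(res_key, levels = residues))
  lip_idx <- split(seq_len(nrow(traj$beads)),
                   factor(traj$beads$lipid_id, levels = lipids))
  nl <- length(lipids); nr <- length(residues); nf <- traj$n_frames
  d <- array(Inf, dim = c(nl, nr, nf))
  for (f in seq_len(nf)) {
    p <- traj$protein_xyz[, , f, drop = FALSE]; dim(p) <- dim(p)[1:2]
    b <- traj$bead_xyz[, , f, drop = FALSE]; dim(b) <- dim(b)[1:2]
    # all bead-atom squared distances for this frame
    d2 <- outer(rowSums(b^2), rowSums(p^2), "+") - 2 * tcrossprod(b, p)
    d2[d2 < 0] <- 0
    for (li in seq_len(nl)) {
      rows <- d2[lip_idx[[li]], , drop = FALSE]
      mins <- apply(rows, 2L, min)
      d[li, , f] <- vapply(res_idx, function(ix) min(mins[ix]), numeric(1L))
    }
  }
  list(dist = sqrt(d), lipids = lipids, residues = residues)
}

# maximal runs of (d <= r_off); an event starts at the first frame of the
# run with d <= r_on and persists to the run end
events_from_series <- function(d, r_on, r_off) {
  within_off <- d <= r_off
  r <- rle(within_off)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (i in which(r$values)) {
    seg <- starts[i]:ends[i]
    hit <- seg[d[seg] <= r_on]
    if (length(hit))
      out[[length(out) + 1L]] <- c(hit[1L], ends[i])
  }
  out
}

#' Dual-cutoff lipid-residue contact events
#'
#' Detects contact events with the dual-cutoff scheme: a contact between a
#' lipid and a residue starts at the first frame where their minimum
#' distance drops to the inner cutoff \code{r_on} or below, persists while
#' the distance stays within the outer cutoff \code{r_off}, and ends the
#' frame before the distance exceeds \code{r_off}. Setting
#' \code{r_on = r_off} recovers a plain single-cutoff scheme.
#'
#' @param traj a \code{\link{frame_series}} (coordinates in
#'   \enc{Å}{Angstrom}).
#' @param r_on,r_off inner/outer cutoffs in nm (defaults 0.5 and 0.8).
#' @return data.frame of events: \code{lipid_id}, \code{residue},
#'   \code{chain_id}, \code{residue_number}, \code{start_frame},
#'   \code{end_frame} (0-based, inclusive), \code{n_frames_event}.
#' @export
dual_cutoff_events <- function(traj, r_on = 0.5, r_off = 0.8) {
  if (!(r_on > 0 && r_on <= r_off)) stop("require 0 < r_on <= r_off")
  if (traj$n_frames < 1L) stop("empty trajectory")
  dd <- lipid_residue_distances(traj)
  on_A <- r_on * 10; off_A <- r_off * 10  # nm -> Angstrom
  rows <- list()
  for (li in seq_along(dd$lipids)) for (ri in seq_along(dd$residues)) {
    ev <- events_from_series(dd$dist[li, ri, ], on_A, off_A)
    for (e in ev)
      rows[[length(rows) + 1L]] <-
        data.frame(lipid_id = dd$lipids[li], residue = dd$residues[ri],
                   start_frame = e[1L] - 1L, end_frame = e[2L] - 1L,
                   stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(lipid_id = character(), residue = character(),
                      chain_id = character(), residue_number = integer(),
                      start_frame = integer(), end_frame = integer(),
                      n_frames_event = integer(), stringsAsFactors = FALSE))
  ev <- do.call(rbind, rows)
  parts <- strsplit(ev$residue, ":", fixed = TRUE)
  ev$chain_id <- vapply(parts, `[`, character(1L), 1L)
  ev$residue_number <- as.integer(vapply(parts, `[`, character(1L), 2L))
  ev$n_frames_event <- ev$end_frame - ev$start_frame + 1L
  ev <- ev[order(ev$lipid_id, ev$residue, ev$start_frame),
           c("lipid_id", "residue", "chain_id", "residue_number",
             "start_frame", "end_frame", "n_frames_event")]
  rownames(ev) <- NULL
  ev
}

# per (lipid, residue) boolean contact-state matrix residue x frame
contact_frames_by_lipid <- function(events, n_frames, residues) {
  lapply(split(events, events$lipid_id), function(e) {
    m <- matrix(FALSE, nrow = length(residues), ncol = n_frames,
                dimnames = list(residues, NULL))
    for (i in seq_len(nrow(e))) {
      ri <- match(e$residue[i], residues)
      m[ri, (e$start_frame[i] + 1L):(e$end_frame[i] + 1L)] <- TRUE
    }
    m
  })
}

#' Per-residue contact occupancy
#'
#' Occupancy of a residue is the percentage of frames in which at least one
#' lipid is in contact with it; simultaneous contacts by several lipids
#' count once per frame.
#'
#' @param events event table from \code{\link{dual_cutoff_events}}.
#' @param n_frames total trajectory frames.
#' @return data.frame: \code{residue}, \code{chain_id},
#'   \code{residue_number}, \code{n_frames_contact}, \code{occupancy_pct},
#'   descending occupancy.
#' @export
residue_occupancy <- function(events, n_frames) {
  if (n_frames < 1L) stop("n_frames must be positive")
  if (nrow(events) == 0L)
    return(data.frame(residue = character(), chain_id = character(),
                      residue_number = integer(),
                      n_frames_contact = integer(),
                      occupancy_pct = numeric(), stringsAsFactors = FALSE))
  residues <- unique(events$residue)
  by_lip <- contact_frames_by_lipid(events, n_frames, residues)
  any_contact <- Reduce(`|`, by_lip)
  nfc <- rowSums(any_contact)
  parts <- strsplit(residues, ":", fixed = TRUE)
  out <- data.frame(residue = residues,
                    chain_id = vapply(parts, `[`, character(1L), 1L),
                    residue_number =
                      as.integer(vapply(parts, `[`, character(1L), 2L)),
                    n_frames_contact = as.integer(nfc),
                    occupancy_pct = 100 * nfc / n_frames,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$occupancy_pct, out$chain_id, out$residue_number), ]
  rownames(out) <- NULL
  out
}

#' Per-residue contact residence times
#'
#' Duration of one event is \code{(end - start + 1) * frame_stride_ps}.
#'
#' @param events event table from \code{\link{dual_cutoff_events}}.
#' @param frame_stride_ps time per frame in ps.
#' @return list: \code{per_residue} data.frame (\code{residue},
#'   \code{n_events}, \code{mean_ps}, \code{max_ps}),
#'   \code{overall_mean_ps}, \code{overall_max_ps}, \code{n_events}.
#' @export
residence_times <- function(events, frame_stride_ps = 1) {
  if (nrow(events) == 0L)
    return(list(per_residue = data.frame(residue = character(),
                                         n_events = integer(),
                                         mean_ps = numeric(),
                                         max_ps = numeric(),
                                         stringsAsFactors = FALSE),
                overall_mean_ps = NA_real_, overall_max_ps = NA_real_,
                n_events = 0L))
  dur <- events$n_frames_event * frame_stride_ps
  agg <- do.call(rbind, lapply(split(dur, events$residue), function(d)
    data.frame(n_events = length(d), mean_ps = mean(d), max_ps = max(d))))
  per <- data.frame(residue = rownames(agg), agg, row.names = NULL,
                    stringsAsFactors = FALSE)
  list(per_residue = per, overall_mean_ps = mean(dur),
       overall_max_ps = max(dur), n_events = length(dur))
}

#' Cluster binding sites by residue co-contact commonality
#'
#' Builds a graph over contacted residues with an edge between two residues
#' whenever the same lipid molecule is simultaneously in contact (within
#' the outer-cutoff contact state) with both in at least \code{min_edge_pct}
#' percent of frames. Connected components with two or more residues become
#' binding sites; contacted residues that join no component are returned as
#' singletons. Sites are ordered by descending occupancy.
#'
#' @param events event table from \code{\link{dual_cutoff_events}}.
#' @param n_frames total trajectory frames.
#' @param min_edge_pct minimum co-contact percentage for an edge
#'   (default 5).
#' @return list: \code{sites} — list of \code{binding_site} objects
#'   (\code{site_id}, \code{residues}, \code{occupancy_pct},
#'   \code{top_residue_occupancies}); \code{singletons} — residue keys.
#' @export
cluster_binding_sites <- function(events, n_frames, min_edge_pct = 5) {
  if (nrow(events) == 0L) return(list(sites = list(), singletons = character()))
  residues <- sort(unique(events$residue))
  by_lip <- contact_frames_by_lipid(events, n_frames, residues)
  nr <- length(residues)
  # co_union[i,j]: frames where at least one lipid co-contacts residues i, j
  co_union <- matrix(0L, nr, nr, dimnames = list(residues, residues))
  for (i in seq_len(nr)) for (j in seq_len(nr)) {
    if (j <= i) next
    frames <- Reduce(`|`, lapply(by_lip, function(m) m[i, ] & m[j, ]))
    co_union[i, j] <- co_union[j, i] <- sum(frames)
  }
  adj <- (100 * co_union / n_frames) >= min_edge_pct
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  occ <- residue_occupancy(events, n_frames)
  groups <- split(residues, comp$membership)
  multi <- groups[lengths(groups) >= 2L]
  singles <- unlist(groups[lengths(groups) == 1L], use.names = FALSE)
  sites <- lapply(multi, function(res) {
    o <- occ[occ$residue %in% res, , drop = FALSE]
    list(residues = sort(res),
         occupancy_pct = site_occupancy(res, events, n_frames),
         top_residue_occupancies = utils::head(o, 10L))
  })
  ord <- order(-vapply(sites, `[[`, numeric(1L), "occupancy_pct"),
               vapply(sites, function(s) s$residues[1L], character(1L)))
  sites <- sites[ord]
  sites <- lapply(seq_along(sites), function(i) {
    s <- sites[[i]]; s$site_id <- i
    structure(s, class = "binding_site")
  })
  list(sites = sites, singletons = sort(singles))
}

#' Occupancy of a binding site
#'
#' Percentage of frames in which at least one lipid is in contact with at
#' least one residue of the site (union semantics, so site occupancy is
#' never below the best single-residue occupancy).
#'
#' @param site_residues character vector of residue keys, or a
#'   \code{binding_site}.
#' @param events event table from \code{\link{dual_cutoff_events}}.
#' @param n_frames total trajectory frames.
#' @return occupancy percentage.
#' @export
site_occupancy <- function(site_residues, events, n_frames) {
  if (inherits(site_residues, "binding_site"))
    site_residues <- site_residues$residues
  if (length(site_residues) == 0L) stop("site has no residues")
  if (n_frames < 1L) stop("n_frames must be positive")
  e <- events[events$residue %in% site_residues, , drop = FALSE]
  if (nrow(e) == 0L) return(0)
  occupied <- logical(n_frames)
  for (i in seq_len(nrow(e)))
    occupied[(e$start_frame[i] + 1L):(e$end_frame[i] + 1L)] <- TRUE
  100 * sum(occupied) / n_frames
}

#' Membrane-plane lipid density map
#'
#' Two-dimensional histogram of lipid reference-bead xy positions,
#' accumulated over all frames and divided by the frame count, optionally
#' restricted to one leaflet by the bead z position relative to the bilayer
#' midplane. Mass is conserved: the cell sum times \code{n_frames} equals
#' the number of bead observations binned.
#'
#' @param traj a \code{\link{frame_series}}.
#' @param grid_spacing cell edge in \enc{Å}{Angstrom}.
#' @param leaflet \code{"inner"} (z below midplane), \code{"outer"}, or
#'   \code{"both"}.
#' @param midplane_z bilayer midplane height, \enc{Å}{Angstrom}.
#' @param reference_bead bead name used as the lipid position marker;
#'   default: the first bead of each lipid.
#' @return list: \code{density} matrix (mean reference beads per cell per
#'   frame; rows = x bins, cols = y bins), \code{origin} (xy of the low
#'   corner), \code{spacing}, \code{n_frames}, \code{n_observations}.
#' @export
density_map <- function(traj, grid_spacing = 2,
                        leaflet = c("both", "inner", "outer"),
                        midplane_z = 0, reference_bead = NULL) {
  leaflet <- match.arg(leaflet)
  if (grid_spacing <= 0) stop("grid spacing must be positive")
  if (is.null(reference_bead)) {
    first <- !duplicated(traj$beads$lipid_id)
    sel <- which(first)
  } else {
    sel <- which(traj$beads$bead_name == reference_bead)
    if (length(sel) == 0L) stop("no bead named ", reference_bead)
  }
  xs <- as.vector(traj$bead_xyz[sel, 1L, ])
  ys <- as.vector(traj$bead_xyz[sel, 2L, ])
  zs <- as.vector(traj$bead_xyz[sel, 3L, ])
  keep <- switch(leaflet, both = rep(TRUE, length(zs)),
                 inner = zs < midplane_z, outer = zs >= midplane_z)
  xs <- xs[keep]; ys <- ys[keep]
  if (length(xs) == 0L)
    return(list(density = matrix(0, 1L, 1L), origin = c(0, 0),
                spacing = grid_spacing, n_frames = traj$n_frames,
                n_observations = 0L))
  origin <- c(floor(min(xs) / grid_spacing),
              floor(min(ys) / grid_spacing)) * grid_spacing
  ix <- floor((xs - origin[1L]) / grid_spacing) + 1L
  iy <- floor((ys - origin[2L]) / grid_spacing) + 1L
  nx <- max(ix); ny <- max(iy)
  dens <- matrix(0, nx, ny)
  for (i in seq_along(ix)) dens[ix[i], iy[i]] <- dens[ix[i], iy[i]] + 1
  list(density = dens / traj$n_frames, origin = origin,
       spacing = grid_spacing, n_frames = traj$n_frames,
       n_observations = length(xs))
}
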