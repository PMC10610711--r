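# Single-linkage water clustering under periodic boundaries, with
# mass-weighted radii of gyration.

#' Single-linkage water clusters in one frame
#'
#' Two water molecules are linked when their minimum-image oxygen-oxygen
#' distance is at most `cutoff`; clusters are the connected components of
#' the linkage graph (union-find). The default cutoff of 3.5 Angstrom sits
#' at the first minimum of the bulk-water O-O pair correlation function.
#' Clusters are reported in descending size, ties broken by smallest member
#' molecule id, so output order is bit-stable.
#'
#' @param coords `atoms x 3` coordinate matrix (Angstrom) for one frame.
#' @param top The matching `topology`; clustering applies to its water
#'   molecules.
#' @param box Orthorhombic box (3-vector, Angstrom).
#' @param cutoff O-O linkage cutoff in Angstrom (default 3.5).
#' @return An object of class `"cluster_set"`: list with `clusters` (list of
#'   molecule-id vectors), `sizes`, and `rg` (mass-weighted radius of
#'   gyration per cluster, Angstrom).
#' @export
cluster_frame <- function(coords, top, box, cutoff = 3.5) {
  stopifnot(cutoff > 0)
  box <- check_box(box)
  atoms <- top$atoms
  wmask <- atoms$species == "water" & atoms$element == "O"
  o_idx <- which(wmask)
  if (length(o_idx) == 0L) stop("no water molecules to cluster")
  mol <- atoms$mol_id[o_idx]
  pr <- pairs_within(matrix(coords[o_idx, ], ncol = 3), box, cutoff)
  comp <- union_find(length(o_idx), pr$i, pr$j)
  groups <- split(mol, comp)
  first_member <- vapply(groups, min, numeric(1))
  ord <- order(-lengths(groups), first_member)
  groups <- lapply(groups[ord], sort)
  names(groups) <- NULL
  rg <- vapply(groups, function(g) cluster_rg(g, coords, top, box, cutoff),
               numeric(1))
  structure(list(clusters = groups, sizes = lengths(groups), rg = rg),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d clusters, sizes: %s\n", length(x$clusters),
              paste(utils::head(x$sizes, 10), collapse = " ")))
  invisible(x)
}

#' Mass-weighted radius of gyration of a water cluster
#'
#' Cluster members are first brought into one periodic image by a
#' breadth-first traversal of the linkage graph, applying minimum-image
#' shifts molecule by molecule, so boundary-spanning clusters are measured
#' un-split. The radius of gyration is then
#' `sqrt(sum(m_i |r_i - r_cm|^2) / sum(m_i))` over all atoms of the member
#' molecules, with `r_cm` the mass-weighted centre. A single-molecule
#' cluster returns the molecule's own (intramolecular) radius of gyration.
#'
#' @param mol_ids Molecule ids of the cluster members.
#' @param coords `atoms x 3` coordinate matrix (Angstrom) for the frame.
#' @param top The matching `topology`.
#' @param box Orthorhombic box (3-vector, Angstrom).
#' @param cutoff Linkage cutoff used for the traversal (default 3.5).
#' @return Radius of gyration in Angstrom. A cluster whose unwrapped
#'   diameter reaches half a box edge is periodically ambiguous and raises a
#'   warning.
#' @export
cluster_rg <- function(mol_ids, coords, top, box, cutoff = 3.5) {
  stopifnot(length(mol_ids) >= 1L)
  box <- check_box(box)
  atoms <- top$atoms
  o_idx <- vapply(mol_ids, function(m)
    which(atoms$mol_id == m & atoms$element == "O")[1], integer(1))
  if (anyNA(o_idx)) {  # non-water members: anchor on the first atom instead
    o_idx <- vapply(mol_ids, function(m) which(atoms$mol_id == m)[1], integer(1))
  }
  n <- length(mol_ids)
  anchor <- matrix(coords[o_idx, ], ncol = 3)
  placed <- anchor
  if (n > 1L) {
    pr <- pairs_within(anchor, box, cutoff)
    adj <- vector("list", n)
    for (e in seq_along(pr$i)) {
      adj[[pr$i[e]]] <- c(adj[[pr$i[e]]], pr$j[e])
      adj[[pr$j[e]]] <- c(adj[[pr$j[e]]], pr$i[e])
    }
    queue <- 1L
    visited <- c(TRUE, rep(FALSE, n - 1L))
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (nb in adj[[cur]]) {
        if (!visited[nb]) {
          visited[nb] <- TRUE
          # position neighbour next to its already-placed parent
          disp <- minimum_image_displacement(placed[cur, ], anchor[nb, ], box)
          placed[nb, ] <- placed[cur, ] + disp
          queue <- c(queue, nb)
        }
      }
    }
    if (!all(visited)) {
      stop("cluster members are not connected at the given cutoff")
    }
    ext <- apply(placed, 2, function(v) diff(range(v)))
    if (any(ext >= box / 2)) {
      warning("cluster diameter reaches L/2 after unwrapping; ",
              "periodic image assignment is ambiguous")
    }
  }
  xyz <- NULL; mass <- NULL
  for (i in seq_len(n)) {
    idx <- which(atoms$mol_id == mol_ids[i])
    at <- matrix(coords[idx, ], ncol = 3)
    # keep each molecule intact relative to its anchor atom, then shift
    rel <- min_image_mat(at - matrix(coords[o_idx[i], ], nrow(at), 3,
                                     byrow = TRUE), box)
    xyz <- rbind(xyz, rel + matrix(placed[i, ], nrow(at), 3, byrow = TRUE))
    mass <- c(mass, atoms$mass[idx])
  }
  cm <- colSums(xyz * mass) / sum(mass)
  sqrt(sum(mass * rowSums(sweep(xyz, 2, cm)^2)) / sum(mass))
}

#' Cluster statistics over a trajectory
#'
#' Per-frame largest-cluster size, cluster count, and largest-cluster radius
#' of gyration at the given stride, with a summary (max, mean, sd) of the
#' largest-cluster size over the run.
#'
#' @param traj A `trajectory`.
#' @param top The matching `topology`.
#' @param cutoff O-O linkage cutoff in Angstrom.
#' @param stride Frame stride (default 1).
#' @return A list of class `"cluster_series"` with `series` (data frame:
#'   `frame`, `time_ps`, `largest_size`, `n_clusters`, `largest_rg_A`) and
#'   `summary` (list: `max_largest`, `mean_largest`, `sd_largest`).
#' @export
cluster_series <- function(traj, top, cutoff = 3.5, stride = 1L) {
  frames <- seq.int(1L, n_frames(traj), by = stride)
  rows <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    f <- frames[i]
    cs <- cluster_frame(frame_coords(traj, f), top, traj$box[f, ], cutoff)
    rows[[i]] <- data.frame(frame = f, time_ps = traj$times[f],
                            largest_size = cs$sizes[1],
                            n_clusters = length(cs$clusters),
                            largest_rg_A = cs$rg[1])
  }
  series <- do.call(rbind, rows)
  structure(list(series = series,
                 summary = list(max_largest = max(series$largest_size),
                                mean_largest = mean(series$largest_size),
                                sd_largest = stats::sd(series$largest_size))),
            class = "cluster_series")
}

#' @export
print.cluster_series <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<cluster_series> %d frames; largest cluster max %d, mean %.2f\n",
              nrow(x$series), s$max_largest, s$mean_largest))
  invisible(x)
}

#' Export a cluster series to CSV
#'
#' @param cs A `cluster_series`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cluster_csv <- function(cs, path) {
  utils::write.csv(cs$series, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
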