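# Time-averaged 1D/2D density projections and a uniformity metric.

# Molecule centres of mass for one wrapped frame, with each molecule made
# whole by taking its atoms minimum-image relative to its first atom.
com_frame_pbc <- function(coords, top, mol_ids, box) {
  atoms <- top$atoms
  keep <- which(atoms$mol_id %in% mol_ids)
  grp <- factor(atoms$mol_id[keep], levels = mol_ids)
  first_atom <- keep[match(levels(grp), as.character(grp))]
  anchor <- matrix(coords[first_atom, ], ncol = 3)
  rel <- min_image_mat(matrix(coords[keep, ], ncol = 3) -
                         anchor[as.integer(grp), , drop = FALSE], box)
  m <- atoms$mass[keep]
  anchor + rowsum(rel * m, grp) / as.numeric(rowsum(m, grp))
}

#' Time-averaged density projection
#'
#' Bins the centre of mass of each selected molecule on one or two box axes
#' (the remaining axes are integrated out) in every frame, then averages
#' over frames. Bins are half-open `[edge, edge + width)` and tile the box
#' exactly: the requested `bin_width` is rounded to the nearest integer
#' divisor of the edge length so refining by an integer factor re-aggregates
#' exactly. Values are densities: count (or mass, amu) per Angstrom of
#' projected length (1D) or per square Angstrom (2D), per frame, so that
#' `sum(values) * bin_measure` equals the mean selected count (or mass) per
#' frame.
#'
#' @param traj A wrapped `trajectory` (projection needs in-box coordinates).
#' @param top The matching `topology`.
#' @param species Species tag selecting the molecules (default `"water"`).
#' @param axes Integer vector of 1 or 2 projected axes (1 = x, 2 = y,
#'   3 = z); default `c(1, 2)`.
#' @param bin_width Target bin width in Angstrom (default 1).
#' @param mode `"number"` or `"mass"` weighting.
#' @return An object of class `"density_map"`: list with `axes`,
#'   `bin_edges` (list per axis), `values` (vector or matrix of densities)
#'   and `n_frames`.
#' @export
project_density <- function(traj, top, species = "water", axes = c(1, 2),
                            bin_width = 1, mode = c("number", "mass")) {
  mode <- match.arg(mode)
  stopifnot(bin_width > 0, length(axes) %in% 1:2, all(axes %in% 1:3),
            !anyDuplicated(axes))
  if (!traj$wrapped) stop("project_density() expects a wrapped trajectory")
  box <- traj$box[1, ]
  if (any(abs(sweep(traj$box, 2, box)) > 1e-9)) {
    stop("project_density() requires a constant box across frames")
  }
  if (bin_width > min(box[axes])) {
    stop("bin_width exceeds the box edge on a projected axis")
  }
  mol_ids <- sort(unique(top$atoms$mol_id[top$atoms$species == species]))
  if (length(mol_ids) == 0L) stop("no molecules with species '", species, "'")
  nbins <- pmax(1L, as.integer(round(box[axes] / bin_width)))
  widths <- box[axes] / nbins
  edges <- lapply(seq_along(axes), function(i) seq(0, box[axes[i]],
                                                   length.out = nbins[i] + 1L))
  w <- if (mode == "mass") {
    m <- top$atoms$mass[top$atoms$mol_id %in% mol_ids]
    as.numeric(rowsum(m, factor(top$atoms$mol_id[top$atoms$mol_id %in% mol_ids],
                                levels = mol_ids)))
  } else {
    rep(1, length(mol_ids))
  }
  nf <- n_frames(traj)
  acc <- if (length(axes) == 2L) matrix(0, nbins[1], nbins[2]) else numeric(nbins[1])
  for (f in seq_len(nf)) {
    # molecule-whole COM: atoms taken min-image relative to the molecule's
    # first atom so boundary-straddling molecules are not torn apart
    pos <- wrap_coords(com_frame_pbc(frame_coords(traj, f), top, mol_ids, box),
                       box)
    idx1 <- pmin(nbins[1], 1L + floor(pos[, axes[1]] / widths[1]))
    if (length(axes) == 2L) {
      idx2 <- pmin(nbins[2], 1L + floor(pos[, axes[2]] / widths[2]))
      for (m_i in seq_along(idx1)) {
        acc[idx1[m_i], idx2[m_i]] <- acc[idx1[m_i], idx2[m_i]] + w[m_i]
      }
    } else {
      for (m_i in seq_along(idx1)) acc[idx1[m_i]] <- acc[idx1[m_i]] + w[m_i]
    }
  }
  values <- acc / nf / prod(widths)
  structure(list(axes = axes, bin_edges = edges, values = values,
                 n_frames = nf, mode = mode),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  dims <- if (is.matrix(x$values)) paste(dim(x$values), collapse = " x ")
          else length(x$values)
  cat(sprintf("<density_map> axes %s, %s bins, %d frames, mode %s\n",
              paste(c("x", "y", "z")[x$axes], collapse = ""), dims,
              x$n_frames, x$mode))
  invisible(x)
}

#' Coefficient of variation of a density map
#'
#' Population coefficient of variation (sd/mean, with the population
#' normalisation) of the bin values. Zero for a perfectly uniform map; for
#' all mass concentrated in one of `k` equal bins it equals `sqrt(k - 1)`.
#' Larger values mean more channelled / less even penetrant distribution.
#'
#' @param map A `density_map`.
#' @return Scalar coefficient of variation.
#' @export
uniformity_cv <- function(map) {
  v <- as.numeric(map$values)
  if (length(v) == 0L) stop("empty density map")
  m <- mean(v)
  if (m == 0) stop("density map has zero mean; CV undefined")
  sqrt(mean((v - m)^2)) / m
}

#' Export a density map to CSV
#'
#' Long format: one row per bin with the lower bin edges and the density
#' value.
#'
#' @param map A `density_map`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_density_csv <- function(map, path) {
  if (is.matrix(map$values)) {
    e1 <- utils::head(map$bin_edges[[1]], -1)
    e2 <- utils::head(map$bin_edges[[2]], -1)
    out <- data.frame(edge1 = rep(e1, times = length(e2)),
                      edge2 = rep(e2, each = length(e1)),
                      value = as.numeric(map$values))
    names(out)[1:2] <- paste0(c("x", "y", "z")[map$axes], "_edge")
  } else {
    out <- data.frame(edge = utils::head(map$bin_edges[[1]], -1),
                      value = map$values)
    names(out)[1] <- paste0(c("x", "y", "z")[map$axes[1]], "_edge")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
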