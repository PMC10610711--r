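# Geometric hydrogen-bond detection and class decomposition.
#
# A hydrogen bond D-H...A is accepted when the minimum-image H...A distance
# is strictly below the cutoff, the donor angle at the hydrogen,
# angle(D-H...A), is at least the donor threshold, and the acceptor angle
# angle(H...A-X) is at least the acceptor threshold for every heavy
# neighbour X of the acceptor (an acceptor with no heavy neighbour, such as
# a water oxygen or bare ion, passes that check vacuously).

#' Geometric hydrogen-bond criteria
#'
#' Defaults follow the common Maestro-style geometric definition: H...A
#' distance strictly less than 2.8 Angstrom, donor angle at least 120
#' degrees, acceptor angle at least 90 degrees (both angle thresholds
#' inclusive).
#'
#' @param max_ha Strict upper bound on the H...A distance (Angstrom).
#' @param min_donor_angle Minimum donor angle at the hydrogen (degrees,
#'   inclusive).
#' @param min_acceptor_angle Minimum acceptor angle at the acceptor
#'   (degrees, inclusive).
#' @return A list of class `"hbond_criteria"`.
#' @export
hbond_criteria <- function(max_ha = 2.8, min_donor_angle = 120,
                           min_acceptor_angle = 90) {
  stopifnot(max_ha > 0,
            min_donor_angle >= 0, min_donor_angle <= 180,
            min_acceptor_angle >= 0, min_acceptor_angle <= 180)
  structure(list(max_ha = max_ha, min_donor_angle = min_donor_angle,
                 min_acceptor_angle = min_acceptor_angle),
            class = "hbond_criteria")
}

#' Detect hydrogen bonds in one frame
#'
#' Scans all donor-flagged hydrogens against all acceptor-flagged heavy
#' atoms under the minimum-image convention and applies the distance and
#' angle criteria. Intramolecular donor-acceptor pairs are excluded for
#' water; for polymer/filler molecules they are kept only when donor and
#' acceptor are separated by more than 3 covalent bonds (crosslinked chains
#' can legitimately self-bond).
#'
#' @param coords `atoms x 3` coordinate matrix (Angstrom) for one frame.
#' @param top The matching `topology` with donor/acceptor flags populated.
#' @param box Orthorhombic box (3-vector, Angstrom).
#' @param criteria An [hbond_criteria()].
#' @return Data frame with one row per bond: `donor`, `hydrogen`,
#'   `acceptor` (atom indices), `dist` (H...A, Angstrom), `donor_angle` and
#'   `acceptor_angle` (degrees; the acceptor angle is the smallest over the
#'   acceptor's heavy neighbours, `NA` if it has none).
#' @export
detect_hbonds <- function(coords, top, box, criteria = hbond_criteria()) {
  stopifnot(inherits(criteria, "hbond_criteria"))
  box <- check_box(box)
  atoms <- top$atoms
  adj <- bond_adjacency(top)
  heavy <- atoms$element != "H"
  h_idx <- which(atoms$donor_h)
  a_idx <- which(atoms$acceptor)
  empty <- data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), dist = numeric(0),
                      donor_angle = numeric(0), acceptor_angle = numeric(0))
  if (length(h_idx) == 0L || length(a_idx) == 0L) return(empty)
  donor_of <- vapply(h_idx, function(h) {
    nb <- adj[[h]]
    nbh <- nb[heavy[nb]]
    if (length(nbh) != 1L) {
      stop("topology defect: donor hydrogen ", h,
           " is not bonded to exactly one heavy atom")
    }
    nbh
  }, integer(1))
  cand <- cross_pairs_within(matrix(coords[h_idx, ], ncol = 3),
                             matrix(coords[a_idx, ], ncol = 3),
                             box, criteria$max_ha)
  if (length(cand$i) == 0L) return(empty)
  # guard band so geometries constructed exactly on a threshold behave per
  # the strict-distance / inclusive-angle rules despite rounding
  eps_d <- 1e-9
  eps_a <- 1e-9
  rows <- vector("list", length(cand$i))
  n_out <- 0L
  for (c_i in seq_along(cand$i)) {
    h <- h_idx[cand$i[c_i]]
    a <- a_idx[cand$j[c_i]]
    d <- donor_of[cand$i[c_i]]
    if (a == d) next
    if (cand$dist[c_i] >= criteria$max_ha - eps_d) next
    same_mol <- atoms$mol_id[d] == atoms$mol_id[a]
    if (same_mol) {
      if (atoms$species[d] == "water") next
      if (bond_distance(adj, d, a, max_depth = 3L) <= 3L) next
    }
    dang <- pbc_angle(coords[d, ], coords[h, ], coords[a, ], box)
    if (dang < criteria$min_donor_angle - eps_a) next
    xs <- adj[[a]]
    xs <- xs[heavy[xs]]
    aang <- NA_real_
    if (length(xs)) {
      aang <- min(vapply(xs, function(x)
        pbc_angle(coords[h, ], coords[a, ], coords[x, ], box), numeric(1)))
      if (aang < criteria$min_acceptor_angle - eps_a) next
    }
    n_out <- n_out + 1L
    rows[[n_out]] <- data.frame(donor = d, hydrogen = h, acceptor = a,
                                dist = cand$dist[c_i], donor_angle = dang,
                                acceptor_angle = aang)
  }
  if (n_out == 0L) return(empty)
  do.call(rbind, rows[seq_len(n_out)])
}

#' Classify hydrogen bonds into water-water / polymer-polymer / polymer-water
#'
#' A bond is `ww` when both the donor's and the acceptor's molecules are
#' water, `pp` when neither is, and `pw` otherwise. Filler molecules count
#' as polymer.
#'
#' @param hbonds Data frame from [detect_hbonds()].
#' @param top The matching `topology`.
#' @return `hbonds` with an added factor column `class` (levels `ww`, `pp`,
#'   `pw`).
#' @export
classify_hbonds <- function(hbonds, top) {
  a <- top$atoms
  dw <- a$species[hbonds$donor] == "water"
  aw <- a$species[hbonds$acceptor] == "water"
  cls <- ifelse(dw & aw, "ww", ifelse(!dw & !aw, "pp", "pw"))
  hbonds$class <- factor(cls, levels = c("ww", "pp", "pw"))
  hbonds
}

#' Per-class hydrogen-bond counts for one frame
#'
#' @param hbonds Data frame from [detect_hbonds()].
#' @param top The matching `topology`.
#' @return One-row data frame with `n_ww`, `n_pp`, `n_pw`, `n_total`
#'   (`n_total = n_ww + n_pp + n_pw` by construction).
#' @export
hbond_counts <- function(hbonds, top) {
  cls <- classify_hbonds(hbonds, top)$class
  tab <- table(cls)
  data.frame(n_ww = as.integer(tab[["ww"]]), n_pp = as.integer(tab[["pp"]]),
             n_pw = as.integer(tab[["pw"]]), n_total = length(cls))
}

#' Polymer-water hydrogen bonds by difference
#'
#' The polymer-water count follows from the total once the two like-species
#' counts are known: `n_pw = n_total - n_pp - n_ww`.
#'
#' @param n_total Total hydrogen-bond count.
#' @param n_pp Polymer-polymer count.
#' @param n_ww Water-water count.
#' @return The polymer-water count. A negative difference means the inputs
#'   are inconsistent and raises an error.
#' @examples
#' pw_by_difference(666, 251, 78) # 337
#' @export
pw_by_difference <- function(n_total, n_pp, n_ww) {
  out <- n_total - n_pp - n_ww
  if (any(out < 0)) {
    stop("inconsistent counts: n_total < n_pp + n_ww")
  }
  out
}

#' Hydrogen-bond count profile over a trajectory
#'
#' Runs [detect_hbonds()] on every `stride`-th frame and tabulates per-class
#' counts, plus a per-class mean and standard deviation summary.
#'
#' @param traj A `trajectory` (coordinates wrapped or wrappable).
#' @param top The matching `topology`.
#' @param criteria An [hbond_criteria()].
#' @param stride Frame stride (default 1).
#' @return A list of class `"hbond_profile"` with `series` (data frame:
#'   `frame`, `time_ps`, `n_ww`, `n_pp`, `n_pw`, `n_total`) and `summary`
#'   (data frame: `class`, `mean`, `sd`).
#' @export
hbond_profile <- function(traj, top, criteria = hbond_criteria(), stride = 1L) {
  frames <- seq.int(1L, n_frames(traj), by = stride)
  rows <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    f <- frames[i]
    hb <- detect_hbonds(frame_coords(traj, f), top, traj$box[f, ], criteria)
    cnt <- hbond_counts(hb, top)
    rows[[i]] <- cbind(data.frame(frame = f, time_ps = traj$times[f]), cnt)
  }
  series <- do.call(rbind, rows)
  summ <- data.frame(
    class = c("ww", "pp", "pw", "total"),
    mean = c(mean(series$n_ww), mean(series$n_pp), mean(series$n_pw),
             mean(series$n_total)),
    sd = c(stats::sd(series$n_ww), stats::sd(series$n_pp),
           stats::sd(series$n_pw), stats::sd(series$n_total)))
  structure(list(series = series, summary = summ), class = "hbond_profile")
}

#' @export
print.hbond_profile <- function(x, ...) {
  cat(sprintf("<hbond_profile> %d frames\n", nrow(x$series)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Export a hydrogen-bond profile
#'
#' Writes the per-frame series as CSV and, optionally, the per-class summary
#' as JSON.
#'
#' @param profile An `hbond_profile`.
#' @param csv_path Output CSV path for the series.
#' @param json_path Optional output JSON path for the summary.
#' @return `csv_path`, invisibly.
#' @export
write_hbond_profile <- function(profile, csv_path, json_path = NULL) {
  utils::write.csv(profile$series, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(profile$summary, json_path, digits = NA,
                         dataframe = "rows")
  }
  invisible(csv_path)
}
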