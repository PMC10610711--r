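# Synthetic trajectory and scene generators with exact ground truth.
#
# These emulate, at desk scale, the situations the analyses are built for:
# free Brownian penetrant motion at a prescribed diffusion coefficient,
# ballistic and confined (plateauing) MSD regimes, planted hydrogen-bond
# geometries straddling the detection criteria, and planted water clusters
# of prescribed sizes. Every generator is bit-reproducible from its seed.

# Rigid ideal water geometry: O-H 0.9572 A, H-O-H 104.52 deg.
WATER_OH <- 0.9572
WATER_HOH <- 104.52

# Canonical water site offsets (3 x 3: O, H, H) with centre of mass at origin.
water_sites <- function() {
  th <- WATER_HOH * pi / 180
  o <- c(0, 0, 0)
  h1 <- WATER_OH * c(sin(th / 2), 0, cos(th / 2))
  h2 <- WATER_OH * c(-sin(th / 2), 0, cos(th / 2))
  sites <- rbind(o, h1, h2)
  m <- c(STANDARD_MASS[["O"]], STANDARD_MASS[["H"]], STANDARD_MASS[["H"]])
  sweep(sites, 2, colSums(sites * m) / sum(m))
}

# Uniform random rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Specification of a synthetic walker ensemble
#'
#' @param mode `"brownian"` (independent Gaussian steps of per-axis variance
#'   `2 D dt`), `"ballistic"` (constant random velocity) or `"confined"`
#'   (Brownian with specular reflection at a spherical cavity wall).
#' @param n_molecules Number of water-like walkers (>= 1).
#' @param n_frames Number of frames (>= 2).
#' @param dt Frame spacing in ps. Default 5 ps, a typical recording interval
#'   for production MD.
#' @param d_true True self-diffusion coefficient in m^2/s (brownian/confined).
#' @param speed Speed in Angstrom/ps (ballistic).
#' @param cavity_radius Cavity radius in Angstrom (confined).
#' @param box Orthorhombic box (3-vector, Angstrom).
#' @param seed Integer RNG seed; identical spec + seed gives bit-identical
#'   output.
#' @return A validated list of class `"synth_spec"`.
#' @export
synth_spec <- function(mode = c("brownian", "ballistic", "confined"),
                       n_molecules, n_frames, dt = 5, d_true = NULL,
                       speed = NULL, cavity_radius = NULL,
                       box = c(50, 50, 50), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_molecules >= 1L, n_frames >= 2L, dt > 0)
  box <- check_box(box)
  if (mode %in% c("brownian", "confined")) {
    if (is.null(d_true) || d_true < 0) stop("brownian/confined mode needs d_true >= 0")
  }
  if (mode == "ballistic" && (is.null(speed) || speed < 0)) {
    stop("ballistic mode needs a non-negative speed")
  }
  if (mode == "confined" && (is.null(cavity_radius) || cavity_radius <= 0)) {
    stop("confined mode needs cavity_radius > 0")
  }
  structure(list(mode = mode, n_molecules = as.integer(n_molecules),
                 n_frames = as.integer(n_frames), dt = dt, d_true = d_true,
                 speed = speed, cavity_radius = cavity_radius, box = box,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' Generate a synthetic walker ensemble with known ground truth
#'
#' Each walker is a rigid ideal water molecule translated along its
#' centre-of-mass path (orientation fixed per molecule; internal motion is
#' irrelevant to the analyses). Brownian steps are Gaussian with per-axis
#' variance `2 D dt`, so the ensemble MSD expectation is `6 D tau` exactly.
#'
#' @param spec A [synth_spec()].
#' @return A list with elements `wrapped` (box-wrapped `trajectory`),
#'   `continuous` (ground-truth unwrapped `trajectory`), `topology`, and
#'   `com_true` (frames x molecules x 3 array of true walker paths).
#' @export
gen_walkers <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed, {
    nm <- spec$n_molecules; nf <- spec$n_frames; dt <- spec$dt
    box <- spec$box
    d_a2ps <- if (!is.null(spec$d_true)) spec$d_true * 1e8 else 0  # m^2/s -> A^2/ps
    com <- array(0, c(nf, nm, 3L))
    start <- matrix(stats::runif(nm * 3) * rep(box, each = nm), nm, 3)
    com[1, , ] <- start
    if (spec$mode == "brownian") {
      sd_step <- sqrt(2 * d_a2ps * dt)
      if (sd_step > min(box) / 4) {
        stop("step standard deviation exceeds L/4; unwrapping would be ambiguous ",
             "(reduce dt or d_true, or enlarge the box)")
      }
      if (nf > 1L && sd_step > 0) {
        for (ax in 1:3) {
          steps <- matrix(stats::rnorm((nf - 1L) * nm, sd = sd_step), nf - 1L, nm)
          com[, , ax] <- rbind(matrix(start[, ax], 1L, nm),
                               matrix(start[, ax], nf - 1L, nm, byrow = TRUE) +
                                 apply(steps, 2, cumsum))
        }
      } else {
        for (f in seq_len(nf)) com[f, , ] <- start
      }
    } else if (spec$mode == "ballistic") {
      v <- matrix(stats::rnorm(nm * 3), nm, 3)
      v <- v / sqrt(rowSums(v^2)) * spec$speed
      for (f in seq_len(nf)) com[f, , ] <- start + (f - 1L) * dt * v
    } else {  # confined
      sd_step <- sqrt(2 * d_a2ps * dt)
      if (sd_step > spec$cavity_radius / 2) {
        stop("step standard deviation exceeds cavity_radius/2")
      }
      centre <- start
      pos <- start
      for (f in 2:nf) {
        pos <- pos + matrix(stats::rnorm(nm * 3, sd = sd_step), nm, 3)
        rel <- pos - centre
        d <- sqrt(rowSums(rel^2))
        out <- which(d > spec$cavity_radius)
        while (length(out)) {  # specular fold at the spherical wall
          fold <- (2 * spec$cavity_radius - d[out]) / d[out]
          rel[out, ] <- rel[out, , drop = FALSE] * fold
          pos[out, ] <- centre[out, , drop = FALSE] + rel[out, , drop = FALSE]
          d[out] <- abs(2 * spec$cavity_radius - d[out])
          out <- out[d[out] > spec$cavity_radius]
        }
        com[f, , ] <- pos
      }
    }
    # rigid water sites, random fixed orientation per molecule
    sites <- water_sites()
    offs <- matrix(0, 3L * nm, 3L)
    for (m in seq_len(nm)) {
      offs[(3L * m - 2L):(3L * m), ] <- sites %*% t(random_rotation())
    }
    coords <- array(0, c(nf, 3L * nm, 3L))
    idx <- rep(seq_len(nm), each = 3L)
    for (f in seq_len(nf)) {
      coords[f, , ] <- com[f, idx, ] + offs
    }
    times <- (seq_len(nf) - 1L) * dt
    continuous <- trajectory(coords, times, box, wrapped = FALSE)
    list(wrapped = wrap(continuous), continuous = continuous,
         topology = water_topology(nm), com_true = com)
  })
}

#' Specification of a planted water-cluster scene
#'
#' @param planted_sizes Integer vector of cluster sizes (molecule counts).
#' @param cutoff O-O linkage cutoff in Angstrom the scene is built for.
#' @param min_gap Minimum inter-cluster O-O distance (Angstrom); must exceed
#'   `cutoff` so the planted partition is the unique single-linkage result.
#' @param span_boundary If `TRUE`, the largest planted cluster is translated
#'   to straddle a periodic box face.
#' @param box Orthorhombic box (3-vector, Angstrom).
#' @param seed Integer RNG seed.
#' @return A validated list of class `"cluster_scene"`.
#' @export
cluster_scene <- function(planted_sizes, cutoff = 3.5, min_gap = 7,
                          span_boundary = FALSE, box = c(40, 40, 40),
                          seed = 1L) {
  stopifnot(length(planted_sizes) >= 1L, all(planted_sizes >= 1L),
            cutoff > 0, min_gap > cutoff)
  structure(list(planted_sizes = as.integer(planted_sizes), cutoff = cutoff,
                 min_gap = min_gap, span_boundary = isTRUE(span_boundary),
                 box = check_box(box), seed = as.integer(seed)),
            class = "cluster_scene")
}

# Grow one connected blob of `size` O positions: each new member is placed
# within (0.75, 0.95) * cutoff of an existing member and at least 2.2 A from
# all members, so connectivity at `cutoff` is guaranteed by construction.
grow_blob <- function(size, cutoff, max_tries = 400L) {
  pts <- matrix(0, size, 3)
  if (size == 1L) return(pts)
  for (k in 2:size) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      anchor <- pts[sample.int(k - 1L, 1L), ]
      dir <- stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      cand <- anchor + dir * stats::runif(1, 0.75, 0.95) * cutoff
      dmin <- min(sqrt(rowSums(sweep(pts[seq_len(k - 1L), , drop = FALSE],
                                     2, cand)^2)))
      if (dmin >= 2.2) { pts[k, ] <- cand; ok <- TRUE; break }
    }
    if (!ok) return(NULL)
  }
  pts
}

#' Generate a single-frame scene of planted water clusters
#'
#' Builds a wrapped one-frame trajectory of water molecules whose oxygen
#' positions form exactly the requested single-linkage clusters at the scene
#' cutoff: every cluster is connected at `cutoff` and distinct clusters are
#' separated by more than `min_gap` under the minimum image convention. The
#' generated partition is verified by an internal re-clustering before
#' returning; packing failure after bounded retries is an error.
#'
#' @param scene A [cluster_scene()].
#' @return A list with `traj` (wrapped single-frame `trajectory`), `topology`,
#'   `partition` (list of molecule-id vectors, the ground truth, in the order
#'   the sizes were given) and `sizes`.
#' @export
gen_cluster_scene <- function(scene) {
  stopifnot(inherits(scene, "cluster_scene"))
  with_seed(scene$seed, {
    sizes <- scene$planted_sizes
    box <- scene$box
    for (attempt in 1:60) {
      placed <- vector("list", length(sizes))
      all_o <- NULL
      failed <- FALSE
      for (c_i in seq_along(sizes)) {
        blob <- grow_blob(sizes[c_i], scene$cutoff)
        if (is.null(blob)) { failed <- TRUE; break }
        ok <- FALSE
        for (try in 1:300) {
          centre <- stats::runif(3) * box
          cand <- sweep(blob, 2, centre, "+")
          if (is.null(all_o)) { ok <- TRUE; break }
          cp <- cross_pairs_within(cand, all_o, box, scene$min_gap + 1e-9)
          if (length(cp$i) == 0L) { ok <- TRUE; break }
        }
        if (!ok) { failed <- TRUE; break }
        placed[[c_i]] <- cand
        all_o <- rbind(all_o, cand)
      }
      if (failed) next
      if (scene$span_boundary) {
        largest <- which.max(sizes)
        centroid <- colMeans(placed[[largest]])
        shift <- c(0, 0, 0) - centroid  # largest cluster centred on a corner
        all_o <- sweep(all_o, 2, shift, "+")
      }
      all_o <- wrap_coords(all_o, box)
      # verify the planted partition is recovered
      labels <- rep(seq_along(sizes), sizes)
      pr <- pairs_within(all_o, box, scene$cutoff)
      comp <- union_find(nrow(all_o), pr$i, pr$j)
      same <- outer(comp, comp, "==") == outer(labels, labels, "==")
      if (!all(same)) next
      nm <- nrow(all_o)
      sites <- water_sites()
      sites <- sweep(sites, 2, sites[1, ])  # O at the planted point
      coords <- matrix(0, 3L * nm, 3L)
      for (m in seq_len(nm)) {
        coords[(3L * m - 2L):(3L * m), ] <-
          sweep(sites %*% t(random_rotation()), 2, all_o[m, ], "+")
      }
      traj <- wrap(trajectory(array(coords, c(1L, 3L * nm, 3L)), 0, box,
                              wrapped = FALSE))
      return(list(traj = traj, topology = water_topology(nm),
                  partition = split(seq_len(nm), labels),
                  sizes = sizes))
    }
    stop("failed to pack the requested clusters; use a larger box")
  })
}

#' Specification of a planted hydrogen-bond scene
#'
#' Each row of `triplets` requests one explicit donor-H...acceptor geometry:
#' H...A distance (Angstrom), donor angle at the hydrogen (degrees), acceptor
#' angle at the acceptor (degrees), and the species of the donor and acceptor
#' molecules (`"water"`, `"polymer"` or `"filler"`).
#'
#' @param dist,donor_angle,acceptor_angle Numeric vectors (recycled to a
#'   common length).
#' @param donor_species,acceptor_species Character vectors of species tags.
#' @return A validated list of class `"hbond_scene"`.
#' @export
hbond_scene <- function(dist, donor_angle, acceptor_angle,
                        donor_species = "water", acceptor_species = "water") {
  n <- max(length(dist), length(donor_angle), length(acceptor_angle),
           length(donor_species), length(acceptor_species))
  tr <- data.frame(dist = rep_len(dist, n),
                   donor_angle = rep_len(donor_angle, n),
                   acceptor_angle = rep_len(acceptor_angle, n),
                   donor_species = rep_len(donor_species, n),
                   acceptor_species = rep_len(acceptor_species, n),
                   stringsAsFactors = FALSE)
  if (n == 0L) stop("triplet list must be nonempty")
  stopifnot(all(tr$dist > 0),
            all(tr$donor_angle >= 0 & tr$donor_angle <= 180),
            all(tr$acceptor_angle >= 0 & tr$acceptor_angle <= 180))
  structure(list(triplets = tr), class = "hbond_scene")
}

#' Generate a single-frame scene of planted donor-H...acceptor geometries
#'
#' Constructs explicit D-H...A(-X) groups realizing each requested
#' (distance, donor angle, acceptor angle) exactly, placed on a coarse grid
#' (20 Angstrom spacing) so no unintended contacts arise. Water acceptors
#' have no heavy neighbour, so their acceptor-angle check is vacuous; the
#' requested acceptor angle is realized against the planted heavy neighbour
#' X for polymer/filler acceptors. Only the bridging hydrogen carries the
#' donor flag and only A the acceptor flag, so each triplet contributes at
#' most the one planted candidate bond.
#'
#' @param scene An [hbond_scene()].
#' @return A list with `traj` (wrapped single-frame `trajectory`), `topology`
#'   and `planted` (data frame of donor/hydrogen/acceptor atom indices with
#'   the requested geometry).
#' @export
gen_hbond_scene <- function(scene) {
  stopifnot(inherits(scene, "hbond_scene"))
  tr <- scene$triplets
  n <- nrow(tr)
  k <- ceiling(n^(1 / 3))
  spacing <- 20
  box <- rep(k * spacing, 3)
  element <- character(0); mol_id <- integer(0); species <- character(0)
  donor_h <- logical(0); acceptor <- logical(0)
  bonds <- NULL; coords <- NULL
  planted <- data.frame(donor = integer(n), hydrogen = integer(n),
                        acceptor = integer(n), dist = tr$dist,
                        donor_angle = tr$donor_angle,
                        acceptor_angle = tr$acceptor_angle)
  mol <- 0L
  for (i in seq_len(n)) {
    al <- tr$donor_angle[i] * pi / 180
    h <- c(0, 0, 0)
    d <- c(WATER_OH, 0, 0)
    a <- tr$dist[i] * c(cos(al), sin(al), 0)
    if (sqrt(sum((a - d)^2)) < 0.1) {
      stop("triplet ", i, ": requested geometry places acceptor on top of donor")
    }
    local_el <- c("O", "H"); local_xyz <- rbind(d, h)
    base <- length(element)
    d_idx <- base + 1L; h_idx <- base + 2L
    local_bonds <- rbind(c(1L, 2L))
    local_donor <- c(FALSE, TRUE); local_acc <- c(FALSE, FALSE)
    dir_dh <- (h - d) / WATER_OH
    th <- WATER_HOH * pi / 180
    if (tr$donor_species[i] == "water") {  # second hydrogen completes the water
      h2 <- d + WATER_OH * (cos(th) * dir_dh + sin(th) * c(0, 0, 1))
      local_el <- c(local_el, "H"); local_xyz <- rbind(local_xyz, h2)
      local_bonds <- rbind(local_bonds, c(1L, 3L))
      local_donor <- c(local_donor, FALSE); local_acc <- c(local_acc, FALSE)
    } else {  # hydroxyl on a carbon
      cpos <- d + 1.43 * (cos(1.91) * dir_dh - sin(1.91) * c(0, 0, 1))
      local_el <- c(local_el, "C"); local_xyz <- rbind(local_xyz, cpos)
      local_bonds <- rbind(local_bonds, c(1L, 3L))
      local_donor <- c(local_donor, FALSE); local_acc <- c(local_acc, FALSE)
    }
    mol <- mol + 1L
    nd <- length(local_el)
    element <- c(element, local_el)
    mol_id <- c(mol_id, rep(mol, nd))
    species <- c(species, rep(tr$donor_species[i], nd))
    donor_h <- c(donor_h, local_donor); acceptor <- c(acceptor, local_acc)
    bonds <- rbind(bonds, local_bonds + base)
    # acceptor group
    abase <- length(element)
    a_idx <- abase + 1L
    u <- (h - a) / sqrt(sum((h - a)^2))       # A -> H direction
    wv <- c(-u[2], u[1], 0)                   # in-plane perpendicular
    wv <- wv / sqrt(sum(wv^2))
    be <- tr$acceptor_angle[i] * pi / 180
    if (tr$acceptor_species[i] == "water") {
      hh1 <- a + WATER_OH * (cos(be) * u + sin(be) * wv)
      th2 <- WATER_HOH * pi / 180
      # second H at the water angle from the first, tilted out of plane
      v1 <- (hh1 - a) / WATER_OH
      hh2 <- a + WATER_OH * (cos(th2) * v1 + sin(th2) * c(0, 0, 1))
      ael <- c("O", "H", "H"); axyz <- rbind(a, hh1, hh2)
      abonds <- rbind(c(1L, 2L), c(1L, 3L))
      aacc <- c(TRUE, FALSE, FALSE); adon <- c(FALSE, FALSE, FALSE)
    } else {
      x <- a + 1.43 * (cos(be) * u + sin(be) * wv)
      ael <- c("O", "C"); axyz <- rbind(a, x)
      abonds <- rbind(c(1L, 2L))
      aacc <- c(TRUE, FALSE); adon <- c(FALSE, FALSE)
    }
    mol <- mol + 1L
    element <- c(element, ael)
    mol_id <- c(mol_id, rep(mol, length(ael)))
    species <- c(species, rep(tr$acceptor_species[i], length(ael)))
    donor_h <- c(donor_h, adon); acceptor <- c(acceptor, aacc)
    bonds <- rbind(bonds, abonds + abase)
    # place the whole triplet at its grid cell centre
    cell <- c((i - 1L) %% k, ((i - 1L) %/% k) %% k, (i - 1L) %/% (k * k))
    centre <- (cell + 0.5) * spacing
    local_all <- rbind(local_xyz, axyz)
    coords <- rbind(coords, sweep(local_all, 2, centre, "+"))
    planted$donor[i] <- d_idx
    planted$hydrogen[i] <- h_idx
    planted$acceptor[i] <- a_idx
  }
  top <- topology(element, mol_id, species, bonds = bonds,
                  donor_h = donor_h, acceptor = acceptor)
  traj <- wrap(trajectory(array(coords, c(1L, nrow(coords), 3L)), 0, box,
                          wrapped = FALSE))
  list(traj = traj, topology = top, planted = planted)
}
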