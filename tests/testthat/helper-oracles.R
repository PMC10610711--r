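# Independent brute-force oracles and small scene builders used across the
# suite. These deliberately re-derive each quantity by the most literal
# method available (explicit loops, all 27 periodic images) and share no
# code path with the package implementations they check.

# Minimum-image distance by explicit minimisation over all 27 image shifts.
brute_min_image <- function(a, b, box) {
  best <- NULL
  bestn <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    d <- (b + c(ix, iy, iz) * box) - a
    n2 <- sum(d^2)
    if (n2 < bestn) { bestn <- n2; best <- d }
  }
  best
}

# Literal double loop over origins and lags for the multi-origin MSD of a
# frames x molecules x 3 centre-of-mass array.
brute_msd <- function(com, dt, kmax, origin_stride = 1L) {
  nf <- dim(com)[1]; nm <- dim(com)[2]
  vals <- numeric(kmax); nsamp <- integer(kmax)
  for (k in seq_len(kmax)) {
    acc <- 0; cnt <- 0L
    for (t0 in seq.int(1L, nf - k, by = origin_stride)) {
      for (m in seq_len(nm)) {
        acc <- acc + sum((com[t0 + k, m, ] - com[t0, m, ])^2)
        cnt <- cnt + 1L
      }
    }
    vals[k] <- acc / cnt
    nsamp[k] <- cnt
  }
  data.frame(lag_ps = seq_len(kmax) * dt, msd_A2 = vals, n_samples = nsamp)
}

brute_angle <- function(p, v, q, box) {
  u1 <- brute_min_image(v, p, box)
  u2 <- brute_min_image(v, q, box)
  acos(min(1, max(-1, sum(u1 * u2) / sqrt(sum(u1^2) * sum(u2^2))))) * 180 / pi
}

# Bond-path distance by literal breadth-first search on the bond table.
brute_bond_dist <- function(top, a, b, cap = 4L) {
  edges <- top$bonds
  frontier <- a; seen <- a
  for (depth in seq_len(cap)) {
    nxt <- c(edges[edges[, 1] %in% frontier, 2],
             edges[edges[, 2] %in% frontier, 1])
    frontier <- setdiff(nxt, seen)
    if (length(frontier) == 0L) return(Inf)
    if (b %in% frontier) return(depth)
    seen <- c(seen, frontier)
  }
  Inf
}

# Literal triple loop over (donor, hydrogen, acceptor) applying the same
# geometric rules as the detector.
brute_hbonds <- function(coords, top, box, crit) {
  atoms <- top$atoms
  out <- NULL
  for (h in which(atoms$donor_h)) {
    nb <- c(top$bonds[top$bonds[, 1] == h, 2], top$bonds[top$bonds[, 2] == h, 1])
    d <- nb[atoms$element[nb] != "H"]
    for (a in which(atoms$acceptor)) {
      if (a == d) next
      if (atoms$mol_id[a] == atoms$mol_id[d]) {
        if (atoms$species[d] == "water") next
        if (brute_bond_dist(top, d, a, cap = 3L) <= 3L) next
      }
      dist <- sqrt(sum(brute_min_image(coords[h, ], coords[a, ], box)^2))
      if (dist >= crit$max_ha) next
      if (brute_angle(coords[d, ], coords[h, ], coords[a, ], box) <
          crit$min_donor_angle) next
      xs <- c(top$bonds[top$bonds[, 1] == a, 2], top$bonds[top$bonds[, 2] == a, 1])
      xs <- xs[atoms$element[xs] != "H"]
      ok <- TRUE
      for (x in xs) {
        if (brute_angle(coords[h, ], coords[a, ], coords[x, ], box) <
            crit$min_acceptor_angle) { ok <- FALSE; break }
      }
      if (!ok) next
      out <- rbind(out, data.frame(donor = d, hydrogen = h, acceptor = a))
    }
  }
  if (is.null(out)) data.frame(donor = integer(0), hydrogen = integer(0),
                               acceptor = integer(0)) else out
}

# All-pairs single-linkage clustering by repeated label propagation until a
# fixed point; distance test per pair via the 27-image brute force.
brute_clusters <- function(o_coords, box, cutoff) {
  n <- nrow(o_coords)
  labels <- seq_len(n)
  linked <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) {
      d <- sqrt(sum(brute_min_image(o_coords[i, ], o_coords[j, ], box)^2))
      linked[i, j] <- linked[j, i] <- d <= cutoff
    }
  }
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (linked[i, j] && labels[j] != labels[i]) {
        lab <- min(labels[i], labels[j])
        labels[labels == labels[i] | labels == labels[j]] <- lab
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(labels, unique(labels))
}

# Random dense water scene: n water molecules in a small box so that
# hydrogen-bond candidates and periodic contacts are plentiful.
random_water_scene <- function(n, box_l = 12, seed = 1) {
  set.seed(seed)
  top <- water_topology(n)
  coords <- matrix(0, 3 * n, 3)
  th <- 104.52 * pi / 180
  for (m in seq_len(n)) {
    o <- runif(3) * box_l
    # random orientation from two random unit vectors at the water angle
    z <- rnorm(3); z <- z / sqrt(sum(z^2))
    p <- rnorm(3); p <- p - sum(p * z) * z; p <- p / sqrt(sum(p^2))
    h1 <- o + 0.9572 * z
    h2 <- o + 0.9572 * (cos(th) * z + sin(th) * p)
    coords[3 * m - 2, ] <- o
    coords[3 * m - 1, ] <- h1
    coords[3 * m, ] <- h2
  }
  list(coords = wrap_coords_for_test(coords, rep(box_l, 3)),
       top = top, box = rep(box_l, 3))
}

wrap_coords_for_test <- function(x, box) {
  x - rep(box, each = nrow(x)) * floor(x / rep(box, each = nrow(x)))
}

# Ideal rigid-geometry water dimer: donor O-H pointing at the acceptor O
# along +x at the given O...O separation, acceptor hydrogens pointing away.
water_dimer <- function(oo = 2.9) {
  top <- water_topology(2)
  th <- 104.52 * pi / 180
  o1 <- c(0, 0, 0)
  h1 <- c(0.9572, 0, 0)                         # bridging hydrogen
  h2 <- o1 + 0.9572 * c(cos(th), sin(th), 0)
  o2 <- c(oo, 0, 0)
  h3 <- o2 + 0.9572 * c(cos(1.0), 0, sin(1.0))  # pointing up and away
  h4 <- o2 + 0.9572 * c(cos(1.0), 0, -sin(1.0))
  coords <- rbind(o1, h1, h2, o2, h3, h4) + 10
  list(coords = coords, top = top, box = c(30, 30, 30))
}

# Synthetic msd_curve from a closed-form function of lag.
make_msd_curve <- function(lags, fn, n_molecules = 1L) {
  out <- data.frame(lag_ps = lags, msd_A2 = fn(lags),
                    n_samples = rep(1L, length(lags)))
  class(out) <- c("msd_curve", "data.frame")
  attr(out, "n_molecules") <- n_molecules
  out
}
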