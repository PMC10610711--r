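# Topology: per-atom annotations driving selections and hydrogen-bond roles.

STANDARD_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
                   Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45)

#' Construct an atom topology
#'
#' Bundles the per-atom annotations every analysis stage relies on: element,
#' mass, molecule id, species class (`water`, `polymer` or `filler`), the
#' covalent bond list, and hydrogen-bond roles (donor hydrogens, acceptor
#' heavy atoms).
#'
#' Invariants enforced: masses strictly positive; species tags known; every
#' donor-flagged hydrogen is bonded to exactly one heavy atom (its donor);
#' every water molecule consists of exactly three atoms (one O, two H).
#'
#' @param element Character vector of element symbols.
#' @param mol_id Integer vector of molecule ids; ids partition the atoms.
#' @param species Character vector, one of `"water"`, `"polymer"`, `"filler"`.
#' @param mass Numeric vector of atomic masses (amu). Defaults to standard
#'   masses looked up by element symbol.
#' @param bonds Two-column integer matrix of covalent bonds (1-based atom
#'   indices).
#' @param donor_h Logical vector: `TRUE` on hydrogens that can donate a
#'   hydrogen bond (i.e. hydrogens bonded to N or O).
#' @param acceptor Logical vector: `TRUE` on N/O atoms that can accept.
#' @return An object of class `"topology"`: a list with elements `atoms`
#'   (data frame) and `bonds` (integer matrix).
#' @export
topology <- function(element, mol_id, species, mass = NULL, bonds = NULL,
                     donor_h = NULL, acceptor = NULL) {
  n <- length(element)
  if (is.null(mass)) {
    mass <- unname(STANDARD_MASS[element])
    if (anyNA(mass)) {
      stop("no standard mass for element(s): ",
           paste(unique(element[is.na(mass)]), collapse = ", "))
    }
  }
  stopifnot(length(mol_id) == n, length(species) == n, length(mass) == n)
  if (any(mass <= 0)) stop("all atomic masses must be strictly positive")
  bad <- setdiff(unique(species), c("water", "polymer", "filler"))
  if (length(bad)) stop("unknown species tag(s): ", paste(bad, collapse = ", "))
  if (is.null(bonds)) bonds <- matrix(integer(0), 0, 2)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) && (min(bonds) < 1L || max(bonds) > n)) {
    stop("bond indices out of range")
  }
  if (is.null(donor_h)) donor_h <- rep(FALSE, n)
  if (is.null(acceptor)) acceptor <- rep(FALSE, n)
  atoms <- data.frame(element = as.character(element), mass = as.numeric(mass),
                      mol_id = as.integer(mol_id),
                      species = as.character(species),
                      donor_h = as.logical(donor_h),
                      acceptor = as.logical(acceptor),
                      stringsAsFactors = FALSE)
  top <- structure(list(atoms = atoms, bonds = bonds), class = "topology")
  validate_topology(top)
  top
}

validate_topology <- function(top) {
  atoms <- top$atoms
  adj <- bond_adjacency(top)
  heavy <- atoms$element != "H"
  for (i in which(atoms$donor_h)) {
    if (atoms$element[i] != "H") {
      stop("donor_h flag set on non-hydrogen atom ", i)
    }
    nb <- adj[[i]]
    if (sum(heavy[nb]) != 1L) {
      stop("donor hydrogen ", i, " must be bonded to exactly one heavy atom")
    }
  }
  if (any(atoms$acceptor & !(atoms$element %in% c("N", "O")))) {
    stop("acceptor flags are restricted to N and O atoms")
  }
  wmol <- unique(atoms$mol_id[atoms$species == "water"])
  for (m in wmol) {
    el <- sort(atoms$element[atoms$mol_id == m])
    if (!identical(el, c("H", "H", "O"))) {
      stop("water molecule ", m, " must consist of exactly O, H, H")
    }
  }
  invisible(top)
}

#' @export
print.topology <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<topology> %d atoms, %d molecules, %d bonds\n",
              nrow(a), length(unique(a$mol_id)), nrow(x$bonds)))
  tab <- table(a$species)
  cat("  species:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Number of atoms in a topology
#' @param top A `topology`.
#' @return Integer atom count.
#' @export
n_atoms <- function(top) nrow(top$atoms)

# Adjacency list (neighbours per atom) from the bond table.
bond_adjacency <- function(top) {
  n <- nrow(top$atoms)
  adj <- vector("list", n)
  b <- top$bonds
  if (nrow(b)) {
    for (e in seq_len(nrow(b))) {
      adj[[b[e, 1]]] <- c(adj[[b[e, 1]]], b[e, 2])
      adj[[b[e, 2]]] <- c(adj[[b[e, 2]]], b[e, 1])
    }
  }
  adj
}

# Bond-graph distance between atoms a and b, capped at `max_depth`
# (returns Inf beyond the cap). Used for the intramolecular exclusion rule.
bond_distance <- function(adj, a, b, max_depth = 4L) {
  if (a == b) return(0L)
  frontier <- a
  seen <- a
  for (depth in seq_len(max_depth)) {
    frontier <- setdiff(unlist(adj[frontier], use.names = FALSE), seen)
    if (length(frontier) == 0L) return(Inf)
    if (b %in% frontier) return(depth)
    seen <- c(seen, frontier)
  }
  Inf
}

#' Build a topology of rigid water molecules
#'
#' Convenience builder for systems of `n` water molecules stored as
#' consecutive O, H, H atom triples: O-H bonds, donor flags on hydrogens and
#' acceptor flags on oxygens.
#'
#' @param n Number of water molecules.
#' @param mol_id_offset Offset added to molecule ids (for composing scenes).
#' @return A `topology` with `3 * n` atoms.
#' @export
water_topology <- function(n, mol_id_offset = 0L) {
  element <- rep(c("O", "H", "H"), n)
  mol_id <- rep(seq_len(n), each = 3L) + mol_id_offset
  o_idx <- 3L * (seq_len(n) - 1L) + 1L
  bonds <- rbind(cbind(o_idx, o_idx + 1L), cbind(o_idx, o_idx + 2L))
  topology(element, mol_id, rep("water", 3L * n), bonds = bonds,
           donor_h = rep(c(FALSE, TRUE, TRUE), n),
           acceptor = rep(c(TRUE, FALSE, FALSE), n))
}

#' Derive a topology from residue names
#'
#' Builds a topology from per-atom element symbols, molecule ids and residue
#' names as read from a PDB or GRO file. Residues named `HOH` or `SOL` are
#' tagged `water` (with O-H bonds and donor/acceptor flags filled in);
#' everything else is tagged `polymer` with no bonds inferred.
#'
#' @param element Character vector of element symbols.
#' @param mol_id Integer vector of molecule (residue) ids.
#' @param resname Character vector of residue names.
#' @return A `topology`.
#' @export
topology_from_residues <- function(element, mol_id, resname) {
  water <- toupper(resname) %in% c("HOH", "SOL", "WAT", "TIP3")
  species <- ifelse(water, "water", "polymer")
  n <- length(element)
  bonds <- NULL
  donor_h <- rep(FALSE, n)
  acceptor <- rep(FALSE, n)
  for (m in unique(mol_id[water])) {
    idx <- which(mol_id == m)
    o <- idx[element[idx] == "O"]
    h <- idx[element[idx] == "H"]
    if (length(o) != 1L || length(h) != 2L) {
      stop("water residue ", m, " does not consist of O, H, H")
    }
    bonds <- rbind(bonds, cbind(o, h))
    donor_h[h] <- TRUE
    acceptor[o] <- TRUE
  }
  topology(element, mol_id, species, bonds = bonds,
           donor_h = donor_h, acceptor = acceptor)
}

#' Select atoms by species tag
#'
#' @param top A `topology`.
#' @param species One of `"water"`, `"polymer"`, `"filler"`.
#' @return Integer vector of atom indices in ascending order. An empty
#'   selection raises a warning, not an error.
#' @export
select_species <- function(top, species) {
  species <- match.arg(species, c("water", "polymer", "filler"))
  idx <- which(top$atoms$species == species)
  if (length(idx) == 0L) {
    warning("selection for species '", species, "' is empty")
  }
  idx
}

#' Write a topology to a JSON or CSV sidecar
#'
#' JSON stores the full topology (atom table plus bond list). CSV stores the
#' atom table with bonds encoded per atom in a `bonded_to` column as
#' `|`-separated indices.
#'
#' @param top A `topology`.
#' @param path Output path; format chosen by extension (`.json` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_topology <- function(top, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(list(atoms = top$atoms,
                              bonds = unclass(top$bonds)),
                         path, digits = NA, auto_unbox = FALSE)
  } else if (ext == "csv") {
    n <- nrow(top$atoms)
    bonded <- rep("", n)
    adj <- bond_adjacency(top)
    for (i in seq_len(n)) bonded[i] <- paste(sort(adj[[i]]), collapse = "|")
    utils::write.csv(cbind(top$atoms, bonded_to = bonded), path,
                     row.names = FALSE, quote = FALSE)
  } else {
    stop("unsupported topology format: .", ext)
  }
  invisible(path)
}

#' Read a topology sidecar written by [write_topology()]
#'
#' @param path Path to a `.json` or `.csv` topology file.
#' @return A `topology`.
#' @export
read_topology <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    a <- as.data.frame(x$atoms)
    bonds <- x$bonds
    if (is.null(bonds) || length(bonds) == 0L) bonds <- matrix(integer(0), 0, 2)
    topology(a$element, a$mol_id, a$species, mass = a$mass,
             bonds = matrix(as.integer(bonds), ncol = 2),
             donor_h = a$donor_h, acceptor = a$acceptor)
  } else if (ext == "csv") {
    a <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(bonded_to = "character"))
    bonds <- NULL
    for (i in seq_len(nrow(a))) {
      if (nzchar(a$bonded_to[i])) {
        nb <- as.integer(strsplit(a$bonded_to[i], "|", fixed = TRUE)[[1]])
        nb <- nb[nb > i]  # store each bond once
        if (length(nb)) bonds <- rbind(bonds, cbind(i, nb))
      }
    }
    topology(a$element, a$mol_id, a$species, mass = a$mass,
             bonds = bonds, donor_h = a$donor_h, acceptor = a$acceptor)
  } else {
    stop("unsupported topology format: .", ext)
  }
}
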