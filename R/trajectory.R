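# Trajectory container and plain-text trajectory I/O (XYZ / PDB / GRO).
# Internal units: Angstrom for coordinates, picoseconds for time.

#' Construct a trajectory
#'
#' @param coords Numeric array `frames x atoms x 3`, Cartesian coordinates in
#'   Angstrom. A single frame may be given as an `atoms x 3` matrix.
#' @param times Numeric vector of frame times in ps; strictly increasing with
#'   uniform spacing.
#' @param box Orthorhombic box: either a 3-vector applied to every frame or a
#'   `frames x 3` matrix of per-frame edge lengths (Angstrom).
#' @param wrapped Logical: are coordinates wrapped into `[0, L)` per axis?
#' @return An object of class `"trajectory"`.
#' @export
trajectory <- function(coords, times, box, wrapped) {
  if (is.matrix(coords)) coords <- array(coords, c(1L, nrow(coords), 3L))
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  nf <- dim(coords)[1]
  if (nf < 1L) stop("trajectory must contain at least one frame")
  if (!all(is.finite(coords))) stop("trajectory coordinates must be finite")
  if (length(times) != nf) stop("length(times) must equal the frame count")
  if (nf > 1L) {
    dts <- diff(times)
    if (any(dts <= 0)) stop("frame times must be strictly increasing")
    if (max(dts) - min(dts) > 1e-6 * max(dts)) {
      stop("frame times must be uniformly spaced")
    }
  }
  if (is.null(dim(box))) box <- matrix(rep(check_box(box), each = nf), nf, 3)
  stopifnot(nrow(box) == nf, ncol(box) == 3L)
  apply(box, 1, check_box)
  wrapped <- isTRUE(wrapped)
  if (wrapped) {
    for (ax in 1:3) {
      sl <- coords[, , ax, drop = FALSE]
      if (min(sl) < 0 || any(apply(sl, 1, max) >= box[, ax])) {
        stop("wrapped = TRUE but coordinates fall outside [0, L) on axis ", ax)
      }
    }
  }
  structure(list(coords = coords, times = as.numeric(times), box = box,
                 wrapped = wrapped),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<trajectory> %d frames x %d atoms, dt = %g ps, %s\n",
              d[1], d[2], frame_dt(x),
              if (x$wrapped) "wrapped" else "unwrapped"))
  cat(sprintf("  box (frame 1): %.3f x %.3f x %.3f A\n",
              x$box[1, 1], x$box[1, 2], x$box[1, 3]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

# Frame spacing in ps (0 for a single frame).
frame_dt <- function(traj) {
  if (n_frames(traj) < 2L) 0 else traj$times[2] - traj$times[1]
}

#' Extract one frame as an atoms x 3 coordinate matrix
#' @param traj A `trajectory`.
#' @param f Frame index (1-based).
#' @return Numeric `atoms x 3` matrix (Angstrom).
#' @export
frame_coords <- function(traj, f) {
  matrix(traj$coords[f, , ], ncol = 3L)
}

#' Wrap a trajectory into its periodic box
#'
#' Maps every coordinate into `[0, L)` per axis using the frame's own box.
#'
#' @param traj A `trajectory`.
#' @return A wrapped `trajectory`.
#' @export
wrap <- function(traj) {
  co <- traj$coords
  for (f in seq_len(n_frames(traj))) {
    co[f, , ] <- wrap_coords(matrix(co[f, , ], ncol = 3), traj$box[f, ])
  }
  trajectory(co, traj$times, traj$box, wrapped = TRUE)
}

#' Unwrap a wrapped trajectory into continuous paths
#'
#' Reconstructs continuous per-atom coordinates such that each successive
#' displacement equals the minimum-image displacement of the wrapped input;
#' frame 1 is kept unchanged. Required before any mean-squared-displacement
#' analysis, which accumulates displacements across boundary crossings.
#'
#' A step of at least half a box edge after unwrapping is ambiguous (the true
#' crossing count cannot be recovered); such steps trigger a warning naming
#' the first offending atom and frame.
#'
#' @param traj A wrapped `trajectory`.
#' @return An unwrapped `trajectory`.
#' @export
unwrap <- function(traj) {
  if (!traj$wrapped) stop("unwrap() expects a wrapped trajectory")
  co <- traj$coords
  nf <- n_frames(traj)
  if (nf > 1L) {
    warned <- FALSE
    prev <- matrix(co[1, , ], ncol = 3)
    for (f in 2:nf) {
      box <- traj$box[f, ]
      step <- min_image_mat(matrix(traj$coords[f, , ], ncol = 3) -
                              matrix(traj$coords[f - 1, , ], ncol = 3), box)
      if (!warned) {
        bad <- which(abs(step) >= rep(box / 2, each = nrow(step)) - 1e-9,
                     arr.ind = TRUE)
        if (nrow(bad)) {
          warning(sprintf(
            "ambiguous unwrap: atom %d step into frame %d is >= L/2 on axis %d",
            bad[1, 1], f, bad[1, 2]))
          warned <- TRUE
        }
      }
      prev <- prev + step
      co[f, , ] <- prev
    }
  }
  trajectory(co, traj$times, traj$box, wrapped = FALSE)
}

#' Per-molecule centre-of-mass trajectory
#'
#' @param traj A `trajectory`.
#' @param top The matching `topology`.
#' @param mol_ids Molecule ids to include (default: all molecules).
#' @return Array `frames x molecules x 3` of mass-weighted centres (Angstrom),
#'   with molecule ids as dimnames on the second margin.
#' @export
com_trajectory <- function(traj, top, mol_ids = NULL) {
  atoms <- top$atoms
  if (nrow(atoms) != dim(traj$coords)[2]) {
    stop("topology atom count does not match trajectory")
  }
  if (is.null(mol_ids)) mol_ids <- sort(unique(atoms$mol_id))
  keep <- atoms$mol_id %in% mol_ids
  grp <- factor(atoms$mol_id[keep], levels = mol_ids)
  m <- atoms$mass[keep]
  mtot <- as.numeric(rowsum(m, grp))
  nf <- n_frames(traj)
  out <- array(NA_real_, c(nf, length(mol_ids), 3L),
               dimnames = list(NULL, as.character(mol_ids), NULL))
  for (f in seq_len(nf)) {
    xyz <- matrix(traj$coords[f, keep, ], ncol = 3)
    out[f, , ] <- rowsum(xyz * m, grp) / mtot
  }
  out
}

# --- readers -----------------------------------------------------------------

#' Read a trajectory file
#'
#' Supported dialects: multi-frame XYZ whose comment line carries
#' `Lattice="Lx Ly Lz"` (and optionally `Time=<ps>`), multi-model PDB with a
#' CRYST1 record, and GRO (nm, converted to Angstrom). Box metadata is
#' mandatory; a missing box is a hard error naming the frame. Non-uniform
#' time spacing and atom-count changes across frames are hard errors.
#'
#' @param path Path to the trajectory file.
#' @param format `"auto"` (by extension), `"xyz"`, `"pdb"` or `"gro"`.
#' @param dt Frame spacing in ps, used when the format carries no time
#'   metadata (PDB always; XYZ/GRO without time stamps). Default 1 ps.
#' @param wrapped Logical override for the wrapped flag; by default the
#'   coordinates are inspected (`TRUE` iff every coordinate is in `[0, L)`).
#' @return A `trajectory`. For PDB and GRO input, a per-atom data frame with
#'   columns `element`, `resname`, `mol_id` is attached as attribute
#'   `"atoms"` for use with [topology_from_residues()].
#' @export
read_trajectory <- function(path, format = c("auto", "xyz", "pdb", "gro"),
                            dt = 1, wrapped = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     xyz = "xyz", pdb = "pdb", gro = "gro",
                     stop("cannot infer trajectory format from extension of ", path))
  }
  parsed <- switch(format,
                   xyz = read_xyz_frames(path),
                   pdb = read_pdb_frames(path),
                   gro = read_gro_frames(path))
  nf <- dim(parsed$coords)[1]
  times <- parsed$times
  if (is.null(times)) times <- (seq_len(nf) - 1) * dt
  if (is.null(wrapped)) {
    wrapped <- TRUE
    for (f in seq_len(nf)) {
      x <- matrix(parsed$coords[f, , ], ncol = 3)
      if (min(x) < 0 ||
          any(x >= rep(parsed$box[f, ], each = nrow(x)))) {
        wrapped <- FALSE
        break
      }
    }
  }
  traj <- trajectory(parsed$coords, times, parsed$box, wrapped = wrapped)
  attr(traj, "atoms") <- parsed$atoms
  traj
}

read_xyz_frames <- function(path) {
  lines <- readLines(path)
  pos <- 1L
  frames <- list(); boxes <- list(); times <- numeric(0)
  has_time <- TRUE
  f <- 0L
  while (pos <= length(lines) && nzchar(trimws(lines[pos]))) {
    f <- f + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(nat)) stop("frame ", f, ": malformed atom-count line")
    comment <- lines[pos + 1L]
    m <- regmatches(comment,
                    regexec('Lattice="\\s*([-0-9.eE+]+)\\s+([-0-9.eE+]+)\\s+([-0-9.eE+]+)\\s*"',
                            comment))[[1]]
    if (length(m) != 4L) {
      stop("frame ", f, ": XYZ comment line lacks Lattice=\"Lx Ly Lz\" box metadata")
    }
    boxes[[f]] <- as.numeric(m[2:4])
    tm <- regmatches(comment, regexec("Time=([-0-9.eE+]+)", comment))[[1]]
    if (length(tm) == 2L) times[f] <- as.numeric(tm[2]) else has_time <- FALSE
    body <- lines[(pos + 2L):(pos + 1L + nat)]
    fields <- strsplit(trimws(body), "\\s+")
    frames[[f]] <- list(
      element = vapply(fields, `[`, "", 1L),
      xyz = t(vapply(fields, function(z) as.numeric(z[2:4]), numeric(3))))
    pos <- pos + 2L + nat
  }
  assemble_frames(frames, boxes, if (has_time && length(times) == f) times,
                  atoms = NULL)
}

read_pdb_frames <- function(path) {
  lines <- readLines(path)
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (length(cr) == 0L) stop("PDB file lacks a CRYST1 box record")
  box <- as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                      substr(cr[1], 25, 33)))
  angles <- as.numeric(c(substr(cr[1], 34, 40), substr(cr[1], 41, 47),
                         substr(cr[1], 48, 54)))
  if (any(abs(angles - 90) > 1e-3)) {
    stop("triclinic cells are not supported (CRYST1 angles must be 90)")
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  nat <- ncol(xyz) / 3L
  coords <- array(NA_real_, c(nf, nat, 3L))
  for (f in seq_len(nf)) coords[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  key <- paste(pdb$atom$chain, pdb$atom$resno)
  atoms <- data.frame(element = pdb$atom$elesy,
                      resname = pdb$atom$resid,
                      mol_id = match(key, unique(key)),
                      stringsAsFactors = FALSE)
  list(coords = coords, box = matrix(rep(box, each = nf), nf, 3),
       times = NULL, atoms = atoms)
}

read_gro_frames <- function(path) {
  lines <- readLines(path)
  pos <- 1L
  frames <- list(); boxes <- list(); times <- numeric(0)
  has_time <- TRUE
  atoms <- NULL
  f <- 0L
  while (pos <= length(lines) && nzchar(trimws(lines[pos]))) {
    f <- f + 1L
    title <- lines[pos]
    tm <- regmatches(title, regexec("t=\\s*([-0-9.eE+]+)", title))[[1]]
    if (length(tm) == 2L) times[f] <- as.numeric(tm[2]) else has_time <- FALSE
    nat <- as.integer(trimws(lines[pos + 1L]))
    if (is.na(nat)) stop("frame ", f, ": malformed GRO atom-count line")
    body <- lines[(pos + 2L):(pos + 1L + nat)]
    boxline <- lines[pos + 2L + nat]
    bv <- as.numeric(strsplit(trimws(boxline), "\\s+")[[1]])
    if (length(bv) < 3L || anyNA(bv[1:3])) {
      stop("frame ", f, ": GRO box line missing or malformed")
    }
    if (length(bv) > 3L && any(abs(bv[4:length(bv)]) > 1e-9)) {
      stop("triclinic GRO cells are not supported")
    }
    xyz <- cbind(as.numeric(substr(body, 21, 28)),
                 as.numeric(substr(body, 29, 36)),
                 as.numeric(substr(body, 37, 44))) * 10  # nm -> Angstrom
    if (f == 1L) {
      resno <- as.integer(substr(body, 1, 5))
      resname <- trimws(substr(body, 6, 10))
      atname <- trimws(substr(body, 11, 15))
      atoms <- data.frame(element = sub("[0-9].*$", "", atname),
                          resname = resname,
                          mol_id = match(resno, unique(resno)),
                          stringsAsFactors = FALSE)
    }
    frames[[f]] <- list(element = NULL, xyz = xyz)
    boxes[[f]] <- bv[1:3] * 10
    pos <- pos + 3L + nat
  }
  assemble_frames(frames, boxes, if (has_time && length(times) == f) times,
                  atoms = atoms)
}

assemble_frames <- function(frames, boxes, times, atoms) {
  nf <- length(frames)
  if (nf == 0L) stop("no frames found in trajectory file")
  nat <- nrow(frames[[1]]$xyz)
  coords <- array(NA_real_, c(nf, nat, 3L))
  for (f in seq_len(nf)) {
    if (nrow(frames[[f]]$xyz) != nat) {
      stop("atom count changes at frame ", f, " (", nrow(frames[[f]]$xyz),
           " vs ", nat, ")")
    }
    coords[f, , ] <- frames[[f]]$xyz
  }
  if (is.null(atoms) && !is.null(frames[[1]]$element)) {
    atoms <- data.frame(element = frames[[1]]$element,
                        resname = NA_character_,
                        mol_id = NA_integer_, stringsAsFactors = FALSE)
  }
  list(coords = coords, box = do.call(rbind, boxes), times = times,
       atoms = atoms)
}

# --- writers -----------------------------------------------------------------

#' Write a trajectory file
#'
#' @param traj A `trajectory`.
#' @param path Output path.
#' @param top Optional `topology` supplying element symbols and residue
#'   grouping (required for PDB and GRO; for XYZ, elements default to `X`).
#' @param format `"auto"` (by extension), `"xyz"`, `"pdb"` or `"gro"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, top = NULL,
                             format = c("auto", "xyz", "pdb", "gro")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     xyz = "xyz", pdb = "pdb", gro = "gro",
                     stop("cannot infer trajectory format from extension of ", path))
  }
  switch(format,
         xyz = write_xyz_frames(traj, path, top),
         pdb = write_pdb_frames(traj, path, top),
         gro = write_gro_frames(traj, path, top))
  invisible(path)
}

write_xyz_frames <- function(traj, path, top) {
  nat <- dim(traj$coords)[2]
  el <- if (!is.null(top)) top$atoms$element else rep("X", nat)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    writeLines(as.character(nat), con)
    writeLines(sprintf('Lattice="%.6f %.6f %.6f" Time=%.6f',
                       traj$box[f, 1], traj$box[f, 2], traj$box[f, 3],
                       traj$times[f]), con)
    xyz <- frame_coords(traj, f)
    writeLines(sprintf("%-2s %14.6f %14.6f %14.6f",
                       el, xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
}

write_pdb_frames <- function(traj, path, top) {
  if (is.null(top)) stop("PDB output requires a topology")
  nat <- dim(traj$coords)[2]
  el <- top$atoms$element
  resname <- ifelse(top$atoms$species == "water", "HOH", "UNK")
  resno <- top$atoms$mol_id %% 10000L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     traj$box[1, 1], traj$box[1, 2], traj$box[1, 3],
                     90, 90, 90), con)
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frame_coords(traj, f)
    writeLines(sprintf(
      "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nat) %% 100000L, paste0(" ", el), resname, resno,
      xyz[, 1], xyz[, 2], xyz[, 3], el), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
}

write_gro_frames <- function(traj, path, top) {
  if (is.null(top)) stop("GRO output requires a topology")
  nat <- dim(traj$coords)[2]
  el <- top$atoms$element
  resname <- ifelse(top$atoms$species == "water", "SOL", "UNK")
  resno <- top$atoms$mol_id %% 100000L
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("sorbtrack frame %d, t= %.6f", f, traj$times[f]), con)
    writeLines(sprintf("%5d", nat), con)
    xyz <- frame_coords(traj, f) / 10  # Angstrom -> nm
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       resno, resname, el, seq_len(nat) %% 100000L,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", traj$box[f, 1] / 10,
                       traj$box[f, 2] / 10, traj$box[f, 3] / 10), con)
  }
}
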