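# Trajectory/topology I/O, periodic-boundary primitives, wrapping.

test_that("minimum-image displacement handles wrap-around and matches the 27-image brute force", {
  box <- c(10, 10, 10)
  expect_equal(minimum_image_displacement(c(1, 0, 0), c(9, 0, 0), box),
               c(-2, 0, 0))
  expect_equal(minimum_image_displacement(c(3, 4, 5), c(3, 4, 5), box),
               c(0, 0, 0))
  set.seed(11)
  box2 <- c(8, 13, 21)
  for (i in 1:50) {
    a <- runif(3) * box2   # wrapped coordinates, the convention's domain
    b <- runif(3) * box2
    mi <- minimum_image_displacement(a, b, box2)
    expect_equal(mi, brute_min_image(a, b, box2), tolerance = 1e-12)
    expect_lte(sqrt(sum(mi^2)), sqrt(3) / 2 * max(box2) + 1e-12)
  }
})

test_that("XYZ parsing reads box, times and coordinates, and round-trips", {
  txt <- c("3",
           'Lattice="30 30 30" Time=0.0',
           "O 1.0 2.0 3.0", "H 1.5 2.0 3.0", "H 0.5 2.0 3.0",
           "3",
           'Lattice="30 30 30" Time=5.0',
           "O 1.1 2.1 3.1", "H 1.6 2.1 3.1", "H 0.6 2.1 3.1")
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(txt, f)
  tr <- read_trajectory(f)
  expect_equal(n_frames(tr), 2L)
  expect_equal(tr$box[1, ], c(30, 30, 30))
  expect_equal(tr$times, c(0, 5))
  expect_equal(tr$coords[2, 1, ], c(1.1, 2.1, 3.1))

  top <- water_topology(4)
  set.seed(3)
  co <- array(runif(2 * 12 * 3) * 20, c(2, 12, 3))
  orig <- trajectory(co, c(0, 5), c(20, 20, 20), wrapped = TRUE)
  f2 <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory(orig, f2, top)
  back <- read_trajectory(f2)
  expect_equal(back$coords, orig$coords, tolerance = 1e-6)
  expect_equal(back$times, orig$times)
  expect_equal(back$box, orig$box)
})

test_that("GRO coordinates convert nm to Angstrom and round-trip at printed precision", {
  top <- water_topology(1)
  gro <- c("one water, t= 0.0", "    3",
           "    1SOL    O    1   1.500   0.800   0.300",
           "    1SOL    H    2   1.550   0.850   0.300",
           "    1SOL    H    3   1.450   0.850   0.300",
           "   3.00000   3.00000   3.00000")
  f <- withr::local_tempfile(fileext = ".gro")
  writeLines(gro, f)
  tr <- read_trajectory(f)
  expect_equal(tr$coords[1, 1, ], c(15.0, 8.0, 3.0))
  expect_equal(tr$box[1, ], c(30, 30, 30))
  at <- attr(tr, "atoms")
  expect_equal(at$resname, rep("SOL", 3))

  f2 <- withr::local_tempfile(fileext = ".gro")
  write_trajectory(tr, f2, top)
  back <- read_trajectory(f2)
  expect_equal(back$coords, tr$coords, tolerance = 0.011)  # 0.001 nm grid
})

test_that("PDB round-trip preserves coordinates and CRYST1 box", {
  top <- water_topology(2)
  set.seed(7)
  co <- array(round(runif(2 * 6 * 3) * 25, 3), c(2, 6, 3))
  orig <- trajectory(co, c(0, 5), c(25, 25, 25), wrapped = TRUE)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(orig, f, top)
  back <- read_trajectory(f, dt = 5)
  expect_equal(n_frames(back), 2L)
  expect_equal(back$box[1, ], c(25, 25, 25))
  expect_equal(back$coords, orig$coords, tolerance = 1e-9)  # stored to 3 dp
  at <- attr(back, "atoms")
  expect_equal(at$mol_id, rep(1:2, each = 3))
})

test_that("malformed trajectory input fails loudly", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", "no box here", "O 1 2 3"), f)
  expect_error(read_trajectory(f), "frame 1.*Lattice")
  # atom count change
  writeLines(c("1", 'Lattice="10 10 10"', "O 1 2 3",
               "2", 'Lattice="10 10 10"', "O 1 2 3", "H 1 1 1"), f)
  expect_error(read_trajectory(f), "atom count changes at frame 2")
  # non-uniform times
  writeLines(c("1", 'Lattice="10 10 10" Time=0', "O 1 2 3",
               "1", 'Lattice="10 10 10" Time=1', "O 1 2 3",
               "1", 'Lattice="10 10 10" Time=3', "O 1 2 3"), f)
  expect_error(read_trajectory(f), "uniformly spaced")
  # triclinic rejection
  fp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("CRYST1   30.000   30.000   30.000  90.00  90.00  60.00 P 1",
               "MODEL        1",
               "ATOM      1  O   HOH A   1       1.000   2.000   3.000  1.00  0.00           O",
               "ENDMDL", "END"), fp)
  expect_error(read_trajectory(fp), "triclinic")
})

test_that("unwrap reconstructs continuous paths and wrap inverts it", {
  # single boundary crossing: 9.8 -> 0.3 in an L = 10 box is a +0.5 step
  co <- array(0, c(2, 1, 3))
  co[1, 1, ] <- c(9.8, 5, 5); co[2, 1, ] <- c(0.3, 5, 5)
  tr <- trajectory(co, c(0, 1), c(10, 10, 10), wrapped = TRUE)
  un <- unwrap(tr)
  expect_equal(un$coords[2, 1, 1], 10.3)
  expect_equal(wrap(un)$coords, tr$coords, tolerance = 1e-12)

  # unwrap(wrap(ground truth)) preserves all displacements, hence the MSD
  sp <- synth_spec("brownian", n_molecules = 5, n_frames = 40, dt = 5,
                   d_true = 1e-9, box = c(12, 12, 12), seed = 2)
  gw <- gen_walkers(sp)
  un2 <- unwrap(gw$wrapped)
  m1 <- compute_msd(un2, gw$topology, max_lag = 50)
  m2 <- compute_msd(gw$continuous, gw$topology, max_lag = 50)
  expect_equal(m1$msd_A2, m2$msd_A2, tolerance = 1e-10)

  # a step of exactly L/2 is ambiguous and warns
  co2 <- array(0, c(2, 1, 3))
  co2[1, 1, ] <- c(0, 5, 5); co2[2, 1, ] <- c(5, 5, 5)
  tr2 <- trajectory(co2, c(0, 1), c(10, 10, 10), wrapped = TRUE)
  expect_warning(unwrap(tr2), "ambiguous unwrap")
  expect_error(unwrap(gw$continuous), "wrapped")
})

test_that("species selections are disjoint and jointly exhaustive", {
  top <- topology(element = c("O", "H", "H", "C", "O", "Si"),
                  mol_id = c(1, 1, 1, 2, 2, 3),
                  species = c("water", "water", "water", "polymer", "polymer",
                              "filler"),
                  bonds = rbind(c(1, 2), c(1, 3), c(4, 5)),
                  donor_h = c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE),
                  acceptor = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE))
  w <- select_species(top, "water")
  p <- select_species(top, "polymer")
  f <- select_species(top, "filler")
  expect_equal(sort(c(w, p, f)), 1:6)
  expect_length(intersect(w, p), 0)
  top2 <- water_topology(3)
  expect_length(select_species(top2, "water"), 9)
  expect_warning(empty <- select_species(top2, "filler"), "empty")
  expect_length(empty, 0)
})

test_that("topology invariants are enforced and sidecars round-trip", {
  # donor hydrogen must have exactly one bonded heavy atom
  expect_error(
    topology(element = c("O", "H"), mol_id = c(1, 1),
             species = c("polymer", "polymer"),
             donor_h = c(FALSE, TRUE), acceptor = c(TRUE, FALSE)),
    "exactly one heavy atom")
  # water molecules must be O, H, H
  expect_error(
    topology(element = c("O", "H"), mol_id = c(1, 1),
             species = c("water", "water"), bonds = rbind(c(1, 2))),
    "O, H, H")
  expect_error(
    topology(element = "O", mol_id = 1, species = "water", mass = -1),
    "positive")

  top <- topology(element = c("O", "H", "H", "C", "O"),
                  mol_id = c(1, 1, 1, 2, 2),
                  species = c("water", "water", "water", "polymer", "polymer"),
                  bonds = rbind(c(1, 2), c(1, 3), c(4, 5)),
                  donor_h = c(FALSE, TRUE, TRUE, FALSE, FALSE),
                  acceptor = c(TRUE, FALSE, FALSE, FALSE, TRUE))
  for (ext in c(".json", ".csv")) {
    f <- withr::local_tempfile(fileext = ext)
    write_topology(top, f)
    back <- read_topology(f)
    expect_equal(back$atoms, top$atoms)
    expect_setequal(paste(pmin(back$bonds[, 1], back$bonds[, 2]),
                          pmax(back$bonds[, 1], back$bonds[, 2])),
                    paste(pmin(top$bonds[, 1], top$bonds[, 2]),
                          pmax(top$bonds[, 1], top$bonds[, 2])))
  }
})

test_that("residue-name topology builder tags water and fills bond roles", {
  at <- data.frame(element = c("O", "H", "H", "C", "C"),
                   mol_id = c(1, 1, 1, 2, 2),
                   resname = c("SOL", "SOL", "SOL", "UNK", "UNK"))
  top <- topology_from_residues(at$element, at$mol_id, at$resname)
  expect_equal(top$atoms$species, c(rep("water", 3), rep("polymer", 2)))
  expect_true(all(top$atoms$donor_h[2:3]))
  expect_true(top$atoms$acceptor[1])
  expect_equal(nrow(top$bonds), 2)
})
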