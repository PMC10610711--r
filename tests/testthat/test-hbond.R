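# Geometric hydrogen-bond detection, classification, Eq-style decomposition.

scene_bonds <- function(scene) {
  g <- gen_hbond_scene(scene)
  detect_hbonds(frame_coords(g$traj, 1), g$topology, g$traj$box[1, ])
}

test_that("criteria boundaries are strict for distance, inclusive for angles", {
  # all criteria comfortably satisfied
  expect_equal(nrow(scene_bonds(hbond_scene(2.7, 180, 120,
                                            acceptor_species = "polymer"))), 1)
  # exactly 2.8 A: rejected (strict less-than)
  expect_equal(nrow(scene_bonds(hbond_scene(2.8, 180, 180,
                                            acceptor_species = "polymer"))), 0)
  # donor angle 119: rejected; 120 exactly: accepted (inclusive)
  expect_equal(nrow(scene_bonds(hbond_scene(2.5, 119, 120,
                                            acceptor_species = "polymer"))), 0)
  expect_equal(nrow(scene_bonds(hbond_scene(2.5, 120, 120,
                                            acceptor_species = "polymer"))), 1)
  # acceptor angle 89: rejected; 90 exactly: accepted
  expect_equal(nrow(scene_bonds(hbond_scene(2.5, 180, 89,
                                            acceptor_species = "polymer"))), 0)
  expect_equal(nrow(scene_bonds(hbond_scene(2.5, 180, 90,
                                            acceptor_species = "polymer"))), 1)
})

test_that("detection matches the brute-force triple loop on random dense scenes", {
  crit <- hbond_criteria()
  for (s in 1:60) {
    n <- sample(5:20, 1)          # up to 60 atoms
    sc <- random_water_scene(n, box_l = runif(1, 9, 14), seed = 1000 + s)
    got <- detect_hbonds(sc$coords, sc$top, sc$box, crit)
    want <- brute_hbonds(sc$coords, sc$top, sc$box, crit)
    key <- function(d) sort(paste(d$donor, d$hydrogen, d$acceptor))
    expect_identical(key(got), key(want))
  }
})

test_that("classification splits counts by molecule species and stays additive", {
  # planted 2 ww + 1 pp + 3 pw
  sc <- hbond_scene(dist = c(2.0, 2.1, 2.2, 2.3, 2.4, 2.5),
                    donor_angle = 170, acceptor_angle = 120,
                    donor_species = c("water", "water", "polymer",
                                      "water", "water", "polymer"),
                    acceptor_species = c("water", "water", "polymer",
                                         "polymer", "polymer", "water"))
  g <- gen_hbond_scene(sc)
  hb <- detect_hbonds(frame_coords(g$traj, 1), g$topology, g$traj$box[1, ])
  cnt <- hbond_counts(hb, g$topology)
  expect_equal(cnt$n_ww, 2)
  expect_equal(cnt$n_pp, 1)
  expect_equal(cnt$n_pw, 3)
  expect_equal(cnt$n_total, 6)

  # a water-donor -> polymer-acceptor bond is class pw
  cls <- classify_hbonds(hb, g$topology)
  one <- cls[cls$donor == g$planted$donor[4], ]
  expect_equal(as.character(one$class), "pw")

  # filler counts as polymer
  scf <- hbond_scene(2.2, 170, 120, donor_species = "filler",
                     acceptor_species = "water")
  gf <- gen_hbond_scene(scf)
  hbf <- detect_hbonds(frame_coords(gf$traj, 1), gf$topology, gf$traj$box[1, ])
  expect_equal(hbond_counts(hbf, gf$topology)$n_pw, 1)

  # additivity on random scenes
  for (s in 1:10) {
    sc2 <- random_water_scene(12, box_l = 10, seed = 3000 + s)
    cnt2 <- hbond_counts(detect_hbonds(sc2$coords, sc2$top, sc2$box), sc2$top)
    expect_equal(cnt2$n_total, cnt2$n_ww + cnt2$n_pp + cnt2$n_pw)
  }
})

test_that("the polymer-water difference identity reproduces the published counts", {
  expect_equal(pw_by_difference(666, 251, 78), 337)
  expect_equal(pw_by_difference(0, 0, 0), 0)
  expect_equal(pw_by_difference(674, 257, 80), 337)
  expect_error(pw_by_difference(10, 8, 5), "inconsistent")
})

test_that("difference identity equals direct classification on every frame", {
  for (s in 1:8) {
    sc <- random_water_scene(14, box_l = 11, seed = 4000 + s)
    cnt <- hbond_counts(detect_hbonds(sc$coords, sc$top, sc$box), sc$top)
    expect_identical(pw_by_difference(cnt$n_total, cnt$n_pp, cnt$n_ww),
                     cnt$n_pw)
  }
})

test_that("loosening any one threshold never decreases the bond count", {
  sc <- random_water_scene(16, box_l = 10, seed = 77)
  base <- hbond_criteria()
  n_base <- nrow(detect_hbonds(sc$coords, sc$top, sc$box, base))
  looser <- list(hbond_criteria(max_ha = 3.2),
                 hbond_criteria(min_donor_angle = 100),
                 hbond_criteria(min_acceptor_angle = 70))
  for (cr in looser) {
    expect_gte(nrow(detect_hbonds(sc$coords, sc$top, sc$box, cr)), n_base)
  }
  tighter <- list(hbond_criteria(max_ha = 2.4),
                  hbond_criteria(min_donor_angle = 150),
                  hbond_criteria(min_acceptor_angle = 130))
  for (cr in tighter) {
    expect_lte(nrow(detect_hbonds(sc$coords, sc$top, sc$box, cr)), n_base)
  }
})

test_that("an ideal water dimer yields one bond, never a mirrored duplicate", {
  dm <- water_dimer(2.9)
  hb <- detect_hbonds(dm$coords, dm$top, dm$box)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$donor, 1)
  expect_equal(hb$acceptor, 4)
  expect_equal(as.character(classify_hbonds(hb, dm$top)$class), "ww")
})

test_that("hydrogen-bond profiles follow a planted schedule over frames", {
  # static scene repeated over frames: constant profile, sd 0
  dm <- water_dimer(2.9)
  nf <- 5
  co <- array(rep(dm$coords, each = nf), c(nf, 6, 3))
  tr <- trajectory(co, (0:(nf - 1)) * 5, dm$box, wrapped = TRUE)
  prof <- hbond_profile(tr, dm$top)
  expect_equal(prof$series$n_total, rep(1, nf))
  expect_equal(prof$summary$sd[prof$summary$class == "total"], 0)

  # two-frame scene: bond present only in frame 2
  far <- water_dimer(5.0)$coords
  co2 <- array(0, c(2, 6, 3))
  co2[1, , ] <- far
  co2[2, , ] <- dm$coords
  tr2 <- trajectory(co2, c(0, 5), dm$box, wrapped = TRUE)
  prof2 <- hbond_profile(tr2, dm$top)
  expect_equal(prof2$series$n_total, c(0, 1))
  expect_equal(prof2$summary$mean[prof2$summary$class == "total"], 0.5)

  # schedule toggled by frame: bond iff the dimer is compressed that frame
  sched <- c(1, 0, 1, 1, 0, 0, 1)
  co3 <- array(0, c(length(sched), 6, 3))
  for (f in seq_along(sched)) {
    co3[f, , ] <- if (sched[f] == 1) dm$coords else far
  }
  tr3 <- trajectory(co3, (seq_along(sched) - 1) * 5, dm$box, wrapped = TRUE)
  prof3 <- hbond_profile(tr3, dm$top)
  expect_equal(prof3$series$n_ww, sched)
  # stride skips frames deterministically
  prof4 <- hbond_profile(tr3, dm$top, stride = 2L)
  expect_equal(prof4$series$frame, c(1, 3, 5, 7))
  expect_equal(prof4$series$n_ww, sched[c(1, 3, 5, 7)])
})

test_that("a donor hydrogen with no bonded heavy atom is a topology defect", {
  top <- water_topology(1)
  top$bonds <- matrix(integer(0), 0, 2)  # corrupt after construction
  co <- matrix(c(0, 0, 0, 0.96, 0, 0, -0.24, 0.93, 0), 3, 3, byrow = TRUE) + 5
  expect_error(detect_hbonds(co, top, c(20, 20, 20)), "topology defect")
})
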