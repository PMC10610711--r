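# Single-linkage clustering under periodic boundaries and radii of gyration.

# Two-water scene at a prescribed O-O separation.
two_waters <- function(oo, box = c(30, 30, 30)) {
  top <- water_topology(2)
  th <- 104.52 * pi / 180
  w <- function(o) rbind(o,
                         o + 0.9572 * c(sin(th / 2), 0, cos(th / 2)),
                         o + 0.9572 * c(-sin(th / 2), 0, cos(th / 2)))
  coords <- rbind(w(c(5, 5, 5)), w(c(5 + oo, 5, 5)))
  list(coords = coords, top = top, box = box)
}

test_that("the linkage cutoff separates single links from singletons", {
  s <- two_waters(3.4)
  cs <- cluster_frame(s$coords, s$top, s$box, cutoff = 3.5)
  expect_equal(cs$sizes, 2L)
  s2 <- two_waters(3.6)
  cs2 <- cluster_frame(s2$coords, s2$top, s2$box, cutoff = 3.5)
  expect_equal(cs2$sizes, c(1L, 1L))
  # cutoff is inclusive: exactly at the cutoff still links
  s3 <- two_waters(3.5)
  expect_equal(cluster_frame(s3$coords, s3$top, s3$box, 3.5)$sizes, 2L)
})

test_that("planted boundary-spanning scenes are recovered exactly", {
  scene <- gen_cluster_scene(cluster_scene(c(19, 7, 3), cutoff = 3.5,
                                           min_gap = 7, span_boundary = TRUE,
                                           box = c(42, 42, 42), seed = 23))
  cs <- cluster_frame(frame_coords(scene$traj, 1), scene$topology,
                      scene$traj$box[1, ], cutoff = 3.5)
  expect_equal(cs$sizes, c(19L, 7L, 3L))
  expect_equal(length(cs$clusters), 3)
  for (k in 1:3) expect_equal(cs$clusters[[k]], sort(scene$partition[[k]]))
})

test_that("clustering equals brute-force all-pairs label propagation", {
  for (s in 1:6) {
    set.seed(500 + s)
    n <- sample(c(30, 80, 200), 1)
    box <- c(24, 24, 24)
    o <- matrix(runif(n * 3) * box[1], n, 3)
    top <- water_topology(n)
    th <- 104.52 * pi / 180
    coords <- matrix(0, 3 * n, 3)
    for (m in seq_len(n)) {
      coords[3 * m - 2, ] <- o[m, ]
      coords[3 * m - 1, ] <- o[m, ] + 0.9572 * c(sin(th / 2), 0, cos(th / 2))
      coords[3 * m, ] <- o[m, ] + 0.9572 * c(-sin(th / 2), 0, cos(th / 2))
    }
    cutoff <- runif(1, 2.5, 4.5)
    # dense scenes can percolate; the rg ambiguity warning is expected there
    cs <- suppressWarnings(cluster_frame(coords, top, box, cutoff))
    labels <- brute_clusters(o, box, cutoff)
    # same partition: membership vectors agree as sets
    got <- lapply(cs$clusters, sort)
    want <- lapply(split(seq_len(n), labels), sort)
    expect_setequal(vapply(got, paste, "", collapse = ","),
                    vapply(want, paste, "", collapse = ","))
  }
})

test_that("increasing the cutoff never increases the cluster count", {
  set.seed(9)
  n <- 60
  box <- c(20, 20, 20)
  o <- matrix(runif(n * 3) * box[1], n, 3)
  top <- water_topology(n)
  coords <- matrix(0, 3 * n, 3)
  for (m in seq_len(n)) {
    coords[3 * m - 2, ] <- o[m, ]
    coords[3 * m - 1, ] <- o[m, ] + c(0.96, 0, 0)
    coords[3 * m, ] <- o[m, ] + c(-0.24, 0.93, 0)
  }
  counts <- vapply(seq(2, 6, by = 0.5), function(cut)
    length(suppressWarnings(cluster_frame(coords, top, box, cut))$clusters),
    integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("radius of gyration has its closed forms and periodic invariance", {
  # single rigid water: rg from the fixed geometry, computed directly
  th <- 104.52 * pi / 180
  sites <- rbind(c(0, 0, 0),
                 0.9572 * c(sin(th / 2), 0, cos(th / 2)),
                 0.9572 * c(-sin(th / 2), 0, cos(th / 2)))
  m <- c(15.999, 1.008, 1.008)
  cm <- colSums(sites * m) / sum(m)
  rg_water <- sqrt(sum(m * rowSums(sweep(sites, 2, cm)^2)) / sum(m))
  s <- two_waters(9)  # far apart: singletons
  cs <- cluster_frame(s$coords, s$top, s$box, cutoff = 3.5)
  expect_equal(cs$rg, rep(rg_water, 2), tolerance = 1e-9)

  # two equal point masses d apart: rg = d/2
  top2 <- topology(element = c("O", "O"), mol_id = c(1, 2),
                   species = rep("polymer", 2), acceptor = c(FALSE, FALSE))
  d <- 4.2
  co2 <- rbind(c(10, 10, 10), c(10 + d, 10, 10))
  expect_equal(cluster_rg(c(1, 2), co2, top2, c(30, 30, 30), cutoff = 5),
               d / 2, tolerance = 1e-12)

  # boundary-spanning pair: same rg as the un-split equivalent
  co3 <- rbind(c(29, 10, 10), c(2, 10, 10))  # min-image distance 3 in L = 30
  rg_span <- cluster_rg(c(1, 2), co3, top2, c(30, 30, 30), cutoff = 3.5)
  co4 <- rbind(c(14, 10, 10), c(17, 10, 10))
  rg_mid <- cluster_rg(c(1, 2), co4, top2, c(30, 30, 30), cutoff = 3.5)
  expect_equal(rg_span, rg_mid, tolerance = 1e-12)
  expect_equal(rg_mid, 1.5, tolerance = 1e-12)
})

test_that("rigid translation modulo the box changes no sizes or rg", {
  scene <- gen_cluster_scene(cluster_scene(c(8, 4, 2), cutoff = 3.5,
                                           min_gap = 7.5, box = c(34, 34, 34),
                                           seed = 31))
  co <- frame_coords(scene$traj, 1)
  box <- scene$traj$box[1, ]
  cs0 <- cluster_frame(co, scene$topology, box, 3.5)
  set.seed(4)
  for (rep in 1:3) {
    shift <- runif(3) * box
    co2 <- co + rep(shift, each = nrow(co))
    co2 <- co2 - rep(box, each = nrow(co)) * floor(co2 / rep(box, each = nrow(co)))
    cs <- cluster_frame(co2, scene$topology, box, 3.5)
    expect_equal(cs$sizes, cs0$sizes)
    expect_equal(cs$rg, cs0$rg, tolerance = 1e-8)
  }
})

test_that("cluster series track planted schedules and run maxima", {
  # static scene over 10 frames: constant series, max = mean
  scene <- gen_cluster_scene(cluster_scene(c(11, 5, 2, 1), cutoff = 3.5,
                                           min_gap = 7.5, box = c(40, 40, 40),
                                           seed = 8))
  one <- frame_coords(scene$traj, 1)
  nf <- 10
  co <- array(rep(one, each = nf), c(nf, nrow(one), 3))
  tr <- trajectory(co, (0:(nf - 1)) * 5, scene$traj$box[1, ], wrapped = TRUE)
  cs <- cluster_series(tr, scene$topology, cutoff = 3.5)
  expect_equal(cs$series$largest_size, rep(11, nf))
  expect_equal(cs$summary$max_largest, 11)
  expect_equal(cs$summary$mean_largest, 11)
  expect_equal(cs$summary$sd_largest, 0)

  # two clusters merging at frame 2: largest size steps up
  s <- two_waters(6)
  merged <- two_waters(3.0)
  co2 <- array(0, c(2, 6, 3))
  co2[1, , ] <- s$coords
  co2[2, , ] <- merged$coords
  tr2 <- trajectory(co2, c(0, 5), s$box, wrapped = TRUE)
  cs2 <- cluster_series(tr2, s$top, cutoff = 3.5)
  expect_equal(cs2$series$largest_size, c(1, 2))
  expect_equal(cs2$series$n_clusters, c(2, 1))
})
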