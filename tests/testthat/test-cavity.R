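# Regular tetrahedron helper: 4 vertices with edge length `edge`.
regular_tetra <- function(edge) {
  rbind(c(0, 0, 0), c(edge, 0, 0), c(edge / 2, edge * sqrt(3) / 2, 0),
        c(edge / 2, edge * sqrt(3) / 6, edge * sqrt(2 / 3)))
}

test_that("alpha-sphere of a regular tetrahedron matches the closed form", {
  edge <- 8
  pts <- regular_tetra(edge)
  m <- toy_model(pts)
  sp <- detect_alpha_spheres(pts, m, r_min = 1, r_max = 10,
                             discard_hull = FALSE)
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$radius, edge * sqrt(3 / 8) - 1.7, tolerance = 1e-3)
  # sphere touches its 4 defining atoms: |centre - atom| = r_atom + r_alpha
  centre <- c(sp$x, sp$y, sp$z)
  d <- sqrt(rowSums(sweep(pts, 2, centre)^2))
  expect_equal(d, rep(1.7 + sp$radius, 4), tolerance = 1e-3)
})

test_that("dense clusters yield no void-sized spheres; degenerate input errors", {
  grid <- as.matrix(expand.grid(seq(0, 3, 1.5), seq(0, 3, 1.5), seq(0, 3, 1.5)))
  m <- toy_model(grid)
  sp <- detect_alpha_spheres(grid, m, r_min = 3, r_max = 6)
  expect_equal(nrow(sp), 0L)

  tri <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0), 3, 3, byrow = TRUE)
  expect_error(detect_alpha_spheres(tri, toy_model(tri)), "at least 4 atoms")
  plane <- cbind(as.matrix(expand.grid(0:3, 0:3)), 0)
  expect_error(detect_alpha_spheres(plane, toy_model(plane)), "coplanar")
})

test_that("our Delaunay tetrahedra all have empty circumspheres (oracle check)", {
  pts <- cetpdyn:::with_preserved_seed(13, matrix(stats::runif(3 * 40, 0, 10), 40, 3))
  tet <- cetpdyn:::.delaunay_tetrahedra(pts, jitter = 0)
  cs <- cetpdyn:::.circumspheres(pts, tet)
  for (k in seq_len(nrow(tet))) {
    d2 <- colSums((t(pts) - cs$center[k, ])^2)
    inside <- which(d2 < cs$r2[k] * (1 - 1e-9))
    expect_true(all(inside %in% tet[k, ]))
  }
  # and the tetrahedra tile the convex hull interior: test a few probes
  vol_sum <- sum(vapply(seq_len(nrow(tet)), function(k) {
    v <- pts[tet[k, ], ]
    abs(det(rbind(v[2, ] - v[1, ], v[3, ] - v[1, ], v[4, ] - v[1, ]))) / 6
  }, numeric(1)))
  expect_gt(vol_sum, 0)
})

test_that("Monte-Carlo union volume matches analytic spheres and is reproducible", {
  one <- data.frame(x = 0, y = 0, z = 0, radius = 3, i1 = 1L, i2 = 2L,
                    i3 = 3L, i4 = 4L)
  class(one) <- c("alpha_spheres", "data.frame")
  cs <- cluster_and_measure(one, min_volume = 10, min_spheres = 1L)
  expect_equal(cs$largest_volume, 4 / 3 * pi * 27, tolerance = 0.02)

  # identical inputs + seed -> identical volume (reproducibility contract)
  cs2 <- cluster_and_measure(one, min_volume = 10, min_spheres = 1L)
  expect_identical(cs$largest_volume, cs2$largest_volume)

  # two disjoint groups far apart: 2 pockets, fragmented, subadditivity
  two <- rbind(one, transform(one, x = 50))
  class(two) <- c("alpha_spheres", "data.frame")
  cs3 <- cluster_and_measure(two, min_volume = 10, min_spheres = 1L)
  expect_equal(nrow(cs3$pockets), 2L)
  expect_equal(cs3$continuity, "fragmented")
  expect_lte(sum(cs3$pockets$volume), 2 * (4 / 3 * pi * 27) * 1.05)

  # overlapping spheres: union strictly below the sum of parts
  olap <- rbind(one, transform(one, x = 2))
  class(olap) <- c("alpha_spheres", "data.frame")
  cs4 <- cluster_and_measure(olap, min_volume = 10, min_spheres = 1L)
  expect_equal(nrow(cs4$pockets), 1L)
  expect_lt(cs4$largest_volume, 0.95 * 2 * (4 / 3 * pi * 27))

  # empty input
  empty <- one[0, ]
  class(empty) <- c("alpha_spheres", "data.frame")
  cs5 <- cluster_and_measure(empty)
  expect_equal(cs5$continuity, "fragmented")
  expect_equal(cs5$largest_volume, 0)
})

test_that("Monte-Carlo error halves when samples quadruple", {
  one <- data.frame(x = 0, y = 0, z = 0, radius = 3, i1 = 1L, i2 = 2L,
                    i3 = 3L, i4 = 4L)
  class(one) <- c("alpha_spheres", "data.frame")
  est <- function(n, seeds) vapply(seeds, function(s)
    cluster_and_measure(one, min_volume = 10, min_spheres = 1L,
                        mc_samples = n, seed = s)$largest_volume, numeric(1))
  se1 <- stats::sd(est(2000, 1:12))
  se2 <- stats::sd(est(8000, 101:112))
  expect_lt(se2 / se1, 0.8)
})

test_that("cage voids are recovered within 15% of the rejection oracle", {
  cg <- make_cage_ensemble(n_shell = 480L, volume_schedule = c(1000, 1000),
                           seed = 5)
  r_void <- (3 * 1000 / (4 * pi))^(1 / 3)
  sp <- detect_alpha_spheres(cg$ensemble$frames[[1]], cg$ensemble$topology,
                             r_min = 2.0, r_max = r_void + 1.5)
  cs <- cluster_and_measure(sp, min_volume = 100, mc_samples = 5e4)
  expect_equal(cs$continuity, "continuous")
  expect_equal(cs$largest_volume, cg$truth$volume[1], tolerance = 0.15)
})

test_that("volumes and continuity are invariant under rigid transforms", {
  cg <- make_cage_ensemble(n_shell = 480L, volume_schedule = c(800, 800),
                           seed = 8)
  f <- cg$ensemble$frames[[1]]
  R <- random_rotation(17)
  g <- f %*% t(R) + 25
  r_void <- (3 * 800 / (4 * pi))^(1 / 3)
  vol <- function(x) {
    sp <- detect_alpha_spheres(x, cg$ensemble$topology, r_min = 2.0,
                               r_max = r_void + 1.5)
    cluster_and_measure(sp, min_volume = 100, mc_samples = 5e4)
  }
  a <- vol(f); b <- vol(g)
  expect_equal(a$continuity, b$continuity)
  expect_equal(a$largest_volume, b$largest_volume, tolerance = 0.05)
})

test_that("cavity series tracks dilation cubically and flags fragmentation", {
  # void dilated 10% in linear dimension: volume ratio ~ 1.331
  cg <- make_cage_ensemble(n_shell = 480L,
                           volume_schedule = c(1000, 1000 * 1.1^3, 1000, 500 * 2),
                           split_at = 4L, split_offset = 60, seed = 3)
  r_void_max <- (3 * 1331 / (4 * pi))^(1 / 3)
  s <- cavity_volume_series(cg$ensemble, r_min = 2.0, r_max = r_void_max + 1.5,
                            min_volume = 100, mc_samples = 5e4, seed = 2)
  expect_equal(s$values[2] / s$values[1], 1.331, tolerance = 0.08)
  expect_equal(attr(s, "continuity"),
               c("continuous", "continuous", "continuous", "fragmented"))
  # continuity flips exactly at the scripted fragmentation frame
  expect_equal(attr(s, "continuity"), cg$truth$continuity)
  # fragmented-frame largest pocket matches the oracle of the larger half
  expect_equal(s$values[4], cg$truth$volume[4], tolerance = 0.15)

  # static ensemble: constant series, zero rate
  cg0 <- make_cage_ensemble(n_shell = 480L, volume_schedule = c(900, 900),
                            seed = 4)
  s0 <- cavity_volume_series(cg0$ensemble, r_min = 2.0,
                             r_max = (3 * 900 / (4 * pi))^(1 / 3) + 1.5,
                             min_volume = 100, mc_samples = 5e4, seed = 2)
  expect_equal(attr(s0, "expansion_rate"), 0, tolerance = 0.05)
})
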