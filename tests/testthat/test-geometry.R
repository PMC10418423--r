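test_that("Kabsch superposition recovers exact fits and proper rotations", {
  X <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.3, 0.4, 1.2))
  fit <- superpose(X, X)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)

  fit_t <- superpose(sweep(X, 2, c(5, 0, 0), `+`), X)
  expect_equal(fit_t$rmsd, 0, tolerance = 1e-12)

  R <- random_rotation(31)
  Y <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  fit_r <- superpose(Y %*% t(R), Y)
  expect_lt(fit_r$rmsd, 1e-9)
  expect_equal(det(fit_r$rotation), 1, tolerance = 1e-9)

  expect_error(superpose(X[1:2, ], X[1:2, ]), "at least 3")
  L <- cbind(0:3, 0, 0)
  expect_error(superpose(L, L), "collinear")
})

test_that("superposed RMSD matches a brute-force rotational minimisation", {
  X <- cetpdyn:::with_preserved_seed(7, matrix(stats::rnorm(15, sd = 3), 5, 3))
  Y <- cetpdyn:::with_preserved_seed(8, X + matrix(stats::rnorm(15, sd = 0.5), 5, 3))
  ours <- superpose(Y, X)$rmsd
  # oracle: direct minimisation over Euler angles from multiple starts
  rot <- function(a) {
    cz <- cos(a[1]); sz <- sin(a[1]); cy <- cos(a[2]); sy <- sin(a[2])
    cx <- cos(a[3]); sx <- sin(a[3])
    matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE) %*%
      matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE) %*%
      matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  }
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  obj <- function(a) sqrt(mean(rowSums((Yc %*% t(rot(a)) - Xc)^2)))
  best <- min(vapply(1:20, function(k) {
    a0 <- cetpdyn:::with_preserved_seed(100 + k, stats::runif(3, -pi, pi))
    stats::optim(a0, obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))$value
  }, numeric(1)))
  expect_equal(ours, best, tolerance = 1e-5)
})

test_that("RMSD series is zero for static and rigidly rotated frames", {
  X <- cetpdyn:::with_preserved_seed(5, matrix(stats::rnorm(30, sd = 4), 10, 3))
  ens_static <- conf_ensemble(toy_model(X), list(X, X, X))
  expect_series_equal(rmsd_series(ens_static, selection = 1:10), rep(0, 3))

  R <- random_rotation(12)
  ens_rot <- conf_ensemble(toy_model(X), list(X, X %*% t(R) + 3))
  s <- rmsd_series(ens_rot, selection = 1:10)
  expect_lt(s$values[2], 1e-9)
  expect_error(rmsd_series(ens_static, selection = integer(0)), "empty")
})

test_that("RMSF recovers analytic fluctuation amplitudes", {
  # static ensemble: zero everywhere
  cube0 <- breathing_cube(c(0, 0, 0))
  expect_equal(unname(rmsf_per_residue(cube0, selection = 1:8)), rep(0, 8))

  # radial alternation +-d/2: RMSF = d/2 exactly
  d <- 0.8
  cube_alt <- breathing_cube(rep(c(d / 2, -d / 2), 10))
  expect_equal(unname(rmsf_per_residue(cube_alt, selection = 1:8)),
               rep(d / 2, 8), tolerance = 1e-8)

  # dense sinusoid of amplitude a: RMSF -> a/sqrt(2) within 1%
  a <- 0.5
  t <- seq(0, 2 * pi, length.out = 401)[-401]
  cube_sin <- breathing_cube(a * sin(t))
  expect_equal(unname(rmsf_per_residue(cube_sin, selection = 1:8)),
               rep(a / sqrt(2), 8), tolerance = 0.01)

  expect_error(rmsf_per_residue(breathing_cube(0), selection = 1:8),
               "at least 2 frames")
})

test_that("radius of gyration matches closed forms and scales linearly", {
  expect_equal(radius_of_gyration(matrix(c(3, 4, 5), 1, 3)), 0)
  two <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(radius_of_gyration(two), 1.0)
  cube <- as.matrix(expand.grid(c(0, 2), c(0, 2), c(0, 2)))
  expect_equal(radius_of_gyration(cube), sqrt(3))
  # scaling coordinates by k scales Rg by k
  expect_equal(radius_of_gyration(cube * 3.7), 3.7 * sqrt(3))
  expect_error(radius_of_gyration(cube, selection = integer(0)), "empty")
})

test_that("mass weighting shifts Rg toward the heavy atoms", {
  m <- toy_model(rbind(c(0, 0, 0), c(2, 0, 0)), element = c("C", "H"))
  rg_u <- radius_of_gyration(coords(m), m)
  rg_w <- radius_of_gyration(coords(m), m, mass_weighted = TRUE)
  expect_lt(rg_w, rg_u)
  # closed form: com at 2*mH/(mC+mH), Rg = sqrt(sum m d^2 / sum m)
  mC <- 12.011; mH <- 1.008
  com <- 2 * mH / (mC + mH)
  expect_equal(rg_w, sqrt((mC * com^2 + mH * (2 - com)^2) / (mC + mH)))
})

test_that("maximum inter-residue distance equals exhaustive enumeration", {
  # two single-atom residues 5 A apart
  m <- toy_model(rbind(c(0, 0, 0), c(5, 0, 0)), resid = c(1, 2))
  expect_equal(as.numeric(max_residue_pair_distance(coords(m), m, 1, 2)), 5)

  # 100 seeded random residue pairs vs brute force
  for (k in 1:100) {
    na <- 3 + k %% 5; nb <- 4 + k %% 4
    xyz <- cetpdyn:::with_preserved_seed(k, matrix(stats::rnorm(3 * (na + nb), sd = 6),
                                                   na + nb, 3))
    m2 <- toy_model(xyz, resid = rep(c(1, 2), c(na, nb)))
    got <- as.numeric(max_residue_pair_distance(xyz, m2, 1, 2))
    brute <- 0
    for (i in seq_len(na)) for (j in (na + 1):(na + nb))
      brute <- max(brute, sqrt(sum((xyz[i, ] - xyz[j, ])^2)))
    expect_equal(got, brute, tolerance = 1e-12)
  }
  expect_error(max_residue_pair_distance(coords(m), m, 1, 1), "must differ")
  expect_error(max_residue_pair_distance(coords(m), m, 1, 9), "absent")
})

test_that("heavy-atom scope excludes hydrogens from gate distances", {
  xyz <- rbind(c(0, 0, 0), c(0, 0, 3), c(10, 0, 0), c(14, 0, 0))
  m <- toy_model(xyz, element = c("C", "H", "C", "H"), resid = c(1, 1, 2, 2))
  all_scope <- as.numeric(max_residue_pair_distance(xyz, m, 1, 2, "all"))
  heavy <- as.numeric(max_residue_pair_distance(xyz, m, 1, 2, "heavy"))
  expect_equal(heavy, 10)
  expect_gt(all_scope, heavy)
})

test_that("gate-open flags are a pure threshold at 10 A", {
  s <- descriptor_series("d", 0:4, c(8, 9.99, 10, 12, 10.0001), "A")
  expect_equal(gate_open_flags(s), c(FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(gate_open_flags(s, threshold = 12), c(FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_error(gate_open_flags(s, threshold = -1), "positive")
})

test_that("orientation angle matches the arccos formula and edge cases", {
  m <- toy_model(rbind(c(-1, 0, 0), c(0, 0, 0), c(2, 0, 0)),
                 name = c("CZ", "CA", "CA"), resid = c(265, 265, 260))
  ang <- sidechain_orientation_angle(coords(m), m)
  expect_equal(ang, 180)

  m90 <- toy_model(rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)),
                   name = c("CZ", "CA", "CA"), resid = c(265, 265, 260))
  expect_equal(sidechain_orientation_angle(coords(m90), m90), 90)

  xyz <- cetpdyn:::with_preserved_seed(3, matrix(stats::rnorm(9, sd = 2), 3, 3))
  mr <- toy_model(xyz, name = c("CZ", "CA", "CA"), resid = c(265, 265, 260))
  u <- xyz[1, ] - xyz[2, ]; v <- xyz[3, ] - xyz[2, ]
  ref <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  expect_equal(sidechain_orientation_angle(coords(mr), mr), ref, tolerance = 1e-10)

  mc <- toy_model(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
                  name = c("CZ", "CA", "CA"), resid = c(265, 265, 260))
  expect_error(sidechain_orientation_angle(coords(mc), mc), "coincide")
})

test_that("domain bend angles recover rod geometries and hinge truth", {
  rod <- function(dir, resid_start) {
    t(vapply(1:12, function(i) dir * (3 + 2.5 * i) +
               0.4 * c(cos(2 * i), sin(2 * i), 0.3 * sin(3 * i)), numeric(3)))
  }
  mk <- function(dirB) {
    xyzA <- rod(c(1, 0, 0)); xyzB <- rod(dirB)
    hinge <- rbind(c(0, 0, 1), c(0.4, 0.3, -0.7), c(-0.3, 0.4, 0))
    xyz <- rbind(xyzA, hinge, xyzB)
    m <- toy_model(xyz, resid = c(1:12, 13:15, 16:27))
    rs <- region_set(list(`N-domain` = c(1, 12), HelixX = c(13, 15),
                          `C-domain` = c(16, 27)))
    domain_bend_angles(xyz, m, rs)
  }
  expect_equal(unname(mk(c(-1, 0, 0))["overall"]), 180, tolerance = 2)
  expect_equal(unname(mk(c(0, 1, 0))["overall"]), 90, tolerance = 2)

  hb <- make_hinge_ensemble(bend_schedule = rep(150, 3), sigma = 0.05, seed = 1)
  ba <- bend_angle_series(hb$ensemble, hb$regions)
  expect_equal(ba$overall, rep(150, 3), tolerance = 2)

  # isotropic domain -> axis undefined
  iso <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  miso <- toy_model(rbind(iso, iso + 10, iso - 10),
                    resid = rep(1:3, each = 8))
  rs3 <- region_set(list(`N-domain` = c(1, 1), HelixX = c(2, 2),
                         `C-domain` = c(3, 3)))
  expect_error(domain_bend_angles(coords(miso), miso, rs3), "axis undefined")
})

test_that("descriptors are invariant under global rigid transforms", {
  hb <- make_hinge_ensemble(bend_schedule = seq(150, 140, length.out = 3),
                            gate_schedule = c(12, 13, 14), sigma = 0.05, seed = 6)
  ens <- hb$ensemble
  R <- random_rotation(44)
  moved <- ens
  moved$frames <- lapply(ens$frames, function(f) f %*% t(R) + 7)
  moved$topology$atoms[, c("x", "y", "z")] <- moved$frames[[1]]

  g1 <- gate_distance_series(ens, hb$truth$gate_resids[1], hb$truth$gate_resids[2])
  g2 <- gate_distance_series(moved, hb$truth$gate_resids[1], hb$truth$gate_resids[2])
  expect_equal(g1$values, g2$values, tolerance = 1e-9)
  expect_equal(rg_series(ens)$values, rg_series(moved)$values, tolerance = 1e-9)
  b1 <- domain_bend_angles(ens$frames[[1]], ens$topology, hb$regions)
  b2 <- domain_bend_angles(moved$frames[[1]], moved$topology, hb$regions)
  expect_equal(b1, b2, tolerance = 1e-6)
})
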