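test_that("Coulomb energy matches closed forms and the pairwise oracle", {
  p <- energy_params()
  expect_equal(coulomb_energy(rbind(c(0, 0, 0), c(10, 0, 0)), c(1, 1), p),
               33.206, tolerance = 1e-9)
  xyz <- cetpdyn:::with_preserved_seed(1, matrix(stats::rnorm(15, sd = 4), 5, 3))
  expect_equal(coulomb_energy(xyz, rep(0, 5), p), 0)
  q <- cetpdyn:::with_preserved_seed(2, stats::runif(5, -1, 1))
  oracle <- 0
  for (i in 1:4) for (j in (i + 1):5)
    oracle <- oracle + 332.06 * q[i] * q[j] / sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  expect_equal(coulomb_energy(xyz, q, p), oracle, tolerance = 1e-10)
  expect_error(coulomb_energy(rbind(c(0, 0, 0), c(0, 0, 0)), c(1, 1), p),
               "singularity")
})

test_that("Lennard-Jones energy has its root at sigma and minimum at -eps", {
  s <- 3.4; e <- 0.25
  expect_equal(lj_energy(rbind(c(0, 0, 0), c(s, 0, 0)), c(s, s), c(e, e)), 0,
               tolerance = 1e-12)
  expect_equal(lj_energy(rbind(c(0, 0, 0), c(2^(1 / 6) * s, 0, 0)),
                         c(s, s), c(e, e)), -e, tolerance = 1e-12)
  # seeded 4-atom cluster vs brute force with Lorentz-Berthelot combining
  xyz <- cetpdyn:::with_preserved_seed(3, matrix(stats::rnorm(12, sd = 3), 4, 3) * 2)
  sig <- c(3.0, 3.4, 3.8, 3.2); eps <- c(0.1, 0.2, 0.15, 0.12)
  oracle <- 0
  for (i in 1:3) for (j in (i + 1):4) {
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    sij <- (sig[i] + sig[j]) / 2; eij <- sqrt(eps[i] * eps[j])
    oracle <- oracle + 4 * eij * ((sij / r)^12 - (sij / r)^6)
  }
  expect_equal(lj_energy(xyz, sig, eps), oracle, tolerance = 1e-10)
})

test_that("GB energy reproduces the Born ion and its asymptotic additivity", {
  p <- energy_params()
  born <- function(q, R) -0.5 * 332.06 * (1 - 1 / 78.5) * q^2 / R
  got <- gb_polar_energy(matrix(0, 1, 3), charges = 1, radii = 2, params = p)
  expect_equal(got, born(1, 2), tolerance = 0.001 * abs(born(1, 2)))
  # uncharged system
  xyz <- cetpdyn:::with_preserved_seed(4, matrix(stats::rnorm(9, sd = 3), 3, 3))
  expect_equal(gb_polar_energy(xyz, rep(0, 3), rep(1.5, 3), p), 0)
  # widely separated ions approach the sum of isolated Born energies
  iso <- 2 * born(1, 2)
  dev <- function(d) abs(gb_polar_energy(rbind(c(0, 0, 0), c(d, 0, 0)),
                                         c(1, -1), c(2, 2), p) - iso) / abs(iso)
  expect_lt(dev(5000), 0.001)
  expect_lt(dev(500), dev(50))
  # GB energy is non-positive for any single-charge system
  expect_lte(gb_polar_energy(matrix(0, 1, 3), 0.3, 1.2, p), 0)
  # vanishes as the solvent dielectric approaches the interior one
  p_eq <- energy_params(eps_solvent = 1 + 1e-9)
  expect_equal(gb_polar_energy(matrix(0, 1, 3), 1, 2, p_eq), 0,
               tolerance = 1e-6)
  expect_error(gb_polar_energy(matrix(0, 1, 3), 1, -1, p), "positive")
})

test_that("nonpolar term is linear in SASA", {
  p <- energy_params()
  expect_equal(nonpolar_energy(0, p), 0)
  expect_equal(nonpolar_energy(1000, p), 7.2)
  expect_equal(nonpolar_energy(2000, p), 2 * nonpolar_energy(1000, p))
  expect_error(nonpolar_energy(-1, p), "non-negative")
})

test_that("energies are invariant under rigid transforms and relabeling", {
  xyz <- cetpdyn:::with_preserved_seed(5, matrix(stats::rnorm(15, sd = 4), 5, 3))
  q <- c(0.3, -0.2, 0.5, -0.4, 0.1)
  sig <- rep(3.2, 5); eps <- rep(0.15, 5); rad <- rep(1.8, 5)
  p <- energy_params()
  R <- random_rotation(6)
  moved <- xyz %*% t(R) + 13
  expect_equal(coulomb_energy(xyz, q, p), coulomb_energy(moved, q, p),
               tolerance = 1e-9)
  expect_equal(lj_energy(xyz, sig, eps), lj_energy(moved, sig, eps),
               tolerance = 1e-9)
  expect_equal(gb_polar_energy(xyz, q, rad, p), gb_polar_energy(moved, q, rad, p),
               tolerance = 1e-9)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(coulomb_energy(xyz[perm, ], q[perm], p), coulomb_energy(xyz, q, p),
               tolerance = 1e-12)
  expect_equal(lj_energy(xyz[perm, ], sig[perm], eps[perm]),
               lj_energy(xyz, sig, eps), tolerance = 1e-12)
})

test_that("snapshot rule draws evenly from the trailing half", {
  idx <- snapshot_indices(100, n = 10)
  expect_true(all(idx > 50))
  expect_equal(length(idx), 10)
  expect_equal(snapshot_indices(6, n = 500), 4:6)
})

test_that("MM/GBSA vanishes without contacts and matches the per-frame oracle", {
  far <- make_toy_binding_system(separations = c(500, 500), seed = 1)
  g_far <- mmgbsa(far$ensemble, far$receptor, far$ligand, far$lj,
                  snapshots = 1:2)
  expect_lt(abs(g_far$G_bind), 0.05)

  fx <- make_toy_binding_system(separations = c(4, 5, 6, 8), seed = 1)
  g <- mmgbsa(fx$ensemble, fx$receptor, fx$ligand, fx$lj, snapshots = 1:4)
  # Eq-1 additivity: reported binding energy equals the component sum
  expect_equal(g$G_bind, g$E_ele + g$E_vdw + g$G_GB + g$G_sur,
               tolerance = 1e-9)

  p <- energy_params()
  at <- fx$ensemble$topology$atoms
  state <- function(f, idx) {
    mdl <- fx$ensemble$topology
    mdl$atoms <- mdl$atoms[idx, , drop = FALSE]
    sasa <- shrake_rupley_sasa(f[idx, , drop = FALSE], mdl)
    coulomb_energy(f[idx, , drop = FALSE], at$charge[idx], p) +
      lj_energy(f[idx, , drop = FALSE], fx$lj$sigma[idx], fx$lj$epsilon[idx]) +
      gb_polar_energy(f[idx, , drop = FALSE], at$charge[idx], at$radius[idx], p) +
      nonpolar_energy(sum(sasa$per_atom), p)
  }
  oracle <- vapply(fx$ensemble$frames, function(f)
    state(f, 1:4) - state(f, 1:3) - state(f, 4), numeric(1))
  expect_equal(g$per_frame$G_bind, oracle, tolerance = 1e-6)
  expect_equal(g$G_bind, mean(oracle), tolerance = 1e-6)

  # binding weakens monotonically beyond contact range
  expect_true(all(diff(abs(oracle)) < 0))

  expect_error(mmgbsa(fx$ensemble, 1:3, 3:4, fx$lj), "overlap")
  expect_error(mmgbsa(fx$ensemble, 1:2, 4, fx$lj), "cover all atoms")
})

test_that("component tables are audited against their stated totals", {
  nt <- read_gbsa_table(system.file("extdata", "cetp_ligand_gbsa_nterm.tsv",
                                    package = "cetpdyn"))
  ct <- read_gbsa_table(system.file("extdata", "cetp_ligand_gbsa_cterm.tsv",
                                    package = "cetpdyn"))
  rn <- check_gbsa_table(nt)
  rc <- check_gbsa_table(ct)
  # the two rescoring anchors sum exactly to their printed totals
  expect_equal(rn$component_sum[rn$id == "ZINC000006242926"], -32.6)
  expect_true(rn$pass[rn$id == "ZINC000006242926"])
  expect_equal(rc$component_sum[rc$id == "ZINC000005871812"], -45.3)
  expect_true(rc$pass[rc$id == "ZINC000005871812"])

  # a fabricated row off by 1 kcal/mol fails
  bad <- nt[1, ]
  bad$G_bind <- bad$G_bind + 1
  expect_false(check_gbsa_table(bad)$pass)
  expect_error(check_gbsa_table(data.frame(x = 1)), "malformed")
})
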