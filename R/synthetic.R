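# ---- synthetic conformational ensembles with known ground truth --------
#
# These generators emulate the statistical/geometric structure the
# analysis modules assume -- two rigid domains joined by a flexible neck,
# prescribed opening schedules, region-wise flexibility contrasts, interior
# cavities that fragment, block-correlated motions, and toy charge systems
# -- and emit the ground truth for every quantity the analysis estimates.
# They are pure functions of their arguments and seed.

# Backbone template for one pseudo-residue: 4 atoms with standard names,
# laid out along `axis` at `base` with a perpendicular offset so residues
# are never collinear (superposition and PCA need full-rank geometry).
.residue_atoms_template <- function(base, axis, perp1, perp2, phase) {
  off <- 0.8 * (cos(phase) * perp1 + sin(phase) * perp2)
  rbind(N  = base - 1.0 * axis + off,
        CA = base + off,
        C  = base + 1.0 * axis + off,
        O  = base + 1.2 * axis + 0.6 * perp1 + off)
}

.unit_perp <- function(u) {
  v <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p1 <- v - sum(v * u) * u
  p1 <- p1 / sqrt(sum(p1^2))
  p2 <- c(u[2] * p1[3] - u[3] * p1[2],
          u[3] * p1[1] - u[1] * p1[3],
          u[1] * p1[2] - u[2] * p1[1])
  list(p1, p2)
}

.build_arm <- function(direction, n_res, resid_start, chain = "A") {
  pp <- .unit_perp(direction)
  atoms <- NULL; xyz <- NULL
  for (i in seq_len(n_res)) {
    base <- direction * (4 + 3.8 * (i - 1))
    blk <- .residue_atoms_template(base, direction, pp[[1]], pp[[2]],
                                   phase = 100 * pi / 180 * i)
    xyz <- rbind(xyz, blk)
    atoms <- rbind(atoms, data.frame(
      name = c("N", "CA", "C", "O"),
      element = c("N", "C", "C", "O"),
      resid = resid_start + i - 1L, stringsAsFactors = FALSE))
  }
  list(atoms = atoms, xyz = xyz)
}

#' Generate a two-domain hinge ensemble with known ground truth
#'
#' Two rigid pseudo-domain arms joined at a flexible neck.  The inter-arm
#' bend angle follows `bend_schedule` (degrees per frame); two dedicated
#' single-atom gate residues follow `gate_schedule` (their distance in
#' Angstrom per frame); per-residue isotropic Gaussian noise emulates
#' thermal fluctuation, with per-region amplitudes derived from
#' `rmsf_targets` (RMSF target T maps to sigma = T/sqrt(3), since for iid
#' 3-D Gaussian displacement RMSF = sigma*sqrt(3)).
#'
#' @param n_res residues per arm (default 20)
#' @param n_hinge neck residues (default 4)
#' @param bend_schedule degrees per frame (length = n_frames)
#' @param gate_schedule optional Angstrom per frame (same length);
#'   when given, two extra one-atom gate residues are appended
#' @param sigma baseline noise sigma per coordinate (Angstrom)
#' @param rmsf_targets optional named vector of RMSF targets (Angstrom)
#'   over the generated regions ("N-domain", "C-domain", "HelixX")
#' @param seed RNG seed (mandatory)
#' @return list with `ensemble` (a `conf_ensemble`), `regions`
#'   (a `region_set`: N-domain, C-domain, HelixX, gates), `truth` (list:
#'   per-frame `bend_angle`, `gate_distance`, per-residue `sigma`,
#'   `gate_resids`)
#' @export
make_hinge_ensemble <- function(n_res = 20L, n_hinge = 4L, bend_schedule,
                                gate_schedule = NULL, sigma = 0.1,
                                rmsf_targets = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (length(bend_schedule) == 0L) stop("empty bend schedule")
  if (!is.null(gate_schedule) && length(gate_schedule) != length(bend_schedule))
    stop("gate schedule length must match bend schedule")
  if (sigma < 0) stop("sigma must be non-negative")
  n_frames <- length(bend_schedule)

  # static arm A along +x; hinge residues near the origin
  armA <- .build_arm(c(1, 0, 0), n_res, resid_start = 1L)
  hinge_xyz <- NULL; hinge_atoms <- NULL
  for (i in seq_len(n_hinge)) {
    base <- c(0.6 * cos(2.4 * i), 0.6 * sin(2.4 * i),
              1.5 * (i - (n_hinge + 1) / 2))
    hinge_xyz <- rbind(hinge_xyz, rbind(CA = base, CB = base + c(0.9, 0.4, 0)))
    hinge_atoms <- rbind(hinge_atoms, data.frame(
      name = c("CA", "CB"), element = c("C", "C"),
      resid = n_res + i, stringsAsFactors = FALSE))
  }
  armB_ids <- (n_res + n_hinge + 1L):(2L * n_res + n_hinge)
  gate_resids <- c(2L * n_res + n_hinge + 1L, 2L * n_res + n_hinge + 2L)

  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    th <- bend_schedule[f] * pi / 180
    armB <- .build_arm(c(cos(th), sin(th), 0), n_res,
                       resid_start = armB_ids[1])
    xyz <- rbind(armA$xyz, hinge_xyz, armB$xyz)
    if (!is.null(gate_schedule)) {
      d <- gate_schedule[f]
      xyz <- rbind(xyz, c(0, d / 2, 6), c(0, -d / 2, 6))
    }
    frames[[f]] <- unname(as.matrix(xyz))
  }
  atoms <- rbind(armA$atoms, hinge_atoms,
                 .build_arm(c(1, 0, 0), n_res, resid_start = armB_ids[1])$atoms)
  if (!is.null(gate_schedule))
    atoms <- rbind(atoms, data.frame(name = c("CA", "CA"),
                                     element = c("C", "C"),
                                     resid = gate_resids,
                                     stringsAsFactors = FALSE))
  n_at <- nrow(atoms)
  topo <- structure_model(data.frame(
    serial = seq_len(n_at), name = atoms$name, altloc = " ",
    resname = "GLY", resid = atoms$resid, chain = "A",
    x = frames[[1]][, 1], y = frames[[1]][, 2], z = frames[[1]][, 3],
    element = atoms$element, hetero = FALSE, stringsAsFactors = FALSE))

  regions <- region_set(list(
    `N-domain` = c(1L, n_res),
    HelixX = c(n_res + 1L, n_res + n_hinge),
    `C-domain` = c(armB_ids[1], armB_ids[length(armB_ids)]),
    gates = c(gate_resids[1], gate_resids[2])))

  # per-residue sigma: baseline, overridden by region RMSF targets
  res_ids <- sort(unique(atoms$resid))
  sig_res <- stats::setNames(rep(sigma, length(res_ids)), res_ids)
  if (!is.null(rmsf_targets)) {
    for (nm in names(rmsf_targets)) {
      rng <- regions[[nm]]
      for (r in seq_len(nrow(rng))) {
        hit <- res_ids >= rng[r, 1] & res_ids <= rng[r, 2]
        sig_res[hit] <- rmsf_targets[[nm]] / sqrt(3)
      }
    }
  }
  atom_sigma <- sig_res[as.character(atoms$resid)]

  frames <- with_preserved_seed(seed, lapply(frames, function(xyz) {
    xyz + matrix(stats::rnorm(length(xyz), 0, rep(atom_sigma, 3)),
                 nrow(xyz), 3)
  }))

  truth <- list(bend_angle = bend_schedule,
                gate_distance = gate_schedule,
                sigma = sig_res,
                gate_resids = if (!is.null(gate_schedule)) gate_resids else NULL)
  list(ensemble = conf_ensemble(topo, frames), regions = regions, truth = truth)
}

# ---- cavity cage --------------------------------------------------------

.fib_shell <- function(n, radius, centre = c(0, 0, 0)) {
  sweep(.sphere_points(n) * radius, 2, centre, `+`)
}

# Two-layer jittered shell enclosing a spherical void of radius r_void.
# The inner-layer radius is corrected for lattice discreteness: probe
# points can sit slightly "between" shell atoms before getting within
# atom_radius of one, which would inflate the delivered void by
# delta = atom_radius - sqrt(atom_radius^2 - g^2) (g = half the lattice
# spacing); the layer is pulled inward by that amount.
.build_cage <- function(n_shell, r_void, atom_radius, centre, seed) {
  n1 <- ceiling(0.6 * n_shell); n2 <- n_shell - n1
  r1 <- r_void + atom_radius
  g <- 0.5 * sqrt(4 * pi * r1^2 / n1)
  delta <- if (g < atom_radius) atom_radius - sqrt(atom_radius^2 - g^2) else 0.3
  # jitter makes some atoms poke into the void; the void boundary follows
  # the innermost atoms, so push the layer out by the mean inward excursion
  r1 <- r1 - delta + 0.125
  r2 <- r1 + 1.8
  with_preserved_seed(seed, {
    s1 <- .fib_shell(n1, r1, centre)
    s2 <- .fib_shell(n2, r2, centre)
    # small tangential/radial jitter breaks cosphericity
    rbind(s1, s2) + matrix(stats::runif(3 * n_shell, -0.25, 0.25), n_shell, 3)
  })
}

#' Rejection-sampling oracle for a cage's interior void volume
#'
#' Samples points uniformly in a sphere of radius `r_enclose` around
#' `centre` and counts those farther than `atom_radius` from every shell
#' atom.  Independent of the alpha-sphere machinery; used as ground truth.
#'
#' @param xyz shell atom coordinates (n x 3)
#' @param centre void centre
#' @param r_enclose enclosing-sphere radius (just inside the shell layer)
#' @param atom_radius Angstrom
#' @param n_samples sample count
#' @param seed RNG seed
#' @return volume in Angstrom^3
#' @export
cage_void_volume_oracle <- function(xyz, centre, r_enclose, atom_radius = 1.7,
                                    n_samples = 2e5, seed = 7L) {
  with_preserved_seed(seed, {
    u <- matrix(stats::rnorm(3 * n_samples), n_samples, 3)
    u <- u / sqrt(rowSums(u^2))
    r <- r_enclose * stats::runif(n_samples)^(1 / 3)
    pts <- sweep(u * r, 2, centre, `+`)
    free <- rep(TRUE, n_samples)
    for (k in seq_len(nrow(xyz))) {
      d2 <- (pts[, 1] - xyz[k, 1])^2 + (pts[, 2] - xyz[k, 2])^2 +
        (pts[, 3] - xyz[k, 3])^2
      free <- free & d2 > atom_radius^2
    }
    4 / 3 * pi * r_enclose^3 * sum(free) / n_samples
  })
}

#' Generate a cavity-cage ensemble that fragments on schedule
#'
#' Frames 1..(split_at-1) hold a single closed shell cage whose interior
#' void follows `volume_schedule` (Angstrom^3); from frame `split_at` on,
#' the shell atoms regroup into two smaller cages (half the scheduled
#' volume each) separated by `split_offset`, emulating a continuous
#' tunnel breaking into fragmented cavities.  True void volumes come from
#' the seeded rejection-sampling oracle.
#'
#' @param n_shell shell atom count (default 560; even)
#' @param volume_schedule target void volume per frame (Angstrom^3)
#' @param split_at first fragmented frame index (Inf = never)
#' @param split_offset centre-to-centre separation of the sub-cages (A)
#' @param atom_radius Angstrom (default 1.7, carbon)
#' @param probe_radius used only for the shell-closure check (default 1.4)
#' @param seed RNG seed (mandatory)
#' @return list with `ensemble` (typed topology), `truth` (list:
#'   per-frame `volume` from the oracle, `continuity`, `centres`)
#' @export
make_cage_ensemble <- function(n_shell = 560L, volume_schedule,
                               split_at = Inf, split_offset = 60,
                               atom_radius = 1.7, probe_radius = 1.4, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (length(volume_schedule) == 0L) stop("empty volume schedule")
  n_frames <- length(volume_schedule)
  n_half <- floor(n_shell / 2)
  frames <- vector("list", n_frames)
  vol_truth <- numeric(n_frames)
  cont_truth <- character(n_frames)
  centres <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    V <- volume_schedule[f]
    if (f < split_at) {
      r_void <- (3 * V / (4 * pi))^(1 / 3)
      xyz <- .build_cage(n_shell, r_void, atom_radius, c(0, 0, 0), seed + f)
      .check_shell_closed(xyz, atom_radius, probe_radius)
      vol_truth[f] <- cage_void_volume_oracle(xyz, c(0, 0, 0),
                                              r_void + atom_radius * 0.8,
                                              atom_radius, seed = seed + 100 + f)
      cont_truth[f] <- "continuous"
      centres[[f]] <- matrix(0, 1, 3)
    } else {
      r_void <- (3 * (V / 2) / (4 * pi))^(1 / 3)
      cA <- c(-split_offset / 2, 0, 0); cB <- c(split_offset / 2, 0, 0)
      xyzA <- .build_cage(n_half, r_void, atom_radius, cA, seed + f)
      xyzB <- .build_cage(n_shell - n_half, r_void, atom_radius, cB, seed - f)
      xyz <- rbind(xyzA, xyzB)
      .check_shell_closed(xyzA, atom_radius, probe_radius)
      .check_shell_closed(xyzB, atom_radius, probe_radius)
      vA <- cage_void_volume_oracle(xyzA, cA, r_void + atom_radius * 0.8,
                                    atom_radius, seed = seed + 200 + f)
      vB <- cage_void_volume_oracle(xyzB, cB, r_void + atom_radius * 0.8,
                                    atom_radius, seed = seed + 300 + f)
      vol_truth[f] <- max(vA, vB)
      cont_truth[f] <- "fragmented"
      centres[[f]] <- rbind(cA, cB)
    }
    frames[[f]] <- xyz
  }
  topo <- structure_model(data.frame(
    serial = seq_len(n_shell), name = "CA", altloc = " ",
    resname = "CAG", resid = seq_len(n_shell), chain = "A",
    x = frames[[1]][, 1], y = frames[[1]][, 2], z = frames[[1]][, 3],
    element = "C", hetero = FALSE, stringsAsFactors = FALSE))
  topo <- assign_atom_types(topo)
  topo$atoms$radius <- atom_radius
  list(ensemble = conf_ensemble(topo, frames),
       truth = list(volume = vol_truth, continuity = cont_truth,
                    centres = centres))
}

.check_shell_closed <- function(xyz, atom_radius, probe_radius) {
  d <- as.matrix(stats::dist(xyz))
  diag(d) <- Inf
  gap <- apply(d, 1, min) - 2 * atom_radius
  if (max(gap) >= 2 * probe_radius)
    stop(sprintf("generator error: shell not closed (max surface gap %.2f A >= %.2f A)",
                 max(gap), 2 * probe_radius))
  invisible(TRUE)
}

# ---- block-correlated motion --------------------------------------------

#' Generate block-correlated/anti-correlated motions
#'
#' Atoms are partitioned into blocks; all blocks share one latent scalar
#' factor per frame, and each block moves along a common direction with a
#' prescribed sign, plus small independent noise.  The inter-block DCCM
#' sign structure equals `sign_matrix` by construction.
#'
#' @param n_atoms total atoms
#' @param blocks list of integer index vectors partitioning 1..n_atoms
#' @param sign_matrix square matrix over blocks with entries +-1;
#'   must be consistent (rank-one, +1 diagonal)
#' @param n_frames frame count
#' @param amplitude latent-motion amplitude (A, default 0.5)
#' @param noise independent noise sigma (A, default 0.1)
#' @param seed RNG seed (mandatory)
#' @return list with `ensemble`, `truth` (list: `blocks`, `block_sign`,
#'   `sign_matrix`)
#' @export
make_correlated_motion <- function(n_atoms, blocks, sign_matrix, n_frames,
                                   amplitude = 0.5, noise = 0.1, seed) {
  if (missing(seed)) stop("seed is mandatory")
  nb <- length(blocks)
  if (!setequal(unlist(blocks), seq_len(n_atoms)))
    stop("blocks must partition 1..n_atoms")
  sign_matrix <- as.matrix(sign_matrix)
  if (nrow(sign_matrix) != nb || ncol(sign_matrix) != nb)
    stop("sign matrix dimension must equal block count")
  if (any(diag(sign_matrix) != 1))
    stop("inconsistent sign matrix: diagonal must be +1")
  s <- sign_matrix[, 1]
  if (any(outer(s, s) != sign_matrix))
    stop("inconsistent sign matrix: not realizable as products of block signs")

  with_preserved_seed(seed, {
    base <- matrix(stats::runif(3 * n_atoms, -15, 15), n_atoms, 3)
    # move blocks along the axis joining the first and last block
    # centroids: for balanced anti-phase blocks this cancels both net
    # translation and net torque, so the motion survives rigid-body
    # fitting (it is a genuine internal breathing mode)
    if (nb >= 2L) {
      v <- colMeans(base[blocks[[nb]], , drop = FALSE]) -
        colMeans(base[blocks[[1]], , drop = FALSE])
      v <- v / sqrt(sum(v^2))
    } else {
      v <- c(1, 0, 0)
    }
    z <- stats::rnorm(n_frames)
    frames <- lapply(seq_len(n_frames), function(f) {
      disp <- matrix(0, n_atoms, 3)
      for (b in seq_len(nb))
        disp[blocks[[b]], ] <- rep(s[b] * amplitude * z[f] * v, each = length(blocks[[b]]))
      base + disp + matrix(stats::rnorm(3 * n_atoms, 0, noise), n_atoms, 3)
    })
    topo <- structure_model(data.frame(
      serial = seq_len(n_atoms), name = "CA", altloc = " ",
      resname = "GLY", resid = seq_len(n_atoms), chain = "A",
      x = frames[[1]][, 1], y = frames[[1]][, 2], z = frames[[1]][, 3],
      element = "C", hetero = FALSE, stringsAsFactors = FALSE))
    list(ensemble = conf_ensemble(topo, frames),
         truth = list(blocks = blocks, block_sign = s,
                      sign_matrix = sign_matrix))
  })
}

# ---- toy binding system -------------------------------------------------

#' Generate a toy host-guest binding ensemble with parameter tables
#'
#' A rigid 3-atom host at the origin and a 1-atom guest placed at the
#' scheduled separations along +x.  One charge sits on the host's first
#' atom and one on the guest.  Emits PQR-style and LJ tables consumable
#' by the energetics module.
#'
#' @param separations Angstrom per frame (all > 0)
#' @param q_host,q_guest charges (e), defaults +1 / -1
#' @param sigma_lj,eps_lj LJ parameters shared by all atoms
#'   (defaults 3.4 A, 0.1 kcal/mol)
#' @param radius intrinsic/SASA radius for all atoms (default 1.7 A)
#' @param seed RNG seed (mandatory; reserved for future noise, the
#'   geometry itself is deterministic)
#' @return list with `ensemble`, `pqr`, `lj`, `receptor`, `ligand`,
#'   `truth` (list: `separations`)
#' @export
make_toy_binding_system <- function(separations, q_host = 1, q_guest = -1,
                                    sigma_lj = 3.4, eps_lj = 0.1,
                                    radius = 1.7, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (any(separations <= 0)) stop("separations must be positive")
  host <- rbind(c(0, 0, 0), c(0, 2.2, 0), c(0, 0, 2.2))
  frames <- lapply(separations, function(d) rbind(host, c(d, 0, 0)))
  topo <- structure_model(data.frame(
    serial = 1:4, name = c("C1", "C2", "C3", "C4"), altloc = " ",
    resname = c("HST", "HST", "HST", "GST"), resid = c(1L, 1L, 1L, 2L),
    chain = c("A", "A", "A", "B"),
    x = frames[[1]][, 1], y = frames[[1]][, 2], z = frames[[1]][, 3],
    element = "C", hetero = c(FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE))
  pqr <- data.frame(serial = 1:4, charge = c(q_host, 0, 0, q_guest),
                    radius = radius)
  lj <- data.frame(serial = 1:4, sigma = sigma_lj, epsilon = eps_lj)
  topo <- assign_atom_types(topo, params = pqr)
  list(ensemble = conf_ensemble(topo, frames), pqr = pqr, lj = lj,
       receptor = 1:3, ligand = 4L,
       truth = list(separations = separations))
}
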