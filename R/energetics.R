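# ---- MM/GBSA rescoring --------------------------------------------------

#' Energy model parameters
#'
#' Defaults follow common implicit-solvent rescoring practice: interior
#' dielectric 1, solvent dielectric 78.5, Coulomb constant 332.06
#' kcal A / (mol e^2), OBC-II generalized-Born rescaling, surface tension
#' 0.0072 kcal/(mol A^2) with zero offset, water probe 1.4 A.  The GB
#' dielectric offset defaults to 0 A so that an isolated ion's effective
#' Born radius equals its intrinsic radius (the Born closed form).
#'
#' @param eps_in interior dielectric
#' @param eps_solvent solvent dielectric
#' @param coulomb_k Coulomb constant, kcal A mol^-1 e^-2
#' @param gb_model "OBC2" (alpha 1.0, beta 0.8, gamma 4.85)
#' @param gb_offset dielectric offset (A)
#' @param gb_scale descreening scaling factor applied to all atoms
#' @param gamma_sur surface tension, kcal mol^-1 A^-2
#' @param beta_sur nonpolar offset, kcal mol^-1
#' @param probe_radius SASA probe, A
#' @param sasa_points SASA lattice points per atom
#' @return object of class `energy_params`
#' @export
energy_params <- function(eps_in = 1.0, eps_solvent = 78.5,
                          coulomb_k = 332.06, gb_model = "OBC2",
                          gb_offset = 0.0, gb_scale = 0.8,
                          gamma_sur = 0.0072, beta_sur = 0.0,
                          probe_radius = 1.4, sasa_points = 960L) {
  if (eps_in <= 0 || eps_solvent <= 0) stop("dielectrics must be positive")
  if (eps_solvent <= eps_in) stop("solvent dielectric must exceed interior dielectric")
  structure(list(eps_in = eps_in, eps_solvent = eps_solvent,
                 coulomb_k = coulomb_k, gb_model = gb_model,
                 gb_offset = gb_offset, gb_scale = gb_scale,
                 gamma_sur = gamma_sur, beta_sur = beta_sur,
                 probe_radius = probe_radius, sasa_points = sasa_points),
            class = "energy_params")
}

.pair_dists <- function(xyz) {
  d <- as.matrix(stats::dist(xyz))
  d
}

#' Coulomb energy
#'
#' Pairwise electrostatic energy `sum_{i<j} k q_i q_j / (eps_in r_ij)`
#' with no cutoff (rescoring context).
#'
#' @param xyz n x 3 coordinates (A)
#' @param charges per-atom charges (e)
#' @param params an `energy_params`
#' @return kcal/mol
#' @export
coulomb_energy <- function(xyz, charges, params = energy_params()) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (length(charges) != n) stop("charges must match atom count")
  if (n < 2L) return(0)
  d <- .pair_dists(xyz)
  iu <- upper.tri(d)
  if (any(d[iu] == 0)) stop("singularity: coincident charged atoms (r = 0)")
  qq <- outer(charges, charges)
  sum(qq[iu] / d[iu]) * params$coulomb_k / params$eps_in
}

#' Lennard-Jones energy
#'
#' `sum_{i<j} 4 eps_ij [ (sigma_ij/r)^12 - (sigma_ij/r)^6 ]` with
#' Lorentz-Berthelot combining (arithmetic sigma, geometric epsilon).
#'
#' @param xyz n x 3 coordinates (A)
#' @param sigma per-atom sigma (A)
#' @param epsilon per-atom epsilon (kcal/mol)
#' @return kcal/mol
#' @export
lj_energy <- function(xyz, sigma, epsilon) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (length(sigma) != n || length(epsilon) != n)
    stop("sigma/epsilon must match atom count")
  if (n < 2L) return(0)
  d <- .pair_dists(xyz)
  iu <- which(upper.tri(d), arr.ind = TRUE)
  r <- d[upper.tri(d)]
  if (any(r == 0)) stop("singularity: coincident atoms (r = 0)")
  sij <- (sigma[iu[, 1]] + sigma[iu[, 2]]) / 2
  eij <- sqrt(epsilon[iu[, 1]] * epsilon[iu[, 2]])
  sr6 <- (sij / r)^6
  sum(4 * eij * (sr6^2 - sr6))
}

# HCT pairwise-descreening integral for atom i (reduced radius rho_i)
# against neighbours with scaled radii sr_j at distances r_ij.
.hct_integral <- function(rho_i, r, sr) {
  total <- 0
  for (k in seq_along(r)) {
    rij <- r[k]; s <- sr[k]
    if (s <= 0) next
    U <- rij + s
    if (rho_i >= U) next            # neighbour fully buried, no descreening
    L <- max(abs(rij - s), rho_i)
    term <- (1 / L - 1 / U) +
      0.25 * (rij - s^2 / rij) * (1 / U^2 - 1 / L^2) +
      0.5 / rij * log(L / U)
    if (rho_i < s - rij)            # atom i engulfed by neighbour sphere
      term <- term + 2 * (1 / rho_i - 1 / L)
    total <- total + 0.5 * term
  }
  total
}

#' Generalized-Born polar solvation energy (OBC-style)
#'
#' Effective Born radii from the pairwise HCT descreening integral with
#' OBC-II tanh rescaling, then
#' `dG = -(k/2) (1/eps_in - 1/eps_solvent) sum_ij q_i q_j / f_GB` with
#' `f_GB = sqrt(r^2 + R_i R_j exp(-r^2 / (4 R_i R_j)))`.
#'
#' @param xyz n x 3 coordinates (A)
#' @param charges per-atom charges (e)
#' @param radii per-atom intrinsic radii (A)
#' @param params an `energy_params`
#' @return kcal/mol (non-positive for any single-charge system)
#' @export
gb_polar_energy <- function(xyz, charges, radii, params = energy_params()) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (length(charges) != n || length(radii) != n)
    stop("charges and radii must match atom count")
  if (any(radii <= 0)) stop("intrinsic radii must be positive")
  rho <- radii - params$gb_offset
  if (any(rho <= 0)) stop("model failure: non-positive reduced radius")
  if (n == 1L) {
    Reff <- rho
  } else {
    d <- .pair_dists(xyz)
    Reff <- numeric(n)
    # OBC-II rescaling constants
    al <- 1.0; be <- 0.8; ga <- 4.85
    for (i in seq_len(n)) {
      j <- setdiff(seq_len(n), i)
      I <- .hct_integral(rho[i], d[i, j], params$gb_scale * rho[j])
      psi <- I * rho[i]
      inv <- 1 / rho[i] - tanh(al * psi - be * psi^2 + ga * psi^3) / radii[i]
      if (inv <= 0)
        stop(sprintf("model failure: non-positive effective Born radius for atom %d", i))
      Reff[i] <- 1 / inv
    }
  }
  pref <- -0.5 * params$coulomb_k * (1 / params$eps_in - 1 / params$eps_solvent)
  total <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    r2 <- sum((xyz[i, ] - xyz[j, ])^2)
    RiRj <- Reff[i] * Reff[j]
    fgb <- sqrt(r2 + RiRj * exp(-r2 / (4 * RiRj)))
    total <- total + charges[i] * charges[j] / fgb
  }
  pref * total
}

#' Nonpolar (surface-area) solvation energy
#'
#' Linear SASA model `gamma * SASA + beta`.
#'
#' @param sasa_total total SASA (A^2), non-negative
#' @param params an `energy_params`
#' @return kcal/mol
#' @export
nonpolar_energy <- function(sasa_total, params = energy_params()) {
  if (sasa_total < 0) stop("SASA must be non-negative")
  params$gamma_sur * sasa_total + params$beta_sur
}

# Full single-state GBSA energy of one coordinate set.
.state_energy <- function(xyz, charges, radii, sigma, epsilon, model, params) {
  sasa <- shrake_rupley_sasa(xyz, model, probe_radius = params$probe_radius,
                             n_points = params$sasa_points)
  c(E_ele = coulomb_energy(xyz, charges, params),
    E_vdw = lj_energy(xyz, sigma, epsilon),
    G_GB = gb_polar_energy(xyz, charges, radii, params),
    G_sur = nonpolar_energy(sum(sasa$per_atom, na.rm = TRUE), params))
}

#' Evenly spaced snapshots from the trailing half of a trajectory
#'
#' Default snapshot rule for MM/GBSA averaging: the production window is
#' taken as the second half of the frames and `n` indices are drawn
#' evenly from it (all of it when fewer frames are available).
#'
#' @param n_total total frame count
#' @param n requested snapshot count (default 500)
#' @param from_fraction start of the window as a fraction (default 0.5)
#' @return integer frame indices
#' @export
snapshot_indices <- function(n_total, n = 500L, from_fraction = 0.5) {
  start <- floor(n_total * from_fraction) + 1L
  if (start > n_total) start <- n_total
  window <- start:n_total
  if (length(window) <= n) return(window)
  unique(round(seq(window[1], window[length(window)], length.out = n)))
}

#' Single-trajectory MM/GBSA binding free energy
#'
#' For each snapshot the complex energy components are computed, then the
#' receptor and ligand components on the same geometries (single-trajectory
#' convention), and the binding components are the differences
#' complex - receptor - ligand, averaged over snapshots with standard
#' deviations.  The binding free energy is the sum of the four components
#' (electrostatic, van der Waals, GB polar, nonpolar surface); the
#' entropy term is not computed.
#'
#' @param ensemble `conf_ensemble` of complex frames (typed topology with
#'   charges; see [assign_atom_types()] and [read_pqr_table()])
#' @param receptor,ligand integer atom-index partitions (must be disjoint
#'   and cover all atoms)
#' @param lj data frame with columns serial, sigma, epsilon
#'   (see [read_lj_table()])
#' @param params an `energy_params`
#' @param snapshots integer frame indices (default: [snapshot_indices()]
#'   with n = 500 over the trailing half)
#' @return object of class `gbsa_components`: list of per-component means
#'   (`E_ele`, `E_vdw`, `G_GB`, `G_sur`, `G_bind`), `sd` per component,
#'   `n_snapshots`, and the per-snapshot table `per_frame`
#' @export
mmgbsa <- function(ensemble, receptor, ligand, lj, params = energy_params(),
                   snapshots = NULL) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  model <- ensemble$topology
  n <- n_atoms(model)
  if (length(intersect(receptor, ligand)) > 0L)
    stop("receptor and ligand partitions overlap")
  if (!setequal(c(receptor, ligand), seq_len(n)))
    stop("partition must cover all atoms exactly")
  a <- model$atoms
  if (is.null(a$charge) || any(is.na(a$charge)))
    stop("charges missing: supply a PQR-style table via assign_atom_types()")
  if (is.null(a$radius) || any(is.na(a$radius)))
    stop("radii missing: run assign_atom_types() first")
  m <- match(a$serial, lj$serial)
  if (any(is.na(m))) stop("LJ parameters missing for some atoms")
  sigma <- lj$sigma[m]; epsilon <- lj$epsilon[m]
  if (is.null(snapshots)) snapshots <- snapshot_indices(n_frames(ensemble))
  if (length(snapshots) == 0L) stop("empty snapshot set")

  sub_model <- function(idx) {
    mm <- model; mm$atoms <- mm$atoms[idx, , drop = FALSE]
    rownames(mm$atoms) <- NULL; mm
  }
  rec_model <- sub_model(receptor); lig_model <- sub_model(ligand)

  comp <- matrix(NA_real_, length(snapshots), 4,
                 dimnames = list(NULL, c("E_ele", "E_vdw", "G_GB", "G_sur")))
  for (k in seq_along(snapshots)) {
    f <- ensemble$frames[[snapshots[k]]]
    e_cplx <- .state_energy(f, a$charge, a$radius, sigma, epsilon, model, params)
    e_rec <- .state_energy(f[receptor, , drop = FALSE], a$charge[receptor],
                           a$radius[receptor], sigma[receptor],
                           epsilon[receptor], rec_model, params)
    e_lig <- .state_energy(f[ligand, , drop = FALSE], a$charge[ligand],
                           a$radius[ligand], sigma[ligand],
                           epsilon[ligand], lig_model, params)
    comp[k, ] <- e_cplx - e_rec - e_lig
  }
  means <- colMeans(comp)
  sds <- apply(comp, 2, stats::sd)
  per_frame <- data.frame(frame = snapshots, comp,
                          G_bind = rowSums(comp))
  structure(list(E_ele = means[["E_ele"]], E_vdw = means[["E_vdw"]],
                 G_GB = means[["G_GB"]], G_sur = means[["G_sur"]],
                 G_bind = sum(means),
                 sd = c(sds, G_bind = stats::sd(per_frame$G_bind)),
                 n_snapshots = length(snapshots),
                 per_frame = per_frame,
                 params = params),
            class = "gbsa_components")
}

#' @export
print.gbsa_components <- function(x, ...) {
  cat(sprintf("MM/GBSA over %d snapshots (kcal/mol, entropy not computed):\n",
              x$n_snapshots))
  cat(sprintf("  dE_ele %8.2f +- %.2f\n", x$E_ele, x$sd[["E_ele"]]))
  cat(sprintf("  dE_vdw %8.2f +- %.2f\n", x$E_vdw, x$sd[["E_vdw"]]))
  cat(sprintf("  dG_sur %8.2f +- %.2f\n", x$G_sur, x$sd[["G_sur"]]))
  cat(sprintf("  dG_GB  %8.2f +- %.2f\n", x$G_GB, x$sd[["G_GB"]]))
  cat(sprintf("  dG_bind%8.2f +- %.2f\n", x$G_bind, x$sd[["G_bind"]]))
  invisible(x)
}

#' Write a GBSA component table as TSV (report column order)
#' @param components named list of `gbsa_components` (names = system ids)
#' @param path output file
#' @return invisible path
#' @export
write_gbsa_tsv <- function(components, path) {
  rows <- do.call(rbind, lapply(names(components), function(nm) {
    x <- components[[nm]]
    data.frame(system = nm, E_ele = x$E_ele, E_vdw = x$E_vdw,
               G_sur = x$G_sur, G_GB = x$G_GB, G_bind = x$G_bind,
               sd_bind = x$sd[["G_bind"]])
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- component-table consistency check ---------------------------------

#' Check MM/GBSA component tables for additive consistency
#'
#' Validates that each row's four components (`E_ele`, `E_vdw`, `G_sur`,
#' `G_GB`) sum to the stated `G_bind` within `tol`, the contract that the
#' binding free energy is defined as the component sum (entropy excluded).
#' Useful for auditing published rescoring tables rounded to one decimal.
#'
#' @param table data frame with columns `id`, `E_ele`, `E_vdw`, `G_sur`,
#'   `G_GB`, `G_bind` (see [read_gbsa_table()])
#' @param tol kcal/mol tolerance (default 0.05, half a printed unit)
#' @return data frame: id, computed sum, stated total, abs deviation, pass
#' @export
check_gbsa_table <- function(table, tol = 0.05) {
  need <- c("id", "E_ele", "E_vdw", "G_sur", "G_GB", "G_bind")
  if (!all(need %in% names(table)))
    stop("malformed table: need columns ", paste(need, collapse = ", "))
  s <- table$E_ele + table$E_vdw + table$G_sur + table$G_GB
  data.frame(id = table$id, component_sum = s, stated_total = table$G_bind,
             deviation = abs(s - table$G_bind),
             pass = abs(s - table$G_bind) <= tol + 1e-12,
             stringsAsFactors = FALSE)
}

#' Read a GBSA component table (TSV)
#'
#' Expects a header `id E_ele E_vdw G_sur G_GB G_bind` (additional
#' `sd_*` columns are carried through).  The package bundles
#' literature-reported CETP-ligand rescoring tables for the N- and
#' C-terminal pockets under `inst/extdata/`.
#'
#' @param path TSV file
#' @return data frame
#' @export
read_gbsa_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
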