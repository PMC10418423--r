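# ---- descriptor series container --------------------------------------

#' Construct a descriptor series
#'
#' Per-frame scalar descriptor values (distances, angles, Rg, SASA, ...).
#'
#' @param name descriptor name
#' @param times numeric, ns
#' @param values numeric, same length as times
#' @param units one of "A", "degrees", "A^2", "A^3", "unitless"
#' @return object of class `descriptor_series`
#' @export
descriptor_series <- function(name, times, values, units) {
  if (length(times) != length(values))
    stop("times and values must have equal length")
  units <- match.arg(units, c("A", "degrees", "A^2", "A^3", "unitless"))
  structure(list(name = name, times = as.numeric(times),
                 values = as.numeric(values), units = units),
            class = "descriptor_series")
}

#' @export
print.descriptor_series <- function(x, ...) {
  cat(sprintf("descriptor_series '%s' [%s]: %d frames, range %.3f..%.3f\n",
              x$name, x$units, length(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.descriptor_series <- function(x, ...) {
  data.frame(time_ns = x$times, value = x$values, units = x$units)
}

#' Write a descriptor series as TSV
#' @param series a `descriptor_series`
#' @param path output file
#' @return invisible path
#' @export
write_series_tsv <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# descriptor: %s (units: %s)", series$name, series$units), con)
  utils::write.table(as.data.frame(series)[, c("time_ns", "value")],
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- superposition -----------------------------------------------------

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares fit of `mobile` onto `reference` over all rigid
#' transforms, with a proper rotation (det = +1).
#'
#' @param mobile n x 3 coordinate matrix
#' @param reference n x 3 coordinate matrix
#' @param weights optional non-negative weights, length n
#' @return list with `coords` (rotated+translated mobile), `rotation`
#'   (3 x 3), `translation` (length 3), `rmsd` (Angstrom)
#' @export
superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference) || ncol(mobile) != 3L || ncol(reference) != 3L)
    stop("mobile and reference must be n x 3 matrices with equal n")
  n <- nrow(mobile)
  if (n < 3L) stop("degenerate superposition: need at least 3 points")
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  cm <- colSums(mobile * w); cr <- colSums(reference * w)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  # collinearity check on the reference: second singular value ~ 0
  sv <- svd(B * sqrt(w))$d
  if (sv[2] < 1e-8 * max(sv[1], 1))
    stop("degenerate superposition: reference points are (near-)collinear")
  H <- t(A * w) %*% B
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  fitted <- A %*% t(R)
  fitted <- sweep(fitted, 2, cr, `+`)
  rmsd <- sqrt(sum(w * rowSums((fitted - reference)^2)))
  list(coords = fitted, rotation = R, translation = cr - as.vector(R %*% cm),
       rmsd = rmsd)
}

.backbone_idx <- function(model) {
  idx <- which(model$atoms$name %in% c("N", "CA", "C", "O") & !model$atoms$hetero)
  if (length(idx) == 0L) idx <- which(!model$atoms$hetero)
  idx
}

.calpha_idx <- function(model) {
  which(model$atoms$name == "CA" & !model$atoms$hetero)
}

#' Per-frame best-fit RMSD series
#'
#' RMSD of every frame to a reference frame after optimal superposition
#' over the selection.  Default selection is the protein backbone
#' (N, CA, C, O), the convention for equilibration monitoring.
#'
#' @param ensemble a `conf_ensemble`
#' @param reference_frame index of the reference frame (default 1)
#' @param selection integer atom indices (default: backbone)
#' @return `descriptor_series` in Angstrom
#' @export
rmsd_series <- function(ensemble, reference_frame = 1L, selection = NULL) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  if (is.null(selection)) selection <- .backbone_idx(ensemble$topology)
  if (length(selection) == 0L) stop("empty selection")
  ref <- ensemble$frames[[reference_frame]][selection, , drop = FALSE]
  vals <- vapply(ensemble$frames, function(f)
    superpose(f[selection, , drop = FALSE], ref)$rmsd, numeric(1))
  descriptor_series("rmsd_backbone", ensemble$times, vals, "A")
}

# Iteratively refined mean structure over a selection: fit all frames to
# the running mean, recompute, repeat.  Returns list(mean, fitted frames).
.iterative_mean_fit <- function(ensemble, selection, iterations = 2L) {
  frames <- lapply(ensemble$frames, function(f) f[selection, , drop = FALSE])
  ref <- frames[[1]]
  for (it in seq_len(iterations)) {
    fitted <- lapply(frames, function(f) superpose(f, ref)$coords)
    ref <- Reduce(`+`, fitted) / length(fitted)
  }
  fitted <- lapply(frames, function(f) superpose(f, ref)$coords)
  list(mean = ref, frames = fitted)
}

#' Per-residue RMSF over C-alpha atoms
#'
#' Root-mean-square fluctuation about the iteratively refined mean
#' structure (2 fitting passes), computed on C-alpha atoms:
#' RMSF_i = sqrt(mean_t |r_i(t) - <r_i>|^2).
#'
#' @param ensemble a `conf_ensemble`
#' @param selection atom indices (default: all C-alpha atoms)
#' @return named numeric vector (Angstrom), names = residue ids
#' @export
rmsf_per_residue <- function(ensemble, selection = NULL) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  if (n_frames(ensemble) < 2L) stop("RMSF needs at least 2 frames")
  if (is.null(selection)) selection <- .calpha_idx(ensemble$topology)
  if (length(selection) == 0L) stop("empty selection")
  fit <- .iterative_mean_fit(ensemble, selection)
  dev2 <- lapply(fit$frames, function(f) rowSums((f - fit$mean)^2))
  rmsf <- sqrt(Reduce(`+`, dev2) / length(dev2))
  names(rmsf) <- ensemble$topology$atoms$resid[selection]
  rmsf
}

#' Radius of gyration
#'
#' Rg = sqrt(sum_i m_i |r_i - r_com|^2 / sum_i m_i).  Unweighted (the
#' default) uses unit masses; `mass_weighted = TRUE` uses standard atomic
#' masses by element.
#'
#' @param frame n x 3 coordinate matrix
#' @param model optional `structure_model` (needed for mass weighting)
#' @param selection atom indices (default all)
#' @param mass_weighted logical
#' @return Rg in Angstrom
#' @export
radius_of_gyration <- function(frame, model = NULL, selection = NULL,
                               mass_weighted = FALSE) {
  frame <- as.matrix(frame)
  if (is.null(selection)) selection <- seq_len(nrow(frame))
  if (length(selection) == 0L) stop("empty selection")
  x <- frame[selection, , drop = FALSE]
  if (mass_weighted) {
    if (is.null(model)) stop("mass weighting requires the structure model")
    masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                P = 30.974, F = 18.998, CL = 35.45, BR = 79.904, I = 126.90,
                SE = 78.971)
    m <- masses[toupper(model$atoms$element[selection])]
    if (any(is.na(m))) stop("unknown element mass in selection")
  } else {
    m <- rep(1, nrow(x))
  }
  com <- colSums(x * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(x, 2, com)^2)) / sum(m))
}

#' Rg time series over an ensemble
#' @inheritParams radius_of_gyration
#' @param ensemble a `conf_ensemble`
#' @return `descriptor_series` in Angstrom
#' @export
rg_series <- function(ensemble, selection = NULL, mass_weighted = FALSE) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  vals <- vapply(ensemble$frames, radius_of_gyration,
                 model = ensemble$topology, selection = selection,
                 mass_weighted = mass_weighted, FUN.VALUE = numeric(1))
  descriptor_series("radius_of_gyration", ensemble$times, vals, "A")
}

# ---- gate distances ----------------------------------------------------

.residue_atoms <- function(model, resid, chain = NULL, atom_scope = "all") {
  a <- model$atoms
  keep <- a$resid == resid
  if (!is.null(chain)) keep <- keep & a$chain == chain
  if (atom_scope == "heavy") keep <- keep & toupper(a$element) != "H"
  which(keep)
}

#' Maximum inter-residue atom-pair distance
#'
#' The opening descriptors (N-opening d_Trp106-Trp162, C-opening
#' d_Phe301-Met412, neck d_Phe265-Met433) are maximum distances over all
#' atom pairs with one atom in each residue.  Scope "all" includes
#' hydrogens when present (protonated MD models); "heavy" restricts to
#' heavy atoms (raw crystal structures).
#'
#' @param frame n x 3 coordinate matrix
#' @param model a `structure_model`
#' @param residue_a,residue_b residue ids (author numbering)
#' @param atom_scope "all" or "heavy"
#' @param chain optional chain id restriction
#' @return maximum distance (Angstrom) with attribute `pair` = the two
#'   atom indices attaining it (first pair in file order on ties)
#' @export
max_residue_pair_distance <- function(frame, model, residue_a, residue_b,
                                      atom_scope = c("all", "heavy"),
                                      chain = NULL) {
  atom_scope <- match.arg(atom_scope)
  if (residue_a == residue_b) stop("residue_a and residue_b must differ")
  ia <- .residue_atoms(model, residue_a, chain, atom_scope)
  ib <- .residue_atoms(model, residue_b, chain, atom_scope)
  if (length(ia) == 0L) stop(sprintf("residue %d absent from model", residue_a))
  if (length(ib) == 0L) stop(sprintf("residue %d absent from model", residue_b))
  A <- frame[ia, , drop = FALSE]; B <- frame[ib, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  best <- which(d2 == max(d2), arr.ind = TRUE)[1, ]
  out <- sqrt(max(d2))
  attr(out, "pair") <- c(ia[best[1]], ib[best[2]])
  out
}

#' Gate-distance time series
#' @inheritParams max_residue_pair_distance
#' @param ensemble a `conf_ensemble`
#' @return `descriptor_series` in Angstrom
#' @export
gate_distance_series <- function(ensemble, residue_a, residue_b,
                                 atom_scope = c("all", "heavy"), chain = NULL) {
  atom_scope <- match.arg(atom_scope)
  stopifnot(inherits(ensemble, "conf_ensemble"))
  vals <- vapply(ensemble$frames, function(f)
    as.numeric(max_residue_pair_distance(f, ensemble$topology, residue_a,
                                         residue_b, atom_scope, chain)),
    numeric(1))
  descriptor_series(sprintf("d_%d-%d", residue_a, residue_b),
                    ensemble$times, vals, "A")
}

#' Flag frames whose gate is open
#'
#' A frame is "open" iff the gate distance is at least the passage
#' threshold; the cholesteryl-ester steroid ring needs about 10 Angstrom
#' to pass without reorientation, the default.
#'
#' @param series a `descriptor_series` of distances
#' @param threshold Angstrom (default 10)
#' @return logical vector per frame
#' @export
gate_open_flags <- function(series, threshold = 10) {
  stopifnot(inherits(series, "descriptor_series"))
  if (threshold <= 0) stop("threshold must be positive")
  series$values >= threshold
}

# ---- angles ------------------------------------------------------------

.vec_angle <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("undefined angle: coincident points")
  ct <- sum(u * v) / (nu * nv)
  ct <- min(1, max(-1, ct))
  acos(ct) * 180 / pi
}

#' Side-chain orientation angle
#'
#' Interior angle at the vertex atom between vertex->tip and vertex->base,
#' in degrees.  For the neck gate of CETP the tip is the extreme edge
#' carbon of the Phe265 ring (CZ by default), the vertex its C-alpha and
#' the base the C-alpha of Met260.
#'
#' @param frame n x 3 coordinate matrix
#' @param model a `structure_model`
#' @param tip,vertex,base lists `list(resid =, name =)` identifying atoms
#' @return angle in degrees, in [0, 180]
#' @export
sidechain_orientation_angle <- function(frame, model,
                                        tip = list(resid = 265, name = "CZ"),
                                        vertex = list(resid = 265, name = "CA"),
                                        base = list(resid = 260, name = "CA")) {
  pick <- function(spec) {
    idx <- which(model$atoms$resid == spec$resid & model$atoms$name == spec$name)
    if (length(idx) == 0L)
      stop(sprintf("atom %s of residue %d absent", spec$name, spec$resid))
    frame[idx[1], ]
  }
  p_tip <- pick(tip); p_vx <- pick(vertex); p_base <- pick(base)
  if (all(p_tip == p_vx) || all(p_base == p_vx))
    stop("undefined angle: vertex coincides with tip or base")
  .vec_angle(p_tip - p_vx, p_base - p_vx)
}

#' Orientation-angle time series
#' @inheritParams sidechain_orientation_angle
#' @param ensemble a `conf_ensemble`
#' @return `descriptor_series` in degrees
#' @export
orientation_angle_series <- function(ensemble,
                                     tip = list(resid = 265, name = "CZ"),
                                     vertex = list(resid = 265, name = "CA"),
                                     base = list(resid = 260, name = "CA")) {
  vals <- vapply(ensemble$frames, sidechain_orientation_angle,
                 model = ensemble$topology, tip = tip, vertex = vertex,
                 base = base, FUN.VALUE = numeric(1))
  descriptor_series(sprintf("angle_%d%s", tip$resid, tip$name),
                    ensemble$times, vals, "degrees")
}

# ---- domain bend angles ------------------------------------------------

.principal_axis <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop("axis undefined: fewer than 3 points")
  xc <- sweep(x, 2, colMeans(x))
  e <- eigen(crossprod(xc) / nrow(xc), symmetric = TRUE)
  if (e$values[1] <= 1e-10 ||
      (e$values[1] - e$values[2]) <= 1e-6 * e$values[1])
    stop("axis undefined: (near-)isotropic domain")
  e$vectors[, 1]
}

#' Domain bend angles from principal axes
#'
#' Each domain axis is the first principal axis of the domain's C-alpha
#' coordinates, with its sign fixed to point from the molecular centroid
#' towards the domain centroid (outward).  `n_bend` is the angle between
#' the N-domain axis and the direction from the N-domain centroid to the
#' Helix X centroid; `c_bend` likewise for the C-domain; `overall` is the
#' inter-domain axis angle.  Differences between frames quantify
#' stretching/huddling of the boomerang.
#'
#' @param frame n x 3 coordinate matrix
#' @param model a `structure_model`
#' @param regions a `region_set` providing "N-domain", "C-domain", "HelixX"
#' @return named numeric: n_bend, c_bend, overall (degrees)
#' @export
domain_bend_angles <- function(frame, model, regions = cetp_regions()) {
  ca <- .calpha_idx(model)
  if (length(ca) == 0L) ca <- seq_len(nrow(model$atoms))
  pick_ca <- function(name) {
    idx <- intersect(select_region(model, regions, name), ca)
    if (length(idx) == 0L) stop(sprintf("region '%s' empty over C-alpha atoms", name))
    frame[idx, , drop = FALSE]
  }
  nd <- pick_ca("N-domain"); cd <- pick_ca("C-domain"); hx <- pick_ca("HelixX")
  all_cent <- colMeans(frame[ca, , drop = FALSE])
  orient <- function(axis, dom_cent) {
    if (sum(axis * (dom_cent - all_cent)) < 0) -axis else axis
  }
  n_cent <- colMeans(nd); c_cent <- colMeans(cd); h_cent <- colMeans(hx)
  n_axis <- orient(.principal_axis(nd), n_cent)
  c_axis <- orient(.principal_axis(cd), c_cent)
  c(n_bend = .vec_angle(n_axis, h_cent - n_cent),
    c_bend = .vec_angle(c_axis, h_cent - c_cent),
    overall = .vec_angle(n_axis, c_axis))
}

#' Bend-angle time series
#' @inheritParams domain_bend_angles
#' @param ensemble a `conf_ensemble`
#' @return data frame: time_ns, n_bend, c_bend, overall (degrees)
#' @export
bend_angle_series <- function(ensemble, regions = cetp_regions()) {
  rows <- t(vapply(ensemble$frames, domain_bend_angles,
                   model = ensemble$topology, regions = regions,
                   FUN.VALUE = numeric(3)))
  data.frame(time_ns = ensemble$times, rows)
}
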