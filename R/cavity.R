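# ---- 3D Delaunay tetrahedralization (incremental Bowyer-Watson) --------

# Circumcenter and squared circumradius of tetrahedra given as an m x 4
# index matrix into pts.  Returns list(center m x 3, r2 length m); rows
# that are degenerate (near-coplanar) get r2 = Inf so they never absorb
# points and are filtered downstream.
.circumspheres <- function(pts, tet) {
  m <- nrow(tet)
  centers <- matrix(NA_real_, m, 3)
  r2 <- rep(Inf, m)
  for (k in seq_len(m)) {
    A <- pts[tet[k, 1], ]; B <- pts[tet[k, 2], ]
    C <- pts[tet[k, 3], ]; D <- pts[tet[k, 4], ]
    M <- rbind(B - A, C - A, D - A)
    if (abs(det(M)) < 1e-10) next
    rhs <- 0.5 * c(sum(B^2 - A^2), sum(C^2 - A^2), sum(D^2 - A^2))
    cen <- tryCatch(solve(M, rhs), error = function(e) NULL)
    if (is.null(cen)) next
    centers[k, ] <- cen
    r2[k] <- sum((cen - A)^2)
  }
  list(center = centers, r2 = r2)
}

# Delaunay tetrahedralization of a point set.  A tiny deterministic jitter
# (scaled by `jitter`) breaks exactly cospherical/coplanar configurations
# such as lattice shells; coordinates returned to callers are unjittered.
# Returns an m x 4 matrix of point indices.
.delaunay_tetrahedra <- function(pts, jitter = 1e-5, seed = 97L) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 4L) stop("triangulation error: need at least 4 points")
  rng <- apply(pts, 2, range)
  span <- max(rng[2, ] - rng[1, ], 1)
  sv <- svd(sweep(pts, 2, colMeans(pts)))$d
  if (sv[3] < 1e-6 * max(sv[1], 1))
    stop("triangulation error: points are (near-)coplanar")
  if (jitter > 0)
    pts <- pts + with_preserved_seed(seed,
      matrix(stats::runif(3 * n, -jitter, jitter) * span, n, 3))

  centre <- colMeans(rng)
  R <- span * 20
  P <- rbind(centre + c(0, 0, 3 * R),
             centre + c(-2 * R, -R, -R),
             centre + c(2 * R, -R, -R),
             centre + c(0, 2.5 * R, -R),
             pts)
  tet <- matrix(1:4, 1, 4)
  cs <- .circumspheres(P, tet)
  centers <- cs$center; r2 <- cs$r2

  for (p in 5:(n + 4L)) {
    px <- P[p, ]
    d2 <- (centers[, 1] - px[1])^2 + (centers[, 2] - px[2])^2 +
      (centers[, 3] - px[3])^2
    bad <- which(d2 < r2)
    if (length(bad) == 0L) {
      # numerical fallback: claim the nearest tetra
      bad <- which.min(d2 / r2)
    }
    faces <- NULL
    for (k in bad) {
      v <- tet[k, ]
      faces <- rbind(faces,
                     sort(v[c(1, 2, 3)]), sort(v[c(1, 2, 4)]),
                     sort(v[c(1, 3, 4)]), sort(v[c(2, 3, 4)]))
    }
    key <- paste(faces[, 1], faces[, 2], faces[, 3])
    boundary <- faces[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    keep <- setdiff(seq_len(nrow(tet)), bad)
    tet <- tet[keep, , drop = FALSE]
    centers <- centers[keep, , drop = FALSE]
    r2 <- r2[keep]
    if (nrow(boundary) > 0L) {
      newt <- cbind(boundary, p)
      cs <- .circumspheres(P, newt)
      ok <- is.finite(cs$r2)
      tet <- rbind(tet, newt[ok, , drop = FALSE])
      centers <- rbind(centers, cs$center[ok, , drop = FALSE])
      r2 <- c(r2, cs$r2[ok])
    }
  }
  real <- rowSums(tet <= 4L) == 0L
  out <- tet[real, , drop = FALSE] - 4L
  if (nrow(out) == 0L) stop("triangulation error: no interior tetrahedra")
  # mark tetrahedra with a boundary (convex-hull) face: their
  # circumspheres leak outside the point cloud
  fk <- character(0)
  for (cols in list(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))) {
    f <- t(apply(out[, cols, drop = FALSE], 1, sort))
    fk <- c(fk, paste(f[, 1], f[, 2], f[, 3]))
  }
  cnt <- table(fk)
  once <- names(cnt)[cnt == 1L]
  m <- nrow(out)
  hull <- matrix(fk %in% once, m, 4)
  attr(out, "hull") <- rowSums(hull) > 0L
  out
}

# ---- alpha-sphere detection --------------------------------------------

#' Detect interior alpha-spheres
#'
#' One candidate sphere per Delaunay tetrahedron of the atom centres: the
#' circumsphere, deflated by the contact atoms' van der Waals radii
#' (tangent to the four inflated atoms when radii are equal).  Candidates
#' are kept when the deflated radius lies in `[r_min, r_max]`; the window
#' selects void-sized spheres, rejecting both packing interstices and the
#' near-infinite spheres of the convex hull.
#'
#' @param frame n x 3 coordinate matrix
#' @param model a typed `structure_model` (radii required)
#' @param r_min,r_max alpha-sphere radius window in Angstrom
#'   (defaults 3.0 and 6.0)
#' @param discard_hull drop candidates from tetrahedra with a face on the
#'   convex hull (default TRUE); their circumspheres bulge outside the
#'   structure and would register as spurious exterior pockets
#' @return data frame of class `alpha_spheres`: columns x, y, z, radius,
#'   i1..i4 (contact atom indices)
#' @export
detect_alpha_spheres <- function(frame, model, r_min = 3.0, r_max = 6.0,
                                 discard_hull = TRUE) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  if (is.null(a$radius) || any(is.na(a$radius)))
    stop("typing error: atom radii missing; run assign_atom_types() first")
  pts <- as.matrix(frame)
  if (nrow(pts) < 4L) stop("triangulation error: need at least 4 atoms")
  tet <- .delaunay_tetrahedra(pts)
  if (discard_hull) {
    hull <- attr(tet, "hull")
    tet <- tet[!hull, , drop = FALSE]
    if (nrow(tet) == 0L)
      return(structure(data.frame(x = numeric(0), y = numeric(0),
                                  z = numeric(0), radius = numeric(0),
                                  i1 = integer(0), i2 = integer(0),
                                  i3 = integer(0), i4 = integer(0)),
                       class = c("alpha_spheres", "data.frame")))
  }
  cs <- .circumspheres(pts, tet)
  ok <- is.finite(cs$r2)
  tet <- tet[ok, , drop = FALSE]
  cen <- cs$center[ok, , drop = FALSE]
  crad <- sqrt(cs$r2[ok])
  mean_r <- rowMeans(matrix(a$radius[tet], nrow(tet), 4))
  alpha_r <- crad - mean_r
  keep <- alpha_r >= r_min & alpha_r <= r_max
  out <- data.frame(x = cen[keep, 1], y = cen[keep, 2], z = cen[keep, 3],
                    radius = alpha_r[keep],
                    i1 = tet[keep, 1], i2 = tet[keep, 2],
                    i3 = tet[keep, 3], i4 = tet[keep, 4])
  class(out) <- c("alpha_spheres", "data.frame")
  out
}

# ---- clustering and volume ---------------------------------------------

# Monte-Carlo volume of a union of spheres (centres m x 3, radii m) using
# uniform sampling over the joint bounding box.  Deterministic given seed.
.mc_union_volume <- function(centres, radii, n_samples = 1e5, seed = 42L) {
  if (nrow(centres) == 0L) return(0)
  lo <- apply(centres - radii, 2, min)
  hi <- apply(centres + radii, 2, max)
  box <- prod(hi - lo)
  hit <- with_preserved_seed(seed, {
    s <- cbind(stats::runif(n_samples, lo[1], hi[1]),
               stats::runif(n_samples, lo[2], hi[2]),
               stats::runif(n_samples, lo[3], hi[3]))
    inside <- rep(FALSE, n_samples)
    for (k in seq_len(nrow(centres))) {
      d2 <- (s[, 1] - centres[k, 1])^2 + (s[, 2] - centres[k, 2])^2 +
        (s[, 3] - centres[k, 3])^2
      inside <- inside | d2 <= radii[k]^2
    }
    sum(inside)
  })
  box * hit / n_samples
}

#' Cluster alpha-spheres into pockets and measure volumes
#'
#' Single-linkage clustering of sphere centres at `linkage_cutoff`; each
#' cluster's volume is the Monte-Carlo volume of the union of its spheres
#' (seeded, hence reproducible).  The cavity system is "continuous" iff
#' exactly one pocket exceeds `min_volume`; otherwise "fragmented".
#'
#' @param spheres an `alpha_spheres` data frame
#' @param linkage_cutoff Angstrom (default 4.5)
#' @param min_volume Angstrom^3 (default 100)
#' @param min_spheres minimum alpha-sphere count per pocket (default 4);
#'   smaller clusters are isolated triangulation artefacts, not cavities
#' @param mc_samples Monte-Carlo samples per pocket (default 1e5)
#' @param seed RNG seed for the volume integration (default 42)
#' @return object of class `cavity_set`: list with `pockets` (data frame:
#'   pocket, n_spheres, volume), `continuity`, `largest_volume`
#' @export
cluster_and_measure <- function(spheres, linkage_cutoff = 4.5,
                                min_volume = 100, min_spheres = 4L,
                                mc_samples = 1e5, seed = 42L) {
  if (nrow(spheres) == 0L) {
    return(structure(list(pockets = data.frame(pocket = integer(0),
                                               n_spheres = integer(0),
                                               volume = numeric(0)),
                          continuity = "fragmented", largest_volume = 0,
                          params = list(linkage_cutoff = linkage_cutoff,
                                        min_volume = min_volume,
                                        mc_samples = mc_samples, seed = seed)),
                     class = "cavity_set"))
  }
  centres <- as.matrix(spheres[, c("x", "y", "z")])
  if (nrow(centres) == 1L) {
    cl <- 1L
  } else {
    hc <- stats::hclust(stats::dist(centres), method = "single")
    cl <- stats::cutree(hc, h = linkage_cutoff)
  }
  ids <- sort(unique(cl))
  ids <- ids[tabulate(cl)[ids] >= min_spheres]
  if (length(ids) == 0L)
    return(structure(list(pockets = data.frame(pocket = integer(0),
                                               n_spheres = integer(0),
                                               volume = numeric(0)),
                          continuity = "fragmented", largest_volume = 0,
                          params = list(linkage_cutoff = linkage_cutoff,
                                        min_volume = min_volume,
                                        min_spheres = min_spheres,
                                        mc_samples = mc_samples, seed = seed)),
                     class = "cavity_set"))
  pockets <- do.call(rbind, lapply(seq_along(ids), function(k) {
    sel <- cl == ids[k]
    data.frame(pocket = k, n_spheres = sum(sel),
               volume = .mc_union_volume(centres[sel, , drop = FALSE],
                                         spheres$radius[sel],
                                         n_samples = mc_samples,
                                         seed = seed + k))
  }))
  pockets <- pockets[order(-pockets$volume), ]
  pockets$pocket <- seq_len(nrow(pockets))
  rownames(pockets) <- NULL
  n_big <- sum(pockets$volume >= min_volume)
  structure(list(pockets = pockets,
                 continuity = if (n_big == 1L) "continuous" else "fragmented",
                 largest_volume = if (nrow(pockets)) max(pockets$volume) else 0,
                 params = list(linkage_cutoff = linkage_cutoff,
                               min_volume = min_volume,
                               min_spheres = min_spheres,
                               mc_samples = mc_samples, seed = seed)),
            class = "cavity_set")
}

#' @export
print.cavity_set <- function(x, ...) {
  cat(sprintf("cavity_set: %d pocket(s), %s, largest %.0f A^3\n",
              nrow(x$pockets), x$continuity, x$largest_volume))
  if (nrow(x$pockets)) print(x$pockets)
  invisible(x)
}

#' Cavity volume series and expansion rate over an ensemble
#'
#' Largest-pocket volume per frame plus an expansion rate relative to the
#' first frame.  `rate_method` "endpoint" (default) is
#' `(V_last - V_first)/V_first`; "mean" averages `(V_t - V_0)/V_0` over
#' all later frames.
#'
#' @param ensemble a `conf_ensemble` with typed topology
#' @param r_min,r_max,linkage_cutoff,min_volume,mc_samples,seed see
#'   [detect_alpha_spheres()] and [cluster_and_measure()]
#' @param rate_method "endpoint" or "mean"
#' @return `descriptor_series` (Angstrom^3) with attributes
#'   `expansion_rate` (fraction) and `continuity` (per frame)
#' @export
cavity_volume_series <- function(ensemble, r_min = 3.0, r_max = 6.0,
                                 linkage_cutoff = 4.5, min_volume = 100,
                                 min_spheres = 4L, mc_samples = 1e5,
                                 seed = 42L,
                                 rate_method = c("endpoint", "mean")) {
  rate_method <- match.arg(rate_method)
  stopifnot(inherits(ensemble, "conf_ensemble"))
  if (n_frames(ensemble) < 2L) stop("need at least 2 frames")
  sets <- lapply(seq_along(ensemble$frames), function(i) {
    sp <- detect_alpha_spheres(ensemble$frames[[i]], ensemble$topology,
                               r_min = r_min, r_max = r_max)
    cluster_and_measure(sp, linkage_cutoff = linkage_cutoff,
                        min_volume = min_volume, min_spheres = min_spheres,
                        mc_samples = mc_samples, seed = seed + i)
  })
  vols <- vapply(sets, `[[`, numeric(1), "largest_volume")
  if (vols[1] <= 0) stop("first-frame cavity volume is zero: expansion rate undefined")
  rate <- switch(rate_method,
                 endpoint = (vols[length(vols)] - vols[1]) / vols[1],
                 mean = mean((vols[-1] - vols[1]) / vols[1]))
  out <- descriptor_series("largest_cavity_volume", ensemble$times, vols, "A^3")
  attr(out, "expansion_rate") <- rate
  attr(out, "continuity") <- vapply(sets, `[[`, character(1), "continuity")
  attr(out, "cavity_sets") <- sets
  out
}

#' Write a pocket report as TSV
#' @param series result of [cavity_volume_series()]
#' @param path output file
#' @return invisible path
#' @export
write_cavity_tsv <- function(series, path) {
  sets <- attr(series, "cavity_sets")
  rows <- do.call(rbind, lapply(seq_along(sets), function(i) {
    p <- sets[[i]]$pockets
    if (nrow(p) == 0L)
      return(data.frame(frame = i, pocket = NA_integer_, n_spheres = 0L,
                        volume = 0, continuity = sets[[i]]$continuity))
    data.frame(frame = i, p, continuity = sets[[i]]$continuity)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  pr <- sets[[1]]$params
  writeLines(sprintf("# cavity report: linkage_cutoff=%g min_volume=%g mc_samples=%g seed=%d expansion_rate=%.6f",
                     pr$linkage_cutoff, pr$min_volume, pr$mc_samples, pr$seed,
                     attr(series, "expansion_rate")), con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
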