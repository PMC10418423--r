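# ---- Shrake-Rupley solvent-accessible surface area ---------------------

# Deterministic golden-spiral (Fibonacci) lattice of n points on the unit
# sphere.  Used instead of random sampling so SASA is reproducible without
# a seed.
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Classic point-counting SASA: each atom's sphere is inflated by the
#' probe radius and covered with a deterministic golden-spiral lattice;
#' a point is exposed unless it lies strictly inside some neighbouring
#' inflated sphere (boundary points count as exposed).  Per-atom area is
#' `exposed/n_points * 4*pi*(r_i + probe)^2`.
#'
#' @param frame n x 3 coordinate matrix
#' @param model a typed `structure_model` (see [assign_atom_types()])
#' @param probe_radius probe radius in Angstrom (default 1.4, water)
#' @param n_points lattice points per atom (default 960; minimum 92)
#' @param regions optional `region_set`; when given, per-region
#'   hydrophobic/hydrophilic/total aggregates are attached
#' @param selection atom indices to compute areas for (occlusion still
#'   considers all atoms); default all
#' @return object of class `sasa_result`: list with `per_atom` (Angstrom^2),
#'   `region_totals` (data frame), `probe_radius`, `n_points`
#' @export
shrake_rupley_sasa <- function(frame, model, probe_radius = 1.4,
                               n_points = 960L, regions = NULL,
                               selection = NULL) {
  stopifnot(inherits(model, "structure_model"))
  if (n_points < 92L) stop("n_points must be at least 92")
  a <- model$atoms
  if (is.null(a$radius) || any(is.na(a$radius)))
    stop("typing error: atom radii missing; run assign_atom_types() first")
  xyz <- as.matrix(frame)
  if (nrow(xyz) != nrow(a)) stop("frame does not match model atom count")
  if (is.null(selection)) selection <- seq_len(nrow(a))
  rad <- a$radius + probe_radius
  pts <- .sphere_points(n_points)
  n <- nrow(xyz)
  per_atom <- rep(NA_real_, n)
  # neighbour lists via squared-distance test against the max reach
  for (i in selection) {
    ri <- rad[i]
    d2 <- colSums((t(xyz) - xyz[i, ])^2)
    nb <- which(d2 < (ri + rad)^2 & seq_len(n) != i)
    if (length(nb) == 0L) {
      per_atom[i] <- 4 * pi * ri^2
      next
    }
    sp <- pts * ri
    sp <- sweep(sp, 2, xyz[i, ], `+`)
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(exposed)) break
      dj2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
        (sp[, 3] - xyz[j, 3])^2
      exposed <- exposed & dj2 >= rad[j]^2   # strict-interior test
    }
    per_atom[i] <- sum(exposed) / n_points * 4 * pi * ri^2
  }
  out <- structure(list(per_atom = per_atom, region_totals = NULL,
                        probe_radius = probe_radius, n_points = n_points),
                   class = "sasa_result")
  if (!is.null(regions)) out$region_totals <- .sasa_region_totals(out, model, regions)
  out
}

.sasa_region_totals <- function(sasa, model, regions,
                                region_names = NULL) {
  if (is.null(region_names)) region_names <- names(regions)
  hydro <- model$atoms$hydro
  if (is.null(hydro) || any(is.na(hydro)))
    stop("typing error: hydrophobicity classes missing; run assign_atom_types()")
  rows <- lapply(region_names, function(nm) {
    idx <- select_region(model, regions, nm)
    area <- sasa$per_atom[idx]
    idx <- idx[!is.na(area)]; area <- area[!is.na(area)]
    data.frame(region = nm,
               hydrophobic = sum(area[hydro[idx] == "hydrophobic"]),
               hydrophilic = sum(area[hydro[idx] == "hydrophilic"]),
               total = sum(area), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("sasa_result: total %.1f A^2 (probe %.2f A, %d points/atom)\n",
              sum(x$per_atom, na.rm = TRUE), x$probe_radius, x$n_points))
  if (!is.null(x$region_totals)) print(x$region_totals)
  invisible(x)
}

# The paper-style report row order for CETP.
.table1_order <- c("N-end", "C-end", "Omega1", "Omega2", "Omega3",
                   "Omega4", "Omega5", "Omega6", "HelixX")

#' SASA alteration table against an initiating-conformation benchmark
#'
#' Signed fractional change per region and hydrophobicity class,
#' `(value - benchmark)/benchmark`, with the initiating conformation as
#' the benchmark.  Cells are stored as fractions (-0.13 corresponds to
#' prose "decreases by 13%"); [format()] renders either notation.
#'
#' @param benchmark,current `sasa_result` objects carrying region totals
#'   computed with the same model typing and region set
#' @return object of class `sasa_alteration_table` (data frame rows:
#'   region, hydrophobic, hydrophilic, total)
#' @export
sasa_alteration_table <- function(benchmark, current) {
  b <- benchmark$region_totals; c_ <- current$region_totals
  if (is.null(b) || is.null(c_))
    stop("both results must carry region totals (pass regions= to shrake_rupley_sasa)")
  if (!identical(b$region, c_$region))
    stop("benchmark and current were computed over different region sets")
  out <- b[, "region", drop = FALSE]
  for (col in c("hydrophobic", "hydrophilic", "total")) {
    if (any(b[[col]] <= 0))
      stop(sprintf("zero benchmark area in cell (%s, %s): fractional change undefined",
                   b$region[which(b[[col]] <= 0)[1]], col))
    out[[col]] <- (c_[[col]] - b[[col]]) / b[[col]]
  }
  class(out) <- c("sasa_alteration_table", "data.frame")
  out
}

#' @export
format.sasa_alteration_table <- function(x, percent = FALSE, ...) {
  y <- as.data.frame(x)
  for (col in c("hydrophobic", "hydrophilic", "total"))
    y[[col]] <- if (percent) sprintf("%+.0f%%", 100 * y[[col]])
                else sprintf("%+.2f", y[[col]])
  y
}

#' Write a SASA alteration table as TSV (paper row order)
#' @param table a `sasa_alteration_table`
#' @param path output file
#' @return invisible path
#' @export
write_alteration_tsv <- function(table, path) {
  y <- as.data.frame(table)
  first <- match(.table1_order, y$region)
  first <- first[!is.na(first)]
  rest <- setdiff(seq_len(nrow(y)), first)
  y <- y[c(first, rest), , drop = FALSE]
  utils::write.table(y, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Window-mean SASA region totals over an ensemble
#'
#' Convenience reducer: mean per-region totals over a frame window, for
#' use as benchmark/current when single representative frames are too
#' noisy.
#'
#' @param ensemble a `conf_ensemble` with typed topology
#' @param frames integer frame indices to average
#' @param regions a `region_set`
#' @param ... passed to [shrake_rupley_sasa()]
#' @return a `sasa_result` whose region totals are window means
#' @export
sasa_window_mean <- function(ensemble, frames, regions, ...) {
  res <- lapply(frames, function(i)
    shrake_rupley_sasa(ensemble$frames[[i]], ensemble$topology,
                       regions = regions, ...))
  out <- res[[1]]
  out$per_atom <- Reduce(`+`, lapply(res, `[[`, "per_atom")) / length(res)
  rt <- res[[1]]$region_totals
  for (col in c("hydrophobic", "hydrophilic", "total"))
    rt[[col]] <- Reduce(`+`, lapply(res, function(r) r$region_totals[[col]])) / length(res)
  out$region_totals <- rt
  out
}
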