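# ---- analysis configuration --------------------------------------------

#' Build an analysis configuration
#'
#' Flat, YAML-serializable configuration for [run_recipe()].  Defaults
#' encode the CETP analysis recipe: the three gate descriptors
#' (N-opening 106-162, C-opening 301-412, neck 265-433), the 10 Angstrom
#' passage threshold, water-probe SASA, the standard alpha-sphere window,
#' and PCA/DCCM on C-alpha atoms.
#'
#' @param input path to a multi-model PDB or XYZ trajectory (optional if
#'   an ensemble is passed to [run_recipe()] directly)
#' @param region_set "cetp" or a path to a YAML file of name: [first, last]
#' @param gates list of length-2 residue-id vectors
#' @param opening_threshold Angstrom (default 10)
#' @param atom_scope "all" or "heavy" for gate distances
#' @param sasa list(probe_radius, n_points)
#' @param cavity list(enabled, r_min, r_max, linkage_cutoff, min_volume,
#'   mc_samples)
#' @param do_pca,do_dccm logical toggles
#' @param energetics NULL, or list(receptor, ligand (index vectors),
#'   pqr, lj (paths or data frames), n_snapshots)
#' @param outdir output directory for the report bundle
#' @param seed integer seed used for all stochastic steps
#' @return object of class `analysis_config`
#' @export
analysis_config <- function(input = NULL, region_set = "cetp",
                            gates = list(c(106L, 162L), c(301L, 412L),
                                         c(265L, 433L)),
                            opening_threshold = 10, atom_scope = "all",
                            sasa = list(probe_radius = 1.4, n_points = 960L),
                            cavity = list(enabled = TRUE, r_min = 3.0,
                                          r_max = 6.0, linkage_cutoff = 4.5,
                                          min_volume = 100, mc_samples = 1e5),
                            do_pca = TRUE, do_dccm = TRUE,
                            energetics = NULL, outdir = tempfile("report"),
                            seed = 1L) {
  if (opening_threshold <= 0) stop("opening threshold must be positive")
  if (!is.null(input) && !file.exists(input))
    stop(sprintf("input file does not exist: %s", input))
  cfg <- list(input = input, region_set = region_set, gates = gates,
              opening_threshold = opening_threshold, atom_scope = atom_scope,
              sasa = sasa, cavity = cavity, do_pca = do_pca,
              do_dccm = do_dccm, energetics = energetics, outdir = outdir,
              seed = as.integer(seed))
  class(cfg) <- "analysis_config"
  cfg
}

#' Save / load an analysis configuration (YAML)
#' @param config an `analysis_config`
#' @param path YAML file
#' @return `save_config`: invisible path; `load_config`: `analysis_config`
#' @export
save_config <- function(config, path) {
  x <- unclass(config)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$gates <- lapply(x$gates, as.integer)
  do.call(analysis_config, x)
}

.load_region_set <- function(spec) {
  if (identical(spec, "cetp")) return(cetp_regions())
  if (inherits(spec, "region_set")) return(spec)
  region_set(yaml::read_yaml(spec))
}

.read_ensemble_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  obj <- if (ext == "xyz") read_xyz(path) else read_pdb(path)
  if (inherits(obj, "structure_model"))
    stop("input holds a single model; an ensemble (MODEL blocks) is required")
  obj
}

# ---- pipeline orchestration --------------------------------------------

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis recipe over one ensemble
#'
#' Executes, in order: structure/typing, geometric descriptors (gate
#' distances with opening flags, RMSD, Rg, per-residue RMSF, bend
#' angles), region SASA alteration (first frame as the initiating
#' benchmark, last frame as current), cavity detection, PCA/DCCM, and
#' optionally MM/GBSA when a partition is configured.  Writes every table
#' as TSV into `config$outdir` plus a run log echoing every effective
#' parameter and seed; reruns with identical config and inputs are
#' byte-identical (the log carries no timestamps).
#'
#' @param config an `analysis_config`
#' @param ensemble optional `conf_ensemble` (otherwise read from
#'   `config$input`)
#' @return object of class `report_bundle`: list of result objects and
#'   file paths
#' @export
run_recipe <- function(config, ensemble = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok && length(written) > 0) unlink(written), add = TRUE)
  emit <- function(fname, writer) {
    p <- file.path(outdir, fname)
    writer(p)
    written <<- c(written, p)
    p
  }
  log_lines <- c("# cetpdyn run log (no timestamps: reruns are byte-identical)",
                 sprintf("package_version: %s",
                         as.character(utils::packageVersion("cetpdyn"))),
                 sprintf("seed: %d", config$seed))

  ens <- .stage("structio", {
    e <- if (is.null(ensemble)) .read_ensemble_file(config$input) else ensemble
    e$topology <- assign_atom_types(e$topology)
    e
  })
  regions <- .stage("structio", .load_region_set(config$region_set))
  # outdir does not influence any result; keep it out of the logged
  # config so reruns into different directories stay byte-identical
  cfg_for_log <- unclass(config)
  cfg_for_log$outdir <- NULL
  cfg_yaml <- yaml::as.yaml(cfg_for_log)
  log_lines <- c(log_lines, sprintf("config_hash: %s", .fnv1a(cfg_yaml)),
                 sprintf("n_frames: %d", n_frames(ens)),
                 sprintf("n_atoms: %d", n_atoms(ens)),
                 "", "# effective parameters", strsplit(cfg_yaml, "\n")[[1]])

  bundle <- list(config = config)

  bundle$gates <- .stage("geometry", {
    lapply(config$gates, function(g) {
      s <- gate_distance_series(ens, g[1], g[2], atom_scope = config$atom_scope)
      attr(s, "open") <- gate_open_flags(s, config$opening_threshold)
      emit(sprintf("gate_%d-%d.tsv", g[1], g[2]),
           function(p) write_series_tsv(s, p))
      s
    })
  })
  bundle$rmsd <- .stage("geometry", {
    s <- rmsd_series(ens)
    emit("rmsd.tsv", function(p) write_series_tsv(s, p))
    s
  })
  bundle$rg <- .stage("geometry", {
    s <- rg_series(ens)
    emit("rg.tsv", function(p) write_series_tsv(s, p))
    s
  })
  bundle$rmsf <- .stage("geometry", {
    if (n_frames(ens) >= 2L) {
      r <- rmsf_per_residue(ens)
      emit("rmsf.tsv", function(p)
        utils::write.table(data.frame(resid = names(r), rmsf_A = r), p,
                           sep = "\t", quote = FALSE, row.names = FALSE))
      r
    } else NULL
  })
  bundle$bend <- .stage("geometry", {
    ok_regions <- all(c("N-domain", "C-domain", "HelixX") %in% names(regions))
    if (ok_regions) {
      b <- bend_angle_series(ens, regions)
      emit("bend_angles.tsv", function(p)
        utils::write.table(b, p, sep = "\t", quote = FALSE, row.names = FALSE))
      b
    } else NULL
  })

  bundle$sasa <- .stage("surface", {
    present <- names(regions)[vapply(names(regions), function(nm)
      length(select_region(ens$topology, regions, nm)) > 0, logical(1))]
    # fractional change needs a positive benchmark in every class; drop
    # regions without both atom classes (e.g. all-carbon pseudo-residues)
    if (length(present) > 0) {
      hydro <- ens$topology$atoms$hydro
      present <- present[vapply(present, function(nm) {
        idx <- select_region(ens$topology, regions, nm)
        all(c("hydrophobic", "hydrophilic") %in% hydro[idx])
      }, logical(1))]
    }
    if (length(present) == 0) NULL else {
      reg_sub <- regions[present]
      class(reg_sub) <- "region_set"
      bench <- shrake_rupley_sasa(ens$frames[[1]], ens$topology,
                                  probe_radius = config$sasa$probe_radius,
                                  n_points = config$sasa$n_points,
                                  regions = reg_sub)
      curr <- shrake_rupley_sasa(ens$frames[[n_frames(ens)]], ens$topology,
                                 probe_radius = config$sasa$probe_radius,
                                 n_points = config$sasa$n_points,
                                 regions = reg_sub)
      tab <- sasa_alteration_table(bench, curr)
      attr(tab, "benchmark_totals") <- bench$region_totals
      attr(tab, "current_totals") <- curr$region_totals
      emit("sasa_alterations.tsv", function(p) write_alteration_tsv(tab, p))
      tab
    }
  })

  if (isTRUE(config$cavity$enabled)) {
    bundle$cavity <- .stage("cavity", {
      s <- cavity_volume_series(ens, r_min = config$cavity$r_min,
                                r_max = config$cavity$r_max,
                                linkage_cutoff = config$cavity$linkage_cutoff,
                                min_volume = config$cavity$min_volume,
                                mc_samples = config$cavity$mc_samples,
                                seed = config$seed)
      emit("cavity.tsv", function(p) write_cavity_tsv(s, p))
      s
    })
  }

  if (isTRUE(config$do_pca) && n_frames(ens) >= 3L) {
    bundle$modes <- .stage("collective", {
      m <- pca_modes(ens)
      emit("modes.tsv", function(p)
        write_collective_tsv(modes = m, modes_path = p))
      emit("pc1_field.tsv", function(p)
        write_collective_tsv(modes = m, field_path = p))
      m
    })
  }
  if (isTRUE(config$do_dccm) && n_frames(ens) >= 2L) {
    bundle$dccm <- .stage("collective", {
      m <- dccm(ens)
      emit("dccm.tsv", function(p)
        write_collective_tsv(mat = m, dccm_path = p))
      m
    })
  }

  if (!is.null(config$energetics)) {
    bundle$gbsa <- .stage("energetics", {
      en <- config$energetics
      pqr <- if (is.character(en$pqr)) read_pqr_table(en$pqr) else en$pqr
      lj <- if (is.character(en$lj)) read_lj_table(en$lj) else en$lj
      ens$topology <- assign_atom_types(ens$topology, params = pqr)
      snaps <- if (!is.null(en$n_snapshots))
        snapshot_indices(n_frames(ens), en$n_snapshots) else NULL
      g <- mmgbsa(ens, receptor = en$receptor, ligand = en$ligand, lj = lj,
                  snapshots = snaps)
      emit("gbsa.tsv", function(p) write_gbsa_tsv(list(complex = g), p))
      g
    })
  }

  emit("run.log", function(p) writeLines(log_lines, p))
  bundle$paths <- written
  ok <- TRUE
  class(bundle) <- "report_bundle"
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("report_bundle: %d tables in %s\n", length(x$paths),
              x$config$outdir))
  cat(paste(" -", basename(x$paths)), sep = "\n")
  invisible(x)
}

#' Compare two ensembles sharing a region set
#'
#' Side-by-side descriptor series, per-region RMSF deltas, SASA
#' alteration tables per ensemble, and bend-angle deltas (b minus a,
#' matched on frame index).
#'
#' @param config an `analysis_config` (outdir is used for two
#'   sub-bundles, `a/` and `b/`)
#' @param ensemble_a,ensemble_b `conf_ensemble` objects over the same
#'   region set
#' @return object of class `comparison_report`
#' @export
compare_ensembles <- function(config, ensemble_a, ensemble_b) {
  regions <- .load_region_set(config$region_set)
  for (e in list(ensemble_a, ensemble_b)) {
    hit <- vapply(names(regions), function(nm)
      length(select_region(e$topology, regions, nm)) > 0, logical(1))
    if (!any(hit)) stop("ensembles do not populate the configured region set")
  }
  cfg_a <- config; cfg_a$outdir <- file.path(config$outdir, "a")
  cfg_b <- config; cfg_b$outdir <- file.path(config$outdir, "b")
  ba <- run_recipe(cfg_a, ensemble_a)
  bb <- run_recipe(cfg_b, ensemble_b)

  rmsf_delta <- NULL
  if (!is.null(ba$rmsf) && !is.null(bb$rmsf)) {
    ids <- intersect(names(ba$rmsf), names(bb$rmsf))
    per_res <- bb$rmsf[ids] - ba$rmsf[ids]
    reg_names <- names(regions)
    rmsf_delta <- do.call(rbind, lapply(reg_names, function(nm) {
      rng <- regions[[nm]]
      keep <- rep(FALSE, length(ids))
      for (r in seq_len(nrow(rng)))
        keep <- keep | (as.integer(ids) >= rng[r, 1] & as.integer(ids) <= rng[r, 2])
      if (!any(keep)) return(NULL)
      data.frame(region = nm, mean_rmsf_delta = mean(per_res[keep]))
    }))
  }
  bend_delta <- NULL
  if (!is.null(ba$bend) && !is.null(bb$bend)) {
    k <- min(nrow(ba$bend), nrow(bb$bend))
    bend_delta <- bb$bend[seq_len(k), -1] - ba$bend[seq_len(k), -1]
    bend_delta <- cbind(frame = seq_len(k), bend_delta)
  }
  gate_delta <- mapply(function(sa, sb) {
    k <- min(length(sa$values), length(sb$values))
    data.frame(frame = seq_len(k),
               delta = sb$values[seq_len(k)] - sa$values[seq_len(k)])
  }, ba$gates, bb$gates, SIMPLIFY = FALSE)

  structure(list(bundle_a = ba, bundle_b = bb, rmsf_delta = rmsf_delta,
                 bend_delta = bend_delta, gate_delta = gate_delta),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("comparison_report (b - a):\n")
  if (!is.null(x$rmsf_delta)) {
    cat("mean RMSF delta per region:\n")
    print(x$rmsf_delta)
  }
  invisible(x)
}
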