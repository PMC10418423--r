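# ---- domain containers -------------------------------------------------

#' Construct a structure model
#'
#' A `structure_model` holds an ordered atom table (one row per atom) plus a
#' residue index.  Coordinates are in Angstrom; residue numbering is the
#' author numbering of the source file (1-based, inclusive ranges
#' everywhere in this package).
#'
#' @param atoms data frame with columns `serial`, `name`, `altloc`,
#'   `resname`, `resid`, `chain`, `x`, `y`, `z`, `element`, `hetero`.
#'   Optional columns `radius`, `charge`, `hydro` are added by
#'   [assign_atom_types()].
#' @return object of class `structure_model`
#' @export
structure_model <- function(atoms) {
  required <- c("serial", "name", "resname", "resid", "chain",
                "x", "y", "z", "element", "hetero")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0L)
    stop("atom table lacks columns: ", paste(missing, collapse = ", "))
  if (nrow(atoms) == 0L) stop("structure model must contain at least one atom")
  if (!all(is.finite(atoms$x)) || !all(is.finite(atoms$y)) || !all(is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("structure_model: %d atoms, %d residues, chains [%s]%s\n",
              nrow(a), length(unique(paste(a$chain, a$resid))),
              paste(unique(a$chain), collapse = ","),
              if (any(a$hetero)) sprintf(", %d HETATM", sum(a$hetero)) else ""))
  invisible(x)
}

#' Number of atoms in a model or ensemble
#' @param x a `structure_model` or `conf_ensemble`
#' @return integer
#' @export
n_atoms <- function(x) {
  if (inherits(x, "conf_ensemble")) nrow(x$topology$atoms) else nrow(x$atoms)
}

#' Coordinate matrix of a model
#' @param model a `structure_model`
#' @return numeric matrix, n_atoms x 3 (Angstrom)
#' @export
coords <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  as.matrix(model$atoms[, c("x", "y", "z")])
}

#' Construct a conformational ensemble
#'
#' Ordered frames over a fixed topology.  Every frame must have the same
#' atom count as the topology; times (ns) must be strictly increasing.
#'
#' @param topology a `structure_model`
#' @param frames list of n_atoms x 3 coordinate matrices (Angstrom)
#' @param times numeric vector of frame times in ns (default 0,1,2,...)
#' @return object of class `conf_ensemble`
#' @export
conf_ensemble <- function(topology, frames, times = NULL) {
  stopifnot(inherits(topology, "structure_model"))
  if (length(frames) < 1L) stop("ensemble needs at least one frame")
  na <- nrow(topology$atoms)
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!is.matrix(f) || ncol(f) != 3L || nrow(f) != na)
      stop(sprintf("frame %d does not match topology (%d atoms expected)", i, na))
    if (!all(is.finite(f))) stop(sprintf("frame %d has non-finite coordinates", i))
  }
  if (is.null(times)) times <- as.numeric(seq_along(frames) - 1L)
  if (length(times) != length(frames)) stop("times must match frame count")
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  structure(list(topology = topology, frames = frames, times = as.numeric(times)),
            class = "conf_ensemble")
}

#' @export
print.conf_ensemble <- function(x, ...) {
  cat(sprintf("conf_ensemble: %d frames x %d atoms, t = %.3g..%.3g ns\n",
              length(x$frames), n_atoms(x), x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble a `conf_ensemble`
#' @return integer
#' @export
n_frames <- function(ensemble) length(ensemble$frames)

# ---- PDB parsing -------------------------------------------------------

.parse_pdb_coord <- function(field, lineno, what) {
  v <- suppressWarnings(as.numeric(field))
  if (any(is.na(v)))
    stop(sprintf("PDB format error at line %d: unparseable %s field '%s'",
                 lineno[which(is.na(v))[1]], what, field[which(is.na(v))[1]]))
  v
}

.parse_atom_lines <- function(lines, linenos) {
  pad <- function(s, n) formatC(s, width = -n)
  lines <- vapply(lines, function(l) if (nchar(l) < 80) pad(l, 80) else l, "",
                  USE.NAMES = FALSE)
  rec <- substr(lines, 1, 6)
  name <- trimws(substr(lines, 13, 16))
  altloc <- substr(lines, 17, 17)
  element <- trimws(substr(lines, 77, 78))
  # fall back to the atom-name convention when the element column is blank
  blank <- element == ""
  if (any(blank)) {
    guess <- sub("^[0-9]*", "", name[blank])
    element[blank] <- toupper(substr(guess, 1, 1))
  }
  data.frame(
    serial  = as.integer(.parse_pdb_coord(substr(lines, 7, 11), linenos, "serial")),
    name    = name,
    altloc  = altloc,
    resname = trimws(substr(lines, 18, 20)),
    chain   = substr(lines, 22, 22),
    resid   = as.integer(.parse_pdb_coord(substr(lines, 23, 26), linenos, "residue id")),
    x = .parse_pdb_coord(substr(lines, 31, 38), linenos, "x"),
    y = .parse_pdb_coord(substr(lines, 39, 46), linenos, "y"),
    z = .parse_pdb_coord(substr(lines, 47, 54), linenos, "z"),
    element = toupper(element),
    hetero  = rec == "HETATM",
    stringsAsFactors = FALSE)
}

#' Read a PDB file or PDB-format text
#'
#' Parses ATOM/HETATM/MODEL/ENDMDL/TER records.  Without MODEL records the
#' result is a single [structure_model()]; with MODEL blocks it is a
#' [conf_ensemble()] with one frame per block (all blocks must agree in
#' atom count and order).  Alternate locations: only blank or 'A' altloc
#' conformers are kept.  HETATM records are parsed and flagged but dropped
#' by default, matching the usual preparation of apo trajectories; set
#' `keep_hetero = TRUE` for ligand-bound structures.
#'
#' @param text character: either a path to a PDB file or PDB-format text
#'   (single string with newlines, or a character vector of lines)
#' @param keep_hetero logical, keep HETATM records (default FALSE)
#' @param times optional frame times (ns) for multi-model input
#' @return `structure_model` or `conf_ensemble`
#' @export
read_pdb <- function(text, keep_hetero = FALSE, times = NULL) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  rec <- substr(text, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM") |
    substr(rec, 1, 4) == "ATOM" & nchar(trimws(rec)) == 4
  is_model <- substr(rec, 1, 5) == "MODEL"
  is_end <- substr(rec, 1, 6) == "ENDMDL"
  if (!any(is_atom)) stop("no ATOM/HETATM records found")

  model_id <- cumsum(is_model)
  if (!any(is_model)) {
    atoms <- .parse_atom_lines(text[is_atom], which(is_atom))
    atoms <- .filter_altloc(atoms)
    if (!keep_hetero) atoms <- atoms[!atoms$hetero, , drop = FALSE]
    if (nrow(atoms) == 0L) stop("no atoms left after HETATM/altloc filtering")
    return(structure_model(atoms))
  }

  ids <- sort(unique(model_id[is_atom & model_id > 0L]))
  frames <- vector("list", length(ids))
  topo <- NULL
  for (k in seq_along(ids)) {
    sel <- is_atom & model_id == ids[k]
    atoms <- .parse_atom_lines(text[sel], which(sel))
    atoms <- .filter_altloc(atoms)
    if (!keep_hetero) atoms <- atoms[!atoms$hetero, , drop = FALSE]
    if (is.null(topo)) {
      topo <- atoms
    } else if (nrow(atoms) != nrow(topo)) {
      stop(sprintf("topology mismatch: MODEL block %d has %d atoms, expected %d",
                   k, nrow(atoms), nrow(topo)))
    }
    frames[[k]] <- as.matrix(atoms[, c("x", "y", "z")])
    dimnames(frames[[k]]) <- NULL
  }
  conf_ensemble(structure_model(topo), frames, times = times)
}

.filter_altloc <- function(atoms) {
  if (!"altloc" %in% names(atoms)) return(atoms)
  atoms[atoms$altloc %in% c(" ", "", "A"), , drop = FALSE]
}

#' Write a structure model as PDB-format text
#'
#' @param model a `structure_model`
#' @param path optional output file; if NULL the text is returned
#' @return character vector of PDB lines (invisibly when `path` given)
#' @export
write_pdb <- function(model, path = NULL) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  if (nrow(a) == 0L) stop("cannot write an empty model")
  xyz <- coords(model)
  if (any(abs(xyz) >= 10000))
    stop("coordinate overflow: |value| >= 10000 does not fit the PDB %8.3f field")
  name4 <- ifelse(nchar(a$name) >= 4, substr(a$name, 1, 4),
                  sprintf(" %-3s", a$name))
  lines <- sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   ifelse(a$hetero, "HETATM", "ATOM"),
                   a$serial %% 100000L, name4,
                   if (!is.null(a$altloc)) a$altloc else " ",
                   a$resname, a$chain, a$resid %% 10000L,
                   a$x, a$y, a$z, 1.00, 0.00, a$element)
  lines <- c(lines, "END")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Write an ensemble as multi-model PDB text
#' @param ensemble a `conf_ensemble`
#' @param path optional output file
#' @return character vector of PDB lines
#' @export
write_pdb_ensemble <- function(ensemble, path = NULL) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  out <- character(0)
  m <- ensemble$topology
  for (i in seq_along(ensemble$frames)) {
    m$atoms[, c("x", "y", "z")] <- ensemble$frames[[i]]
    body <- write_pdb(m)
    body <- body[body != "END"]
    out <- c(out, sprintf("MODEL     %4d", i), body, "ENDMDL")
  }
  out <- c(out, "END")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

# ---- XYZ trajectories --------------------------------------------------

#' Read a plain XYZ trajectory
#'
#' Standard XYZ blocks: atom count line, comment line (parsed for
#' `t= <ns>` if present), then `element x y z` rows.  Residues are not
#' encoded in XYZ; each atom becomes a one-atom residue.
#'
#' @param text path or text (as in [read_pdb()])
#' @return `conf_ensemble`
#' @export
read_xyz <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  i <- 1L; frames <- list(); times <- numeric(0); topo <- NULL
  while (i <= length(text)) {
    if (trimws(text[i]) == "") { i <- i + 1L; next }
    na <- suppressWarnings(as.integer(trimws(text[i])))
    if (is.na(na)) stop(sprintf("XYZ format error at line %d: expected atom count", i))
    comment <- text[i + 1L]
    tm <- regmatches(comment, regexpr("t\\s*=\\s*[-0-9.eE+]+", comment))
    t_val <- if (length(tm) == 1L)
      as.numeric(sub("t\\s*=\\s*", "", tm)) else length(frames)
    rows <- text[(i + 2L):(i + 1L + na)]
    parts <- strsplit(trimws(rows), "\\s+")
    bad <- which(vapply(parts, length, 1L) < 4L)
    if (length(bad) > 0L)
      stop(sprintf("XYZ format error at line %d", i + 1L + bad[1]))
    el <- toupper(vapply(parts, `[[`, "", 1L))
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(is.na(xyz))) stop("XYZ format error: non-numeric coordinate")
    if (is.null(topo)) {
      topo <- structure_model(data.frame(
        serial = seq_len(na), name = el, altloc = " ",
        resname = "UNK", chain = "A", resid = seq_len(na),
        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
        element = el, hetero = FALSE, stringsAsFactors = FALSE))
    } else if (na != n_atoms(topo)) {
      stop("XYZ topology mismatch between frames")
    }
    frames[[length(frames) + 1L]] <- xyz
    times <- c(times, t_val)
    i <- i + 2L + na
  }
  conf_ensemble(topo, frames, times = times)
}

# ---- atom typing -------------------------------------------------------

# Bondi van der Waals radii (Angstrom) and an element-level hydrophobicity
# rule: carbon and sulfur hydrophobic; N, O, P hydrophilic; halogens
# hydrophobic; hydrogens inherit the class of the nearest heavy atom
# (proxy for the covalent partner -- bond perception is out of scope).
.vdw_table <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90)
.hydro_table <- c(C = "hydrophobic", S = "hydrophobic",
                  N = "hydrophilic", O = "hydrophilic", P = "hydrophilic",
                  F = "hydrophobic", CL = "hydrophobic", BR = "hydrophobic",
                  I = "hydrophobic", SE = "hydrophobic")

#' Assign radii, hydrophobicity classes and optional charges
#'
#' Applies the default typing rule: Bondi van der Waals radii per element,
#' atom-level hydrophobicity (C/S and halogens hydrophobic; N/O/P
#' hydrophilic; H takes the class of its nearest heavy atom).  Charges and
#' radius overrides come only from an explicit PQR-style parameter table
#' (`serial charge radius`); the package never guesses force-field charges.
#'
#' @param model a `structure_model`
#' @param params optional data frame with columns `serial`, `charge`,
#'   `radius` (see [read_pqr_table()])
#' @return the model with `radius`, `hydro` (and possibly `charge`) columns
#' @export
assign_atom_types <- function(model, params = NULL) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  el <- toupper(a$element)
  unknown <- setdiff(unique(el), names(.vdw_table))
  if (length(unknown) > 0L) {
    idx <- which(el %in% unknown)[1]
    stop(sprintf("typing error: unknown element '%s' (atom serial %d, %s %s%d)",
                 el[idx], a$serial[idx], a$name[idx], a$resname[idx], a$resid[idx]))
  }
  a$radius <- unname(.vdw_table[el])
  a$hydro <- unname(.hydro_table[el])
  h <- which(el == "H")
  if (length(h) > 0L) {
    heavy <- which(el != "H")
    if (length(heavy) == 0L) {
      a$hydro[h] <- "hydrophilic"
    } else {
      hx <- as.matrix(a[h, c("x", "y", "z")])
      hv <- as.matrix(a[heavy, c("x", "y", "z")])
      for (k in seq_along(h)) {
        d2 <- colSums((t(hv) - hx[k, ])^2)
        a$hydro[h[k]] <- a$hydro[heavy[which.min(d2)]]
      }
    }
  }
  if (!is.null(params)) {
    m <- match(a$serial, params$serial)
    hit <- !is.na(m)
    a$charge <- NA_real_
    a$charge[hit] <- params$charge[m[hit]]
    if ("radius" %in% names(params)) {
      r <- params$radius[m[hit]]
      ok <- !is.na(r)
      a$radius[hit][ok] <- r[ok]
    }
    if (any(!is.na(a$radius) & a$radius <= 0))
      stop("typing error: non-positive radius in parameter table")
  }
  model$atoms <- a
  model
}

#' Read a PQR-style parameter table
#'
#' Whitespace-separated columns: atom serial, charge (e), radius (Angstrom).
#' @param path file path or character vector of lines
#' @return data frame with columns serial, charge, radius
#' @export
read_pqr_table <- function(path) {
  df <- utils::read.table(path, header = FALSE, col.names = c("serial", "charge", "radius"))
  df$serial <- as.integer(df$serial)
  df
}

#' Read a Lennard-Jones parameter table
#'
#' Whitespace/tab-separated columns: atom serial, sigma (Angstrom),
#' epsilon (kcal/mol).
#' @param path file path or character vector of lines
#' @return data frame with columns serial, sigma, epsilon
#' @export
read_lj_table <- function(path) {
  df <- utils::read.table(path, header = FALSE, col.names = c("serial", "sigma", "epsilon"))
  df$serial <- as.integer(df$serial)
  df
}

#' Drop HETATM atoms from a model
#' @param model a `structure_model`
#' @return model without hetero atoms
#' @export
strip_hetero <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  model$atoms <- model$atoms[!model$atoms$hetero, , drop = FALSE]
  if (nrow(model$atoms) == 0L) stop("no atoms left after removing HETATM records")
  rownames(model$atoms) <- NULL
  model
}

# ---- region registry ---------------------------------------------------

#' Build a region set
#'
#' A region set maps names to inclusive residue-id ranges.  Composite
#' regions are unions of ranges.  Ranges are given as a list whose elements
#' are 2-column matrices (first, last) or length-2 vectors.
#'
#' @param regions named list of ranges
#' @return object of class `region_set`
#' @export
region_set <- function(regions) {
  out <- lapply(regions, function(r) {
    m <- if (is.matrix(r)) r else matrix(as.integer(r), ncol = 2, byrow = TRUE)
    storage.mode(m) <- "integer"
    colnames(m) <- c("first", "last")
    if (any(m[, 2] < m[, 1])) stop("region range with last < first")
    m
  })
  structure(out, class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  for (nm in names(x)) {
    cat(sprintf("%-8s %s\n", nm,
                paste(apply(x[[nm]], 1, function(r) sprintf("%d-%d", r[1], r[2])),
                      collapse = ", ")))
  }
  invisible(x)
}

#' The CETP flexible-region registry
#'
#' Named residue ranges of the seven flexible regions of CETP plus the
#' composite barrel ends and the domain split used for bend angles:
#' Omega1 290-318, Omega2 351-358, Omega3 392-404 (C-terminal end),
#' Omega4 46-55, Omega5 100-111, Omega6 155-162 (N-terminal end),
#' HelixX 465-476.  "N-end" is the union of Omega4-6, "C-end" of
#' Omega1-3.  "N-domain" (1-240) and "C-domain" (241-464) are this
#' package's convention for the two beta-barrel domains used in
#' [domain_bend_angles()].  Greek-letter aliases ("Ω1" ...) are
#' registered alongside the ASCII names.
#'
#' @return a `region_set`
#' @export
cetp_regions <- function() {
  base <- list(
    Omega1 = c(290L, 318L), Omega2 = c(351L, 358L), Omega3 = c(392L, 404L),
    Omega4 = c(46L, 55L),   Omega5 = c(100L, 111L), Omega6 = c(155L, 162L),
    HelixX = c(465L, 476L),
    `N-end` = matrix(c(46L, 55L, 100L, 111L, 155L, 162L), ncol = 2, byrow = TRUE),
    `C-end` = matrix(c(290L, 318L, 351L, 358L, 392L, 404L), ncol = 2, byrow = TRUE),
    `N-domain` = c(1L, 240L), `C-domain` = c(241L, 464L))
  rs <- region_set(base)
  for (i in 1:6) rs[[paste0("Ω", i)]] <- rs[[paste0("Omega", i)]]
  rs[["Helix X"]] <- rs[["HelixX"]]
  class(rs) <- "region_set"
  rs
}

#' Select the atoms of a named region
#'
#' Returns the indices (row numbers in the atom table) of all atoms whose
#' residue id falls inside the region's inclusive range(s).
#'
#' @param model a `structure_model`
#' @param regions a `region_set`
#' @param name region name
#' @return integer vector of atom indices
#' @export
select_region <- function(model, regions, name) {
  stopifnot(inherits(model, "structure_model"), inherits(regions, "region_set"))
  if (!name %in% names(regions))
    stop(sprintf("unknown region '%s' (known: %s)", name,
                 paste(names(regions), collapse = ", ")))
  rng <- regions[[name]]
  resid <- model$atoms$resid
  keep <- rep(FALSE, length(resid))
  for (r in seq_len(nrow(rng)))
    keep <- keep | (resid >= rng[r, 1] & resid <= rng[r, 2])
  which(keep)
}

#' Select atoms by name over the whole model or a residue subset
#' @param model a `structure_model`
#' @param atom_names character vector of atom names (e.g. `c("CA")`)
#' @param within optional atom-index subset to intersect with
#' @return integer vector of atom indices
#' @export
select_atoms <- function(model, atom_names, within = NULL) {
  idx <- which(model$atoms$name %in% atom_names)
  if (!is.null(within)) idx <- intersect(idx, within)
  idx
}
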