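# ---- essential dynamics (C-alpha PCA) ----------------------------------

# Superpose all frames onto the iteratively refined mean over `selection`
# (fit = TRUE) and return the n_frames x 3N matrix of selected
# coordinates.  fit = FALSE takes the frames as already sharing a common
# reference frame (synthetic ensembles generated in the lab frame).
.fitted_matrix <- function(ensemble, selection, iterations = 2L, fit = TRUE) {
  if (fit) {
    f2 <- .iterative_mean_fit(ensemble, selection, iterations = iterations)
    frames <- f2$frames
    mn <- f2$mean
  } else {
    frames <- lapply(ensemble$frames, function(f) f[selection, , drop = FALSE])
    mn <- Reduce(`+`, frames) / length(frames)
  }
  X <- t(vapply(frames, function(f) as.vector(t(f)),
                numeric(3L * length(selection))))
  list(X = X, mean = mn)
}

#' Principal component analysis of C-alpha fluctuations
#'
#' Eigendecomposition of the 3N x 3N covariance matrix of C-alpha
#' positional fluctuations after iterative mean-structure superposition
#' (2 passes).  Eigenvector signs follow the convention that the
#' largest-magnitude component of each mode is positive (mode signs are
#' otherwise arbitrary, so arrow directions in vector-field plots are
#' convention-dependent).
#'
#' @param ensemble a `conf_ensemble`
#' @param selection atom indices (default: all C-alpha atoms)
#' @param fit superpose frames to the iterative mean first (default TRUE;
#'   set FALSE for ensembles already in a common reference frame)
#' @return object of class `collective_modes`: list with `mean_structure`
#'   (N x 3), `eigenvalues` (Angstrom^2, descending), `eigenvectors`
#'   (3N x 3N, orthonormal columns), `variance_fraction`, `selection`
#' @export
pca_modes <- function(ensemble, selection = NULL, fit = TRUE) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  if (n_frames(ensemble) < 3L) stop("PCA needs at least 3 frames")
  if (is.null(selection)) selection <- .calpha_idx(ensemble$topology)
  if (length(selection) == 0L) stop("empty selection")
  fm <- .fitted_matrix(ensemble, selection, fit = fit)
  X <- sweep(fm$X, 2, colMeans(fm$X))
  C <- crossprod(X) / (nrow(X) - 1L)
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  vecs <- e$vectors
  for (k in seq_len(ncol(vecs))) {
    j <- which.max(abs(vecs[, k]))
    if (vecs[j, k] < 0) vecs[, k] <- -vecs[, k]
  }
  structure(list(mean_structure = fm$mean,
                 eigenvalues = vals,
                 eigenvectors = vecs,
                 variance_fraction = vals / sum(vals),
                 selection = selection,
                 trace = sum(diag(C))),
            class = "collective_modes")
}

#' @export
print.collective_modes <- function(x, ...) {
  cat(sprintf("collective_modes: %d modes; PC1 %.1f%%, PC2 %.1f%%, PC3 %.1f%% of variance\n",
              length(x$eigenvalues),
              100 * x$variance_fraction[1], 100 * x$variance_fraction[2],
              100 * x$variance_fraction[3]))
  invisible(x)
}

#' Porcupine vector field of a mode
#'
#' Per-atom displacement vectors of one principal component, scaled and
#' anchored at the mean structure; the raw material of "porcupine"
#' renderings of the dominant collective motion.
#'
#' @param modes a `collective_modes` object
#' @param mode_index which mode (1 = PC1)
#' @param scale multiplier applied to the unit eigenvector
#' @return data frame: x, y, z (anchor, mean structure), dx, dy, dz
#' @export
porcupine_field <- function(modes, mode_index = 1L, scale = 1) {
  stopifnot(inherits(modes, "collective_modes"))
  if (mode_index < 1L || mode_index > ncol(modes$eigenvectors))
    stop(sprintf("mode index %d out of range (1..%d)", mode_index,
                 ncol(modes$eigenvectors)))
  v <- matrix(modes$eigenvectors[, mode_index], ncol = 3, byrow = TRUE) * scale
  data.frame(x = modes$mean_structure[, 1], y = modes$mean_structure[, 2],
             z = modes$mean_structure[, 3],
             dx = v[, 1], dy = v[, 2], dz = v[, 3])
}

# ---- dynamic cross-correlation matrix ----------------------------------

#' Dynamic cross-correlation matrix
#'
#' Isotropic (scalar-product) cross-correlations of positional
#' fluctuations over superposed frames:
#' `C_ij = <dr_i . dr_j> / sqrt(<dr_i^2><dr_j^2>)`, values in [-1, 1],
#' diagonal exactly 1.  Positive values mark correlated residue motions,
#' negative values anti-correlated ones.
#'
#' @param ensemble a `conf_ensemble`
#' @param selection atom indices (default: all C-alpha atoms)
#' @param fit superpose frames first (default TRUE; see [pca_modes()])
#' @return object of class `dccm_matrix` (square symmetric matrix with
#'   residue ids as dimnames)
#' @export
dccm <- function(ensemble, selection = NULL, fit = TRUE) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  if (n_frames(ensemble) < 2L) stop("DCCM needs at least 2 frames")
  if (is.null(selection)) selection <- .calpha_idx(ensemble$topology)
  if (length(selection) == 0L) stop("empty selection")
  fm <- .fitted_matrix(ensemble, selection, fit = fit)
  X <- sweep(fm$X, 2, colMeans(fm$X))   # n_frames x 3N fluctuations
  n <- length(selection)
  # <dr_i . dr_j> = sum over the 3 coordinate blocks of covariances
  ix <- seq(1L, 3L * n, by = 3L)
  S <- matrix(0, n, n)
  for (d in 0:2) {
    Xi <- X[, ix + d, drop = FALSE]
    S <- S + crossprod(Xi) / nrow(X)
  }
  v <- diag(S)
  zero <- which(v <= 0 | v < 1e-300)
  if (length(zero) > 0L) {
    resid <- ensemble$topology$atoms$resid[selection[zero[1]]]
    stop(sprintf("undefined correlation: zero-variance atom at residue %d", resid))
  }
  M <- S / sqrt(outer(v, v))
  M <- (M + t(M)) / 2
  M[M > 1] <- 1; M[M < -1] <- -1
  diag(M) <- 1
  resids <- ensemble$topology$atoms$resid[selection]
  dimnames(M) <- list(resids, resids)
  class(M) <- c("dccm_matrix", "matrix")
  M
}

#' Mean cross-correlation between two atom groups
#' @param mat a `dccm_matrix`
#' @param idx_a,idx_b indices into the DCCM selection (rows/cols)
#' @return mean of `mat[idx_a, idx_b]`
#' @export
dccm_block_mean <- function(mat, idx_a, idx_b) {
  mean(unclass(mat)[idx_a, idx_b])
}

#' Write modes and DCCM reports as TSV
#' @param modes a `collective_modes`
#' @param mat a `dccm_matrix`
#' @param modes_path,field_path,dccm_path output files (NULL to skip)
#' @param n_modes number of modes to tabulate
#' @return invisible NULL
#' @export
write_collective_tsv <- function(modes = NULL, mat = NULL,
                                 modes_path = NULL, field_path = NULL,
                                 dccm_path = NULL, n_modes = 10L) {
  if (!is.null(modes) && !is.null(modes_path)) {
    k <- min(n_modes, length(modes$eigenvalues))
    utils::write.table(
      data.frame(mode = seq_len(k),
                 eigenvalue_A2 = modes$eigenvalues[seq_len(k)],
                 variance_fraction = modes$variance_fraction[seq_len(k)]),
      modes_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(modes) && !is.null(field_path))
    utils::write.table(porcupine_field(modes, 1L, 1), field_path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(mat) && !is.null(dccm_path)) {
    con <- file(dccm_path, "w")
    on.exit(close(con))
    writeLines("# DCCM (isotropic scalar-product convention)", con)
    utils::write.table(as.data.frame(unclass(mat)), con, sep = "\t",
                       quote = FALSE, row.names = TRUE, col.names = NA)
  }
  invisible(NULL)
}
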