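# Shared in-code fixtures; everything is generated at test time.

# Minimal atom table -> structure_model with typing applied.
toy_model <- function(xyz, element = "C", name = NULL, resid = NULL,
                      typed = TRUE) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (is.null(name)) name <- rep("CA", n)
  if (is.null(resid)) resid <- seq_len(n)
  m <- structure_model(data.frame(
    serial = seq_len(n), name = name, altloc = " ", resname = "UNK",
    resid = as.integer(resid), chain = "A",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    element = rep(element, length.out = n), hetero = FALSE,
    stringsAsFactors = FALSE))
  if (typed) assign_atom_types(m) else m
}

# A 3-atom PDB text block used for parser round-trips.
toy_pdb_text <- function() {
  paste(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      10.566   5.568  -4.195  1.00  0.00           C",
    "END", sep = "\n")
}

# Random rotation matrix from a seeded quaternion.
random_rotation <- function(seed) {
  q <- cetpdyn:::with_preserved_seed(seed, stats::rnorm(4))
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

# Breathing-cube ensemble: 8 atoms at cube corners, each displaced
# radially by amp*f(t); no net translation/rotation, so rigid fitting is
# the identity and per-atom fluctuations are purely radial.
breathing_cube <- function(radial_offsets) {
  corners <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) * 2
  u <- corners / sqrt(rowSums(corners^2))
  frames <- lapply(radial_offsets, function(a) corners + a * u)
  conf_ensemble(toy_model(corners), frames)
}

expect_series_equal <- function(s, values, tol = 1e-8) {
  expect_s3_class(s, "descriptor_series")
  expect_equal(s$values, values, tolerance = tol)
}
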