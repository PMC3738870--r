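# Deterministic fixtures built in code.

# Planar zigzag chain: every consecutive distance == spacing, every interior
# vertex angle == angle (degrees). Protein-like for spacing 3.8, angle in
# (70, 120); clash-free since the chain marches monotonically along x.
zigzagChain <- function(n, spacing = 3.8, angle = 100) {
  half <- (180 - angle) / 2 * pi / 180
  dirA <- c(cos(half), sin(half), 0)
  dirB <- c(cos(half), -sin(half), 0)
  xyz <- matrix(0, n, 3)
  for (j in 2:n)
    xyz[j, ] <- xyz[j - 1, ] + spacing * (if (j %% 2 == 0) dirA else dirB)
  CaTrace(xyz)
}

# Hand-written three-residue PDB with CAs at (0,0,0), (3.8,0,0), (7.6,0,0),
# plus N atoms and a HETATM CA that the reader must ignore.
threeResiduePdb <- function() c(
  "HEADER    SYNTHETIC FIXTURE",
  "ATOM      1  N   ALA A   1      -1.000   0.500   0.000  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
  "ATOM      3  N   GLY A   2       3.000   0.500   0.000  1.00  0.00           N",
  "ATOM      4  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
  "ATOM      5  CA  SER A   3       7.600   0.000   0.000  1.00  0.00           C",
  "HETATM    6  CA  MSE A   4      11.400   0.000   0.000  1.00  0.00           C",
  "END")

# Same chain but residue 2 has two alternate CA locations (B listed first).
altlocPdb <- function() c(
  "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
  "ATOM      2  CA BGLY A   2       3.800   0.000   0.000  0.50  0.00           C",
  "ATOM      3  CA AGLY A   2       3.900   0.100   0.000  0.50  0.00           C",
  "ATOM      4  CA  SER A   3       7.600   0.000   0.000  1.00  0.00           C",
  "END")

# Random tiny instance for oracle comparisons: points with spacings drawn
# around the feasible window so instances mix feasible and infeasible.
randomTinyInstance <- function(n) {
  sp <- stats::runif(n - 1, 3.5, 4.2)
  xyz <- matrix(0, n, 3)
  for (j in 2:n) {
    dir <- stats::rnorm(3)
    xyz[j, ] <- xyz[j - 1, ] + sp[j - 1] * dir / sqrt(sum(dir^2))
  }
  be <- stats::runif(n - 1) < 0.15
  ba <- c(TRUE, if (n > 2) (be[-(n - 1)] | be[-1]) else NULL, TRUE)[1:n]
  list(points = xyz, brokenEdge = be, brokenAngle = ba)
}

randomRotation <- function() {
  axis <- stats::rnorm(3)
  axis <- axis / sqrt(sum(axis^2))
  th <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
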