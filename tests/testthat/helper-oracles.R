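# Independent oracles used to cross-check the package implementations.

# Quaternion (QCP) RMSD: eigenvalue of the 4x4 key matrix. Independent of
# the SVD-based Kabsch implementation in the package.
qcp_rmsd <- function(mobile, reference) {
  n <- nrow(mobile)
  pm <- scale(mobile, scale = FALSE)
  pr <- scale(reference, scale = FALSE)
  m <- t(pm) %*% pr
  s <- function(i, j) m[i, j]
  f <- matrix(c(
    s(1,1)+s(2,2)+s(3,3), s(2,3)-s(3,2),        s(3,1)-s(1,3),        s(1,2)-s(2,1),
    s(2,3)-s(3,2),        s(1,1)-s(2,2)-s(3,3), s(1,2)+s(2,1),        s(3,1)+s(1,3),
    s(3,1)-s(1,3),        s(1,2)+s(2,1),       -s(1,1)+s(2,2)-s(3,3), s(2,3)+s(3,2),
    s(1,2)-s(2,1),        s(3,1)+s(1,3),        s(2,3)+s(3,2),       -s(1,1)-s(2,2)+s(3,3)),
    4, 4, byrow = TRUE)
  lambda <- max(eigen(f, symmetric = TRUE, only.values = TRUE)$values)
  g <- sum(pm^2) + sum(pr^2)
  sqrt(max(0, (g - 2 * lambda) / n))
}

# Random rigid transform (rotation with det +1, translation)
random_rigid <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  r <- matrix(c(
    1-2*(q[3]^2+q[4]^2), 2*(q[2]*q[3]-q[1]*q[4]), 2*(q[2]*q[4]+q[1]*q[3]),
    2*(q[2]*q[3]+q[1]*q[4]), 1-2*(q[2]^2+q[4]^2), 2*(q[3]*q[4]-q[1]*q[2]),
    2*(q[2]*q[4]-q[1]*q[3]), 2*(q[3]*q[4]+q[1]*q[2]), 1-2*(q[2]^2+q[3]^2)),
    3, 3, byrow = TRUE)
  list(rot = r, trans = rnorm(3, 0, 10))
}

apply_rigid <- function(x, rt) sweep(as.matrix(x) %*% t(rt$rot), 2, rt$trans, `+`)

rigid_monomer <- function(mon, rt) {
  transform_monomer(mon, rotation = t(rt$rot), translation = rt$trans)
}

# Reference DSSP assignment through mdtraj (independent Kabsch-Sander
# implementation); returns per-residue codes, or NULL if unavailable.
mdtraj_dssp <- function(pdb_path) {
  py <- Sys.which("python")
  if (py == "") return(NULL)
  script <- sprintf(
    "import mdtraj; t = mdtraj.load_pdb(%s); print(','.join(mdtraj.compute_dssp(t, simplified=False)[0]))",
    shQuote(pdb_path))
  out <- tryCatch(suppressWarnings(system2(py, c("-c", shQuote(script)),
                                           stdout = TRUE, stderr = FALSE)),
                  error = function(e) NULL)
  if (is.null(out) || !length(out)) return(NULL)
  strsplit(out[length(out)], ",")[[1]]
}

# build a single-chain fixture monomer (second chain parked far away so
# inter-chain terms cannot interfere)
helix_fixture <- function(n = 12, phi = -57, psi = -47, seq_a = NULL) {
  if (is.null(seq_a)) seq_a <- strrep("A", n)
  at <- build_backbone(seq_a, rep(phi, n), rep(psi, n), chain = "A")
  b <- build_backbone(strrep("A", 30), rep(-120, 30), rep(135, 30), chain = "B")
  b$x <- b$x + 100
  insulin_monomer(rbind(at, b))
}
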