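# Shared fixtures built in code at test time.

# tiny hand-written PDB text, 3 atoms
toy_pdb_lines <- function() {
  c("REMARK toy fixture",
    "ATOM      1  CA  ALA A  80       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A  81       4.500  -1.250   0.000  1.00  0.00           C",
    "ATOM      3  CB  GLY A  81       2.000   2.000   2.000  1.00  0.00           C",
    "TER",
    "END")
}

write_tmp_pdb <- function(lines, envir = parent.frame()) {
  f <- withr::local_tempfile(fileext = ".pdb", .local_envir = envir)
  writeLines(lines, f)
  f
}

# wrap a structure's coordinates in a 1-frame (or n-frame) trajectory
as_traj <- function(structure, nframes = 1L, timeStep = 0.1) {
  xyz <- as.vector(t(coords(structure)))
  MolTrajectory(structure, matrix(rep(xyz, nframes), nrow = nframes,
                                  byrow = TRUE), timeStep = timeStep)
}

# random uniform rotation matrix (quaternion method), local RNG
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

apply_rigid <- function(xyz, R, t) sweep(xyz %*% t(R), 2, t, "+")

# apply one global rigid motion to every frame of a trajectory
transform_traj <- function(traj, R, t) {
  n <- nFrames(traj)
  m <- traj@coords
  for (i in seq_len(n)) {
    xyz <- apply_rigid(matrix(m[i, ], ncol = 3, byrow = TRUE), R, t)
    m[i, ] <- as.vector(t(xyz))
  }
  MolTrajectory(traj@topology, m, times = traj@times)
}

# brute-force superposition oracle: best RMSD over nrot random proper
# rotations with centroid matching, via the cross-covariance identity
# sum_i q_i.(R p_i) = <R, t(Q) %*% P>
oracle_best_rmsd <- function(P, Q, nrot = 1e5) {
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  M <- crossprod(Qc, Pc)
  q <- matrix(stats::rnorm(4 * nrot), ncol = 4)
  q <- q / sqrt(rowSums(q^2))
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  Rflat <- cbind(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z),
                 2 * (x * z + w * y),
                 2 * (x * y + w * z), 1 - 2 * (x^2 + z^2),
                 2 * (y * z - w * x),
                 2 * (x * z - w * y), 2 * (y * z + w * x),
                 1 - 2 * (x^2 + y^2))
  score <- as.vector(Rflat %*% as.vector(t(M)))
  ss <- sum(Pc^2) + sum(Qc^2) - 2 * max(score)
  sqrt(max(ss, 0) / nrow(P))
}

# direct double-sum pair-energy oracle (scalar loop, no vectorisation)
oracle_group_energy <- function(xyzA, xyzB, pa, pb, scheme) {
  vdw <- elec <- 0
  for (i in seq_len(nrow(xyzA))) for (j in seq_len(nrow(xyzB))) {
    e <- pairEnergy(xyzA[i, ], xyzB[j, ], pa[i, , drop = FALSE],
                    pb[j, , drop = FALSE], scheme)
    vdw <- vdw + e[["vdw"]]; elec <- elec + e[["elec"]]
  }
  c(vdw = vdw, elec = elec)
}

make_random_system <- function(nA, nB, spread = 8) {
  xyzA <- matrix(stats::runif(3 * nA, 0, spread), ncol = 3)
  xyzB <- matrix(stats::runif(3 * nB, 2, spread + 4), ncol = 3)
  pa <- data.frame(charge_e = stats::runif(nA, -0.5, 0.5),
                   epsilon_kcal = stats::runif(nA, 0.01, 0.3),
                   rmin_half_A = stats::runif(nA, 1.2, 2.2))
  pb <- data.frame(charge_e = stats::runif(nB, -0.5, 0.5),
                   epsilon_kcal = stats::runif(nB, 0.01, 0.3),
                   rmin_half_A = stats::runif(nB, 1.2, 2.2))
  list(xyzA = xyzA, xyzB = xyzB, pa = pa, pb = pb)
}

random_system_traj <- function(sys) {
  nA <- nrow(sys$xyzA); nB <- nrow(sys$xyzB)
  atoms <- data.frame(
    serial = seq_len(nA + nB),
    name = paste0("X", seq_len(nA + nB)),
    resname = c(rep("AAA", nA), rep("BBB", nB)),
    chain = c(rep("A", nA), rep("B", nB)),
    resno = seq_len(nA + nB),
    x = c(sys$xyzA[, 1], sys$xyzB[, 1]),
    y = c(sys$xyzA[, 2], sys$xyzB[, 2]),
    z = c(sys$xyzA[, 3], sys$xyzB[, 3]),
    element = "C")
  params <- data.frame(residue_name = atoms$resname,
                       atom_name = atoms$name,
                       charge_e = c(sys$pa$charge_e, sys$pb$charge_e),
                       epsilon_kcal = c(sys$pa$epsilon_kcal,
                                        sys$pb$epsilon_kcal),
                       rmin_half_A = c(sys$pa$rmin_half_A,
                                       sys$pb$rmin_half_A))
  list(traj = as_traj(MolStructure(atoms)), params = params)
}
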