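# Group-group nonbonded energetics: Lennard-Jones (12-6, CHARMM Rmin
# convention, Lorentz-Berthelot combining) plus Coulomb electrostatics
# under a smooth C1 switched cutoff.  Analysis sums run over inter-
# group pairs only; there are no periodic images and no intra-group or
# bonded-exclusion terms.

# Coulomb constant in kcal*A/(mol*e^2), vacuum dielectric of 1
.COULOMB_K <- 332.0636

#' Smooth switching function
#'
#' The standard C1 polynomial switch: 1 for `r <= rOn`, 0 for
#' `r >= rOff`, and
#' `S(r) = (rOff^2 - r^2)^2 (rOff^2 + 2 r^2 - 3 rOn^2) /
#' (rOff^2 - rOn^2)^3` in between.  With the default scheme this is
#' the 10--12 Angstrom smooth cutoff.
#'
#' @param r distance(s), Angstrom, `>= 0`; vectorised.
#' @param scheme a [CutoffScheme-class].
#' @return unitless value(s) in `[0, 1]`.
#' @export
switchingFunction <- function(r, scheme = CutoffScheme()) {
  ron2 <- scheme@rOn^2
  roff2 <- scheme@rOff^2
  s <- (roff2 - r^2)^2 * (roff2 + 2 * r^2 - 3 * ron2) / (roff2 - ron2)^3
  s[r <= scheme@rOn] <- 1
  s[r >= scheme@rOff] <- 0
  s
}

#' Resolve per-atom nonbonded parameters against a structure
#'
#' Looks up every atom's `(residue_name, atom_name)` row in the
#' parameter table; every atom must have exactly one row.
#'
#' @param params data.frame from [readNonbondParams()].
#' @param structure a [MolStructure-class].
#' @param indices optional atom indices to resolve (default all).
#' @return data.frame with columns `charge_e`, `epsilon_kcal`,
#'   `rmin_half_A`, one row per requested atom.
#' @export
resolveParams <- function(params, structure, indices = NULL) {
  a <- structure@atoms
  if (is.null(indices)) indices <- seq_len(nrow(a))
  key <- paste(a$resname[indices], a$name[indices])
  tabkey <- paste(params$residue_name, params$atom_name)
  hit <- match(key, tabkey)
  if (anyNA(hit)) {
    miss <- unique(key[is.na(hit)])
    stop("no nonbonded parameters for atom type(s): ",
         paste(utils::head(miss, 5L), collapse = "; "), call. = FALSE)
  }
  params[hit, c("charge_e", "epsilon_kcal", "rmin_half_A"), drop = FALSE]
}

#' Switched nonbonded pair energy
#'
#' `vdw = S(r) * eps_ij * ((Rmin_ij/r)^12 - 2 (Rmin_ij/r)^6)` with
#' `eps_ij = sqrt(eps_i eps_j)` and `Rmin_ij = Rmin/2_i + Rmin/2_j`;
#' `elec = S(r) * 332.0636 * q_i q_j / r` (kcal/mol, charges in e,
#' distances in Angstrom).  Both terms are exactly zero at and beyond
#' the cutoff.
#'
#' @param ri,rj numeric(3) positions, Angstrom.
#' @param pi_,pj_ single-row parameter data.frames (columns `charge_e`,
#'   `epsilon_kcal`, `rmin_half_A`).
#' @param scheme a [CutoffScheme-class].
#' @param switchElec apply the switch to the electrostatic term as well
#'   (default `TRUE`); with `FALSE` the Coulomb term is plainly
#'   truncated at `rOff`.
#' @return named numeric: `vdw`, `elec` (kcal/mol).
#' @export
pairEnergy <- function(ri, rj, pi_, pj_, scheme = CutoffScheme(),
                       switchElec = TRUE) {
  r <- sqrt(sum((ri - rj)^2))
  if (r < 1e-6) stop("pairEnergy: coincident atoms (r < 1e-6 A)")
  if (r >= scheme@rOff) return(c(vdw = 0, elec = 0))
  s <- switchingFunction(r, scheme)
  eps <- sqrt(pi_$epsilon_kcal * pj_$epsilon_kcal)
  rmin <- pi_$rmin_half_A + pj_$rmin_half_A
  sr6 <- (rmin / r)^6
  se <- if (switchElec) s else 1
  c(vdw = s * eps * (sr6^2 - 2 * sr6),
    elec = se * .COULOMB_K * pi_$charge_e * pj_$charge_e / r)
}

# vectorised inter-group sum for one frame; pair parameter vectors are
# precomputed once per series
.group_energy_frame <- function(xyzA, xyzB, qq, eps_ij, rmin_ij, scheme,
                                switchElec = TRUE) {
  nA <- nrow(xyzA); nB <- nrow(xyzB)
  dx <- outer(xyzA[, 1L], xyzB[, 1L], "-")
  dy <- outer(xyzA[, 2L], xyzB[, 2L], "-")
  dz <- outer(xyzA[, 3L], xyzB[, 3L], "-")
  r <- sqrt(dx * dx + dy * dy + dz * dz)
  if (any(r < 1e-6)) stop("coincident atoms between groups (r < 1e-6 A)")
  live <- r < scheme@rOff
  if (!any(live)) return(c(vdw = 0, elec = 0))
  rl <- r[live]
  s <- switchingFunction(rl, scheme)
  sr6 <- (rmin_ij[live] / rl)^6
  se <- if (switchElec) s else 1
  c(vdw = sum(s * eps_ij[live] * (sr6^2 - 2 * sr6)),
    elec = sum(se * .COULOMB_K * qq[live] / rl))
}

#' Group-group interaction-energy series
#'
#' Per frame, the sum of switched pair energies over all pairs with one
#' atom in `groupA` and one in `groupB`.  The groups must be disjoint;
#' intra-group terms are never included.
#'
#' @param traj a [MolTrajectory-class].
#' @param groupA,groupB selection expressions (disjoint).
#' @param params nonbonded parameter table covering both groups.
#' @param scheme a [CutoffScheme-class].
#' @param switchElec apply the switch to the electrostatic term as well
#'   (default `TRUE`).
#' @return An [EnergyProfile-class].
#' @export
groupEnergySeries <- function(traj, groupA, groupB, params,
                              scheme = CutoffScheme(),
                              switchElec = TRUE) {
  topo <- traj@topology
  ia <- resolveSelection(groupA, topo)
  ib <- resolveSelection(groupB, topo)
  if (length(intersect(ia, ib)))
    stop("groupA and groupB must be disjoint")
  pa <- resolveParams(params, topo, ia)
  pb <- resolveParams(params, topo, ib)
  qq <- outer(pa$charge_e, pb$charge_e)
  eps_ij <- sqrt(outer(pa$epsilon_kcal, pb$epsilon_kcal))
  rmin_ij <- outer(pa$rmin_half_A, pb$rmin_half_A, "+")
  nf <- nFrames(traj)
  vdw <- elec <- numeric(nf)
  for (i in seq_len(nf)) {
    xyz <- coords(traj, i)
    e <- .group_energy_frame(xyz[ia, , drop = FALSE],
                             xyz[ib, , drop = FALSE],
                             qq, eps_ij, rmin_ij, scheme, switchElec)
    vdw[i] <- e[["vdw"]]; elec[i] <- e[["elec"]]
  }
  EnergyProfile(times = traj@times, vdw = vdw, elec = elec)
}

#' Adjacent-domain hinge interaction-energy table
#'
#' For each adjacent pair of the supplied domain selections, computes
#' the total interaction energy per frame in every trajectory, averages
#' over time within each trajectory first, and then reports mean and
#' sample SD of those per-trajectory means across trajectories
#' (two-stage averaging).  With a single trajectory the SD is reported
#' as `NA`.
#'
#' @param trajs list of [MolTrajectory-class] objects sharing a
#'   topology.
#' @param domainSels named character vector of >= 2 domain selections
#'   in chain order.
#' @param params nonbonded parameter table.
#' @param scheme a [CutoffScheme-class].
#' @return data.frame with columns `pair`, `n_traj`, `mean_kcal`,
#'   `sd_kcal`.
#' @export
hingeEnergyTable <- function(trajs, domainSels, params,
                             scheme = CutoffScheme()) {
  if (is(trajs, "MolTrajectory")) trajs <- list(trajs)
  if (length(domainSels) < 2L) stop("need at least 2 domain selections")
  nms <- names(domainSels)
  if (is.null(nms)) nms <- paste0("D", seq_along(domainSels))
  rows <- list()
  for (k in seq_len(length(domainSels) - 1L)) {
    per_traj <- vapply(trajs, function(tr) {
      prof <- groupEnergySeries(tr, domainSels[[k]], domainSels[[k + 1L]],
                                params, scheme)
      mean(prof@total)
    }, numeric(1))
    rows[[k]] <- data.frame(
      pair = paste0(nms[k], "-", nms[k + 1L]),
      n_traj = length(per_traj),
      mean_kcal = mean(per_traj),
      sd_kcal = if (length(per_traj) >= 2L) stats::sd(per_traj)
                else NA_real_)
  }
  do.call(rbind, rows)
}
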