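# Synthetic rigid-body trajectory generator.  Builds a toy multi-domain
# receptor + ligand with fully known ground truth: a lectin-like domain
# carrying a 9-residue binding loop, an EGF-like domain that rotates
# about a two-residue hinge, two consensus-repeat-like domains, a short
# ligand peptide with a sugar marker, and a bound calcium marker.  The
# generator emulates the phenomenology the analysis pipeline is built
# to measure -- hinge reorientation, loop state interconversion, and
# forced unbinding with an intramolecular-extension phase preceding
# separation -- with no physical dynamics.  Every output carries a
# machine-readable ground-truth log.
#
# All randomness uses R's Mersenne-Twister with inversion normals under
# an explicit seed; outputs are bit-reproducible for a fixed seed.

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

#' Toy receptor-ligand topology
#'
#' Describes the synthetic architecture: receptor chain A with one
#' C-alpha pseudo-atom per residue -- lectin-like domain (residues
#' 81-120) containing the binding loop 81-89 and rigid core 90-119,
#' Lec-EGF hinge 120-121, EGF-like domain 121-158 with main body
#' 122-141, EGF-CR1 hinge 159-160, CR1 161-190 and CR2 191-220 -- plus
#' ligand chain B (residues 610-618 ending at the pulled C-alpha of
#' residue 618, with a FUC sugar marker residue 619) and a calcium
#' marker (chain C, resname CAL).  Residue numbering deliberately
#' mirrors the landmark numbering used for the real receptor so the
#' published selections read naturally.
#'
#' @return list with the region residue ranges, the published selection
#'   expressions (`$selections`) and loop-state displacement vectors.
#' @export
toyTopology <- function() {
  list(
    regions = list(
      lec = 81:120, loop = 81:89, lecRigid = 90:119,
      hingeLecEgf = 120:121, egf = 121:158, egfBody = 122:141,
      hingeEgfCr1 = 159:160, cr1 = 161:190, cr2 = 191:220,
      ligand = 610:618, fuc = 619L, calcium = 701L),
    rotBlockEgf = 121L,     # chain A residues >= this rotate with EGF
    rotBlockCr1 = 161L,     # chain A residues >= this rotate with CR1
    loopDisp = list(S1 = c(0, 0, 0), S1p = c(-12, 0, 0),
                    S2 = c(0, -12, 0)),
    selections = c(
      receptor    = "chain A",
      ligand      = "chain B",
      lecDomain   = "chain A and resid 81-120",
      loop        = "chain A and resid 81-89 and name CA",
      lecRigid    = "chain A and resid 90-119 and name CA",
      hingeLecEgf = "chain A and resid 120-121 and heavy",
      egfDomain   = "chain A and resid 121-158",
      egfBody     = "chain A and resid 122-141 and heavy",
      hingeEgfCr1 = "chain A and resid 159-160 and heavy",
      cr1Body     = "chain A and resid 161-190 and heavy",
      cr2Body     = "chain A and resid 191-220 and heavy",
      fixedEnd    = "chain A and resid 220 and name CA",
      pulled      = "chain B and resid 618 and name CA",
      markerFuc   = "resname FUC",
      markerCal   = "resname CAL"))
}

.toy_receptor_resnames <- c("ALA", "GLY", "SER", "VAL")
.toy_ligand_resnames <- c("TYS", "THR", "PRO")

# deterministic base coordinates; jitter breaks exact symmetry
.toy_base_atoms <- function(topo) {
  rr <- 81:220
  i <- seq_along(rr) - 1L
  rec <- data.frame(
    serial = seq_along(rr), name = "CA",
    resname = .toy_receptor_resnames[(i %% 4L) + 1L],
    chain = "A", resno = rr,
    x = 3 * cos(0.7 * i), y = 3 * sin(0.7 * i), z = 1.5 * i,
    element = "C", stringsAsFactors = FALSE)
  lr <- 610:619
  j <- seq_along(lr) - 1L
  lig <- data.frame(
    serial = max(rec$serial) + seq_along(lr),
    name = c(rep("CA", 9L), "C1"),
    resname = c(.toy_ligand_resnames[(j[1:9] %% 3L) + 1L], "FUC"),
    chain = "B", resno = lr,
    x = 9 + 0.5 * cos(1.1 * j), y = 0.5 * sin(1.1 * j),
    z = 20 + 2.2 * j,
    element = "C", stringsAsFactors = FALSE)
  cal <- data.frame(
    serial = max(lig$serial) + 1L, name = "CA", resname = "CAL",
    chain = "C", resno = 701L, x = 6, y = 0, z = 28,
    element = "CA", stringsAsFactors = FALSE)
  rbind(rec, lig, cal)
}

.toy_params <- function(atoms) {
  key <- !duplicated(paste(atoms$resname, atoms$name))
  u <- atoms[key, c("resname", "name")]
  charge <- ifelse(u$resname %in% .toy_receptor_resnames, 0.15,
            ifelse(u$resname %in% c(.toy_ligand_resnames, "FUC"), -0.25,
                   2.0))                       # CAL
  data.frame(residue_name = u$resname, atom_name = u$name,
             charge_e = charge,
             epsilon_kcal = 0.1,
             rmin_half_A = ifelse(u$resname == "CAL", 1.4, 2.0),
             stringsAsFactors = FALSE)
}

#' Build the toy system
#'
#' Deterministically (for a fixed seed) constructs the toy structure,
#' the three loop reference states and a covering nonbonded parameter
#' table.  The three loop reference conformations are uniform
#' displacements of the same loop and are pairwise >= 10 Angstrom apart
#' in loop RMSD, so the 4.0 Angstrom classification rule separates
#' them cleanly.
#'
#' @param topo a [toyTopology()] list.
#' @param seed integer seed for the coordinate jitter.
#' @return list with `structure` ([MolStructure-class]), `references`
#'   (list of three [ReferenceState-class], labels `S1`, `S1p`, `S2`),
#'   `params` (nonbonded table), `topo` and `selections`.
#' @export
buildToy <- function(topo = toyTopology(), seed = 1L) {
  atoms <- .toy_base_atoms(topo)
  jit <- .with_seed(seed, matrix(stats::runif(3L * nrow(atoms), -0.2, 0.2),
                                 ncol = 3L))
  atoms$x <- atoms$x + jit[, 1L]
  atoms$y <- atoms$y + jit[, 2L]
  atoms$z <- atoms$z + jit[, 3L]
  s <- MolStructure(atoms, label = sprintf("toy(seed=%d)", seed))
  sel <- topo$selections
  loop_idx <- resolveSelection(sel[["loop"]], s)
  refs <- lapply(names(topo$loopDisp), function(lab) {
    a2 <- atoms
    d <- topo$loopDisp[[lab]]
    a2$x[loop_idx] <- a2$x[loop_idx] + d[1L]
    a2$y[loop_idx] <- a2$y[loop_idx] + d[2L]
    a2$z[loop_idx] <- a2$z[loop_idx] + d[3L]
    ReferenceState(lab, MolStructure(a2, label = paste0("ref_", lab)),
                   alignSel = sel[["lecRigid"]], loopSel = sel[["loop"]])
  })
  names(refs) <- names(topo$loopDisp)
  list(structure = s, references = refs, params = .toy_params(atoms),
       topo = topo, selections = sel)
}

#' Synthetic-trajectory specification
#'
#' Schedules and parameters of one synthetic run.  Angle schedules are
#' piecewise-linear in frame number; the loop schedule is piecewise
#' constant (instant switches by default, optionally linearly
#' interpolated over `interpWindow` frames after each switch).
#' Coordinate noise defaults to 0.3 Angstrom for equilibration runs and
#' 0 for pulling runs; per-frame random global rigid motions default to
#' on for equilibration (so that alignment is genuinely exercised) and
#' off for pulling (the pulling axis is lab-fixed).
#'
#' @param mode `"equilibration"`, `"cf"` or `"cv"`.
#' @param seed integer seed.
#' @param nFrames number of frames (default 201).
#' @param timeStep frame spacing, ns (default 0.1).
#' @param sigma isotropic Gaussian coordinate noise SD, Angstrom.
#' @param globalMotion apply a random global rigid motion per frame.
#' @param thetaSchedule data.frame(frame, angle_deg): EGF hinge angle,
#'   piecewise-linear.
#' @param crSchedule data.frame(frame, angle_deg): CR1 hinge angle.
#' @param loopSchedule data.frame(frame, state): loop state from each
#'   switch frame on; states are reference labels.
#' @param interpWindow frames of linear interpolation after each loop
#'   switch (default 0 = instant).
#' @param eventFrame programmed dissociation frame (pulling modes).
#' @param phase1End last frame of the intramolecular-extension phase.
#' @param onsetExtension extension at the end of phase 1, Angstrom.
#' @param preEventExtra ligand-only displacement added between phase 1
#'   and the event, Angstrom.
#' @param postEventStep per-frame displacement after the event,
#'   Angstrom.
#' @param peakFrame frame of the programmed force peak (cv mode).
#' @param peakForcePN programmed peak force, pN (cv mode).
#' @param forcePN constant force, pN (cf mode).
#' @param springPNperA spring constant, pN/Angstrom (cv mode).
#' @return list of class `"SyntheticSpec"`.
#' @export
syntheticSpec <- function(mode = c("equilibration", "cf", "cv"),
                          seed = 1L, nFrames = 201L, timeStep = 0.1,
                          sigma = NULL, globalMotion = NULL,
                          thetaSchedule = NULL, crSchedule = NULL,
                          loopSchedule = NULL, interpWindow = 0L,
                          eventFrame = 120L, phase1End = 80L,
                          onsetExtension = 25, preEventExtra = 2,
                          postEventStep = 0.5, peakFrame = 110L,
                          peakForcePN = 200, forcePN = 300,
                          springPNperA = 70) {
  mode <- match.arg(mode)
  if (is.null(sigma)) sigma <- if (mode == "equilibration") 0.3 else 0
  if (is.null(globalMotion)) globalMotion <- mode == "equilibration"
  if (is.null(thetaSchedule))
    thetaSchedule <- data.frame(frame = c(1, 60, 100, nFrames),
                                angle_deg = c(0, 0, 60, 60))
  if (is.null(crSchedule))
    crSchedule <- data.frame(frame = c(1, 20, 50, nFrames),
                             angle_deg = c(0, 0, 40, 40))
  if (is.null(loopSchedule))
    loopSchedule <- data.frame(frame = c(1, 120), state = c("S1", "S1p"),
                               stringsAsFactors = FALSE)
  stopifnot(sigma >= 0, nFrames >= 2L)
  if (mode != "equilibration")
    stopifnot(eventFrame > phase1End + 1L, eventFrame < nFrames,
              peakFrame > 1L, peakFrame < eventFrame)
  structure(list(mode = mode, seed = seed, nFrames = as.integer(nFrames),
                 timeStep = timeStep, sigma = sigma,
                 globalMotion = globalMotion,
                 thetaSchedule = thetaSchedule, crSchedule = crSchedule,
                 loopSchedule = loopSchedule,
                 interpWindow = as.integer(interpWindow),
                 eventFrame = as.integer(eventFrame),
                 phase1End = as.integer(phase1End),
                 onsetExtension = onsetExtension,
                 preEventExtra = preEventExtra,
                 postEventStep = postEventStep,
                 peakFrame = as.integer(peakFrame),
                 peakForcePN = peakForcePN, forcePN = forcePN,
                 springPNperA = springPNperA),
            class = "SyntheticSpec")
}

# piecewise-linear evaluation of a (frame, value) schedule; duplicate
# breakpoints keep the later value
.sched_eval <- function(sched, frames, col = "angle_deg") {
  sched <- sched[order(sched$frame), , drop = FALSE]
  sched <- sched[!duplicated(sched$frame, fromLast = TRUE), ,
                 drop = FALSE]
  if (nrow(sched) == 1L) return(rep(sched[[col]], length(frames)))
  stats::approx(sched$frame, sched[[col]], xout = frames, rule = 2)$y
}

# per-frame loop interpolation: returns list(fromState, toState,
# fraction) with fraction in [0, 1] toward toState
.loop_eval <- function(sched, nframes, window) {
  from <- to <- character(nframes)
  frac <- numeric(nframes)
  cur <- sched$state[1L]
  from[] <- cur; to[] <- cur; frac[] <- 1
  if (nrow(sched) > 1L) for (k in 2:nrow(sched)) {
    f0 <- sched$frame[k]; st <- sched$state[k]; prev <- sched$state[k - 1L]
    for (i in f0:nframes) {
      if (window > 0L && i < f0 + window) {
        from[i] <- prev; to[i] <- st; frac[i] <- (i - f0 + 1) / window
      } else {
        from[i] <- st; to[i] <- st; frac[i] <- 1
      }
    }
  }
  list(from = from, to = to, fraction = frac)
}

# closed-form expected loop classification for noise-free runs: with
# uniform-displacement states, rmsd to state X is |disp(frame)-disp(X)|
.expected_calls <- function(loop_eval, disp, threshold = 4.0) {
  labs <- names(disp)
  n <- length(loop_eval$from)
  rmsd <- matrix(0, n, length(labs), dimnames = list(NULL, labs))
  for (i in seq_len(n)) {
    d <- (1 - loop_eval$fraction[i]) * disp[[loop_eval$from[i]]] +
      loop_eval$fraction[i] * disp[[loop_eval$to[i]]]
    rmsd[i, ] <- vapply(labs,
                        function(l) sqrt(sum((d - disp[[l]])^2)),
                        numeric(1))
  }
  call <- apply(rmsd, 1L, function(row) {
    q <- labs[row <= threshold]
    if (!length(q)) return("unassigned")
    if (all(c("S1", "S1p") %in% q)) q <- setdiff(q, "S1")
    q[which.min(row[q])]
  })
  list(rmsd = rmsd, call = call)
}

# assemble one deformed frame of the toy receptor (no noise, no global
# motion): loop displacement, CR1 rotation, then EGF rotation
.toy_frame_xyz <- function(base_xyz, atoms, topo, theta, cr_theta,
                           loop_disp, geom) {
  xyz <- base_xyz
  xyz[geom$loop_idx, ] <- sweep(xyz[geom$loop_idx, , drop = FALSE], 2L,
                                loop_disp, "+")
  if (cr_theta != 0) {
    R <- .axis_rotation(geom$cr_axis, cr_theta)
    blk <- geom$cr_block
    xyz[blk, ] <- sweep(sweep(xyz[blk, , drop = FALSE], 2L,
                              geom$cr_center) %*% t(R), 2L,
                        geom$cr_center, "+")
  }
  if (theta != 0) {
    R <- .axis_rotation(geom$egf_axis, theta)
    blk <- geom$egf_block
    xyz[blk, ] <- sweep(sweep(xyz[blk, , drop = FALSE], 2L,
                              geom$egf_center) %*% t(R), 2L,
                        geom$egf_center, "+")
  }
  xyz
}

# fixed rotation geometry derived from the reference structure
.toy_geom <- function(toy) {
  s <- toy$structure
  a <- s@atoms
  sel <- toy$selections
  xyz <- coords(s)
  hinge_e <- resolveSelection(sel[["hingeLecEgf"]], s)
  body_e <- resolveSelection(sel[["egfBody"]], s)
  hinge_c <- resolveSelection(sel[["hingeEgfCr1"]], s)
  body_c <- resolveSelection(sel[["cr1Body"]], s)
  egf_center <- geometricCenter(xyz[hinge_e, , drop = FALSE])
  v_egf <- geometricCenter(xyz[body_e, , drop = FALSE]) - egf_center
  cr_center <- geometricCenter(xyz[hinge_c, , drop = FALSE])
  v_cr <- geometricCenter(xyz[body_c, , drop = FALSE]) - cr_center
  perp <- function(v) {
    u <- c(-v[2L], v[1L], 0)
    if (sqrt(sum(u^2)) < 1e-6) u <- c(1, 0, 0)
    u / sqrt(sum(u^2))
  }
  list(loop_idx = resolveSelection(sel[["loop"]], s),
       egf_center = egf_center, egf_axis = perp(v_egf),
       egf_block = which(a$chain == "A" & a$resno >= toy$topo$rotBlockEgf),
       cr_center = cr_center, cr_axis = perp(v_cr),
       cr_block = which(a$chain == "A" & a$resno >= toy$topo$rotBlockCr1))
}

.add_noise_motion <- function(xyz, sigma, global_motion) {
  if (sigma > 0)
    xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, sigma), ncol = 3L)
  if (global_motion) {
    R <- .random_rotation()
    t <- stats::runif(3L, -20, 20)
    xyz <- sweep(xyz %*% t(R), 2L, t, "+")
  }
  xyz
}

#' Generate a synthetic equilibration trajectory
#'
#' Per frame: the loop is placed by the loop-state schedule (with
#' optional linear interpolation), the CR1 block is rotated about the
#' EGF-CR1 hinge centre by the CR schedule, the EGF block (everything
#' C-terminal of the Lec-EGF hinge) is rotated about the Lec-EGF hinge
#' centre by the angle schedule (both about fixed axes perpendicular to
#' the respective reference hinge-to-body vectors, so the recovered
#' orientation equals the schedule exactly in the noise-free case),
#' isotropic Gaussian noise is added, and finally a random global rigid
#' motion is applied.  Everything programmed is logged.
#'
#' @param toy a [buildToy()] result.
#' @param spec a [syntheticSpec()] with `mode = "equilibration"`.
#' @return list with `trajectory` ([MolTrajectory-class]) and `truth`
#'   (frames, times, programmed angles, loop schedule fractions,
#'   closed-form expected loop RMSDs and calls valid at `sigma = 0`,
#'   programmed loop switch frames).
#' @export
generateEquilibration <- function(toy, spec = syntheticSpec("equilibration")) {
  stopifnot(inherits(spec, "SyntheticSpec"), spec$mode == "equilibration")
  geom <- .toy_geom(toy)
  base_xyz <- coords(toy$structure)
  n <- spec$nFrames
  frames <- seq_len(n)
  theta <- .sched_eval(spec$thetaSchedule, frames)
  crth <- .sched_eval(spec$crSchedule, frames)
  le <- .loop_eval(spec$loopSchedule, n, spec$interpWindow)
  disp <- toy$topo$loopDisp
  exp_cls <- .expected_calls(le, disp)
  coords_mat <- matrix(0, n, 3L * nrow(base_xyz))
  .with_seed(spec$seed, {
    for (i in frames) {
      d <- (1 - le$fraction[i]) * disp[[le$from[i]]] +
        le$fraction[i] * disp[[le$to[i]]]
      xyz <- .toy_frame_xyz(base_xyz, toy$structure@atoms, toy$topo,
                            theta[i], crth[i], d, geom)
      xyz <- .add_noise_motion(xyz, spec$sigma, spec$globalMotion)
      coords_mat[i, ] <- as.vector(t(xyz))
    }
  })
  traj <- MolTrajectory(toy$structure, coords_mat,
                        timeStep = spec$timeStep)
  truth <- list(
    mode = "equilibration", seed = spec$seed, sigma = spec$sigma,
    globalMotion = spec$globalMotion,
    frame = frames, time_ns = traj@times,
    theta_deg = theta, cr_theta_deg = crth,
    loop_from = le$from, loop_to = le$to, loop_fraction = le$fraction,
    expected_rmsd = exp_cls$rmsd, expected_call = exp_cls$call,
    loop_switch_frames = if (nrow(spec$loopSchedule) > 1L)
      spec$loopSchedule$frame[-1L] else integer(0),
    loop_switch_from = if (nrow(spec$loopSchedule) > 1L)
      spec$loopSchedule$state[-nrow(spec$loopSchedule)] else character(0),
    loop_switch_to = if (nrow(spec$loopSchedule) > 1L)
      spec$loopSchedule$state[-1L] else character(0))
  list(trajectory = traj, truth = truth)
}

#' Generate a synthetic forced-dissociation trajectory
#'
#' Emulates a steered unbinding run.  Phase 1 (frames 1 to
#' `phase1End`): the lectin block, loop, ligand and calcium translate
#' together along the fixed-to-pulled axis (hinge-opening-like
#' intramolecular extension; separation stays constant).  Phase 2: the
#' ligand and sugar marker continue alone; just before the programmed
#' event the receptor-ligand gap is still small enough that the
#' interaction energy is far from zero, and at `eventFrame` the ligand
#' is displaced beyond the cutoff (plus a safety margin) so the
#' switched interaction energy is exactly zero from that frame on.  A
#' force log is emitted: constant `forcePN` for cf runs; for cv runs,
#' `spring * (pull schedule - extension)` with a programmed unique peak
#' at `peakFrame`.
#'
#' @param toy a [buildToy()] result.
#' @param spec a [syntheticSpec()] with mode `"cf"` or `"cv"`.
#' @return list with `trajectory`, `forceLog` (data.frame `time_ns`,
#'   `force_pN`) and `truth` (programmed event frame, extension series,
#'   separation-onset extension, peak force/extension/frame, axis).
#' @export
generateDissociation <- function(toy, spec = syntheticSpec("cv")) {
  stopifnot(inherits(spec, "SyntheticSpec"), spec$mode %in% c("cf", "cv"))
  s <- toy$structure
  a <- s@atoms
  sel <- toy$selections
  base_xyz <- coords(s)
  n <- spec$nFrames
  frames <- seq_len(n)
  fixed_idx <- resolveSelection(sel[["fixedEnd"]], s)
  pulled_idx <- resolveSelection(sel[["pulled"]], s)
  axis <- base_xyz[pulled_idx, ] -
    geometricCenter(base_xyz[fixed_idx, , drop = FALSE])
  axis <- axis / sqrt(sum(axis^2))
  # moving blocks
  lec_block <- which(a$chain == "A" & a$resno <= max(toy$topo$regions$lec))
  lig_block <- which(a$chain == "B")
  cal_block <- which(a$chain == "C")
  rec_idx <- which(a$chain == "A")
  k1 <- spec$phase1End; ke <- spec$eventFrame
  # displacement schedules along the axis (ground truth, pre-noise)
  phase1 <- pmin(frames - 1, k1 - 1) / (k1 - 1) * spec$onsetExtension
  lig_extra <- numeric(n)
  pre <- frames > k1 & frames < ke
  lig_extra[pre] <- (frames[pre] - k1) / (ke - 1 - k1) * spec$preEventExtra
  lig_extra[frames >= ke] <- spec$preEventExtra
  # event jump: displace the ligand so that every receptor-ligand pair
  # distance exceeds the cutoff with margin, then keep receding
  roff_margin <- 14.0
  probe <- base_xyz
  probe[c(lec_block, lig_block, cal_block), ] <-
    sweep(probe[c(lec_block, lig_block, cal_block), , drop = FALSE], 2L,
          spec$onsetExtension * axis, "+")
  probe[lig_block, ] <- sweep(probe[lig_block, , drop = FALSE], 2L,
                              spec$preEventExtra * axis, "+")
  min_gap <- function(xyz) {
    rl <- xyz[rec_idx, , drop = FALSE]; ll <- xyz[lig_block, , drop = FALSE]
    min(sqrt(pmax(outer(rowSums(rl^2), rowSums(ll^2), "+") -
                  2 * rl %*% t(ll), 0)))
  }
  jump <- 0
  repeat {
    g <- min_gap({
      p2 <- probe
      p2[lig_block, ] <- sweep(p2[lig_block, , drop = FALSE], 2L,
                               jump * axis, "+")
      p2
    })
    if (g >= roff_margin) break
    jump <- jump + (roff_margin - g)
  }
  lig_extra[frames >= ke] <- lig_extra[frames >= ke] + jump +
    (frames[frames >= ke] - ke) * spec$postEventStep
  ext_true <- phase1 + lig_extra            # pulled-atom displacement
  coords_mat <- matrix(0, n, 3L * nrow(base_xyz))
  .with_seed(spec$seed, {
    for (i in frames) {
      xyz <- base_xyz
      mv1 <- c(lec_block, lig_block, cal_block)
      xyz[mv1, ] <- sweep(xyz[mv1, , drop = FALSE], 2L,
                          phase1[i] * axis, "+")
      xyz[lig_block, ] <- sweep(xyz[lig_block, , drop = FALSE], 2L,
                                lig_extra[i] * axis, "+")
      if (i >= ke && min_gap(xyz) <= 12.01)
        stop("internal: post-event receptor-ligand gap fell inside cutoff")
      xyz <- .add_noise_motion(xyz, spec$sigma, FALSE)
      coords_mat[i, ] <- as.vector(t(xyz))
    }
  })
  traj <- MolTrajectory(toy$structure, coords_mat,
                        timeStep = spec$timeStep)
  # force log
  if (spec$mode == "cf") {
    force <- rep(spec$forcePN, n)
    peak_frame <- 1L
  } else {
    lagmax <- spec$peakForcePN / spec$springPNperA
    lag <- stats::approx(
      x = c(1, spec$peakFrame, ke, n),
      y = c(0, lagmax, 0.1 * lagmax, 0.05 * lagmax),
      xout = frames)$y
    force <- spec$springPNperA * lag
    peak_frame <- spec$peakFrame
  }
  force_log <- data.frame(time_ns = traj@times, force_pN = force)
  truth <- list(
    mode = spec$mode, seed = spec$seed, sigma = spec$sigma,
    frame = frames, time_ns = traj@times,
    axis = axis, extension_A = ext_true,
    event_frame = ke, event_time_ns = traj@times[ke],
    separation_onset_frame = k1,
    separation_onset_extension_A = spec$onsetExtension,
    peak_frame = peak_frame,
    peak_force_pN = if (spec$mode == "cf") spec$forcePN
                    else spec$peakForcePN,
    peak_extension_A = ext_true[peak_frame])
  list(trajectory = traj, forceLog = force_log, truth = truth)
}

#' Write a ground-truth log as JSON
#'
#' @param truth a `truth` list from [generateEquilibration()] or
#'   [generateDissociation()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
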