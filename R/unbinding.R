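# Forced-dissociation observables: the fixed pulling axis, molecular
# extension (pulled-atom displacement along the axis), the two
# complex-separation measures, dissociation-time detection by the
# zero-energy criterion, force-profile features and replicate
# statistics.

#' Fixed pulling axis from the first frame
#'
#' Unit vector from the held atom to the pulled atom in the first
#' frame, held constant over the whole trajectory (steered-dynamics
#' convention: pulling acts along a single fixed vector).
#'
#' @param setup a [PullingSetup-class]; `pulledSel` must resolve to
#'   exactly one atom.
#' @param traj a [MolTrajectory-class].
#' @return unit numeric(3).
#' @export
forceAxis <- function(setup, traj) {
  topo <- traj@topology
  fi <- resolveSelection(setup@fixedSel, topo)
  pi1 <- resolveSelection(setup@pulledSel, topo)
  if (length(pi1) != 1L)
    stop("pulledSel must resolve to exactly one atom")
  xyz <- coords(traj, 1L)
  fixed <- geometricCenter(xyz[fi, , drop = FALSE])
  pulled <- xyz[pi1, ]
  v <- pulled - fixed
  nv <- sqrt(sum(v^2))
  if (nv <= 1e-9) stop("fixed and pulled atoms coincide in frame 1")
  v / nv
}

#' Molecular-extension series
#'
#' Signed projection of the pulled atom's displacement from its
#' first-frame position on the fixed force axis; frame 1 is 0 by
#' construction.
#'
#' @param traj a [MolTrajectory-class].
#' @param setup a [PullingSetup-class].
#' @return data.frame with columns `frame`, `time_ns`, `extension_A`.
#' @export
extensionSeries <- function(traj, setup) {
  axis <- forceAxis(setup, traj)
  pi1 <- resolveSelection(setup@pulledSel, traj@topology)
  p0 <- coords(traj, 1L)[pi1, ]
  ext <- vapply(seq_len(nFrames(traj)), function(i) {
    projectAlong(coords(traj, i)[pi1, ], p0, axis)
  }, numeric(1))
  data.frame(frame = seq_len(nFrames(traj)), time_ns = traj@times,
             extension_A = ext)
}

#' Axis-projected complex-separation series
#'
#' Per frame, the projection of (centre of the ligand group minus
#' centre of the receptor group) on the supplied axis -- the
#' receptor-ligand separation measured along the force vector.
#'
#' @param traj a [MolTrajectory-class].
#' @param recSel,ligSel selection expressions for the receptor and
#'   ligand groups.
#' @param axis numeric(3), normalised internally.
#' @return data.frame with columns `frame`, `time_ns`, `separation_A`.
#' @export
separationSeries <- function(traj, recSel, ligSel, axis) {
  topo <- traj@topology
  ir <- resolveSelection(recSel, topo)
  il <- resolveSelection(ligSel, topo)
  na <- sqrt(sum(axis^2))
  if (na <= 1e-9) stop("zero separation axis")
  axis <- axis / na
  sep <- vapply(seq_len(nFrames(traj)), function(i) {
    xyz <- coords(traj, i)
    sum((geometricCenter(xyz[il, , drop = FALSE]) -
         geometricCenter(xyz[ir, , drop = FALSE])) * axis)
  }, numeric(1))
  data.frame(frame = seq_len(nFrames(traj)), time_ns = traj@times,
             separation_A = sep)
}

#' Euclidean marker-distance series
#'
#' Plain (unprojected) distance between the geometric centres of two
#' marker selections, e.g. the ligand fucose and the receptor calcium
#' ion.
#'
#' @param traj a [MolTrajectory-class].
#' @param markerA,markerB selection expressions.
#' @return data.frame with columns `frame`, `time_ns`, `distance_A`.
#' @export
markerDistanceSeries <- function(traj, markerA, markerB) {
  topo <- traj@topology
  ia <- resolveSelection(markerA, topo)
  ib <- resolveSelection(markerB, topo)
  d <- vapply(seq_len(nFrames(traj)), function(i) {
    xyz <- coords(traj, i)
    sqrt(sum((geometricCenter(xyz[ia, , drop = FALSE]) -
              geometricCenter(xyz[ib, , drop = FALSE]))^2))
  }, numeric(1))
  data.frame(frame = seq_len(nFrames(traj)), time_ns = traj@times,
             distance_A = d)
}

#' Dissociation-time detection by the zero-energy criterion
#'
#' The dissociation time is the time of the first frame at which the
#' interaction energy has reached zero: `|E| <= zeroTol` and stays
#' within tolerance for `persistence` consecutive frames.  Returns
#' `NULL` when the criterion is never met.
#'
#' @param profile an [EnergyProfile-class].
#' @param zeroTol tolerance on "zero", kcal/mol (default 0.5).
#' @param persistence required consecutive frames within tolerance
#'   (default 5).
#' @param component `"total"` (default), `"vdw"` or `"elec"`.
#' @return list with `frame` (1-based), `time_ns` and `component`, or
#'   `NULL`.
#' @export
dissociationTime <- function(profile, zeroTol = 0.5, persistence = 5L,
                             component = c("total", "vdw", "elec")) {
  stopifnot(zeroTol > 0, persistence >= 1L)
  persistence <- as.integer(persistence)
  component <- match.arg(component)
  e <- slot(profile, component)
  n <- length(e)
  if (!n) stop("empty energy profile")
  ok <- abs(e) <= zeroTol
  if (n >= persistence) {
    run <- 0L
    for (i in seq_len(n)) {
      run <- if (ok[i]) run + 1L else 0L
      if (run == persistence) {
        first <- i - persistence + 1L
        return(list(frame = first, time_ns = profile@times[first],
                    component = component))
      }
    }
  }
  NULL
}

#' Assemble a dissociation event with its extension/separation context
#'
#' Combines [dissociationTime()] with the extension and separation
#' series to report the event in full: when it happened, and how far
#' the complex had extended and separated by then.  Per-component
#' (vdW-only and electrostatics-only) event times are also reported.
#'
#' @param profile an [EnergyProfile-class] for the receptor-ligand
#'   interaction.
#' @param extension data.frame from [extensionSeries()].
#' @param separation data.frame from [separationSeries()].
#' @param zeroTol,persistence see [dissociationTime()].
#' @return list with `frame`, `time_ns`, `extension_at_event_A`,
#'   `separation_at_event_A`, `time_vdw_ns`, `time_elec_ns`; or `NULL`
#'   when no event.
#' @export
unbindingSummary <- function(profile, extension, separation,
                             zeroTol = 0.5, persistence = 5L) {
  ev <- dissociationTime(profile, zeroTol, persistence, "total")
  if (is.null(ev)) return(NULL)
  evv <- dissociationTime(profile, zeroTol, persistence, "vdw")
  eve <- dissociationTime(profile, zeroTol, persistence, "elec")
  list(frame = ev$frame, time_ns = ev$time_ns,
       extension_at_event_A = extension$extension_A[ev$frame],
       separation_at_event_A = separation$separation_A[ev$frame],
       time_vdw_ns = if (is.null(evv)) NA_real_ else evv$time_ns,
       time_elec_ns = if (is.null(eve)) NA_real_ else eve$time_ns)
}

#' Peak of a force profile
#'
#' Global maximum of the force series and the extension at that frame;
#' ties are resolved to the earliest frame.
#'
#' @param force numeric per-frame force, pN.
#' @param extension numeric per-frame extension, Angstrom (equal
#'   length).
#' @return named numeric: `peak_force_pN`, `peak_extension_A`,
#'   `peak_frame`.
#' @export
forceProfileFeatures <- function(force, extension) {
  if (length(force) != length(extension))
    stop("force and extension must have equal length")
  i <- which.max(force)                      # earliest global maximum
  c(peak_force_pN = force[i], peak_extension_A = extension[i],
    peak_frame = i)
}

#' Mean and sample SD over replicate runs
#'
#' @param values numeric per-run scalars, n >= 1.
#' @return named numeric: `mean`, `sd` (`NA` for n = 1), `n`.
#' @export
replicateStatistics <- function(values) {
  values <- as.numeric(values)
  if (!length(values)) stop("need at least one value")
  c(mean = mean(values),
    sd = if (length(values) >= 2L) stats::sd(values) else NA_real_,
    n = length(values))
}
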