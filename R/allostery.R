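# Conformational metrics: interdomain orientation angles, binding-loop
# RMSD series against labelled reference states, threshold
# classification with the S1/S1' tie rule, per-state statistics and
# dwell-filtered transition detection.

#' Interdomain orientation-angle series
#'
#' For each frame: (1) the frame is superposed onto the reference using
#' `alignSel`; (2) the reference vector runs from the geometric centre
#' of the hinge heavy atoms to that of the domain body, both on the
#' reference; the frame vector runs from the same reference hinge
#' centre to the aligned frame's body centre (both vectors share the
#' reference hinge origin); (3) the angle between the two vectors is
#' reported in degrees.  This realises the orientation metric of a
#' domain about a two-residue hinge, e.g. the EGF domain about the
#' Lec-EGF hinge aligned on the lectin rigid core, or the CR1 domain
#' about the EGF-CR1 hinge aligned on the EGF domain.
#'
#' @param traj a [MolTrajectory-class].
#' @param odef an [OrientationDefinition-class].
#' @param perFrameHinge if `TRUE`, the frame vector emanates from the
#'   aligned frame's own hinge centre instead of the reference hinge
#'   centre.
#' @return data.frame with columns `frame`, `time_ns`, `angle_deg`.
#' @export
orientationSeries <- function(traj, odef, perFrameHinge = FALSE) {
  topo <- traj@topology
  ref <- odef@reference
  ai_f <- resolveSelection(odef@alignSel, topo)
  ai_r <- resolveSelection(odef@alignSel, ref)
  if (length(ai_f) != length(ai_r))
    stop("alignment selection resolves to different counts on frame and reference")
  hi_f <- resolveSelection(odef@hingeSel, topo)
  hi_r <- resolveSelection(odef@hingeSel, ref)
  bi_f <- resolveSelection(odef@bodySel, topo)
  bi_r <- resolveSelection(odef@bodySel, ref)
  rxyz <- coords(ref)
  hinge_ref <- geometricCenter(rxyz[hi_r, , drop = FALSE])
  v_ref <- geometricCenter(rxyz[bi_r, , drop = FALSE]) - hinge_ref
  nf <- nFrames(traj)
  ang <- numeric(nf)
  for (i in seq_len(nf)) {
    fxyz <- coords(traj, i)
    fit <- superpose(fxyz[ai_f, , drop = FALSE],
                     rxyz[ai_r, , drop = FALSE])
    body <- applyTransform(fit$transform, fxyz[bi_f, , drop = FALSE])
    origin <- if (perFrameHinge) {
      geometricCenter(applyTransform(fit$transform,
                                     fxyz[hi_f, , drop = FALSE]))
    } else hinge_ref
    v_frame <- geometricCenter(body) - origin
    ang[i] <- vectorAngle(v_ref, v_frame)
  }
  data.frame(frame = seq_len(nf), time_ns = traj@times, angle_deg = ang)
}

#' Loop-RMSD series against a set of reference states
#'
#' One [rmsdAfterAlignment()] value per frame and reference state: the
#' frame is aligned on each reference's `alignSel` and the RMSD is
#' measured over its `loopSel`.
#'
#' @param traj a [MolTrajectory-class].
#' @param refs list of [ReferenceState-class] objects with unique
#'   labels.
#' @return data.frame with columns `frame`, `time_ns` and one
#'   `rmsd_<label>` column per reference, Angstrom.
#' @export
loopRmsdSeries <- function(traj, refs) {
  labels <- vapply(refs, function(r) r@label, character(1))
  if (anyDuplicated(labels)) stop("reference labels must be unique")
  topo <- traj@topology
  nf <- nFrames(traj)
  out <- data.frame(frame = seq_len(nf), time_ns = traj@times)
  for (r in refs) {
    ai_f <- resolveSelection(r@alignSel, topo)
    ai_r <- resolveSelection(r@alignSel, r@structure)
    li_f <- resolveSelection(r@loopSel, topo)
    li_r <- resolveSelection(r@loopSel, r@structure)
    rxyz <- coords(r@structure)
    vals <- vapply(seq_len(nf), function(i) {
      .rmsd_aligned_xyz(coords(traj, i), rxyz, ai_f, ai_r, li_f, li_r)
    }, numeric(1))
    out[[paste0("rmsd_", r@label)]] <- vals
  }
  out
}

#' Classify frames into loop reference states
#'
#' A frame qualifies for every state whose loop RMSD is less than or
#' equal to `threshold` (boundary inclusive).  A frame qualifying for
#' exactly one state is called that state; a frame qualifying for both
#' `S1` and `S1p` is called `S1p` (the intermediate takes precedence
#' over the unligated crystal); any other multi-qualifier is resolved
#' to the smallest RMSD; a frame qualifying for no state is
#' `unassigned`.  The function is total and deterministic.
#'
#' @param series data.frame from [loopRmsdSeries()] (columns
#'   `rmsd_<label>`), or a numeric matrix/data.frame whose columns are
#'   state labels.
#' @param threshold qualification threshold, Angstrom (default 4.0).
#' @return data.frame with columns `frame`, the `rmsd_<label>` columns
#'   and `call`.
#' @export
classifyFrames <- function(series, threshold = 4.0) {
  stopifnot(threshold > 0)
  series <- as.data.frame(series)
  rcols <- grep("^rmsd_", names(series), value = TRUE)
  if (length(rcols)) {
    labels <- sub("^rmsd_", "", rcols)
    rm <- as.matrix(series[, rcols, drop = FALSE])
  } else {
    labels <- names(series)
    rm <- as.matrix(series)
    rcols <- paste0("rmsd_", labels)
  }
  colnames(rm) <- labels
  call <- apply(rm, 1L, function(row) {
    qual <- which(row <= threshold)
    if (!length(qual)) return("unassigned")
    qlab <- labels[qual]
    if (all(c("S1", "S1p") %in% qlab)) {
      qlab <- setdiff(qlab, "S1")            # S1/S1' overlap goes to S1'
    }
    qlab[which.min(row[qlab])]
  })
  out <- data.frame(frame = seq_len(nrow(rm)))
  out[rcols] <- rm
  out$call <- call
  out
}

#' Per-state counts, fractions and weighted statistics
#'
#' For every state label (and `unassigned`): the number of frames, the
#' fraction of all frames, and -- when per-frame weights such as
#' receptor-ligand interaction energies are supplied -- the mean and
#' sample standard deviation (n-1 denominator) of the weights over that
#' state's frames.  Unassigned frames never contribute to weighted
#' statistics.  Empty states report `NA` statistics, not zero.
#'
#' @param calls data.frame from [classifyFrames()] or a character
#'   vector of calls.
#' @param weights optional numeric vector aligned with the calls by
#'   frame.
#' @return data.frame with columns `state`, `n`, `fraction`,
#'   `mean_weight`, `sd_weight`.
#' @export
stateStatistics <- function(calls, weights = NULL) {
  cv <- if (is.data.frame(calls)) calls$call else as.character(calls)
  if (!is.null(weights) && length(weights) != length(cv))
    stop("weights must align with calls (one value per frame)")
  states <- unique(c(setdiff(sort(unique(cv)), "unassigned"),
                     if ("unassigned" %in% cv) "unassigned"))
  n_total <- length(cv)
  rows <- lapply(states, function(st) {
    idx <- which(cv == st)
    mw <- sw <- NA_real_
    if (!is.null(weights) && st != "unassigned" && length(idx)) {
      w <- weights[idx]
      mw <- mean(w)
      sw <- if (length(w) >= 2L) stats::sd(w) else NA_real_
    }
    data.frame(state = st, n = length(idx),
               fraction = length(idx) / n_total,
               mean_weight = mw, sd_weight = sw)
  })
  do.call(rbind, rows)
}

#' Detect dwell-filtered state transitions
#'
#' Emits a transition whenever the call changes to a new assigned state
#' that then persists for at least `minDwell` frames; unassigned frames
#' neither start nor terminate a dwell.  Single-frame blips shorter
#' than the dwell are ignored.
#'
#' @param calls data.frame from [classifyFrames()] or character vector.
#' @param minDwell minimum persistence in frames (default 5).
#' @return data.frame with columns `from_state`, `to_state`, `frame`
#'   (first frame of the new dwell, 1-based); zero rows when no
#'   transition qualifies.
#' @export
transitionDetect <- function(calls, minDwell = 5L) {
  stopifnot(minDwell >= 1L)
  cv <- if (is.data.frame(calls)) calls$call else as.character(calls)
  n <- length(cv)
  empty <- data.frame(from_state = character(0), to_state = character(0),
                      frame = integer(0))
  assigned <- which(cv != "unassigned")
  if (!length(assigned)) return(empty)
  current <- cv[assigned[1L]]
  res <- empty
  i <- assigned[1L] + 1L
  while (i <= n) {
    st <- cv[i]
    if (st != "unassigned" && st != current) {
      # candidate dwell: frames where the call is st or unassigned,
      # terminated by any different assigned call
      j <- i
      while (j <= n && (cv[j] == st || cv[j] == "unassigned")) j <- j + 1L
      if (j - i >= minDwell) {
        res <- rbind(res, data.frame(from_state = current,
                                     to_state = st, frame = i))
        current <- st
        i <- j
        next
      }
    }
    i <- i + 1L
  }
  res
}
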