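#' @import methods
NULL

#' Molecular structure container
#'
#' A `MolStructure` holds one set of named atoms with residue and chain
#' identity and 3-D coordinates in Angstrom, in file order.  The `atoms`
#' slot is a data.frame with columns `serial` (integer), `name` (atom
#' name, e.g. `"CA"`), `resname` (3-letter residue name), `chain`
#' (single character), `resno` (author residue number, kept verbatim),
#' `x`, `y`, `z` (Angstrom) and `element`.
#'
#' @slot atoms data.frame of per-atom records, one row per atom, file order.
#' @slot label character(1) free-text label.
#' @aliases MolStructure
#' @exportClass MolStructure
setClass("MolStructure",
  representation(atoms = "data.frame", label = "character"),
  prototype(label = ""))

setValidity("MolStructure", function(object) {
  a <- object@atoms
  need <- c("serial", "name", "resname", "chain", "resno",
            "x", "y", "z", "element")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) == 0L) return("structure must contain at least one atom")
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("all coordinates must be finite")
  key <- paste(a$chain, a$resno, a$name)
  if (anyDuplicated(key))
    return("(chain, resno, name) must be unique within a structure")
  TRUE
})

#' Construct a MolStructure from an atom table
#'
#' @param atoms data.frame with columns `serial`, `name`, `resname`,
#'   `chain`, `resno`, `x`, `y`, `z`, `element`.
#' @param label optional character label.
#' @return A [MolStructure-class] object.
#' @export
MolStructure <- function(atoms, label = "") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  new("MolStructure", atoms = atoms, label = as.character(label))
}

#' Trajectory container
#'
#' Ordered coordinate frames sharing one topology.  Coordinates are
#' stored as an `nframes x (3 * natoms)` matrix in the usual
#' `x1,y1,z1,x2,...` layout; times are in nanoseconds and strictly
#' increasing.
#'
#' @slot topology a [MolStructure-class].
#' @slot coords numeric matrix, one row per frame, `3 * natoms` columns.
#' @slot times numeric vector of frame times, ns.
#' @aliases MolTrajectory
#' @exportClass MolTrajectory
setClass("MolTrajectory",
  representation(topology = "MolStructure", coords = "matrix",
                 times = "numeric"))

setValidity("MolTrajectory", function(object) {
  n <- nrow(object@topology@atoms)
  if (ncol(object@coords) != 3L * n)
    return(sprintf("coords must have %d columns (3 x %d atoms), found %d",
                   3L * n, n, ncol(object@coords)))
  if (nrow(object@coords) != length(object@times))
    return("one time stamp per frame is required")
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  if (!all(is.finite(object@coords)))
    return("all frame coordinates must be finite")
  TRUE
})

#' Construct a MolTrajectory
#'
#' @param topology a [MolStructure-class].
#' @param coords numeric matrix `nframes x (3 * natoms)`, Angstrom.
#' @param times numeric vector of times in ns; defaults to
#'   `(0:(nframes-1)) * timeStep`.
#' @param timeStep frame spacing in ns used when `times` is missing.
#' @return A [MolTrajectory-class] object.
#' @export
MolTrajectory <- function(topology, coords, times = NULL, timeStep = 0.1) {
  coords <- as.matrix(coords)
  if (is.null(times)) times <- (seq_len(nrow(coords)) - 1) * timeStep
  new("MolTrajectory", topology = topology, coords = coords,
      times = as.numeric(times))
}

#' Proper rigid-body transform
#'
#' @slot rotation 3x3 proper orthogonal matrix.
#' @slot translation numeric(3), Angstrom.
#' @aliases RigidTransform
#' @exportClass RigidTransform
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
  if (max(abs(R %*% t(R) - diag(3))) > 1e-10)
    return("rotation must be orthogonal to 1e-10")
  if (abs(det(R) - 1) > 1e-10)
    return("rotation must be proper (det = +1 to 1e-10)")
  if (length(object@translation) != 3L)
    return("translation must be length 3")
  TRUE
})

#' Labelled reference conformation
#'
#' A reference state of the binding-loop classification (conventionally
#' `S1` for the unligated crystal, `S1p` for the equilibrated
#' intermediate, `S2` for the ligated crystal), together with the
#' selection the structures are aligned on and the loop selection the
#' RMSD is measured over.
#'
#' @slot label character(1) state label.
#' @slot structure the reference [MolStructure-class].
#' @slot alignSel selection expression for the alignment atoms.
#' @slot loopSel selection expression for the loop atoms.
#' @aliases ReferenceState
#' @exportClass ReferenceState
setClass("ReferenceState",
  representation(label = "character", structure = "MolStructure",
                 alignSel = "character", loopSel = "character"))

setValidity("ReferenceState", function(object) {
  if (length(object@label) != 1L || !nzchar(object@label))
    return("label must be a non-empty string")
  TRUE
})

#' @rdname ReferenceState-class
#' @param label state label, e.g. `"S1"`.
#' @param structure reference [MolStructure-class].
#' @param alignSel,loopSel selection expressions (see
#'   [resolveSelection()]).
#' @export
ReferenceState <- function(label, structure, alignSel, loopSel) {
  new("ReferenceState", label = label, structure = structure,
      alignSel = alignSel, loopSel = loopSel)
}

#' Domain-orientation definition
#'
#' Defines one interdomain orientation angle: structures are aligned on
#' `alignSel`, and the angle is measured between the reference vector
#' (hinge centre to body centre, both on the reference) and the
#' per-frame vector (reference hinge centre to the aligned frame's body
#' centre).
#'
#' @slot hingeSel selection for the heavy atoms of the two hinge residues.
#' @slot bodySel selection for the heavy atoms of the oriented domain.
#' @slot alignSel selection the structures are aligned on first.
#' @slot reference reference [MolStructure-class].
#' @aliases OrientationDefinition
#' @exportClass OrientationDefinition
setClass("OrientationDefinition",
  representation(hingeSel = "character", bodySel = "character",
                 alignSel = "character", reference = "MolStructure"))

#' @rdname OrientationDefinition-class
#' @param hingeSel,bodySel,alignSel selection expressions.
#' @param reference reference [MolStructure-class].
#' @export
OrientationDefinition <- function(hingeSel, bodySel, alignSel, reference) {
  hi <- resolveSelection(hingeSel, reference)
  bi <- resolveSelection(bodySel, reference)
  if (length(intersect(hi, bi)))
    stop("hinge and body selections must be disjoint on the reference")
  new("OrientationDefinition", hingeSel = hingeSel, bodySel = bodySel,
      alignSel = alignSel, reference = reference)
}

#' Smooth cutoff scheme for nonbonded interactions
#'
#' Interactions are at full strength up to `rOn`, tapered by a C1
#' polynomial switch between `rOn` and `rOff`, and exactly zero beyond
#' `rOff`.  Defaults are the conventional 10--12 Angstrom smooth cutoff.
#'
#' @slot rOn switch-on distance, Angstrom.
#' @slot rOff cutoff distance, Angstrom.
#' @aliases CutoffScheme
#' @exportClass CutoffScheme
setClass("CutoffScheme",
  representation(rOn = "numeric", rOff = "numeric"),
  prototype(rOn = 10, rOff = 12))

setValidity("CutoffScheme", function(object) {
  if (!(object@rOn > 0 && object@rOff > object@rOn))
    return("require 0 < rOn < rOff")
  TRUE
})

#' @rdname CutoffScheme-class
#' @param rOn,rOff switch-on and cutoff distances in Angstrom.
#' @export
CutoffScheme <- function(rOn = 10, rOff = 12) {
  new("CutoffScheme", rOn = rOn, rOff = rOff)
}

#' Per-frame interaction-energy profile
#'
#' @slot times frame times, ns.
#' @slot vdw van der Waals energy per frame, kcal/mol.
#' @slot elec electrostatic energy per frame, kcal/mol.
#' @slot total total nonbonded energy per frame, kcal/mol
#'   (`vdw + elec`).
#' @aliases EnergyProfile
#' @exportClass EnergyProfile
setClass("EnergyProfile",
  representation(times = "numeric", vdw = "numeric", elec = "numeric",
                 total = "numeric"))

setValidity("EnergyProfile", function(object) {
  n <- length(object@times)
  if (length(object@vdw) != n || length(object@elec) != n ||
      length(object@total) != n)
    return("times, vdw, elec and total must have equal length")
  if (n && max(abs(object@total - (object@vdw + object@elec))) > 1e-9)
    return("total must equal vdw + elec to 1e-9 kcal/mol")
  TRUE
})

#' @rdname EnergyProfile-class
#' @param times,vdw,elec numeric vectors of equal length.
#' @export
EnergyProfile <- function(times, vdw, elec) {
  new("EnergyProfile", times = as.numeric(times), vdw = as.numeric(vdw),
      elec = as.numeric(elec), total = as.numeric(vdw) + as.numeric(elec))
}

#' Steered-pulling setup
#'
#' Describes a forced-dissociation protocol: the held atom, the single
#' pulled atom, and either a constant force (`mode = "cf"`) or constant
#' pulling velocity with a spring (`mode = "cv"`).
#'
#' @slot fixedSel selection of the held atom(s).
#' @slot pulledSel selection resolving to exactly one atom.
#' @slot mode `"cf"` or `"cv"`.
#' @slot forcePN constant force, pN (cf mode).
#' @slot velocityAps pulling velocity, Angstrom per ps (cv mode).
#' @slot springPNperA spring constant, pN per Angstrom (cv mode).
#' @aliases PullingSetup
#' @exportClass PullingSetup
setClass("PullingSetup",
  representation(fixedSel = "character", pulledSel = "character",
                 mode = "character", forcePN = "numeric",
                 velocityAps = "numeric", springPNperA = "numeric"))

setValidity("PullingSetup", function(object) {
  if (!object@mode %in% c("cf", "cv"))
    return("mode must be 'cf' or 'cv'")
  if (object@mode == "cf" && !length(object@forcePN))
    return("cf mode requires forcePN")
  if (object@mode == "cv" &&
      (!length(object@velocityAps) || !length(object@springPNperA)))
    return("cv mode requires velocityAps and springPNperA")
  TRUE
})

#' @rdname PullingSetup-class
#' @param fixedSel,pulledSel selection expressions.
#' @param mode `"cf"` (constant force) or `"cv"` (constant velocity).
#' @param forcePN constant force in pN (default 300, cf mode).
#' @param velocityAps pulling velocity in Angstrom/ps (default 0.01, cv).
#' @param springPNperA spring constant in pN/Angstrom (default 70, cv).
#' @export
PullingSetup <- function(fixedSel, pulledSel, mode = c("cv", "cf"),
                         forcePN = 300, velocityAps = 0.01,
                         springPNperA = 70) {
  mode <- match.arg(mode)
  new("PullingSetup", fixedSel = fixedSel, pulledSel = pulledSel,
      mode = mode, forcePN = forcePN, velocityAps = velocityAps,
      springPNperA = springPNperA)
}

# ---- accessors -------------------------------------------------------------

#' Number of atoms
#' @param x a MolStructure or MolTrajectory.
#' @return integer(1).
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "MolStructure", function(x) nrow(x@atoms))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "MolTrajectory", function(x) nrow(x@topology@atoms))

#' Number of frames in a trajectory
#' @param x a MolTrajectory.
#' @return integer(1).
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "MolTrajectory", function(x) nrow(x@coords))

#' Atom table of a structure
#' @param x a MolStructure or MolTrajectory.
#' @return data.frame of atom records in file order.
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @rdname atomTable
#' @export
setMethod("atomTable", "MolStructure", function(x) x@atoms)

#' @rdname atomTable
#' @export
setMethod("atomTable", "MolTrajectory", function(x) x@topology@atoms)

#' Coordinates as an N x 3 matrix
#'
#' @param x a MolStructure or MolTrajectory.
#' @param frame frame index (1-based) for trajectories.
#' @return numeric N x 3 matrix, Angstrom.
#' @export
setGeneric("coords", function(x, frame = 1L) standardGeneric("coords"))

#' @rdname coords
#' @export
setMethod("coords", "MolStructure", function(x, frame = 1L) {
  unname(as.matrix(x@atoms[, c("x", "y", "z")]))
})

#' @rdname coords
#' @export
setMethod("coords", "MolTrajectory", function(x, frame = 1L) {
  matrix(x@coords[frame, ], ncol = 3L, byrow = TRUE)
})

#' Frame times of a trajectory, ns
#' @param x a MolTrajectory or EnergyProfile.
#' @return numeric vector.
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname frameTimes
#' @export
setMethod("frameTimes", "MolTrajectory", function(x) x@times)

#' @rdname frameTimes
#' @export
setMethod("frameTimes", "EnergyProfile", function(x) x@times)

#' Convert an energy profile to a data.frame
#'
#' @param x an EnergyProfile.
#' @param row.names,optional,... ignored, present for generic
#'   compatibility.
#' @return data.frame with columns `time_ns`, `vdw`, `elec`, `total`
#'   (kcal/mol).
#' @export
as.data.frame.EnergyProfile <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  data.frame(time_ns = x@times, vdw = x@vdw, elec = x@elec,
             total = x@total)
}

setMethod("show", "MolStructure", function(object) {
  a <- object@atoms
  cat(sprintf("MolStructure '%s': %d atoms, %d residues, chains %s\n",
              object@label, nrow(a),
              length(unique(paste(a$chain, a$resno))),
              paste(sort(unique(a$chain)), collapse = ",")))
})

setMethod("show", "MolTrajectory", function(object) {
  cat(sprintf(
    "MolTrajectory: %d frames x %d atoms, t = %.4g..%.4g ns\n",
    nFrames(object), nAtoms(object),
    object@times[1L], object@times[length(object@times)]))
})

setMethod("show", "EnergyProfile", function(object) {
  cat(sprintf(
    "EnergyProfile: %d frames, total %.4g..%.4g kcal/mol\n",
    length(object@times),
    if (length(object@total)) min(object@total) else NA,
    if (length(object@total)) max(object@total) else NA))
})

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform\n  rotation:\n")
  print(round(object@rotation, 6))
  cat("  translation:", paste(round(object@translation, 6),
                              collapse = " "), "\n")
})
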