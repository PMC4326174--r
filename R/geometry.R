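# Rigid-body geometry kernels: geometric centres, optimal superposition
# (Kabsch, SVD form with reflection guard), selection-based RMSD,
# vector angles and axis projections.  Everything downstream is built
# from these.

#' Geometric centre of a coordinate set
#'
#' The unweighted arithmetic mean of the coordinates (no mass
#' weighting).
#'
#' @param xyz numeric N x 3 matrix, Angstrom, N >= 1.
#' @return numeric(3), Angstrom.
#' @export
geometricCenter <- function(xyz) {
  xyz <- rbind(xyz)
  if (nrow(xyz) == 0L) stop("geometricCenter: empty coordinate set")
  colMeans(xyz)
}

#' Optimal rigid-body superposition
#'
#' Finds the proper rigid transform (rotation + translation, no
#' reflection) minimising the RMSD between `mobile` and `target`, with
#' point correspondence by row index.  Uses the SVD solution of the
#' cross-covariance matrix with the determinant sign guard that
#' excludes improper rotations.
#'
#' @param mobile,target numeric N x 3 matrices, N >= 3, non-collinear.
#' @return list with elements `transform` (a [RigidTransform-class])
#'   and `rmsd` (the minimised RMSD, Angstrom).  Applying the transform
#'   to `mobile` (see [applyTransform()]) gives the least-RMSD fit onto
#'   `target`.
#' @export
superpose <- function(mobile, target) {
  mobile <- rbind(mobile); target <- rbind(target)
  if (!all(dim(mobile) == dim(target)))
    stop("superpose: point sets must have equal dimensions")
  n <- nrow(mobile)
  if (n < 3L) stop("superpose: at least 3 points are required")
  cm <- colMeans(mobile); ct <- colMeans(target)
  P <- sweep(mobile, 2L, cm); Q <- sweep(target, 2L, ct)
  H <- crossprod(P, Q)                      # sum_i p_i q_i^T
  sv <- svd(H)
  scale <- max(svd(P)$d[1L], svd(Q)$d[1L])
  if (scale <= 0 || min(svd(P)$d[2L], svd(Q)$d[2L]) <= 1e-10 * scale)
    stop("superpose: degenerate (collinear or coincident) point set")
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  trans <- as.numeric(ct - R %*% cm)
  ss <- sum(P^2) + sum(Q^2) - 2 * sum(sv$d * c(1, 1, d))
  rmsd <- sqrt(max(ss, 0) / n)
  list(transform = new("RigidTransform", rotation = R,
                       translation = trans),
       rmsd = rmsd)
}

#' Apply a rigid transform to coordinates
#'
#' @param transform a [RigidTransform-class].
#' @param xyz numeric N x 3 matrix.
#' @return transformed N x 3 matrix: `xyz %*% t(R) + t`.
#' @export
applyTransform <- function(transform, xyz) {
  xyz <- rbind(xyz)
  sweep(xyz %*% t(transform@rotation), 2L, transform@translation, "+")
}

.rmsd_plain <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

# coordinate-level core shared by rmsdAfterAlignment and the series ops
.rmsd_aligned_xyz <- function(frame_xyz, ref_xyz, align_idx_frame,
                              align_idx_ref, meas_idx_frame,
                              meas_idx_ref) {
  if (length(align_idx_frame) != length(align_idx_ref))
    stop("alignment selections resolve to different atom counts")
  if (length(meas_idx_frame) != length(meas_idx_ref))
    stop("measurement selections resolve to different atom counts")
  fit <- superpose(frame_xyz[align_idx_frame, , drop = FALSE],
                   ref_xyz[align_idx_ref, , drop = FALSE])
  moved <- applyTransform(fit$transform,
                          frame_xyz[meas_idx_frame, , drop = FALSE])
  .rmsd_plain(moved, ref_xyz[meas_idx_ref, , drop = FALSE])
}

#' RMSD of a selection after alignment on another selection
#'
#' The rigid transform fitted on the `alignSel` atoms is applied to the
#' `measureSel` atoms of `mobile`, and the RMSD against the reference
#' is computed over `measureSel` only.  This is the construction behind
#' loop-RMSD metrics such as the binding-loop RMSD relative to labelled
#' reference conformations, aligned on the rigid core of the domain.
#'
#' @param mobile a [MolStructure-class] (e.g. one trajectory frame).
#' @param reference a [MolStructure-class].
#' @param alignSel,measureSel selection expressions resolved on both
#'   structures; each must give equal atom counts on the two.
#' @return RMSD in Angstrom.
#' @export
rmsdAfterAlignment <- function(mobile, reference, alignSel, measureSel) {
  .rmsd_aligned_xyz(coords(mobile), coords(reference),
                    resolveSelection(alignSel, mobile),
                    resolveSelection(alignSel, reference),
                    resolveSelection(measureSel, mobile),
                    resolveSelection(measureSel, reference))
}

#' Angle between two vectors
#'
#' @param u,v numeric(3) vectors with norm > 1e-9.
#' @return angle in degrees, in `[0, 180]`.  Computed with the
#'   half-angle `atan2` form, which is accurate near 0 and 180 degrees
#'   where the arccosine of a clamped dot product loses precision.
#' @export
vectorAngle <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu <= 1e-9 || nv <= 1e-9)
    stop("vectorAngle: zero-length vector")
  un <- u / nu; vn <- v / nv
  2 * atan2(sqrt(sum((un - vn)^2)), sqrt(sum((un + vn)^2))) * 180 / pi
}

#' Signed projection of a point on an axis
#'
#' @param point,origin numeric(3), Angstrom.
#' @param axis numeric(3); normalised internally, must be non-zero.
#' @return signed scalar projection of `point - origin` on `axis`,
#'   Angstrom.
#' @export
projectAlong <- function(point, origin, axis) {
  na <- sqrt(sum(axis^2))
  if (na <= 1e-9) stop("projectAlong: zero axis")
  sum((point - origin) * axis) / na
}

# uniform random rotation matrices (quaternion method), used by the
# synthetic generator and invariance tests
.random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3L, byrow = TRUE)
}

# rotation by angle (degrees) about unit axis through the origin
.axis_rotation <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  c1 <- cos(th); s1 <- sin(th)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
              nrow = 3L, byrow = TRUE)
  diag(3) + s1 * K + (1 - c1) * (K %*% K)
}
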