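#' Body pose: ZYZ Euler angles and in-plane origin shift
#'
#' A pose holds the orientation of a rigid body in a particle image as
#' intrinsic ZYZ Euler angles (`rot`, `tilt`, `psi`, degrees) together with
#' an in-plane origin shift (`shift_x`, `shift_y`, pixels). The rotation
#' matrix of a pose maps reference-frame coordinates into the projection
#' frame; the projection integrates along the rotated +Z axis.
#'
#' @param rot,tilt,psi Euler angles in degrees (ZYZ intrinsic).
#' @param shift_x,shift_y Origin shift in pixels.
#' @return An object of class `"pose"`.
#' @export
pose <- function(rot = 0, tilt = 0, psi = 0, shift_x = 0, shift_y = 0) {
  vals <- c(rot, tilt, psi, shift_x, shift_y)
  if (!all(is.finite(vals)))
    stop_invalid("pose parameters must be finite")
  structure(list(rot = rot, tilt = tilt, psi = psi,
                 shift_x = shift_x, shift_y = shift_y),
            class = "pose")
}

#' @export
print.pose <- function(x, ...) {
  cat(sprintf("pose: rot %.3f deg, tilt %.3f deg, psi %.3f deg, shift (%.3f, %.3f) px\n",
              x$rot, x$tilt, x$psi, x$shift_x, x$shift_y))
  invisible(x)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Wrap an angle in degrees to (-180, 180].
wrap_angle <- function(a) {
  w <- (a + 180) %% 360 - 180
  ifelse(w == -180, 180, w)
}

rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}

rot_y <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3)
}

#' Euler angles to rotation matrix
#'
#' Composes `Rz(psi) %*% Ry(tilt) %*% Rz(rot)` (intrinsic ZYZ). The
#' resulting matrix takes reference-frame coordinates into the particle's
#' projection frame, whose +Z axis is the projection direction.
#'
#' @param pose A [pose()] (shifts are ignored here).
#' @return A 3x3 rotation matrix (orthonormal, determinant +1).
#' @export
euler_to_matrix <- function(pose) {
  if (!inherits(pose, "pose")) {
    v <- as.numeric(pose)
    if (length(v) < 3 || !all(is.finite(v)))
      stop_invalid("pose must be a pose object or three finite Euler angles")
    pose <- list(rot = v[1], tilt = v[2], psi = v[3])
  }
  if (!all(is.finite(c(pose$rot, pose$tilt, pose$psi))))
    stop_invalid("Euler angles must be finite")
  rot_z(deg2rad(pose$psi)) %*% rot_y(deg2rad(pose$tilt)) %*% rot_z(deg2rad(pose$rot))
}

check_rotation <- function(m, tol = 1e-6) {
  if (!is.matrix(m) || any(dim(m) != 3) || !all(is.finite(m)))
    stop_invalid("not a 3x3 numeric matrix")
  if (max(abs(crossprod(m) - diag(3))) > tol || abs(det(m) - 1) > tol)
    stop_invalid("matrix is not a proper rotation (orthonormality/det check failed)")
  invisible(m)
}

#' Rotation matrix to Euler angles
#'
#' Inverse of [euler_to_matrix()]. At the tilt degeneracies (0 or 180
#' degrees) the split between `rot` and `psi` is undefined; the tie-break
#' sets `rot = 0` and puts the whole in-plane angle into `psi`.
#'
#' @param m A 3x3 rotation matrix.
#' @return A [pose()] with zero shifts.
#' @export
matrix_to_euler <- function(m) {
  check_rotation(m)
  ct <- max(-1, min(1, m[3, 3]))
  tilt <- acos(ct)
  if (abs(ct) > 1 - 1e-12) {
    rot <- 0
    psi <- if (ct > 0) atan2(m[2, 1], m[1, 1]) else atan2(-m[2, 1], -m[1, 1])
  } else {
    rot <- atan2(m[3, 2], -m[3, 1])
    psi <- atan2(m[2, 3], m[1, 3])
  }
  pose(rot = wrap_angle(rad2deg(rot)),
       tilt = rad2deg(tilt),
       psi = wrap_angle(rad2deg(psi)))
}

#' Relative rotation between two poses
#'
#' Computes `R = E_a %*% t(E_b)` together with the total rotation angle
#' `acos((tr(R) - 1) / 2)` in degrees and the per-Euler-angle decomposition
#' of `R`. The total angle is the geodesic distance on SO(3) and is what the
#' conformational-distribution analysis histograms.
#'
#' @param pose_a,pose_b Poses ([pose()]).
#' @return List with `matrix`, `angle` (degrees) and `euler` (pose of `R`).
#' @export
relative_rotation <- function(pose_a, pose_b) {
  ea <- euler_to_matrix(pose_a)
  eb <- euler_to_matrix(pose_b)
  r <- ea %*% t(eb)
  ang <- acos(max(-1, min(1, (sum(diag(r)) - 1) / 2)))
  list(matrix = r, angle = rad2deg(ang), euler = matrix_to_euler(r))
}

#' Predicted in-image shift of a body anchor
#'
#' Projects a body's 3D anchor offset (its center relative to the composite
#' volume center, in voxels) onto the image plane for a given pose and adds
#' the pose's own origin shift: `P_XY(E %*% anchor) + shift`. This is the
#' predicted in-image center of the body relative to the box center.
#'
#' @param anchor Numeric length-3 voxel offset of the body center.
#' @param pose A [pose()].
#' @return Numeric `c(dx, dy)` in pixels.
#' @export
project_anchor <- function(anchor, pose) {
  anchor <- as.numeric(anchor)
  if (length(anchor) != 3 || !all(is.finite(anchor)))
    stop_invalid("anchor must be a finite length-3 vector")
  e <- euler_to_matrix(pose)
  p <- e %*% anchor
  c(p[1] + pose$shift_x, p[2] + pose$shift_y)
}
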