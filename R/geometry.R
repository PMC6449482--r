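# Small 3D geometry kernel used by the forward-kinematics builder and the
# analysis code.  Coordinates are plain numeric length-3 vectors or n x 3
# matrices, units are Angstrom; angles are radians unless a function name says
# otherwise.

DEG <- pi / 180

deg2rad <- function(x) x * DEG
rad2deg <- function(x) x / DEG

#' Wrap angles into (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return angles wrapped to the principal interval (-pi, pi].
#' @keywords internal
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- pi  # map the -pi boundary to +pi so the interval is (-pi, pi]
  y
}

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Bond angle at b formed by atoms a-b-c (radians)
#' @keywords internal
bond_angle <- function(a, b, c) {
  u <- unit(a - b); v <- unit(c - b)
  acos(max(-1, min(1, sum(u * v))))
}

#' Dihedral angle of the chain a-b-c-d (radians, IUPAC sign convention)
#' @keywords internal
dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

#' Place an atom by internal coordinates (natural extension reference frame)
#'
#' Given positions of three reference atoms \code{a} (great-grandparent),
#' \code{b} (grandparent) and \code{c} (parent), returns the position of the
#' new atom at bond length \code{blen} from \code{c}, bond angle \code{bang}
#' at \code{c} with respect to \code{b}, and dihedral \code{tors} about the
#' b-c axis with respect to \code{a}.
#'
#' @param a,b,c reference positions (length-3 numerics).
#' @param blen bond length, Angstrom.
#' @param bang bond angle, radians.
#' @param tors dihedral, radians.
#' @keywords internal
nerf_place <- function(a, b, c, blen, bang, tors) {
  bc <- unit(c - b)
  n <- cross3(b - a, bc)
  nn <- vnorm(n)
  if (nn < 1e-10) {
    # collinear reference: pick any perpendicular
    ref <- if (abs(bc[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    n <- cross3(ref, bc)
    nn <- vnorm(n)
  }
  n <- n / nn
  m <- cross3(n, bc)
  d2 <- blen * sin(bang)
  c + (-blen * cos(bang)) * bc + (d2 * cos(tors)) * m - (d2 * sin(tors)) * n
}

#' Rotation matrix from intrinsic Z-Y-X Euler angles
#'
#' @param e numeric length-3, Euler angles (radians): yaw about z, pitch about
#'   the new y, roll about the new x.
#' @return 3x3 proper rotation matrix.
#' @export
euler_to_rot <- function(e) {
  cz <- cos(e[1]); sz <- sin(e[1])
  cy <- cos(e[2]); sy <- sin(e[2])
  cx <- cos(e[3]); sx <- sin(e[3])
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

#' Euler angles (intrinsic Z-Y-X) from a rotation matrix
#' @param R 3x3 proper rotation matrix.
#' @return Euler angles (radians), intrinsic Z-Y-X.
#' @export
rot_to_euler <- function(R) {
  sy <- -R[3, 1]
  sy <- max(-1, min(1, sy))
  pitch <- asin(sy)
  if (abs(sy) < 1 - 1e-9) {
    yaw <- atan2(R[2, 1], R[1, 1])
    roll <- atan2(R[3, 2], R[3, 3])
  } else {
    yaw <- atan2(-R[1, 2], R[2, 2])
    roll <- 0
  }
  c(yaw, pitch, roll)
}

#' Rotation matrix about an arbitrary axis
#'
#' @param axis rotation axis (length-3, any norm).
#' @param theta angle, radians.
#' @return 3x3 proper rotation matrix.
#' @export
axis_rot <- function(axis, theta) {
  u <- unit(axis)
  ct <- cos(theta); st <- sin(theta)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct), ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct), uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), 3, 3, byrow = TRUE)
}

# package version, tolerant of running from a source tree
.pkg_version <- function() {
  tryCatch(as.character(utils::packageVersion("channelmcm")),
           error = function(e) "dev")
}
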