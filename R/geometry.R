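#' Rigid-body transform
#'
#' A rigid transform maps points as `p_out = rotation %*% p + translation`.
#' In this package a head pose is the rigid transform taking a frame's
#' coordinates into the reference coordinate system. All lengths are in
#' millimetres, angles in radians.
#'
#' @param rotation 3x3 rotation matrix (orthonormal, determinant +1).
#' @param translation length-3 numeric translation vector (mm).
#' @return An object of class `rigid_transform` with fields `rotation` and
#'   `translation`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(identical(dim(rotation), c(3L, 3L)), length(translation) == 3L)
  if (!all(is.finite(rotation)) || !all(is.finite(translation)))
    stop("rigid_transform: non-finite entries")
  err <- max(abs(crossprod(rotation) - diag(3)))
  if (err > 1e-6)
    stop(sprintf("rigid_transform: rotation not orthonormal (max dev %.3g)", err))
  if (abs(det(rotation) - 1) > 1e-6)
    stop("rigid_transform: rotation determinant is not +1 (reflection?)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @export
rt_identity <- function() rigid_transform()

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle(x$rotation)
  cat(sprintf("<rigid_transform> |t| = %.4g mm, rotation angle = %.4g deg\n",
              sqrt(sum(x$translation^2)), ang * 180 / pi))
  invisible(x)
}

is_rigid_transform <- function(x) inherits(x, "rigid_transform")

rotation_angle <- function(R) {
  c <- (sum(diag(R)) - 1) / 2
  acos(min(1, max(-1, c)))
}

#' Compose two rigid transforms
#'
#' `rt_compose(a, b)` is the transform applying `b` first, then `a`:
#' `rt_compose(a, b)(p) = a(b(p))`.
#'
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
rt_compose <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#'
#' @param t A `rigid_transform`.
#' @return The inverse transform, so that `rt_compose(t, rt_invert(t))` is
#'   the identity.
#' @export
rt_invert <- function(t) {
  Rt <- t(t$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% t$translation))
}

#' Apply a rigid transform to points
#'
#' @param t A `rigid_transform`.
#' @param points N x 3 numeric matrix, or a length-3 vector.
#' @return Transformed points, same shape as the input.
#' @export
rt_apply <- function(t, points) {
  if (is.null(dim(points))) {
    as.numeric(t$rotation %*% points) + t$translation
  } else {
    sweep(points %*% t(t$rotation), 2, t$translation, "+")
  }
}

#' Elementary transforms
#'
#' `rt_translate` builds a pure translation; `rt_rotate` a rotation by
#' `angle` radians about a unit `axis` through the point `center`.
#'
#' @param x,y,z translation components (mm), or `x` a length-3 vector.
#' @param angle rotation angle in radians.
#' @param axis length-3 rotation axis (normalized internally).
#' @param center point on the rotation axis (mm).
#' @return A `rigid_transform`.
#' @export
rt_translate <- function(x, y = NULL, z = NULL) {
  v <- if (is.null(y)) as.numeric(x) else c(x, y, z)
  rigid_transform(diag(3), v)
}

#' @rdname rt_translate
#' @export
rt_rotate <- function(angle, axis = c(0, 0, 1), center = c(0, 0, 0)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  center <- as.numeric(center)
  rigid_transform(R, center - as.numeric(R %*% center))
}

#' Quaternion representation of rotations
#'
#' Quaternions are stored scalar-first as `c(w, x, y, z)` and normalized to
#' unit length. `q` and `-q` encode the same rotation; no global hemisphere
#' convention is imposed here — sign continuity is enforced where sequences
#' of quaternions are averaged (trace resampling) or concatenated
#' (respiration mutual information).
#'
#' @param t A `rigid_transform` (or 3x3 rotation matrix for
#'   `quat_from_rotation`).
#' @return `as_quaternion` returns a length-4 unit quaternion.
#' @export
as_quaternion <- function(t) {
  R <- if (is_rigid_transform(t)) t$rotation else as.matrix(t)
  quat_from_rotation(R)
}

#' @rdname as_quaternion
#' @param R 3x3 rotation matrix.
#' @export
quat_from_rotation <- function(R) {
  if (max(abs(crossprod(R) - diag(3))) > 1e-6)
    stop("quat_from_rotation: matrix is not a rotation")
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
             (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
             0.25 * s, (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, 0.25 * s)
    }
  }
  q / sqrt(sum(q^2))
}

#' @rdname as_quaternion
#' @param q length-4 quaternion, scalar first (normalized internally).
#' @export
rotation_from_quat <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

#' @rdname as_quaternion
#' @param translation length-3 translation (mm).
#' @export
from_quaternion <- function(q, translation = c(0, 0, 0)) {
  rigid_transform(rotation_from_quat(q), translation)
}

#' Head ball model
#'
#' The head is modelled as a ball over which pose differences are averaged;
#' the default radius of 82.5 mm is the population-average distance from the
#' face to the head center. The center is given in the working (anatomical
#' or scanner) coordinate system in mm.
#'
#' @param center length-3 ball center (mm).
#' @param radius ball radius (mm), positive.
#' @return An object of class `ball_model`.
#' @export
ball_model <- function(center = c(0, 0, 0), radius = 82.5) {
  center <- as.numeric(center)
  stopifnot(length(center) == 3L, is.finite(radius), radius > 0)
  structure(list(center = center, radius = radius), class = "ball_model")
}

#' Head pose difference (HPD)
#'
#' Root-mean-square displacement, over a ball modelling the head, induced by
#' the relative transform between two poses. For the left-relative transform
#' `D = b o a^-1`, with `A = D$rotation - I` and ball center `c`,
#'
#'   `hpd = sqrt( radius^2/5 * tr(A'A) + || D$translation + A c ||^2 )`
#'
#' which equals the RMS of `||D(p) - p||` over points `p` uniform in the
#' ball. HPD is a pseudo-metric: non-negative, symmetric, zero iff the
#' relative transform moves no point of the ball; and it is invariant to
#' right-composition of both poses by a common transform (a change of the
#' reference pose).
#'
#' @param a,b `rigid_transform` head poses.
#' @param ball A `ball_model`.
#' @return Displacement in mm.
#' @export
hpd <- function(a, b, ball = ball_model()) {
  D <- rt_compose(b, rt_invert(a))
  A <- D$rotation - diag(3)
  v <- D$translation + as.numeric(A %*% ball$center)
  sqrt(ball$radius^2 / 5 * sum(A * A) + sum(v * v))
}

# hpd between pose i and i+1 of quaternion/translation arrays (used by the
# motion score); qmat N x 4, tmat N x 3.
hpd_consecutive <- function(qmat, tmat, ball) {
  n <- nrow(qmat)
  if (n < 2) return(numeric(0))
  out <- numeric(n - 1)
  for (i in seq_len(n - 1)) {
    Ri <- rotation_from_quat(qmat[i, ])
    Rj <- rotation_from_quat(qmat[i + 1, ])
    Rd <- Rj %*% t(Ri)
    td <- tmat[i + 1, ] - as.numeric(Rd %*% tmat[i, ])
    A <- Rd - diag(3)
    v <- td + as.numeric(A %*% ball$center)
    out[i] <- sqrt(ball$radius^2 / 5 * sum(A * A) + sum(v * v))
  }
  out
}
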