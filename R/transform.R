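#' Rigid transform
#'
#' A proper rigid transform `x -> R x + t` with `R` a 3x3 rotation matrix
#' (orthonormal, determinant +1) and `t` a translation in mm.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation 3-vector (mm).
#' @return an object of class `ctma_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || length(translation) != 3L)
    stop("rotation must be 3x3 and translation length 3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation matrix is not orthonormal (within 1e-9)")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation matrix is not proper (det != +1): reflection rejected")
  structure(list(rotation = rotation, translation = translation),
            class = "ctma_transform")
}

#' @export
print.ctma_transform <- function(x, ...) {
  e <- euler_angles(x)
  cat(sprintf(
    "ctma_transform: rot (deg, clinical sign) X %.3f Y %.3f Z %.3f; t (%.3f, %.3f, %.3f) mm\n",
    e[1], e[2], e[3], x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Compose two rigid transforms
#'
#' `compose_transform(t1, t2)` applies `t2` first, then `t1`.
#'
#' @param t1,t2 `ctma_transform` objects.
#' @return their composition as a `ctma_transform`.
#' @export
compose_transform <- function(t1, t2) {
  rigid_transform(t1$rotation %*% t2$rotation,
                  as.numeric(t1$rotation %*% t2$translation) + t1$translation)
}

#' Invert a rigid transform
#' @param t a `ctma_transform`.
#' @return the inverse transform.
#' @export
invert_transform <- function(t) {
  rigid_transform(t(t$rotation),
                  -as.numeric(crossprod(t$rotation, t$translation)))
}

#' Apply a rigid transform to points or a mesh
#'
#' @param t a `ctma_transform`.
#' @param x an n x 3 point matrix, a 3-vector, or a `ctma_mesh`.
#' @return the transformed object, of the same kind as the input.
#' @export
apply_transform <- function(t, x) {
  if (inherits(x, "ctma_mesh")) {
    x$vertices <- apply_transform(t, x$vertices)
    return(x)
  }
  if (is.null(dim(x))) {
    stopifnot(length(x) == 3L)
    return(as.numeric(t$rotation %*% x) + t$translation)
  }
  sweep(x %*% t(t$rotation), 2, t$translation, "+")
}

rot_x <- function(rad) {
  c0 <- cos(rad); s0 <- sin(rad)
  matrix(c(1, 0, 0, 0, c0, s0, 0, -s0, c0), 3, 3)
}
rot_y <- function(rad) {
  c0 <- cos(rad); s0 <- sin(rad)
  matrix(c(c0, 0, -s0, 0, 1, 0, s0, 0, c0), 3, 3)
}
rot_z <- function(rad) {
  c0 <- cos(rad); s0 <- sin(rad)
  matrix(c(c0, s0, 0, -s0, c0, 0, 0, 0, 1), 3, 3)
}

#' Rotation about a coordinate axis, clinical sign convention
#'
#' Builds the rotation matrix for a rotation about the X, Y or Z axis where
#' a positive angle is clockwise when looking along the positive axis
#' direction (the sign convention of the deformity report); this is the
#' negative of the mathematical right-hand-rule angle.
#'
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param angle_deg angle in degrees (clinical sign).
#' @param right_handed if `TRUE`, interpret `angle_deg` with the usual
#'   right-hand rule instead.
#' @return 3x3 rotation matrix.
#' @export
axis_rotation <- function(axis, angle_deg, right_handed = FALSE) {
  rad <- angle_deg * pi / 180
  if (!right_handed) rad <- -rad
  switch(tolower(axis), x = rot_x(rad), y = rot_y(rad), z = rot_z(rad),
         stop("axis must be x, y or z"))
}

#' Euler-angle decomposition of a rigid transform
#'
#' Decomposes the rotation as fixed-axis rotations applied in the order X,
#' then Y, then Z (`R = Rz Ry Rx` in right-handed matrices) and reports the
#' three angles in degrees under the clinical sign convention: clockwise
#' positive when looking along the positive axis.  Anatomically, the X
#' angle is recurvatum/antecurvatum, the Y angle varus/valgus and the Z
#' angle internal/external rotation of the distal segment.
#'
#' At gimbal lock (`|rotY| = 90` degrees) the X/Z split is not unique; the
#' convention `rotX = 0` is applied and the result carries attribute
#' `"gimbal_lock" = TRUE`.
#'
#' @param t a `ctma_transform` (or bare 3x3 rotation matrix).
#' @return named numeric vector `c(rotX, rotY, rotZ)` in degrees, each in
#'   (-180, 180].
#' @export
euler_angles <- function(t) {
  R <- if (inherits(t, "ctma_transform")) t$rotation else t
  gimbal <- FALSE
  sy <- -R[3, 1]                       # sin of right-handed Y angle
  if (abs(sy) >= 1 - 1e-12) {
    gimbal <- TRUE
    b <- if (sy > 0) pi / 2 else -pi / 2
    a <- 0
    cc <- if (sy > 0) -atan2(R[1, 2], R[1, 3]) else atan2(-R[1, 2], -R[1, 3])
  } else {
    b <- asin(sy)
    a <- atan2(R[3, 2], R[3, 3])
    cc <- atan2(R[2, 1], R[1, 1])
  }
  ang <- -c(a, b, cc) * 180 / pi       # clinical sign = negated right-hand
  ang[ang <= -180] <- ang[ang <= -180] + 360
  names(ang) <- c("rotX", "rotY", "rotZ")
  attr(ang, "gimbal_lock") <- gimbal
  ang
}

#' Build a rotation from clinical Euler angles
#'
#' Inverse of [euler_angles()]: fixed-axis X, then Y, then Z rotations with
#' clockwise-positive (clinical) angles in degrees.
#'
#' @param rotX,rotY,rotZ angles in degrees, clinical sign convention.
#' @return 3x3 rotation matrix.
#' @export
rotation_from_euler <- function(rotX = 0, rotY = 0, rotZ = 0) {
  rot_z(-rotZ * pi / 180) %*% rot_y(-rotY * pi / 180) %*%
    rot_x(-rotX * pi / 180)
}

#' Rotation angle of a transform
#'
#' Total rotation angle (degrees, always >= 0) of the rotation part,
#' independent of axis: `acos((trace(R) - 1) / 2)`.
#'
#' @param t a `ctma_transform` or 3x3 rotation matrix.
#' @export
rotation_angle <- function(t) {
  R <- if (inherits(t, "ctma_transform")) t$rotation else t
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

#' Serialize a rigid transform to JSON
#'
#' Writes the transform as a 4x4 homogeneous matrix in row-major order.
#'
#' @param t a `ctma_transform`.
#' @param path output path; if `NULL`, the JSON string is returned.
#' @export
write_transform_json <- function(t, path = NULL) {
  m <- rbind(cbind(t$rotation, t$translation), c(0, 0, 0, 1))
  obj <- list(matrix_4x4_row_major = as.numeric(t(m)))
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read a rigid transform from JSON
#' @param path path or JSON string produced by [write_transform_json()].
#' @return a `ctma_transform`.
#' @export
read_transform_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  m <- matrix(obj$matrix_4x4_row_major, 4, 4, byrow = TRUE)
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}
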