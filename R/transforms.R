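#' Rigid transform utilities
#'
#' A rigid transform is a 4x4 homogeneous matrix whose rotation block is
#' orthonormal with determinant +1 and whose translation is in millimetres.
#' These are the currency of tracked ultrasound: the probe calibration maps
#' image coordinates to the probe's pose sensor, and the electromagnetic
#' tracker reports a sensor-to-tracker pose per frame.
#'
#' @param m a 4x4 numeric matrix.
#' @param tol orthonormality / determinant tolerance.
#' @return `rigid_transform()` returns the validated matrix with class
#'   `"rigid_transform"`; `is_rigid_transform()` returns a logical.
#' @examples
#' rigid_transform(diag(4))
#' is_rigid_transform(diag(4))
#' @export
rigid_transform <- function(m, tol = 1e-6) {
  m <- as.matrix(m)
  if (!is.numeric(m) || !identical(dim(m), c(4L, 4L)))
    stop("a rigid transform must be a 4x4 numeric matrix", call. = FALSE)
  R <- m[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > tol)
    stop("rotation block is not orthonormal (R'R != I within tolerance)",
         call. = FALSE)
  if (abs(det(R) - 1) > tol)
    stop("rotation block has determinant != +1 (reflection rejected)",
         call. = FALSE)
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > tol)
    stop("bottom row of a homogeneous rigid transform must be (0 0 0 1)",
         call. = FALSE)
  structure(m, class = "rigid_transform")
}

#' @rdname rigid_transform
#' @export
is_rigid_transform <- function(m, tol = 1e-6) {
  is.matrix(m) && is.numeric(m) && identical(dim(m), c(4L, 4L)) &&
    max(abs(crossprod(m[1:3, 1:3]) - diag(3))) <= tol &&
    abs(det(m[1:3, 1:3]) - 1) <= tol &&
    max(abs(m[4, ] - c(0, 0, 0, 1))) <= tol
}

#' Apply a rigid transform to 3D points
#'
#' @param transform a 4x4 rigid transform.
#' @param p a length-3 vector or an N x 3 matrix of points (mm).
#' @return transformed points in the same shape as `p`.
#' @export
apply_transform <- function(transform, p) {
  transform <- rigid_transform(transform)
  if (is.null(dim(p))) {
    stopifnot(length(p) == 3)
    drop(transform %*% c(p, 1))[1:3]
  } else {
    stopifnot(ncol(p) == 3)
    ph <- cbind(p, 1) %*% t(transform)
    ph[, 1:3, drop = FALSE]
  }
}

#' Build a rigid transform from an axis-angle rotation and a translation
#'
#' @param axis rotation axis (length 3, need not be unit).
#' @param angle_deg rotation angle in degrees.
#' @param translation translation vector in mm (default zero).
#' @return a `rigid_transform`.
#' @export
rigid_from_axis_angle <- function(axis, angle_deg, translation = c(0, 0, 0)) {
  n <- sqrt(sum(axis^2))
  if (n == 0) {
    R <- diag(3)
  } else {
    a <- axis / n
    th <- angle_deg * pi / 180
    K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- translation
  rigid_transform(m)
}

# evaluate expr under a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
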