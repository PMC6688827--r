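#' Mass-weighted centre of mass
#'
#' No periodic unwrapping is applied here; callers working with molecules
#' split across the boundary should unwrap first (the synthetic systems are
#' always whole).
#'
#' @param top a [topology()]
#' @param fr a [frame()] (or N x 3 coordinate matrix)
#' @param indices particle indices (1-based); defaults to all particles
#' @return length-3 numeric (nm)
#' @export
center_of_mass <- function(top, fr, indices = seq_len(n_particles(top))) {
  if (!length(indices)) stop("center_of_mass: empty particle set")
  coords <- if (inherits(fr, "frame")) fr$coords else as.matrix(fr)
  m <- top$particles$mass[indices]
  colSums(coords[indices, , drop = FALSE] * m) / sum(m)
}

#' Minimum-image displacement and distance
#'
#' Each component of `p - q` is wrapped into `(-L/2, L/2]` for an
#' orthorhombic box with edge lengths `L`.
#'
#' @param p,q length-3 positions (nm)
#' @param box length-3 box edges (nm)
#' @return `min_image_disp`: length-3 displacement; `min_image_distance`:
#'   scalar distance (nm)
#' @export
min_image_disp <- function(p, q, box) {
  if (any(box <= 0)) stop("min_image: box edges must be > 0")
  d <- p - q
  d - box * round(d / box)
}

#' @rdname min_image_disp
#' @export
min_image_distance <- function(p, q, box) {
  sqrt(sum(min_image_disp(p, q, box)^2))
}

# wrap a matrix of displacements (rows) component-wise
wrap_disp <- function(d, box) {
  d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
}

# squared minimum-image distances between all rows of a and b: |a| x |b|
min_image_dist2_matrix <- function(a, b, box) {
  out <- matrix(0, nrow(a), nrow(b))
  for (k in 1:3) {
    d <- outer(a[, k], b[, k], "-")
    d <- d - box[k] * round(d / box[k])
    out <- out + d * d
  }
  out
}

#' Optimal (Kabsch) superposition rotation
#'
#' Returns the proper rotation `R` minimising the weighted RMSD of
#' `R (X - com_X)` onto `(Y - com_Y)`.  A reflection correction via the sign
#' of the determinant guarantees `det(R) = +1`.
#'
#' @param X,Y N x 3 coordinate matrices (N >= 3, not collinear)
#' @param weights per-particle weights (default uniform; pass masses for a
#'   mass-weighted fit)
#' @return 3 x 3 rotation matrix
#' @export
kabsch <- function(X, Y, weights = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y), ncol(X) == 3, ncol(Y) == 3)
  if (nrow(X) < 3) stop("kabsch: need at least 3 points")
  w <- if (is.null(weights)) rep(1, nrow(X)) else as.numeric(weights)
  w <- w / sum(w)
  Xc <- sweep(X, 2, colSums(X * w))
  Yc <- sweep(Y, 2, colSums(Y * w))
  H <- t(Xc * w) %*% Yc   # covariance of X onto Y
  sv <- svd(H)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1e-300))
    stop("kabsch: degenerate (collinear or coincident) input")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  R
}

#' In-plane (xy) fit of coordinates onto a reference
#'
#' Removes the xy translation (weighted COM match) and the rotation about the
#' z axis by closed-form 2D least squares; z coordinates and the tilt of the
#' structure are untouched.  This is the alignment applied before recording
#' the orientation scalar, so that only out-of-plane rotation is measured.
#'
#' @param coords,ref matched N x 3 matrices
#' @param weights optional per-particle weights
#' @return aligned N x 3 matrix
#' @export
fit_in_plane <- function(coords, ref, weights = NULL) {
  coords <- as.matrix(coords); ref <- as.matrix(ref)
  stopifnot(nrow(coords) == nrow(ref), ncol(coords) == 3)
  w <- if (is.null(weights)) rep(1, nrow(coords)) else as.numeric(weights)
  w <- w / sum(w)
  cxy <- colSums(coords[, 1:2, drop = FALSE] * w)
  rxy <- colSums(ref[, 1:2, drop = FALSE] * w)
  x <- sweep(coords[, 1:2, drop = FALSE], 2, cxy)
  y <- sweep(ref[, 1:2, drop = FALSE], 2, rxy)
  num <- sum(w * (x[, 1] * y[, 2] - x[, 2] * y[, 1]))
  den <- sum(w * (x[, 1] * y[, 1] + x[, 2] * y[, 2]))
  if (abs(num) < 1e-300 && abs(den) < 1e-300)
    stop("fit_in_plane: degenerate xy projection")
  th <- atan2(num, den)
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  out <- coords
  out[, 1:2] <- sweep(x %*% t(rot), 2, rxy, "+")
  out
}

#' Orientation scalar Rzz
#'
#' The frame is first fitted in the xy plane (parallel to the membrane
#' surface) against the reference; the (3,3) element of the residual Kabsch
#' rotation onto the reference is returned.  It equals the cosine of the tilt
#' away from the reference pose: 1 for the reference orientation, -1 for the
#' structure flipped upside down, and is invariant under rotations about z
#' and translations in xy.
#'
#' @inheritParams fit_in_plane
#' @return scalar in `[-1, 1]`
#' @export
rzz <- function(coords, ref, weights = NULL) {
  aligned <- fit_in_plane(coords, ref, weights)
  R <- kabsch(aligned, ref, weights)
  max(-1, min(1, R[3, 3]))
}

# ---- rotation helpers ------------------------------------------------------

#' Axis-angle rotation matrix
#' @param axis length-3 axis (normalised internally)
#' @param angle radians
#' @return 3 x 3 rotation matrix
#' @export
rotation_axis_angle <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# axis-angle decomposition of a rotation matrix
rotation_to_axis_angle <- function(R) {
  angle <- acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
  if (angle < 1e-12) return(list(axis = c(0, 0, 1), angle = 0))
  if (abs(angle - pi) < 1e-8) {
    # axis from the largest diagonal element of (R + I)/2
    B <- (R + diag(3)) / 2
    i <- which.max(diag(B))
    axis <- B[, i] / sqrt(B[i, i])
    return(list(axis = axis / sqrt(sum(axis^2)), angle = pi))
  }
  axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(angle))
  list(axis = axis, angle = angle)
}

# uniform random rotation (axis uniform on sphere, angle given)
random_small_rotation <- function(sd_angle) {
  v <- stats::rnorm(3)
  rotation_axis_angle(v, stats::rnorm(1, 0, sd_angle))
}
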