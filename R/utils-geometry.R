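# Small 3D linear-algebra helpers shared across the geometry, posing and
# shape modules. All coordinates are millimetres in a right-handed frame:
# +x lateral (mediolateral axis), +y palmar, +z distal.

vec_norm <- function(v) sqrt(sum(v * v))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues' formula for a right-handed rotation of `angle_deg` degrees
#' about the unit axis `axis`.
#'
#' @param axis length-3 axis vector (normalized internally).
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @keywords internal
rotation_about_axis <- function(axis, angle_deg) {
  u <- unit_vec(axis)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Minimal rotation taking unit vector a onto unit vector b.
rotation_between <- function(a, b) {
  a <- unit_vec(a); b <- unit_vec(b)
  v <- cross3(a, b)
  c_ <- sum(a * b)
  if (vec_norm(v) < 1e-12) {
    if (c_ > 0) return(diag(3))
    # opposite vectors: rotate pi about any axis perpendicular to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- unit_vec(cross3(a, p))
    return(rotation_about_axis(ax, 180))
  }
  K <- matrix(c(0, v[3], -v[2],
                -v[3], 0, v[1],
                v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K * ((1 - c_) / sum(v * v))
}

# Best-fit plane through points (n x 3): returns centroid and unit normal
# (smallest singular vector of the centred cloud).
fit_plane <- function(pts) {
  stopifnot(is.matrix(pts), ncol(pts) == 3, nrow(pts) >= 3)
  ctr <- colMeans(pts)
  X <- sweep(pts, 2, ctr)
  sv <- svd(X)
  d <- sv$d
  if (d[2] < 1e-9 * max(d[1], 1e-300)) {
    stop("degenerate facet: points are collinear")
  }
  list(centroid = ctr, normal = sv$v[, 3])
}

# Optimal rotation-only superimposition (Kabsch): rotation R minimizing
# ||A %*% R - B||_F for centred point sets A, B (n x 3). det(R) = +1 always;
# reflection is never folded into the fit.
kabsch_rotation <- function(A, B) {
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  sv$u %*% D %*% t(sv$v)
}
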