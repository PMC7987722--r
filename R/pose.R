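#' Pose a first metacarpal against a trapezium
#'
#' Programmatic stand-in for the manual articulation protocol: the two
#' bones are brought together at the geometric centres of their articular
#' facets, the metacarpal is spun about the shared facet normal until the
#' facet outlines register (least-squares), flexed toward palmar about the
#' mediolateral axis, and finally separated along the facet normal by a
#' cartilage-thickness gap.
#'
#' The mediolateral axis and the palmar direction are derived intrinsically
#' from the trapezium facet (its in-plane principal axis and the normal),
#' so the posed configuration is equivariant under rigid motions applied
#' jointly to both input bones. The flexion rotation passes through the
#' metacarpal facet centroid, which keeps the centroid-to-centroid distance
#' exactly equal to `gap_mm` after flexion.
#'
#' @param metacarpal,trapezium [bone_model()] objects carrying ordered
#'   articular facet outlines of equal length (>= 3 non-collinear points,
#'   matched ordering).
#' @param gap_mm intra-articular space between the facet centroids in mm
#'   (default 1.5, the mean combined cartilage thickness of the human TMC
#'   joint).
#' @param flexion_deg palmar flexion of the metacarpal at the joint in
#'   degrees (default 11, about a third of the mean maximum TMC flexion
#'   excursion).
#' @return an object of class `posed_thumb`: list with transformed
#'   `metacarpal`, untouched `trapezium`, joint point `j` (midpoint of the
#'   posed facet centroids), `gap`, `flexion_deg`, and `frame` tag.
#' @export
pose_tmc <- function(metacarpal, trapezium, gap_mm = 1.5, flexion_deg = 11) {
  stopifnot(inherits(metacarpal, "bone_model"), inherits(trapezium, "bone_model"))
  if (is.null(metacarpal$facet) || is.null(trapezium$facet))
    stop("both bones need articular facet outlines to be posed")
  if (nrow(metacarpal$facet) != nrow(trapezium$facet))
    stop("facet outlines must have matching point counts and ordering")
  if (gap_mm < 0) stop("gap_mm must be >= 0")
  if (!all(is.finite(c(gap_mm, flexion_deg)))) stop("non-finite posing parameters")

  tf <- facet_frame(trapezium)
  mf <- facet_frame(metacarpal)

  # 1. rotate the metacarpal so its facet normal faces the trapezium facet
  R1 <- rotation_between(mf$normal, -tf$normal)
  met <- transform_bone(metacarpal, R1, mf$centroid, mf$centroid)

  # 2. spin about the shared normal: least-squares registration of the two
  #    facet outlines (replaces the visual interlocking assessment)
  theta <- outline_spin_angle(met$facet, trapezium$facet, tf)
  R2 <- rotation_about_axis(tf$normal, theta)
  met <- transform_bone(met, R2, colMeans(met$facet), colMeans(met$facet))

  # 3. bring the facet centroids into contact at the trapezium centroid
  met <- translate_bone(met, tf$centroid - colMeans(met$facet))

  # 4. palmar flexion about the mediolateral axis through the (shared)
  #    facet centroid; sign chosen so the distal direction tilts palmar
  Rf <- rotation_about_axis(tf$axis_ml, -flexion_deg)
  met <- transform_bone(met, Rf, tf$centroid, tf$centroid)

  # 5. open the joint space along the trapezium facet normal
  met <- translate_bone(met, gap_mm * tf$normal)

  j <- (colMeans(met$facet) + tf$centroid) / 2
  structure(list(metacarpal = met, trapezium = trapezium, j = j,
                 gap = gap_mm, flexion_deg = flexion_deg,
                 frame = "RH mm; +x lateral, +y palmar, +z distal"),
            class = "posed_thumb")
}

#' @export
print.posed_thumb <- function(x, ...) {
  cat(sprintf("<posed_thumb> %s on %s; gap %.3g mm, flexion %.3g deg\n",
              x$metacarpal$bone_id, x$trapezium$bone_id, x$gap, x$flexion_deg))
  cat(sprintf("  joint point j = (%.3f, %.3f, %.3f) mm\n", x$j[1], x$j[2], x$j[3]))
  invisible(x)
}

# Intrinsic frame of an articular facet: centroid, outward unit normal
# (away from the bone's landmark cloud), in-plane principal (mediolateral)
# axis with sign fixed by the first outline point, and the derived palmar
# direction. All three are equivariant under rigid motion of the bone.
facet_frame <- function(bone) {
  pl <- fit_plane(bone$facet)
  interior <- colMeans(rbind(bone$landmarks, bone$facet))
  n <- pl$normal
  if (sum(n * (pl$centroid - interior)) < 0) n <- -n
  X <- sweep(bone$facet, 2, pl$centroid)
  # remove the normal component, take first principal direction in-plane
  Xp <- X - outer(c(X %*% n), n)
  a1 <- svd(Xp)$v[, 1]
  a1 <- a1 - sum(a1 * n) * n
  a1 <- unit_vec(a1)
  if (sum(a1 * (bone$facet[1, ] - pl$centroid)) < 0) a1 <- -a1
  list(centroid = pl$centroid, normal = n, axis_ml = a1,
       palmar = cross3(n, a1))
}

# Optimal spin (radians -> degrees) about the trapezium facet normal that
# registers the metacarpal outline onto the trapezium outline, via the 2D
# orthogonal-Procrustes closed form in the facet plane.
outline_spin_angle <- function(facet_m, facet_t, tf) {
  u <- unit_vec(tf$axis_ml)
  v <- cross3(tf$normal, u)
  to2d <- function(F3) {
    X <- sweep(F3, 2, colMeans(F3))
    cbind(c(X %*% u), c(X %*% v))
  }
  A <- to2d(facet_m)  # rotated onto B
  B <- to2d(facet_t)
  num <- sum(A[, 1] * B[, 2] - A[, 2] * B[, 1])
  den <- sum(A[, 1] * B[, 1] + A[, 2] * B[, 2])
  atan2(num, den) * 180 / pi
}

transform_bone <- function(bone, R, pivot_in, pivot_out) {
  ap <- function(m) {
    if (is.null(m)) return(NULL)
    out <- sweep(sweep(m, 2, pivot_in) %*% t(R), 2, pivot_out, `+`)
    dimnames(out) <- dimnames(m)
    out
  }
  bone$landmarks <- ap(bone$landmarks)
  bone$facet <- ap(bone$facet)
  if (!is.null(bone$mesh)) bone$mesh$vertices <- ap(bone$mesh$vertices)
  bone
}

translate_bone <- function(bone, dv) {
  ap <- function(m) { if (is.null(m)) return(NULL); sweep(m, 2, dv, `+`) }
  bone$landmarks <- ap(bone$landmarks)
  bone$facet <- ap(bone$facet)
  if (!is.null(bone$mesh)) bone$mesh$vertices <- ap(bone$mesh$vertices)
  bone
}

#' Scale a substitute trapezium to match a metacarpal facet
#'
#' Fossil metacarpals often lack an associated trapezium; a substitute
#' (human or chimpanzee) trapezium is then scaled so its articular facet
#' outline matches the adjoining metacarpal facet as closely as possible.
#' The uniform scale factor minimizes the summed squared distances between
#' the centred facet outlines and is applied about the trapezium facet
#' centroid to the whole bone.
#'
#' @param trapezium a [bone_model()] with a facet outline.
#' @param target_facet matrix of target facet outline points (same
#'   cardinality and ordering as the trapezium facet).
#' @return the scaled `bone_model`, with the factor in attribute `"scale"`.
#' @export
scale_trapezium_to_facet <- function(trapezium, target_facet) {
  stopifnot(inherits(trapezium, "bone_model"), !is.null(trapezium$facet))
  target_facet <- as.matrix(target_facet)
  if (nrow(target_facet) != nrow(trapezium$facet))
    stop("facet point sets must have the same cardinality and ordering")
  X <- sweep(trapezium$facet, 2, colMeans(trapezium$facet))
  Y <- sweep(target_facet, 2, colMeans(target_facet))
  ss <- sum(X * X)
  if (ss <= 0) stop("degenerate (zero-size) facet")
  s <- sum(X * Y) / ss
  ctr <- colMeans(trapezium$facet)
  sc <- function(m) {
    if (is.null(m)) return(NULL)
    out <- sweep(sweep(m, 2, ctr) * s, 2, ctr, `+`)
    dimnames(out) <- dimnames(m)
    out
  }
  out <- trapezium
  out$landmarks <- sc(out$landmarks)
  out$facet <- sc(out$facet)
  if (!is.null(out$mesh)) out$mesh$vertices <- sc(out$mesh$vertices)
  attr(out, "scale") <- s
  out
}

#' Apply an additional palmar flexion to a posed thumb
#'
#' Rotates the metacarpal of a posed configuration about the mediolateral
#' axis through its facet centroid. `apply_flexion(p, d)` followed by
#' `apply_flexion(., -d)` restores the original coordinates.
#'
#' @param posed a [pose_tmc()] result.
#' @param flexion_deg additional palmar flexion in degrees.
#' @return the modified `posed_thumb` (with `flexion_deg` updated).
#' @export
apply_flexion <- function(posed, flexion_deg) {
  stopifnot(inherits(posed, "posed_thumb"))
  tf <- facet_frame(posed$trapezium)
  pivot <- colMeans(posed$metacarpal$facet)
  Rf <- rotation_about_axis(tf$axis_ml, -flexion_deg)
  posed$metacarpal <- transform_bone(posed$metacarpal, Rf, pivot, pivot)
  posed$flexion_deg <- posed$flexion_deg + flexion_deg
  posed$j <- (colMeans(posed$metacarpal$facet) +
                colMeans(posed$trapezium$facet)) / 2
  posed
}
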