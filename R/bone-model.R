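#' Bone model: named 3D landmarks plus an optional triangle mesh
#'
#' A `bone_model` holds the landmark configuration of one bone (first
#' metacarpal or trapezium) in millimetres, in a right-handed frame with
#' +x lateral, +y palmar, +z distal. Landmarks are split into named model
#' landmarks (muscle origin/insertion candidates `ORI1`-`ORI3`,
#' `INS1`-`INS3`, entheseal fixed landmarks `F1`-`F6`, ...) and an ordered
#' articular-facet outline used for posing.
#'
#' @param bone_id specimen/bone identifier.
#' @param side `"left"` or `"right"`.
#' @param landmarks numeric matrix (n x 3) with unique rownames; mm.
#' @param facet numeric matrix (>= 3 x 3) of ordered articular facet
#'   outline points; mm. May be `NULL` for bones that are never posed.
#' @param mesh optional triangle mesh (see [make_mesh()]) in the same frame.
#' @param mesh_tol landmark-to-mesh sanity bound in mm (default 2).
#' @return an object of class `bone_model`.
#' @examples
#' lm <- rbind(INS1 = c(6, 5, 20), INS2 = c(6, 4, 25), INS3 = c(5, 5, 30))
#' facet <- cbind(cos(seq(0, 2 * pi, length.out = 13)[-13]) * 5,
#'                sin(seq(0, 2 * pi, length.out = 13)[-13]) * 5, 0)
#' b <- bone_model("mc1", "right", lm, facet)
#' centroid_size(b$landmarks)
#' @export
bone_model <- function(bone_id, side = c("right", "left"), landmarks,
                       facet = NULL, mesh = NULL, mesh_tol = 2) {
  side <- match.arg(side)
  landmarks <- as.matrix(landmarks)
  if (ncol(landmarks) != 3) stop("landmarks must be an n x 3 matrix")
  if (is.null(rownames(landmarks)) || anyDuplicated(rownames(landmarks)))
    stop("landmarks need unique rownames")
  if (!all(is.finite(landmarks))) stop("non-finite landmark coordinates")
  if (!is.null(facet)) {
    facet <- as.matrix(facet)
    if (ncol(facet) != 3 || nrow(facet) < 3)
      stop("facet must be an ordered (>= 3) x 3 outline matrix")
    if (!all(is.finite(facet))) stop("non-finite facet coordinates")
  }
  if (!is.null(mesh)) {
    stopifnot(inherits(mesh, "tri_mesh"))
    d <- point_mesh_distance(landmarks, mesh)
    if (any(d > mesh_tol))
      warning(sprintf("%d landmark(s) lie further than %g mm from the mesh",
                      sum(d > mesh_tol), mesh_tol))
  }
  structure(list(bone_id = bone_id, side = side, landmarks = landmarks,
                 facet = facet, mesh = mesh),
            class = "bone_model")
}

#' @export
print.bone_model <- function(x, ...) {
  cat(sprintf("<bone_model> %s (%s): %d landmarks%s%s\n", x$bone_id, x$side,
              nrow(x$landmarks),
              if (!is.null(x$facet)) sprintf(", facet outline of %d points", nrow(x$facet)) else "",
              if (!is.null(x$mesh)) sprintf(", mesh with %d triangles", nrow(x$mesh$faces)) else ""))
  invisible(x)
}

#' Centroid size of a landmark configuration
#'
#' Square root of the summed squared distances of the points to their
#' centroid -- the standard geometric-morphometric size measure.
#'
#' @param points numeric matrix (n x 3), n >= 2.
#' @return centroid size (same length units as the input).
#' @examples
#' centroid_size(rbind(c(0, 0, 0), c(2, 0, 0)))  # sqrt(2)
#' @export
centroid_size <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2) stop("centroid size needs at least 2 points")
  ctr <- colMeans(points)
  sqrt(sum(sweep(points, 2, ctr)^2))
}

#' Mirror a bone across a principal plane
#'
#' Reflects every landmark (and mesh vertex) across the given coordinate
#' plane and flips the side flag. Used for specimens whose right-side bones
#' are not preserved and are analysed as mirrored left bones.
#'
#' @param bone a [bone_model()].
#' @param plane `"x"`, `"y"` or `"z"`: the coordinate set to zero sign-flip
#'   (`"x"` reflects across the plane x = 0).
#' @return the mirrored `bone_model`.
#' @export
mirror_bone <- function(bone, plane = c("x", "y", "z")) {
  stopifnot(inherits(bone, "bone_model"))
  plane <- match.arg(plane)
  ax <- match(plane, c("x", "y", "z"))
  flip <- function(m) { if (is.null(m)) return(NULL); m[, ax] <- -m[, ax]; m }
  mesh <- bone$mesh
  if (!is.null(mesh)) {
    mesh$vertices <- flip(mesh$vertices)
    # reverse winding so triangle orientation stays outward
    mesh$faces <- mesh$faces[, c(1, 3, 2), drop = FALSE]
  }
  bone_model(bone$bone_id,
             side = if (bone$side == "left") "right" else "left",
             landmarks = flip(bone$landmarks),
             facet = flip(bone$facet),
             mesh = mesh)
}

#' Uniformly scale a landmark set to a target centroid size
#'
#' Scales about the centroid of `points` so that `centroid_size()` of the
#' result equals `target_cs`. Size adjustment of a posed thumb model uses
#' the seven model points (INS1-3, ORI1-3, joint point) to define the scale
#' factor, then applies it to all coordinates (see [size_adjusted_table()]).
#'
#' @param points numeric matrix (n x 3) with positive centroid size.
#' @param target_cs target centroid size (> 0).
#' @return scaled matrix (same dimnames).
#' @export
scale_to_centroid_size <- function(points, target_cs) {
  points <- as.matrix(points)
  cs <- centroid_size(points)
  if (cs <= 0) stop("zero centroid size")
  if (target_cs <= 0) stop("target centroid size must be positive")
  ctr <- colMeans(points)
  out <- sweep(points, 2, ctr) * (target_cs / cs)
  out <- sweep(out, 2, ctr, `+`)
  dimnames(out) <- dimnames(points)
  out
}
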