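#' Triangle meshes and straight-line clearance of the muscle path
#'
#' The muscle model assumes a straight line of action between an origin
#' landmark on the trapezium and an insertion landmark on the metacarpal.
#' A landmark pair is admissible only if that segment does not pass through
#' bone; [segment_clear_of_mesh()] performs the test against an optional
#' surface mesh. Meshes are stored as a plain vertex/face list.
#'
#' @param vertices numeric matrix (v x 3), mm.
#' @param faces integer matrix (f x 3) of 1-based vertex indices.
#' @return an object of class `tri_mesh`.
#' @export
make_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3,
            all(is.finite(vertices)), all(faces >= 1),
            all(faces <= nrow(vertices)))
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# Unsigned distance from each point to the nearest mesh vertex (coarse
# sanity bound for "landmark lies on the bone surface"; exact triangle
# distance is unnecessary at the 2 mm tolerance used).
point_mesh_distance <- function(points, mesh) {
  points <- as.matrix(points)
  apply(points, 1, function(p) {
    sqrt(min(rowSums(sweep(mesh$vertices, 2, p)^2)))
  })
}

#' Test whether a straight muscle path is clear of bone
#'
#' Counts transversal intersections of the open segment `p0`--`p1` with the
#' triangles of `mesh` (Moeller-Trumbore test per triangle), ignoring
#' crossings within `eps` mm of either endpoint since entheseal landmarks
#' lie on the bone surface by construction. With no mesh supplied the pair
#' is clear by assumption (m. opponens pollicis is the deepest muscle in
#' the region, so no other tissue is modelled as blocking the line).
#'
#' @param p0,p1 segment endpoints (length-3, mm), distinct.
#' @param mesh a [make_mesh()] object, or `NULL`.
#' @param eps endpoint exclusion radius in mm (default 0.05).
#' @return a list of class `clearance_verdict` with elements `clear`,
#'   `n_intersections`, and `n_degenerate` (triangles skipped).
#' @examples
#' segment_clear_of_mesh(c(0, 0, 0), c(1, 1, 1), mesh = NULL)
#' @export
segment_clear_of_mesh <- function(p0, p1, mesh = NULL, eps = 0.05) {
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  stopifnot(length(p0) == 3, length(p1) == 3, all(is.finite(c(p0, p1))))
  L <- vec_norm(p1 - p0)
  if (L == 0) stop("degenerate segment: p0 == p1")
  if (is.null(mesh)) {
    return(structure(list(clear = TRUE, n_intersections = 0L,
                          n_degenerate = 0L), class = "clearance_verdict"))
  }
  d <- (p1 - p0) / L
  tmin <- eps / L
  tmax <- 1 - eps / L
  V <- mesh$vertices
  t_hits <- numeric(0)
  n_degen <- 0L
  for (k in seq_len(nrow(mesh$faces))) {
    f <- mesh$faces[k, ]
    a <- V[f[1], ]; e1 <- V[f[2], ] - a; e2 <- V[f[3], ] - a
    pv <- cross3(d, e2)
    det <- sum(e1 * pv)
    area2 <- vec_norm(cross3(e1, e2))
    if (area2 < 1e-12) { n_degen <- n_degen + 1L; next }
    if (abs(det) < 1e-12) next  # segment parallel to triangle plane
    inv <- 1 / det
    tv <- p0 - a
    u <- sum(tv * pv) * inv
    if (u < 0 || u > 1) next
    qv <- cross3(tv, e1)
    v <- sum(d * qv) * inv
    if (v < 0 || u + v > 1) next
    tt <- sum(e2 * qv) * inv / L
    if (tt > tmin && tt < tmax) t_hits <- c(t_hits, tt)
  }
  if (n_degen > 0)
    warning(sprintf("%d degenerate triangle(s) skipped", n_degen))
  # a crossing on a shared triangle edge is reported by both triangles:
  # merge hits closer than 1e-9 of the segment length into one
  n_hit <- 0L
  if (length(t_hits) > 0) {
    t_hits <- sort(t_hits)
    n_hit <- 1L + sum(diff(t_hits) > 1e-9)
  }
  structure(list(clear = n_hit == 0L, n_intersections = n_hit,
                 n_degenerate = n_degen), class = "clearance_verdict")
}

#' Read a triangle mesh from an STL file
#'
#' Supports both ASCII and binary STL. Coincident vertices are merged
#' exactly (bitwise identical coordinates), which suffices for meshes
#' written by [write_stl()] and typical exports.
#'
#' @param path STL file path.
#' @return a [make_mesh()] object.
#' @export
read_stl <- function(path) {
  con <- file(path, "rb")
  head <- readBin(con, "raw", 80)
  close(con)
  txt_head <- rawToChar(head[head != as.raw(0)])
  if (startsWith(trimws(tolower(txt_head)), "solid") && is_ascii_stl(path)) {
    read_stl_ascii(path)
  } else {
    read_stl_binary(path)
  }
}

is_ascii_stl <- function(path) {
  lines <- tryCatch(readLines(path, n = 5, warn = FALSE), error = function(e) "")
  any(grepl("facet normal|endsolid", lines))
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  coords <- t(vapply(strsplit(trimws(vl), "\\s+"), function(x)
    as.numeric(x[2:4]), numeric(3)))
  stl_triangles_to_mesh(coords)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  coords <- matrix(0, ntri * 3, 3)
  for (i in seq_len(ntri)) {
    vals <- readBin(con, "numeric", 12, size = 4, endian = "little")
    readBin(con, "raw", 2)
    coords[(3 * i - 2):(3 * i), ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
  }
  stl_triangles_to_mesh(coords)
}

stl_triangles_to_mesh <- function(coords) {
  if (nrow(coords) %% 3 != 0 || nrow(coords) == 0)
    stop("malformed STL: vertex count not a multiple of 3")
  key <- apply(coords, 1, paste, collapse = ",")
  uk <- !duplicated(key)
  verts <- coords[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  make_mesh(verts, matrix(idx, ncol = 3, byrow = TRUE))
}

#' Write a triangle mesh as ASCII STL
#'
#' @param mesh a [make_mesh()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path) {
  stopifnot(inherits(mesh, "tri_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid mesh", con)
  for (k in seq_len(nrow(mesh$faces))) {
    tri <- mesh$vertices[mesh$faces[k, ], , drop = FALSE]
    n <- cross3(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
    if (vec_norm(n) > 0) n <- n / vec_norm(n)
    writeLines(sprintf("  facet normal %.12g %.12g %.12g", n[1], n[2], n[3]), con)
    writeLines("    outer loop", con)
    for (i in 1:3)
      writeLines(sprintf("      vertex %.12g %.12g %.12g",
                         tri[i, 1], tri[i, 2], tri[i, 3]), con)
    writeLines("    endloop", con)
    writeLines("  endfacet", con)
  }
  writeLines("endsolid mesh", con)
  invisible(path)
}
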