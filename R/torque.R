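#' Muscle line-of-action vectors
#'
#' From an origin landmark o (trapezium), insertion landmark i (metacarpal)
#' and joint point j, computes the muscle length l_M = |i - o|, the unit
#' direction of the line of action e_M = (i - o) / l_M, and the force
#' application vector r = o - j.
#'
#' @param o,i,j length-3 numeric vectors, mm.
#' @return list with `l_M` (mm), `e_M` (unit vector), `r` (mm).
#' @examples
#' muscle_vectors(c(0, 0, 0), c(30, 40, 0), c(0, 0, 0))$l_M  # 50
#' @export
muscle_vectors <- function(o, i, j) {
  o <- as.numeric(o); i <- as.numeric(i); j <- as.numeric(j)
  stopifnot(length(o) == 3, length(i) == 3, length(j) == 3,
            all(is.finite(c(o, i, j))))
  d <- i - o
  l_M <- vec_norm(d)
  if (l_M == 0) stop("origin and insertion landmarks coincide")
  list(l_M = l_M, e_M = d / l_M, r = o - j)
}

#' Joint torque of one origin-insertion pair
#'
#' tau = r x (F_M * e_M): the cross product of the force application
#' vector with the muscle force vector. Reports the torque vector, its
#' magnitude (the scalar analysed downstream), the moment arm
#' |tau| / F_M, and the signed flexion component (projection of tau on the
#' mediolateral axis), which is used only as a direction check.
#'
#' @param o,i,j origin, insertion and joint point, mm.
#' @param F_M scalar muscle force, N (>= 0).
#' @param axis_ml unit mediolateral axis for the flexion component
#'   (default +x, the canonical frame convention).
#' @return list of class `torque_result`: `tau` (N mm), `magnitude`,
#'   `moment_arm` (mm), `F_M`, `flexion_component` (signed N mm), `l_M`.
#' @examples
#' tq <- joint_torque(c(0, 0, 0), c(40, 0, 0), c(0, 10, 0), F_M = 66)
#' tq$magnitude   # 660
#' tq$moment_arm  # 10
#' @export
joint_torque <- function(o, i, j, F_M, axis_ml = c(1, 0, 0)) {
  if (F_M < 0) stop("F_M must be >= 0")
  mv <- muscle_vectors(o, i, j)
  tau <- cross3(mv$r, F_M * mv$e_M)
  mag <- vec_norm(tau)
  structure(list(tau = tau, magnitude = mag,
                 moment_arm = if (F_M > 0) mag / F_M else NA_real_,
                 F_M = F_M,
                 flexion_component = sum(tau * unit_vec(axis_ml)),
                 l_M = mv$l_M),
            class = "torque_result")
}

#' Torque table of a posed specimen
#'
#' Evaluates the Hill model and the joint torque for every admissible
#' (origin, insertion) landmark pair of a posed thumb. Up to 3 x 3 = 9
#' pairs enter; pairs are dropped when their origin landmark is absent
#' (damaged tubercles are masked, never reconstructed) or when the
#' straight line of action fails the bone clearance check. Muscle lengths
#' are converted from mm to cm at this boundary, matching the cm units of
#' the muscle model.
#'
#' @param posed a [pose_tmc()] result (or compatible list with
#'   `metacarpal`, `trapezium`, `j`).
#' @param params a [muscle_parameters()] object.
#' @param clearance `"assume"` to waive mesh checks (landmark-only inputs),
#'   or `"mesh"` to test each segment against the bone meshes present.
#' @param origins,insertions landmark names to use (defaults ORI1-3 on the
#'   trapezium and INS1-3 on the metacarpal; missing names are masked).
#' @return a data frame of class `torque_table`, one row per admissible
#'   pair: origin, insertion, l_M (mm), F_M (N), tau components, magnitude
#'   (N mm), moment arm (mm), flexion component, clearance flag.
#' @export
torque_table <- function(posed, params,
                         clearance = c("assume", "mesh"),
                         origins = paste0("ORI", 1:3),
                         insertions = paste0("INS", 1:3)) {
  clearance <- match.arg(clearance)
  met <- posed$metacarpal; tra <- posed$trapezium
  origins <- intersect(origins, rownames(tra$landmarks))
  insertions <- intersect(insertions, rownames(met$landmarks))
  if (length(origins) == 0 || length(insertions) == 0)
    stop("no origin/insertion landmarks present")
  axis_ml <- tryCatch(facet_frame(tra)$axis_ml, error = function(e) c(1, 0, 0))
  rows <- list()
  n_warn_sign <- 0L
  for (on in origins) {
    for (ins in insertions) {
      o <- tra$landmarks[on, ]; i <- met$landmarks[ins, ]
      clear_flag <- TRUE
      if (clearance == "mesh") {
        for (mesh in list(met$mesh, tra$mesh)) {
          if (!is.null(mesh)) {
            v <- segment_clear_of_mesh(o, i, mesh)
            clear_flag <- clear_flag && v$clear
          }
        }
      }
      if (!clear_flag) next
      mv <- muscle_vectors(o, i, posed$j)
      fm <- solve_isometric(params, mv$l_M / 10)  # mm -> cm
      tq <- joint_torque(o, i, posed$j, fm$F_M, axis_ml = axis_ml)
      if (tq$flexion_component < 0) n_warn_sign <- n_warn_sign + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        origin = on, insertion = ins, l_M = mv$l_M, F_M = fm$F_M,
        tau_x = tq$tau[1], tau_y = tq$tau[2], tau_z = tq$tau[3],
        magnitude = tq$magnitude, moment_arm = tq$moment_arm,
        flexion_component = tq$flexion_component, clear = clear_flag,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) stop("no clear origin-insertion pairs")
  if (n_warn_sign > 0)
    warning(sprintf(paste("%d pair(s) have a flexion component opposite to",
                          "the expected palmar-flexion direction"), n_warn_sign))
  out <- do.call(rbind, rows)
  class(out) <- c("torque_table", class(out))
  out
}

#' Size-adjusted torque tables for a cohort
#'
#' Re-runs the torque computation in size-adjusted space: each posed
#' specimen is uniformly scaled (about the centroid of its seven model
#' points INS1-3, ORI1-3 and j) so that those points reach a common target
#' centroid size, then the torque table is recomputed. The muscle force is
#' unchanged by construction (gamma scaling), so size-adjusted torque is
#' degree-1 homogeneous in the coordinates.
#'
#' @param cohort named list of posed specimens.
#' @param params a [muscle_parameters()] object (or list of one per
#'   specimen, matched by name).
#' @param target_cs target centroid size in mm; default the cohort mean of
#'   the model-point centroid sizes.
#' @param ... passed on to [torque_table()].
#' @return list with `tables` (named list of torque tables), `target_cs`,
#'   and `centroid_sizes` (original model-point sizes).
#' @export
size_adjusted_table <- function(cohort, params, target_cs = NULL, ...) {
  if (length(cohort) == 0) stop("empty cohort")
  sizes <- vapply(cohort, function(p) centroid_size(model_points(p)), numeric(1))
  if (is.null(target_cs)) target_cs <- mean(sizes)
  tabs <- lapply(seq_along(cohort), function(k) {
    p <- scale_posed(cohort[[k]], target_cs)
    pk <- if (inherits(params, "muscle_parameters")) params else params[[k]]
    torque_table(p, pk, ...)
  })
  names(tabs) <- names(cohort)
  list(tables = tabs, target_cs = target_cs, centroid_sizes = sizes)
}

# The seven model points defining the size measure: insertion and origin
# candidates plus the joint point.
model_points <- function(posed) {
  ins <- posed$metacarpal$landmarks[
    intersect(paste0("INS", 1:3), rownames(posed$metacarpal$landmarks)), ,
    drop = FALSE]
  ori <- posed$trapezium$landmarks[
    intersect(paste0("ORI", 1:3), rownames(posed$trapezium$landmarks)), ,
    drop = FALSE]
  rbind(ins, ori, j = posed$j)
}

# Uniform scaling of a posed configuration about the model-point centroid
# so the model points attain target_cs.
scale_posed <- function(posed, target_cs) {
  mp <- model_points(posed)
  cs <- centroid_size(mp)
  if (cs <= 0) stop("zero centroid size")
  s <- target_cs / cs
  ctr <- colMeans(mp)
  sc <- function(m) {
    if (is.null(m)) return(NULL)
    out <- sweep(sweep(m, 2, ctr) * s, 2, ctr, `+`)
    dimnames(out) <- dimnames(m)
    out
  }
  posed$metacarpal$landmarks <- sc(posed$metacarpal$landmarks)
  posed$metacarpal$facet <- sc(posed$metacarpal$facet)
  if (!is.null(posed$metacarpal$mesh))
    posed$metacarpal$mesh$vertices <- sc(posed$metacarpal$mesh$vertices)
  posed$trapezium$landmarks <- sc(posed$trapezium$landmarks)
  posed$trapezium$facet <- sc(posed$trapezium$facet)
  if (!is.null(posed$trapezium$mesh))
    posed$trapezium$mesh$vertices <- sc(posed$trapezium$mesh$vertices)
  posed$j <- c(sc(matrix(posed$j, 1, 3)))
  posed$gap <- posed$gap * s
  posed
}

#' Torque-to-thumb-length ratio (TTL)
#'
#' 100 * torque / thumb_length, a basic proxy of fingertip force. Thumb
#' length is the summed maximum lengths of the first metacarpal and the
#' two phalanges, in mm.
#'
#' @param torque torque in N mm.
#' @param thumb_length thumb length in mm (> 0).
#' @return dimensionless score.
#' @export
ttl <- function(torque, thumb_length) {
  if (any(thumb_length <= 0)) stop("thumb_length must be positive")
  100 * torque / thumb_length
}
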