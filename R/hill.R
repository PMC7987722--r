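#' Four-element Hill-type muscle model (static, isometric)
#'
#' The muscle force of m. opponens pollicis is predicted by a macroscopic
#' Hill-type model with four structural elements: the contractile element
#' (CE, the muscle fibres), a parallel elastic element (PEE, intramuscular
#' connective tissue), a series elastic element (SEE, tendon elasticity)
#' and a series damping element (SDE, tendon viscosity). Only a static
#' posture is analysed, so all velocities are zero, the SDE transmits no
#' force, and the internal state l_CE is fixed by the force equilibrium
#'
#'   F_CE(l_CE, a) + F_PEE(l_CE) = F_SEE(l_M - l_CE)
#'
#' from which the muscle force F_M = F_CE + F_PEE follows.
#'
#' Curve shapes and their generic constants follow the standard forms of
#' this model family: an exponential bell for the CE active force-length
#' relation, a power-law PEE engaging beyond a slack length, a piecewise
#' quadratic-then-linear SEE, and a linear SDE. All force-scale constants
#' are expressed as multiples of F_max, which makes the predicted force
#' exactly linear in F_max and scale-invariant in l_M at fixed gamma.
#'
#' @name hill_model
NULL

# Generic curve constants (model-family defaults; forces as multiples of
# F_max, lengths as fractions of l_CE_opt / l_SEE_0):
#   CE  : bell width 0.45 both limbs, exponent 3 ascending / 1.5 descending
#   PEE : slack at 0.9 l_CE_opt, exponent 2.5, force 2 F_max at the
#         descending-limb end l_CE_opt * (1 + 0.45)
#   SEE : rest strain region quadratic up to 4.25% strain where it carries
#         0.4 F_max, linear above with stiffness 0.4 F_max per 1.7% strain
#   SDE : dimensionless damping 0.3 (irrelevant at zero velocity)
hill_curve_constants <- function() {
  list(dW_asc = 0.45, nu_asc = 3, dW_des = 0.45, nu_des = 1.5,
       L_PEE0 = 0.9, nu_PEE = 2.5, F_PEE = 2.0,
       dU_SEE_nll = 0.0425, dU_SEE_l = 0.017, dF_SEE0 = 0.4,
       D_SE = 0.3)
}

#' Maximum isometric force from PCSA
#'
#' F_max = sigma * A_PCSA, the product of specific muscle tension and
#' physiological cross-sectional area, optionally rounded to the nearest
#' integer newton (round-half-up, the printed convention; internal
#' computation keeps full precision).
#'
#' @param sigma specific tension in N per cm^2 (default 25).
#' @param pcsa physiological cross-sectional area in cm^2.
#' @param rounding `"none"` or `"nearest_newton"`.
#' @return maximum isometric force in N.
#' @examples
#' fmax_from_pcsa(25, 2.63, "nearest_newton")  # 66
#' fmax_from_pcsa(25, 1.55, "nearest_newton")  # 39
#' @export
fmax_from_pcsa <- function(sigma, pcsa, rounding = c("none", "nearest_newton")) {
  rounding <- match.arg(rounding)
  if (sigma < 0 || pcsa < 0) stop("sigma and pcsa must be non-negative")
  f <- sigma * pcsa
  if (rounding == "nearest_newton") f <- floor(f + 0.5)
  f
}

#' Muscle parameter set
#'
#' Bundles the muscle-specific constants of the Hill model. The reference
#' lengths of the contractile element and tendon are derived from the
#' muscle-tendon length via the fixed ratio gamma (see [derive_lengths()]),
#' so they are set per landmark pair at solve time when `l_CE_opt` is `NA`.
#'
#' @param F_max maximum isometric force, N.
#' @param gamma CE fraction of the muscle-tendon length, in (0, 1).
#' @param activation muscular activity a in \[0, 1\] (default 1, maximal).
#' @param l_CE_opt,l_SEE_0 optional fixed reference lengths in cm; if `NA`
#'   they are derived from l_M and gamma at solve time.
#' @param sigma,pcsa optional provenance of F_max (recorded only).
#' @param curves list of generic curve constants
#'   (default [hill_curve_constants()]).
#' @return an object of class `muscle_parameters`.
#' @export
muscle_parameters <- function(F_max, gamma = 0.55, activation = 1,
                              l_CE_opt = NA_real_, l_SEE_0 = NA_real_,
                              sigma = NA_real_, pcsa = NA_real_,
                              curves = hill_curve_constants()) {
  if (F_max < 0) stop("F_max must be >= 0")
  if (gamma <= 0 || gamma >= 1) stop("gamma must lie in (0, 1)")
  if (activation < 0 || activation > 1) stop("activation must lie in [0, 1]")
  structure(list(F_max = F_max, gamma = gamma, activation = activation,
                 l_CE_opt = l_CE_opt, l_SEE_0 = l_SEE_0,
                 sigma = sigma, pcsa = pcsa, curves = curves),
            class = "muscle_parameters")
}

#' @export
print.muscle_parameters <- function(x, ...) {
  cat(sprintf("<muscle_parameters> F_max = %g N, gamma = %g, a = %g\n",
              x$F_max, x$gamma, x$activation))
  invisible(x)
}

#' PCSA paradigms for m. opponens pollicis
#'
#' The four force-scaling assumptions used throughout the pipeline:
#' \enumerate{
#'   \item human PCSA 2.63 cm^2 at sigma = 25 N/cm^2, F_max = 66 N;
#'   \item chimpanzee PCSA 1.55 cm^2 at 25 N/cm^2, F_max = 39 N;
#'   \item normalized, F_max = 1;
#'   \item normalized scaled by the chimp/human PCSA ratio, F_max = 0.59.
#' }
#'
#' @param id paradigm number 1-4.
#' @return a [muscle_parameters()] object with full activation.
#' @examples
#' make_paradigm(1)$F_max  # 66
#' @export
make_paradigm <- function(id) {
  if (!id %in% 1:4) stop("paradigm id must be 1, 2, 3 or 4")
  switch(id,
    muscle_parameters(fmax_from_pcsa(25, 2.63, "nearest_newton"),
                      sigma = 25, pcsa = 2.63),
    muscle_parameters(fmax_from_pcsa(25, 1.55, "nearest_newton"),
                      sigma = 25, pcsa = 1.55),
    muscle_parameters(1),
    muscle_parameters(0.59))
}

#' Derive CE and tendon reference lengths from the muscle-tendon length
#'
#' l_CE_opt = gamma * l_M and l_SEE_0 = l_M - l_CE_opt. The default gamma
#' of 0.55 comes from human cadaveric fibre length (2.29 cm) over the
#' muscle-tendon length of a reference modern human geometry (4.14 cm).
#'
#' @param l_M muscle-tendon length, cm (> 0).
#' @param gamma CE fraction in (0, 1).
#' @return list with `l_CE_opt` and `l_SEE_0` (cm), summing to `l_M`.
#' @export
derive_lengths <- function(l_M, gamma = 0.55) {
  if (l_M <= 0) stop("l_M must be positive")
  if (gamma <= 0 || gamma >= 1) stop("gamma must lie in (0, 1)")
  l_CE_opt <- gamma * l_M
  list(l_CE_opt = l_CE_opt, l_SEE_0 = l_M - l_CE_opt)
}

resolve_lengths <- function(params, l_M) {
  if (is.na(params$l_CE_opt) || is.na(params$l_SEE_0)) {
    derive_lengths(l_M, params$gamma)
  } else {
    list(l_CE_opt = params$l_CE_opt, l_SEE_0 = params$l_SEE_0)
  }
}

#' Element forces of the Hill model at a given state
#'
#' Evaluates the four element force laws at CE length `l_CE` and
#' muscle-tendon length `l_M` (cm). At the zero velocities of a static
#' posture the SDE force is exactly zero.
#'
#' @param params a [muscle_parameters()] object.
#' @param l_CE contractile-element length, cm.
#' @param l_M muscle-tendon length, cm.
#' @param v_CE,v_M CE and muscle-tendon velocities, cm/s (default 0).
#' @return list with `F_CE`, `F_PEE`, `F_SEE`, `F_SDE` in N.
#' @export
element_forces <- function(params, l_CE, l_M, v_CE = 0, v_M = 0) {
  stopifnot(inherits(params, "muscle_parameters"))
  if (!all(is.finite(c(l_CE, l_M, v_CE, v_M)))) stop("non-finite state")
  if (l_CE <= 0 || l_M <= 0) stop("lengths must be positive")
  k <- params$curves
  ln <- resolve_lengths(params, l_M)
  l_CE_opt <- ln$l_CE_opt; l_SEE_0 <- ln$l_SEE_0

  # CE: active isometric force-length (exponential bell, two limbs)
  q <- l_CE / l_CE_opt
  if (q <= 1) {
    f_isom <- exp(-abs((q - 1) / k$dW_asc)^k$nu_asc)
  } else {
    f_isom <- exp(-abs((q - 1) / k$dW_des)^k$nu_des)
  }
  F_CE <- params$activation * params$F_max * f_isom  # at v_CE = 0

  # PEE: engages beyond the slack length L_PEE0 * l_CE_opt
  l_PEE0 <- k$L_PEE0 * l_CE_opt
  K_PEE <- k$F_PEE * params$F_max /
    (l_CE_opt * (k$dW_des + 1 - k$L_PEE0))^k$nu_PEE
  F_PEE <- if (l_CE > l_PEE0) K_PEE * (l_CE - l_PEE0)^k$nu_PEE else 0

  # SEE: quadratic toe region up to strain dU_SEE_nll, linear above
  l_SEE <- l_M - l_CE
  dF0 <- k$dF_SEE0 * params$F_max
  l_nll <- (1 + k$dU_SEE_nll) * l_SEE_0
  nu_SEE <- k$dU_SEE_nll / k$dU_SEE_l
  if (l_SEE <= l_SEE_0) {
    F_SEE <- 0
  } else if (l_SEE < l_nll) {
    K_nl <- dF0 / (k$dU_SEE_nll * l_SEE_0)^nu_SEE
    F_SEE <- K_nl * (l_SEE - l_SEE_0)^nu_SEE
  } else {
    K_l <- dF0 / (k$dU_SEE_l * l_SEE_0)
    F_SEE <- dF0 + K_l * (l_SEE - l_nll)
  }

  # SDE: linear damping on the tendon stretch rate; zero when static
  d_SDE <- k$D_SE * params$F_max / max(l_CE_opt, .Machine$double.eps)
  F_SDE <- d_SDE * (v_M - v_CE)

  list(F_CE = F_CE, F_PEE = F_PEE, F_SEE = F_SEE, F_SDE = F_SDE)
}

#' Solve the static isometric force equilibrium
#'
#' Finds the CE length l_CE in (0, l_M) at which
#' F_CE + F_PEE = F_SEE (a bracketed root solve), and returns the muscle
#' force F_M = F_CE + F_PEE. This fixed point is the steady state of the
#' contraction ODE the dynamic formulation integrates to.
#'
#' With reference lengths derived via gamma, F_M / F_max is the same for
#' every muscle-tendon length, and F_M is exactly linear in F_max.
#'
#' @param params a [muscle_parameters()] object.
#' @param l_M muscle-tendon length, cm.
#' @param tol solver tolerance on l_CE and on the force residual
#'   (relative to F_max; default 1e-6).
#' @return list of class `muscle_force_result` with `F_M` (N), `l_CE_eq`
#'   (cm), `converged`, `residual` (N).
#' @examples
#' p <- make_paradigm(1)
#' solve_isometric(p, l_M = 4.14)$F_M  # slightly below 66 N
#' @export
solve_isometric <- function(params, l_M, tol = 1e-6) {
  stopifnot(inherits(params, "muscle_parameters"))
  if (l_M <= 0) stop("l_M must be positive")
  if (params$F_max == 0) {
    return(structure(list(F_M = 0, l_CE_eq = resolve_lengths(params, l_M)$l_CE_opt,
                          converged = TRUE, residual = 0),
                     class = "muscle_force_result"))
  }
  g <- function(l_CE) {
    f <- element_forces(params, l_CE, l_M)
    f$F_CE + f$F_PEE - f$F_SEE
  }
  lo <- 1e-6 * l_M
  hi <- l_M * (1 - 1e-9)
  glo <- g(lo); ghi <- g(hi)
  if (is.na(glo) || is.na(ghi) || glo * ghi > 0)
    stop("no sign change in (0, l_M): equilibrium bracket not found")
  root <- stats::uniroot(g, c(lo, hi), tol = min(tol, 1e-12) * l_M)
  l_eq <- root$root
  f <- element_forces(params, l_eq, l_M)
  res <- abs(f$F_CE + f$F_PEE - f$F_SEE)
  structure(list(F_M = f$F_CE + f$F_PEE, l_CE_eq = l_eq,
                 converged = res <= max(tol * params$F_max, 1e-12),
                 residual = res),
            class = "muscle_force_result")
}

#' @export
print.muscle_force_result <- function(x, ...) {
  cat(sprintf("<muscle_force_result> F_M = %.6g N at l_CE = %.6g cm (%s)\n",
              x$F_M, x$l_CE_eq,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
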