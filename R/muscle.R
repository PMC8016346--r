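#' Maximal isometric force from muscle architecture
#'
#' Estimates a muscle's maximal isometric force from its belly mass and
#' optimal fibre length, assuming fibres develop a fixed maximum stress:
#' \deqn{F_{max} = m \sigma / (\rho \, \ell_o).}
#' Pennation is deliberately not applied here; the pennation angle enters
#' the contraction geometry (constant-thickness fibre model) instead, so
#' applying it twice would double-count it.
#'
#' @param m Belly mass (kg). May be a vector.
#' @param ell_o Optimal fibre length (m). May be a vector.
#' @param constants A [tissue_constants()] object.
#' @return Maximal isometric force (N).
#' @examples
#' # iliotrochantericus caudalis (anterior part): 1.35 g belly, 15.5 mm fibres
#' compute_fmax(1.35e-3, 15.5e-3)
#' @export
compute_fmax <- function(m, ell_o, constants = tissue_constants()) {
  if (any(m < 0)) stop("belly mass must be non-negative")
  if (any(ell_o <= 0)) stop("optimal fibre length must be positive")
  m * constants$sigma / (constants$rho_muscle * ell_o)
}

#' Dimensionless tendon stiffness
#'
#' Normalized slope of the tendon force-strain relation,
#' \deqn{k_T = E A_T / F_{max}^{proj} = E A_T \rho \ell_o /
#'   (m \sigma \cos\alpha_o),}
#' where the projection by \eqn{\cos\alpha_o} appears because the muscle is
#' here reduced to a force along the MTU line of action in series with the
#' tendon (fibre kinematics are irrelevant to the tendon itself).
#'
#' @param E Tendon Young's modulus (Pa).
#' @param A_T Tendon cross-sectional area (m^2).
#' @param m Belly mass (kg).
#' @param ell_o Optimal fibre length (m).
#' @param alpha_o Pennation angle at optimal fibre length (rad).
#' @param constants A [tissue_constants()] object (supplies muscle stress
#'   and density).
#' @return Dimensionless tendon stiffness.
#' @export
compute_tendon_stiffness <- function(E, A_T, m, ell_o, alpha_o = 0,
                                     constants = tissue_constants()) {
  if (any(c(E, A_T, m, ell_o) <= 0)) {
    stop("E, A_T, m and ell_o must be strictly positive")
  }
  if (any(alpha_o < 0) || any(alpha_o >= pi / 2)) {
    stop("pennation angle must lie in [0, pi/2)")
  }
  E * A_T * constants$rho_muscle * ell_o /
    (m * constants$sigma * cos(alpha_o))
}

#' Allometric scaling of activation time constants
#'
#' Scales an activation or deactivation time constant from a reference body
#' mass to a target body mass in proportion to mass^(1/6), reflecting the
#' shorter electromechanical delays of smaller animals.
#'
#' @param tau_ref Reference time constant (s).
#' @param m_ref Reference body mass (kg).
#' @param m_target Target body mass (kg).
#' @return Scaled time constant (s).
#' @examples
#' scale_time_constant(0.015, 64.8, 0.545)  # ~0.007 s
#' scale_time_constant(0.060, 64.8, 0.545)  # ~0.027 s
#' @export
scale_time_constant <- function(tau_ref, m_ref, m_target) {
  if (any(m_ref <= 0) || any(m_target <= 0)) {
    stop("body masses must be strictly positive")
  }
  if (any(tau_ref <= 0)) stop("time constants must be strictly positive")
  tau_ref * (m_target / m_ref)^(1 / 6)
}

#' First-approximation tendon slack length
#'
#' Estimates tendon slack length from the MTU length extremes over the
#' joint range of motion, under the classical assumption that fibres can
#' traverse 0.5-1.5 x optimal length across that range. With the projected
#' fibre span \eqn{w(\ell) = \sqrt{\ell^2 - (\ell_o \sin\alpha_o)^2}}
#' (taken as 0 when the radicand is negative), the two anchor conditions
#' \eqn{L_S = l_{MT,min} - w(0.5\ell_o)} and
#' \eqn{L_S = l_{MT,max} - w(1.5\ell_o)} are reconciled by least squares,
#' i.e. their mean, clamped at zero. This is an explicit first
#' approximation; slack lengths are expected to be refined downstream by
#' the redundancy solver's tuning factors.
#'
#' @param l_MT_min,l_MT_max MTU length extremes over the range of motion (m).
#' @param ell_o Optimal fibre length (m).
#' @param alpha_o Pennation angle at optimal fibre length (rad).
#' @return Estimated tendon slack length (m), non-negative.
#' @export
estimate_slack_length <- function(l_MT_min, l_MT_max, ell_o, alpha_o = 0) {
  if (any(l_MT_min >= l_MT_max)) stop("l_MT_min must be below l_MT_max")
  if (any(ell_o <= 0)) stop("optimal fibre length must be positive")
  h <- ell_o * sin(alpha_o)
  w <- function(l) sqrt(pmax(l^2 - h^2, 0))
  pmax(0.5 * ((l_MT_min - w(0.5 * ell_o)) + (l_MT_max - w(1.5 * ell_o))), 0)
}

#' Muscle-tendon unit parameters
#'
#' Container for the architecture and physiology of one muscle-tendon unit
#' (MTU). All quantities are SI: metres, newtons, seconds, radians,
#' kilograms. If `F_max` is omitted it is derived from belly mass and
#' optimal fibre length via [compute_fmax()].
#'
#' @param name MTU identifier.
#' @param m Belly mass (kg).
#' @param ell_o Optimal fibre length (m).
#' @param L_S Tendon slack length (m).
#' @param alpha_o Pennation angle at optimal fibre length (rad).
#' @param F_max Maximal isometric force (N); derived from `m` and `ell_o`
#'   if `NULL`.
#' @param k_T Dimensionless tendon stiffness (default 100, a first-pass
#'   estimate for small-bodied animals whose tendons are relatively stiff).
#' @param v_max Maximal fibre contraction velocity (optimal fibre lengths
#'   per second; default 10).
#' @param tau_act,tau_deact Activation and deactivation time constants (s).
#' @param constants [tissue_constants()] used when deriving `F_max`.
#' @return An object of class `muscle_params`.
#' @export
muscle_params <- function(name, m, ell_o, L_S, alpha_o = 0, F_max = NULL,
                          k_T = 100, v_max = 10,
                          tau_act = 0.007, tau_deact = 0.027,
                          constants = tissue_constants()) {
  if (m < 0) stop("belly mass must be non-negative")
  if (ell_o <= 0) stop("optimal fibre length must be positive")
  if (L_S < 0) stop("tendon slack length must be non-negative")
  if (alpha_o < 0 || alpha_o >= pi / 2) {
    stop("pennation angle must lie in [0, pi/2)")
  }
  if (is.null(F_max)) F_max <- compute_fmax(m, ell_o, constants)
  if (F_max < 0) stop("F_max must be non-negative")
  if (k_T <= 0) stop("k_T must be strictly positive")
  if (v_max <= 0) stop("v_max must be strictly positive")
  if (tau_act <= 0 || tau_act > tau_deact) {
    stop("time constants must satisfy 0 < tau_act <= tau_deact")
  }
  structure(list(name = as.character(name), m = m, ell_o = ell_o, L_S = L_S,
                 alpha_o = alpha_o, F_max = F_max, k_T = k_T, v_max = v_max,
                 tau_act = tau_act, tau_deact = tau_deact),
            class = "muscle_params")
}

#' @export
print.muscle_params <- function(x, ...) {
  cat(sprintf(
    "MTU '%s': m=%.4g g, ell_o=%.4g mm, L_S=%.4g mm, alpha_o=%.3g deg,\n",
    x$name, 1e3 * x$m, 1e3 * x$ell_o, 1e3 * x$L_S, x$alpha_o * 180 / pi))
  cat(sprintf(
    "  F_max=%.4g N, k_T=%g, v_max=%g lo/s, tau=%.3g/%.3g s\n",
    x$F_max, x$k_T, x$v_max, x$tau_act, x$tau_deact))
  invisible(x)
}

# Collect a per-field vector across a list of muscle_params.
mp_field <- function(mtus, field) {
  vapply(mtus, function(p) p[[field]], numeric(1))
}
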