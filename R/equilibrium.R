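# Muscle-tendon equilibrium with tendon force as the contraction state.
#
# Throughout, `ftilde` denotes tendon force normalized by F_max. The fibre
# geometry follows the constant-thickness pennation model: the muscle
# "height" h = l_o sin(alpha_o) is invariant, the projected fibre span is
# l_MT - l_T, and fibre length is the hypotenuse.

# geometric floor on the projected fibre span (m)
.geom_eps <- 1e-6

# numerical damping added to the normalized fibre force; regularizes the
# velocity inversion when activation is near zero
.default_beta <- 0.01

# Vectorized fibre geometry from normalized tendon force.
# All arguments recycle; returns list of vectors.
fibre_geom <- function(ftilde, l_MT, ell_o, L_S, h, tc) {
  ltn <- tc$finv(pmax(ftilde, -tc$c3 + 1e-9))
  l_T <- ifelse(L_S > 0, L_S * ltn, 0)
  proj <- l_MT - l_T
  ell <- sqrt(pmax(proj, .geom_eps)^2 + h^2)
  list(l_T = l_T, proj = proj, ell = ell, lstar = ell / ell_o,
       cosa = pmax(proj, .geom_eps) / ell)
}

#' Fibre state from tendon force
#'
#' Inverts the tendon force-strain curve to obtain tendon length, then
#' recovers fibre length and pennation from the constant-thickness
#' geometry: \eqn{\ell = \sqrt{(l_{MT} - l_T)^2 + (\ell_o\sin\alpha_o)^2}}.
#'
#' @param F_T_norm Tendon force normalized by `F_max` (>= 0).
#' @param l_MT MTU length (m).
#' @param params A [muscle_params()] object.
#' @return A list with `ell` (m), `ell_norm`, `alpha` (rad) and `l_T` (m).
#' @export
fibre_state_from_tendon_force <- function(F_T_norm, l_MT, params) {
  if (any(F_T_norm < 0)) stop("normalized tendon force must be >= 0")
  tc <- tendon_curve(params$k_T)
  h <- params$ell_o * sin(params$alpha_o)
  g <- fibre_geom(F_T_norm, l_MT, params$ell_o, params$L_S, h, tc)
  if (any(g$proj <= 0)) {
    stop("infeasible geometry: MTU length does not exceed tendon length")
  }
  list(ell = g$ell, ell_norm = g$lstar,
       alpha = atan2(h, g$proj), l_T = g$l_T)
}

#' Muscle-tendon equilibrium residual
#'
#' Dimensionless force balance across the pennated fibre and the in-series
#' tendon:
#' \deqn{(a f_{act}(\ell^*) f_v(\tilde v) + f_{pass}(\ell^*) +
#'   \beta \tilde v)\cos\alpha - F_T/F_{max},}
#' where \eqn{\tilde v} is fibre velocity as a fraction of maximal
#' contraction velocity and \eqn{\beta} is a small numerical damping.
#' Zero at physical equilibrium.
#'
#' @param state A list with at least `ell_norm`, `v_norm` (fibre velocity
#'   in optimal fibre lengths per second), `alpha` (rad) and `F_T` (N),
#'   e.g. from [solve_static_equilibrium()].
#' @param a Activation in `[0, 1]`.
#' @param params A [muscle_params()] object.
#' @param beta Numerical damping coefficient (default 0.01).
#' @return Dimensionless residual.
#' @export
equilibrium_residual <- function(state, a, params, beta = .default_beta) {
  vt <- state$v_norm / params$v_max
  (a * f_active(state$ell_norm) * f_velocity(vt) +
     f_passive(state$ell_norm) + beta * vt) * cos(state$alpha) -
    state$F_T / params$F_max
}

# Vectorized static (v = 0) equilibrium in normalized tendon force.
# Safeguarded Newton with a maintained bracket; distinct from the plain
# bisection used as an independent oracle in the tests.
# Returns list(ftilde, lstar, cosa, feasible, converged).
static_eq_ftilde <- function(a, l_MT, ell_o, L_S, h, tc,
                             tol = 1e-13, maxit = 80) {
  n <- max(length(a), length(l_MT), length(ell_o), length(L_S), length(h))
  a <- rep_len(a, n); l_MT <- rep_len(l_MT, n)
  ell_o <- rep_len(ell_o, n); L_S <- rep_len(L_S, n); h <- rep_len(h, n)

  feasible <- l_MT - L_S > .geom_eps
  # rigid attachment (no free tendon): force follows directly from geometry
  rigid <- L_S <= 0
  ftilde <- rep(NA_real_, n)
  converged <- feasible
  if (any(rigid & feasible)) {
    i <- which(rigid & feasible)
    ell <- sqrt(l_MT[i]^2 + h[i]^2)
    ls <- ell / ell_o[i]
    ftilde[i] <- (a[i] * f_active(ls) + f_passive(ls)) * (l_MT[i] / ell)
  }

  act <- which(feasible & !rigid)
  if (length(act)) {
    a_s <- a[act]; lmt_s <- l_MT[act]; lo_s <- ell_o[act]
    ls_s <- L_S[act]; h_s <- h[act]
    resid_s <- function(f) {
      g <- fibre_geom(f, lmt_s, lo_s, ls_s, h_s, tc)
      (a_s * f_active(g$lstar) + f_passive(g$lstar)) * g$cosa - f
    }
    lo <- rep(0, length(act))
    # slack solution: equilibrium wants non-positive tendon force
    slack <- resid_s(lo) <= 0
    hi <- a_s + 1.5
    for (k in 1:8) {
      bad <- resid_s(hi) > 0 & !slack
      if (!any(bad)) break
      hi[bad] <- hi[bad] * 2
    }
    f <- 0.5 * (lo + hi)
    fd_h <- 1e-8
    for (it in seq_len(maxit)) {
      rf <- resid_s(f)
      # maintain bracket
      pos <- rf > 0
      lo[pos] <- f[pos]; hi[!pos] <- f[!pos]
      dr <- (resid_s(f + fd_h) - rf) / fd_h
      step <- ifelse(abs(dr) > 1e-12, -rf / dr, 0)
      fn <- f + step
      # fall back to bisection when Newton leaves the bracket
      outb <- !(fn > lo & fn < hi) | !is.finite(fn)
      fn[outb] <- 0.5 * (lo[outb] + hi[outb])
      conv <- abs(fn - f) < tol * pmax(1, abs(fn))
      f <- fn
      if (all(conv | slack)) break
    }
    f[slack] <- 0
    ftilde[act] <- f
  }

  g <- fibre_geom(ifelse(is.na(ftilde), 0, ftilde), l_MT, ell_o, L_S, h, tc)
  list(ftilde = ftilde, lstar = g$lstar, cosa = g$cosa,
       feasible = feasible, converged = converged)
}

#' Solve static muscle-tendon equilibrium
#'
#' Finds the tendon force at which the pennated fibre (at zero velocity)
#' balances the in-series tendon for a fixed activation and MTU length,
#' using safeguarded Newton iteration on the normalized tendon force.
#' Infeasibility (`l_MT < L_S`: the tendon alone exceeds the available
#' length, so no equilibrium exists) is reported distinctly from
#' non-convergence.
#'
#' @param a Activation in `[0, 1]`.
#' @param l_MT MTU length (m).
#' @param params A [muscle_params()] object.
#' @return A `muscle_state` list with `a`, `F_T` (N), `ell` (m),
#'   `ell_norm`, `v_norm` (= 0), `alpha` (rad) and `F_passive` (N).
#' @export
solve_static_equilibrium <- function(a, l_MT, params) {
  if (a < 0 || a > 1) stop("activation must lie in [0, 1]")
  tc <- tendon_curve(params$k_T)
  h <- params$ell_o * sin(params$alpha_o)
  sol <- static_eq_ftilde(a, l_MT, params$ell_o, params$L_S, h, tc)
  if (!sol$feasible) {
    stop(sprintf(
      "infeasible: l_MT (%.4g m) does not exceed tendon slack length (%.4g m)",
      l_MT, params$L_S))
  }
  if (!sol$converged) stop("equilibrium iteration failed to converge")
  structure(list(
    a = a, F_T = sol$ftilde * params$F_max,
    ell = sol$lstar * params$ell_o, ell_norm = sol$lstar, v_norm = 0,
    alpha = acos(pmin(sol$cosa, 1)),
    F_passive = f_passive(sol$lstar) * params$F_max
  ), class = "muscle_state")
}

# --- excitation-activation dynamics ---------------------------------------

# smooth switch width (activation units) between the two time constants
.act_blend_width <- 0.1

# first-order activation rate with a smooth blend between tau_act
# (excitation above activation) and tau_deact (below)
activation_rate <- function(e, a, tau_act, tau_deact,
                            width = .act_blend_width) {
  s <- 0.5 + 0.5 * tanh((e - a) / width)
  tau <- tau_deact + (tau_act - tau_deact) * s
  (e - a) / tau
}

# analytic derivative of activation_rate with respect to a
activation_rate_da <- function(e, a, tau_act, tau_deact,
                               width = .act_blend_width) {
  u <- (e - a) / width
  s <- 0.5 + 0.5 * tanh(u)
  ds_da <- -0.5 * (1 - tanh(u)^2) / width
  tau <- tau_deact + (tau_act - tau_deact) * s
  dtau_da <- (tau_act - tau_deact) * ds_da
  -1 / tau - (e - a) * dtau_da / tau^2
}

#' Activation dynamics residual
#'
#' First-order excitation-activation dynamics with a smooth blend between
#' the activation time constant (when excitation exceeds activation) and
#' the deactivation time constant (when it falls below). The residual is
#' `dadt` minus the model rate, so it is zero when the supplied derivative
#' matches the dynamics.
#'
#' @param e Excitation in `[0, 1]`.
#' @param a Activation in `[0, 1]`.
#' @param dadt Activation time derivative (1/s).
#' @param params A [muscle_params()] object (supplies the time constants).
#' @return Residual (1/s).
#' @export
activation_dynamics_residual <- function(e, a, dadt, params) {
  if (any(e < 0 | e > 1) || any(a < 0 | a > 1)) {
    stop("excitation and activation must lie in [0, 1]")
  }
  dadt - activation_rate(e, a, params$tau_act, params$tau_deact)
}
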