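# Smooth, continuously differentiable Hill characteristic curves.
#
# Forms follow the widely used differentiable Hill-model family (Gaussian-sum
# active force-length, exponential passive curve, asinh-type force-velocity,
# exponential tendon force-strain), with constants recalibrated so the
# normalization anchors hold exactly:
#   f_act(1) = 1, f_pass(1) = 0, f_v(0) = 1, f_T(1) = 0,
# and so the tendon curve attains local slope k_T at the strain where
# f_T = 1, for any k_T (the human-model default of ~35 does not apply here).

# active force-length Gaussian-sum coefficients
.fl_b1 <- c(0.814483478343008, 0.433004984392647, 0.1)
.fl_b2 <- c(1.055033428970575, 0.716775413397760, 1.0)
.fl_b3 <- c(0.162384573599574, -0.029947116970696, 0.5 * sqrt(0.5))
.fl_b4 <- c(0.063303448465465, 0.200356847296188, 0.0)

.fl_raw <- function(x) {
  out <- 0
  for (i in 1:3) {
    out <- out + .fl_b1[i] *
      exp(-0.5 * (x - .fl_b2[i])^2 / (.fl_b3[i] + .fl_b4[i] * x)^2)
  }
  out
}
.fl_norm <- .fl_raw(1)

# passive curve: exponential with strain scale e0 above optimal length,
# taken through a C1 smooth one-sided ramp so that f_pass is exactly 0 at
# l* = 1 and numerically 0 (|f_pass| < 1e-7) below it
.fp_kpe <- 4
.fp_e0 <- 0.6
.fp_delta <- 1e-6
.fp_ramp <- function(d) 0.5 * (d + sqrt(d^2 + .fp_delta^2) - .fp_delta)

# force-velocity asinh coefficients; d4 re-solved so f_v(0) = 1 exactly
.fv_d1 <- -0.318323436899127
.fv_d2 <- -8.149156043475250
.fv_d3 <- -0.374121508647863
.fv_d4 <- 1 - .fv_d1 * asinh(.fv_d3)

# tendon curve shape constants; per-k_T constants via tendon_curve()
.ft_c2 <- 0.995
.ft_c3 <- 0.25

#' Active force-length multiplier
#' @param ell_norm Normalized fibre length (l/l_o).
#' @return Dimensionless active force-length multiplier, 1 at `ell_norm = 1`.
#' @export
f_active <- function(ell_norm) .fl_raw(ell_norm) / .fl_norm

#' Passive force-length multiplier
#' @inheritParams f_active
#' @return Dimensionless passive force multiplier; 0 at and (to ~1e-7)
#'   below optimal length, rising exponentially above it.
#' @export
f_passive <- function(ell_norm) {
  expm1(.fp_kpe * .fp_ramp(ell_norm - 1) / .fp_e0) / expm1(.fp_kpe)
}

#' Force-velocity multiplier
#' @param v_norm Fibre velocity as a fraction of maximal contraction
#'   velocity (positive = lengthening); the physiological range is
#'   `[-1, 1]`.
#' @return Dimensionless force-velocity multiplier, 1 at zero velocity,
#'   approaching 0 at maximal shortening.
#' @export
f_velocity <- function(v_norm) {
  .fv_d1 * asinh(.fv_d2 * v_norm + .fv_d3) + .fv_d4
}

# inverse and slope of the force-velocity curve
fv_inverse <- function(f) (sinh((f - .fv_d4) / .fv_d1) - .fv_d3) / .fv_d2
fv_slope <- function(v_norm) {
  .fv_d1 * .fv_d2 / sqrt((.fv_d2 * v_norm + .fv_d3)^2 + 1)
}

# derivatives of the length curves (used by analytic optimizer gradients)
fl_slope <- function(x) {
  out <- 0
  for (i in 1:3) {
    w <- .fl_b3[i] + .fl_b4[i] * x
    z <- (x - .fl_b2[i]) / w
    # d/dx exp(-z^2/2) with z = (x - b2)/(b3 + b4 x)
    dz <- (w - (x - .fl_b2[i]) * .fl_b4[i]) / w^2
    out <- out + .fl_b1[i] * exp(-0.5 * z^2) * (-z) * dz
  }
  out / .fl_norm
}
fp_slope <- function(x) {
  d <- x - 1
  rp <- 0.5 * (1 + d / sqrt(d^2 + .fp_delta^2))
  (.fp_kpe / .fp_e0) * rp *
    exp(.fp_kpe * .fp_ramp(d) / .fp_e0) / expm1(.fp_kpe)
}

#' Tendon force-strain curve for a given dimensionless stiffness
#'
#' Constructs the exponential tendon curve
#' \eqn{f_T(x) = c_1 e^{k'(x - c_2)} - c_3} with constants re-solved so
#' that \eqn{f_T(1) = 0} and the local slope equals `k_T` exactly at the
#' strain where \eqn{f_T = 1} (the top of the physiological operating
#' region), for any `k_T`.
#'
#' @param k_T Dimensionless tendon stiffness.
#' @return A list with functions `f` (force from normalized tendon length
#'   `l_T / L_S`), `finv` (normalized tendon length from force) and
#'   `slope` (d f_T / d x), plus the constants used.
#' @export
tendon_curve <- function(k_T) {
  if (any(k_T <= 0)) stop("k_T must be strictly positive")
  kp <- k_T / (1 + .ft_c3)
  c3 <- .ft_c3
  list(
    f = function(x) c3 * expm1(kp * (x - 1)),
    finv = function(f) 1 + log1p(f / c3) / kp,
    slope = function(x) kp * c3 * exp(kp * (x - 1)),
    k_T = k_T, kp = kp, c3 = c3
  )
}

#' Evaluate all four Hill characteristic curves
#'
#' @param ell_norm Normalized fibre length (l/l_o), > 0.
#' @param v_norm Normalized fibre velocity as a fraction of maximal
#'   contraction velocity.
#' @param tendon_strain_ratio Normalized tendon length `l_T / L_S`, > 0.
#' @param k_T Dimensionless tendon stiffness.
#' @return A list with numeric components `f_act`, `f_pass`, `f_v`, `f_T`.
#'   Evaluation outside the usual operating region
#'   (`ell_norm` in `[0.2, 1.8]`) is permitted; the returned object carries
#'   the count of such extrapolated points in attribute `"extrapolated"`,
#'   and a message is emitted when `options(fibreops.log_extrapolation =
#'   TRUE)` is set.
#' @export
evaluate_hill_curves <- function(ell_norm, v_norm = 0,
                                 tendon_strain_ratio = 1, k_T = 100) {
  if (any(ell_norm <= 0)) stop("ell_norm must be strictly positive")
  if (any(tendon_strain_ratio <= 0)) {
    stop("tendon_strain_ratio must be strictly positive")
  }
  tc <- tendon_curve(k_T)
  out <- list(f_act = f_active(ell_norm),
              f_pass = f_passive(ell_norm),
              f_v = f_velocity(v_norm),
              f_T = tc$f(tendon_strain_ratio))
  n_out <- sum(ell_norm < 0.2 | ell_norm > 1.8)
  attr(out, "extrapolated") <- n_out
  if (n_out > 0 && isTRUE(getOption("fibreops.log_extrapolation"))) {
    message(sprintf(
      "evaluate_hill_curves: %d point(s) outside l* in [0.2, 1.8]", n_out))
  }
  out
}

#' Instantaneous pennation angle under constant muscle thickness
#'
#' The constant-thickness fibre geometry keeps
#' \eqn{\ell \sin\alpha = \ell_o \sin\alpha_o}, so
#' \eqn{\alpha(\ell) = \arcsin(\ell_o \sin\alpha_o / \ell)}.
#'
#' @param ell Fibre length (m).
#' @param params A [muscle_params()] object.
#' @return Pennation angle (rad).
#' @export
pennation_angle <- function(ell, params) {
  h <- params$ell_o * sin(params$alpha_o)
  if (any(ell < h)) {
    stop("fibre length below muscle thickness: pennation undefined")
  }
  asin(h / pmax(ell, .Machine$double.eps))
}
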