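# Shared builders and independent oracles for the test suite.

# a parallel-fibred reference MTU (SI units)
simple_mtu <- function(name = "m1", ell_o = 0.02, L_S = 0.03,
                       alpha_o = 0, k_T = 100, F_max = 10) {
  muscle_params(name, m = F_max * 1060 * ell_o / 3e5, ell_o = ell_o,
                L_S = L_S, alpha_o = alpha_o, F_max = F_max, k_T = k_T)
}

# one-DOF limb with an antagonist pair of monoarticular MTUs with constant
# moment arms; neutral MTU lengths put fibres at optimal length when the
# tendon is slack and the joint is at zero
pair_limb <- function(arm = 0.004, ell_o = 0.02, L_S = 0.03,
                      alpha_o = 0, k_T = 100, F_max = 10,
                      range = c(-1, 1)) {
  d <- dof_spec("q1", range[1], range[2])
  mk <- function(name, sense) {
    p <- simple_mtu(name, ell_o, L_S, alpha_o, k_T, F_max)
    c0 <- L_S + sqrt(ell_o^2 - (ell_o * sin(alpha_o))^2)
    g <- mtu_geometry(name, "q1", coeffs = c(c0, -sense * arm),
                      powers = matrix(c(0, 1), 2, 1))
    list(params = p, geometry = g)
  }
  limb_model(list(d), list(mk("ago", +1), mk("ant", -1)))
}

# independent bisection oracle for static muscle-tendon equilibrium in
# normalized tendon force (v = 0)
bisect_equilibrium <- function(a, l_MT, params, iters = 80) {
  tc <- tendon_curve(params$k_T)
  h <- params$ell_o * sin(params$alpha_o)
  resid <- function(f) {
    lt <- params$L_S * tc$finv(f)
    proj <- l_MT - lt
    ell <- sqrt(proj^2 + h^2)
    ls <- ell / params$ell_o
    (a * f_active(ls) + f_passive(ls)) * (proj / ell) - f
  }
  if (resid(0) <= 0) return(0)
  lo <- 0; hi <- a + 1.5
  while (resid(hi) > 0) hi <- 2 * hi
  for (i in seq_len(iters)) {
    mid <- 0.5 * (lo + hi)
    if (resid(mid) > 0) lo <- mid else hi <- mid
  }
  0.5 * (lo + hi)
}
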