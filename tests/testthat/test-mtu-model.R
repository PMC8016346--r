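# Hill-type MTU parameterization, characteristic curves, pennation
# geometry and equilibrium.

test_that("maximal isometric force follows the stress-density formula", {
  # worked architecture values (printed precision: g, mm)
  expect_equal(compute_fmax(1.35e-3, 15.5e-3), 24.65, tolerance = 1e-3)
  expect_equal(compute_fmax(2.55e-3, 24.2e-3), 29.816, tolerance = 5e-3)
  expect_identical(compute_fmax(0, 0.01), 0)
  # exact linearity in mass, inverse proportionality in fibre length
  expect_identical(compute_fmax(2e-3, 0.02), 2 * compute_fmax(1e-3, 0.02))
  expect_identical(compute_fmax(1e-3, 0.04), compute_fmax(1e-3, 0.02) / 2)
  expect_error(compute_fmax(1e-3, 0), "positive")
  expect_error(compute_fmax(-1e-3, 0.02), "non-negative")
})

test_that("packaged architecture table reproduces printed forces", {
  tab <- tinamou_fixture()
  expect_equal(nrow(tab), 36)
  fpred <- compute_fmax(tab$mass_g * 1e-3, tab$fibre_length_mm * 1e-3)
  rel <- abs(fpred - tab$fmax_N) / tab$fmax_N
  # documented anomalies: printed forces inconsistent with printed
  # (rounded) mass and fibre length for these five entries
  anomalies <- c("FMTL", "ILFB", "ILPOa", "ILPOp", "OL")
  expect_true(all(rel[!tab$abbreviation %in% anomalies] < 0.01))
  expect_gte(sum(rel < 0.01), 30)
  # spot rows
  itcaa <- tab[tab$abbreviation == "ITCaa", ]
  expect_equal(itcaa$mass_g, 1.35)
  expect_equal(itcaa$fibre_length_mm, 15.5)
  expect_equal(itcaa$pennation_deg, 26.2)
  expect_equal(itcaa$fmax_N, 24.65)
  gi <- tab[tab$abbreviation == "GI", ]
  expect_equal(gi$slack_length_mm, 44)
  expect_equal(gi$tuned_slack_length_mm, 53.5)
})

test_that("dimensionless tendon stiffness matches its definition", {
  # hand evaluation: E*A_T * rho * l_o / (m * sigma * cos a)
  expect_equal(
    compute_tendon_stiffness(1.2e9, 0.5e-6, 2.55e-3, 24.2e-3, 30 * pi / 180),
    23.23, tolerance = 1e-3)
  # numerator equal to pennation-adjusted F_max gives k_T = 1
  cst <- tissue_constants()
  m <- 2e-3; lo <- 0.02; a <- 0.3
  EA <- m * cst$sigma * cos(a) / (cst$rho_muscle * lo)
  expect_equal(compute_tendon_stiffness(EA, 1, m, lo, a), 1)
  expect_equal(compute_tendon_stiffness(1.2e9, 1e-6, m, lo, a),
               2 * compute_tendon_stiffness(1.2e9, 0.5e-6, m, lo, a))
  expect_error(compute_tendon_stiffness(1.2e9, 1e-6, m, lo, pi / 2),
               "pennation")
})

test_that("time constants scale with body mass to the one-sixth power", {
  ratio <- (0.545 / 64.8)^(1 / 6)
  expect_equal(scale_time_constant(0.015, 64.8, 0.545), 0.015 * ratio)
  expect_equal(round(scale_time_constant(0.015, 64.8, 0.545), 3), 0.007)
  expect_equal(round(scale_time_constant(0.060, 64.8, 0.545), 3), 0.027)
  expect_identical(scale_time_constant(0.02, 3, 3), 0.02)
  expect_error(scale_time_constant(0.02, 0, 1), "positive")
})

test_that("slack-length first approximation reconciles the two anchors", {
  # range exactly l_o: both anchor equations agree
  expect_equal(estimate_slack_length(0.020, 0.030, 0.010, 0), 0.015)
  # inconsistent anchors: least-squares mean of 15 and 17 mm
  expect_equal(estimate_slack_length(0.020, 0.032, 0.010, 0), 0.016)
  # pennated: w(0.5 l_o) = 0 (radicand negative), w(1.5 l_o) = 14.142 mm
  expect_equal(estimate_slack_length(0.020, 0.030, 0.010, 30 * pi / 180),
               0.5 * (0.020 + 0.030 - sqrt(0.015^2 - 0.005^2)),
               tolerance = 1e-6)
  expect_error(estimate_slack_length(0.03, 0.02, 0.01), "below")
})

test_that("characteristic curves hold their normalization anchors", {
  expect_equal(f_active(1), 1, tolerance = 1e-10)
  expect_equal(f_passive(1), 0, tolerance = 1e-10)
  expect_equal(f_velocity(0), 1, tolerance = 1e-10)
  for (kT in c(5, 35, 100, 1000)) {
    tc <- tendon_curve(kT)
    expect_equal(tc$f(1), 0, tolerance = 1e-10)
    # slope at the strain where f_T = 1 equals k_T
    x1 <- tc$finv(1)
    expect_equal(tc$slope(x1), kT, tolerance = 1e-8 * kT)
    # finite-difference cross-check of the analytic slope
    fd <- (tc$f(x1 + 1e-7) - tc$f(x1 - 1e-7)) / 2e-7
    expect_equal(fd, kT, tolerance = 0.1 * kT)
  }
})

test_that("curve shapes are physiological", {
  # ascending limb of the active curve is monotone
  expect_true(f_active(0.5) < f_active(0.8))
  expect_true(f_active(0.8) < f_active(1.0))
  # and decays on both sides of optimal
  expect_true(f_active(1.5) < f_active(1.0))
  # passive: ~0 below optimal, strictly increasing above
  expect_true(all(abs(f_passive(seq(0.3, 0.99, by = 0.01))) < 1e-4))
  fp <- f_passive(seq(1, 1.8, by = 0.01))
  expect_true(all(diff(fp) > 0))
  # force-velocity: monotone increasing, near zero at maximal shortening
  fv <- f_velocity(seq(-1, 1, by = 0.05))
  expect_true(all(diff(fv) > 0))
  expect_lt(abs(f_velocity(-1)), 0.06)
  out <- evaluate_hill_curves(1, 0, 1, 100)
  expect_equal(unname(unlist(out)), c(1, 0, 1, 0), tolerance = 1e-10)
  expect_identical(attr(evaluate_hill_curves(c(0.1, 1)), "extrapolated"), 1L)
})

test_that("pennation follows the constant-thickness relation", {
  p <- simple_mtu(alpha_o = 30 * pi / 180)
  expect_equal(pennation_angle(p$ell_o, p), 30 * pi / 180)
  expect_equal(pennation_angle(2 * p$ell_o, p), asin(0.25))
  p0 <- simple_mtu(alpha_o = 0)
  expect_identical(pennation_angle(0.005, p0), 0)
  expect_error(pennation_angle(0.5 * p$ell_o * sin(p$alpha_o), p),
               "thickness")
})

test_that("fibre state inverts the tendon curve", {
  p <- simple_mtu(ell_o = 0.02, L_S = 0.03, alpha_o = 0)
  # slack tendon anchor
  st <- fibre_state_from_tendon_force(0, p$L_S + p$ell_o, p)
  expect_equal(st$ell_norm, 1, tolerance = 1e-12)
  expect_equal(st$l_T, p$L_S, tolerance = 1e-12)
  # increasing tendon force at fixed MTU length strictly shortens fibres
  fs <- seq(0, 1, by = 0.1)
  ls <- vapply(fs, function(f) {
    fibre_state_from_tendon_force(f, p$L_S + p$ell_o, p)$ell
  }, numeric(1))
  expect_true(all(diff(ls) < 0))
  expect_error(fibre_state_from_tendon_force(2, p$L_S + 1e-5, p),
               "infeasible")
})

test_that("constant-thickness relation holds at equilibrium states", {
  p <- simple_mtu(alpha_o = 25 * pi / 180)
  st <- solve_static_equilibrium(0.7, p$L_S + 0.9 * p$ell_o, p)
  expect_equal(st$ell * sin(st$alpha), p$ell_o * sin(p$alpha_o),
               tolerance = 1e-9)
})

test_that("equilibrium residual is zero at solutions and flips sign", {
  p <- simple_mtu()
  st <- solve_static_equilibrium(0.6, p$L_S + 0.95 * p$ell_o, p)
  expect_lt(abs(equilibrium_residual(st, 0.6, p)), 1e-6)
  # slack system
  st0 <- list(ell_norm = 1, v_norm = 0, alpha = 0, F_T = 0)
  expect_equal(equilibrium_residual(st0, 0, p), 0, tolerance = 1e-10)
  # monotonicity scan: residual positive below equilibrium force, negative
  # above (unique root over the bracket)
  lmt <- p$L_S + 0.95 * p$ell_o
  f_eq <- st$F_T / p$F_max
  for (f in c(0.25, 0.5, 1.5, 2) * f_eq) {
    fs <- fibre_state_from_tendon_force(f, lmt, p)
    r <- equilibrium_residual(
      list(ell_norm = fs$ell_norm, v_norm = 0, alpha = fs$alpha,
           F_T = f * p$F_max), 0.6, p)
    expect_identical(r > 0, f < f_eq)
  }
})

test_that("static equilibrium matches the bisection oracle", {
  set.seed(42)
  for (i in 1:200) {
    p <- simple_mtu(ell_o = runif(1, 0.008, 0.06),
                    L_S = runif(1, 0.002, 0.2),
                    alpha_o = runif(1, 0, 0.6),
                    k_T = runif(1, 20, 500),
                    F_max = runif(1, 0.6, 30))
    a <- runif(1)
    w <- sqrt(p$ell_o^2 - (p$ell_o * sin(p$alpha_o))^2)
    lmt <- p$L_S + runif(1, 0.55, 1.6) * w
    st <- solve_static_equilibrium(a, lmt, p)
    oracle <- bisect_equilibrium(a, lmt, p)
    expect_equal(st$F_T / p$F_max, oracle, tolerance = 1e-8)
  }
})

test_that("rigid-tendon limit pins fibre length to the MTU projection", {
  for (a in c(0, 0.5, 1)) {
    p <- simple_mtu(k_T = 1e6)
    st <- solve_static_equilibrium(a, p$L_S + p$ell_o, p)
    expect_equal(st$ell_norm, 1, tolerance = 1e-4)
  }
  # higher activation stretches the tendon, shortening fibres
  p <- simple_mtu(k_T = 100)
  l0 <- solve_static_equilibrium(0, p$L_S + p$ell_o, p)$ell
  l1 <- solve_static_equilibrium(1, p$L_S + p$ell_o, p)$ell
  expect_lte(l1, l0)
})

test_that("infeasible geometry is reported distinctly", {
  p <- simple_mtu(L_S = 0.03)
  expect_error(solve_static_equilibrium(0.5, 0.02, p), "infeasible")
})

test_that("activation dynamics blend the two time constants", {
  p <- simple_mtu()
  expect_equal(activation_dynamics_residual(0.4, 0.4, 0, p), 0)
  expect_error(activation_dynamics_residual(1.4, 0.2, 0, p), "0, 1")
  # step response oracle: integrate the rate equation with deSolve
  step_up <- deSolve::ode(
    y = c(a = 0), times = seq(0, 0.05, by = 1e-4),
    func = function(t, y, parms) {
      list(-activation_dynamics_residual(1, min(max(y, 0), 1), 0, p))
    }, parms = NULL)
  t63 <- unname(step_up[min(which(step_up[, "a"] >= 0.632)), "time"])
  expect_equal(t63, p$tau_act, tolerance = 0.2)
  decay <- deSolve::ode(
    y = c(a = 1), times = seq(0, 0.2, by = 1e-4),
    func = function(t, y, parms) {
      list(-activation_dynamics_residual(0, min(max(y, 0), 1), 0, p))
    }, parms = NULL)
  t37 <- unname(decay[min(which(decay[, "a"] <= exp(-1))), "time"])
  expect_equal(t37, p$tau_deact, tolerance = 0.2)
})
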