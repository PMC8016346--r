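# Redundancy solver components: static optimization seeding, the batched
# transcription evaluator (R reference vs compiled), reserve reporting and
# a small end-to-end zero-moment solve.

make_small_problem <- function(seed = 21, n_samples = 41, mesh = 12) {
  limb <- make_toy_limb(1, 2, seed = seed)
  spec <- gait_spec(0.39, 0.71, 0.5, n_samples, "walk")
  kin <- make_gait_kinematics(spec, limb, seed = seed)
  act <- make_activation_profiles(limb, kin, seed = seed)
  gen <- forward_generate_trial(limb, kin, act)
  list(limb = limb, trial = gen$trial, truth = gen$truth, mesh = mesh)
}

test_that("static optimization seed solves hand-checkable moment balances", {
  # one muscle, one DOF, constant arm 10 mm, F_max 10 N: with unit
  # force-length/velocity multipliers, M = a * F_max * r => a = 0.5
  d <- dof_spec("q1", -1, 1)
  p <- simple_mtu("solo", ell_o = 0.02, L_S = 0.005, F_max = 10)
  g <- mtu_geometry("solo", "q1", coeffs = c(0.005 + 0.02, -0.010),
                    powers = matrix(c(0, 1), 2, 1))
  limb <- limb_model(list(d), list(list(params = p, geometry = g)))
  tt <- seq(0, 0.5, length.out = 21)
  trial <- gait_trial(tt, matrix(0, 21, 1, dimnames = list(NULL, "q1")),
                      matrix(0.05, 21, 1, dimnames = list(NULL, "q1")),
                      model = limb)
  # rigid first pass: fibres sit exactly at optimal length, isometric,
  # so f_act * f_v = 1 and the balance gives a = M / (F_max r) = 0.5
  sg <- static_optimization_seed(list(trial), limb, n_refine = 0)
  expect_equal(unname(sg[[1]]$a[11, 1]), 0.5, tolerance = 1e-6)

  # zero moment, no passive force: all activations zero; an antagonist
  # pair does not co-contract under the minimum-norm solution
  pl <- pair_limb()
  trial0 <- gait_trial(tt, matrix(0, 21, 1, dimnames = list(NULL, "q1")),
                       matrix(0, 21, 1, dimnames = list(NULL, "q1")),
                       model = pl)
  sg0 <- static_optimization_seed(list(trial0), pl)
  expect_lt(max(abs(sg0[[1]]$a)), 1e-10)
})

test_that("compiled and reference transcription evaluators agree", {
  sp <- make_small_problem()
  prob <- fibreops:::build_rs_problem(list(sp$trial), sp$limb,
                                      objective_weights(), sp$mesh,
                                      c(0.5, 2), TRUE, FALSE, 0.01)
  set.seed(31)
  theta <- matrix(runif(prob$n_par * 4), prob$n_par, 4)
  theta <- prob$lower + theta * (prob$upper - prob$lower)
  evR <- fibreops:::rs_batch_eval(theta, prob)
  evC <- fibreops:::rs_eval_J(theta, prob, use_cpp = TRUE)
  expect_equal(evC$J, evR$J, tolerance = 1e-7)
  expect_equal(unname(evC$parts), unname(evR$parts), tolerance = 1e-6)
})

test_that("batched finite-difference gradient matches central differences", {
  sp <- make_small_problem()
  prob <- fibreops:::build_rs_problem(list(sp$trial), sp$limb,
                                      objective_weights(), sp$mesh,
                                      c(0.5, 2), TRUE, TRUE, 0.01)
  set.seed(32)
  par <- prob$lower + runif(prob$n_par) * (prob$upper - prob$lower) * 0.8
  g <- fibreops:::rs_gradient(par, prob)
  for (i in sample(prob$n_par, 5)) {
    hstep <- 1e-5
    pp <- par; pp[i] <- pp[i] + hstep
    pm <- par; pm[i] <- pm[i] - hstep
    gc <- (fibreops:::rs_eval_J(matrix(pp, ncol = 1), prob)$J -
             fibreops:::rs_eval_J(matrix(pm, ncol = 1), prob)$J) /
      (2 * hstep)
    expect_equal(g$grad[i], gc, tolerance = 1e-3 * max(1, abs(gc)))
  }
})

test_that("the analytic contraction-rate derivative matches finite
          differences", {
  set.seed(35)
  tc <- tendon_curve(100)
  for (i in 1:25) {
    lo <- runif(1, 0.01, 0.06); LS <- runif(1, 0.005, 0.2)
    h <- lo * sin(runif(1, 0, 0.6))
    lmt <- LS * 1.002 + runif(1, 0.6, 1.3) * sqrt(lo^2 - h^2)
    lmtdot <- runif(1, -0.1, 0.1)
    a <- runif(1); f <- runif(1, 0.01, 1.2)
    r <- fibreops:::contraction_rate(f, a, lmt, lmtdot, lo, LS, h, 10,
                                     tc, 0.01, grad = TRUE)
    # skip states where the velocity solve is pinned at its bracket (the
    # implicit-function derivative does not apply there)
    if (abs(r$vtilde) > 45) next
    fd <- (fibreops:::contraction_rate(f + 1e-7, a, lmt, lmtdot, lo, LS,
                                       h, 10, tc, 0.01)$dftilde -
             fibreops:::contraction_rate(f - 1e-7, a, lmt, lmtdot, lo, LS,
                                         h, 10, tc, 0.01)$dftilde) / 2e-7
    expect_equal(r$ddftilde, fd, tolerance = 1e-3 * max(1, abs(fd)))
  }
})

test_that("a zero-moment trial is solved with near-zero activations", {
  pl <- pair_limb(L_S = 0.01)
  tt <- seq(0, 0.5, length.out = 41)
  # fixed neutral pose, no external moments, fibres at optimal length
  trial <- gait_trial(tt, matrix(0, 41, 1, dimnames = list(NULL, "q1")),
                      matrix(0, 41, 1, dimnames = list(NULL, "q1")),
                      model = pl, label = "static", duty_factor = 0.6)
  sol <- solve_redundancy(trial, pl, mesh = 10, freeze_tuning = TRUE,
                          control = list(maxit = 150))
  expect_lt(max(sol$trials[[1]]$activation), 0.02)
  expect_lt(sol$objective, 0.01)
  # tuning variant: with no data pressure the factors stay at one
  sol2 <- solve_redundancy(trial, pl, mesh = 10,
                           control = list(maxit = 150))
  expect_equal(unname(sol2$tuning$p_ell), c(1, 1), tolerance = 0.02)
  expect_equal(unname(sol2$tuning$p_L), c(1, 1), tolerance = 0.02)
})

test_that("reserve contribution report computes the stated fractions", {
  # hand-built: a_res = 0.1, cap = 0.02 N m, |M_ext| = 0.04 N m -> 0.05
  sol <- list(trials = list(list(
    label = "t", time = seq(0.01, 0.49, length.out = 20),
    duty_factor = 0.6,
    reserve_activation = matrix(0.1, 1, 20, dimnames = list("q1", NULL)),
    reserve_caps = c(q1 = 0.02))))
  tt <- seq(0, 0.5, length.out = 21)
  trial <- list(time = tt,
                M_ext = matrix(0.04, 21, 1, dimnames = list(NULL, "q1")))
  rep <- reserve_contribution_report(sol, list(trial))
  expect_equal(rep$summary$max_fraction, 0.05, tolerance = 1e-9)
  expect_equal(unname(rep$series$t[1, 1]), 0.05, tolerance = 1e-9)
  # reserves disabled (all-zero reserve activations) give zero fractions
  sol$trials[[1]]$reserve_activation[] <- 0
  rep0 <- reserve_contribution_report(sol, list(trial))
  expect_identical(max(rep0$summary$max_fraction), 0)
})

test_that("trial smoothing is zero-phase and preserves slow content", {
  b <- make_synthetic_bundle(1, 2, seed = 13, n_samples = 101)
  tr <- b$trials$walk
  sm <- smooth_trial(tr, cutoff_hz = 20)
  # synthetic content is well below 20 Hz: filtering is nearly lossless
  expect_equal(sm$lmt, tr$lmt, tolerance = 1e-4)
  expect_lt(max(abs(sm$M_ext - tr$M_ext)),
            0.05 * max(abs(tr$M_ext)) + 1e-9)
})
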