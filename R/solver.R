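# Multi-trial inverse (muscle-redundancy) solver.
#
# The optimal control problem minimizes, over all trials jointly,
#   J = sum_trials integral( w1 sum a^2 + w2 sum a_res^2
#        + w3 sum (da/dt)^2 + w3 sum (dFT/dt)^2 + w4 sum f_pass^2 ) dt
#       + w5 sum (p_ell - 1)^2 + w6 sum (p_L - 1)^2,
# subject to excitation-activation dynamics, implicit contraction dynamics
# with tendon force as the state, muscle-tendon equilibrium, collocation
# continuity, and per-DOF moment balance with reserve actuators. The shared
# tuning factors p_ell, p_L scale optimal fibre length and tendon slack
# length across all trials simultaneously.
#
# Transcription: the trial time axis is split into `mesh` evenly spaced
# intervals and states are propagated with 2-stage Radau IIA collocation
# (3rd order, stiffly accurate; the collocation defects are driven to zero
# by an inner Newton iteration, which eliminates the state variables).
# Reserve activations are eliminated exactly through the moment balance.
# The remaining decision variables -- per-interval excitations, initial
# states and the tuning factors -- are bound-constrained only, and are
# optimized with L-BFGS-B using batched finite-difference gradients.

# Radau IIA, 2 stages: c = (1/3, 1), order 3, stiffly accurate
.radau_c <- c(1 / 3, 1)
.radau_A <- matrix(c(5 / 12, -1 / 12, 3 / 4, 1 / 4), 2, 2, byrow = TRUE)
.radau_b <- c(3 / 4, 1 / 4)

#' Objective weights for the redundancy problem
#'
#' Defaults: activation effort `w1 = 2`; reserve effort `w2 = 500`
#' (reserves are heavily penalized so muscles do the work); derivative
#' smoothing `w3 = 1`; passive fibre force `w4 = 100` (discourages tuning
#' fibres onto the descending limb where passive force is free);
#' fibre-length tuning deviation `w5 = 2`; slack-length tuning deviation
#' `w6 = 1` (slack lengths were estimated, not measured, so they are held
#' less tightly).
#'
#' @param w1,w2,w3,w4,w5,w6 Non-negative weights.
#' @return An `objective_weights` object.
#' @export
objective_weights <- function(w1 = 2, w2 = 500, w3 = 1, w4 = 100,
                              w5 = 2, w6 = 1) {
  w <- c(w1 = w1, w2 = w2, w3 = w3, w4 = w4, w5 = w5, w6 = w6)
  if (any(w < 0)) stop("objective weights must be non-negative")
  structure(as.list(w), class = "objective_weights")
}

# solve  a * f_v(v) + beta * v = rhs  for v (vectorized, monotone): warm
# closed-form start (exact for beta -> 0) plus safeguarded Newton within
# a maintained bracket (branchless mask arithmetic)
solve_vtilde <- function(rhs, afa, beta, bracket = 50) {
  lo <- rhs * 0 - bracket
  hi <- rhs * 0 + bracket
  arg <- pmin(pmax(rhs / (afa + 1e-12), f_velocity(-49.9)),
              f_velocity(49.9))
  v <- pmin(pmax(fv_inverse(arg), -bracket), bracket)
  for (it in 1:8) {
    gv <- afa * f_velocity(v) + beta * v - rhs
    pos <- (gv > 0) + 0
    hi <- pos * v + (1 - pos) * hi
    lo <- (1 - pos) * v + pos * lo
    dv <- afa * fv_slope(v) + beta
    vn <- v - gv / dv
    bad <- ((vn < lo) | (vn > hi) | !is.finite(vn)) + 0
    v <- bad * 0.5 * (lo + hi) + (1 - bad) * vn
  }
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Implicit contraction dynamics: time derivative of normalized tendon
# force given activation and MTU kinematics. Vectorized; per-muscle
# parameters recycle down the rows of matrix inputs. With grad = TRUE the
# exact derivative of the rate with respect to the normalized tendon
# force is returned (chain rule through the tendon inverse, the
# constant-thickness geometry and the implicit velocity solve).
contraction_rate <- function(ftilde, a, lmt, lmtdot, ell_o, L_S, h,
                             v_max, tc, beta = .default_beta,
                             grad = FALSE) {
  ftc <- pmax(ftilde, -tc$c3 + 1e-9)
  ltn <- tc$finv(ftc)
  lT <- L_S * ltn
  proj <- pmax(lmt - lT, .geom_eps)
  ell <- sqrt(proj^2 + h^2)
  cosa <- proj / ell
  lstar <- ell / ell_o
  fpass <- f_passive(lstar)
  afa <- a * f_active(lstar)
  rhs <- ftc / cosa - fpass
  vtilde <- solve_vtilde(rhs, afa, beta)
  elldot <- vtilde * v_max * ell_o
  lTdot <- lmtdot - elldot / cosa
  dftilde <- tc$kp * (ftc + tc$c3) * lTdot / L_S
  out <- list(dftilde = dftilde, lstar = lstar, vtilde = vtilde,
              fpass = fpass, cosa = cosa)
  if (grad) {
    dproj <- -L_S / (tc$kp * (ftc + tc$c3))
    dcosa <- dproj * (1 - cosa^2) / ell
    dlstar <- cosa * dproj / ell_o
    drhs <- 1 / cosa - ftc * dcosa / cosa^2 - fp_slope(lstar) * dlstar
    dafa <- a * fl_slope(lstar) * dlstar
    dvt <- (drhs - dafa * f_velocity(vtilde)) /
      (afa * fv_slope(vtilde) + beta)
    delldot <- dvt * v_max * ell_o
    dlTdot <- -(delldot * cosa - elldot * dcosa) / cosa^2
    out$ddftilde <- tc$kp * (lTdot + (ftc + tc$c3) * dlTdot) / L_S
  }
  out
}

# --- problem assembly ------------------------------------------------------

build_rs_problem <- function(trials, limb, weights, mesh, tuning_bounds,
                             reserves_enabled, freeze_tuning, beta) {
  if (mesh < 10) stop("mesh must be at least 10 intervals")
  params <- lapply(limb$mtus, `[[`, "params")
  mn <- limb_mtu_names(limb)
  dn <- limb_dof_names(limb)
  m <- length(mn); K <- length(dn)
  kT <- mp_field(params, "k_T")
  base <- list(
    mn = mn, dn = dn, m = m, K = K,
    lo0 = mp_field(params, "ell_o"),
    LS0 = mp_field(params, "L_S"),
    sina0 = sin(mp_field(params, "alpha_o")),
    Fmax = mp_field(params, "F_max"),
    vmax = mp_field(params, "v_max"),
    tau_a = mp_field(params, "tau_act"),
    tau_d = mp_field(params, "tau_deact"),
    tc = tendon_curve(kT[1]))
  if (any(base$LS0 <= 0)) {
    stop("the redundancy solver requires strictly positive slack lengths")
  }
  if (length(unique(kT)) > 1) base$tc <- tendon_curve(kT)

  glob_peak <- max(vapply(trials, function(tr) max(abs(tr$M_ext)),
                          numeric(1)))
  tr_dat <- lapply(trials, function(tr) {
    Tdur <- diff(range(tr$time))
    n <- mesh
    hstep <- Tdur / n
    t0 <- min(tr$time)
    ts <- t0 + rep((0:(n - 1)) * hstep, each = 2) + .radau_c * hstep
    LMT <- matrix(NA_real_, m, 2 * n)
    LMTD <- matrix(NA_real_, m, 2 * n)
    for (i in seq_len(m)) {
      sf <- splinefun(tr$time, tr$lmt[, mn[i]], method = "fmm")
      LMT[i, ] <- sf(ts)
      LMTD[i, ] <- sf(ts, deriv = 1)
    }
    ARMS <- array(0, dim = c(m, 2 * n, K))
    for (i in seq_len(m)) for (k in seq_len(K)) {
      if (any(tr$arms[, mn[i], dn[k]] != 0)) {
        ARMS[i, , k] <- splinefun(tr$time, tr$arms[, mn[i], dn[k]],
                                  method = "fmm")(ts)
      }
    }
    MEXT <- matrix(NA_real_, K, 2 * n)
    for (k in seq_len(K)) {
      MEXT[k, ] <- splinefun(tr$time, tr$M_ext[, dn[k]],
                             method = "fmm")(ts)
    }
    caps <- limb$reserve_caps[dn]
    for (k in seq_len(K)) {
      if (is.na(caps[k])) caps[k] <- 0.1 * max(abs(tr$M_ext[, dn[k]]))
      caps[k] <- max(caps[k], 1e-3 * glob_peak, 1e-9)
    }
    wq <- rep(.radau_b, n) * hstep
    list(n = n, h = hstep, ts = ts, Tdur = Tdur, LMT = LMT, LMTD = LMTD,
         ARMS = ARMS, MEXT = MEXT, caps = caps, wq = wq,
         s_rate = 100 / Tdur, label = tr$label,
         duty = tr$duty_factor, t0 = t0)
  })

  # decision-vector layout
  idx <- list(); pos <- 0
  for (j in seq_along(trials)) {
    idx[[j]] <- list(a0 = pos + seq_len(m),
                     f0 = pos + m + seq_len(m),
                     E = pos + 2 * m + seq_len(m * 2 * mesh))
    pos <- pos + 2 * m + m * 2 * mesh
  }
  tune_idx <- NULL
  if (!freeze_tuning) {
    tune_idx <- list(p_ell = pos + seq_len(m), p_L = pos + m + seq_len(m))
    pos <- pos + 2 * m
  }
  lower <- numeric(pos); upper <- numeric(pos)
  for (j in seq_along(trials)) {
    lower[idx[[j]]$a0] <- 0; upper[idx[[j]]$a0] <- 1
    lower[idx[[j]]$f0] <- 0; upper[idx[[j]]$f0] <- 2.5
    lower[idx[[j]]$E] <- 0; upper[idx[[j]]$E] <- 1
  }
  if (!freeze_tuning) {
    lower[c(tune_idx$p_ell, tune_idx$p_L)] <- tuning_bounds[1]
    upper[c(tune_idx$p_ell, tune_idx$p_L)] <- tuning_bounds[2]
  }

  par_trial <- integer(pos)     # 0 = affects every trial
  par_start <- integer(pos)     # first mesh interval affected (0-based)
  for (j in seq_along(trials)) {
    par_trial[c(idx[[j]]$a0, idx[[j]]$f0, idx[[j]]$E)] <- j
    par_start[idx[[j]]$E] <- rep(0:(mesh - 1), each = 2 * m)
  }
  c(base, list(trials = tr_dat, idx = idx, tune_idx = tune_idx,
               par_trial = par_trial, par_start = par_start,
               n_par = pos, lower = lower, upper = upper,
               weights = weights, mesh = mesh, beta = beta,
               reserves_enabled = reserves_enabled,
               freeze_tuning = freeze_tuning))
}

# Batched objective evaluation. theta: n_par x C matrix. Returns J (length
# C); with keep = TRUE (C must be 1) also the full trajectories.
rs_batch_eval <- function(theta, prob, keep = FALSE) {
  C <- ncol(theta)
  m <- prob$m; K <- prob$K
  w <- prob$weights
  beta <- prob$beta
  tc <- prob$tc

  if (is.null(prob$tune_idx)) {
    p_ell <- matrix(1, m, C); p_L <- matrix(1, m, C)
  } else {
    p_ell <- matrix(theta[prob$tune_idx$p_ell, ], m, C)
    p_L <- matrix(theta[prob$tune_idx$p_L, ], m, C)
  }
  lo <- prob$lo0 * p_ell          # m x C
  LS <- prob$LS0 * p_L
  h_geo <- lo * prob$sina0
  vmax <- prob$vmax

  J <- numeric(C)
  parts <- matrix(0, 6, C,
                  dimnames = list(paste0("w", 1:6, "_term"), NULL))
  traj <- if (keep) vector("list", length(prob$trials)) else NULL
  A11 <- .radau_A[1, 1]; A12 <- .radau_A[1, 2]
  A21 <- .radau_A[2, 1]; A22 <- .radau_A[2, 2]

  for (j in seq_along(prob$trials)) {
    tr <- prob$trials[[j]]
    n <- tr$n; hstep <- tr$h
    id <- prob$idx[[j]]
    A <- matrix(theta[id$a0, ], m, C)
    Fv <- matrix(theta[id$f0, ], m, C)
    Emat <- theta[id$E, , drop = FALSE]     # (m*n) x C
    kprev <- matrix(0, m, C)
    if (keep) {
      st <- list(a = matrix(NA_real_, m, 2 * n),
                 f = matrix(NA_real_, m, 2 * n),
                 lstar = matrix(NA_real_, m, 2 * n),
                 vtilde = matrix(NA_real_, m, 2 * n),
                 fpass = matrix(NA_real_, m, 2 * n),
                 ares = matrix(NA_real_, K, 2 * n),
                 defect = 0)
    }
    acc <- matrix(0, 5, C)   # w1..w4 (two w3 halves folded), rows 1,2,3,4,5

    for (i in seq_len(n)) {
      # excitation parameterized directly at the two collocation stages
      E1 <- matrix(Emat[(2 * i - 2) * m + seq_len(m), ], m, C)
      E2 <- matrix(Emat[(2 * i - 1) * m + seq_len(m), ], m, C)
      s1 <- 2 * i - 1; s2 <- 2 * i

      # activation stages (analytic Newton on the 2x2 stage system)
      A1 <- A; A2 <- A
      for (it in 1:4) {
        f1 <- activation_rate(E1, A1, prob$tau_a, prob$tau_d)
        f2 <- activation_rate(E2, A2, prob$tau_a, prob$tau_d)
        g1 <- A1 - A - hstep * (A11 * f1 + A12 * f2)
        g2 <- A2 - A - hstep * (A21 * f1 + A22 * f2)
        d1 <- activation_rate_da(E1, A1, prob$tau_a, prob$tau_d)
        d2 <- activation_rate_da(E2, A2, prob$tau_a, prob$tau_d)
        J11 <- 1 - hstep * A11 * d1; J12 <- -hstep * A12 * d2
        J21 <- -hstep * A21 * d1;    J22 <- 1 - hstep * A22 * d2
        det <- J11 * J22 - J12 * J21
        dA1 <- -(J22 * g1 - J12 * g2) / det
        dA2 <- -(-J21 * g1 + J11 * g2) / det
        A1 <- A1 + dA1; A2 <- A2 + dA2
      }
      f1 <- activation_rate(E1, A1, prob$tau_a, prob$tau_d)
      f2 <- activation_rate(E2, A2, prob$tau_a, prob$tau_d)

      # contraction stages (Newton with finite-difference stage Jacobian)
      lmt1 <- tr$LMT[, s1]; lmt2 <- tr$LMT[, s2]
      lmd1 <- tr$LMTD[, s1]; lmd2 <- tr$LMTD[, s2]
      F1 <- Fv + kprev * (hstep / 3); F2 <- Fv + kprev * hstep
      # Newton with the exact analytic stage Jacobian
      for (it in 1:6) {
        r1 <- contraction_rate(F1, A1, lmt1, lmd1, lo, LS, h_geo, vmax,
                               tc, beta, grad = TRUE)
        r2 <- contraction_rate(F2, A2, lmt2, lmd2, lo, LS, h_geo, vmax,
                               tc, beta, grad = TRUE)
        k1 <- r1$dftilde; k2 <- r2$dftilde
        g1 <- F1 - Fv - hstep * (A11 * k1 + A12 * k2)
        g2 <- F2 - Fv - hstep * (A21 * k1 + A22 * k2)
        J11 <- 1 - hstep * A11 * r1$ddftilde
        J12 <- -hstep * A12 * r2$ddftilde
        J21 <- -hstep * A21 * r1$ddftilde
        J22 <- 1 - hstep * A22 * r2$ddftilde
        det <- J11 * J22 - J12 * J21
        dF1 <- -(J22 * g1 - J12 * g2) / det
        dF2 <- -(-J21 * g1 + J11 * g2) / det
        F1 <- F1 + dF1; F2 <- F2 + dF2
        if (max(abs(dF1), abs(dF2)) < 1e-11) break  # stages converged
      }
      r1 <- contraction_rate(F1, A1, lmt1, lmd1, lo, LS, h_geo, vmax,
                             tc, beta)
      r2 <- contraction_rate(F2, A2, lmt2, lmd2, lo, LS, h_geo, vmax,
                             tc, beta)
      k1 <- r1$dftilde; k2 <- r2$dftilde

      # quadrature accumulation at both stages
      wq1 <- tr$wq[s1]; wq2 <- tr$wq[s2]
      acc[1, ] <- acc[1, ] + wq1 * .colSums(A1 * A1, m, C) +
        wq2 * .colSums(A2 * A2, m, C)
      sr <- tr$s_rate
      acc[3, ] <- acc[3, ] +
        wq1 * .colSums((f1 / sr)^2, m, C) + wq2 * .colSums((f2 / sr)^2, m, C)
      acc[4, ] <- acc[4, ] +
        wq1 * .colSums((k1 / sr)^2, m, C) + wq2 * .colSums((k2 / sr)^2, m, C)
      acc[5, ] <- acc[5, ] + wq1 * .colSums(r1$fpass^2, m, C) +
        wq2 * .colSums(r2$fpass^2, m, C)

      for (k in seq_len(K)) {
        Mm1 <- .colSums(F1 * (prob$Fmax * tr$ARMS[, s1, k]), m, C)
        Mm2 <- .colSums(F2 * (prob$Fmax * tr$ARMS[, s2, k]), m, C)
        ar1 <- (tr$MEXT[k, s1] - Mm1) / tr$caps[k]
        ar2 <- (tr$MEXT[k, s2] - Mm2) / tr$caps[k]
        acc[2, ] <- acc[2, ] + wq1 * ar1^2 + wq2 * ar2^2
        if (keep) {
          st$ares[k, s1] <- ar1[1]; st$ares[k, s2] <- ar2[1]
        }
      }
      if (keep) {
        st$a[, s1] <- A1[, 1]; st$a[, s2] <- A2[, 1]
        st$f[, s1] <- F1[, 1]; st$f[, s2] <- F2[, 1]
        st$lstar[, s1] <- r1$lstar[, 1]; st$lstar[, s2] <- r2$lstar[, 1]
        st$vtilde[, s1] <- r1$vtilde[, 1]; st$vtilde[, s2] <- r2$vtilde[, 1]
        st$fpass[, s1] <- r1$fpass[, 1]; st$fpass[, s2] <- r2$fpass[, 1]
        g2d <- F2 - Fv - hstep * (A21 * k1 + A22 * k2)
        st$defect <- max(st$defect, max(abs(g2d)))
      }
      A <- A2; Fv <- F2
      kprev <- k2
    }
    if (keep) traj[[j]] <- st
    J <- J + w$w1 * acc[1, ] + w$w2 * acc[2, ] +
      w$w3 * (acc[3, ] + acc[4, ]) + w$w4 * acc[5, ]
    parts[1, ] <- parts[1, ] + w$w1 * acc[1, ]
    parts[2, ] <- parts[2, ] + w$w2 * acc[2, ]
    parts[3, ] <- parts[3, ] + w$w3 * (acc[3, ] + acc[4, ])
    parts[4, ] <- parts[4, ] + w$w4 * acc[5, ]
  }
  t5 <- w$w5 * .colSums((p_ell - 1)^2, m, C)
  t6 <- w$w6 * .colSums((p_L - 1)^2, m, C)
  J <- J + t5 + t6
  parts[5, ] <- t5; parts[6, ] <- t6
  list(J = J, parts = parts, traj = traj)
}

# dispatch to the compiled batched evaluator (default) or the reference R
# implementation (used for trajectory extraction and as a cross-check);
# col_trial/col_start describe which trial and mesh interval each column
# first affects, letting the compiled evaluator skip unaffected work
rs_eval_J <- function(theta, prob, use_cpp = TRUE,
                      col_trial = integer(ncol(theta)),
                      col_start = integer(ncol(theta))) {
  if (use_cpp) {
    ev <- rs_batch_eval_cpp(theta, prob, as.integer(col_trial),
                            as.integer(col_start))
    list(J = as.numeric(ev$J), parts = ev$parts)
  } else {
    ev <- rs_batch_eval(theta, prob)
    list(J = ev$J, parts = ev$parts)
  }
}

# forward-difference gradient via one batched evaluation; column j + 1
# perturbs parameter j, so its simulation can start at the parameter's
# first affected interval of its own trial
rs_gradient <- function(par, prob, fd_h = 1e-6, use_cpp = TRUE) {
  n <- length(par)
  hvec <- rep(fd_h, n)
  flip <- par + hvec > prob$upper
  hvec[flip] <- -fd_h
  theta <- matrix(par, n, n + 1)
  theta[cbind(seq_len(n), seq_len(n) + 1)] <-
    par + hvec
  ev <- rs_eval_J(theta, prob, use_cpp,
                  col_trial = c(0L, prob$par_trial),
                  col_start = c(0L, prob$par_start))
  list(value = ev$J[1], grad = (ev$J[-1] - ev$J[1]) / hvec,
       parts = ev$parts[, 1])
}

# minimum-norm solution of A x = b with x in [0, 1], by active-set
# pinv iterations: variables driven outside their bounds are fixed there
# and the equality system is re-solved over the remaining free set
bounded_min_norm <- function(A, b, max_pass = NULL) {
  m <- ncol(A)
  x <- numeric(m)
  free <- rep(TRUE, m)
  if (is.null(max_pass)) max_pass <- 2 * m + 2
  for (pass in seq_len(max_pass)) {
    if (!any(free)) break
    rhs <- b - A[, !free, drop = FALSE] %*% x[!free]
    xf <- as.numeric(pracma::pinv(A[, free, drop = FALSE]) %*% rhs)
    x[free] <- xf
    viol_lo <- free & x < -1e-12
    viol_hi <- free & x > 1 + 1e-12
    if (!any(viol_lo) && !any(viol_hi)) break
    # fix the worst violator at its bound and re-solve
    excess <- pmax(-x, x - 1, 0)
    worst <- which.max(excess * free)
    x[worst] <- if (x[worst] < 0) 0 else 1
    free[worst] <- FALSE
  }
  pmin(pmax(x, 0), 1)
}

#' Static optimization seed
#'
#' Per-time-step minimum-activation-squared solution: at each sample the
#' muscle force coefficients are evaluated at the instantaneous fibre
#' length and velocity, and the minimum-norm activations satisfying the
#' moment balance are obtained through the pseudoinverse, clamped to
#' `[0, 1]`. The first pass uses rigid-tendon kinematics; subsequent
#' fixed-point passes re-evaluate fibre lengths and tendon-rate-corrected
#' velocities from the previous pass's tendon forces, so the seed
#' accounts for tendon compliance. Used to seed the redundancy solver;
#' time steps with infeasible geometry fall back to zero activation
#' (reserves absorb the moment) and are flagged.
#'
#' @param trials List of [gait_trial()] objects.
#' @param limb A [limb_model()].
#' @param beta Numerical damping for the velocity term.
#' @param n_refine Number of compliant-tendon refinement passes after the
#'   rigid first pass.
#' @return List (one element per trial) with `a` (activations,
#'   `n x n_mtu`), `ftilde` (normalized tendon forces) and `infeasible`
#'   (logical per sample).
#' @export
static_optimization_seed <- function(trials, limb, beta = .default_beta,
                                     n_refine = 3) {
  params <- lapply(limb$mtus, `[[`, "params")
  mn <- limb_mtu_names(limb); dn <- limb_dof_names(limb)
  m <- length(mn)
  lo <- mp_field(params, "ell_o"); LS <- mp_field(params, "L_S")
  h <- lo * sin(mp_field(params, "alpha_o"))
  Fmax <- mp_field(params, "F_max"); vmax <- mp_field(params, "v_max")
  tc <- tendon_curve(mp_field(params, "k_T"))
  kp <- rep_len(tc$kp, m)

  lapply(trials, function(tr) {
    nt <- length(tr$time)
    a_out <- matrix(0, nt, m, dimnames = list(NULL, mn))
    f_out <- matrix(0, nt, m, dimnames = list(NULL, mn))
    infeas <- logical(nt)
    lmtdot <- apply(tr$lmt[, mn, drop = FALSE], 2, function(x) {
      splinefun(tr$time, x, method = "fmm")(tr$time, deriv = 1)
    })
    ft_prev <- matrix(0, nt, m)     # pass 0: slack tendon (rigid lengths)
    for (pass in 0:n_refine) {
      lT_rate <- matrix(0, nt, m)
      if (pass > 0) {
        for (i in seq_len(m)) {
          dft <- splinefun(tr$time, ft_prev[, i],
                           method = "fmm")(tr$time, deriv = 1)
          lT_rate[, i] <- dft * LS[i] / (kp[i] * (ft_prev[, i] + tc$c3))
        }
      }
      for (t in seq_len(nt)) {
        ltn <- 1 + log1p(pmax(ft_prev[t, ], 0) / tc$c3) / kp
        proj <- tr$lmt[t, mn] - LS * ltn
        if (any(proj <= .geom_eps)) {
          infeas[t] <- TRUE
          next
        }
        ell <- sqrt(proj^2 + h^2)
        cosa <- proj / ell
        lstar <- ell / lo
        vt <- (cosa * (lmtdot[t, ] - lT_rate[t, ])) / (lo * vmax)
        vt <- pmin(pmax(vt, -1), 1)
        cf <- Fmax * f_active(lstar) * f_velocity(vt) * cosa
        Pf <- Fmax * (f_passive(lstar) + beta * vt) * cosa
        R <- t(matrix(tr$arms[t, mn, dn], nrow = m))   # K x m
        rhs <- tr$M_ext[t, dn] - as.numeric(R %*% Pf)
        Ac <- R * rep(cf, each = nrow(R))
        a_t <- bounded_min_norm(Ac, rhs)
        a_out[t, ] <- a_t
        f_out[t, ] <- (a_t * f_active(lstar) * f_velocity(vt) +
                         f_passive(lstar) + beta * vt) * cosa
      }
      ft_prev <- pmax(f_out, 0)
    }
    if (any(infeas)) {
      message(sprintf(
        "static seed: %d/%d samples infeasible; zero seed used there",
        sum(infeas), nt))
    }
    list(a = a_out, ftilde = f_out, infeasible = infeas)
  })
}

# invert the blended activation dynamics: find e with rate(e, a) = adot
# (fixed-point on the smoothly blended time constant)
invert_activation_rate <- function(a, adot, tau_a, tau_d,
                                   width = .act_blend_width) {
  e <- a + ifelse(adot > 0, tau_a, tau_d) * adot
  for (it in 1:6) {
    s <- 0.5 + 0.5 * tanh((e - a) / width)
    tau <- tau_d + (tau_a - tau_d) * s
    e <- a + tau * adot
  }
  pmin(pmax(e, 0), 1)
}

# Refine the static-optimization seed by inverting the contraction and
# activation dynamics along the static force trajectory: given the
# normalized tendon-force series, fibre velocity follows from the tendon
# rate equation, activation from the equilibrium, and excitation from the
# activation dynamics. Places the optimizer start close to the dynamic
# optimum for well-posed inputs.
dynamic_seed <- function(trials, limb, static_seed, beta = .default_beta) {
  params <- lapply(limb$mtus, `[[`, "params")
  mn <- limb_mtu_names(limb)
  m <- length(mn)
  lo <- mp_field(params, "ell_o"); LS <- mp_field(params, "L_S")
  h <- lo * sin(mp_field(params, "alpha_o"))
  vmax <- mp_field(params, "v_max")
  tau_a <- mp_field(params, "tau_act"); tau_d <- mp_field(params, "tau_deact")
  tc <- tendon_curve(mp_field(params, "k_T"))

  out <- vector("list", length(trials))
  for (j in seq_along(trials)) {
    tr <- trials[[j]]
    sg <- static_seed[[j]]
    nt <- length(tr$time)
    a_out <- matrix(0, nt, m, dimnames = list(NULL, mn))
    e_out <- matrix(0, nt, m, dimnames = list(NULL, mn))
    f_out <- sg$ftilde
    for (i in seq_len(m)) {
      fsp <- splinefun(tr$time, pmax(sg$ftilde[, i], 0), method = "fmm")
      ft <- pmax(fsp(tr$time), 0)
      dft <- fsp(tr$time, deriv = 1)
      lsp <- splinefun(tr$time, tr$lmt[, mn[i]], method = "fmm")
      lmtdot <- lsp(tr$time, deriv = 1)
      kp_i <- if (length(tc$kp) > 1) tc$kp[i] else tc$kp
      ltn <- 1 + log1p(pmax(ft, 1e-9) / tc$c3) / kp_i
      proj <- pmax(tr$lmt[, mn[i]] - LS[i] * ltn, .geom_eps)
      ell <- sqrt(proj^2 + h[i]^2)
      cosa <- proj / ell
      lstar <- ell / lo[i]
      lTdot <- dft * LS[i] / (kp_i * (ft + tc$c3))
      vt <- (cosa * (lmtdot - lTdot)) / (lo[i] * vmax[i])
      vt <- pmin(pmax(vt, -1), 1)
      denom <- f_active(lstar) * f_velocity(vt)
      a_i <- (ft / cosa - f_passive(lstar) - beta * vt) / pmax(denom, 1e-3)
      a_i <- pmin(pmax(a_i, 0), 1)
      a_out[, i] <- a_i
      f_out[, i] <- ft
      asp <- splinefun(tr$time, a_i, method = "fmm")
      adot <- asp(tr$time, deriv = 1)
      e_out[, i] <- invert_activation_rate(a_i, adot, tau_a[i], tau_d[i])
    }
    out[[j]] <- list(a = a_out, e = e_out, ftilde = f_out,
                     infeasible = sg$infeasible)
  }
  out
}

#' Solve the multi-trial muscle-redundancy problem
#'
#' Estimates muscle excitations, activations and tendon forces that
#' reproduce each trial's external joint moments, while simultaneously
#' tuning optimal fibre length and tendon slack length through factors
#' `p_ell`, `p_L` shared across all trials. See the package vignette for
#' the formulation and numerical scheme.
#'
#' @param trials A [gait_trial()] or list of them. All trials must share
#'   the limb model.
#' @param limb A [limb_model()].
#' @param weights An [objective_weights()].
#' @param mesh Number of collocation mesh intervals per trial (>= 10;
#'   default 100).
#' @param tuning_bounds Length-2 bounds on the tuning factors.
#' @param reserves_enabled If `FALSE`, reserve caps are shrunk to a
#'   negligible value so any moment imbalance is penalized essentially as
#'   a hard constraint.
#' @param freeze_tuning Hold `p_ell = p_L = 1` fixed.
#' @param seed_guess Optional initial guess (as returned by
#'   [static_optimization_seed()]); computed internally when `NULL`.
#' @param beta Numerical damping in the contraction dynamics.
#' @param control List of optimizer controls: `maxit` (default 400),
#'   `factr` (default 1e7), `fd_h` (gradient step, default 1e-6),
#'   `trace` (default 0).
#' @return A `redundancy_solution` object: per-trial stage-time series of
#'   excitation, activation, tendon force (N), normalized fibre length and
#'   velocity, passive force and reserve activations; tuned factors;
#'   objective value and per-term breakdown; convergence status; maximum
#'   collocation defect.
#' @export
solve_redundancy <- function(trials, limb, weights = objective_weights(),
                             mesh = 100, tuning_bounds = c(0.5, 2),
                             reserves_enabled = TRUE, freeze_tuning = FALSE,
                             seed_guess = NULL, beta = .default_beta,
                             control = list()) {
  if (inherits(trials, "gait_trial")) trials <- list(trials)
  if (!length(trials)) stop("at least one trial is required")
  ctrl <- modifyList(list(maxit = 400, factr = 1e7, fd_h = 1e-6, trace = 0,
                          use_cpp = TRUE, two_phase = TRUE,
                          phase1_maxit = 250),
                     control)
  prob <- build_rs_problem(trials, limb, weights, mesh, tuning_bounds,
                           reserves_enabled, freeze_tuning, beta)
  if (!reserves_enabled) {
    for (j in seq_along(prob$trials)) {
      prob$trials[[j]]$caps[] <- 1e-6 * max(abs(prob$trials[[j]]$MEXT))
    }
  }

  if (is.null(seed_guess)) {
    seed_guess <- dynamic_seed(trials, limb,
                               static_optimization_seed(trials, limb),
                               beta = beta)
  }
  par0 <- numeric(prob$n_par)
  for (j in seq_along(trials)) {
    sg <- seed_guess[[j]]
    tr <- prob$trials[[j]]
    id <- prob$idx[[j]]
    par0[id$a0] <- pmin(pmax(sg$a[1, ], 0), 1)
    par0[id$f0] <- pmin(pmax(sg$ftilde[1, ], 0), 2.5)
    e_seed <- if (!is.null(sg$e)) sg$e else sg$a
    for (i in seq_len(prob$m)) {
      ai <- splinefun(trials[[j]]$time, e_seed[, i],
                      method = "fmm")(tr$ts)
      par0[id$E[(seq_len(2 * tr$n) - 1) * prob$m + i]] <-
        pmin(pmax(ai, 0), 1)
    }
  }
  if (!freeze_tuning) {
    par0[c(prob$tune_idx$p_ell, prob$tune_idx$p_L)] <- 1
  }

  cache <- new.env(parent = emptyenv())
  cache$par <- NULL
  fn <- function(p) {
    if (!is.null(cache$par) && identical(p, cache$par)) return(cache$value)
    rs_eval_J(matrix(p, ncol = 1), prob, ctrl$use_cpp)$J[1]
  }
  gr <- function(p) {
    res <- rs_gradient(p, prob, fd_h = ctrl$fd_h, use_cpp = ctrl$use_cpp)
    cache$par <- p
    cache$value <- res$value
    res$grad
  }
  if (!freeze_tuning && isTRUE(ctrl$two_phase)) {
    # phase 1: excitations with the tuning factors pinned at one; the
    # subsequent joint solve then starts inside the feasible valley and
    # only has to trade the tuning factors against it
    lo1 <- prob$lower; hi1 <- prob$upper
    pin <- c(prob$tune_idx$p_ell, prob$tune_idx$p_L)
    lo1[pin] <- 1; hi1[pin] <- 1
    opt1 <- optim(par0, fn = fn, gr = gr, method = "L-BFGS-B",
                  lower = lo1, upper = hi1,
                  control = list(maxit = ctrl$phase1_maxit,
                                 factr = ctrl$factr,
                                 trace = ctrl$trace, lmm = 20))
    par0 <- opt1$par
    cache$par <- NULL
  }
  opt <- optim(par0, fn = fn, gr = gr, method = "L-BFGS-B",
               lower = prob$lower, upper = prob$upper,
               control = list(maxit = ctrl$maxit, factr = ctrl$factr,
                              trace = ctrl$trace, lmm = 20))
  if (!opt$convergence %in% c(0, 1) && !is.finite(fn(opt$par))) {
    stop(sprintf("redundancy NLP failed: %s (code %d)",
                 opt$message, opt$convergence))
  }
  if (!opt$convergence %in% c(0, 1)) {
    # L-BFGS-B line searches can terminate abnormally once the
    # finite-difference gradient noise floor is reached; the incumbent
    # iterate is still the converged solution for practical purposes
    warning(sprintf(
      "redundancy NLP stopped early: %s (code %d); returning incumbent",
      opt$message, opt$convergence))
  }

  fin <- rs_batch_eval(matrix(opt$par, ncol = 1), prob, keep = TRUE)
  mn <- prob$mn; dn <- prob$dn
  per_trial <- vector("list", length(trials))
  for (j in seq_along(trials)) {
    tr <- prob$trials[[j]]
    id <- prob$idx[[j]]
    st <- fin$traj[[j]]
    e_mat <- matrix(opt$par[id$E], prob$m, 2 * tr$n,
                    dimnames = list(mn, NULL))
    per_trial[[j]] <- list(
      label = tr$label, time = tr$ts, duty_factor = tr$duty,
      excitation = e_mat,
      activation = `dimnames<-`(st$a, list(mn, NULL)),
      tendon_force = `dimnames<-`(st$f * prob$Fmax, list(mn, NULL)),
      ftilde = `dimnames<-`(st$f, list(mn, NULL)),
      lstar = `dimnames<-`(st$lstar, list(mn, NULL)),
      vtilde = `dimnames<-`(st$vtilde, list(mn, NULL)),
      passive_force = `dimnames<-`(st$fpass * prob$Fmax, list(mn, NULL)),
      reserve_activation = `dimnames<-`(st$ares, list(dn, NULL)),
      reserve_caps = setNames(tr$caps, dn),
      max_defect = st$defect)
  }
  names(per_trial) <- vapply(per_trial, `[[`, character(1), "label")
  tuning <- if (freeze_tuning) {
    list(p_ell = setNames(rep(1, prob$m), mn),
         p_L = setNames(rep(1, prob$m), mn))
  } else {
    list(p_ell = setNames(opt$par[prob$tune_idx$p_ell], mn),
         p_L = setNames(opt$par[prob$tune_idx$p_L], mn))
  }
  structure(list(
    trials = per_trial, tuning = tuning,
    objective = fin$J[1],
    objective_parts = setNames(fin$parts[, 1], rownames(fin$parts)),
    convergence = opt$convergence, message = opt$message,
    counts = opt$counts, mesh = mesh,
    max_defect = max(vapply(per_trial, `[[`, numeric(1), "max_defect")),
    weights = weights, freeze_tuning = freeze_tuning
  ), class = "redundancy_solution")
}

#' @export
print.redundancy_solution <- function(x, ...) {
  cat(sprintf(
    "Redundancy solution: %d trial(s), mesh %d, objective %.6g\n",
    length(x$trials), x$mesh, x$objective))
  cat("  terms:", paste(sprintf("%s=%.4g", names(x$objective_parts),
                                x$objective_parts), collapse = ", "), "\n")
  if (!x$freeze_tuning) {
    cat(sprintf("  tuning p_ell: %s\n",
                paste(sprintf("%.3f", x$tuning$p_ell), collapse = " ")))
    cat(sprintf("  tuning p_L:   %s\n",
                paste(sprintf("%.3f", x$tuning$p_L), collapse = " ")))
  }
  cat(sprintf("  convergence %d (%s); max collocation defect %.2g\n",
              x$convergence, if (is.null(x$message)) "" else x$message,
              x$max_defect))
  invisible(x)
}

#' Reserve actuator contribution report
#'
#' Expresses each DOF's reserve moment as a fraction of the external
#' joint moment, with a floor on the denominator to avoid blow-up near
#' moment zero-crossings.
#'
#' @param solution A [solve_redundancy()] result.
#' @param trials The trials the solution was computed from.
#' @param floor_frac Denominator floor as a fraction of the trial's peak
#'   absolute external moment per DOF.
#' @return List with `series` (per trial, `n_dof x n_stage` matrix of
#'   fractions) and `summary` (data frame with per-trial, per-DOF maximum
#'   and stance/swing means).
#' @export
reserve_contribution_report <- function(solution, trials,
                                        floor_frac = 0.05) {
  if (inherits(trials, "gait_trial")) trials <- list(trials)
  series <- list(); rows <- list()
  for (j in seq_along(solution$trials)) {
    stj <- solution$trials[[j]]
    tr <- trials[[j]]
    dn <- rownames(stj$reserve_activation)
    frac <- stj$reserve_activation
    for (k in seq_along(dn)) {
      Mk <- splinefun(tr$time, tr$M_ext[, dn[k]],
                      method = "fmm")(stj$time)
      flo <- floor_frac * max(abs(tr$M_ext[, dn[k]]), 1e-12)
      frac[k, ] <- abs(stj$reserve_activation[k, ] * stj$reserve_caps[k]) /
        pmax(abs(Mk), flo)
    }
    series[[stj$label]] <- frac
    phase <- (stj$time - min(tr$time)) / diff(range(tr$time))
    stance <- if (is.na(stj$duty_factor)) rep(TRUE, length(phase)) else
      phase <= stj$duty_factor
    for (k in seq_along(dn)) {
      rows[[length(rows) + 1]] <- data.frame(
        trial = stj$label, dof = dn[k],
        max_fraction = max(frac[k, ]),
        mean_stance = mean(frac[k, stance]),
        mean_swing = if (all(stance)) NA_real_ else mean(frac[k, !stance]))
    }
  }
  list(series = series, summary = do.call(rbind, rows))
}

#' Zero-phase low-pass filtering of a trial
#'
#' Optional input conditioning: a fourth-order zero-phase (forward-
#' backward) Butterworth low-pass applied to the external moments, MTU
#' lengths and moment arms, as a second filtering pass for experimental
#' inputs. Off by default in all pipelines; synthetic data does not need
#' it.
#'
#' @param trial A [gait_trial()].
#' @param cutoff_hz Cutoff frequency (Hz).
#' @param order Filter order.
#' @return The filtered [gait_trial()].
#' @export
smooth_trial <- function(trial, cutoff_hz = 20, order = 4) {
  fs <- 1 / mean(diff(trial$time))
  if (cutoff_hz >= fs / 2) return(trial)
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  npad <- min(length(trial$time) - 1, 30)
  filt <- function(x) {
    # mirror padding suppresses the forward-backward edge transients
    n <- length(x)
    xp <- c(2 * x[1] - rev(x[2:(npad + 1)]), x,
            2 * x[n] - rev(x[(n - npad):(n - 1)]))
    as.numeric(signal::filtfilt(bf, xp))[(npad + 1):(npad + n)]
  }
  trial$M_ext <- apply(trial$M_ext, 2, filt)
  trial$lmt <- apply(trial$lmt, 2, filt)
  for (k in seq_len(dim(trial$arms)[3])) {
    trial$arms[, , k] <- apply(trial$arms[, , k, drop = FALSE][, , 1],
                               2, filt)
  }
  trial
}
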