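# Synthetic-data generator: toy limb models and gait trials with known
# ground truth. The generator manufactures dynamically consistent external
# joint moments by integrating each MTU's contraction dynamics forward
# under prescribed activations, so that the inverse (redundancy) solver's
# ability to recover activations and tuning factors can be tested exactly.

#' Gait trial specification
#'
#' @param speed Forward speed (m/s).
#' @param duty_factor Stance fraction of the stride, in (0, 1).
#' @param stride_time Stride duration (s).
#' @param n_samples Number of time samples over one stride (>= 20).
#' @param label `"walk"` or `"run"`.
#' @return A `gait_spec` object.
#' @export
gait_spec <- function(speed, duty_factor, stride_time, n_samples = 101,
                      label = c("walk", "run")) {
  label <- match.arg(label)
  if (duty_factor <= 0 || duty_factor >= 1) {
    stop("duty factor must lie strictly between 0 and 1")
  }
  if (n_samples < 20) stop("n_samples must be at least 20")
  if (stride_time <= 0 || speed < 0) stop("invalid gait parameters")
  structure(list(speed = speed, duty_factor = duty_factor,
                 stride_time = stride_time, n_samples = n_samples,
                 label = label), class = "gait_spec")
}

#' Default two-trial gait specifications
#'
#' A slow walk (0.39 m/s, duty factor 0.71) and a grounded run
#' (1.39 m/s, duty factor 0.57), the two locomotor conditions the
#' analyses are designed around.
#'
#' @param n_samples Samples per stride.
#' @return Named list of two [gait_spec()] objects.
#' @export
default_gait_specs <- function(n_samples = 101) {
  list(walk = gait_spec(0.39, 0.71, 0.55, n_samples, "walk"),
       run = gait_spec(1.39, 0.57, 0.33, n_samples, "run"))
}

#' Generate a toy limb model
#'
#' Samples a limb with `n_dof` actuated rotational DOFs and `n_mtu` MTUs
#' whose architecture spreads emulate a small ground bird's hindlimb:
#' pennation 0-35 degrees, tendon slack to fibre length ratios 0.05-8,
#' maximal isometric forces ~0.6-30 N. The first `2 * n_dof` MTUs form a
#' monoarticular antagonist pair about each DOF (guaranteeing both moment
#' senses everywhere); any further MTUs are biarticular. Neutral MTU
#' lengths are chosen so fibres sit slightly below optimal length at a
#' moderate tendon load in the mid-range pose, and moment arms are sized
#' so fibre excursions over the joint ranges span roughly the ascending
#' limb and plateau of the force-length curve.
#'
#' @param n_dof Number of actuated DOFs (>= 1).
#' @param n_mtu Number of MTUs (>= 2, and >= `2 * n_dof` so every DOF has
#'   an antagonist pair).
#' @param seed RNG seed (the function sets the seed; identical seeds give
#'   bit-identical models).
#' @param k_T Dimensionless tendon stiffness assigned to every MTU.
#' @param tuning_truth Optional list with `p_ell`, `p_L` giving the true
#'   per-MTU architecture multipliers. The limb's *geometry* (neutral MTU
#'   lengths, moment-arm sizes) is laid out around the true,
#'   tuning-applied architecture -- a simulated animal whose anatomy is
#'   adapted to its behaviour -- while the stored muscle parameters keep
#'   the untuned values, which play the role of mismeasured dissection
#'   estimates that downstream tuning should correct.
#' @param constants [tissue_constants()] for mass/force conversions.
#' @return A [limb_model()].
#' @export
make_toy_limb <- function(n_dof = 2, n_mtu = 2 * n_dof, seed = 1,
                          k_T = 100, tuning_truth = NULL,
                          constants = tissue_constants()) {
  if (n_dof < 1) stop("n_dof must be >= 1")
  if (n_mtu < 2 * n_dof) {
    stop("n_mtu must be at least 2 * n_dof (one antagonist pair per DOF)")
  }
  set.seed(seed)
  dofs <- lapply(seq_len(n_dof), function(d) {
    dof_spec(sprintf("dof%d", d),
             range_min = runif(1, -1.9, -1.0),
             range_max = runif(1, 0.3, 0.7))
  })
  dof_names <- vapply(dofs, `[[`, character(1), "name")
  tc <- tendon_curve(k_T)

  p_ell <- rep_len(if (is.null(tuning_truth)) 1 else tuning_truth$p_ell,
                   n_mtu)
  p_L <- rep_len(if (is.null(tuning_truth)) 1 else tuning_truth$p_L,
                 n_mtu)

  mtus <- vector("list", n_mtu)
  for (i in seq_len(n_mtu)) {
    ell_o <- exp(runif(1, log(0.010), log(0.065)))
    alpha_o <- runif(1, 0, 35) * pi / 180
    ls_ratio <- exp(runif(1, log(0.05), log(8)))
    L_S <- ls_ratio * ell_o
    F_max <- exp(runif(1, log(0.6), log(30)))
    m <- F_max * constants$rho_muscle * ell_o / constants$sigma
    params <- muscle_params(sprintf("mtu%02d", i), m, ell_o, L_S, alpha_o,
                            F_max = F_max, k_T = k_T)
    # the geometry is sized around the true (tuning-applied) architecture
    ell_true <- ell_o * p_ell[i]
    LS_true <- L_S * p_L[i]
    h_true <- ell_true * sin(alpha_o)

    if (i <= 2 * n_dof) {
      d <- (i + 1) %/% 2
      sense <- if (i %% 2 == 1) 1 else -1
      cross <- d
    } else {
      d <- ((i - 1) %% n_dof) + 1
      sense <- sample(c(-1, 1), 1)
      cross <- c(d, (d %% n_dof) + 1)
    }
    r0 <- 0.16 * ell_true * runif(1, 0.8, 1.25) / sqrt(length(cross))
    # reference fibre length just below optimal at a moderate tendon load
    proj_ref <- sqrt((0.95 * ell_true)^2 - h_true^2)
    c0 <- LS_true * tc$finv(0.25) + proj_ref

    qm <- vapply(cross, function(k) {
      0.5 * (dofs[[k]]$range_min + dofs[[k]]$range_max)
    }, numeric(1))
    half <- vapply(cross, function(k) {
      0.5 * (dofs[[k]]$range_max - dofs[[k]]$range_min)
    }, numeric(1))
    # l = c0 - sum_k s_k [ r0 (q_k - qm_k) + 0.5 kappa_k (q_k - qm_k)^2 ]
    senses <- sense * c(1, rep(-1, length(cross) - 1))
    kappa <- 0.2 * r0 / half
    nd <- length(cross)
    coeffs <- c0
    powers <- matrix(0, 1, nd)
    for (k in seq_len(nd)) {
      # expand in raw powers of q_k
      ck <- senses[k]
      coeffs <- c(coeffs,
                  ck * (-r0 + kappa[k] * qm[k]) + ck * (-0.5 * kappa[k]) * 0,
                  -ck * 0.5 * kappa[k])
      coeffs[1] <- coeffs[1] + ck * (r0 * qm[k] - 0.5 * kappa[k] * qm[k]^2)
      p1 <- rep(0, nd); p1[k] <- 1
      p2 <- rep(0, nd); p2[k] <- 2
      powers <- rbind(powers, p1, p2)
    }
    geom <- mtu_geometry(params$name, dof_names[cross], coeffs, powers)
    mtus[[i]] <- list(params = params, geometry = geom)
  }

  model <- limb_model(dofs, mtus)
  # guard: every actuated DOF must have arms of both senses somewhere
  probe <- pose_grid_probe(model)
  arms <- moment_arms(model, probe)
  for (k in seq_len(n_dof)) {
    ak <- arms[, , k]
    if (max(ak) <= 0 || min(ak) >= 0) {
      stop(sprintf("generated limb leaves DOF '%s' unactuatable",
                   dof_names[k]))
    }
  }
  model
}

#' Generate smooth periodic gait kinematics
#'
#' Produces smooth periodic joint-angle trajectories (a two-harmonic
#' sinusoid mix per DOF) confined to each DOF's range, with the
#' stance/swing boundary placed at the gait specification's duty factor.
#' Amplitudes scale mildly with speed so the faster trial uses larger
#' joint excursions.
#'
#' @param spec A [gait_spec()].
#' @param limb A [limb_model()].
#' @param seed RNG seed.
#' @return A `gait_kinematics` object: list with `time` (s), `q` (rad,
#'   matrix), `qdot` (rad/s), `phase` (stride fraction) and `spec`.
#' @export
make_gait_kinematics <- function(spec, limb, seed = 1) {
  set.seed(seed + 1000L)
  tt <- seq(0, spec$stride_time, length.out = spec$n_samples)
  phase <- tt / spec$stride_time
  omega <- 2 * pi / spec$stride_time
  rng <- dof_ranges(limb)
  n_dof <- nrow(rng)
  amp_frac <- min(0.25 + 0.15 * spec$speed, 0.5)
  q <- matrix(NA_real_, length(tt), n_dof,
              dimnames = list(NULL, rownames(rng)))
  qdot <- q
  for (k in seq_len(n_dof)) {
    qm <- 0.5 * (rng[k, 1] + rng[k, 2])
    half <- 0.5 * (rng[k, 2] - rng[k, 1])
    A1 <- amp_frac * half * runif(1, 0.8, 1.0)
    A2 <- 0.25 * A1
    ph1 <- runif(1, 0, 2 * pi)
    ph2 <- runif(1, 0, 2 * pi)
    q[, k] <- qm + A1 * sin(omega * tt + ph1) + A2 * sin(2 * omega * tt + ph2)
    qdot[, k] <- A1 * omega * cos(omega * tt + ph1) +
      2 * A2 * omega * cos(2 * omega * tt + ph2)
  }
  structure(list(time = tt, q = q, qdot = qdot, phase = phase, spec = spec),
            class = "gait_kinematics")
}

#' Ground-truth activation profiles
#'
#' Smoothed boxcar activation bursts aligned to stance or swing: the
#' agonist of each DOF (positive moment arm) is assigned a stance burst
#' and its antagonist a swing burst, so bursts of an antagonist pair never
#' overlap and the minimum-activation inverse solution coincides with the
#' ground truth. Amplitudes stay at or below 0.8 to keep recovery away
#' from bound saturation; the walk trial uses lower amplitudes than the
#' run.
#'
#' @param limb A [limb_model()].
#' @param kin A `gait_kinematics` object (supplies phase and duty factor).
#' @param seed RNG seed.
#' @param amp_range Amplitude range to sample per muscle.
#' @return Matrix `n_samples x n_mtu` of activations in `[0, 1]`.
#' @export
make_activation_profiles <- function(limb, kin, seed = 1,
                                     amp_range = NULL) {
  set.seed(seed + 2000L)
  spec <- kin$spec
  if (is.null(amp_range)) {
    amp_range <- if (spec$label == "walk") c(0.25, 0.45) else c(0.5, 0.75)
  }
  duty <- spec$duty_factor
  phase <- kin$phase
  mn <- limb_mtu_names(limb)
  n_dof <- length(limb$dofs)
  a <- matrix(0, length(phase), length(mn), dimnames = list(NULL, mn))
  # classify by the sign of the mean arm about the first crossed DOF
  mid <- matrix(colMeans(dof_ranges(limb)), 1)[rep(1, 1), , drop = FALSE]
  mid <- matrix(0.5 * (dof_ranges(limb)[, 1] + dof_ranges(limb)[, 2]),
                nrow = 1, dimnames = list(NULL, limb_dof_names(limb)))
  arms_mid <- moment_arms(limb, mid)
  for (i in seq_along(mn)) {
    g <- limb$mtus[[i]]$geometry
    k1 <- match(g$dofs[1], limb_dof_names(limb))
    stance_muscle <- arms_mid[1, i, k1] > 0
    amp <- runif(1, amp_range[1], amp_range[2])
    if (stance_muscle) {
      on <- runif(1, 0.05, 0.12) * duty
      off <- runif(1, 0.78, 0.92) * duty
    } else {
      on <- duty + runif(1, 0.08, 0.15) * (1 - duty)
      off <- duty + runif(1, 0.75, 0.88) * (1 - duty)
    }
    w <- 0.035
    a[, i] <- amp * 0.5 * (tanh((phase - on) / w) - tanh((phase - off) / w))
  }
  pmin(pmax(a, 0), 0.8)
}

#' Forward-generate a dynamically consistent gait trial
#'
#' Projects the requested activation profiles onto the dynamically
#' feasible set (by inverting the excitation-activation dynamics, clamping
#' excitations to `[0, 1]`, and re-integrating -- activation cannot decay
#' faster than the deactivation time constant permits), then integrates
#' each MTU's contraction dynamics (tendon force as the state) forward
#' along the prescribed kinematics, and defines the external joint moments
#' as the exact muscular moments plus optional Gaussian noise. With zero
#' noise the returned (trial, ground truth) pair is an exact feasible
#' point of the muscle-redundancy problem -- excitation-activation
#' dynamics, contraction dynamics, equilibrium and moment balance all hold
#' with zero reserve usage -- which is what makes solver recovery testable.
#'
#' @param limb A [limb_model()].
#' @param kin A `gait_kinematics` object.
#' @param activations Matrix `n_samples x n_mtu` of requested activations
#'   in `[0, 1]` (e.g. from [make_activation_profiles()]). The realized
#'   ground-truth activations equal the request wherever it respects the
#'   activation dynamics.
#' @param tuning_truth Optional list with numeric vectors `p_ell` and
#'   `p_L` (per-MTU multipliers applied to optimal fibre length and tendon
#'   slack length before integrating); defaults to all ones.
#' @param noise_sd Standard deviation of Gaussian noise added to the
#'   external moments (N m).
#' @param seed RNG seed for the noise.
#' @param beta Numerical damping passed to the contraction dynamics.
#' @return A list with `trial` (a [gait_trial()]) and `truth` (list with
#'   `activations` (realized), `excitations`, `tendon_forces` (N),
#'   `lstar`, `tuning_truth`).
#' @export
forward_generate_trial <- function(limb, kin, activations,
                                   tuning_truth = NULL, noise_sd = 0,
                                   seed = 1, beta = .default_beta) {
  mn <- limb_mtu_names(limb)
  n_mtu <- length(mn)
  if (is.null(tuning_truth)) {
    tuning_truth <- list(p_ell = rep(1, n_mtu), p_L = rep(1, n_mtu))
  }
  if (any(activations < 0 | activations > 1)) {
    stop("activation profiles must lie in [0, 1]")
  }
  tt <- kin$time
  lmt <- mtu_length(limb, kin$q)
  arms <- moment_arms(limb, kin$q)
  # analytic MTU velocity from tendon excursion: dl/dt = -sum_k r_k qdot_k
  lmtdot <- matrix(0, length(tt), n_mtu)
  for (k in seq_len(dim(arms)[3])) {
    lmtdot <- lmtdot - arms[, , k, drop = FALSE][, , 1] * kin$qdot[, k]
  }

  ell_o <- mp_field(lapply(limb$mtus, `[[`, "params"), "ell_o") *
    tuning_truth$p_ell
  L_S <- mp_field(lapply(limb$mtus, `[[`, "params"), "L_S") *
    tuning_truth$p_L
  alpha_o0 <- mp_field(lapply(limb$mtus, `[[`, "params"), "alpha_o")
  h <- mp_field(lapply(limb$mtus, `[[`, "params"), "ell_o") * sin(alpha_o0)
  F_max <- mp_field(lapply(limb$mtus, `[[`, "params"), "F_max")
  v_max <- mp_field(lapply(limb$mtus, `[[`, "params"), "v_max")
  k_T <- limb$mtus[[1]]$params$k_T
  tc <- tendon_curve(k_T)

  tau_a <- mp_field(lapply(limb$mtus, `[[`, "params"), "tau_act")
  tau_d <- mp_field(lapply(limb$mtus, `[[`, "params"), "tau_deact")

  # project the requested activations onto the dynamically feasible set:
  # excitation from inverting the activation dynamics, clamped to [0, 1]
  excitations <- sapply(seq_len(n_mtu), function(i) {
    asp <- splinefun(tt, activations[, i], method = "natural")
    invert_activation_rate(pmin(pmax(activations[, i], 0), 1),
                           asp(tt, deriv = 1), tau_a[i], tau_d[i])
  })

  e_fun <- lapply(seq_len(n_mtu), function(i) {
    splinefun(tt, excitations[, i], method = "natural")
  })
  lmt_fun <- lapply(seq_len(n_mtu), function(i) {
    splinefun(tt, lmt[, i], method = "natural")
  })
  lmtdot_fun <- lapply(seq_len(n_mtu), function(i) {
    splinefun(tt, lmtdot[, i], method = "natural")
  })

  deriv <- function(t, y, parms) {
    a_t <- pmin(pmax(y[seq_len(n_mtu)], 0), 1)
    f_t <- y[n_mtu + seq_len(n_mtu)]
    e_t <- pmin(pmax(vapply(e_fun, function(f) f(t), numeric(1)), 0), 1)
    lmt_t <- vapply(lmt_fun, function(f) f(t), numeric(1))
    lmtdot_t <- vapply(lmtdot_fun, function(f) f(t), numeric(1))
    da <- activation_rate(e_t, a_t, tau_a, tau_d)
    r <- contraction_rate(f_t, a_t, lmt_t, lmtdot_t, ell_o, L_S, h,
                          v_max, tc, beta)
    list(c(da, r$dftilde))
  }

  a0 <- pmin(pmax(activations[1, ], 0), 1)
  f0 <- static_eq_ftilde(a0, lmt[1, ], ell_o, L_S, h, tc)
  if (any(!f0$feasible)) {
    stop(sprintf("infeasible geometry at t = 0 for MTU '%s'",
                 mn[which(!f0$feasible)[1]]))
  }
  sol <- deSolve::ode(y = c(a0, f0$ftilde), times = tt, func = deriv,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-8, atol = 1e-10)
  if (attr(sol, "istate")[1] < 0 || any(!is.finite(sol[, -1]))) {
    bad <- which(!is.finite(sol[, -1]), arr.ind = TRUE)
    stop(sprintf(
      "contraction integration failed for MTU '%s' near t = %.4g s",
      mn[if (nrow(bad)) (bad[1, 2] - 1) %% n_mtu + 1 else 1],
      tt[if (nrow(bad)) bad[1, 1] else length(tt)]))
  }
  a_real <- pmin(pmax(unname(sol[, 1 + seq_len(n_mtu), drop = FALSE]),
                      0), 1)
  ftilde <- unname(sol[, 1 + n_mtu + seq_len(n_mtu), drop = FALSE])
  forces <- sweep(ftilde, 2, F_max, "*")
  lstar <- sapply(seq_len(n_mtu), function(i) {
    fibre_geom(ftilde[, i], lmt[, i], ell_o[i], L_S[i], h[i], tc)$lstar
  })
  colnames(a_real) <- mn
  colnames(excitations) <- mn
  colnames(forces) <- mn
  colnames(lstar) <- mn

  n_dof <- dim(arms)[3]
  M <- matrix(0, length(tt), n_dof,
              dimnames = list(NULL, dimnames(arms)[[3]]))
  for (k in seq_len(n_dof)) {
    M[, k] <- rowSums(forces * arms[, , k])
  }
  if (noise_sd > 0) {
    set.seed(seed + 3000L)
    M <- M + matrix(rnorm(length(M), sd = noise_sd), nrow(M), ncol(M))
  }
  trial <- gait_trial(tt, kin$q, M, lmt = lmt, arms = arms,
                      label = kin$spec$label,
                      duty_factor = kin$spec$duty_factor)
  list(trial = trial,
       truth = list(activations = a_real, excitations = excitations,
                    tendon_forces = forces, lstar = lstar,
                    tuning_truth = tuning_truth))
}

#' Generate a complete two-trial synthetic bundle
#'
#' Convenience wrapper: builds a toy limb, walk and run kinematics,
#' stance/swing-aligned activation profiles, and forward-generates both
#' trials with the same tuning truth.
#'
#' @param n_dof,n_mtu Limb dimensions (see [make_toy_limb()]).
#' @param seed Master seed; all stage seeds derive from it.
#' @param tuning_truth As in [forward_generate_trial()].
#' @param noise_sd Moment noise (N m).
#' @param n_samples Samples per stride.
#' @return List with `limb`, `trials` (list of two [gait_trial()]s),
#'   `truth` (per-trial ground truth) and `kinematics`.
#' @export
make_synthetic_bundle <- function(n_dof = 2, n_mtu = 2 * n_dof, seed = 1,
                                  tuning_truth = NULL, noise_sd = 0,
                                  n_samples = 101) {
  limb <- make_toy_limb(n_dof, n_mtu, seed = seed,
                        tuning_truth = tuning_truth)
  specs <- default_gait_specs(n_samples)
  kins <- lapply(specs, make_gait_kinematics, limb = limb, seed = seed)
  acts <- lapply(kins, function(k) {
    make_activation_profiles(limb, k, seed = seed)
  })
  gen <- lapply(names(specs), function(nm) {
    forward_generate_trial(limb, kins[[nm]], acts[[nm]],
                           tuning_truth = tuning_truth,
                           noise_sd = noise_sd, seed = seed)
  })
  names(gen) <- names(specs)
  list(limb = limb,
       trials = lapply(gen, `[[`, "trial"),
       truth = lapply(gen, `[[`, "truth"),
       kinematics = kins)
}

#' Packaged tinamou MTU architecture table
#'
#' The 36-MTU hindlimb architecture table of a ~545 g elegant-crested
#' tinamou: belly mass, optimal fibre length (original and tuned), tendon
#' slack length (original and tuned), pennation angle and maximal
#' isometric force, in the printed units (g, mm, deg, N). One tuned fibre
#' length (ILPOp) is printed with an obvious misplaced decimal in the
#' source table; the fixture stores the corrected value (74.9 mm).
#'
#' @return Data frame with 36 rows.
#' @export
tinamou_fixture <- function() {
  path <- system.file("extdata", "tinamou_mtu_table.csv",
                      package = "fibreops", mustWork = TRUE)
  read.csv(path, check.names = TRUE)
}

#' Tinamou MTUs as muscle parameter objects
#'
#' Converts [tinamou_fixture()] rows (printed units) to SI
#' [muscle_params()] objects, optionally using the tuned fibre and slack
#' lengths.
#'
#' @param tuned Use tuned fibre/slack lengths instead of the originals.
#' @param k_T,v_max,tau_act,tau_deact Physiology applied to every MTU.
#' @return Named list of [muscle_params()].
#' @export
tinamou_muscle_params <- function(tuned = FALSE, k_T = 100, v_max = 10,
                                  tau_act = 0.007, tau_deact = 0.027) {
  tab <- tinamou_fixture()
  out <- lapply(seq_len(nrow(tab)), function(i) {
    muscle_params(
      name = tab$abbreviation[i],
      m = tab$mass_g[i] * 1e-3,
      ell_o = (if (tuned) tab$tuned_fibre_length_mm[i]
               else tab$fibre_length_mm[i]) * 1e-3,
      L_S = (if (tuned) tab$tuned_slack_length_mm[i]
             else tab$slack_length_mm[i]) * 1e-3,
      alpha_o = tab$pennation_deg[i] * pi / 180,
      F_max = tab$fmax_N[i],
      k_T = k_T, v_max = v_max, tau_act = tau_act, tau_deact = tau_deact)
  })
  names(out) <- tab$abbreviation
  out
}
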