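# Static posture battery: four static simulations over randomly sampled
# limb postures, delimiting each muscle's viable fibre operating range.
#
# Simulations 1 and 2 minimize / maximize the summed squared muscle
# activations subject to whole-limb static moment balance
# (sum_m F_m r_mk = 0 for every DOF; gravity and inertia ignored) and
# per-MTU muscle-tendon equilibrium. Simulations 3 and 4 treat each MTU
# in isolation at fixed activation 0 or 1 and solve its static
# equilibrium alone.
#
# Viability filter rules, applied in order with the first failure recorded:
#   i   equilibrium-infeasible: no activation pattern achieves equilibrium
#       in all MTUs and moment balance (sims 1-2);
#   ii  lmt-below-slack: l_MT < L_S for an MTU (sims 3-4);
#   iii lmt-cap-exceeded: a configured per-MTU cap on l_MT (all sims).

#' Sample random limb postures
#'
#' Uniform independent sampling per actuated DOF over its range;
#' DOFs listed in `overrides` (or declared `"fixed"` in the model) are
#' held at fixed angles.
#'
#' @param limb A [limb_model()].
#' @param n Number of poses.
#' @param seed RNG seed (recorded in the result).
#' @param overrides Named numeric vector of fixed DOF angles (rad).
#' @return A `pose_set`: list with `q` (n x n_dof matrix, rad), `seed`,
#'   `ranges` and `overrides`.
#' @export
sample_poses <- function(limb, n = 5000, seed = 1, overrides = NULL) {
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  rng <- dof_ranges(limb)
  dn <- rownames(rng)
  q <- matrix(NA_real_, n, length(dn), dimnames = list(NULL, dn))
  kinds <- vapply(limb$dofs, `[[`, character(1), "kind")
  for (k in seq_along(dn)) {
    if (!is.null(overrides) && dn[k] %in% names(overrides)) {
      q[, k] <- overrides[[dn[k]]]
    } else if (kinds[k] == "fixed") {
      q[, k] <- 0.5 * (rng[k, 1] + rng[k, 2])
    } else {
      q[, k] <- runif(n, rng[k, 1], rng[k, 2])
    }
  }
  structure(list(q = q, seed = seed, ranges = rng,
                 overrides = overrides), class = "pose_set")
}

# shared per-pose muscle tables used by all simulations
battery_tables <- function(poses, limb) {
  params <- lapply(limb$mtus, `[[`, "params")
  list(mn = limb_mtu_names(limb), dn = limb_dof_names(limb),
       lo = mp_field(params, "ell_o"),
       LS = mp_field(params, "L_S"),
       h = mp_field(params, "ell_o") * sin(mp_field(params, "alpha_o")),
       Fmax = mp_field(params, "F_max"),
       tc = tendon_curve(mp_field(params, "k_T")[1]),
       lmt = mtu_length(limb, poses$q),
       arms = moment_arms(limb, poses$q))
}

#' Isolated-muscle static simulations (simulations 3 and 4)
#'
#' Solves each MTU's static muscle-tendon equilibrium independently at
#' every pose, with activation fixed at 0 (simulation 3) or 1
#' (simulation 4). Poses where an MTU's length falls below its tendon
#' slack length admit no equilibrium and are flagged (filter rule ii).
#'
#' @param poses A [sample_poses()] result.
#' @param limb A [limb_model()].
#' @param activation_level 0 or 1.
#' @return A `pose_battery` object (see [filter_viable()]).
#' @export
run_isolated_muscle <- function(poses, limb, activation_level) {
  if (!activation_level %in% c(0, 1)) {
    stop("activation_level must be 0 or 1")
  }
  tb <- battery_tables(poses, limb)
  n <- nrow(poses$q); m <- length(tb$mn)
  sim <- if (activation_level == 0) 3L else 4L
  lmt_flat <- as.vector(tb$lmt[, tb$mn])
  sol <- static_eq_ftilde(activation_level, lmt_flat,
                          rep(tb$lo, each = n), rep(tb$LS, each = n),
                          rep(tb$h, each = n), tb$tc)
  rec <- data.frame(
    pose = rep(seq_len(n), times = m),
    sim = sim,
    mtu = rep(tb$mn, each = n),
    lmt = lmt_flat,
    lstar = ifelse(sol$feasible, sol$lstar, NA_real_),
    F_T = ifelse(sol$feasible, sol$ftilde, NA_real_) * rep(tb$Fmax, each = n),
    activation = activation_level,
    viable = sol$feasible & sol$converged,
    reason = ifelse(sol$feasible,
                    ifelse(sol$converged, "", "solver-failure"),
                    "lmt-below-slack"),
    stringsAsFactors = FALSE)
  new_pose_battery(rec, poses, limb, sims = sim)
}

# closed-form activation required for equilibrium at a given normalized
# tendon force (static, v = 0); vectorized
activation_from_ftilde <- function(ftilde, lmt, lo, LS, h, tc) {
  g <- fibre_geom(ftilde, lmt, lo, LS, h, tc)
  (ftilde / g$cosa - f_passive(g$lstar)) / f_active(g$lstar)
}

# activation and its analytic derivative with respect to normalized
# tendon force (chain rule through the tendon inverse and the
# constant-thickness geometry); vectorized
activation_grad_ftilde <- function(ftilde, lmt, lo, LS, h, tc) {
  g <- fibre_geom(ftilde, lmt, lo, LS, h, tc)
  fa <- f_active(g$lstar)
  fp <- f_passive(g$lstar)
  a <- (ftilde / g$cosa - fp) / fa
  dproj <- -LS / (tc$kp * (pmax(ftilde, -tc$c3 + 1e-9) + tc$c3))
  dell <- g$cosa * dproj
  dcosa <- dproj * (1 - g$cosa^2) / g$ell
  dlstar <- dell / lo
  dnum <- 1 / g$cosa - ftilde * dcosa / g$cosa^2 - fp_slope(g$lstar) * dlstar
  da <- (dnum * fa - (ftilde / g$cosa - fp) * fl_slope(g$lstar) * dlstar) /
    fa^2
  list(a = a, da = da)
}

#' Whole-limb min/max activation simulations (simulations 1 and 2)
#'
#' At every pose, finds activations minimizing (simulation 1) or
#' maximizing (simulation 2) the summed squared activation subject to
#' static moment balance about every DOF and muscle-tendon equilibrium in
#' every MTU. Gravity is ignored. The problem is solved in tendon-force
#' space (where the moment balance is linear and activation follows in
#' closed form) with an augmented-Lagrangian method; maximization uses
#' three seeded multistarts. Proven infeasibility -- the convex
#' feasibility problem has positive minimum residual -- is recorded as
#' filter rule i, distinctly from solver failure.
#'
#' @param poses A [sample_poses()] result.
#' @param limb A [limb_model()].
#' @param mode `"min"` or `"max"`.
#' @param feas_tol Normalized moment-residual tolerance for viability.
#' @param seed Seed for the maximization multistarts.
#' @return A `pose_battery` object with one record per (pose, MTU) plus a
#'   per-pose objective table in `$pose_info`.
#' @export
run_min_max_activation <- function(poses, limb, mode = c("min", "max"),
                                   feas_tol = 1e-6, seed = 1) {
  mode <- match.arg(mode)
  tb <- battery_tables(poses, limb)
  n <- nrow(poses$q); m <- length(tb$mn); K <- length(tb$dn)
  sim <- if (mode == "min") 1L else 2L

  # bounds of the feasible tendon-force interval per (pose, muscle)
  lmt_flat <- as.vector(tb$lmt[, tb$mn])
  lo_r <- rep(tb$lo, each = n); LS_r <- rep(tb$LS, each = n)
  h_r <- rep(tb$h, each = n)
  s0 <- static_eq_ftilde(0, lmt_flat, lo_r, LS_r, h_r, tb$tc)
  s1 <- static_eq_ftilde(1, lmt_flat, lo_r, LS_r, h_r, tb$tc)
  Flo <- matrix(s0$ftilde, n, m)
  Fhi <- matrix(s1$ftilde, n, m)
  feas_mtu <- matrix(s0$feasible, n, m)

  rec_rows <- vector("list", n)
  pose_obj <- rep(NA_real_, n)
  pose_viable <- logical(n)
  pose_reason <- character(n)
  set.seed(seed + 7000L)
  start_seeds <- matrix(runif(2 * m * n), ncol = 2 * m)

  for (p in seq_len(n)) {
    if (!all(feas_mtu[p, ])) {
      pose_viable[p] <- FALSE
      pose_reason[p] <- "equilibrium-infeasible"
      rec_rows[[p]] <- battery_row(p, sim, tb, rep(NA_real_, m), FALSE,
                                   "equilibrium-infeasible")
      next
    }
    lmt_p <- tb$lmt[p, ]
    flo <- Flo[p, ]; fhi <- Fhi[p, ]
    R <- t(matrix(tb$arms[p, tb$mn, tb$dn], nrow = m))    # K x m
    Rw <- R * rep(tb$Fmax, each = K)
    scal <- pmax(rowSums(abs(Rw) * rep(0.5 * (fhi - flo) + 1e-9,
                                       each = K)), 1e-12)
    Rs <- Rw / scal                                        # normalized
    cfun <- function(f) as.numeric(Rs %*% f)

    afun <- function(f) {
      activation_from_ftilde(f, lmt_p, tb$lo, tb$LS, tb$h, tb$tc)
    }
    agfun <- function(f) {
      activation_grad_ftilde(f, lmt_p, tb$lo, tb$LS, tb$h, tb$tc)
    }

    # quick exits: zero-passive trivial equilibrium
    if (mode == "min" && max(abs(cfun(flo))) < feas_tol) {
      pose_obj[p] <- sum(afun(flo)^2)
      pose_viable[p] <- TRUE
      pose_reason[p] <- ""
      rec_rows[[p]] <- battery_row(p, sim, tb, flo, TRUE, "")
      next
    }

    res <- battery_al_solve(flo, fhi, cfun, afun, mode,
                            starts = if (mode == "max") 3 else 1,
                            start_unif = start_seeds[p, ],
                            feas_tol = feas_tol,
                            Rs = Rs, agfun = agfun)
    if (!res$feasible) {
      # restoration failed; prove or refute feasibility
      fs <- battery_feasibility(flo, fhi, Rs)
      if (fs > feas_tol) {
        pose_viable[p] <- FALSE
        pose_reason[p] <- "equilibrium-infeasible"
        rec_rows[[p]] <- battery_row(p, sim, tb, rep(NA_real_, m), FALSE,
                                     "equilibrium-infeasible")
      } else {
        pose_viable[p] <- FALSE
        pose_reason[p] <- "solver-failure"
        rec_rows[[p]] <- battery_row(p, sim, tb, rep(NA_real_, m), FALSE,
                                     "solver-failure")
      }
      next
    }
    pose_obj[p] <- sum(afun(res$f)^2)
    pose_viable[p] <- TRUE
    pose_reason[p] <- ""
    rec_rows[[p]] <- battery_row(p, sim, tb, res$f, TRUE, "")
  }

  rec <- do.call(rbind, rec_rows)
  out <- new_pose_battery(rec, poses, limb, sims = sim)
  out$pose_info <- data.frame(pose = seq_len(n), sim = sim,
                              objective = pose_obj, viable = pose_viable,
                              reason = pose_reason)
  out
}

battery_row <- function(p, sim, tb, f, viable, reason) {
  m <- length(tb$mn)
  if (viable) {
    g <- fibre_geom(f, tb$lmt[p, ], tb$lo, tb$LS, tb$h, tb$tc)
    a <- activation_from_ftilde(f, tb$lmt[p, ], tb$lo, tb$LS, tb$h, tb$tc)
    data.frame(pose = p, sim = sim, mtu = tb$mn, lmt = tb$lmt[p, ],
               lstar = g$lstar, F_T = f * tb$Fmax,
               activation = pmin(pmax(a, 0), 1), viable = TRUE,
               reason = "", stringsAsFactors = FALSE)
  } else {
    data.frame(pose = p, sim = sim, mtu = tb$mn, lmt = tb$lmt[p, ],
               lstar = NA_real_, F_T = NA_real_, activation = NA_real_,
               viable = FALSE, reason = reason, stringsAsFactors = FALSE)
  }
}

# convex feasibility: minimum normalized moment residual over the box
battery_feasibility <- function(flo, fhi, Rs) {
  obj <- function(f) sum((Rs %*% f)^2)
  grd <- function(f) as.numeric(2 * t(Rs) %*% (Rs %*% f))
  o <- optim(0.5 * (flo + fhi), obj, grd, method = "L-BFGS-B",
             lower = flo, upper = fhi,
             control = list(maxit = 200, factr = 1e4))
  sqrt(o$value)
}

# augmented-Lagrangian solve of min/max sum a(f)^2 s.t. c(f) = 0, box f,
# with analytic objective and constraint gradients
battery_al_solve <- function(flo, fhi, cfun, afun, mode, starts = 1,
                             start_unif = NULL, feas_tol = 1e-6,
                             Rs = NULL, agfun = NULL) {
  sgn <- if (mode == "min") 1 else -1
  m <- length(flo)
  best <- NULL
  for (s in seq_len(starts)) {
    f0 <- if (s == 1 && mode == "min") flo
    else if (s == 1) fhi
    else flo + (fhi - flo) * start_unif[((s - 2) * m + 1):((s - 1) * m)]
    lam <- rep(0, length(cfun(f0)))
    mu <- 100
    f <- f0
    ok <- FALSE
    for (outer in 1:6) {
      phi <- function(x) {
        cc <- cfun(x)
        sgn * sum(afun(x)^2) + sum(lam * cc) + 0.5 * mu * sum(cc^2)
      }
      phi_grad <- if (!is.null(agfun)) function(x) {
        ag <- agfun(x)
        cc <- cfun(x)
        sgn * 2 * ag$a * ag$da + as.numeric(t(Rs) %*% (lam + mu * cc))
      } else NULL
      o <- optim(f, phi, gr = phi_grad, method = "L-BFGS-B",
                 lower = flo, upper = fhi,
                 control = list(maxit = 60, factr = 1e5))
      f <- o$par
      cc <- cfun(f)
      if (max(abs(cc)) < feas_tol) { ok <- TRUE; break }
      lam <- lam + mu * cc
      mu <- mu * 10
    }
    if (ok) {
      val <- sum(afun(f)^2)
      if (is.null(best) || sgn * val < sgn * best$val) {
        best <- list(f = f, val = val)
      }
    }
  }
  if (is.null(best)) list(feasible = FALSE) else
    list(feasible = TRUE, f = best$f)
}

new_pose_battery <- function(records, poses, limb, sims) {
  params <- lapply(limb$mtus, `[[`, "params")
  structure(list(
    records = records, poses = poses, sims = sims,
    mtu_table = data.frame(
      mtu = limb_mtu_names(limb),
      ell_o = mp_field(params, "ell_o"),
      L_S = mp_field(params, "L_S"),
      alpha_o = mp_field(params, "alpha_o"),
      F_max = mp_field(params, "F_max"))
  ), class = "pose_battery")
}

#' @export
print.pose_battery <- function(x, ...) {
  cat(sprintf(
    "Pose battery: sims {%s}, %d poses, %d records (%.1f%% viable)\n",
    paste(sort(unique(x$records$sim)), collapse = ","),
    nrow(x$poses$q), nrow(x$records),
    100 * mean(x$records$viable)))
  if (!is.null(x$counts)) {
    print(x$counts)
  }
  invisible(x)
}

#' Combine batteries of different simulations over the same pose set
#'
#' @param ... `pose_battery` objects sharing a pose set.
#' @return A single `pose_battery` with pooled records.
#' @export
combine_batteries <- function(...) {
  bats <- list(...)
  out <- bats[[1]]
  for (b in bats[-1]) {
    if (!isTRUE(all.equal(b$poses$q, out$poses$q))) {
      stop("batteries were run on different pose sets")
    }
    out$records <- rbind(out$records, b$records)
    out$sims <- sort(unique(c(out$sims, b$sims)))
    if (!is.null(b$pose_info)) {
      out$pose_info <- rbind(out$pose_info, b$pose_info)
    }
  }
  out
}

#' Apply the viability filters
#'
#' Applies filter rule iii (per-MTU caps on MTU length, e.g. the 80 mm
#' cap used to exclude non-physiological hip-flexion poses for a muscle
#' with poorly behaved modelled geometry at those extremes) on top of the
#' rule i / rule ii flags already recorded by the simulations, in the
#' order i, ii, iii with the first failure kept. Pose-level viability for
#' a simulation pair requires every record of the pose in that pair to be
#' viable; viable-pose counts per pair are recomputed.
#'
#' @param results A `pose_battery` (possibly combined across sims).
#' @param lmt_caps Named numeric vector of per-MTU MTU-length caps (m);
#'   muscles not listed are uncapped.
#' @return The filtered `pose_battery`, with `$counts` (viable poses per
#'   simulation pair) attached.
#' @export
filter_viable <- function(results, lmt_caps = NULL) {
  rec <- results$records
  if (!is.null(lmt_caps)) {
    for (mtu in names(lmt_caps)) {
      hit <- rec$mtu == mtu & rec$lmt > lmt_caps[[mtu]] & rec$viable
      rec$viable[hit] <- FALSE
      rec$reason[hit] <- "lmt-cap-exceeded"
      # a capped pose is excluded from every simulation it appears in
      bad_poses <- unique(rec$pose[rec$mtu == mtu &
                                     rec$lmt > lmt_caps[[mtu]]])
      hit2 <- rec$pose %in% bad_poses & rec$viable
      rec$viable[hit2] <- FALSE
      rec$reason[hit2] <- "lmt-cap-exceeded"
    }
  }
  results$records <- rec
  pair_counts <- list()
  for (pair in list(c(1L, 2L), c(3L, 4L))) {
    have <- intersect(pair, unique(rec$sim))
    if (!length(have)) next
    sub <- rec[rec$sim %in% have, ]
    ok <- tapply(sub$viable, sub$pose, all)
    pair_counts[[paste(pair, collapse = "-")]] <- sum(ok)
  }
  results$counts <- data.frame(
    pair = names(pair_counts),
    viable_poses = as.integer(unlist(pair_counts)),
    total_poses = nrow(results$poses$q))
  results
}
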