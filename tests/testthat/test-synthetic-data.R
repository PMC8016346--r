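# Synthetic limb and gait generation: determinism, architecture bounds,
# kinematic structure and forward-generated dynamic consistency.

test_that("toy limb generation is seed-deterministic and bounded", {
  l1 <- make_toy_limb(2, 6, seed = 10)
  l2 <- make_toy_limb(2, 6, seed = 10)
  expect_identical(mtu_length(l1, c(0, 0)), mtu_length(l2, c(0, 0)))
  expect_identical(vapply(l1$mtus, function(m) m$params$F_max, numeric(1)),
                   vapply(l2$mtus, function(m) m$params$F_max, numeric(1)))
  # architecture spreads over many seeds
  for (s in 1:25) {
    limb <- make_toy_limb(1, 3, seed = s)
    alpha <- vapply(limb$mtus, function(m) m$params$alpha_o, numeric(1))
    expect_true(all(alpha >= 0 & alpha <= 35 * pi / 180))
    lr <- vapply(limb$mtus, function(m) m$params$L_S / m$params$ell_o,
                 numeric(1))
    expect_true(all(lr >= 0.05 & lr <= 8))
    fm <- vapply(limb$mtus, function(m) m$params$F_max, numeric(1))
    expect_true(all(fm >= 0.6 & fm <= 30))
  }
  expect_error(make_toy_limb(2, 3), "antagonist")
})

test_that("minimal limb is an antagonist pair with opposite arm senses", {
  limb <- make_toy_limb(1, 2, seed = 1)
  mid <- matrix(mean(dof_ranges(limb)[1, ]), 1, 1,
                dimnames = list(NULL, "dof1"))
  arms <- moment_arms(limb, mid)
  expect_true(arms[1, 1, 1] * arms[1, 2, 1] < 0)
})

test_that("gait kinematics respect ranges, period and duty structure", {
  limb <- make_toy_limb(2, 4, seed = 2)
  specs <- default_gait_specs(81)
  expect_equal(specs$walk$duty_factor, 0.71)
  expect_equal(specs$run$duty_factor, 0.57)
  expect_equal(specs$walk$speed, 0.39)
  expect_equal(specs$run$speed, 1.39)
  kin <- make_gait_kinematics(specs$walk, limb, seed = 2)
  rng <- dof_ranges(limb)
  for (k in 1:2) {
    expect_true(all(kin$q[, k] >= rng[k, 1] & kin$q[, k] <= rng[k, 2]))
  }
  # periodic: first and last samples coincide to within one sample step
  expect_equal(kin$q[1, ], kin$q[nrow(kin$q), ], tolerance = 1e-8)
  # stance fraction of the phase grid matches the duty factor
  expect_equal(mean(kin$phase[-length(kin$phase)] < 0.71), 0.71,
               tolerance = 1.5 / 80)
  # activation bursts of an antagonist pair do not overlap
  act <- make_activation_profiles(limb, kin, seed = 2)
  expect_true(all(act >= 0 & act <= 0.8))
  overlap <- colSums(act[, c(1, 3)] * act[, c(2, 4)])
  expect_lt(max(overlap), 1e-3 * nrow(act))
})

test_that("forward generation is exactly self-consistent without noise", {
  b <- make_synthetic_bundle(2, 4, seed = 6, n_samples = 61)
  for (nm in names(b$trials)) {
    tr <- b$trials[[nm]]
    forces <- b$truth[[nm]]$tendon_forces
    M2 <- sapply(seq_len(ncol(tr$M_ext)), function(k) {
      rowSums(forces * tr$arms[, , k])
    })
    expect_lt(max(abs(M2 - tr$M_ext)), 1e-9)
    # initial state is a static equilibrium (residual < 1e-6)
    for (i in seq_along(b$limb$mtus)) {
      p <- b$limb$mtus[[i]]$params
      st <- list(ell_norm = b$truth[[nm]]$lstar[1, i], v_norm = 0,
                 alpha = pennation_angle(
                   b$truth[[nm]]$lstar[1, i] * p$ell_o, p),
                 F_T = forces[1, i])
      expect_lt(abs(equilibrium_residual(
        st, b$truth[[nm]]$activations[1, i], p)), 1e-5)
    }
  }
  # seed determinism end-to-end
  b2 <- make_synthetic_bundle(2, 4, seed = 6, n_samples = 61)
  expect_identical(b$trials$walk$M_ext, b2$trials$walk$M_ext)
  expect_identical(b$truth$run$tendon_forces, b2$truth$run$tendon_forces)
})

test_that("zero activation with slack fibres produces negligible moments", {
  limb <- make_toy_limb(1, 2, seed = 8)
  spec <- gait_spec(0.39, 0.71, 0.55, 51, "walk")
  kin <- make_gait_kinematics(spec, limb, seed = 8)
  act <- matrix(0, 51, 2)
  gen <- forward_generate_trial(limb, kin, act, noise_sd = 0)
  # forces are passive-only; where fibres stay at or below optimal length
  # the moments essentially vanish
  expect_lt(max(abs(gen$trial$M_ext)),
            1e-3 * max(abs(mtu_length(limb, kin$q))))
  gen_noise <- forward_generate_trial(limb, kin, act, noise_sd = 1e-4,
                                      seed = 8)
  expect_lt(max(abs(gen_noise$trial$M_ext)), 3 * 1e-4 + max(abs(gen$trial$M_ext)))
})

test_that("an isometric rigid-tendon muscle contributes linearly in
          activation", {
  # constant arm, rigid tendon, constant posture at optimal fibre length
  limb <- pair_limb(arm = 0.004, k_T = 1e6, L_S = 0.005)
  spec <- gait_spec(0.39, 0.71, 0.5, 41, "walk")
  kin <- make_gait_kinematics(spec, limb, seed = 1)
  kin$q[] <- 0          # freeze the pose: isometric
  kin$qdot[] <- 0
  a1 <- cbind(rep(0.3, 41), 0)
  a2 <- cbind(rep(0.6, 41), 0)
  g1 <- forward_generate_trial(limb, kin, a1)
  g2 <- forward_generate_trial(limb, kin, a2)
  m1 <- g1$trial$M_ext[21, 1]
  m2 <- g2$trial$M_ext[21, 1]
  expect_equal(unname(m2 / m1), 2, tolerance = 0.05)
})

test_that("tuning truth scales the architecture before integration", {
  tt <- list(p_ell = c(1.1, 1), p_L = c(1, 1))
  limb <- make_toy_limb(1, 2, seed = 9)
  spec <- gait_spec(0.39, 0.71, 0.5, 41, "walk")
  kin <- make_gait_kinematics(spec, limb, seed = 9)
  act <- make_activation_profiles(limb, kin, seed = 9)
  g1 <- forward_generate_trial(limb, kin, act)
  g2 <- forward_generate_trial(limb, kin, act, tuning_truth = tt)
  # scaling optimal fibre length changes normalized lengths and forces
  expect_gt(max(abs(g1$truth$lstar[, 1] - g2$truth$lstar[, 1])), 0.02)
  expect_identical(g2$truth$tuning_truth$p_ell, c(1.1, 1))
})
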