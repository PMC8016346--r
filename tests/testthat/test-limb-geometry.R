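# Polynomial limb geometry: MTU lengths, moment arms, the tendon-excursion
# identity, and serialization.

test_that("MTU length evaluation matches an independent polynomial oracle", {
  d1 <- dof_spec("hip", -1.5, 0.5)
  d2 <- dof_spec("knee", -2, -0.2)
  p <- simple_mtu("biart", L_S = 0.05)
  # l = 0.08 - 0.004 q1 + 0.002 q2 + 0.001 q1 q2 - 0.0005 q2^2
  g <- mtu_geometry("biart", c("hip", "knee"),
                    coeffs = c(0.08, -0.004, 0.002, 0.001, -0.0005),
                    powers = rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1),
                                   c(0, 2)))
  limb <- limb_model(list(d1, d2), list(list(params = p, geometry = g)))
  set.seed(7)
  q <- cbind(hip = runif(20, -1.5, 0.5), knee = runif(20, -2, -0.2))
  oracle <- 0.08 - 0.004 * q[, 1] + 0.002 * q[, 2] +
    0.001 * q[, 1] * q[, 2] - 0.0005 * q[, 2]^2
  expect_equal(unname(mtu_length(limb, q)[, 1]), oracle, tolerance = 1e-12)

  # degree-0 geometry is constant; linear geometry returns c0 at q = 0
  limb0 <- pair_limb(arm = 0.004)
  expect_equal(mtu_length(limb0, 0.3)[1, ],
               mtu_length(limb0, c(q1 = 0))[1, ] -
                 c(ago = 0.004, ant = -0.004) * 0.3, tolerance = 1e-12)
})

test_that("moment arms are the negative length gradient", {
  d1 <- dof_spec("hip", -1.5, 0.5)
  d2 <- dof_spec("knee", -2, -0.2)
  p <- simple_mtu("biart", L_S = 0.05)
  g <- mtu_geometry("biart", c("hip", "knee"),
                    coeffs = c(0.08, -0.004, 0.002, 0.001, -0.0005),
                    powers = rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1),
                                   c(0, 2)))
  p2 <- simple_mtu("mono")
  g2 <- mtu_geometry("mono", "hip", coeffs = c(0.06, 0.003),
                     powers = rbind(c(0), c(1)))
  limb <- limb_model(list(d1, d2),
                     list(list(params = p, geometry = g),
                          list(params = p2, geometry = g2)))
  set.seed(8)
  q <- cbind(hip = runif(10, -1.4, 0.4), knee = runif(10, -1.9, -0.3))
  arms <- moment_arms(limb, q)
  # linear term: arm is exactly -c1 everywhere
  expect_equal(unname(arms[, "mono", "hip"]), rep(-0.003, 10))
  # uncoupled DOF is exactly zero
  expect_identical(unname(arms[, "mono", "knee"]), rep(0, 10))
  # central finite differences agree
  hstep <- 1e-6
  for (k in 1:2) {
    qp <- q; qp[, k] <- qp[, k] + hstep
    qm <- q; qm[, k] <- qm[, k] - hstep
    fd <- -(mtu_length(limb, qp) - mtu_length(limb, qm)) / (2 * hstep)
    expect_equal(unname(arms[, , k]), unname(fd), tolerance = 1e-6)
  }
})

test_that("tendon-excursion audit passes for consistent geometry and flags
          a corrupted arm polynomial", {
  limb <- make_toy_limb(2, 5, seed = 3)
  rep_ok <- check_tendon_excursion(limb, n_samples = 30, seed = 1)
  expect_true(all(!rep_ok$flagged))
  expect_true(all(rep_ok$max_discrepancy_m < 1e-6))
  # corrupt one MTU by attaching an inconsistent explicit arm polynomial
  g <- limb$mtus[[1]]$geometry
  bad <- mtu_geometry(g$muscle, g$dofs, g$coeffs, g$powers,
                      arm_coeffs = list(list(coeffs = 0.001, powers = 0)))
  limb$mtus[[1]]$geometry <- bad
  rep_bad <- check_tendon_excursion(limb, n_samples = 30, seed = 1)
  expect_true(rep_bad$flagged[1])
  # a degree-0 (constant-length) MTU has zero arms everywhere
  d <- dof_spec("q1", -1, 1)
  pz <- simple_mtu("const")
  gz <- mtu_geometry("const", "q1", coeffs = 0.06,
                     powers = matrix(0, 1, 1))
  limbz <- limb_model(list(d), list(list(params = pz, geometry = gz)))
  expect_identical(unname(moment_arms(limbz, 0.5)[1, 1, 1]), 0)
})

test_that("pose range checking enforces the expanded DOF box", {
  limb <- pair_limb(range = c(-1, 1))
  expect_silent(mtu_length(limb, 1.05))   # within +10%
  expect_error(mtu_length(limb, 1.5), "box")
})

test_that("limb model serialization round-trips bit-identically", {
  limb <- make_toy_limb(2, 5, seed = 11)
  path <- tempfile(fileext = ".json")
  write_limb_model(limb, path)
  limb2 <- read_limb_model(path)
  set.seed(5)
  q <- cbind(runif(25, -1, 0.3), runif(25, -1, 0.3))
  colnames(q) <- rownames(dof_ranges(limb))
  expect_identical(mtu_length(limb, q), mtu_length(limb2, q))
  expect_identical(moment_arms(limb, q), moment_arms(limb2, q))
  unlink(path)
})

test_that("gait trial CSV round-trips", {
  b <- make_synthetic_bundle(1, 2, seed = 4, n_samples = 31)
  tr <- b$trials$walk
  path <- tempfile(fileext = ".csv")
  write_gait_trial(tr, path)
  tr2 <- read_gait_trial(path, label = "walk", duty_factor = 0.71)
  expect_equal(tr2$q, tr$q, tolerance = 1e-9)
  expect_equal(tr2$M_ext, tr$M_ext, tolerance = 1e-9)
  expect_equal(tr2$lmt, tr$lmt, tolerance = 1e-9)
  expect_equal(tr2$arms, tr$arms, tolerance = 1e-9)
  unlink(path)
  # explicit columns win over model-derived values
  lmt_mod <- tr$lmt * 1.01
  tr3 <- gait_trial(tr$time, tr$q, tr$M_ext, model = b$limb,
                    lmt = lmt_mod, arms = tr$arms)
  expect_equal(tr3$lmt, lmt_mod)
})
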