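# Static posture battery: pose sampling, the four simulations, and the
# viability filters.

test_that("pose sampling is uniform within bounds and seed-deterministic", {
  limb <- make_toy_limb(2, 4, seed = 5)
  ps <- sample_poses(limb, 500, seed = 9)
  expect_equal(nrow(ps$q), 500)
  rng <- dof_ranges(limb)
  for (k in 1:2) {
    expect_true(all(ps$q[, k] >= rng[k, 1] & ps$q[, k] <= rng[k, 2]))
  }
  expect_identical(ps$q, sample_poses(limb, 500, seed = 9)$q)
  # fixed-DOF override
  ps2 <- sample_poses(limb, 50, seed = 9, overrides = c(dof2 = -0.3))
  expect_true(all(ps2$q[, "dof2"] == -0.3))
})

test_that("isolated-muscle simulations honour equilibrium anchors", {
  # construct a pose where l_MT = L_S + l_o exactly: slack tendon at a = 0
  pl <- pair_limb(arm = 0.004, ell_o = 0.02, L_S = 0.03)
  ps <- sample_poses(pl, 1, seed = 1)
  ps$q[1, 1] <- 0     # neutral: c0 = L_S + l_o for both muscles
  b3 <- run_isolated_muscle(ps, pl, 0)
  expect_true(all(b3$records$viable))
  expect_equal(b3$records$lstar, c(1, 1), tolerance = 1e-9)
  expect_equal(b3$records$F_T, c(0, 0), tolerance = 1e-9)
  # activation stretches the tendon: lstar at a = 1 <= lstar at a = 0
  ps50 <- sample_poses(pl, 50, seed = 2)
  r0 <- run_isolated_muscle(ps50, pl, 0)$records
  r1 <- run_isolated_muscle(ps50, pl, 1)$records
  expect_true(all(r1$lstar <= r0$lstar + 1e-12))
})

test_that("poses shorter than the slack length are flagged as rule ii", {
  pl <- pair_limb(arm = 0.02, ell_o = 0.02, L_S = 0.03, range = c(-2, 2))
  ps <- sample_poses(pl, 1, seed = 1)
  ps$q[1, 1] <- 1.8    # shortens the agonist below its slack length
  lmt <- mtu_length(pl, ps$q)
  expect_lt(lmt[1, "ago"], 0.03)
  b <- run_isolated_muscle(ps, pl, 0)
  rec <- b$records
  expect_false(rec$viable[rec$mtu == "ago"])
  expect_identical(rec$reason[rec$mtu == "ago"], "lmt-below-slack")
  expect_true(rec$viable[rec$mtu == "ant"])
})

test_that("min/max whole-limb simulations bracket the activation effort", {
  limb <- make_toy_limb(2, 4, seed = 5)
  ps <- sample_poses(limb, 60, seed = 3)
  bmin <- run_min_max_activation(ps, limb, "min", seed = 1)
  bmax <- run_min_max_activation(ps, limb, "max", seed = 1)
  both <- merge(bmin$pose_info, bmax$pose_info, by = "pose")
  ok <- both$viable.x & both$viable.y
  expect_gt(sum(ok), 0)
  expect_true(all(both$objective.x[ok] <= both$objective.y[ok] + 1e-6))
  # every viable state re-checks as a static equilibrium
  rec <- bmin$records[bmin$records$viable, ]
  for (i in seq_len(min(nrow(rec), 40))) {
    p <- limb$mtus[[match(rec$mtu[i], limb_mtu_names(limb))]]$params
    st <- list(ell_norm = rec$lstar[i], v_norm = 0,
               alpha = pennation_angle(rec$lstar[i] * p$ell_o, p),
               F_T = rec$F_T[i])
    expect_lt(abs(equilibrium_residual(st, rec$activation[i], p)), 1e-5)
  }
  # and the moment balance holds at the solution
  for (pz in unique(rec$pose)[1:10]) {
    sub <- rec[rec$pose == pz, ]
    arms <- moment_arms(limb, ps$q[pz, , drop = FALSE])
    M <- sapply(1:2, function(k) sum(sub$F_T * arms[1, sub$mtu, k]))
    scale <- sum(abs(sub$F_T)) * max(abs(arms)) + 1e-9
    expect_lt(max(abs(M)) / scale, 1e-4)
  }
})

test_that("a lone muscle with passive force at a pose cannot balance", {
  # single-MTU limb: any nonzero passive force contradicts sum F r = 0
  d <- dof_spec("q1", -1, 1)
  p <- simple_mtu("solo", ell_o = 0.02, L_S = 0.01, F_max = 5)
  # neutral length puts fibres well above optimal: passive force > 0
  g <- mtu_geometry("solo", "q1", coeffs = c(0.01 + 0.024, -0.004),
                    powers = matrix(c(0, 1), 2, 1))
  limb <- limb_model(list(d), list(list(params = p, geometry = g)))
  ps <- sample_poses(limb, 1, seed = 1)
  ps$q[1, 1] <- 0
  bmin <- run_min_max_activation(ps, limb, "min")
  expect_false(bmin$pose_info$viable[1])
  expect_identical(bmin$pose_info$reason[1], "equilibrium-infeasible")
})

test_that("the MTU-length cap removes poses with the recorded reason", {
  pl <- pair_limb(arm = 0.02, ell_o = 0.02, L_S = 0.03, range = c(-2, 2))
  ps <- sample_poses(pl, 40, seed = 4)
  bat <- combine_batteries(run_isolated_muscle(ps, pl, 0),
                           run_isolated_muscle(ps, pl, 1))
  lmt <- mtu_length(pl, ps$q)
  # cap at 80 mm: the antagonist exceeds it at strongly flexed poses
  over <- which(lmt[, "ant"] > 0.080)
  expect_gt(length(over), 0)
  filt <- filter_viable(bat, lmt_caps = c(ant = 0.080))
  rec <- filt$records
  hit <- rec[rec$pose %in% over, ]
  expect_true(all(!hit$viable))
  expect_true(all(hit$reason[hit$reason != "lmt-below-slack"] %in%
                    c("lmt-cap-exceeded")))
  # no caps: rule iii removes nothing
  filt0 <- filter_viable(bat)
  expect_identical(sum(filt0$records$viable), sum(bat$records$viable))
})

test_that("viable-pose counts respect the simulation-pair ordering", {
  limb <- make_toy_limb(2, 4, seed = 15)
  ps <- sample_poses(limb, 80, seed = 6)
  bat <- combine_batteries(
    run_min_max_activation(ps, limb, "min", seed = 1),
    run_min_max_activation(ps, limb, "max", seed = 1),
    run_isolated_muscle(ps, limb, 0),
    run_isolated_muscle(ps, limb, 1))
  filt <- filter_viable(bat)
  cnt <- setNames(filt$counts$viable_poses, filt$counts$pair)
  expect_lte(cnt[["1-2"]], cnt[["3-4"]])
  # determinism of the full battery
  bat2 <- combine_batteries(
    run_min_max_activation(ps, limb, "min", seed = 1),
    run_min_max_activation(ps, limb, "max", seed = 1),
    run_isolated_muscle(ps, limb, 0),
    run_isolated_muscle(ps, limb, 1))
  expect_identical(filter_viable(bat2)$records, filt$records)
})
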