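# Operating-range analyses: hyperplane fits, region classification,
# range summaries and decoupling regressions.

test_that("hyperplane fit recovers exactly affine data", {
  q <- seq(-1, 1, length.out = 50)
  y <- 0.5 + 0.01 * q
  fit <- hyperplane_fit(y, q)
  expect_equal(fit$C, c(0.01, 0.5), tolerance = 1e-12)
  expect_equal(as.numeric(fit$r2), 1, tolerance = 1e-12)
  expect_equal(fit$rmse, 0, tolerance = 1e-12)
  expect_equal(fit$eps_max, 0, tolerance = 1e-12)
})

test_that("hyperplane coefficients match a normal-equations oracle", {
  set.seed(50)
  ang <- cbind(runif(200, -1.5, 0.5), runif(200, -2, 0))
  y <- 0.9 + 0.05 * ang[, 1] - 0.08 * ang[, 2] + rnorm(200, sd = 0.02)
  fit <- hyperplane_fit(y, ang)
  X <- cbind(ang, 1)
  oracle <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit$C, as.numeric(oracle), tolerance = 1e-8)
  # goodness-of-fit statistics from their definitions
  res <- y - X %*% oracle
  expect_equal(fit$rmse, sqrt(mean(res^2)), tolerance = 1e-10)
  expect_equal(fit$eps_max, max(abs(res)), tolerance = 1e-10)
  expect_equal(as.numeric(fit$r2),
               1 - sum(res^2) / sum((y - mean(y))^2), tolerance = 1e-10)
  expect_lte(fit$rmse, fit$eps_max)
  # duplicating observations leaves the full-rank solution unchanged
  fit2 <- hyperplane_fit(c(y, y), rbind(ang, ang))
  expect_equal(fit2$C, fit$C, tolerance = 1e-8)
})

test_that("rank-deficient designs return the minimum-norm solution", {
  # constant angle column: infinitely many exact fits; the pseudoinverse
  # picks the coefficient vector of least norm
  y <- rnorm(30, mean = 0.8, sd = 0.05)
  ang <- matrix(0.7, 30, 1)
  fit <- hyperplane_fit(y, ang)
  # oracle via explicit SVD pseudoinverse
  X <- cbind(ang, 1)
  sv <- svd(X)
  keep <- sv$d > 1e-10 * sv$d[1]
  Xp <- sv$v[, keep, drop = FALSE] %*%
    diag(1 / sv$d[keep], sum(keep)) %*% t(sv$u[, keep, drop = FALSE])
  expect_equal(fit$C, as.numeric(Xp %*% y), tolerance = 1e-8)
  # zero-variance observations flag r2 as undefined
  fit0 <- hyperplane_fit(rep(1, 10), seq_len(10))
  expect_true(is.na(fit0$r2))
  expect_true(isTRUE(attr(fit0$r2, "undefined")))
  expect_error(hyperplane_fit(c(1, 2), matrix(1, 2, 2)), "observations")
})

test_that("force-length regions partition the positive axis", {
  expect_identical(as.character(classify_fl_region(1.0)), "plateau")
  expect_identical(as.character(classify_fl_region(0.55)),
                   "steep_ascending")
  expect_identical(as.character(classify_fl_region(1.30)), "descending")
  set.seed(51)
  x <- runif(500, 0.01, 2.5)
  lab <- classify_fl_region(x)
  expect_false(anyNA(lab))
  expect_identical(levels(lab), c("steep_ascending", "shallow_ascending",
                                  "plateau", "descending"))
  # custom boundaries shift the partition but keep it exhaustive
  lab2 <- classify_fl_region(x, boundaries = c(0.6, 0.9, 1.2))
  expect_false(anyNA(lab2))
  expect_error(classify_fl_region(0), "positive")
  expect_error(classify_fl_region(1, boundaries = c(1, 0.9, 1.2)),
               "increasing")
})

test_that("operating-range summary is faithful bookkeeping", {
  pl <- pair_limb(arm = 0.004, ell_o = 0.02, L_S = 0.03)
  ps <- sample_poses(pl, 200, seed = 7)
  bat <- filter_viable(combine_batteries(run_isolated_muscle(ps, pl, 0),
                                         run_isolated_muscle(ps, pl, 1)))
  rs <- operating_range_summary(bat)
  rec <- bat$records[bat$records$viable & bat$records$mtu == "ago", ]
  row <- rs$summary[rs$summary$mtu == "ago", ]
  expect_equal(row$lstar_min, min(rec$lstar))
  expect_equal(row$lstar_max, max(rec$lstar))
  expect_equal(row$lmt_min, min(rec$lmt))
  expect_equal(row$lmt_max, max(rec$lmt))
  # range ratio from a single simulation (here sim 3)
  r3 <- rec[rec$sim == 3, ]
  expect_equal(row$range_ratio,
               diff(range(r3$lstar)) / (diff(range(r3$lmt)) / 0.02))
  # fibre range never exceeds the normalized MTU range
  expect_true(all(rs$summary$range_ratio <= 1 + 1e-9))
  # histogram counts every viable observation once
  expect_equal(sum(rs$histogram$count[rs$histogram$mtu == "ago"]),
               nrow(rec))
})

test_that("in-vivo fraction of the viable range is computed per solution", {
  pl <- pair_limb(arm = 0.004)
  ps <- sample_poses(pl, 100, seed = 8)
  bat <- filter_viable(run_isolated_muscle(ps, pl, 0))
  rec <- bat$records[bat$records$mtu == "ago", ]
  # a fake solution whose in-vivo range equals the viable range
  sol <- list(trials = list(list(
    lstar = rbind(ago = range(rec$lstar), ant = c(1, 1)))))
  rs <- operating_range_summary(bat, solutions = list(sol))
  expect_equal(rs$summary$fraction_used[rs$summary$mtu == "ago"], 1,
               tolerance = 1e-9)
})

test_that("decoupling regression matches closed-form least squares and
          detects pennation-driven decoupling", {
  # family of isolated MTUs differing only in pennation, stiff tendons:
  # fibre/MTU range ratio declines as pennation grows
  d <- dof_spec("q1", -1, 1)
  alphas <- c(0, 10, 20, 30, 34) * pi / 180
  mtus <- lapply(seq_along(alphas), function(i) {
    nm <- sprintf("m%d", i)
    p <- muscle_params(nm, 1e-3, 0.02, 0.002, alphas[i], F_max = 10,
                       k_T = 1e4)
    c0 <- 0.002 + sqrt((0.95 * 0.02)^2 - (0.02 * sin(alphas[i]))^2)
    g <- mtu_geometry(nm, "q1", coeffs = c(c0, -0.003),
                      powers = matrix(c(0, 1), 2, 1))
    list(params = p, geometry = g)
  })
  limb <- limb_model(list(d), mtus)
  ps <- sample_poses(limb, 150, seed = 9)
  bat <- filter_viable(run_isolated_muscle(ps, limb, 0))
  rs <- operating_range_summary(bat)
  params <- lapply(limb$mtus, `[[`, "params")
  reg <- suppressWarnings(decoupling_regression(rs, params))
  alpha_row <- reg[reg$predictor == "alpha", ]
  expect_lt(alpha_row$slope, 0)
  # closed-form simple-regression oracle
  df <- rs$summary
  x <- alphas; y <- df$range_ratio
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(alpha_row$slope, slope, tolerance = 1e-10)
  expect_equal(alpha_row$intercept, mean(y) - slope * mean(x),
               tolerance = 1e-10)
  # identical MTUs give a degenerate design
  same <- lapply(params, function(p) { p$alpha_o <- 0.1; p$L_S <- 0.002; p })
  expect_error(decoupling_regression(rs, same), "degenerate")
})
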