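# Post-processing of the battery and redundancy solutions: hyperplane
# linearity fits of normalized fibre length against joint angles,
# force-length region classification, operating-range summaries and
# fibre/MTU range decoupling regressions.

#' Hyperplane fit of normalized fibre length against joint angles
#'
#' Minimum-norm least-squares fit of
#' \eqn{\ell^* = c_1 q_1 + ... + c_{\eta-1} q_{\eta-1} + c_\eta}
#' via the Moore-Penrose pseudoinverse of the angle matrix augmented with
#' a column of ones, with goodness-of-fit statistics computed against the
#' observations.
#'
#' @param ell_norm_obs Numeric vector of normalized fibre lengths.
#' @param angles Matrix `n x (eta - 1)` of joint angles (rad); a vector is
#'   treated as a single angle.
#' @return A `hyperplane_fit` object: `C` (slopes then intercept), `r2`
#'   (`NA` with attribute `"undefined"` when the observations have zero
#'   variance), `rmse`, `eps_max`, `n_obs`, `fitted`.
#' @export
hyperplane_fit <- function(ell_norm_obs, angles) {
  angles <- as.matrix(angles)
  n <- length(ell_norm_obs)
  if (nrow(angles) != n) stop("angles must have one row per observation")
  eta <- ncol(angles) + 1
  if (n < eta) stop("need at least as many observations as coefficients")
  X <- cbind(angles, 1)
  C <- as.numeric(pracma::pinv(X) %*% ell_norm_obs)
  fitted <- as.numeric(X %*% C)
  resid <- ell_norm_obs - fitted
  ss_res <- sum(resid^2)
  ss_tot <- sum((ell_norm_obs - mean(ell_norm_obs))^2)
  r2 <- if (ss_tot <= 0) {
    structure(NA_real_, undefined = TRUE)
  } else 1 - ss_res / ss_tot
  structure(list(C = C, r2 = r2, rmse = sqrt(ss_res / n),
                 eps_max = max(abs(resid)), n_obs = n, fitted = fitted),
            class = "hyperplane_fit")
}

#' @export
print.hyperplane_fit <- function(x, ...) {
  cat(sprintf(
    "Hyperplane fit (%d obs): r2 = %s, RMSE = %.4g, eps_max = %.4g\n",
    x$n_obs,
    if (is.na(x$r2)) "undefined (zero variance)" else sprintf("%.4f", x$r2),
    x$rmse, x$eps_max))
  cat("  coefficients:", paste(sprintf("%.5g", x$C), collapse = ", "), "\n")
  invisible(x)
}

#' Classify a fibre length on the active force-length curve
#'
#' Maps normalized fibre length to one of the four classical regions of
#' the active force-length curve. The default boundaries (steep ascending
#' below 0.80, shallow ascending to 0.95, plateau to 1.05, descending
#' above) approximately correspond to the divisions in common use; no
#' canonical numeric boundaries exist, so they are explicit configuration.
#'
#' @param ell_norm Normalized fibre length(s), > 0.
#' @param boundaries Increasing length-3 numeric vector: upper bounds of
#'   the steep-ascending and shallow-ascending regions and of the plateau.
#' @return Factor with levels `steep_ascending`, `shallow_ascending`,
#'   `plateau`, `descending`.
#' @export
classify_fl_region <- function(ell_norm,
                               boundaries = c(0.80, 0.95, 1.05)) {
  if (any(ell_norm <= 0)) stop("ell_norm must be strictly positive")
  if (length(boundaries) != 3 || any(diff(boundaries) <= 0)) {
    stop("boundaries must be three increasing values")
  }
  lv <- c("steep_ascending", "shallow_ascending", "plateau", "descending")
  cut(ell_norm, breaks = c(0, boundaries, Inf), labels = lv,
      right = TRUE)
}

#' Operating-range summary
#'
#' Per-MTU extrema of normalized fibre length and MTU length over the
#' viable battery poses (overall and per simulation pair), the
#' fibre-to-MTU range ratio, in-vivo ranges from redundancy solutions,
#' the fraction of the viable range used in vivo, and a histogram of
#' normalized fibre length.
#'
#' @param battery A filtered `pose_battery` (see [filter_viable()]).
#' @param solutions Optional list of `redundancy_solution` objects
#'   providing in-vivo fibre length trajectories.
#' @param bin_width Histogram bin width in units of normalized fibre
#'   length (default 0.02).
#' @param boundaries Region boundaries for [classify_fl_region()].
#' @return A `range_summary`: list with `summary` (data frame, one row
#'   per MTU) and `histogram` (long data frame of bin counts).
#' @export
operating_range_summary <- function(battery, solutions = NULL,
                                    bin_width = 0.02,
                                    boundaries = c(0.80, 0.95, 1.05)) {
  rec <- battery$records[battery$records$viable, ]
  mtus <- battery$mtu_table$mtu
  lo <- setNames(battery$mtu_table$ell_o, mtus)
  rows <- list(); hists <- list()
  for (mtu in mtus) {
    sub <- rec[rec$mtu == mtu & is.finite(rec$lstar), ]
    if (!nrow(sub)) {
      rows[[mtu]] <- data.frame(
        mtu = mtu, empty = TRUE, lstar_min = NA, lstar_max = NA,
        lmt_min = NA, lmt_max = NA, range_ratio = NA,
        lstar_min_12 = NA, lstar_max_12 = NA,
        lstar_min_34 = NA, lstar_max_34 = NA,
        invivo_min = NA, invivo_max = NA, fraction_used = NA)
      next
    }
    ls_rng <- range(sub$lstar)
    lmt_rng <- range(sub$lmt)
    # the fibre-vs-MTU range comparison is meaningful within a single
    # simulation (pooling different activation levels lets tendon stretch
    # widen the fibre range beyond the MTU range); use the lowest
    # simulation present
    ref <- sub[sub$sim == min(sub$sim), ]
    ref_ls <- diff(range(ref$lstar))
    ref_lmt <- diff(range(ref$lmt))
    rng_pair <- function(sims) {
      s <- sub[sub$sim %in% sims, ]
      if (nrow(s)) range(s$lstar) else c(NA_real_, NA_real_)
    }
    r12 <- rng_pair(1:2); r34 <- rng_pair(3:4)
    iv <- c(NA_real_, NA_real_)
    if (!is.null(solutions)) {
      vals <- unlist(lapply(solutions, function(sol) {
        unlist(lapply(sol$trials, function(tr) tr$lstar[mtu, ]))
      }))
      if (length(vals)) iv <- range(vals)
    }
    viable_range <- diff(ls_rng)
    frac <- if (!is.na(iv[1]) && viable_range > 0) {
      (iv[2] - iv[1]) / viable_range
    } else NA_real_
    rows[[mtu]] <- data.frame(
      mtu = mtu, empty = FALSE,
      lstar_min = ls_rng[1], lstar_max = ls_rng[2],
      lmt_min = lmt_rng[1], lmt_max = lmt_rng[2],
      range_ratio = ref_ls / (ref_lmt / lo[[mtu]]),
      lstar_min_12 = r12[1], lstar_max_12 = r12[2],
      lstar_min_34 = r34[1], lstar_max_34 = r34[2],
      invivo_min = iv[1], invivo_max = iv[2], fraction_used = frac)
    breaks <- seq(floor(ls_rng[1] / bin_width) * bin_width,
                  ceiling(ls_rng[2] / bin_width) * bin_width + bin_width,
                  by = bin_width)
    idx <- findInterval(sub$lstar, breaks, rightmost.closed = TRUE)
    counts <- tabulate(idx, nbins = length(breaks) - 1)
    mids <- breaks[-length(breaks)] + bin_width / 2
    hists[[mtu]] <- data.frame(
      mtu = mtu, bin_mid = mids, count = counts,
      region = classify_fl_region(mids, boundaries))
  }
  structure(list(summary = do.call(rbind, c(rows, make.row.names = FALSE)),
                 histogram = do.call(rbind, c(hists,
                                              make.row.names = FALSE)),
                 bin_width = bin_width),
            class = "range_summary")
}

#' Fibre/MTU range decoupling regressions
#'
#' Ordinary least squares regressions of the per-MTU ratio of fibre
#' length range to (fibre-length-normalized) MTU length range against
#' (a) pennation angle and (b) relative tendon length `L_S / ell_o`.
#' Greater pennation or a relatively longer tendon decouples fibre length
#' change from MTU length change, driving the ratio below one.
#'
#' @param summary A [operating_range_summary()] result.
#' @param params List of [muscle_params()] in MTU order (e.g.
#'   `lapply(limb$mtus, `[[`, "params")`); pennation and tendon ratios
#'   may alternatively be taken from the battery's MTU table.
#' @return Data frame with one row per predictor: slope, intercept, r2,
#'   p-value, n.
#' @export
decoupling_regression <- function(summary, params) {
  df <- summary$summary[!summary$summary$empty, ]
  if (nrow(df) < 3) stop("need at least 3 MTUs with defined ranges")
  nm <- vapply(params, `[[`, character(1), "name")
  alpha <- setNames(vapply(params, `[[`, numeric(1), "alpha_o"), nm)
  lrat <- setNames(vapply(params, function(p) p$L_S / p$ell_o,
                          numeric(1)), nm)
  df$alpha <- alpha[df$mtu]
  df$tendon_ratio <- lrat[df$mtu]
  preds <- c("alpha", "tendon_ratio")
  degen <- vapply(preds, function(v) sd(df[[v]]) == 0, logical(1))
  if (all(degen)) {
    stop("degenerate design: every predictor has zero variance")
  }
  out <- lapply(preds[!degen], function(v) {
    fit <- lm(df$range_ratio ~ df[[v]])
    sm <- summary(fit)
    data.frame(predictor = v,
               slope = coef(fit)[2], intercept = coef(fit)[1],
               r2 = sm$r.squared,
               p_value = sm$coefficients[2, 4], n = nrow(df))
  })
  if (any(degen)) {
    warning(sprintf("predictor(s) with zero variance skipped: %s",
                    paste(preds[degen], collapse = ", ")))
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
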