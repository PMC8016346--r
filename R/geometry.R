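# Limb geometry: MTU length and moment arms as smooth multivariate
# polynomial functions of joint angles. Polynomials preserve the two
# properties the downstream mathematics relies on -- smoothness and exact
# gradients -- and moment arms follow from tendon excursion:
# r_{m,k} = -d l_MT / d q_k, so an MTU that shortens as a joint angle
# increases produces a positive moment about that joint.

#' Degree of freedom specification
#'
#' @param name Identifier.
#' @param range_min,range_max Joint angle bounds (rad).
#' @param kind `"actuated"` or `"fixed"`.
#' @return A `dof_spec` object.
#' @export
dof_spec <- function(name, range_min, range_max, kind = "actuated") {
  if (range_min >= range_max) stop("range_min must be below range_max")
  kind <- match.arg(kind, c("actuated", "fixed"))
  structure(list(name = as.character(name), range_min = range_min,
                 range_max = range_max, kind = kind), class = "dof_spec")
}

#' Polynomial MTU geometry
#'
#' Represents one MTU's length as a multivariate polynomial of the joint
#' angles it crosses: \eqn{l_{MT}(q) = \sum_j c_j \prod_k q_k^{e_{jk}}}.
#' Moment arms are the exact negative gradient. An optional independent
#' arm polynomial (`arm_coeffs`) may be supplied for imported geometries;
#' [check_tendon_excursion()] verifies its consistency with the length
#' polynomial.
#'
#' @param muscle MTU identifier (must match a [muscle_params()] name).
#' @param dofs Character vector of DOF names the MTU crosses.
#' @param coeffs Numeric vector of polynomial coefficients (m per rad^power).
#' @param powers Integer matrix, `length(coeffs)` rows by `length(dofs)`
#'   columns, of exponents.
#' @param arm_coeffs Optional list (one element per DOF crossed) of
#'   `list(coeffs, powers)` overriding the derived moment-arm polynomials.
#' @return An `mtu_geometry` object.
#' @export
mtu_geometry <- function(muscle, dofs, coeffs, powers, arm_coeffs = NULL) {
  powers <- matrix(as.numeric(powers), nrow = length(coeffs),
                   ncol = length(dofs))
  if (any(powers < 0) || any(powers != round(powers))) {
    stop("powers must be non-negative integers")
  }
  structure(list(muscle = as.character(muscle), dofs = as.character(dofs),
                 coeffs = as.numeric(coeffs), powers = powers,
                 arm_coeffs = arm_coeffs), class = "mtu_geometry")
}

# evaluate a polynomial term set at q (matrix n x n_dofs, columns matching
# geometry$dofs)
poly_eval <- function(coeffs, powers, q) {
  out <- numeric(nrow(q))
  for (j in seq_along(coeffs)) {
    term <- rep(coeffs[j], nrow(q))
    for (k in seq_len(ncol(powers))) {
      p <- powers[j, k]
      if (p > 0) term <- term * q[, k]^p
    }
    out <- out + term
  }
  out
}

# derivative of the polynomial with respect to its k-th local DOF
poly_deriv_eval <- function(coeffs, powers, q, k) {
  out <- numeric(nrow(q))
  for (j in seq_along(coeffs)) {
    p <- powers[j, k]
    if (p == 0) next
    term <- rep(coeffs[j] * p, nrow(q))
    for (kk in seq_len(ncol(powers))) {
      pw <- powers[j, kk] - (kk == k)
      if (pw > 0) term <- term * q[, kk]^pw
    }
    out <- out + term
  }
  out
}

#' Limb model
#'
#' A set of degrees of freedom with angular ranges, plus one
#' ([muscle_params()], [mtu_geometry()]) pair per MTU and optional per-DOF
#' reserve-moment caps.
#'
#' @param dofs List of [dof_spec()] objects.
#' @param mtus List of `list(params = muscle_params, geometry =
#'   mtu_geometry)`.
#' @param reserve_caps Optional named numeric vector of per-DOF maximal
#'   reserve moments (N m); `NA` entries are resolved per trial by the
#'   redundancy solver.
#' @return A `limb_model` object.
#' @export
limb_model <- function(dofs, mtus, reserve_caps = NULL) {
  dof_names <- vapply(dofs, `[[`, character(1), "name")
  if (anyDuplicated(dof_names)) stop("duplicated DOF names")
  for (mtu in mtus) {
    g <- mtu$geometry
    if (length(g$dofs) < 1) stop("every MTU must couple at least one DOF")
    if (!all(g$dofs %in% dof_names)) {
      stop(sprintf("MTU '%s' references unknown DOFs", g$muscle))
    }
    if (!identical(g$muscle, mtu$params$name)) {
      stop("geometry and params names disagree for an MTU")
    }
  }
  if (is.null(reserve_caps)) {
    reserve_caps <- setNames(rep(NA_real_, length(dof_names)), dof_names)
  }
  if (any(!is.na(reserve_caps) & reserve_caps < 0)) {
    stop("reserve caps must be non-negative")
  }
  model <- structure(list(dofs = dofs, mtus = mtus,
                          reserve_caps = reserve_caps), class = "limb_model")
  # positivity of l_MT over the DOF box, checked on a coarse probe
  probe <- pose_grid_probe(model)
  if (any(mtu_length(model, probe) <= 0)) {
    stop("l_MT(q) must be strictly positive over the DOF box")
  }
  model
}

pose_grid_probe <- function(model, n_random = 64) {
  rng <- dof_ranges(model)
  corners <- as.matrix(expand.grid(lapply(seq_len(nrow(rng)), function(i) {
    c(rng[i, 1], rng[i, 2])
  })))
  if (nrow(rng) > 6) corners <- corners[seq_len(64), , drop = FALSE]
  rand <- with_preserved_rng(20260101, {
    sapply(seq_len(nrow(rng)), function(i) {
      runif(n_random, rng[i, 1], rng[i, 2])
    })
  })
  q <- rbind(corners, matrix(rand, ncol = nrow(rng)))
  colnames(q) <- rownames(rng)
  q
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_preserved_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' @export
print.limb_model <- function(x, ...) {
  cat(sprintf("Limb model: %d DOFs, %d MTUs\n",
              length(x$dofs), length(x$mtus)))
  for (d in x$dofs) {
    cat(sprintf("  %s [%.1f, %.1f] deg (%s)\n", d$name,
                d$range_min * 180 / pi, d$range_max * 180 / pi, d$kind))
  }
  cat("  MTUs:", paste(limb_mtu_names(x), collapse = ", "), "\n")
  invisible(x)
}

limb_mtu_names <- function(model) {
  vapply(model$mtus, function(m) m$params$name, character(1))
}

limb_dof_names <- function(model) {
  vapply(model$dofs, `[[`, character(1), "name")
}

dof_ranges <- function(model) {
  rng <- t(vapply(model$dofs, function(d) {
    c(d$range_min, d$range_max)
  }, numeric(2)))
  rownames(rng) <- limb_dof_names(model)
  colnames(rng) <- c("min", "max")
  rng
}

# coerce q to a pose matrix with named columns and check the expanded box
check_pose <- function(model, q, expand = 0.1) {
  dn <- limb_dof_names(model)
  if (is.null(dim(q))) q <- matrix(q, nrow = 1)
  if (ncol(q) != length(dn)) {
    stop(sprintf("pose must have %d columns (one per DOF)", length(dn)))
  }
  if (is.null(colnames(q))) colnames(q) <- dn
  q <- q[, dn, drop = FALSE]
  rng <- dof_ranges(model)
  span <- rng[, 2] - rng[, 1]
  lo <- rng[, 1] - expand * span
  hi <- rng[, 2] + expand * span
  bad <- sweep(q, 2, lo, "<") | sweep(q, 2, hi, ">")
  if (any(bad)) {
    stop("pose outside the expanded DOF box (ranges +/- 10%)")
  }
  q
}

#' MTU lengths at a pose
#'
#' Evaluates every MTU's length polynomial at the supplied joint angles.
#'
#' @param model A [limb_model()].
#' @param q Joint angles (rad): a vector (one pose) or a matrix with one
#'   row per pose and one column per DOF (in model DOF order, or with
#'   matching column names). Poses must lie within the DOF box expanded by
#'   10% of each range.
#' @return Matrix of MTU lengths (m), poses in rows, MTUs in columns.
#' @export
mtu_length <- function(model, q) {
  q <- check_pose(model, q)
  dn <- limb_dof_names(model)
  out <- matrix(NA_real_, nrow(q), length(model$mtus),
                dimnames = list(NULL, limb_mtu_names(model)))
  for (i in seq_along(model$mtus)) {
    g <- model$mtus[[i]]$geometry
    out[, i] <- poly_eval(g$coeffs, g$powers,
                          q[, match(g$dofs, dn), drop = FALSE])
  }
  out
}

#' Moment arms at a pose
#'
#' Moment arms from tendon excursion: \eqn{r_{m,k} = -\partial l_{MT,m} /
#' \partial q_k}, evaluated analytically from the length polynomial
#' (or from an MTU's override arm polynomial when one is present).
#' Arms about DOFs an MTU does not cross are exactly zero.
#'
#' @inheritParams mtu_length
#' @return Array `n_poses x n_mtus x n_dofs` of moment arms (m).
#' @export
moment_arms <- function(model, q) {
  q <- check_pose(model, q)
  dn <- limb_dof_names(model)
  mn <- limb_mtu_names(model)
  out <- array(0, dim = c(nrow(q), length(mn), length(dn)),
               dimnames = list(NULL, mn, dn))
  for (i in seq_along(model$mtus)) {
    g <- model$mtus[[i]]$geometry
    qi <- q[, match(g$dofs, dn), drop = FALSE]
    for (k in seq_along(g$dofs)) {
      kk <- match(g$dofs[k], dn)
      if (!is.null(g$arm_coeffs)) {
        ak <- g$arm_coeffs[[k]]
        out[, i, kk] <- poly_eval(ak$coeffs,
                                  matrix(ak$powers, nrow = length(ak$coeffs)),
                                  qi)
      } else {
        out[, i, kk] <- -poly_deriv_eval(g$coeffs, g$powers, qi, k)
      }
    }
  }
  out
}

#' Verify moment arms against tendon excursion
#'
#' Samples random poses and compares the model's moment arms with central
#' finite differences of MTU length. For a purely polynomial geometry the
#' two are identical up to truncation error; a discrepancy flags an
#' inconsistent (e.g. corrupted or separately imported) arm description.
#'
#' @param model A [limb_model()].
#' @param n_samples Number of random poses.
#' @param seed RNG seed.
#' @param step Finite-difference step (rad).
#' @param tol Flag threshold on the maximum absolute discrepancy (m).
#' @return Data frame with one row per MTU: maximum absolute discrepancy
#'   and a logical `flagged`.
#' @export
check_tendon_excursion <- function(model, n_samples = 50, seed = 1,
                                   step = 1e-5, tol = 1e-6) {
  set.seed(seed)
  rng <- dof_ranges(model)
  q <- sapply(seq_len(nrow(rng)), function(i) {
    runif(n_samples, rng[i, 1], rng[i, 2])
  })
  q <- matrix(q, ncol = nrow(rng), dimnames = list(NULL, rownames(rng)))
  arms <- moment_arms(model, q)
  worst <- setNames(numeric(length(model$mtus)), limb_mtu_names(model))
  for (k in seq_along(model$dofs)) {
    qp <- q; qp[, k] <- qp[, k] + step
    qm <- q; qm[, k] <- qm[, k] - step
    fd <- -(mtu_length(model, qp) - mtu_length(model, qm)) / (2 * step)
    dev <- abs(fd - arms[, , k])
    worst <- pmax(worst, apply(dev, 2, max))
  }
  data.frame(mtu = names(worst), max_discrepancy_m = as.numeric(worst),
             flagged = as.numeric(worst) > tol, row.names = NULL)
}

# --- serialization ---------------------------------------------------------

#' Write / read a limb model
#'
#' The on-disk format is JSON. Numeric values are encoded as decimal
#' strings with 17 significant digits, which round-trip IEEE doubles
#' exactly, so a save/load cycle reproduces every evaluation
#' bit-identically. Angles are stored in degrees and lengths in
#' millimetres (declared in the file header block); polynomial
#' coefficients are stored in internal SI/rad units verbatim.
#'
#' @param model A [limb_model()].
#' @param path File path.
#' @return `write_limb_model` returns `path` invisibly; `read_limb_model`
#'   returns a [limb_model()].
#' @export
write_limb_model <- function(model, path) {
  enc <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  obj <- list(
    format = "fibreops-limb-model",
    units = list(angle = "deg", length = "mm", mass = "g",
                 note = paste("polynomial coefficients are SI (m, rad);",
                              "numbers are exact decimal strings")),
    dofs = lapply(model$dofs, function(d) list(
      name = d$name, range_min_deg = enc(d$range_min * 180 / pi),
      range_max_deg = enc(d$range_max * 180 / pi), kind = d$kind)),
    reserve_caps_Nm = lapply(as.list(model$reserve_caps), enc),
    mtus = lapply(model$mtus, function(m) {
      p <- m$params; g <- m$geometry
      list(name = p$name, mass_g = enc(p$m * 1e3),
           fibre_length_mm = enc(p$ell_o * 1e3),
           slack_length_mm = enc(p$L_S * 1e3),
           pennation_deg = enc(p$alpha_o * 180 / pi),
           fmax_N = enc(p$F_max),
           k_T = enc(p$k_T), v_max = enc(p$v_max),
           tau_act_s = enc(p$tau_act), tau_deact_s = enc(p$tau_deact),
           dofs = g$dofs, coeffs = enc(g$coeffs),
           powers = enc(as.vector(g$powers)),
           arm_coeffs = if (is.null(g$arm_coeffs)) NULL else {
             lapply(g$arm_coeffs, function(a) {
               list(coeffs = enc(a$coeffs), powers = enc(a$powers))
             })
           })
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_limb_model
#' @export
read_limb_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (!identical(obj$format, "fibreops-limb-model")) {
    stop("not a fibreops limb-model file")
  }
  dec <- function(x) as.numeric(unlist(x))
  dofs <- lapply(obj$dofs, function(d) {
    dof_spec(d$name, dec(d$range_min_deg) * pi / 180,
             dec(d$range_max_deg) * pi / 180, d$kind)
  })
  mtus <- lapply(obj$mtus, function(m) {
    coeffs <- dec(m$coeffs)
    dofn <- unlist(m$dofs)
    params <- muscle_params(m$name, dec(m$mass_g) * 1e-3,
                            dec(m$fibre_length_mm) * 1e-3,
                            dec(m$slack_length_mm) * 1e-3,
                            dec(m$pennation_deg) * pi / 180,
                            F_max = dec(m$fmax_N), k_T = dec(m$k_T),
                            v_max = dec(m$v_max),
                            tau_act = dec(m$tau_act_s),
                            tau_deact = dec(m$tau_deact_s))
    arm_coeffs <- m$arm_coeffs
    if (!is.null(arm_coeffs)) {
      arm_coeffs <- lapply(arm_coeffs, function(a) {
        list(coeffs = dec(a$coeffs), powers = dec(a$powers))
      })
    }
    list(params = params,
         geometry = mtu_geometry(m$name, dofn, coeffs,
                                 matrix(dec(m$powers),
                                        nrow = length(coeffs),
                                        ncol = length(dofn)),
                                 arm_coeffs = arm_coeffs))
  })
  caps <- vapply(obj$reserve_caps_Nm, function(x) {
    if (is.null(x) || identical(x, "NA")) NA_real_ else as.numeric(x)
  }, numeric(1))
  names(caps) <- names(obj$reserve_caps_Nm)
  limb_model(dofs, mtus, reserve_caps = caps)
}

# --- gait trials -----------------------------------------------------------

#' Gait trial container
#'
#' Time series of joint angles and external joint moments for one
#' locomotor trial, with MTU lengths and moment arms either supplied
#' explicitly or derived from a limb model (explicit columns win, so
#' externally computed muscle analyses can be imported).
#'
#' @param time Time grid (s), strictly increasing.
#' @param q Joint angles (rad), matrix `n x n_dof` with DOF-named columns.
#' @param M_ext External joint moments (N m), matrix `n x n_dof`.
#' @param model Optional [limb_model()] used to derive `lmt`/`arms`.
#' @param lmt Optional explicit MTU lengths (m), `n x n_mtu`.
#' @param arms Optional explicit moment arms (m), `n x n_mtu x n_dof`.
#' @param label Trial label (e.g. `"walk"`).
#' @param duty_factor Optional duty factor (stance fraction of the stride).
#' @return A `gait_trial` object.
#' @export
gait_trial <- function(time, q, M_ext, model = NULL, lmt = NULL,
                       arms = NULL, label = "trial", duty_factor = NA) {
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  q <- as.matrix(q); M_ext <- as.matrix(M_ext)
  if (nrow(q) != length(time) || nrow(M_ext) != length(time)) {
    stop("q and M_ext must have one row per time sample")
  }
  if (is.null(lmt) || is.null(arms)) {
    if (is.null(model)) {
      stop("either a limb model or explicit lmt and arms must be supplied")
    }
    if (is.null(lmt)) lmt <- mtu_length(model, q)
    if (is.null(arms)) arms <- moment_arms(model, q)
  }
  structure(list(time = time, q = q, M_ext = M_ext, lmt = lmt, arms = arms,
                 label = label, duty_factor = duty_factor),
            class = "gait_trial")
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf(
    "Gait trial '%s': %d samples over %.3g s, %d DOFs, %d MTUs%s\n",
    x$label, length(x$time), diff(range(x$time)), ncol(x$q), ncol(x$lmt),
    if (is.na(x$duty_factor)) "" else
      sprintf(", duty factor %.2f", x$duty_factor)))
  invisible(x)
}

#' Write / read a gait trial as CSV
#'
#' Columns follow the convention `time_s`, `q_<dof>_deg`, `M_<dof>_Nm`,
#' plus optional `lmt_<mtu>_mm` and `r_<mtu>_<dof>_mm` columns carrying
#' the muscle analysis.
#'
#' @param trial A [gait_trial()].
#' @param path File path.
#' @param model Optional [limb_model()] for deriving `lmt`/`arms` when the
#'   file does not carry them.
#' @param label,duty_factor Metadata for the loaded trial.
#' @return `write_gait_trial` returns `path` invisibly; `read_gait_trial`
#'   returns a [gait_trial()].
#' @export
write_gait_trial <- function(trial, path) {
  df <- data.frame(time_s = trial$time)
  for (j in colnames(trial$q)) {
    df[[paste0("q_", j, "_deg")]] <- trial$q[, j] * 180 / pi
  }
  for (j in colnames(trial$M_ext)) {
    df[[paste0("M_", j, "_Nm")]] <- trial$M_ext[, j]
  }
  for (m in colnames(trial$lmt)) {
    df[[paste0("lmt_", m, "_mm")]] <- trial$lmt[, m] * 1e3
  }
  mn <- dimnames(trial$arms)[[2]]; dn <- dimnames(trial$arms)[[3]]
  for (m in seq_along(mn)) for (k in seq_along(dn)) {
    if (any(trial$arms[, m, k] != 0)) {
      df[[paste0("r_", mn[m], "_", dn[k], "_mm")]] <-
        trial$arms[, m, k] * 1e3
    }
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gait_trial
#' @export
read_gait_trial <- function(path, model = NULL, label = NULL,
                            duty_factor = NA) {
  df <- read.csv(path, check.names = FALSE)
  time <- df$time_s
  qn <- grep("^q_.*_deg$", names(df), value = TRUE)
  dofs <- sub("^q_(.*)_deg$", "\\1", qn)
  q <- as.matrix(df[qn]) * pi / 180
  colnames(q) <- dofs
  mn_cols <- grep("^M_.*_Nm$", names(df), value = TRUE)
  M <- as.matrix(df[mn_cols])
  colnames(M) <- sub("^M_(.*)_Nm$", "\\1", mn_cols)
  M <- M[, dofs, drop = FALSE]
  lmt_cols <- grep("^lmt_.*_mm$", names(df), value = TRUE)
  lmt <- NULL; arms <- NULL
  if (length(lmt_cols)) {
    mtus <- sub("^lmt_(.*)_mm$", "\\1", lmt_cols)
    lmt <- as.matrix(df[lmt_cols]) * 1e-3
    colnames(lmt) <- mtus
    arms <- array(0, dim = c(nrow(df), length(mtus), length(dofs)),
                  dimnames = list(NULL, mtus, dofs))
    for (m in mtus) for (k in dofs) {
      col <- paste0("r_", m, "_", k, "_mm")
      if (col %in% names(df)) arms[, m, k] <- df[[col]] * 1e-3
    }
  }
  if (is.null(label)) {
    label <- sub("\\.csv$", "", basename(path))
  }
  gait_trial(time, q, M, model = model, lmt = lmt, arms = arms,
             label = label, duty_factor = duty_factor)
}
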