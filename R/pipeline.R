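# End-to-end orchestration of the synthetic study: generate limb and
# trials, solve the multi-trial redundancy problem with tuning, run the
# static posture battery, and analyze fibre operating ranges. Every run
# writes its resolved configuration, a manifest with file hashes, and
# per-stage timings beside its outputs, so runs are reproducible and
# auditable.

#' Pipeline run configuration
#'
#' Builds and validates the configuration for [run_pipeline()]. Defaults
#' mirror the study conditions: two trials (walk and run), 100 mesh
#' intervals, 5,000 battery poses. Validation happens here, before any
#' compute.
#'
#' @param seed Master seed; stage seeds derive from it.
#' @param n_dof,n_mtu Toy limb dimensions.
#' @param n_samples Samples per stride.
#' @param noise_sd Moment noise (N m).
#' @param mesh Collocation mesh intervals (>= 10).
#' @param weights An [objective_weights()] or list of overrides.
#' @param tuning_bounds Bounds on the tuning factors.
#' @param n_poses Battery pose count.
#' @param lmt_caps Named vector of per-MTU MTU-length caps (m) for filter
#'   rule iii.
#' @param region_boundaries Force-length region boundaries.
#' @param sims Integer subset of simulations 1:4 to run.
#' @param battery_overrides Named vector of fixed DOF angles (rad) for
#'   pose sampling; `"from_trials"` fixes nothing here and instead holds
#'   non-primary DOFs at their mean trial angles (only meaningful for
#'   limbs with more DOFs than the battery should vary).
#' @return A validated `run_config` (list).
#' @export
run_config <- function(seed = 1, n_dof = 2, n_mtu = 2 * n_dof,
                       n_samples = 101, noise_sd = 0, mesh = 100,
                       weights = objective_weights(),
                       tuning_bounds = c(0.5, 2),
                       n_poses = 5000, lmt_caps = NULL,
                       region_boundaries = c(0.80, 0.95, 1.05),
                       sims = 1:4, battery_overrides = NULL,
                       solver_control = list()) {
  if (is.list(weights) && !inherits(weights, "objective_weights")) {
    weights <- do.call(objective_weights, weights)
  }
  if (mesh < 10) stop("config invalid: mesh must be at least 10")
  if (n_poses < 1) stop("config invalid: n_poses must be >= 1")
  if (!all(sims %in% 1:4)) stop("config invalid: sims must be within 1:4")
  if (length(tuning_bounds) != 2 || tuning_bounds[1] >= tuning_bounds[2] ||
      tuning_bounds[1] <= 0) {
    stop("config invalid: tuning bounds must be positive and increasing")
  }
  structure(list(seed = seed, n_dof = n_dof, n_mtu = n_mtu,
                 n_samples = n_samples, noise_sd = noise_sd, mesh = mesh,
                 weights = weights, tuning_bounds = tuning_bounds,
                 n_poses = n_poses, lmt_caps = lmt_caps,
                 region_boundaries = region_boundaries, sims = sims,
                 battery_overrides = battery_overrides,
                 solver_control = solver_control),
            class = "run_config")
}

#' Write / read a run configuration (YAML)
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns a validated [run_config()].
#' @export
write_run_config <- function(config, path) {
  obj <- unclass(config)
  obj$weights <- unclass(obj$weights)
  # explicit lists so YAML keeps the names of length-1 vectors
  if (!is.null(obj$lmt_caps)) obj$lmt_caps <- as.list(obj$lmt_caps)
  if (!is.null(obj$battery_overrides)) {
    obj$battery_overrides <- as.list(obj$battery_overrides)
  }
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  obj$weights <- do.call(objective_weights, obj$weights)
  if (!is.null(obj$lmt_caps)) obj$lmt_caps <- unlist(obj$lmt_caps)
  if (!is.null(obj$battery_overrides)) {
    obj$battery_overrides <- unlist(obj$battery_overrides)
  }
  do.call(run_config, obj)
}

#' Run the full synthetic pipeline
#'
#' Executes the four stages in order -- synthesize, tune, battery,
#' analyze -- writing each stage's outputs (CSV/JSON), the resolved
#' configuration (YAML) and a manifest with MD5 hashes and per-stage
#' timings under `out_dir`. A stage failure aborts with the stage name;
#' outputs of completed stages are preserved.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_run_config(config, file.path(out_dir, "config_resolved.yaml"))
  stage_times <- list()
  outputs <- character(0)
  add_output <- function(...) outputs <<- c(outputs, ...)
  say <- function(...) if (!quiet) message(sprintf(...))
  run_stage <- function(name, expr) {
    say("pipeline stage: %s", name)
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    stage_times[[name]] <<- proc.time()[["elapsed"]] - t0
    res
  }

  bundle <- run_stage("synth", {
    b <- make_synthetic_bundle(config$n_dof, config$n_mtu,
                               seed = config$seed,
                               noise_sd = config$noise_sd,
                               n_samples = config$n_samples)
    write_limb_model(b$limb, file.path(out_dir, "limb_model.json"))
    for (nm in names(b$trials)) {
      write_gait_trial(b$trials[[nm]],
                       file.path(out_dir, sprintf("trial_%s.csv", nm)))
      truth_df <- data.frame(time_s = b$trials[[nm]]$time,
                             b$truth[[nm]]$activations)
      write.csv(truth_df,
                file.path(out_dir, sprintf("ground_truth_%s.csv", nm)),
                row.names = FALSE)
    }
    add_output("limb_model.json",
               sprintf("trial_%s.csv", names(b$trials)),
               sprintf("ground_truth_%s.csv", names(b$trials)))
    b
  })

  solution <- run_stage("tune", {
    sol <- solve_redundancy(bundle$trials, bundle$limb,
                            weights = config$weights, mesh = config$mesh,
                            tuning_bounds = config$tuning_bounds,
                            control = config$solver_control)
    meta <- list(objective = sol$objective,
                 objective_parts = as.list(sol$objective_parts),
                 tuning = lapply(sol$tuning, as.list),
                 convergence = sol$convergence,
                 max_defect = sol$max_defect, mesh = sol$mesh)
    jsonlite::write_json(meta, file.path(out_dir, "solution_meta.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (nm in names(sol$trials)) {
      tr <- sol$trials[[nm]]
      df <- data.frame(time_s = tr$time, t(tr$activation))
      names(df) <- c("time_s", paste0("a_", rownames(tr$activation)))
      write.csv(df, file.path(out_dir,
                              sprintf("solution_activation_%s.csv", nm)),
                row.names = FALSE)
    }
    add_output("solution_meta.json",
               sprintf("solution_activation_%s.csv", names(sol$trials)))
    sol
  })

  battery <- run_stage("battery", {
    poses <- sample_poses(bundle$limb, config$n_poses,
                          seed = config$seed + 10L,
                          overrides = config$battery_overrides)
    parts <- list()
    if (1 %in% config$sims) {
      parts <- c(parts, list(run_min_max_activation(poses, bundle$limb,
                                                    "min",
                                                    seed = config$seed)))
    }
    if (2 %in% config$sims) {
      parts <- c(parts, list(run_min_max_activation(poses, bundle$limb,
                                                    "max",
                                                    seed = config$seed)))
    }
    if (3 %in% config$sims) {
      parts <- c(parts, list(run_isolated_muscle(poses, bundle$limb, 0)))
    }
    if (4 %in% config$sims) {
      parts <- c(parts, list(run_isolated_muscle(poses, bundle$limb, 1)))
    }
    bat <- do.call(combine_batteries, parts)
    bat <- filter_viable(bat, config$lmt_caps)
    write.csv(bat$records, file.path(out_dir, "battery_records.csv"),
              row.names = FALSE)
    jsonlite::write_json(list(counts = bat$counts, seed = poses$seed),
                         file.path(out_dir, "battery_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    add_output("battery_records.csv", "battery_summary.json")
    bat
  })

  analysis <- run_stage("analyze", {
    rs <- operating_range_summary(battery, solutions = list(solution),
                                  boundaries = config$region_boundaries)
    write.csv(rs$summary, file.path(out_dir, "range_summary.csv"),
              row.names = FALSE)
    write.csv(rs$histogram, file.path(out_dir, "lstar_histogram.csv"),
              row.names = FALSE)
    params <- lapply(bundle$limb$mtus, `[[`, "params")
    reg <- tryCatch(decoupling_regression(rs, params),
                    error = function(e) NULL)
    if (!is.null(reg)) {
      write.csv(reg, file.path(out_dir, "decoupling_regression.csv"),
                row.names = FALSE)
      add_output("decoupling_regression.csv")
    }
    fits <- hyperplane_fits_by_mtu(battery, bundle$limb)
    write.csv(fits, file.path(out_dir, "hyperplane_fits.csv"),
              row.names = FALSE)
    add_output("range_summary.csv", "lstar_histogram.csv",
               "hyperplane_fits.csv")
    list(ranges = rs, regression = reg, fits = fits)
  })

  paths <- file.path(out_dir, outputs)
  manifest <- list(
    outputs = data.frame(file = outputs,
                         md5 = unname(tools::md5sum(paths))),
    stage_seconds = stage_times,
    config = "config_resolved.yaml")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("pipeline complete: %d outputs in %s", length(outputs), out_dir)
  invisible(list(bundle = bundle, solution = solution, battery = battery,
                 analysis = analysis, manifest = manifest))
}

#' Per-MTU hyperplane fits from a battery
#'
#' Fits [hyperplane_fit()] of normalized fibre length against the joint
#' angles each MTU crosses, separately for the whole-limb pair
#' (simulations 1 and 2) and the isolated pair (simulations 3 and 4).
#'
#' @param battery A filtered `pose_battery`.
#' @param limb The [limb_model()] the battery was run on.
#' @return Data frame: one row per MTU and simulation pair, with `r2`,
#'   `rmse`, `eps_max` and `n`.
#' @export
hyperplane_fits_by_mtu <- function(battery, limb) {
  rec <- battery$records[battery$records$viable, ]
  dn <- limb_dof_names(limb)
  rows <- list()
  for (i in seq_along(limb$mtus)) {
    g <- limb$mtus[[i]]$geometry
    mtu <- g$muscle
    for (pair in list(c(1, 2), c(3, 4))) {
      sub <- rec[rec$mtu == mtu & rec$sim %in% pair &
                   is.finite(rec$lstar), ]
      if (nrow(sub) < length(g$dofs) + 1) next
      q <- battery$poses$q[sub$pose, g$dofs, drop = FALSE]
      fit <- hyperplane_fit(sub$lstar, q)
      rows[[length(rows) + 1]] <- data.frame(
        mtu = mtu, pair = paste(pair, collapse = "-"),
        r2 = as.numeric(fit$r2), rmse = fit$rmse,
        eps_max = fit$eps_max, n = fit$n_obs)
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
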