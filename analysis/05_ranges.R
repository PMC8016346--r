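#!/usr/bin/env Rscript
# Fibre operating-range analysis: per-MTU viable ranges of normalized
# fibre length, force-length region occupancy, hyperplane linearity fits
# of fibre length against joint angles, and the decoupling of fibre from
# MTU length change by pennation and relative tendon length.

library(fibreops)

sim_dir <- file.path("results", "02_simulate")
bat_dir <- file.path("results", "04_battery")
out_dir <- file.path("results", "05_ranges")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
if (!file.exists(file.path(bat_dir, "battery_records.csv"))) {
  stop("run analysis/04_battery.R first")
}

limb <- read_limb_model(file.path(sim_dir, "limb_model.json"))
records <- read.csv(file.path(bat_dir, "battery_records.csv"))
poses_q <- as.matrix(read.csv(file.path(bat_dir, "poses.csv")))
params <- lapply(limb$mtus, `[[`, "params")
bat <- fibreops:::new_pose_battery(records,
                                   structure(list(q = poses_q),
                                             class = "pose_set"),
                                   limb, sims = sort(unique(records$sim)))
bat <- filter_viable(bat)

rs <- operating_range_summary(bat)
cat("per-MTU viable operating ranges (normalized fibre length):\n")
print(rs$summary[, c("mtu", "lstar_min", "lstar_max", "range_ratio")],
      row.names = FALSE)

reg <- decoupling_regression(rs, params)
cat("\nfibre/MTU range decoupling regressions:\n")
print(reg, row.names = FALSE)

fits <- hyperplane_fits_by_mtu(bat, limb)
cat("\nhyperplane linearity of fibre length vs joint angles:\n")
print(fits, row.names = FALSE)

write.csv(rs$summary, file.path(out_dir, "range_summary.csv"),
          row.names = FALSE)
write.csv(rs$histogram, file.path(out_dir, "lstar_histogram.csv"),
          row.names = FALSE)
write.csv(reg, file.path(out_dir, "decoupling_regression.csv"),
          row.names = FALSE)
write.csv(fits, file.path(out_dir, "hyperplane_fits.csv"),
          row.names = FALSE)
cat(sprintf("\nwritten: %s\n", out_dir))
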