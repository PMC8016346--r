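#!/usr/bin/env Rscript
# Static posture battery over the synthetic limb: sample random poses
# across the full joint ranges and run the four static simulations
# (whole-limb minimum and maximum activation; each MTU isolated at
# activation 0 and 1), then apply the viability filters.

library(fibreops)

in_dir <- file.path("results", "02_simulate")
out_dir <- file.path("results", "04_battery")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
if (!file.exists(file.path(in_dir, "limb_model.json"))) {
  stop("run analysis/02_simulate.R first")
}
limb <- read_limb_model(file.path(in_dir, "limb_model.json"))

n_poses <- 5000
poses <- sample_poses(limb, n_poses, seed = 11)
bat <- combine_batteries(
  run_min_max_activation(poses, limb, "min", seed = 1),
  run_min_max_activation(poses, limb, "max", seed = 1),
  run_isolated_muscle(poses, limb, 0),
  run_isolated_muscle(poses, limb, 1))
bat <- filter_viable(bat)
print(bat)
cat("viable poses per simulation pair:\n")
print(bat$counts, row.names = FALSE)
tab <- table(bat$records$reason[!bat$records$viable])
if (length(tab)) {
  cat("inviability reasons (record level):\n")
  print(tab)
}

write.csv(bat$records, file.path(out_dir, "battery_records.csv"),
          row.names = FALSE)
write.csv(data.frame(poses$q), file.path(out_dir, "poses.csv"),
          row.names = FALSE)
write.csv(bat$counts, file.path(out_dir, "viable_counts.csv"),
          row.names = FALSE)
cat(sprintf("written: %s\n", out_dir))
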