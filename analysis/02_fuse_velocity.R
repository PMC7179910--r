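#!/usr/bin/env Rscript
# Build True Velocity from censored GPS fixes, screen accelerometers for
# malfunction, train the random-forest velocity model, and fuse the True
# and Predicted streams into Velocity Combined.

library(lunardiel)

seed <- 20160420
ds <- read_dataset("results/data")

tv <- track_velocities(censor_fixes(ds$gps))
cat("True Velocity records after censoring:", nrow(tv), "\n")

tab <- build_training_table(tv, ds$accel)
flags <- detect_accel_malfunction(tab)
print(flags)
bad <- flags$individual_id[!is.na(flags$flagged) & flags$flagged]
cat("censored from training:", paste(bad, collapse = ", "), "\n")

tab_ok <- tab[!tab$individual_id %in% bad, ]
model <- fit_velocity_model(tab_ok, n_trees = 1000, seed = seed)
print(model)

species_map <- with(ds$gps[!duplicated(ds$gps$individual_id), ],
  setNames(as.character(species), individual_id))
accel_ok <- ds$accel[!ds$accel$individual_id %in% bad, ]
pred <- predict_velocity(model, accel_ok, species = species_map)
val <- validate_prediction(tv, pred)
cat(sprintf(
  "validation: slope %.3f, R2 %.4f, BP = %.2f (p = %.2g, df = %d)\n",
  val$slope, val$r_squared, val$bp_statistic, val$bp_p_value, val$bp_df))

# does the activity-velocity relationship depend on anything it should not?
key <- match(paste(tv$individual_id, as.numeric(tv$interval_end)),
  paste(pred$individual_id, as.numeric(pred$interval_end)))
ok <- !is.na(key)
cat(sprintf("added variance from a Species interaction: %.3f%%\n",
  interaction_check(tv$velocity[ok], pred$velocity[key[ok]],
    factor(tv$species[ok]))))

vc <- combine_velocity(tv, pred)
cat("Velocity Combined:", nrow(vc), "records (",
  sum(vc$type == "True"), "True /", sum(vc$type == "Predicted"),
  "Predicted )\n")
vc$interval_end <- iso8601_utc(vc$interval_end)
write.csv(vc, "results/velocity_combined.csv", row.names = FALSE)
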