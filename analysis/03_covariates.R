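#!/usr/bin/env Rscript
# Attach ephemeris and weather covariates, categorize every record into
# diel / moon-phase / lunar-diel / season levels, and summarize velocity
# by 10-degree sun-angle bins.

library(lunardiel)

ds <- read_dataset("results/data")
vc <- read.csv("results/velocity_combined.csv")
vc$interval_end <- parse_iso8601_utc(vc$interval_end)
stopifnot(!anyNA(vc$interval_end))

at <- build_analysis_table(vc, ds$weather, lon = -97.44, lat = 26.54)
out <- at
out$timestamp <- iso8601_utc(out$timestamp)
out$local_date <- as.character(out$local_date)
write.csv(out, "results/analysis_table.csv", row.names = FALSE)

cat("analysis records:", nrow(at), "\n")
print(table(at$Species, at$LunarDiel))
print(table(at$Species, at$Season))

prof <- sun_angle_profile(at)
write.csv(prof, "results/sun_angle_profile.csv", row.names = FALSE)
used <- prof[prof$n > 0, ]
cat("\nmean velocity by sun-angle sign (per species, True records):\n")
print(with(used[used$type == "True", ], tapply(mean_velocity,
  list(species, ifelse(bin_hi <= 0, "night-side", "day-side")),
  mean, na.rm = TRUE)))
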