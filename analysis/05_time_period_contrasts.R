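#!/usr/bin/env Rscript
# Fit the final interactive LunarDiel x Season x Species model and
# compare time periods via estimated marginal means with Tukey-adjusted
# pairwise contrasts: (1) between time periods within species, and
# (2) between species within a time period.

library(lunardiel)

at <- read.csv("results/analysis_table.csv")
at$interval_end <- parse_iso8601_utc(at$timestamp)
stopifnot(!anyNA(at$interval_end))
for (v in c("LunarDiel", "Season", "Species", "type"))
  at[[v]] <- factor(at[[v]])

final <- fit_final_model(at)
print(final)
write.csv(final$coefficients, "results/coefficients.csv",
  row.names = FALSE)

specs <- intersect(c("LunarDiel", "Season", "Species"),
  names(final$xlev))
emm <- estimate_marginal_means(final, specs)
write.csv(as.data.frame(emm), "results/emmeans.csv", row.names = FALSE)
cat("\nestimated marginal means (95% CI):\n")
print(as.data.frame(emm), digits = 3)

within_species <- pairwise_contrasts(emm, by = "Species")
between_species <- pairwise_contrasts(emm,
  by = intersect(c("LunarDiel", "Season"), specs))
write.csv(within_species, "results/contrasts_time_periods.csv",
  row.names = FALSE)
write.csv(between_species, "results/contrasts_species.csv",
  row.names = FALSE)

cat("\nsignificant species differences within time periods:\n")
print(between_species[between_species$significant,
  setdiff(names(between_species), "significant")], digits = 3)
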