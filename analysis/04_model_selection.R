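#!/usr/bin/env Rscript
# Fit the 9 exploratory AR1 mixed models (continuous drivers) per
# species and rank them by AIC.

library(lunardiel)

at <- read.csv("results/analysis_table.csv")
at$interval_end <- parse_iso8601_utc(at$timestamp)
stopifnot(!anyNA(at$interval_end))

comparison <- do.call(rbind, lapply(split(at, at$species), function(d) {
  tab <- rank_aic(fit_candidates(d))
  tab$species <- d$species[1]
  tab
}))
rownames(comparison) <- NULL
write.csv(comparison, "results/model_comparison.csv", row.names = FALSE)

for (sp in unique(comparison$species)) {
  tab <- comparison[comparison$species == sp, ]
  cat("\n", sp, "model ranking:\n")
  print(tab[, c("model", "df", "AIC", "delta_AIC", "BIC", "logLik")],
    digits = 6)
  cat("top model:", tab$model[1], "(", tab$formula[1], ")\n")
}
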