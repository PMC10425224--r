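#!/usr/bin/env Rscript
# Minimal forward demonstration: the photosynthesis response curve as a
# daily stress multiplier on a potential-growth accumulator, waterlogging
# starting 15 days after sowing, assessed at day 30.

library(cottonwl)
dir.create("results", showWarnings = FALSE)

durations <- seq(0, 14, by = 2)
runs <- do.call(rbind, lapply(durations, function(d) {
  sched <- wl_schedule(duration = d, onset = 15, horizon = 30)
  data.frame(
    duration = d,
    relative_biomass = simulate_growth(sched)$relative_biomass,
    relative_biomass_anoxic_driver =
      simulate_growth(sched, driver = "anoxic_days")$relative_biomass)
}))
utils::write.csv(runs, "results/relative_biomass.csv", row.names = FALSE)
print(runs, row.names = FALSE, digits = 4)

cat("\nBiomass falls monotonically with waterlogging duration;",
    "driving stress by\nanoxic days (which lag elapsed days by the 5-day",
    "depletion time) is milder.\n")

sched5 <- wl_schedule(duration = 5, onset = 15, horizon = 30)
held <- simulate_growth(sched5)$relative_biomass
relaxed <- simulate_growth(sched5, recovery_days = 5)$relative_biomass
cat(sprintf("5-day treatment, post-release handling: factor held %.4f vs 5-day linear recovery %.4f\n",
            held, relaxed))
cat("wrote results/relative_biomass.csv\n")
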