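#!/usr/bin/env Rscript
# The packaged response-curve registry: load it, surface the rows whose
# printed coefficients needed interpretation, and export the canonical form.

library(cottonwl)
dir.create("results", showWarnings = FALSE)

reg <- load_registry()
cat("Loaded", length(reg$entries), "curves —", reg$version, "\n\n")
tab <- registry_report(reg)

# The re-oriented linear rows all carry stress-physiology intercepts near 1;
# NPQ's printed pair (0.051, 0.052) is anomalous either way and is kept as
# printed, flagged.
swapped <- tab$parameter_code[grepl("column_swapped", tab$flags)]
cat("\nLinear rows read as (intercept, slope):",
    paste(swapped, collapse = ", "), "\n")

write_registry(reg, "results/registry_canonical.csv")
cat("wrote results/registry_canonical.csv\n")
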