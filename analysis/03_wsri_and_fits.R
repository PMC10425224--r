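#!/usr/bin/env Rscript
# Compute WSRI from the synthetic replicate table and refit the response
# curves, both with the published family assignments and by free model
# selection; then check coefficient recovery from noiseless WSRI-space data.

library(cottonwl)
dir.create("results", showWarnings = FALSE)

tab <- read_treatment_table("results/synthetic_treatments.csv")
wsri <- compute_wsri(tab)
utils::write.csv(wsri, "results/wsri.csv", row.names = FALSE)
cat("WSRI table:", nrow(wsri), "cells; control indices all exactly 1:",
    all(wsri$index[wsri$duration == 0] == 1), "\n")

reg <- load_registry()
fits <- fit_wsri_table(wsri, mode = "published_families", registry = reg)
write_registry(fits, "results/fitted_curves.csv")

auto <- fit_wsri_table(wsri, mode = "auto_select", registry = reg)
fam_match <- vapply(names(auto), function(p)
  auto[[p]]$curve$family == reg$entries[[p]]$family, logical(1))
cat(sprintf("Free model selection matches the published family for %d/%d parameters\n",
            sum(fam_match), length(fam_match)))

# Noiseless WSRI-space recovery: the fitting stack returns every printed
# coefficient set; this is the package's core reproducibility claim.
recovery <- do.call(rbind, lapply(names(reg$entries), function(p) {
  truth <- reg$entries[[p]]
  fit <- fit_family(generate_wsri_points(p, noise_sd = 0), truth$family)
  data.frame(parameter_code = p, family = truth$family,
             max_abs_error = max(abs(fit$curve$coefficients -
                                       truth$coefficients)))
}))
utils::write.csv(recovery, "results/noiseless_recovery.csv",
                 row.names = FALSE)
cat(sprintf("Noiseless recovery: worst coefficient error %.2e (%s)\n",
            max(recovery$max_abs_error),
            recovery$parameter_code[which.max(recovery$max_abs_error)]))
cat("wrote results/wsri.csv, results/fitted_curves.csv, results/noiseless_recovery.csv\n")
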