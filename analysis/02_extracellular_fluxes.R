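#!/usr/bin/env Rscript
# Stage 2 — specific growth rates, glutamine degradation, and uptake /
# secretion fluxes from the simulated time courses, reported side by side
# with integer percent changes and the lactate/glucose ratio.

library(mfa13c)

seed <- 1L
tc <- read.delim("results/synthetic/timecourses.tsv")

exo <- fit_all_exchange_rates(tc, n_boot = 1000L, seed = seed)
message(sprintf("Growth rates: parental %.4f 1/h, FH-dim %.4f 1/h",
                exo$parental$mu$mu, exo$fhdim$mu$mu))
message(sprintf("Cell-free glutamine degradation: k = %.5f 1/h",
                exo$k_glutamine))

tab <- data.frame(
  metabolite = exo$parental$rates$metabolite,
  direction = exo$parental$rates$direction,
  parental = round(exo$parental$rates$flux, 1),
  parental_lb = round(exo$parental$rates$lb, 1),
  parental_ub = round(exo$parental$rates$ub, 1),
  fhdim = round(exo$fhdim$rates$flux[match(exo$parental$rates$metabolite,
                                           exo$fhdim$rates$metabolite)], 1),
  stringsAsFactors = FALSE)
cmp <- exchange_table(tab)
tab$percent_change <- cmp$table$percent_change
print(tab)
message(sprintf("Lactate/glucose flux ratio: parental %.2f, FH-dim %.2f",
                cmp$lactate_glucose_ratio["parental"],
                cmp$lactate_glucose_ratio["fhdim"]))

dir.create("results", showWarnings = FALSE)
write.table(tab, "results/exchange_fluxes.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
message("Wrote results/exchange_fluxes.tsv")
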