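#!/usr/bin/env Rscript
# Stage 5 — cofactor balances (NADH/NADPH/FADH2/ATP) and the pathway-
# attributed ATP production ledger for both conditions, compared
# side by side (difference and fold change per pathway row).

library(mfa13c)

fitted <- read.delim("results/fitted_fluxes.tsv")
scen <- make_scenario(seed = 1L)
stoich <- read_cofactor_table(model = scen$model)

ledgers <- list()
for (cn in c("parental", "fhdim")) {
  sub <- fitted[fitted$condition == cn, ]
  net <- stats::setNames(sub$net, sub$reaction)
  fl <- flux_vector(scen$model, net)
  bal <- cofactor_balance(fl, stoich)
  message(sprintf("%s net cofactor production (nmol/1e6 cells/h):", cn))
  for (cf in names(bal)) {
    message(sprintf("  %-6s %8.1f", cf, bal[[cf]]$net))
  }
  ledgers[[cn]] <- atp_production(fl, stoich)
  print(ledgers[[cn]])
}

tab <- ledger_report(ledgers$parental, ledgers$fhdim)
print(tab)
write.table(tab, "results/atp_ledger.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
message("Wrote results/atp_ledger.tsv")
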