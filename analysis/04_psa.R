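#!/usr/bin/env Rscript
# Probabilistic sensitivity analysis: 5000 second-order Monte Carlo
# iterations over the fitted parameter distributions, cost-effectiveness
# plane draws and the acceptability curve. Writes draws and CEAC tables.
# Usage: Rscript analysis/04_psa.R [iterations] [seed]

library(htncea)

args <- commandArgs(trailingOnly = TRUE)
n_iter <- if (length(args) >= 1) as.integer(args[1]) else 5000L
seed <- if (length(args) >= 2) as.integer(args[2]) else 1L

dir.create("results", showWarnings = FALSE)
cfg <- default_config()
lt <- read_life_table(system.file("extdata",
                                  "life_table_argentina_synthetic.csv",
                                  package = "htncea"))

cat(sprintf("Running PSA: %d iterations, seed %d ...\n", n_iter, seed))
psa <- run_psa(cfg, lt, n_iter = n_iter, seed = seed)
write_table(psa$draws, "results/psa_draws.csv")
cat(sprintf("Redraws for out-of-bound samples: %d\n", psa$redraws))

ceac <- compute_ceac(psa, cfg$wtp_grid)
write_table(ceac, "results/ceac.csv")

at_wtp <- compute_ceac(psa, cfg$params$wtp)$probability_cost_effective
cat(sprintf("Mean (dCost, dQALY): (%.1f, %.4f)\n",
            mean(psa$draws$delta_cost), mean(psa$draws$delta_qaly)))
cat(sprintf("P(cost-effective) at WTP INT$%d/QALY: %.3f\n",
            cfg$params$wtp, at_wtp))
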