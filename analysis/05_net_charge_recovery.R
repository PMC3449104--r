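#!/usr/bin/env Rscript
# Parameter recovery: reading the channel net charge off noisy
# reversal-potential data.
#
# Forward-simulates a selectivity campaign (20 gradient ratios, 1 mV
# measurement noise, salt-bridge junction contributions included), then
# fits a single charge-scale factor by least squares against the PNP model
# and compares the recovered net charge to the generating truth.

suppressPackageStartupMessages(library(pnporin))
dir.create("results", showWarnings = FALSE)

seed <- 20260901
sc <- scenario_spec("wt", "1:1-asymmetric", noise_sd = 1, seed = seed)
ratios <- seq(2, 10, length.out = 20)
design <- data.frame(C_cis = 0.1 * ratios, C_trans = 0.1, pH = 6)

dat <- simulate_experiment(sc, design, options = pnp_options(n_nodes = 151))
write.csv(dat, "results/recovery_dataset.csv", row.names = FALSE)

wt <- make_profile("wt")
asym <- make_salt_tables("1:1-asymmetric")
fit <- fit_net_charge(dat, wt, asym)

truth <- net_charge(wt)
out <- data.frame(seed = seed, n_ratios = length(ratios), noise_sd_mV = 1,
                  true_net_charge_e = round(truth, 4),
                  recovered_net_charge_e = round(fit$net_charge_e, 4),
                  scale = round(fit$scale, 4),
                  rel_err_pct = round(100 * abs(fit$net_charge_e - truth) /
                                        abs(truth), 2))
write.csv(out, "results/net_charge_recovery.csv", row.names = FALSE)
print(out)

message(sprintf(
  "Recovered net charge %.2f e vs true %.2f e (%.1f%% error) from %d noisy",
  fit$net_charge_e, truth, out$rel_err_pct, length(ratios)))
message("reversal potentials - selectivity data constrain the effective channel")
message("charge to within a few percent at this noise level.")
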