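#!/usr/bin/env Rscript
# pH titration of the channel charge and divalent-cation binding.
#
# The channel's ionizable residues give its selectivity a strong pH
# dependence in 1:1 salts: anionic at low pH (acids protonated, net charge
# positive), cationic above the crossover. Divalent cations that bind the
# constriction acids compete with protons, which (i) flattens the pH
# dependence at high divalent concentration and (ii) shifts the apparent
# half-titration point to lower pH by log10(1 + Kb*M2). Diluting the
# divalent restores the pH sensitivity.

suppressPackageStartupMessages(library(pnporin))
dir.create("results", showWarnings = FALSE)

sites <- make_sites("wt")   # acids pKa_eff 4 (constriction pair Kb = 20), bases pKa_eff 10
asym <- make_salt_tables("1:1-asymmetric")
opts <- pnp_options(n_nodes = 121)

phs <- seq(2, 7, by = 0.5)
M2s <- c(0, 0.01, 0.1, 1)
sweep <- do.call(rbind, lapply(M2s, function(M2) {
  data.frame(M2 = M2, pH = phs,
             net_charge_e = vapply(phs, function(p)
               net_charge(titrate(sites, p, M2)), 1),
             rp_mV = vapply(phs, function(p)
               reversal_potential(titrate(sites, p, M2),
                                  bath_state(asym, 1),
                                  bath_state(asym, 0.1), opts), 1))
}))
sweep$net_charge_e <- round(sweep$net_charge_e, 3)
sweep$rp_mV <- round(sweep$rp_mV, 2)
write.csv(sweep, "results/titration_ph_sweeps.csv", row.names = FALSE)

span <- vapply(M2s, function(m) {
  s <- sweep[sweep$M2 == m, ]
  s$rp_mV[s$pH == 3] - s$rp_mV[s$pH == 7]
}, 1)
cross <- vapply(M2s, function(m) {
  s <- sweep[sweep$M2 == m, ]
  i <- which(diff(sign(s$rp_mV)) != 0)[1]
  if (is.na(i)) NA_real_
  else approx(s$rp_mV[i:(i + 1)], s$pH[i:(i + 1)], xout = 0)$y
}, 1)
summary_tab <- data.frame(M2 = M2s, rp_span_pH3_minus_pH7_mV = round(span, 2),
                          zero_crossing_pH = round(cross, 2))
write.csv(summary_tab, "results/titration_summary.csv", row.names = FALSE)
print(summary_tab)

message(sprintf(
  "RP(pH 3) - RP(pH 7) grows from %.1f mV at M2 = 1 M to %.1f mV as M2 -> 0:",
  span[M2s == 1], span[M2s == 0]))
message("binding suppresses the pH sensitivity and dilution restores it. The")
message("bound acids' residual proton response concentrates at lower pH (the")
message("apparent pKa drops by log10(1 + Kb*M2)), while the channel's overall")
message("selectivity crossover drifts up as the constriction charge is")
message("neutralized by the bound divalents.")
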