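#!/usr/bin/env Rscript
# Dissecting the reversal potential into electrostatic exclusion and
# diffusion contributions, and in-silico constriction mutants.
#
# With a 2:1 salt (slow divalent cation, fast monovalent anion) a channel
# whose net fixed charge is negative can still show anionic selectivity:
# the diffusion potential of the electrolyte overwhelms the electrostatic
# preference for cations. Running the solver with equalized diffusion
# coefficients (exclusion only) even yields the opposite RP sign from the
# full model.

suppressPackageStartupMessages(library(pnporin))
dir.create("results", showWarnings = FALSE)

mg <- make_salt_tables("2:1")
wt <- make_profile("wt")
zfg <- make_profile("zfg")
opts_ex <- pnp_options(n_nodes = 201, mode = "exclusion")
opts <- pnp_options(n_nodes = 201)

ratios <- c(2, 3, 5, 7, 10)
scan <- do.call(rbind, lapply(ratios, function(r) {
  bL <- bath_state(mg, 0.1 * r); bR <- bath_state(mg, 0.1)
  data.frame(
    ratio = r,
    rp_wt_exclusion_mV = reversal_potential(wt, bL, bR, opts_ex),
    rp_zfg_exclusion_mV = reversal_potential(zfg, bL, bR, opts_ex),
    diffusion_potential_mV = diffusion_potential(mg, 0.1 * r, 0.1),
    rp_zfg_full_mV = reversal_potential(zfg, bL, bR, opts))
}))
scan[-1] <- round(scan[-1], 2)
write.csv(scan, "results/selectivity_dissection.csv", row.names = FALSE)
print(scan)

message(sprintf(
  "At a tenfold 2:1 gradient: exclusion-only RP %.1f mV (cationic sign),",
  scan$rp_zfg_exclusion_mV[nrow(scan)]))
message(sprintf(
  "full model %.1f mV (anionic) - the diffusion potential (%.1f mV) sets",
  scan$rp_zfg_full_mV[nrow(scan)],
  scan$diffusion_potential_mV[nrow(scan)]))
message("both the sign and most of the magnitude; exclusion alone gets the sign wrong.")

# constriction mutants: net charge bookkeeping and RP in 1:1 vs 2:1 salts
asym <- make_salt_tables("1:1-asymmetric")
mut <- do.call(rbind, lapply(c("wt", "cc", "rr"), function(k) {
  p <- make_profile(k)
  data.frame(
    profile = k,
    delta_q_vs_wt = round(net_charge(p) - net_charge(make_profile("wt")), 3),
    net_charge_e = round(net_charge(p), 3),
    rp_1to1_mV = round(reversal_potential(p, bath_state(asym, 1),
                                          bath_state(asym, 0.1), opts), 2),
    rp_2to1_mV = round(reversal_potential(p, bath_state(mg, 1),
                                          bath_state(mg, 0.1), opts), 2))
}))
write.csv(mut, "results/mutant_scenarios.csv", row.names = FALSE)
print(mut)

message("Mutant scenarios: removing the two constriction acids (cc, +2 e) keeps")
message("the 1:1-salt selectivity cationic and the 2:1-salt RP anionic; the")
message("arginine replacement (rr, +4 e) is anion-selective in both salts, so no")
message("selectivity inversion remains to speak of.")
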