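#!/usr/bin/env Rscript
# Channel conductance versus electrolyte conductivity.
#
# For 1:1 salts at low-to-moderate concentration the pore behaves like a
# resistive element filled with the bulk electrolyte: G tracks kappa
# linearly through the origin. For 2:1 salts the electrolyte itself is
# strongly nonideal - its conductivity saturates with activity - and once
# that is folded into effective salt-dependent diffusion coefficients the
# model conductance saturates to a plateau. The model never reproduces the
# *decrease* measured at very high 2:1 concentrations: that requires
# channel-ion interactions outside the mean-field picture (documented
# negative control).

suppressPackageStartupMessages(library(pnporin))
dir.create("results", showWarnings = FALSE)

neutral <- charge_profile(seq(0, 4, length.out = 5), rep(0, 5))
asym <- make_salt_tables("1:1-asymmetric")
mg <- make_salt_tables("2:1")
opts <- pnp_options(n_nodes = 101)
opts_eff <- pnp_options(n_nodes = 101, mode = "effective")

Cs <- c(0.1, 0.2, 0.5, 0.75, 1, 1.5, 2, 2.5, 3)
scan <- data.frame(
  C = Cs,
  kappa_ideal_1to1_S_per_m = ideal_conductivity(asym, Cs),
  G_1to1_ideal_nS = vapply(Cs, function(C)
    conductance(neutral, bath_state(asym, C), options = opts), 1),
  kappa_meas_2to1_S_per_m = approx(mg$kappa_table[[1]], mg$kappa_table[[2]],
                                   xout = Cs)$y,
  G_2to1_ideal_nS = vapply(Cs, function(C)
    conductance(neutral, bath_state(mg, C), options = opts), 1),
  G_2to1_effective_nS = vapply(Cs, function(C)
    conductance(neutral, bath_state(mg, C), options = opts_eff), 1))
scan[-1] <- round(scan[-1], 4)
write.csv(scan, "results/conductance_scan.csv", row.names = FALSE)
print(scan)

fit <- lm(G_1to1_ideal_nS ~ 0 + kappa_ideal_1to1_S_per_m, scan)
message(sprintf(
  "1:1 salt: G vs kappa through the origin, R^2 = %.6f, slope %.3g nS/(S/m)",
  summary(fit)$r.squared, coef(fit)))
message(sprintf("  (geometric A/L = %.3g nS/(S/m))", 1e-18 / 4e-9 * 1e9))
ge <- scan$G_2to1_effective_nS
sl <- diff(ge) / diff(Cs)
message(sprintf(
  "2:1 salt with effective D's: G rises %.2f -> %.2f nS and flattens (slope",
  ge[1], ge[length(ge)]))
message(sprintf(
  "%.1f nS/M at 0.1 M down to %.1f nS/M at 3 M); it never decreases - the",
  sl[1], sl[length(sl)]))
message("measured high-concentration drop is beyond the mean-field model.")
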