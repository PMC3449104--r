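# shared fixtures: real-ion salts and small solver settings used across tests

fx_ions <- standard_ions()
fx_kcl <- salt_definition(fx_ions$K, fx_ions$Cl, 1, 1)
fx_mgcl2 <- salt_definition(fx_ions$Mg, fx_ions$Cl, 1, 2)

fx_neutral <- charge_profile(seq(0, 4, length.out = 5), rep(0, 5))

# coarse options keep the suite fast; accuracy-sensitive tests override
fx_opts <- pnp_options(n_nodes = 101)

# synthetic gamma table with known knots for interpolation tests
fx_gamma_salt <- salt_definition(
  fx_ions$K, fx_ions$Cl, 1, 1,
  gamma_table = data.frame(C_mol_per_L = c(0.1, 1.0),
                           gamma_pm = c(0.80, 0.60)))
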