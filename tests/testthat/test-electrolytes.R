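test_that("mean activity interpolates the gamma table linearly", {
  # midpoint of the two knots: gamma = 0.70 -> a = 0.70 * 0.55
  expect_equal(mean_activity(fx_gamma_salt, 0.55), 0.70 * 0.55)
  # at the knots, gamma recovered as a/C equals the table value exactly
  for (i in 1:2) {
    C <- fx_gamma_salt$gamma_table$C_mol_per_L[i]
    g <- fx_gamma_salt$gamma_table$gamma_pm[i]
    expect_equal(mean_activity(fx_gamma_salt, C) / C, g)
  }
  expect_error(mean_activity(fx_gamma_salt, 2), "range error")
  expect_equal(mean_activity(fx_gamma_salt, 2, extrapolate = TRUE), 0.60 * 2)
  expect_error(mean_activity(fx_kcl, 0.5), "empty or missing")
})

test_that("activity is monotone where gamma*C is, on synthetic tables", {
  for (kind in c("1:1-equitransferent", "1:1-asymmetric", "2:1")) {
    s <- make_salt_tables(kind)
    Cs <- seq(0.02, 3, length.out = 120)
    a <- mean_activity(s, Cs)
    expect_true(all(diff(a) > 0), info = kind)
  }
})

test_that("molal/molar gamma conversion is the exact scale bijection", {
  # dilute limit: m*rho0 = C -> scales coincide
  expect_equal(molal_to_molar_gamma(0.77, 0.5, 0.5 * 0.997, 0.997), 0.77)
  expect_equal(molal_to_molar_gamma(0.6, 1.0, 0.95, 0.997),
               0.6 * 1.0 * 0.997 / 0.95)
  # forward then inverse returns the input to machine precision
  g_c <- molal_to_molar_gamma(0.62, 1.3, 1.21, 1.01)
  g_m_back <- g_c * 1.21 / (1.3 * 1.01)
  expect_equal(g_m_back, 0.62, tolerance = 1e-14)
  expect_error(molal_to_molar_gamma(0.6, -1, 1, 1), "domain error")
})

test_that("ideal conductivity matches the molar-conductivity shortcut", {
  k <- phys_constants()
  D <- 2e-9
  s <- salt_definition(ion_species("Ap", 1, D), ion_species("Bm", -1, D), 1, 1)
  # shortcut: Lambda = F^2/(RT) * 2 D, kappa = Lambda * C
  lam <- k$F^2 / (k$R * k$T) * 2 * D
  expect_equal(ideal_conductivity(s, 0.1), lam * 100, tolerance = 1e-12)
  expect_equal(ideal_conductivity(s, 0), 0)
  expect_equal(ideal_conductivity(s, 0.2), 2 * ideal_conductivity(s, 0.1))
  # 2:1 stoichiometry weighting
  expect_equal(ideal_conductivity(fx_mgcl2, 0.1),
               k$F^2 / (k$R * k$T) *
                 (4 * 0.706e-9 + 2 * 2.032e-9) * 100)
})

test_that("effective diffusion coefficients reproduce measured conductivity", {
  s <- make_salt_tables("2:1")
  for (C in c(0.05, 0.5, 2)) {
    de <- effective_diffusion_coefficients(s, C)
    s_eff <- salt_definition(
      ion_species(s$cation$name, s$cation$z, de[[1]]),
      ion_species(s$anion$name, s$anion$z, de[[2]]),
      s$nu_plus, s$nu_minus)
    kap_meas <- interp_table(s$kappa_table, 2, C)
    expect_equal(ideal_conductivity(s_eff, C), kap_meas, tolerance = 1e-10)
    # scaling preserves the bulk transport-number ratio
    expect_equal(de[[1]] / de[[2]], s$cation$D_bulk / s$anion$D_bulk,
                 tolerance = 1e-12)
  }
  # ideal solution -> no rescaling
  ideal <- make_salt_tables("1:1-equitransferent")
  de <- effective_diffusion_coefficients(ideal, 0.5)
  expect_equal(de$factor, 1, tolerance = 1e-10)
  expect_equal(de[[1]], ideal$cation$D_bulk, tolerance = 1e-12)
  # cation-only attribution also reproduces kappa, anion untouched
  # (mild deficit: a large one cannot be carried by the cation alone)
  dc <- effective_diffusion_coefficients(s, 0.05, attribution = "cation")
  expect_equal(dc[[2]], s$anion$D_bulk)
  s_c <- salt_definition(ion_species("M", 2, dc[[1]]),
                         ion_species("X", -1, dc[[2]]), 1, 2)
  expect_equal(ideal_conductivity(s_c, 0.05),
               interp_table(s$kappa_table, 2, 0.05), tolerance = 1e-10)
  expect_error(effective_diffusion_coefficients(s, 2, attribution = "cation"),
               "data error")
})

test_that("invalid ion and salt definitions are rejected", {
  expect_error(ion_species("X", 0, 1e-9), "valence")
  expect_error(ion_species("X", 1, -1e-9), "positive")
  expect_error(salt_definition(fx_ions$Mg, fx_ions$Cl, 1, 1), "electroneutral")
  expect_error(salt_definition(fx_ions$K, fx_ions$Cl, 1, 1,
                               gamma_table = data.frame(C = c(1, 0.5),
                                                        g = c(0.7, 0.8))),
               "strictly increasing")
})

test_that("ion and salt TSV round-trips preserve values", {
  path <- system.file("extdata", "ions.tsv", package = "pnporin")
  ions <- read_ion_table(path)
  expect_equal(ions$K$D_bulk, 1.957e-9)
  expect_equal(ions$Mg$z, 2L)
  stab <- read_salt_property_table(
    system.file("extdata", "salt_2to1_synthetic.tsv", package = "pnporin"))
  s <- salt_definition(fx_ions$Mg, fx_ions$Cl, 1, 2,
                       gamma_table = stab$gamma_table,
                       kappa_table = stab$kappa_table)
  ref <- make_salt_tables("2:1")
  expect_equal(mean_activity(s, 0.3), mean_activity(ref, 0.3),
               tolerance = 1e-6)
})
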