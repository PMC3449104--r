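test_that("identical baths at zero bias give the trivial equilibrium", {
  b <- bath_state(fx_kcl, 0.1)
  sol <- solve_pnp(fx_neutral, b, b, 0, fx_opts)
  expect_lt(abs(sol$I_pA), 1e-10)
  expect_lt(max(abs(sol$flux)), 1e-22)
  expect_lt(max(abs(sol$phi_mV)), 1e-8)
  expect_equal(unname(sol$conc[, 1]), rep(0.1, length(sol$x_nm)),
               tolerance = 1e-8)
  expect_true(all(sol$conc >= 0))
})

test_that("flux conservation holds at convergence in charged, biased runs", {
  wt <- make_profile("wt")
  sol <- solve_pnp(wt, bath_state(fx_kcl, 1), bath_state(fx_kcl, 0.1), 50,
                   pnp_options(n_nodes = 201))
  expect_lt(sol$residual, 1e-6)
  expect_true(all(sol$conc >= 0))
  sol2 <- solve_pnp(wt, bath_state(fx_mgcl2, 0.5), bath_state(fx_mgcl2, 0.1),
                    -40, pnp_options(n_nodes = 201))
  expect_lt(sol2$residual, 1e-6)
})

test_that("neutral uniform cylinder is ohmic: G = kappa*A/L", {
  for (C in c(0.1, 1)) {
    g <- conductance(fx_neutral, bath_state(fx_kcl, C), options = fx_opts)
    kap <- ideal_conductivity(fx_kcl, C)
    expect_equal(g, kap * 1e-18 / 4e-9 * 1e9, tolerance = 0.01)
  }
  # G -> 0 as C -> 0
  expect_lt(conductance(fx_neutral, bath_state(fx_kcl, 1e-4),
                        options = fx_opts), 1e-3)
})

test_that("neutral-pore reversal potential matches the 1:1 closed form", {
  Vt <- phys_constants()$Vt_mV
  Dp <- fx_ions$K$D_bulk; Dm <- fx_ions$Cl$D_bulk
  closed <- -Vt * (Dp - Dm) / (Dp + Dm) * log(1 / 0.1)
  # electroneutral closure reproduces the closed form essentially exactly
  rp_tms <- reversal_potential(fx_neutral, bath_state(fx_kcl, 1),
                               bath_state(fx_kcl, 0.1),
                               pnp_options(closure = "tms",
                                           rp_tol_mV = 1e-6,
                                           ode_rtol = 1e-12))
  expect_equal(rp_tms, closed, tolerance = 1e-6)
  # Poisson closure carries space charge at these Debye lengths: 1 mV level
  rp_p <- reversal_potential(fx_neutral, bath_state(fx_kcl, 1),
                             bath_state(fx_kcl, 0.1),
                             pnp_options(n_nodes = 201))
  expect_lt(abs(rp_p - closed), 1)
})

test_that("strongly charged pore approaches the Nernst slope", {
  profX <- charge_profile(seq(0, 4, length.out = 9), rep(-10, 9))
  rp <- reversal_potential(profX, bath_state(fx_kcl, 1),
                           bath_state(fx_kcl, 0.1),
                           pnp_options(n_nodes = 401))
  nernst <- -phys_constants()$Vt_mV * log(10)
  expect_lt(abs(rp - nernst), 1)
})

test_that("identical baths give zero reversal potential", {
  b <- bath_state(fx_kcl, 0.3)
  wt <- make_profile("wt")
  expect_equal(reversal_potential(wt, b, b, fx_opts), 0, tolerance = 0.02)
})

test_that("at the reversal potential current vanishes but fluxes do not", {
  wt <- make_profile("wt")
  bL <- bath_state(fx_kcl, 1); bR <- bath_state(fx_kcl, 0.1)
  opts <- pnp_options(n_nodes = 201)
  rp <- reversal_potential(wt, bL, bR, opts)
  sol <- solve_pnp(wt, bL, bR, rp, opts)
  # root tolerance 0.01 mV at nS-scale conductance: |I| well under 0.1 pA
  expect_lt(abs(sol$I_pA), 0.1)
  # multi-ionic: both ions still flow at zero net current
  expect_gt(min(abs(sol$flux)), 1e-18)
})

test_that("reversal potential is stable under grid doubling", {
  wt <- make_profile("wt")
  bL <- bath_state(fx_kcl, 1); bR <- bath_state(fx_kcl, 0.1)
  rp1 <- reversal_potential(wt, bL, bR, pnp_options(n_nodes = 401))
  rp2 <- reversal_potential(wt, bL, bR, pnp_options(n_nodes = 801))
  expect_lt(abs(rp2 - rp1) / abs(rp1), 0.005)
  g1 <- conductance(wt, bath_state(fx_kcl, 1),
                    options = pnp_options(n_nodes = 401))
  g2 <- conductance(wt, bath_state(fx_kcl, 1),
                    options = pnp_options(n_nodes = 801))
  expect_lt(abs(g2 - g1) / g1, 0.005)
})

test_that("Poisson and electroneutral closures agree where Debye layers are thin", {
  lowq <- charge_profile(seq(0, 4, length.out = 41), rep(-0.05, 41))
  asym <- make_salt_tables("1:1-asymmetric")
  for (cc in list(c(3, 1), c(2, 0.5))) {
    rp_p <- reversal_potential(lowq, bath_state(asym, cc[1]),
                               bath_state(asym, cc[2]),
                               pnp_options(n_nodes = 401))
    rp_t <- reversal_potential(lowq, bath_state(asym, cc[1]),
                               bath_state(asym, cc[2]),
                               pnp_options(closure = "tms"))
    expect_lt(abs(rp_p - rp_t), 1)
  }
})

test_that("TMS closure separates Donnan and internal contributions", {
  profX <- charge_profile(seq(0, 4, length.out = 9), rep(-0.5, 9))
  sol <- solve_pnp(profX, bath_state(fx_mgcl2, 0.5),
                   bath_state(fx_mgcl2, 0.1), 10,
                   pnp_options(closure = "tms"))
  d <- sol$donnan_mV
  # the three pieces add up to the applied bias
  expect_equal(-d[["left"]] + d[["internal"]] + d[["right"]], 10,
               tolerance = 1e-6)
  # negative fixed charge -> membrane phase negative vs both baths
  expect_lt(d[["left"]], 0)
  expect_lt(d[["right"]], 0)
  # in divalent-salt gradients the interfacial Donnan part and the internal
  # diffusion part can carry opposite signs
  sol0 <- solve_pnp(profX, bath_state(fx_mgcl2, 1),
                    bath_state(fx_mgcl2, 0.1), 0,
                    pnp_options(closure = "tms"))
  expect_lt(sign(sol0$donnan_mV[["internal"]]) *
              sign(sol0$donnan_mV[["left"]]), 0)
})

test_that("non-bracketed reversal searches raise a bracket error", {
  profX <- charge_profile(seq(0, 4, length.out = 9), rep(-10, 9))
  expect_error(
    reversal_potential(profX, bath_state(fx_kcl, 1), bath_state(fx_kcl, 0.1),
                       pnp_options(n_nodes = 201, rp_bracket = c(-5, 5))),
    "bracket error")
})

test_that("exclusion mode suppresses the diffusion potential", {
  # neutral pore, exclusion mode: equal D's -> RP identically ~0
  rp <- reversal_potential(fx_neutral, bath_state(fx_mgcl2, 1),
                           bath_state(fx_mgcl2, 0.1),
                           pnp_options(n_nodes = 201, mode = "exclusion"))
  expect_lt(abs(rp), 0.5)
})
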