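test_that("site charge follows Henderson-Hasselbalch with competitive binding", {
  acid <- titratable_site(2, 4.5, "acid", Kb = 20)
  base <- titratable_site(1, 10, "base")
  expect_equal(site_charge_fraction(acid, 4.5), -0.5)
  expect_equal(site_charge_fraction(base, 10), 0.5)
  # half occupancy by the divalent at Kb*M2 = 1, high pH
  expect_equal(site_charge_fraction(acid, 14, M2 = 1 / 20), -0.5,
               tolerance = 1e-4)
  # bound state counted +1 flips the high-M2 limit to positive
  expect_equal(site_charge_fraction(acid, 14, M2 = 1e6, bound_charge = 1), 1,
               tolerance = 1e-4)
  # monotonicity: |charge| non-increasing as pH drops and as M2 grows
  phs <- seq(12, 1, by = -0.5)
  f <- vapply(phs, function(p) abs(site_charge_fraction(acid, p)), 1)
  expect_true(all(diff(f) <= 1e-12))
  m2s <- c(0, 10^seq(-4, 0, 0.5))
  g <- vapply(m2s, function(m) abs(site_charge_fraction(acid, 7, m)), 1)
  expect_true(all(diff(g) < 0))
  fb <- vapply(phs, function(p) site_charge_fraction(base, p), 1)
  expect_true(all(diff(fb) >= 0))
})

test_that("binding shifts the half-titration pH down by log10(1 + Kb*M2)", {
  acid <- titratable_site(2, 4.0, "acid", Kb = 20)
  for (KbM2 in c(0.5, 10, 100)) {
    M2 <- KbM2 / 20
    fmax <- abs(site_charge_fraction(acid, 14, M2))
    ph_half <- uniroot(function(p) abs(site_charge_fraction(acid, p, M2)) -
                         fmax / 2, c(-2, 14), tol = 1e-13)$root
    expect_equal(ph_half, 4.0 - log10(1 + KbM2), tolerance = 1e-8)
  }
})

test_that("titration deposits the summed fractional charge into the volume", {
  sites <- list(titratable_site(1.0, 4, "acid"),
                titratable_site(2.5, 4, "acid", width_nm = 0.2),
                titratable_site(3.2, 10, "base"))
  grid <- seq(0, 4, length.out = 801)
  for (pH in c(3, 5, 7)) {
    p <- titrate(sites, pH, grid_nm = grid)
    want <- sum(vapply(sites, site_charge_fraction, 1, pH = pH))
    expect_equal(net_charge(p), want, tolerance = 1e-6)
  }
  expect_error(titrate(list(titratable_site(5, 4, "acid")), 7,
                       grid_nm = grid), "outside")
})

test_that("net charge matches the analytic value for a uniform cylinder", {
  # X = -0.1 M in a 4 nm x 1 nm^2 cylinder
  p <- charge_profile(seq(0, 4, length.out = 11), rep(-0.1, 11),
                      area_nm2 = 1)
  vol_L <- 4e-9 * 1e-18 * 1000
  expect_equal(net_charge(p), -0.1 * vol_L * 6.02214076e23, tolerance = 1e-12)
  expect_equal(net_charge(charge_profile(seq(0, 4, length.out = 11),
                                         rep(0, 11))), 0)
})

test_that("trapezoid integral agrees with Simpson quadrature on smooth profiles", {
  skip_if_not_installed("pracma")
  f <- function(x) -0.4 * exp(-(x - 2)^2 / 0.5) + 0.1 * sin(pi * x / 4)
  grid <- seq(0, 4, length.out = 40001)
  p <- charge_profile(grid, f(grid))
  simpson <- pracma::simpadpt(f, 0, 4, tol = 1e-12) *
    1000 * 1e-18 * 1e-9 * 6.02214076e23
  expect_equal(net_charge(p), simpson, tolerance = 1e-8)
})

test_that("region edits are local and point charges cancel exactly", {
  wt <- make_profile("wt")
  edited <- neutralize_region(wt, 1.6, 2.4)
  outside <- wt$grid_nm < 1.6 | wt$grid_nm > 2.4
  expect_identical(edited$X_molar[outside], wt$X_molar[outside])
  expect_true(all(edited$X_molar[!outside] == 0))
  expect_error(neutralize_region(wt, 2.4, 1.6), "domain error")
  # neutralize everything
  allz <- neutralize_region(wt, 0, 4)
  expect_true(all(allz$X_molar == 0))
  # +q then -q at the same position restores the profile
  p2 <- add_point_charges(add_point_charges(wt, 2.0, +1.3), 2.0, -1.3)
  expect_equal(p2$X_molar, wt$X_molar, tolerance = 1e-12)
})

test_that("constriction mutations change net charge by whole site-equivalents", {
  wt <- make_profile("wt")
  cc <- make_profile("cc")
  rr <- make_profile("rr")
  expect_equal(net_charge(cc) - net_charge(wt), 2, tolerance = 1e-4)
  expect_equal(net_charge(rr) - net_charge(wt), 4, tolerance = 1e-4)
  # in-silico neutralization of an eyelet region holding exactly the two
  # constriction acids reproduces the CC-like +2 bookkeeping via the
  # integral (other sites kept clear of the cut window)
  p <- charge_profile(seq(0, 4, length.out = 801), numeric(801))
  p <- add_point_charges(p, c(0.5, 1.8, 2.2, 3.5), c(-1, -1, -1, -1),
                         width_nm = 0.15)
  cut <- neutralize_region(p, 1.2, 2.8)
  expect_equal(net_charge(cut) - net_charge(p), 2, tolerance = 2e-3)
})

test_that("mutation operations commute with titration on disjoint regions", {
  sites <- make_sites("wt")
  p <- titrate(sites, 5, 0)
  a <- add_point_charges(neutralize_region(p, 0, 0.2), 3.8, 0.5,
                         width_nm = 0.1)
  b <- neutralize_region(add_point_charges(p, 3.8, 0.5, width_nm = 0.1),
                         0, 0.2)
  expect_equal(a$X_molar, b$X_molar, tolerance = 1e-12)
})

test_that("profile and site TSV round-trips are faithful", {
  wt <- make_profile("wt", n_nodes = 81)
  path <- tempfile(fileext = ".tsv")
  write_charge_profile(wt, path)
  back <- read_charge_profile(path)
  expect_equal(back$X_molar, wt$X_molar, tolerance = 1e-7)
  sites <- read_sites(system.file("extdata", "sites_wt_synthetic.tsv",
                                  package = "pnporin"))
  expect_length(sites, 11)
  expect_equal(sum(vapply(sites, function(s) s$Kb, 1) > 0), 2)
})
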