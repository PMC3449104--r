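# Synthetic inputs: charge profiles with realistic axial shapes, salt
# property tables with the qualitative monovalent/divalent signatures, and
# noisy pseudo-experimental datasets for end-to-end and recovery tests.

.with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Standard ion set
#'
#' Limiting diffusion coefficients at 25 C (m^2/s) for the small inorganic
#' ions used throughout: K+, Na+, Cl-, Mg2+, Ca2+.
#'
#' @return Named list of `ion_species`.
#' @export
standard_ions <- function() {
  list(K  = ion_species("K", 1, 1.957e-9),
       Na = ion_species("Na", 1, 1.334e-9),
       Cl = ion_species("Cl", -1, 2.032e-9),
       Mg = ion_species("Mg", 2, 0.706e-9),
       Ca = ion_species("Ca", 2, 0.792e-9))
}

#' Scenario specification for pseudo-experiments
#'
#' @param profile_kind One of `"neutral"`, `"wt"` (net-negative, charge
#'   concentrated near mid-channel), `"zfg"` (positive lobe at the
#'   constriction, net charge still negative), `"cc"` (wild type with the
#'   two constriction acids removed), `"rr"` (constriction acids replaced by
#'   +1 sites).
#' @param salt_kind One of `"1:1-equitransferent"`, `"1:1-asymmetric"`,
#'   `"2:1"`.
#' @param noise_sd Measurement noise: additive SD in mV for reversal
#'   potentials, lognormal sigma for conductances. Default 1 (mV).
#' @param seed Integer seed for reproducibility.
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(profile_kind = c("wt", "neutral", "zfg", "cc", "rr"),
                          salt_kind = c("1:1-equitransferent",
                                        "1:1-asymmetric", "2:1"),
                          noise_sd = 1, seed = 1L) {
  if (noise_sd < 0) stop("domain error: noise_sd must be >= 0")
  structure(list(profile_kind = match.arg(profile_kind),
                 salt_kind = match.arg(salt_kind),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "scenario_spec")
}

# fixed-charge deposition plan per profile kind: position (nm), magnitude
# (elementary charges, signed at full ionization), width (nm)
.profile_plan <- function(kind, L_nm) {
  s <- L_nm / 4  # plans are laid out for L = 4 nm and scale with L
  bg_acids <- data.frame(x = s * c(0.7, 1.2, 2.8, 3.2, 3.6), q = -1, w = 0.3)
  bases    <- data.frame(x = s * c(0.5, 1.5, 2.6, 3.4), q = +1, w = 0.3)
  constr   <- data.frame(x = s * c(1.8, 2.2), q = -1, w = 0.2)
  switch(kind,
    neutral = data.frame(x = numeric(), q = numeric(), w = numeric()),
    wt = rbind(bg_acids, bases, constr),                      # net -3 e
    cc = rbind(bg_acids, bases),                              # net -1 e
    rr = rbind(bg_acids, bases, transform(constr, q = +1)),   # net +1 e
    zfg = rbind(bg_acids,                                     # net -1.5 e
                transform(bases, q = +0.5),
                data.frame(x = s * 2.0, q = +1.5, w = 0.25)),
    stop("unknown profile kind: ", kind))
}

#' Generate a synthetic axial fixed-charge profile
#'
#' Parametric profiles emulating the qualitative shapes of structure-derived
#' effective charge profiles of a wide porin: the wild-type-like profile is
#' net negative with charge concentrated near mid-channel; the `"zfg"` kind
#' (modelled on a structure crystallized in concentrated MgCl2) carries a
#' positive lobe at the central constriction while its net charge stays
#' negative; `"cc"` and `"rr"` emulate constriction mutants whose net charge
#' is shifted by exactly +2 and +4 site-equivalents relative to wild type.
#' Profiles are shape-calibrated only; charges are deposited as normalized
#' Gaussians at full ionization.
#'
#' @param kind Profile kind, see [scenario_spec()].
#' @param L_nm Channel length, nm (default 4).
#' @param area_nm2 Uniform cross-section, nm^2 (default 1).
#' @param n_nodes Nodes of the output grid (default 401).
#' @param jitter_sd Positional jitter SD applied to the deposition sites, nm
#'   (default 0.02); requires `seed`.
#' @param seed Integer seed; same seed gives a bit-identical profile.
#' @return A `charge_profile`.
#' @examples
#' wt <- make_profile("wt", seed = 7)
#' net_charge(wt)  # close to -3
#' @export
make_profile <- function(kind = c("wt", "neutral", "zfg", "cc", "rr"),
                         L_nm = 4, area_nm2 = 1, n_nodes = 401,
                         jitter_sd = 0.02, seed = NULL) {
  kind <- match.arg(kind)
  grid <- seq(0, L_nm, length.out = n_nodes)
  plan <- .profile_plan(kind, L_nm)
  prof <- charge_profile(grid, numeric(n_nodes), L_nm, rep(area_nm2, n_nodes))
  if (nrow(plan) == 0) return(prof)
  if (!is.null(seed) && jitter_sd > 0) {
    plan <- .with_seed(seed, function() {
      plan$x <- pmin(pmax(plan$x + stats::rnorm(nrow(plan), 0, jitter_sd), 0),
                     L_nm)
      plan$w <- plan$w * exp(stats::rnorm(nrow(plan), 0, 0.05))
      plan
    })
  }
  for (i in seq_len(nrow(plan)))
    prof <- add_point_charges(prof, plan$x[i], plan$q[i], plan$w[i],
                              default_area_nm2 = area_nm2)
  prof
}

#' Titratable-site list behind a synthetic profile
#'
#' The protonatable sites whose full-ionization deposition gives
#' [make_profile()]'s wild-type-like profile: acidic sites with apparent pKa
#' 4.0 (the two constriction acids additionally carry a divalent-cation
#' association constant `Kb`) and basic sites with apparent pKa 10.0. Use
#' with [titrate()] to obtain pH- and divalent-dependent profiles.
#'
#' @param kind Profile kind (`"wt"`, `"cc"`, `"rr"`; kinds without a
#'   titration reading are not provided).
#' @param L_nm Channel length, nm.
#' @param Kb Divalent association constant of the constriction acids, L/mol
#'   (default 20).
#' @return List of `titratable_site`.
#' @export
make_sites <- function(kind = c("wt", "cc", "rr"), L_nm = 4, Kb = 20) {
  kind <- match.arg(kind)
  plan <- .profile_plan(kind, L_nm)
  lapply(seq_len(nrow(plan)), function(i) {
    acid <- plan$q[i] < 0
    constriction <- acid && plan$w[i] < 0.25
    titratable_site(plan$x[i],
                    pKa_eff = if (acid) 4.0 else 10.0,
                    kind = if (acid) "acid" else "base",
                    width_nm = plan$w[i],
                    Kb = if (constriction) Kb else 0)
  })
}

#' Generate synthetic salt property tables
#'
#' Emulates the qualitative concentration dependence of real electrolytes:
#' 1:1 salts have a near-flat mean activity coefficient and conductivity
#' proportional to activity; 2:1 salts (divalent cation) have a gamma curve
#' that passes through a minimum and then rises steeply, and a conductivity
#' that saturates with activity (Michaelis-type, concave). Shapes are
#' parametric, not digitized from any dataset.
#'
#' @param kind Salt kind, see [scenario_spec()].
#' @param C_grid Molar concentration knots of the tables.
#' @return A `salt_definition` with `gamma_table`, `kappa_table` and a
#'   pure-water `density_table`.
#' @export
make_salt_tables <- function(kind = c("1:1-equitransferent", "1:1-asymmetric",
                                      "2:1"),
                             C_grid = c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5,
                                        0.75, 1, 1.5, 2, 2.5, 3)) {
  kind <- match.arg(kind)
  if (any(diff(C_grid) <= 0)) stop("domain error: C grid must be increasing")
  dens <- data.frame(m_mol_per_kg = c(0.001, 6), rho_kg_per_L = 0.997)
  if (kind == "1:1-equitransferent") {
    cat_ <- ion_species("Aeq", 1, 2.0e-9)
    an_ <- ion_species("Beq", -1, 2.0e-9)
    salt0 <- salt_definition(cat_, an_, 1, 1)
    gam <- rep(1, length(C_grid))
    kap <- ideal_conductivity(salt0, C_grid)
  } else if (kind == "1:1-asymmetric") {
    cat_ <- ion_species("Asl", 1, 1.0e-9)   # slow cation
    an_ <- ion_species("Bfa", -1, 2.0e-9)   # fast anion
    salt0 <- salt_definition(cat_, an_, 1, 1)
    gam <- exp(-1.172 * sqrt(C_grid) / (1 + 1.3 * sqrt(C_grid)) +
                 0.06 * C_grid)
    kap <- ideal_conductivity(salt0, C_grid) / (1 + 0.15 * sqrt(C_grid))
  } else {
    cat_ <- ion_species("M2", 2, 0.706e-9)  # Mg-like divalent
    an_ <- ion_species("Xm", -1, 2.032e-9)
    salt0 <- salt_definition(cat_, an_, 1, 2)
    I <- 3 * C_grid
    gam <- exp(-2.344 * sqrt(I) / (1 + 1.8 * sqrt(I)) + 0.2 * I)
    a <- gam * C_grid
    kap <- 27 * a / (0.8 + a)
  }
  salt_definition(cat_, an_, salt0$nu_plus, salt0$nu_minus,
                  gamma_table = data.frame(C_mol_per_L = C_grid,
                                           gamma_pm = gam),
                  kappa_table = data.frame(C_mol_per_L = C_grid,
                                           kappa_S_per_m = kap),
                  density_table = dens)
}

# concentrated-KCl salt bridge used in the pseudo-experiments
.bridge_salt <- function() {
  ions <- standard_ions()
  salt_definition(ions$K, ions$Cl, 1, 1)
}

#' Simulate a pseudo-experimental measurement campaign
#'
#' Runs the full forward chain for each design row: titrate the channel
#' sites at the row's pH and divalent concentration, solve the PNP model for
#' the reversal potential (or conductance in symmetric baths), add the
#' salt-bridge liquid-junction contribution, and add seeded measurement
#' noise (additive Gaussian in mV for RP, multiplicative lognormal for G).
#' Both the noiseless truth and the noisy "measured" values are returned.
#' Solver failures are recorded per row, not fatal.
#'
#' @param scenario A [scenario_spec()].
#' @param design Data frame with columns `C_cis`, `C_trans` (mol/L) and
#'   optionally `pH` (default 6) and `M2` (divalent concentration for the
#'   titration; defaults to the mean bath concentration for 2:1 salts, else
#'   0).
#' @param response `"rp"` or `"conductance"` (conductance requires symmetric
#'   rows).
#' @param options [pnp_options()] used for the solves.
#' @param bridge_C Salt-bridge KCl concentration, mol/L (default 2).
#' @return A data.frame: design columns, `truth` (mV or nS), `ljp_mV`
#'   (RP only), `v_exp_mV` (raw zero-current reading including junction
#'   contribution and noise), `measured` (junction-corrected measurement),
#'   and `note` (solver diagnostics).
#' @export
simulate_experiment <- function(scenario, design, response = c("rp",
                                                               "conductance"),
                                options = pnp_options(n_nodes = 201),
                                bridge_C = 2) {
  stopifnot(inherits(scenario, "scenario_spec"))
  response <- match.arg(response)
  if (!all(c("C_cis", "C_trans") %in% names(design)))
    stop("domain error: design needs C_cis and C_trans columns")
  if (is.null(design$pH)) design$pH <- 6
  salt <- make_salt_tables(scenario$salt_kind)
  divalent <- salt$cation$z == 2
  if (is.null(design$M2))
    design$M2 <- if (divalent) (design$C_cis + design$C_trans) / 2 else 0
  sites <- if (scenario$profile_kind %in% c("wt", "cc", "rr"))
    make_sites(scenario$profile_kind) else NULL
  bridge <- .bridge_salt()
  n <- nrow(design)
  truth <- ljp <- rep(NA_real_, n)
  note <- character(n)
  for (i in seq_len(n)) {
    row <- design[i, ]
    prof <- tryCatch({
      if (is.null(sites)) make_profile(scenario$profile_kind,
                                       seed = scenario$seed)
      else titrate(sites, row$pH, row$M2)
    }, error = function(e) e)
    res <- tryCatch({
      if (response == "rp") {
        rp <- reversal_potential(prof,
                                 bath_state(salt, row$C_cis, row$pH),
                                 bath_state(salt, row$C_trans, row$pH),
                                 options)
        lj <- suppressWarnings(
          bridge_correction(bridge, bridge_C, salt, row$C_cis,
                            salt, row$C_trans))
        c(rp, lj)
      } else {
        if (row$C_cis != row$C_trans)
          stop("conductance rows must be symmetric")
        c(conductance(prof, bath_state(salt, row$C_cis, row$pH),
                      options = options), 0)
      }
    }, error = function(e) e)
    if (inherits(res, "error")) note[i] <- conditionMessage(res)
    else { truth[i] <- res[1]; ljp[i] <- res[2] }
  }
  noise <- .with_seed(scenario$seed, function() stats::rnorm(n))
  out <- design
  out$truth <- truth
  if (response == "rp") {
    out$ljp_mV <- ljp
    out$v_exp_mV <- truth + ljp + scenario$noise_sd * noise
    out$measured <- correct_rp(out$v_exp_mV, out$ljp_mV)
  } else {
    out$measured <- truth * exp(scenario$noise_sd * noise)
  }
  out$note <- note
  out
}

#' Recover the channel net charge from reversal-potential data
#'
#' One-parameter least squares: the template profile's fixed charge is
#' scaled by a factor `s` and the PNP reversal potential is fit to the
#' measured RP-versus-gradient data; the recovered net charge is
#' `s * net_charge(template)`. This is the inverse problem behind reading an
#' effective channel charge off selectivity measurements.
#'
#' @param rp_data Data frame with columns `C_cis`, `C_trans` and `measured`
#'   (junction-corrected RP, mV), e.g. from [simulate_experiment()].
#' @param template A `charge_profile` giving the assumed axial shape.
#' @param salt The `salt_definition` used in the measurements.
#' @param options [pnp_options()] used for the solves (a coarser grid than
#'   the default keeps the fit fast).
#' @param scale_interval Search interval for the scale factor `s`.
#' @return List with `net_charge_e`, `scale`, and the residual sum of
#'   squares `sse`.
#' @export
fit_net_charge <- function(rp_data, template, salt,
                           options = pnp_options(n_nodes = 151),
                           scale_interval = c(0.1, 4)) {
  keep <- stats::complete.cases(rp_data[, c("C_cis", "C_trans", "measured")])
  rp_data <- rp_data[keep, ]
  obj <- function(s) {
    prof <- charge_profile(template$grid_nm, s * template$X_molar,
                           template$L_nm, template$area_nm2)
    pred <- vapply(seq_len(nrow(rp_data)), function(i)
      reversal_potential(prof,
                         bath_state(salt, rp_data$C_cis[i]),
                         bath_state(salt, rp_data$C_trans[i]),
                         options),
      numeric(1))
    sum((pred - rp_data$measured)^2)
  }
  opt <- stats::optimize(obj, scale_interval, tol = 1e-3)
  list(net_charge_e = opt$minimum * net_charge(template),
       scale = opt$minimum, sse = opt$objective)
}
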