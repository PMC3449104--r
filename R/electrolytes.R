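#' Define a mobile ionic species
#'
#' A charge carrier described by its signed valence and bulk (infinite
#' dilution) diffusion coefficient. These are the `z_i` and `D_i` that enter
#' both the Henderson liquid-junction expression and the Nernst-Planck fluxes.
#'
#' @param name Species label, e.g. `"K"`, `"Cl"`, `"Mg"`.
#' @param z Integer valence (signed, nonzero).
#' @param D_bulk Bulk diffusion coefficient, m^2/s (positive). Limiting values
#'   at 25 C are the conventional choice.
#' @return An object of class `ion_species`.
#' @examples
#' ion_species("K", 1, 1.957e-9)
#' @export
ion_species <- function(name, z, D_bulk) {
  stopifnot(is.character(name), length(name) == 1)
  if (length(z) != 1 || z != round(z) || z == 0)
    stop("domain error: valence z must be a nonzero integer")
  if (length(D_bulk) != 1 || !is.finite(D_bulk) || D_bulk <= 0)
    stop("domain error: D_bulk must be positive")
  structure(list(name = name, z = as.integer(z), D_bulk = D_bulk),
            class = "ion_species")
}

#' @export
print.ion_species <- function(x, ...) {
  cat(sprintf("<ion_species> %s  z=%+d  D=%.4g m^2/s\n", x$name, x$z, x$D_bulk))
  invisible(x)
}

#' Define a stoichiometric salt with property tables
#'
#' A fully dissociating salt (e.g. 1:1 KCl, 2:1 MgCl2) with optional measured
#' property tables: mean activity coefficient and conductivity versus molar
#' concentration. Tables are interpolated piecewise-linearly; extrapolation is
#' disabled by default and clamps to the end values when enabled.
#'
#' @param cation,anion `ion_species` objects.
#' @param nu_plus,nu_minus Stoichiometric counts (positive integers). Must be
#'   electroneutral: `nu_plus*z_plus + nu_minus*z_minus = 0`.
#' @param gamma_table Optional data.frame `C_mol_per_L`, `gamma_pm` (gamma > 0).
#' @param kappa_table Optional data.frame `C_mol_per_L`, `kappa_S_per_m`.
#' @param density_table Optional data.frame `m_mol_per_kg`, `rho_kg_per_L`
#'   used for molal/molar conversions.
#' @return An object of class `salt_definition`.
#' @examples
#' K <- ion_species("K", 1, 1.957e-9)
#' Cl <- ion_species("Cl", -1, 2.032e-9)
#' kcl <- salt_definition(K, Cl, 1, 1)
#' @export
salt_definition <- function(cation, anion, nu_plus, nu_minus,
                            gamma_table = NULL, kappa_table = NULL,
                            density_table = NULL) {
  stopifnot(inherits(cation, "ion_species"), inherits(anion, "ion_species"))
  if (cation$z <= 0 || anion$z >= 0)
    stop("domain error: cation must have z > 0 and anion z < 0")
  if (nu_plus < 1 || nu_minus < 1 ||
      nu_plus != round(nu_plus) || nu_minus != round(nu_minus))
    stop("domain error: stoichiometric counts must be positive integers")
  if (nu_plus * cation$z + nu_minus * anion$z != 0)
    stop("domain error: salt stoichiometry is not electroneutral")
  chk <- function(tab, vcol, nm) {
    if (is.null(tab)) return(invisible())
    if (nrow(tab) < 2) stop("configuration error: ", nm, " needs >= 2 rows")
    if (any(diff(tab[[1]]) <= 0))
      stop("configuration error: ", nm, " grid must be strictly increasing")
    if (any(tab[[vcol]] <= 0))
      stop("configuration error: ", nm, " values must be positive")
  }
  chk(gamma_table, 2, "gamma_table")
  chk(kappa_table, 2, "kappa_table")
  chk(density_table, 2, "density_table")
  structure(list(cation = cation, anion = anion,
                 nu_plus = as.integer(nu_plus), nu_minus = as.integer(nu_minus),
                 gamma_table = gamma_table, kappa_table = kappa_table,
                 density_table = density_table),
            class = "salt_definition")
}

#' @export
print.salt_definition <- function(x, ...) {
  cat(sprintf("<salt_definition> %s%s%s%s (%d:%d)  gamma table: %s  kappa table: %s\n",
              x$cation$name, if (x$nu_plus > 1) x$nu_plus else "",
              x$anion$name, if (x$nu_minus > 1) x$nu_minus else "",
              x$cation$z, -x$anion$z,
              if (is.null(x$gamma_table)) "none" else nrow(x$gamma_table),
              if (is.null(x$kappa_table)) "none" else nrow(x$kappa_table)))
  invisible(x)
}

#' Mean ionic activity of a salt solution
#'
#' `a = gamma_pm(C) * C` on the molar scale, with the mean activity
#' coefficient linearly interpolated from the salt's table. In the
#' infinite-dilution limit `gamma_pm -> 1` so the activity tends to the
#' concentration.
#'
#' @param salt A `salt_definition` with a `gamma_table`.
#' @param C Molar salt concentration(s), mol/L, within the table range.
#' @param extrapolate Allow clamped extrapolation outside the table range.
#' @return Activity in mol/L.
#' @export
mean_activity <- function(salt, C, extrapolate = FALSE) {
  stopifnot(inherits(salt, "salt_definition"))
  if (any(C < 0)) stop("domain error: C must be >= 0")
  g <- interp_table(salt$gamma_table, 2, C, extrapolate, "gamma_pm")
  g * C
}

#' Convert a mean activity coefficient from the molal to the molar scale
#'
#' Equality of the activity across concentration scales gives the standard
#' thermodynamic conversion `gamma_c = gamma_m * m * rho0 / C`, where `rho0`
#' is the density of the pure solvent (kg/L), `m` the molality (mol/kg) and
#' `C` the molarity (mol/L). At infinite dilution `m * rho0 = C` and the two
#' scales coincide.
#'
#' @param gamma_m Molal-scale mean activity coefficient (dimensionless).
#' @param m Molality, mol/kg.
#' @param C Molarity, mol/L.
#' @param rho0 Pure solvent density, kg/L; default 0.997 (water at 25 C).
#' @return Molar-scale mean activity coefficient.
#' @export
molal_to_molar_gamma <- function(gamma_m, m, C, rho0 = 0.997) {
  if (any(gamma_m <= 0) || any(m <= 0) || any(C <= 0) || any(rho0 <= 0))
    stop("domain error: all inputs must be positive")
  gamma_m * m * rho0 / C
}

#' Ideal (Nernst-Einstein) conductivity of a salt solution
#'
#' Reference conductivity of a fully dissociated salt with bulk diffusion
#' coefficients and no ion-ion interactions:
#' `kappa = (F^2/RT) * sum_i z_i^2 * D_i * nu_i * C` (SI; C converted to
#' mol/m^3 internally). Used as the denominator when rescaling diffusion
#' coefficients to match a measured conductivity.
#'
#' @param salt A `salt_definition`.
#' @param C Molar salt concentration(s), mol/L (>= 0).
#' @param constants Output of [phys_constants()].
#' @return Conductivity in S/m.
#' @export
ideal_conductivity <- function(salt, C, constants = phys_constants()) {
  stopifnot(inherits(salt, "salt_definition"))
  if (any(C < 0)) stop("domain error: C must be >= 0")
  k <- constants
  pref <- k$F^2 / (k$R * k$T)
  smob <- salt$nu_plus * salt$cation$z^2 * salt$cation$D_bulk +
    salt$nu_minus * salt$anion$z^2 * salt$anion$D_bulk
  pref * smob * C * 1000
}

#' Effective salt-dependent diffusion coefficients from measured conductivity
#'
#' Rescales the bulk diffusion coefficients so that the ideal-solution
#' conductivity computed with the rescaled values reproduces the measured
#' conductivity at concentration `C`. By default both ions are scaled by the
#' common factor `kappa_measured(C) / kappa_ideal(C)`, which preserves the
#' bulk transport numbers; the alternative `attribution = "cation"` loads the
#' whole conductivity deficit onto the cation (useful for sensitivity
#' analysis when the cation, e.g. a divalent, is believed to slow down most).
#'
#' @param salt A `salt_definition` with a `kappa_table`.
#' @param C Molar salt concentration, mol/L, within the kappa table range.
#' @param constants Output of [phys_constants()].
#' @param attribution `"both"` (default) or `"cation"`.
#' @param extrapolate Allow clamped extrapolation outside the table range.
#' @return Named list with the effective diffusion coefficients (m^2/s) for
#'   the cation and anion, and the scaling `factor` applied.
#' @export
effective_diffusion_coefficients <- function(salt, C,
                                             constants = phys_constants(),
                                             attribution = c("both", "cation"),
                                             extrapolate = FALSE) {
  stopifnot(inherits(salt, "salt_definition"))
  attribution <- match.arg(attribution)
  kap_meas <- interp_table(salt$kappa_table, 2, C, extrapolate, "kappa")
  if (kap_meas <= 0) stop("data error: measured conductivity must be positive")
  kap_id <- ideal_conductivity(salt, C, constants)
  fac <- kap_meas / kap_id
  if (attribution == "both") {
    out <- list(fac * salt$cation$D_bulk, fac * salt$anion$D_bulk)
  } else {
    # keep the anion at bulk mobility, solve the cation term for kappa match
    pref <- constants$F^2 / (constants$R * constants$T) * C * 1000
    anion_part <- pref * salt$nu_minus * salt$anion$z^2 * salt$anion$D_bulk
    Dc <- (kap_meas - anion_part) / (pref * salt$nu_plus * salt$cation$z^2)
    if (Dc <= 0)
      stop("data error: conductivity deficit too large to attribute to the ",
           "cation alone (implied D_cation <= 0)")
    out <- list(Dc, salt$anion$D_bulk)
  }
  names(out) <- c(salt$cation$name, salt$anion$name)
  out$factor <- fac
  out
}

#' Read an ion table from TSV
#'
#' Columns `name`, `z`, `D_bulk_m2_per_s`; header row required, `#` comments
#' allowed.
#'
#' @param path Path to the TSV file.
#' @return Named list of `ion_species`.
#' @export
read_ion_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("name", "z", "D_bulk_m2_per_s")
  if (!all(need %in% names(tab)))
    stop("parse error in ", path, ": expected columns ",
         paste(need, collapse = ", "))
  ions <- lapply(seq_len(nrow(tab)), function(i)
    ion_species(tab$name[i], tab$z[i], tab$D_bulk_m2_per_s[i]))
  names(ions) <- tab$name
  ions
}

#' Read salt property tables from TSV
#'
#' Columns `C_mol_per_L`, `gamma_pm`, `kappa_S_per_m`; header row required,
#' `#` comments allowed.
#'
#' @param path Path to the TSV file.
#' @return A list with `gamma_table` and `kappa_table` data.frames, ready to
#'   pass to [salt_definition()].
#' @export
read_salt_property_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  need <- c("C_mol_per_L", "gamma_pm", "kappa_S_per_m")
  if (!all(need %in% names(tab)))
    stop("parse error in ", path, ": expected columns ",
         paste(need, collapse = ", "))
  list(gamma_table = tab[, c("C_mol_per_L", "gamma_pm")],
       kappa_table = tab[, c("C_mol_per_L", "kappa_S_per_m")])
}
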