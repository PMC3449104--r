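#' Axial effective fixed-charge profile
#'
#' The one-dimensional, volume-averaged concentration of ionized protein
#' residue charge seen by permeating ions, `X(x)` (signed, mol/L), on a
#' strictly increasing axial grid covering `[0, L]` nm. The coordinate
#' convention is that `x = 0` is the cis mouth (the side of protein addition).
#'
#' @param grid_nm Strictly increasing axial positions covering `[0, L]`, nm.
#' @param X_molar Fixed charge concentration at each node, mol/L (signed;
#'   negative = excess acidic charge, cation-selective tendency).
#' @param L_nm Channel length, nm. Defaults to `max(grid_nm)`.
#' @param area_nm2 Optional cross-section profile A(x), nm^2: scalar or one
#'   value per node, all positive.
#' @return An object of class `charge_profile`.
#' @examples
#' p <- charge_profile(seq(0, 4, length.out = 81), rep(-0.5, 81))
#' net_charge(p)
#' @export
charge_profile <- function(grid_nm, X_molar, L_nm = max(grid_nm),
                           area_nm2 = NULL) {
  if (length(grid_nm) < 2 || any(diff(grid_nm) <= 0))
    stop("domain error: grid must be strictly increasing with >= 2 nodes")
  if (length(X_molar) != length(grid_nm))
    stop("domain error: X must have one value per grid node")
  if (abs(grid_nm[1]) > 1e-9 || abs(grid_nm[length(grid_nm)] - L_nm) > 1e-9)
    stop("domain error: grid must cover [0, L]")
  if (!is.null(area_nm2)) {
    if (length(area_nm2) == 1) area_nm2 <- rep(area_nm2, length(grid_nm))
    if (length(area_nm2) != length(grid_nm) || any(area_nm2 <= 0))
      stop("domain error: area must be positive, scalar or one per node")
  }
  structure(list(grid_nm = as.numeric(grid_nm), X_molar = as.numeric(X_molar),
                 L_nm = L_nm, area_nm2 = area_nm2),
            class = "charge_profile")
}

#' @export
print.charge_profile <- function(x, ...) {
  cat(sprintf("<charge_profile> L = %.3g nm, %d nodes, X in [%.3g, %.3g] M, net %.3g e\n",
              x$L_nm, length(x$grid_nm), min(x$X_molar), max(x$X_molar),
              net_charge(x)))
  invisible(x)
}

.profile_area_m2 <- function(profile, default_area_nm2 = 1) {
  a <- if (is.null(profile$area_nm2)) rep(default_area_nm2,
                                          length(profile$grid_nm))
       else profile$area_nm2
  a * 1e-18
}

#' A titratable residue site on the channel axis
#'
#' A protonatable group characterized by its apparent (effective) pKa, i.e.
#' the dissociation constant shifted by the protein electrostatic
#' environment. Acidic sites (charge 0/-1) may additionally carry an
#' association constant `Kb` for a divalent cation, which competes with the
#' proton for the site.
#'
#' @param x_nm Axial position, nm (within `[0, L]` of the target profile).
#' @param pKa_eff Apparent pKa (dimensionless).
#' @param kind `"acid"` (neutral/deprotonated -1) or `"base"` (+1/neutral).
#' @param width_nm Gaussian smearing width used when depositing the site
#'   charge onto the axis, nm. Default 0.3 nm.
#' @param Kb Divalent-cation association constant, L/mol (acids only; >= 0).
#' @return An object of class `titratable_site`.
#' @export
titratable_site <- function(x_nm, pKa_eff, kind = c("acid", "base"),
                            width_nm = 0.3, Kb = 0) {
  kind <- match.arg(kind)
  if (width_nm <= 0) stop("domain error: width must be positive")
  if (Kb < 0) stop("domain error: Kb must be >= 0")
  if (kind == "base" && Kb != 0)
    stop("domain error: divalent binding (Kb) applies to acidic sites only")
  structure(list(x_nm = x_nm, pKa_eff = pKa_eff, kind = kind,
                 width_nm = width_nm, Kb = Kb),
            class = "titratable_site")
}

#' Fractional charge of a titratable site
#'
#' Henderson-Hasselbalch occupancy with competitive proton / divalent-cation
#' binding at acidic sites. For an acid the fractional charge is
#' `f = -1 / (1 + 10^(pKa_eff - pH) + Kb*M2)`; a site with a bound divalent
#' cation counts as neutralized by default, or as `+1` when
#' `bound_charge = 1` (the overcompensation reading, enabling charge-inversion
#' scenarios). For a base, `f = +1 / (1 + 10^(pH - pKa_eff))`.
#'
#' @param site A `titratable_site`.
#' @param pH Solution pH.
#' @param M2 Divalent cation concentration, mol/L (>= 0).
#' @param bound_charge Charge assigned to the divalent-bound state of an
#'   acidic site: 0 (default, neutralized) or +1 (overcompensation).
#' @return Fractional charge in elementary-charge units (signed).
#' @export
site_charge_fraction <- function(site, pH, M2 = 0, bound_charge = 0) {
  stopifnot(inherits(site, "titratable_site"))
  if (any(M2 < 0)) stop("domain error: M2 must be >= 0")
  if (!bound_charge %in% c(0, 1))
    stop("domain error: bound_charge must be 0 or +1")
  if (site$kind == "base") {
    1 / (1 + 10^(pH - site$pKa_eff))
  } else {
    denom <- 1 + 10^(site$pKa_eff - pH) + site$Kb * M2
    f_ion <- -1 / denom                      # deprotonated, unbound
    f_bound <- bound_charge * (site$Kb * M2) / denom
    f_ion + f_bound
  }
}

# Gaussian deposition kernel on [0, L], analytically normalized including the
# truncation at the channel ends; returns a linear density (1/m) on the grid.
.deposit_kernel <- function(x_nm, x0_nm, width_nm, L_nm) {
  z <- (x_nm - x0_nm) / width_nm
  norm <- stats::pnorm((L_nm - x0_nm) / width_nm) -
    stats::pnorm((0 - x0_nm) / width_nm)
  stats::dnorm(z) / (width_nm * 1e-9) / norm
}

#' Titrate a set of sites into a fixed-charge profile
#'
#' Evaluates the fractional charge of every site at the given pH and divalent
#' cation concentration, smears each site as a normalized Gaussian of its
#' width along the axis, converts to a volume concentration using the
#' cross-section area, and sums node-wise. The integral of the deposited
#' charge over the pore volume equals the sum of the fractional site charges
#' (in elementary-charge units).
#'
#' @param sites List of `titratable_site` objects.
#' @param pH Solution pH.
#' @param M2 Divalent cation concentration, mol/L.
#' @param grid_nm Axial grid for the output profile, nm.
#' @param L_nm Channel length, nm.
#' @param area_nm2 Cross-section area, nm^2 (scalar or per node).
#' @param bound_charge Passed to [site_charge_fraction()].
#' @return A `charge_profile`.
#' @export
titrate <- function(sites, pH, M2 = 0,
                    grid_nm = seq(0, 4, length.out = 401), L_nm = max(grid_nm),
                    area_nm2 = 1, bound_charge = 0) {
  if (inherits(sites, "titratable_site")) sites <- list(sites)
  N_A <- 6.02214076e23
  if (length(area_nm2) == 1) area_nm2 <- rep(area_nm2, length(grid_nm))
  A_m2 <- area_nm2 * 1e-18
  X <- numeric(length(grid_nm))
  for (s in sites) {
    stopifnot(inherits(s, "titratable_site"))
    if (s$x_nm < 0 || s$x_nm > L_nm)
      stop("domain error: site at x = ", s$x_nm, " nm outside [0, ", L_nm, "]")
    f <- site_charge_fraction(s, pH, M2, bound_charge)
    w <- .deposit_kernel(grid_nm, s$x_nm, s$width_nm, L_nm)   # 1/m
    X <- X + f / N_A * w / A_m2 / 1000                        # mol/L
  }
  charge_profile(grid_nm, X, L_nm, area_nm2)
}

#' Net channel charge
#'
#' Volume integral of the fixed charge concentration over the pore, in
#' elementary-charge units. Negative values indicate a cation-selective
#' tendency.
#'
#' @param profile A `charge_profile`.
#' @param default_area_nm2 Cross-section used when the profile carries none.
#' @return Net charge, elementary charges.
#' @export
net_charge <- function(profile, default_area_nm2 = 1) {
  stopifnot(inherits(profile, "charge_profile"))
  A <- .profile_area_m2(profile, default_area_nm2)
  x_m <- profile$grid_nm * 1e-9
  X_m3 <- profile$X_molar * 1000
  trapz_int(x_m, X_m3 * A) * 6.02214076e23
}

#' In-silico mutation: neutralize a region of the profile
#'
#' Sets `X(x) = 0` for nodes with `x_lo <= x <= x_hi`, leaving the rest of
#' the profile bit-for-bit unchanged. Emulates replacing charged residues by
#' neutral ones.
#'
#' @param profile A `charge_profile`.
#' @param x_lo,x_hi Interval bounds, nm, with `0 <= x_lo < x_hi <= L`.
#' @return A new `charge_profile`.
#' @export
neutralize_region <- function(profile, x_lo, x_hi) {
  stopifnot(inherits(profile, "charge_profile"))
  if (!(x_lo < x_hi) || x_lo < 0 || x_hi > profile$L_nm)
    stop("domain error: need 0 <= x_lo < x_hi <= L")
  X <- profile$X_molar
  X[profile$grid_nm >= x_lo & profile$grid_nm <= x_hi] <- 0
  charge_profile(profile$grid_nm, X, profile$L_nm, profile$area_nm2)
}

#' In-silico mutation: add smeared point charges
#'
#' Adds Gaussian-smeared charges of the given magnitudes (elementary-charge
#' units, signed) at the given axial positions. Emulates introducing charged
#' residues, e.g. acid-to-arginine substitutions.
#'
#' @param profile A `charge_profile`.
#' @param positions_nm Axial positions, nm.
#' @param magnitudes_e Charges in elementary-charge units (recycled).
#' @param width_nm Gaussian smearing width, nm.
#' @param default_area_nm2 Cross-section used when the profile carries none.
#' @return A new `charge_profile`.
#' @export
add_point_charges <- function(profile, positions_nm, magnitudes_e,
                              width_nm = 0.3, default_area_nm2 = 1) {
  stopifnot(inherits(profile, "charge_profile"))
  if (any(positions_nm < 0) || any(positions_nm > profile$L_nm))
    stop("domain error: positions must lie in [0, L]")
  magnitudes_e <- rep_len(magnitudes_e, length(positions_nm))
  N_A <- 6.02214076e23
  A <- .profile_area_m2(profile, default_area_nm2)
  X <- profile$X_molar
  for (i in seq_along(positions_nm)) {
    w <- .deposit_kernel(profile$grid_nm, positions_nm[i], width_nm,
                         profile$L_nm)
    X <- X + magnitudes_e[i] / N_A * w / A / 1000
  }
  charge_profile(profile$grid_nm, X, profile$L_nm, profile$area_nm2)
}

#' Read / write charge profiles as TSV
#'
#' Format: columns `x_nm`, `X_mol_per_L`, optional `A_nm2`; header row
#' required, `#` comments allowed.
#'
#' @param path Path to the TSV file.
#' @return `read_charge_profile` returns a `charge_profile`;
#'   `write_charge_profile` returns `path` invisibly.
#' @export
read_charge_profile <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  if (!all(c("x_nm", "X_mol_per_L") %in% names(tab)))
    stop("parse error in ", path, ": expected columns x_nm, X_mol_per_L")
  charge_profile(tab$x_nm, tab$X_mol_per_L,
                 area_nm2 = if ("A_nm2" %in% names(tab)) tab$A_nm2 else NULL)
}

#' @rdname read_charge_profile
#' @param profile A `charge_profile` to write.
#' @export
write_charge_profile <- function(profile, path) {
  stopifnot(inherits(profile, "charge_profile"))
  tab <- data.frame(x_nm = profile$grid_nm, X_mol_per_L = profile$X_molar)
  if (!is.null(profile$area_nm2)) tab$A_nm2 <- profile$area_nm2
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a titratable-site table from TSV
#'
#' Format: columns `x_nm`, `pKa_eff`, `kind`, `width_nm`, `Kb_L_per_mol`;
#' header row required, `#` comments allowed.
#'
#' @param path Path to the TSV file.
#' @return List of `titratable_site` objects.
#' @export
read_sites <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("x_nm", "pKa_eff", "kind", "width_nm", "Kb_L_per_mol")
  if (!all(need %in% names(tab)))
    stop("parse error in ", path, ": expected columns ",
         paste(need, collapse = ", "))
  lapply(seq_len(nrow(tab)), function(i)
    titratable_site(tab$x_nm[i], tab$pKa_eff[i], tab$kind[i],
                    tab$width_nm[i], tab$Kb_L_per_mol[i]))
}
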