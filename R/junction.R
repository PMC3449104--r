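#' Specify a liquid junction between two electrolyte solutions
#'
#' Each side is a table of ions with signed valence `z`, diffusion
#' coefficient `D` (m^2/s) and concentration `C` (mol/L). Both sides must be
#' electroneutral and at least one ion must differ across sides.
#'
#' @param left,right Data frames with columns `z`, `D`, `C` (and optionally
#'   `name`). Rows are matched by position: row i on the left and row i on
#'   the right describe the same species (use `C = 0` for a species absent
#'   from one side).
#' @param constants Output of [phys_constants()].
#' @return An object of class `junction_spec`.
#' @export
junction_spec <- function(left, right, constants = phys_constants()) {
  chk <- function(s, nm) {
    if (!all(c("z", "D", "C") %in% names(s)))
      stop("domain error: ", nm, " side needs columns z, D, C")
    if (any(s$C < 0) || any(s$D <= 0) || any(s$z == 0))
      stop("domain error: ", nm, " side has invalid z, D or C")
    if (abs(sum(s$z * s$C)) > 1e-9 * max(sum(abs(s$z) * s$C), 1e-300))
      stop("domain error: ", nm, " side is not electroneutral")
  }
  chk(left, "left"); chk(right, "right")
  if (nrow(left) != nrow(right) || any(left$z != right$z) ||
      any(left$D != right$D))
    stop("domain error: sides must list the same species (same z and D rows)")
  structure(list(left = left, right = right, constants = constants),
            class = "junction_spec")
}

#' Henderson liquid-junction potential
#'
#' Evaluates the Henderson expression for the potential difference
#' `LJP = phi_L - phi_R` across a junction of two electrolyte solutions,
#' assuming ideal solutions mixing linearly across the junction:
#' \deqn{LJP = -\frac{k_BT}{e}\,
#'   \frac{\sum_i z_i D_i (C_{i,L}-C_{i,R})}{\sum_i z_i^2 D_i (C_{i,L}-C_{i,R})}
#'   \ln \frac{\sum_i z_i^2 D_i C_{i,L}}{\sum_i z_i^2 D_i C_{i,R}}}
#' The degenerate case where the denominator vanishes (equal weighted ionic
#' strengths) is handled by its analytic limit rather than a division
#' blow-up; identical compositions return exactly 0.
#'
#' @param spec A `junction_spec`.
#' @param warn_ratio Warn when the weighted ionic-strength ratio of the two
#'   sides exceeds this factor, where the linear-mixing assumption degrades.
#' @return Signed potential, mV (`phi_L - phi_R`).
#' @export
henderson_ljp <- function(spec, warn_ratio = 20) {
  stopifnot(inherits(spec, "junction_spec"))
  z <- spec$left$z; D <- spec$left$D
  CL <- spec$left$C; CR <- spec$right$C
  Vt <- spec$constants$Vt_mV
  if (max(abs(CL - CR)) <= 1e-15 * max(CL, CR, 1e-300)) return(0)
  SL <- sum(z^2 * D * CL)
  SR <- sum(z^2 * D * CR)
  num <- sum(z * D * (CL - CR))
  den <- SL - SR
  if (max(SL, SR) / min(SL, SR) > warn_ratio)
    warning("ionic strengths differ by more than ", warn_ratio,
            "x: the Henderson linear-mixing assumption is a poor ",
            "approximation here")
  if (abs(den) < 1e-12 * max(SL, SR)) {
    # limit den -> 0: ln(SL/SR) ~ den/S, the ratio cancels
    return(-Vt * num / sqrt(SL * SR))
  }
  -Vt * (num / den) * log(SL / SR)
}

# ion table (z, D, C per species) for a bath of a single salt
.salt_bath_ions <- function(salt, C, use_activity = FALSE,
                            extrapolate = FALSE, D_override = NULL) {
  a <- if (use_activity) mean_activity(salt, C, extrapolate) else C
  D <- if (is.null(D_override)) c(salt$cation$D_bulk, salt$anion$D_bulk)
       else D_override
  data.frame(name = c(salt$cation$name, salt$anion$name),
             z = c(salt$cation$z, salt$anion$z),
             D = D,
             C = c(salt$nu_plus, salt$nu_minus) * a)
}

#' Net salt-bridge junction correction
#'
#' Total liquid-junction contribution of a double salt-bridge measurement to
#' the raw zero-current voltage, with the sign convention of the cis-minus-
#' trans applied potential: the bridge meets the cis bath at one electrode
#' and the trans bath at the other, so the net contribution is
#' `henderson_ljp(bridge vs cis) - henderson_ljp(bridge vs trans)`. This is
#' the `LJP` to subtract from `V_exp` to obtain the reversal potential.
#'
#' @param bridge_salt,bridge_C Bridge composition (a `salt_definition` and
#'   mol/L), typically concentrated KCl.
#' @param cis_salt,cis_C,trans_salt,trans_C Bath compositions.
#' @param use_activity Replace concentrations by mean activities in the
#'   Henderson expression (activity-corrected variant for nonideal
#'   solutions).
#' @param constants Output of [phys_constants()].
#' @param extrapolate Allow clamped extrapolation of the gamma tables.
#' @return Signed net LJP, mV.
#' @export
bridge_correction <- function(bridge_salt, bridge_C, cis_salt, cis_C,
                              trans_salt, trans_C, use_activity = FALSE,
                              constants = phys_constants(),
                              extrapolate = FALSE) {
  b <- .salt_bath_ions(bridge_salt, bridge_C, use_activity, extrapolate)
  ljp_side <- function(bath_salt, bath_C) {
    s <- .salt_bath_ions(bath_salt, bath_C, use_activity, extrapolate)
    # align species across the junction by name; absent species get C = 0
    allsp <- unique(rbind(b[c("name", "z", "D")], s[c("name", "z", "D")]))
    pad <- function(side) {
      cc <- side$C[match(allsp$name, side$name)]
      cc[is.na(cc)] <- 0
      cbind(allsp, C = cc)
    }
    henderson_ljp(junction_spec(pad(b), pad(s), constants))
  }
  ljp_side(cis_salt, cis_C) - ljp_side(trans_salt, trans_C)
}

#' Correct a raw zero-current voltage for the liquid-junction contribution
#'
#' `RP = V_exp - LJP`: the overall junction potential is subtracted from the
#' raw zero-current potential reading to obtain the channel reversal
#' potential.
#'
#' @param V_exp Raw zero-current voltage, mV.
#' @param ljp Net liquid-junction potential, mV (e.g. from
#'   [bridge_correction()]).
#' @return Reversal potential, mV.
#' @export
correct_rp <- function(V_exp, ljp) V_exp - ljp

#' Diffusion potential of a neutral ideal pore
#'
#' The potential drop across a neutral pore (devoid of fixed charge)
#' connecting two concentrations of a single salt, caused solely by the
#' unequal mobilities of the cation and anion. Evaluated with the Henderson
#' expression, which is exact for a single binary electrolyte; with
#' `use_activity` the boundary concentrations are replaced by mean
#' activities.
#'
#' @param salt A `salt_definition`.
#' @param C_L,C_R Bath concentrations, mol/L (left = cis).
#' @param use_activity Use mean activities instead of concentrations.
#' @param constants Output of [phys_constants()].
#' @param extrapolate Allow clamped extrapolation of the gamma table.
#' @param D_override Optional length-2 vector (cation, anion) of diffusion
#'   coefficients replacing the bulk values, e.g. effective salt-dependent
#'   ones for consistency studies.
#' @return Signed potential `phi_L - phi_R`, mV.
#' @export
diffusion_potential <- function(salt, C_L, C_R, use_activity = FALSE,
                                constants = phys_constants(),
                                extrapolate = FALSE, D_override = NULL) {
  if (C_L <= 0 || C_R <= 0) stop("domain error: concentrations must be > 0")
  l <- .salt_bath_ions(salt, C_L, use_activity, extrapolate, D_override)
  r <- .salt_bath_ions(salt, C_R, use_activity, extrapolate, D_override)
  henderson_ljp(junction_spec(l, r, constants))
}
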