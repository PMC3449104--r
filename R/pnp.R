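#' Bath (bulk solution) state at one side of the channel
#'
#' @param salt A `salt_definition`.
#' @param C Salt concentration, mol/L (> 0).
#' @param pH Solution pH (bookkeeping; the solver itself treats only the
#'   salt ions, pH enters through the titrated charge profile).
#' @param use_activity Replace the boundary concentrations by mean
#'   activities `gamma_pm(C) * C` (bulk nonideality correction; inside the
#'   pore concentrations are used).
#' @return An object of class `bath_state`.
#' @export
bath_state <- function(salt, C, pH = 7, use_activity = FALSE) {
  stopifnot(inherits(salt, "salt_definition"))
  if (C <= 0) stop("domain error: bath concentration must be > 0")
  structure(list(salt = salt, C = C, pH = pH, use_activity = use_activity),
            class = "bath_state")
}

#' Solver options for the 1D PNP model
#'
#' @param n_nodes Number of axial nodes (Poisson closure). Default 401.
#' @param closure `"poisson"` (full Poisson equation, default) or `"tms"`
#'   (local electroneutrality with Donnan interfacial jumps, in the spirit of
#'   the Teorell-Meyer-Sievers description; binary salts only).
#' @param L_nm Channel length, nm (used when the profile covers a different
#'   axis length than requested; default taken from the profile).
#' @param area_nm2 Uniform cross-section area, nm^2, used when the profile
#'   carries no area column. Default 1 nm^2.
#' @param temperature Kelvin. @param epsilon_r Solvent relative permittivity.
#' @param mode Diffusion-coefficient mode: `"ideal"` (bulk values),
#'   `"effective"` (salt-dependent values rescaled to the measured
#'   conductivity at the mean bath concentration), or `"exclusion"` (both
#'   ions share one diffusion coefficient, which suppresses the diffusion
#'   potential and isolates electrostatic exclusion).
#' @param attribution Passed to [effective_diffusion_coefficients()].
#' @param tol Convergence tolerance on the potential update, thermal units.
#' @param max_iter Maximum Gummel iterations per continuation stage.
#' @param refine Grade the mesh towards the channel mouths (boundary/Donnan
#'   layers) and where `|X|` is large.
#' @param rp_bracket Voltage bracket for the reversal-potential search, mV.
#' @param rp_tol_mV Reversal-potential root tolerance, mV. Default 0.01.
#' @param ode_rtol,ode_atol Integration tolerances of the TMS closure.
#' @param extrapolate Allow clamped extrapolation of salt property tables.
#' @return A list of class `pnp_options`.
#' @export
pnp_options <- function(n_nodes = 401, closure = c("poisson", "tms"),
                        L_nm = NULL, area_nm2 = 1,
                        temperature = 298.15, epsilon_r = 80,
                        mode = c("ideal", "effective", "exclusion"),
                        attribution = c("both", "cation"),
                        tol = 1e-9, max_iter = 500, refine = TRUE,
                        rp_bracket = c(-200, 200), rp_tol_mV = 0.01,
                        ode_rtol = 1e-10, ode_atol = 1e-8,
                        extrapolate = FALSE) {
  structure(list(n_nodes = n_nodes, closure = match.arg(closure), L_nm = L_nm,
                 area_nm2 = area_nm2, temperature = temperature,
                 epsilon_r = epsilon_r, mode = match.arg(mode),
                 attribution = match.arg(attribution), tol = tol,
                 max_iter = max_iter, refine = refine,
                 rp_bracket = rp_bracket, rp_tol_mV = rp_tol_mV,
                 ode_rtol = ode_rtol, ode_atol = ode_atol,
                 extrapolate = extrapolate),
            class = "pnp_options")
}

# ion bookkeeping shared by both closures: z, D (per mode) and boundary
# concentrations in mol/m^3
.solver_setup <- function(left, right, options) {
  stopifnot(inherits(left, "bath_state"), inherits(right, "bath_state"))
  sl <- left$salt; sr <- right$salt
  same <- identical(c(sl$cation$name, sl$anion$name, sl$cation$z, sl$anion$z,
                      sl$nu_plus, sl$nu_minus),
                    c(sr$cation$name, sr$anion$name, sr$cation$z, sr$anion$z,
                      sr$nu_plus, sr$nu_minus))
  if (!same)
    stop("domain error: both baths must contain the same salt family")
  k <- phys_constants(options$temperature, options$epsilon_r)
  D <- switch(options$mode,
    ideal = c(sl$cation$D_bulk, sl$anion$D_bulk),
    exclusion = rep(sqrt(sl$cation$D_bulk * sl$anion$D_bulk), 2),
    effective = {
      de <- effective_diffusion_coefficients(
        sl, mean(c(left$C, right$C)), k,
        attribution = options$attribution, extrapolate = options$extrapolate)
      c(de[[1]], de[[2]])
    })
  bvals <- function(b) {
    a <- if (b$use_activity)
      mean_activity(b$salt, b$C, options$extrapolate) else b$C
    c(b$salt$nu_plus, b$salt$nu_minus) * a * 1000   # mol/m^3
  }
  list(k = k, z = c(sl$cation$z, sl$anion$z), D = D,
       names = c(sl$cation$name, sl$anion$name),
       cL = bvals(left), cR = bvals(right))
}

# graded axial mesh (meters): clustered at the mouths and where |X| is large
.solver_grid <- function(profile, options) {
  L_m <- (if (is.null(options$L_nm)) profile$L_nm else options$L_nm) * 1e-9
  n <- options$n_nodes
  if (!options$refine) return(seq(0, L_m, length.out = n))
  s <- seq(0, 1, length.out = 4001)
  Xs <- stats::approx(profile$grid_nm / profile$L_nm, abs(profile$X_molar),
                      xout = s, rule = 2)$y
  Xn <- if (max(Xs) > 0) Xs / max(Xs) else 0 * Xs
  dens <- 1 + 4 * (exp(-s / 0.06) + exp(-(1 - s) / 0.06)) + 1.5 * Xn
  cum <- cumsum(c(0, (dens[-1] + dens[-length(dens)]) / 2 * diff(s)))
  cum <- cum / cum[length(cum)]
  x <- stats::approx(cum, s, xout = seq(0, 1, length.out = n), ties = "ordered")$y * L_m
  x[1] <- 0; x[n] <- L_m
  x
}

# Scharfetter-Gummel interface fluxes for one ion, mol/s
.sg_flux <- function(cvec, u, z, D, A_half, h) {
  du <- z * diff(u)
  n <- length(cvec)
  D * A_half / h * (bernoulli_fn(du) * cvec[-n] - bernoulli_fn(-du) * cvec[-1])
}

# tridiagonal continuity solve for one ion given the potential
.continuity_solve <- function(u, z, D, A_half, h, cb_L, cb_R) {
  n <- length(u)
  du <- z * diff(u)
  g <- D * A_half / h
  Bp <- bernoulli_fn(du)    # weight on left node
  Bm <- bernoulli_fn(-du)   # weight on right node
  # row j (interior): g[j-1]*Bp[j-1]*c[j-1] - (g[j-1]*Bm[j-1]+g[j]*Bp[j])*c[j]
  #                   + g[j]*Bm[j]*c[j+1] = 0
  a <- c(g[-(n - 1)] * Bp[-(n - 1)], 0)              # sub-diagonal, length n-1
  b <- c(1, -(g[-(n - 1)] * Bm[-(n - 1)] + g[-1] * Bp[-1]), 1)
  cc <- c(0, g[-1] * Bm[-1])                         # super-diagonal
  d <- c(cb_L, rep(0, n - 2), cb_R)
  tridiag_solve(a, b, cc, d)
}

.solve_pnp_fd <- function(profile, left, right, V_mV, options, init = NULL) {
  su <- .solver_setup(left, right, options)
  k <- su$k
  x <- .solver_grid(profile, options)
  n <- length(x)
  h <- diff(x)
  X <- stats::approx(profile$grid_nm * 1e-9, profile$X_molar * 1000,
                     xout = x, rule = 2)$y
  A <- if (is.null(profile$area_nm2)) rep(options$area_nm2 * 1e-18, n)
       else stats::approx(profile$grid_nm * 1e-9, profile$area_nm2 * 1e-18,
                          xout = x, rule = 2)$y
  A_half <- (A[-1] + A[-n]) / 2
  Vt_V <- k$Vt_mV / 1000
  uL <- V_mV / k$Vt_mV
  pref <- k$F / (k$eps0 * k$epsilon_r * Vt_V)    # 1/m^2 per (mol/m^3)
  nion <- length(su$z)

  # Laplacian coefficients (interior nodes)
  hm <- h[-(n - 1)]; hp <- h[-1]
  alo <- 2 / ((hm + hp) * hm)
  ahi <- 2 / ((hm + hp) * hp)

  run_gummel <- function(lambda, u, cmat) {
    for (iter in seq_len(options$max_iter)) {
      for (i in seq_len(nion)) {
        ci <- .continuity_solve(u, su$z[i], su$D[i], A_half, h,
                                su$cL[i], su$cR[i])
        cmat[, i] <- pmax(ci, 0)
      }
      u_prev <- u
      u_cont <- u
      for (inner in 1:60) {
        expo <- outer(u - u_cont, su$z)
        ctil <- cmat * exp(pmin(pmax(-expo, -50), 50))
        rho <- drop(ctil %*% su$z) + lambda * X
        lap <- alo * u[-c(n - 1, n)] - (alo + ahi) * u[-c(1, n)] +
          ahi * u[-c(1, 2)]
        R <- lap + pref * rho[-c(1, n)]
        diag_extra <- pref * drop((ctil * rep(su$z^2, each = n)) %*% rep(1, nion))
        bdiag <- -(alo + ahi) - diag_extra[-c(1, n)]
        du <- tridiag_solve(alo[-1], bdiag, ahi[-(n - 2)], -R)
        du <- pmin(pmax(du, -2), 2)
        u[-c(1, n)] <- u[-c(1, n)] + du
        if (max(abs(du)) < 1e-11) break
      }
      if (max(abs(u - u_prev)) < options$tol && iter > 1)
        return(list(u = u, cmat = cmat, iter = iter, converged = TRUE))
    }
    list(u = u, cmat = cmat, iter = options$max_iter, converged = FALSE)
  }

  # initial iterate: linear potential and linearly mixed concentrations,
  # or a previous solution on the same grid (warm start)
  if (!is.null(init) && length(init$u) == n) {
    u0 <- init$u; c0 <- init$cmat
    u0[1] <- uL; u0[n] <- 0
  } else {
    frac <- (x - x[1]) / (x[n] - x[1])
    u0 <- uL * (1 - frac)
    c0 <- sapply(seq_len(nion), function(i)
      su$cL[i] * (1 - frac) + su$cR[i] * frac)
  }

  res <- run_gummel(1, u0, c0)
  if (!res$converged) {
    # continuation: ramp the fixed charge up from a weakly charged state
    for (lam in c(0.1, 0.25, 0.5, 0.75, 1)) {
      res <- run_gummel(lam, res$u, res$cmat)
      if (!res$converged && lam == 1)
        stop("solver error: PNP iteration did not converge (last potential ",
             "update ", format(max(abs(res$u)), digits = 3), " Vt)")
    }
  }
  u <- res$u; cmat <- res$cmat

  flux <- numeric(nion)
  resid <- 0
  for (i in seq_len(nion)) {
    Jk <- .sg_flux(cmat[, i], u, su$z[i], su$D[i], A_half, h)
    flux[i] <- mean(Jk)
    Jref <- su$D[i] * mean(A) * max(su$cL[i], su$cR[i]) / (x[n] - x[1])
    resid <- max(resid, max(abs(Jk - flux[i])) / max(abs(flux[i]), 1e-6 * Jref))
  }
  names(flux) <- su$names
  I_A <- k$F * sum(su$z * flux)
  conc <- cmat / 1000
  colnames(conc) <- su$names
  structure(list(x_nm = x * 1e9, phi_mV = u * k$Vt_mV, conc = conc,
                 flux = flux, I_pA = I_A * 1e12, V_mV = V_mV,
                 residual = resid, iterations = res$iter,
                 closure = "poisson", donnan_mV = NULL,
                 D_used = stats::setNames(su$D, su$names)),
            class = "pnp_solution")
}

# Donnan potential (thermal units) equilibrating a bath with local fixed
# charge X (mol/m^3): sum_i z_i c_i exp(-z_i d) + X = 0
.donnan_root <- function(z, cb, X) {
  g <- function(d) sum(z * cb * exp(-z * d)) + X
  stats::uniroot(g, c(-60, 60), tol = 1e-14)$root
}

# small damped Newton with numerical Jacobian for the TMS shooting residual;
# `scale` sets the finite-difference step and guards against zero unknowns
.newton2 <- function(fn, x0, scale = pmax(abs(x0), 1e-12), tol = 1e-9,
                     max_iter = 60) {
  x <- x0
  f <- tryCatch(fn(x), error = function(e) NULL)
  if (is.null(f)) return(list(x = x, f = Inf, converged = FALSE))
  for (it in seq_len(max_iter)) {
    if (max(abs(f)) < tol) return(list(x = x, f = f, converged = TRUE))
    Jc <- matrix(0, length(f), length(x))
    for (j in seq_along(x)) {
      dx <- max(abs(x[j]), scale[j]) * 1e-7
      xp <- x; xp[j] <- xp[j] + dx
      fp <- tryCatch(fn(xp), error = function(e) NULL)
      if (is.null(fp)) {
        xp[j] <- x[j] - dx
        fp <- tryCatch(fn(xp), error = function(e) NULL)
        if (is.null(fp)) return(list(x = x, f = f, converged = FALSE))
        dx <- -dx
      }
      Jc[, j] <- (fp - f) / dx
    }
    step <- tryCatch(solve(Jc, -f), error = function(e) NULL)
    if (is.null(step)) return(list(x = x, f = f, converged = FALSE))
    lam <- 1
    repeat {
      xn <- x + lam * step
      fn_new <- tryCatch(fn(xn), error = function(e) NULL)
      if (!is.null(fn_new) && all(is.finite(fn_new)) &&
          (sum(fn_new^2) < sum(f^2) || lam < 1 / 256)) break
      lam <- lam / 2
    }
    if (is.null(fn_new) || !all(is.finite(fn_new)))
      return(list(x = x, f = f, converged = FALSE))
    x <- xn; f <- fn_new
  }
  list(x = x, f = f, converged = max(abs(f)) < tol * 100)
}

.solve_pnp_tms <- function(profile, left, right, V_mV, options, init = NULL) {
  su <- .solver_setup(left, right, options)
  k <- su$k
  z <- su$z; D <- su$D
  L_m <- (if (is.null(options$L_nm)) profile$L_nm else options$L_nm) * 1e-9
  A_m2 <- (if (is.null(profile$area_nm2)) options$area_nm2
           else mean(profile$area_nm2)) * 1e-18
  xs <- profile$grid_nm * 1e-9 * (L_m / (profile$L_nm * 1e-9))
  Xs <- profile$X_molar * 1000
  if (length(xs) >= 3 && any(Xs != 0)) {
    Xf <- stats::splinefun(xs, Xs, method = "monoH.FC")
    Xfun <- function(x) Xf(x); Xpfun <- function(x) Xf(x, deriv = 1)
  } else {
    Xf <- stats::approxfun(xs, Xs, rule = 2)
    Xfun <- function(x) Xf(x); Xpfun <- function(x) 0
  }
  dL <- .donnan_root(z, su$cL, Xfun(0))
  cp0 <- su$cL[1] * exp(-z[1] * dL)
  cscale <- max(su$cL, su$cR)
  u0_at <- function(V) V / k$Vt_mV + dL

  floor_c <- 1e-10 * cscale
  derivs <- function(x, y, parms) {
    # clamp trial iterates away from zero; positivity of the accepted
    # solution is checked in shoot()
    cp <- max(y[1], floor_c); u <- y[2]
    Xx <- Xfun(x); Xp <- Xpfun(x)
    cm <- max(-(z[1] * cp + Xx) / z[2], floor_c)
    # D+ A (cp' + z+ cp u') = -J+ ; D- A (cm' + z- cm u') = -J-
    a11 <- D[1] * A_m2;            a12 <- D[1] * A_m2 * z[1] * cp
    a21 <- -D[2] * A_m2 * z[1] / z[2]; a22 <- D[2] * A_m2 * z[2] * cm
    r1 <- -parms[1]
    r2 <- -parms[2] + D[2] * A_m2 * Xp / z[2]
    det <- a11 * a22 - a12 * a21
    list(c((r1 * a22 - a12 * r2) / det, (a11 * r2 - r1 * a21) / det))
  }

  shoot <- function(J, u0, times = c(0, L_m)) {
    sol <- suppressWarnings(
      deSolve::lsoda(c(cp0, u0), times, derivs, parms = J,
                     rtol = options$ode_rtol,
                     atol = c(options$ode_atol * cscale, 1e-12),
                     maxsteps = 20000))
    if (attr(sol, "istate")[1] < 0 || any(!is.finite(sol[nrow(sol), -1])) ||
        any(sol[, 2] <= floor_c))
      stop("solver error: TMS integration failed (depleted or divergent)")
    sol
  }
  resid_at <- function(V) {
    u0 <- u0_at(V)
    function(J) {
      sol <- shoot(J, u0)
      cpL <- sol[nrow(sol), 2]; uLend <- sol[nrow(sol), 3]
      cmL <- -(z[1] * cpL + Xfun(L_m)) / z[2]
      c((cpL - su$cR[1] * exp(-z[1] * uLend)) / cscale,
        (cmL - su$cR[2] * exp(-z[2] * uLend)) / cscale)
    }
  }
  guess_at <- function(V) {
    dR_guess <- .donnan_root(z, su$cR, Xfun(L_m))
    cpR_face <- su$cR[1] * exp(-z[1] * dR_guess)
    cmR_face <- -(z[1] * cpR_face + Xfun(L_m)) / z[2]
    cm0 <- -(z[1] * cp0 + Xfun(0)) / z[2]
    c(D[1] * A_m2 * ((cp0 - cpR_face) / L_m +
                       z[1] * (cp0 + cpR_face) / 2 *
                       (u0_at(V) - dR_guess) / L_m),
      D[2] * A_m2 * ((cm0 - cmR_face) / L_m))
  }
  Jscale <- D * A_m2 * cscale / L_m
  solve_at <- function(V, Jstart)
    .newton2(resid_at(V), Jstart, scale = Jscale, tol = 1e-10)

  J0 <- if (!is.null(init) && length(init) == 2 && all(is.finite(init)))
    init else guess_at(V_mV)
  nt <- solve_at(V_mV, J0)
  if (!nt$converged) {
    # continuation in applied bias from 0, warm-starting each step and
    # falling back to the fresh diffusive guess where the warm start fails
    Jcur <- NULL
    for (frac in seq(0.1, 1, by = 0.1)) {
      Vf <- V_mV * frac
      nt <- if (is.null(Jcur)) solve_at(Vf, guess_at(Vf))
            else solve_at(Vf, Jcur)
      if (!nt$converged) nt <- solve_at(Vf, guess_at(Vf))
      if (!nt$converged)
        stop("solver error: TMS shooting did not converge at V = ",
             format(Vf, digits = 4), " mV (residual ",
             format(max(abs(nt$f)), digits = 3), ")")
      Jcur <- nt$x
    }
  }
  J <- nt$x
  sol <- shoot(J, u0_at(V_mV), times = seq(0, L_m, length.out = 101))
  u <- sol[, 3]; cp <- sol[, 2]
  cm <- -(z[1] * cp + Xfun(sol[, 1])) / z[2]
  conc <- cbind(cp, cm) / 1000
  colnames(conc) <- su$names
  flux <- stats::setNames(J, su$names)
  I_A <- k$F * sum(z * J)
  structure(list(x_nm = sol[, 1] * 1e9, phi_mV = u * k$Vt_mV, conc = conc,
                 flux = flux, I_pA = I_A * 1e12, V_mV = V_mV,
                 residual = max(abs(nt$f)), iterations = NA_integer_,
                 closure = "tms",
                 donnan_mV = c(left = dL * k$Vt_mV,
                               right = u[length(u)] * k$Vt_mV,
                               internal = (u[1] - u[length(u)]) * k$Vt_mV),
                 D_used = stats::setNames(D, su$names)),
            class = "pnp_solution")
}

#' Solve the steady-state 1D PNP system for one bias voltage
#'
#' Solves the coupled Nernst-Planck fluxes
#' `J_i = -D_i A(x) [dC_i/dx + z_i C_i (e/kT) dphi/dx]` (constant in x at
#' steady state) and the Poisson equation
#' `d2phi/dx2 = -(F / eps0 eps_r) (sum_i z_i C_i + X(x))` over the channel
#' axis, with Dirichlet bulk boundary conditions at the mouths. The
#' discretization uses exponential-fitting (Scharfetter-Gummel) fluxes with
#' damped Gummel iteration and fixed-charge continuation for strongly
#' charged pores. The `"tms"` closure instead imposes local electroneutrality
#' `sum_i z_i C_i + X = 0` with equilibrium Donnan jumps at both interfaces
#' (binary salts), reported separately in `donnan_mV`.
#'
#' @param profile A `charge_profile` (use an all-zero profile for a neutral
#'   pore).
#' @param left,right `bath_state` objects; `left` is the cis side (`x = 0`).
#' @param V_mV Applied bias, mV, defined as cis minus trans.
#' @param options A [pnp_options()] list.
#' @param init Optional warm start (a previous solution's internal state).
#' @return A `pnp_solution`: node positions `x_nm`, potential `phi_mV`,
#'   per-ion concentrations `conc` (mol/L), constant fluxes `flux` (mol/s,
#'   cis-to-trans positive), total current `I_pA`, the applied `V_mV`, the
#'   relative flux-constancy `residual`, and for the TMS closure the Donnan
#'   and internal potential contributions.
#' @export
solve_pnp <- function(profile, left, right, V_mV, options = pnp_options(),
                      init = NULL) {
  stopifnot(inherits(profile, "charge_profile"), is.finite(V_mV))
  if (options$closure == "poisson")
    .solve_pnp_fd(profile, left, right, V_mV, options, init)
  else
    .solve_pnp_tms(profile, left, right, V_mV, options, init)
}

#' @export
print.pnp_solution <- function(x, ...) {
  cat(sprintf("<pnp_solution> %s closure, V = %.3g mV, I = %.4g pA, residual %.2g\n",
              x$closure, x$V_mV, x$I_pA, x$residual))
  invisible(x)
}

# internal state of a solution usable as warm start
.warm_state <- function(sol, Vt_mV) {
  if (is.null(sol) || sol$closure != "poisson") return(NULL)
  list(u = sol$phi_mV / Vt_mV, cmat = sol$conc * 1000)
}

#' Reversal potential of the channel
#'
#' The applied transmembrane voltage (cis minus trans) at which the total
#' ionic current vanishes, found by bracketed root search of `I(V)` to the
#' requested tolerance. At the reversal potential the net current is zero
#' but the individual ionic fluxes are in general nonzero (multi-ionic
#' transport).
#'
#' @param profile A `charge_profile`.
#' @param left,right `bath_state` objects.
#' @param options A [pnp_options()] list (`rp_bracket`, `rp_tol_mV` control
#'   the search).
#' @return Reversal potential, mV.
#' @export
reversal_potential <- function(profile, left, right, options = pnp_options()) {
  Vt_mV <- phys_constants(options$temperature)$Vt_mV
  cache <- new.env(parent = emptyenv())
  cache$last <- NULL
  f <- function(V) {
    init <- if (options$closure == "poisson") .warm_state(cache$last, Vt_mV)
            else cache$init_J
    sol <- solve_pnp(profile, left, right, V, options, init = init)
    cache$last <- sol
    if (options$closure == "tms") cache$init_J <- unname(sol$flux)
    sol$I_pA
  }
  lo <- options$rp_bracket[1]; hi <- options$rp_bracket[2]
  I0 <- f(0)
  if (abs(I0) < 1e-13) return(0)
  # walk outward from 0 toward the sign change rather than jumping to the
  # bracket ends, so warm starts stay effective
  step <- if (I0 > 0) -10 else 10
  Va <- 0; Ia <- I0; Vb <- 0
  repeat {
    Vb <- Vb + step
    if (Vb < lo || Vb > hi) {
      Ib <- f(max(min(Vb, hi), lo))
      if (sign(Ib) == sign(Ia))
        stop("bracket error: I(V) has no sign change in [", lo, ", ", hi,
             "] mV; I = ", format(Ia, digits = 4), " pA and ",
             format(Ib, digits = 4), " pA at the ends")
      Vb <- max(min(Vb, hi), lo)
      break
    }
    Ib <- f(Vb)
    if (sign(Ib) != sign(Ia)) break
    Va <- Vb; Ia <- Ib
  }
  stats::uniroot(f, lower = min(Va, Vb), upper = max(Va, Vb),
                 f.lower = if (Va < Vb) Ia else Ib,
                 f.upper = if (Va < Vb) Ib else Ia,
                 tol = options$rp_tol_mV)$root
}

#' Channel conductance in symmetric solutions
#'
#' `G = I(V)/V` with the current from the PNP solution, by convention at
#' +100 mV applied bias in symmetric baths. With `options$mode =
#' "effective"` the diffusion coefficients are rescaled to the measured
#' electrolyte conductivity at the bath concentration.
#'
#' @param profile A `charge_profile`.
#' @param bath A `bath_state` used on both sides.
#' @param V_mV Applied bias, mV. Default +100.
#' @param options A [pnp_options()] list.
#' @return Conductance in nS.
#' @export
conductance <- function(profile, bath, V_mV = 100, options = pnp_options()) {
  if (V_mV == 0) stop("domain error: conductance needs a nonzero bias")
  sol <- solve_pnp(profile, bath, bath, V_mV, options)
  sol$I_pA / V_mV
}

#' Junction potential from a numerical free-junction PNP solution
#'
#' Solves the Nernst-Planck / electroneutrality system across a neutral
#' mixing zone joining the two solutions and returns the zero-current
#' potential difference. An independent numerical route to the junction
#' potential, complementary to the closed-form Henderson expression.
#'
#' @param salt A `salt_definition`.
#' @param C_L,C_R Concentrations on the two sides, mol/L.
#' @param use_activity Replace boundary concentrations by mean activities.
#' @param options A [pnp_options()] list; the closure is forced to `"tms"`
#'   (a free junction is electroneutral).
#' @return Signed potential `phi_L - phi_R`, mV.
#' @export
junction_potential_pnp <- function(salt, C_L, C_R, use_activity = FALSE,
                                   options = pnp_options(closure = "tms")) {
  options$closure <- "tms"
  L_nm <- if (is.null(options$L_nm)) 4 else options$L_nm
  neutral <- charge_profile(seq(0, L_nm, length.out = 5), rep(0, 5), L_nm)
  reversal_potential(neutral,
                     bath_state(salt, C_L, use_activity = use_activity),
                     bath_state(salt, C_R, use_activity = use_activity),
                     options)
}
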