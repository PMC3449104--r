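---
title: "Modelling selectivity and conductance of wide ion channels with 1D PNP"
author: "pnporin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling selectivity and conductance of wide ion channels with 1D PNP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pnporin)
```

## The problem

Wide, water-filled protein channels (bacterial porins such as OmpF being the
canonical example) conduct small inorganic ions passively and
multi-ionically. Their weak selectivity — a preference for cations or anions
read off the sign of the reversal potential (RP), the applied voltage at
which net current vanishes under a salt gradient — is set by an interplay
of three effects:

1. **Electrostatic exclusion/accumulation** by the ionized protein
   residues, summarized as an axial effective fixed-charge concentration
   profile $X(x)$ along the pore;
2. **Diffusional asymmetry** of the electrolyte: when cation and anion
   mobilities differ (dramatically so for 2:1 salts such as MgCl$_2$ or
   CaCl$_2$), a diffusion potential contributes to the measured RP;
3. **Specific binding** of divalent cations to acidic residues, which
   competes with protonation and retitrates the channel charge.

In 1:1 salts with nearly equal mobilities (KCl) the first effect dominates
and RP measurements read out the channel charge almost directly. In salts
of divalent cations all three effects are comparable, and a channel with
net *negative* charge can show *anionic* selectivity. This package
implements the modelling chain needed to dissect these contributions, plus
a synthetic-data layer that stands in for structure-derived charge
profiles and wet-lab measurements.

## The model

### Electrodiffusion core

Steady-state Nernst–Planck fluxes for each ion over the pore axis
$x \in [0, L]$ (cis mouth at $x = 0$, the side of protein addition; applied
voltage is cis minus trans):

$$J_i = -D_i A(x) \left[\frac{dC_i}{dx}
        + z_i C_i \frac{e}{k_B T}\frac{d\phi}{dx}\right],$$

constant in $x$ at steady state, coupled to the Poisson equation

$$\frac{d^2\phi}{dx^2} = -\frac{F}{\varepsilon_0\varepsilon_r}
  \left(\sum_i z_i C_i + X(x)\right),$$

with Dirichlet bulk boundary conditions at the mouths (access resistance is
neglected). $X(x)$ is the signed, volume-averaged concentration of ionized
residue charge. The default geometry is a uniform cylinder with
$L = 4\,\mathrm{nm}$ and $A = 1\,\mathrm{nm}^2$, chosen so that the
neutral-pore conductance in molar 1:1 salt lands in the familiar nS range;
both are configurable, and a per-node area column is honoured.

An alternative **electroneutral closure** (`closure = "tms"`, in the spirit
of the Teorell–Meyer–Sievers description of charged membranes) replaces
Poisson with local electroneutrality $\sum_i z_i C_i + X = 0$ plus
equilibrium Donnan jumps at both interfaces; the Donnan and internal
(diffusional) contributions are reported separately. The two closures are
not interchangeable at porin dimensions: at 0.1 M the Debye length
($\sim$1 nm) is a quarter of the pore length, so the Poisson closure
retains genuine space charge and the closures differ at the mV level. They
agree to well under 1 mV at molar concentrations, where Debye layers are
thin — the regime the closure-agreement test uses.

### Junctions and measurement corrections

Experimental RPs are read off against salt-bridge electrodes, so the raw
zero-current voltage contains liquid-junction potentials (LJP):
$\mathrm{RP} = V_{\exp} - \mathrm{LJP}$. The package evaluates the
Henderson expression for arbitrary ion mixtures, takes its analytic limit
when the weighted-ionic-strength denominator vanishes (instead of dividing
by zero), warns when the two solutions' ionic strengths differ more than
20-fold (where the linear-mixing assumption degrades), and offers an
activity-corrected variant that replaces concentrations by mean
activities. For a single binary electrolyte the junction potential is
profile-independent, so Henderson is exact there; the package also computes
the junction numerically (electroneutral PNP across a neutral mixing zone)
as an independent cross-check — the two routes agree to well below 0.1 mV.

With KCl baths the net correction for a 2 M KCl double bridge is about
1 mV and is routinely ignored; in divalent-cation salts it is several-fold
larger and comparable to the RPs themselves, which is why the simulation
chain includes it explicitly.

### Electrolyte nonideality

Measured properties enter as tables: mean activity coefficient
$\gamma_\pm(C)$ and conductivity $\kappa(C)$ versus molar concentration,
interpolated **piecewise-linearly**. Linear interpolation was chosen over
splines because such tables are coarse and a spline can oscillate near the
$\gamma_\pm$ minimum of 2:1 salts; extrapolation is disabled by default
and clamps to the end values when enabled. Molal-scale coefficients are
converted with the exact thermodynamic relation
$\gamma_c = \gamma_m m \rho_0 / C$; the density table is a user input with
a pure-water default ($\rho_0 = 0.997$ kg/L), since the choice barely
matters at these precisions.

The strong conductivity saturation of 2:1 salts is folded into the
transport model as **effective salt-dependent diffusion coefficients**:
both ions' bulk $D_i$ are scaled by
$\kappa_\mathrm{meas}(C)/\kappa_\mathrm{ideal}(C)$, where
$\kappa_\mathrm{ideal} = (F^2/RT)\sum_i z_i^2 D_i \nu_i C$. Scaling both
ions equally preserves the bulk transport numbers; this is the model's
single-parameter choice, made because conductivity alone cannot apportion
the deficit between the ions. An alternative attribution that loads the
whole deficit onto the (divalent) cation — plausibly the species slowed
most — is available for sensitivity analysis, with a validity check: a
deficit larger than the cation's ideal share cannot be attributed to it.

In asymmetric baths the effective coefficients are evaluated at the mean of
the two bath concentrations. With `use_activity`, *boundary* concentrations
are replaced by activities; inside the pore concentrations are used (bulk
nonideality is corrected, intra-pore nonideality is not modelled).

### Titration and divalent binding

Each titratable site carries an apparent (effective) pKa — the dissociation
constant shifted by the protein environment; computing those shifts from a
3D structure is upstream of this package, which takes them as inputs.
Acidic sites additionally carry an association constant $K_b$ (L/mol) for
a divalent cation that competes with the proton:

$$f_\mathrm{acid} = \frac{-1}{1 + 10^{pK_a^\mathrm{eff} - pH} + K_b M_2},$$

with the bound state counted as neutral by default. The alternative
reading — a bound divalent overcompensating the site to net $+1$, the
"charge inversion" scenario — is available via `bound_charge = 1`; the
experimental record deliberately leaves the two interpretations open, so
both are implemented and the neutral one is the default (it is the weaker
assumption). Bases titrate as
$f = +1/(1 + 10^{pH - pK_a^\mathrm{eff}})$. A consequence of the
competitive form, verified numerically to $10^{-8}$, is that the
half-titration point (half of the *attainable* charge at given $M_2$)
sits at $pK_a^\mathrm{eff} - \log_{10}(1 + K_b M_2)$: binding pushes the
site's proton response to lower pH, while dilution of the divalent
restores the full pH sensitivity.

Sites are deposited onto the axis as normalized Gaussians (width default
0.3 nm, truncation at the channel ends handled analytically) and converted
to concentration through the pore cross-section; the deposited integral
equals the summed fractional site charges exactly. Averaging 3D charge
onto an axis has no canonical kernel, so the width is an explicit knob,
not a hidden constant.

## Numerical choices

* **Discretization**: finite volumes with Scharfetter–Gummel exponential
  fitting of the drift-diffusion flux, which stays stable at large
  $|z\phi|$; 401 nodes by default on a mesh graded toward the mouths
  (boundary/Donnan layers) and toward regions of large $|X|$. RP and
  conductance move by well under 0.5% when the mesh is doubled.
* **Nonlinear solve**: Gummel (alternating) iteration — tridiagonal
  continuity solves per ion given the potential, then a damped Newton
  solve of the nonlinear Poisson step with Boltzmann-linearized
  concentrations (update clamp $\pm 2\,k_BT/e$). Convergence is declared
  when the potential update falls below $10^{-9}\,k_BT/e$; because the
  continuity solves enforce flux constancy exactly, the reported residual
  (relative flux non-constancy, measured against the larger of the flux
  itself and $10^{-6}$ of the diffusive flux scale) is at numerical noise
  on converged solutions. Strongly charged pores that fail to converge
  directly are reached by ramping $X$ up in stages.
* **TMS closure**: for binary salts the electroneutral system reduces to
  two ODEs (cation concentration and potential) with the two constant
  fluxes as unknowns; these are found by damped-Newton shooting
  (finite-difference Jacobian scaled to the diffusive flux, `lsoda`
  integration at rtol $10^{-10}$, tightened to $10^{-12}$ for the
  exact-limit checks). Trial iterates that would deplete a concentration
  are clamped during integration and rejected on exit; biases the Newton
  cannot reach directly are approached by continuation in the applied
  voltage.
* **Reversal potential**: bracketed root search of $I(V)$ within
  $[-200, 200]$ mV to 0.01 mV, walking outward from 0 V so that warm
  starts (previous solution as initial iterate) stay effective; a missing
  sign change raises a bracket error reporting $I$ at both ends.
* **Degenerate inputs**: identical junction compositions return exactly
  0 mV; a vanishing Henderson denominator takes the analytic limit;
  equilibrium runs (equal baths, zero bias) return zero fluxes with
  machine-zero currents.

## The synthetic-data layer

The generator replaces the two external inputs of the real analysis:

* **Charge profiles** (`make_profile`): parametric shapes emulating
  structure-derived profiles — a wild-type-like net $-3$ e profile with
  two constriction acids; a variant with the constriction pair removed
  ($+2$ e) or replaced by positive sites ($+4$ e), matching the
  whole-site bookkeeping of constriction mutants; and a divalent-bound
  ("zfg") variant with a $+1.5$ e lobe at the constriction and net
  $-1.5$ e. The absolute concentration scale of real profiles is not
  available numerically, so these are *shape-calibrated only*: tests
  assert signs, orderings and integral bookkeeping, never absolute RPs.
  Gaussian deposition sites get a seeded positional jitter
  (SD 0.02 nm), so one seed gives a bit-identical profile and different
  seeds differ in the smearing details but not the integrals.
* **Salt tables** (`make_salt_tables`): a 1:1 equitransferent reference
  ($\gamma_\pm \equiv 1$, $\kappa$ ideal), a 1:1 salt with a 2:1 mobility
  ratio and a near-flat $\gamma_\pm$, and a 2:1 salt with Mg-like
  mobilities, a $\gamma_\pm$ curve that dips through a single interior
  minimum (near 0.5 M) before rising steeply, and a Michaelis-type
  $\kappa(a)$ that saturates concavely. The shapes are parametric
  (extended Debye–Hückel-like form for $\gamma_\pm$), not digitized from
  any published figure; the package itself never predicts $\gamma_\pm$
  from theory — it only consumes tables.
* **Pseudo-experiments** (`simulate_experiment`): the full chain
  titrate → solve → RP or G → add bridge LJP → add noise, with additive
  Gaussian noise (default SD 1 mV, the order of reported experimental
  SDs) on voltages and multiplicative lognormal noise on conductances,
  emitting both truth and "measured" columns, seeded and reproducible.
  Solver failures are recorded per row rather than aborting a campaign.

What passing tests on these synthetics do **not** show: agreement with any
real channel's absolute conductance or RP (geometry and charge scale are
nominal), access-region effects, gating/substate kinetics, or the
measured conductance *decrease* of 2:1 salts above $\sim$1 M — the
mean-field model with effective diffusion coefficients saturates to a
plateau and never decreases, and the suite asserts that discrepancy as a
negative control rather than hiding it.

## Problem sizes

The shipped analyses and tests use 101–401 axial nodes (801 for
grid-doubling checks), conductance scans over eight concentrations spanning
0.1–3 M, pH sweeps over 2–7 at four divalent levels, junction grids over
ratios 2–100 for 1:1 and 2:1 salts, and a recovery study of 20 gradient
ratios at 1 mV noise fit by one-parameter least squares. These sizes were
chosen as the smallest at which the asserted properties are comfortably
resolved (grid-convergence and closure-agreement tests document the
margins).

## Known limitations

* One-dimensional mean field: no transverse structure, no ion–ion
  correlations, no short-range chemistry — exactly the physics the
  high-concentration 2:1 conductance drop appears to require.
* The TMS closure is implemented for a single binary salt per run;
  mixtures require the Poisson closure.
* Bulk Dirichlet mouths: access resistance and bulk convergence regions
  are outside the model.
* The Henderson junction uses limiting (25 °C) diffusion coefficients by
  default; concentration-dependent mobilities enter only through the
  effective-D mechanism, not the junction.

## A worked dissection

```{r dissection}
mg <- make_salt_tables("2:1")
zfg <- make_profile("zfg")
net_charge(zfg)  # negative net charge

opts <- pnp_options(n_nodes = 201)
# exclusion only: equalized mobilities
reversal_potential(zfg, bath_state(mg, 1), bath_state(mg, 0.1),
                   pnp_options(n_nodes = 201, mode = "exclusion"))
# full model: mobility contrast included
reversal_potential(zfg, bath_state(mg, 1), bath_state(mg, 0.1), opts)
# the electrolyte's own diffusion potential
diffusion_potential(mg, 1, 0.1)
```

The exclusion-only RP is negative (cationic, as the net charge suggests);
the full model flips the sign because the anion outruns the divalent
cation. The same dissection over a ratio sweep, the titration/binding
analysis, the conductance regimes and the net-charge recovery study are
scripted under `analysis/01` – `analysis/05`, each writing its tables to
`results/`.
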