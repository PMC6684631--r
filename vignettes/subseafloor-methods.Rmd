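---
title: "Models and numerical choices in subseafloor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical choices in subseafloor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subseafloor)
```

This vignette documents the models the package implements, the tunable
parameters that matter, what the synthetic-data generators do and do not
emulate, and the numerical and design choices made where the design was
genuinely open. It states no empirical result that the test suite or the
acceptance script does not itself compute.

## 1. The electron-equivalent redox ledger

Subseafloor burial of reduced carbon, nitrogen and sulfur is a net export
of reducing power from the surface world. To compare unlike fluxes the
ledger converts each to moles of electrons per year using the difference
between the element's dominant oxidation state in contact with the
oxygenated atmosphere and its state in marine sediment:

| element | surface state | buried state | e⁻/mol |
|---|---|---|---|
| C | +IV (CO2) | 0 (organic C) | 4 |
| N | +V (NO3⁻) | −III (amine N) | 8 |
| S | +VI (SO4²⁻) | −I (pyrite S) | 7 |
| Fe | +III | +II | 1 |

Two deliberate choices deserve a note:

* **Nitrogen.** The dominant *elemental* surface reservoir of N is N2
  (state 0), which would give 3 e⁻/mol; but the dissolved electron
  acceptor actually delivered to and consumed in sediment is nitrate
  (+V), and only the 8 e⁻ conversion is consistent with the
  electron-equivalent N fluxes the ledger is designed to reproduce. The
  default is therefore +V → −III, and `element_redox("N", 0, -3)`
  remains available.
* **Basement sulfur.** Whether basaltic sulfide sulfur sits at −I
  (pyrite-like, 7 e⁻) or −II (8 e⁻) is not resolved; the default is
  7 e⁻, and `basement_oxidizing_power()` exposes `e_per_s` so either
  stoichiometry can be used. Both land on the same value at one
  significant figure.

Fluxes travel as `flux_range(low, high)` pairs, propagated
endpoint-wise — the source estimates are themselves ranges with no
stated distribution, so nothing fancier is defensible.

**Rounding.** Published derived values are printed at 1–2 significant
figures, and some are derived *from already-rounded* intermediates
(e.g. the reduced-S electron flux is the 1-s.f. S burial range times 7).
`redox_ledger(rounded = TRUE)` reproduces that chain exactly;
`rounded = FALSE` gives the unrounded arithmetic. The
`pyrite_alkalinity_fraction()` is the pyrite share of the *combined*
(pyrite + riverine) primary alkalinity supply, which is the quantity the
24–58 % bracket describes.

The turnover-time calculation is plain arithmetic:
concentration / (stoichiometric factor × sulfate-reduction rate), with
factors 1.0 (acetate), 0.67 (lactate), 0.5 (formate) relating each
acid's consumption to the sulfate-reduction rate. The formate factor is
taken as given even though it is hard to reconcile with a naive
2-electron budget for formate oxidation; it is a stated stoichiometric
convention, not something this package re-derives.

## 2. Carbonate-system solver

State is (total alkalinity, DIC, T, S); alkalinity is approximated by
its carbonate, borate and water terms,

ALK = [HCO3⁻] + 2[CO3²⁻] + [B(OH)4⁻] + [OH⁻] − [H⁺].

This minimal form is appropriate for the "how much does pCO2 fall if
alkalinity rises" question the package asks; phosphate, silicate and
fluoride corrections are secondary at that precision and the form is
extensible.

* **Constants:** K0 (Weiss 1974), K1/K2 (Lueker et al. 2000, total pH
  scale), KB (Dickson 1990), KW (Millero 1995), total boron
  0.0004157 · S/35 (Uppström 1974). The choice is recorded in solver
  output (`$constants`). Any internally consistent set would do for the
  qualitative alkalinity-response question; the Lueker set is the
  conventional modern recommendation for surface-ocean pCO2 work.
* **Root solve:** bisection on pH ∈ [2, 12], iterated to interval
  < 1e−14, chosen for guaranteed bracketing over speed. At convergence,
  DIC partitioning is exact by construction and alkalinity
  reconstruction holds to ~1e−12 relative (tested).
* **Degenerate inputs:** DIC = 0 returns zero carbonate species and
  pCO2 = 0 after verifying the alkalinity is attainable from borate +
  water alone; otherwise the solver signals "no solution" rather than
  returning a spurious root.
* **Baseline state:** `pco2_alkalinity_response()` defaults to ALK 2300,
  DIC 2000 µmol/kg at 25 °C, S 35 — a documented representative
  present-day surface state, not a measured value. With DIC held fixed,
  a 25 % alkalinity increase lowers pCO2 by a factor the tests require
  only to be ≥ 5: the magnitude of the response depends strongly on the
  assumed baseline and on what is held fixed, so the "order of
  magnitude" characterization is treated as qualitative.
* **Independent cross-check:** no established CO2-system package is
  available in the build environment, so the 1 % cross-check in the test
  suite is against a deliberately separate implementation (different
  root variable — implied-DIC at trial pH — and independently re-typed
  constants), not against the solver's own code path.

## 3. Porewater rate inversion

At steady state without advection or bio-irrigation, the net consumption
rate of a dissolved species is the divergence of its diffusive flux:

R(z) = (1/φ) d/dz [ φ(z) D_s(z) dc/dz ],

positive where the species is consumed. A consumed species (O2, SO4²⁻
diffusing down from the ocean) has a concave-*up* steady profile, so
this sign convention makes observed consumption positive; the
closed-form corollary is that a concave-down parabola `c0 − b z²`
corresponds to net *production* 2 b D_s. The tests pin this convention
via the forward-model round trip.

* **Smoothing:** the concentration model is an **Akima (1970) local
  cubic** through the data (optionally after depth-binning replicate
  samples; off by default), differentiated analytically. The Akima
  interpolant is C¹ only: its second derivative jumps at the knots, so
  rates are evaluated at the **midpoints** of the sample depths by
  default, where the curvature of a cubic Hermite is most accurate.
  (Evaluating at the knots roughly decuples the round-trip error; the
  default query grid is part of the method.)
* **Diffusivity:** free-solution coefficients use the standard
  linear-in-T tabulation (in 1e−6 cm²/s): O2 11.70 + 0.344 T, SO4
  4.88 + 0.232 T, DIC-as-HCO3⁻ 5.06 + 0.275 T, tortuosity-corrected by
  D_s = D0/(1 − ln φ²). The exact temperature table behind the cited
  compilation lives in a textbook; the parameterization used is attached
  to every `sediment_diffusivity()` result as metadata. The tortuosity
  relation is the standard diagenetic choice and is the identity at
  φ = 1.
* **Porosity/temperature:** interpolated linearly between samples,
  constant beyond the sampled range; constant-temperature profiles are
  allowed (some sites have no downhole temperature data).
* **Monte Carlo:** n = 50 replicates by default; each replicate
  perturbs every sample by its own Gaussian SD, clips negative
  concentrations to zero (a physical constraint the source procedure is
  silent on — documented deviation), refits and re-differentiates.
  `rate_sd` is the per-depth SD across replicates. All randomness is
  seeded through an explicit argument and never leaks to global state.
* **Diagnostics:** the integrated rate ∫φR dz is attached along with
  the spline-derived boundary fluxes; steady-state closure
  (integral = flux_top − flux_bottom) holds to 1 % on smooth synthetic
  input and is tested.

With realistic absolute noise (2 % of the surface concentration),
single-depth rate estimates are noise-dominated for weakly curved
profiles — second derivatives amplify noise by 1/h². That is a property
of the method, not a bug; the Monte-Carlo SDs quantify it, and the
calibration test requires the true rate to lie within ±2 SD at ≥ 90 % of
depths across 20 seeded runs.

## 4. Affinity-limited organic oxidation

When a catabolic reaction sequence runs at its minimum biologically
harvestable affinity (A = −ΔG, roughly 2–5 kJ per mole of electrons
transferred), the production rate of the accumulating product (HCO3⁻)
is throttled linearly:

P(z) = P_max (1 − c(z)/c_A-min),

and the steady balance with diffusion, 0 = D c'' + P, with c(0) = c_top
and closed bottom, is solved by

c(z) = c_A-min + (c_top − c_A-min) e^(−z/L), L = √(D c_A-min / P_max),

so the rate decays exponentially: P(z) = P_max (1 − c_top/c_A-min)
e^(−z/L). The printed closed form in the source is typographically
corrupted (unbalanced parentheses, ambiguous exponent); the
implementation therefore derives the solution from the governing ODE and
validates it against an independent finite-difference boundary-value
oracle (`fd_steady_state()`, second-order differences, ghost-node
Neumann bottom). The oracle, not the typo, is authoritative; agreement
is < 1e−4 maximum relative error at 1000 nodes over 10 e-folding
lengths, with ~quadratic convergence under refinement (both tested —
the convergence study uses a 16 L domain so the finite-depth truncation
term e^(−z_max/L) does not mask the discretization error).

Modelling choices: the product is the only varying metabolite (the other
reactants are assumed in excess or buffered); P_max is constant with
depth; the bottom boundary is zero-gradient, consistent with thick
sediment columns tending toward closed systems. `is_harvestable()`
applies the affinity threshold per electron transferred,
boundary-inclusive, and reports the margin at both the 2 and 5 kJ
bounds.

## 5. Geomapping and zonation

* **Geotherm:** steady, purely vertical conduction with two layers —
  T rises at q/k through sediment (k_sed default 1.0 W m⁻¹ K⁻¹) then
  basement (k_bas 2.0), from a 2 °C seafloor. No hydrothermal advection;
  on young, permeable crust this overestimates temperature and hence
  *underestimates* habitable volume. Defaults are configurable
  documented choices.
* **Habitable volume:** basement thickness above the 122 °C isotherm;
  pore volume integrates 10 % porosity over the upper 500 m of basement,
  linearly to zero at 1000 m (maximum pore column exactly 75 m, tested).
* **Spherical integration:** cell areas R²Δλ(sin φ₂ − sin φ₁) with
  R = 6371 km; a global grid sums to 4πR² to 1e−10 relative.
* **Zonation:** sulfate is depleted within the sediment where thickness
  > 500 m *or* mean sedimentation rate (thickness/basement age)
  > 35 m Myr⁻¹; O2 persists to basement where thickness ≤ 150 m *and*
  rate ≤ 15 m Myr⁻¹; the remainder keeps sulfate but not O2 to
  basement. "Exceeds" is strict, so boundary cells stay in the
  less-reduced category. The published maps distinguish minimum and
  maximum oxic extents; only the minimum (150 m, 15 m Myr⁻¹) threshold
  set is printed, so no second default is invented — run
  `classify_zone()` with a user-supplied `zone_thresholds()` for
  alternative sets.

## 6. Synthetic data: what it does and does not emulate

**Profiles** are generated by solving the same steady diagenetic balance
the inverter assumes, on a uniform fine grid (≥ 10× the sample density,
conservative finite differences), with an exponential-decay or tabulated
consumption-rate profile, exponential compaction porosity
(φ0 e^(−z/1000 m)), linear geotherm, and i.i.d. Gaussian noise whose SD
is a fraction (default 0.02) of the *surface* concentration — absolute,
not proportional, because analytical error does not shrink as
concentration falls. The measurement error of shipboard data is not
published, so 0.02 is a configuration choice. Defaults (SO4 at 28
mol m⁻³, surface rate 3 × 10⁻⁵ mol m⁻³ yr⁻¹ ≈ 3 × 10⁻⁸ mol L⁻¹ yr⁻¹,
20 m e-folding, 100 m profile) mirror the magnitudes reported for an
open-ocean sulfate-reducing site. Not emulated: advection, bio-irrigation,
brines, lithologic layering, non-steady sedimentation. A green round-trip
test therefore establishes that the inverter is the correct inverse of
the stated physics — not that the stated physics captures any particular
real site.

**Grids** are Gaussian random fields (FFT circular convolution of white
noise with a Gaussian kernel of SD = `smoothness` cells, unit-variance
normalized, mapped into each range through the normal CDF). They are
spatially smooth and co-registered but carry no plate-tectonic
structure: age does not increase away from ridges, thickness is not
correlated with age or margins. Volumes and zone fractions computed on
them exercise the *algorithms*; they do not estimate real-world totals,
which require the real compilations.

Determinism: every generator takes an explicit seed and restores the
caller's RNG state; identical specs and seeds give identical output
(tested byte-for-byte).

## 7. Known limitations

* The ledger propagates ranges only — no uncertainty distributions, no
  isotope systematics, no spatial resolution of burial.
* The carbonate solver omits minor acid-base systems and does not
  re-equilibrate the whole-ocean carbon inventory; its alkalinity
  response is a local equilibrium statement.
* The rate inverter is single-species and assumes steady state; sites
  with recent sedimentation-rate changes violate that assumption.
* Grid I/O is ESRI ASCII and CSV only (no netCDF reader is available in
  the supported dependency set).
* The affinity model is a one-metabolite idealization; coupled
  SO4–DIC–sulfide networks and multi-pool organic reactivity models are
  out of scope.
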