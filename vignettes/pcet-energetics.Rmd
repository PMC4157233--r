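---
title: "Proton-coupled electron-transfer energetics with pcetr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proton-coupled electron-transfer energetics with pcetr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcetr)
```

## The scientific problem

Dark-operative (light-independent) protochlorophyllide oxidoreductase
reduces the C17=C18 double bond of protochlorophyllide with two electrons,
delivered one at a time by a (Cys)3Asp-ligated [4Fe-4S] cluster, and two
protons, donated by the active-site aspartate (Asp274) and by the
substrate's own propionic acid side chain. Quantum chemistry supplies
relative enthalpies of the mechanism's intermediates and transition states;
continuum electrostatics supplies intrinsic pKa values, intrinsic midpoint
potentials and site-site interaction energies for the titratable residues.
`pcetr` implements everything downstream of those calculations:

* bookkeeping of mechanism-state enthalpies at several dielectric
  constants, with step barriers, pathway barriers and reduction potentials
  derived from them;
* thermodynamic conversions (free energy to potential, pH-effective free
  energies, Eyring rates, occupancy-probability barrier penalties, photon
  energy to potential shift);
* Marcus theory for electron-transfer activation energies, including the
  case where the diabatic parabolas never intersect;
* Metropolis Monte Carlo titration of coupled protonation/reduction sites
  over a pH x potential grid, with an exact-enumeration oracle;
* a Boltzmann-averaged electrostatic correction over all protonation
  microstates of the protein, factorized over weakly correlated site
  groups.

The quantum-chemical and Poisson-Boltzmann calculations themselves are out
of scope: their outputs enter as data (packaged CSV fixtures, site lists
with interaction matrices, PQR charge sets).

## Energy bookkeeping and pathway barriers

A mechanism state is the combination of added electrons (0-2) and the two
proton positions, named by the field's labels (`"Asp274"`, `"C17"`,
`"C18*"` for wrong stereochemistry, `"Asp274...C17"` for an in-flight
proton marking a transition state). The packaged table holds 25 states at
dielectric constants 4, 10, 20 and 78.36; energies are relative enthalpies
in kcal/mol against the unreduced state with both protons on their donors.
Energies are stored at the precision they were printed at (one decimal)
and never re-rounded internally; typographic minus signs and bullet
ellipses are normalized on load.

```{r}
tab <- read_energy_table(system.file("extdata", "table1.csv",
                                     package = "pcetr"))
step_barrier(tab, 10, mechanism_state(0, "Asp274", "Propionate"),
             mechanism_state(0, "Asp274", "Propionate...C18"))
redox_potential(tab, 10, "Asp274", "Propionate", 0)
```

Pathway barriers use an energetic-span convention within each reduction
surface: the effective barrier of a step is its transition-state energy
minus the lowest minimum visited earlier on the same surface, and the
overall barrier is the maximum over steps. Electron-uptake steps carry an
externally supplied activation energy (default 4 kcal/mol, an upper bound
for these transfers) and reset the reference minimum, since relative
enthalpies on different reduction surfaces are not comparable. This
convention was chosen because it reproduces the published two-step
barriers exactly from the printed table (13.6 kcal/mol for the
Asp274-to-C17-first sequence; 18.8 for the C18-first sequence).

```{r}
cmp <- compare_mechanisms(tab, 10, et_activation = 4, eyring_limit = 19.3)
cmp$A$overall
cmp$B$overall
cmp$rate_limiting
```

Ties between equal span barriers resolve to the earliest step. Where a
transition state sits below its reactant (which happens for the final
proton transfer on the two-electron surface — the step is effectively
barrier-less), the negative value is reported with a warning rather than
silently clipped.

One known limitation of working from the printed table: the published
potential for one-electron reduction of the singly-protonated
(C17, Propionate) intermediate is 3.11 V, while the printed one-decimal
enthalpies give (-142.1) - (-70.5) = -71.6 kcal/mol = 3.105 -> 3.10 V.
Stereochemistry penalties quoted in prose (11 and 16 kcal/mol at one
added electron for C17 and C18, 8.5 and 9.5 at two) similarly cannot be
reconstructed exactly from the printed table at any single dielectric; the
package reports the table arithmetic (12.1, 14.3, 9.2, 8.2 at dielectric
10) and treats the fixture as authoritative.

## Thermodynamic conversions

All constants live in one place (`thermo_constants()`), and a copy ships
as machine-readable JSON for documentation tests. Energies are kcal/mol
throughout, so the Faraday constant is used as 23.0605 kcal mol-1 V-1.
Two default temperatures coexist deliberately: 300 K for titration and
protonation-probability work (the temperature of the electrostatic
protocol — the published probability penalties reproduce at 300 K, not
298.15 K) and 298.15 K for Eyring kinetics; every function also accepts an
explicit temperature. Reported potentials are absolute (vacuum-referenced);
`potential_vs_she()` subtracts 4.43 V explicitly rather than hiding the
convention inside other functions.

The Eyring bound on the rate-determining barrier requires converting a
specific activity to a turnover number, which needs a molecular mass the
activity measurement does not state; `kcat_from_specific_activity()`
therefore takes the mass as an explicit argument.

## Marcus construction

The reactant diabat is parametrized as `E_R(x) = lambda_R * x^2` with its
minimum at x = 0 and the product diabat as
`E_P(x) = dG + lambda_P * (1 - x)^2` with its minimum at x = 1 — the
minimal construction consistent with two independent reorganization
energies. The activation energy is `E_R` at the lowest-energy real
intersection; with equal curvatures this collapses to the textbook
`(lambda + dG)^2 / (4 lambda)`. When the discriminant of the intersection
quadratic is negative the parabolas never touch; this is a reportable
`NO_CROSSING` status, not an error, because a non-crossing pair is itself
a finding for thermodynamically uphill transfers. When two real roots
exist, the one with lower `E_R` is the physically traversed crossing.
Degenerate flat diabats (both reorganization energies zero) give
activation 0 when the driving force is zero and `NO_CROSSING` otherwise.
The solver is validated against a dense grid search at 1e-6 resolution
over the reaction coordinate.

## Monte Carlo titration

A titratable site binds a proton (intrinsic value in pKa units) or an
electron (intrinsic midpoint in volts). The microstate energy convention —
which the source protocols leave implicit — is pinned down as:

```
E(s) = sum_i s_i g_i + sum_{i<j} W_ij s_i s_j
g_i  = RT ln10 (pH - pKa_i)        proton sites
g_i  = F (E - E0_i)                electron sites
```

with s_i = 1 meaning proton bound / electron bound (reduced), so occupancy
is penalized above the midpoint and the all-unbound state is the zero of
energy. Couplings W are pairwise energies in kcal/mol paid when both sites
are occupied; the matrix must be symmetric with zero diagonal (asymmetric
input is rejected rather than symmetrized, since the upstream convention
is not standardized).

The sampler follows the standard two-phase protocol. Defaults: pH 5-9 in
0.1 steps, potential -750 to -200 mV in 20 mV steps, 2e5 scan steps and
1e6 production steps per grid point at 300 K. After the scan, sites whose
occupancy stays at or above the clamp threshold (default 0.9) at *every*
grid point are frozen protonated (correspondingly deprotonated below
1 - threshold) and excluded from production moves; clamping is decided
over the whole grid, not per point. Single-site Metropolis flips are
supplemented by two-site flips for strongly coupled pairs (|W| above
2 pKa units = 2.73 kcal/mol at 300 K), which restores mixing for pairs
locked by a large coupling. All randomness derives from the grid seed;
each grid point gets its own derived seed, so results are reproducible
under any evaluation order and bit-identical across runs.

Numerical choices worth recording:

* Sampled statistics are thinned at roughly one sweep, but the thinning
  interval is kept odd: when a site is exactly at its midpoint every flip
  is accepted and the total-occupancy parity alternates each step, which
  an even interval would alias into a frozen-parity subsequence.
* Standard errors come from 20 batch means, floored by an episode-based
  binomial estimate `sqrt((minority_steps + 2 n_free) n_free) / n_steps`.
  For near-deterministic sites the batch variance collapses to zero while
  the true error is Poisson noise on minority episodes of length ~n_free
  steps; the floor keeps sigma-based comparisons honest there.
* `exact_titration()` enumerates all 2^N microstates (N <= 20) and is the
  oracle for every sampler property: detailed balance on small systems,
  Henderson-Hasselbalch and Nernst limits for single sites, and the
  -59.5 mV/pH slope of a fully proton-coupled electron site at 300 K.

Midpoints are read off the occupancy grid by monotone linear interpolation
at half-reduction; slopes come from least squares over the evaluated pH
values (default 5, 7, 9, the values used in slope reporting upstream), and
the implied proton uptake per electron is `-slope / (1000 RT ln10 / F)`.
A midpoint that never crosses one half inside the potential window is an
explicit error, never an extrapolation.

Site correlations are computed from accumulated second moments of the
thinned production samples; correlation with a clamped site is undefined
and reported as NA.

## Ensemble electrostatic correction

The protein's electrostatic contribution to a reaction step is the
total-system electrostatic energy minus the active-site-only energy,
evaluated by a plain pairwise Coulomb sum (332.0636 q_i q_j / r_ij, unit
dielectric, no cutoffs, no periodicity). The environment self-energy is
included, as the decomposition implies, but documented as cancelling in
step differences; a `cross_only` flag computes the active/environment
cross term alone for diagnostics.

Because per-site contributions to a step's electrostatic energy are
additive, the energy of any protonation microstate is a sum over
protonated sites, and the ensemble correction is the Boltzmann average
`exp(-dE_avg/RT) = sum_i p_i exp(-dE_i/RT)` over the population of
microstates sampled by the titration. The average factorizes exactly over
site groups when the population is a product over those groups, so sites
are grouped by occupancy correlation (greedy agglomeration, visiting pairs
in decreasing |correlation| under a size cap of 10 sites, i.e. at most
2^10 sub-states per group) and the total is the sum of group terms; the
largest neglected inter-group correlation is reported. Evaluation is in
log-sum-exp form because contributions span tens of kcal/mol and naive
exponentials overflow. The average always lies between the smallest and
largest per-microstate energy, and the factorization error grows with the
inter-group correlation the grouping failed to capture — both properties
are exercised by the test suite with populations of tunable correlation.

Fixed-geometry unit-dielectric electrostatics exaggerates stabilization
because protein and solvent relaxation are neglected;
`screen_by_effective_dielectric()` divides a correction by an effective
dielectric constant (site-dependent, of order 1) to model this, shifting a
derived potential by `-dE (1 - 1/eps_eff) / F` volts.

## Synthetic data and what the tests do and do not show

Every input the pipeline consumes has a seeded generator with planted
ground truth: titration systems with known intrinsic values and sparse
symmetric couplings (defaults: pKa 3-10, midpoints -0.6 to -0.2 V so that
midpoints fall inside the standard sampling windows; coupling density 0.3
at a 2 kcal/mol scale, typical of electrostatic site-site interactions);
mechanism energy tables with the four canonical pathway barriers planted
as exact energetic spans; random point-charge boxes with a 1 angstrom
minimum separation; and 2^N microstate populations with tunable
correlation built from a two-component latent mixture (exactly product-form
at strength zero). Generators restore the global RNG state on exit, so
they are pure functions of their seed.

The generators emulate the *structure* of the real inputs — coupled sites
in the experimental pH/potential windows, barrier topologies, charge
distributions — not the real protein: no 44-site coupling topology from a
crystal structure, no conformational relaxation, no structure-derived
intrinsic values. Passing recovery tests therefore demonstrates that the
machinery is correct (planted barriers, midpoints and couplings are
recovered; the sampler agrees with exact enumeration), not that any
protein-specific published number is independently confirmed. The
published protein-specific midpoint table is explicitly out of reach at
desk scale, since it requires the structure-derived electrostatics; its
Nernstian behavior (about -50 mV/pH, 0.8 protons per electron) is covered
by the property tests instead.

Problem sizes used by the test suite, chosen to exercise every code path
at desk scale: exact-vs-MC agreement on 10-15-site systems over a 3 x 3
grid at the full 1e6 production steps across 20 seeds; detailed balance on
3-site systems at 1e6 steps; Marcus grid-search validation on 1000 random
triples; Coulomb validation on 100 random 50-atom fixtures; ensemble
factorization on 12-site populations against full 2^12 enumeration.

## Reporting

`run_analysis()` drives the analyses from a serializable config (a named
list, or a YAML/JSON file), writes TSV and JSON reports, and echoes the
config next to them; re-running from the echoed config reproduces the
numeric reports byte-identically. Barriers are rounded to one decimal and
potentials to two in reports — the precision of the source tables — while
the programmatic API always returns full precision.
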