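---
title: "Methods: simulating and estimating glycosylase site transfer under crowding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and estimating glycosylase site transfer under crowding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoslide)
```

# The scientific problem

DNA repair glycosylases such as hUNG and hOGG1 locate rare damaged bases by
facilitated diffusion: after associating nonspecifically with a DNA chain
they translocate along it by *associative* steps (sliding in loose contact
with the DNA surface) interleaved with *dissociative* excursions (microscopic
hops off the chain that either re-land or lose the enzyme to bulk solution).
The gel-based molecular-clock assay measures this as the probability
`P_trans` that an enzyme that has just excised one lesion on a two-site
substrate reaches and excises the second lesion within the same binding
event. A small-molecule active-site trap captures enzymes during
dissociative excursions, isolating the associative share `P_assoc`, so that

```
P_trans = P_assoc + P_diss
```

Macromolecular crowders (PEG polymers at cell-like concentrations) raise
viscosity, deplete from surfaces, and compress the enzyme's search; this
package provides the machinery to simulate such experiments and analyze
their outputs: a mechanistic lattice walker, a population-level reaction
sampler that emulates the band quantification tables, the transfer
probability estimators, stopped-flow and steady-state fitters, and the
crowding-physics calculations.

# The lattice walker

`simulate_walker()` releases each molecule at site 1 immediately after a
first excision and follows the search pathway on a 0-based bp lattice:

* **Slide**: with probability `1 - q` per step, move one bp left or right
  with equal probability.
* **Dissociative excursion**: with probability `q` per step the enzyme
  leaves the chain. With the trap present it is captured with probability
  `trap_capture_prob` (default 1, the saturating-trap regime). A surviving
  excursion re-lands with probability `p_return` — the rate ratio
  `k_return / (k_return + k_bulk)` — at a displacement drawn from a
  two-sided geometric law with mean `hop_scale` bp, clamped to the chain;
  otherwise the enzyme escapes to bulk and the molecule is lost.
* **Encounter**: arriving at site 2 is an encounter; excision succeeds with
  probability `E` per encounter. Chemistry is treated as instantaneous
  because the chemical step (`k_cl` = 240 s^-1) is far faster than
  dissociation; a failed encounter continues the walk.

Successful paths with no returned hop are *associative* transfers; paths
containing at least one hop are *dissociative*. With a saturating trap all
dissociative paths terminate in capture, which is exactly the experimental
logic of the molecular clock.

Design choices where the experiments are silent:

* **Hop-length law.** No hop displacement distribution is measurable from
  the assay; the two-sided geometric is the minimal memoryless choice and is
  isolated behind the `hop_scale` config parameter rather than asserted as
  mechanism.
* **Chain ends.** Sliding off either end is treated as a dissociative
  excursion from the end position, keeping end effects consistent with the
  dissociative-pathway definition rather than inventing a reflecting cap.
* **Two-layer time.** Within a binding event time is counted in
  dimensionless lattice steps; laboratory seconds appear only in the
  population sampler. `P_trans` is invariant to the step-to-seconds mapping,
  so none is needed for estimation (`steps_per_second` exists for users who
  want trajectories on a clock).

## The exact first-passage oracle

`first_passage_oracle()` validates the walker independently. For pure
sliding (the saturating-trap regime) the transfer probability solves the
discrete boundary-value problem

```
u(x) = (1 - q)/2 * [u(x-1) + u(x+1)],   u(spacing) = 1
```

with a reflecting wall at `-left_extent`. At the wall we use the bounce
convention — the walker survives dissociation with probability `1 - q` and
takes its one available step inward, `u(-L) = (1-q) u(-L+1)` — which makes
the smallest nontrivial case (spacing 2, reflecting at the start, q = 0.5)
a one-unknown linear system solvable by hand: `u(1) = 2/7`, `u(0) = 1/7`.
The tridiagonal system is solved exactly and the walker is required, in the
test suite, to agree within three Monte-Carlo standard errors across a
(spacing, q) grid. The walker treats the far chain end as lossy rather than
reflecting; the comparison therefore places site 1 150 bp from the end,
several times the typical excursion span `~1/sqrt(q)`, where the two
conventions are indistinguishable.

# The population sampler

`simulate_population()` emulates the band-table statistics of the assay.
Substrate molecules receive a first productive enzyme arrival at rate
`first_hit_rate * E` (exponential waiting time), excising a random one of
the two sites. With probability `true_P_trans * E` the same binding event
also excises the partner site — a double event producing fragments A + C;
otherwise a single event (A + BC or AB + C by the fixed labelling
convention). Singly-cleaved molecules are later converted to doubly-cleaved
by *independent* fresh-enzyme arrivals at rate `rebind_rate * E`. This
rebinding channel inflates the apparent per-timepoint transfer probability

```
P_obs = (A + C - AB - BC) / (A + C + AB + BC)
```

at later times, which is precisely why the assay extrapolates `P_obs`
to zero time. The sampler exposes the hidden per-timepoint counts
(`truth` attribute) so estimator tests can compare against ground truth,
and flags timepoints after full substrate consumption.

The config needs a first-arrival rate that is distinct from `rebind_rate`:
with rebinding disabled the substrate must still react. `first_hit_rate`
(default 0.01 s^-1) fills this role; with the default quench times of
15–75 s it yields 14–53% reaction extents, the low-to-moderate extents at
which the assay is actually quantified. The default `rebind_rate` of
0.002 s^-1 produces roughly 10–20% extra double events by the last
timepoint — enough to make extrapolation matter, small enough that the
linear extrapolation is accurate.

# Estimators

* `compute_ptrans_obs()` implements the band-fraction formula above; the
  full-length band cancels and is excluded, and the estimator is invariant
  to per-lane rescaling. An all-zero lane is reported as missing, not zero.
* `extrapolate_zero_time()` fits an unweighted OLS line of `P_obs` against
  time. Time is the default regressor; fraction-of-substrate-consumed is
  available behind `regressor = "extent"` because quenching happens at
  varying reaction extents, but the zero-time reading of the assay is the
  default and the two agree well under the generator's conditions. Negative
  `P_obs` values from noise are retained in the regression — clamping before
  regression would bias the intercept — and only the final reported value is
  clamped, with the raw value preserved.
* `transfer_analysis()` additionally computes a binomial Monte-Carlo
  standard error of the intercept (`se_mc`) when the molecule count is
  known, by propagating the per-timepoint counting variance `p(1-p)/m`
  through the OLS intercept weights. The regression SE alone understates
  the sampling error because cumulative counts are correlated across
  timepoints.
* `partition_pathways()` computes `P_diss = P_trans - P_assoc` with
  quadrature error propagation, warning (not clamping) when the difference
  is negative beyond the propagated error.
* `correct_efficiency()` applies `P_trans_true = P_trans / E` and flags
  corrected values above 1 as inconsistent.

# Kinetic fitting

All nonlinear fits use Levenberg-Marquardt least squares with analytic
starting values, positivity bounds on rates, and internal dimensionless
parameter scaling: the association fit works with the pseudo-first-order
rate `kappa = k_on * P0` (s^-1), the Michaelis-Menten fit with rates in
units of the maximum observed rate and `K_m` in units of its half-max
guess, and the isotherm with `K_D` in units of its half-saturation guess.
Without this scaling, parameters spanning nine orders of magnitude
(`k_on ~ 1e9` next to signal offsets of order 1) make the Jacobian
numerically singular. Parameter covariances come from an eigenvalue
pseudo-inverse of the Gauss-Newton Hessian, which stays defined at the
zero-residual optima reached on noiseless traces.

The equal-concentration second-order association signal is fitted as

```
Y(t) = Yf - (Yf - Y0) / (k_on * P0 * t + 1)
```

This is the standard solution for irreversible equal-concentration
bimolecular binding; it is the unique physically meaningful reading of the
association model (a time-independent expression cannot describe a trace),
and the implementation states it explicitly rather than leaving the time
dependence implicit.

Dissociation traces are fitted with one and two exponentials and the model
is selected by AICc; the extra-sum-of-squares F-test is deliberately not
the default because AICc behaves symmetrically for nested and non-nested
alternatives and needs no alpha choice. On effectively noiseless data every
candidate reaches an RSS at numerical rounding level, where AICc would
compare noise; the RSS is therefore floored at `n * (1e-8 * range(Y))^2`,
which makes the simpler model win ties without affecting any realistic
noise level. Components are reported with `k_fast > k_slow`, and a selected
biphasic fit with under 3-fold rate separation carries an identifiability
warning.

`fit_michaelis_menten()` offers the full hyperbolic fit (five or more
substrate concentrations) and a `kcat_only` mode that averages saturating
rates but refuses if they disagree by more than 20%, mirroring the
experimental saturation check. `fit_titration()` fits the 1:1 anisotropy
isotherm, optionally with ligand-depletion correction. `fit_ise()` fits the
Nernstian semi-log electrode response; the slope is reported per decade of
concentration, and the crowded/dilute slope ratio estimates the ion
activity-coefficient ratio.

# Crowding physics

* `rg_peg()` implements the PEG light-scattering power law
  `R_g = 0.0215 * M_w^0.583` nm (valid 200–1e6 g/mol), which reproduces the
  standard coil sizes (4.1 nm for PEG 8K, 0.9 nm for PEG 600, a 4.5-fold
  ratio).
* `depletion_layer()` equals `R_g` in the dilute regime; no semi-dilute
  correction is attempted and the regime is labelled in the output.
  `encounter_distance()` reconstructs the effective center-of-mass capture
  distance as `2*delta + r_protein + r_dna` (~11 nm for PEG 8K with 2 and
  1 nm radii); the formula is explicitly labelled a reconstruction in its
  output since an authoritative functional form is not available.
* `pdiss_partition()` implements the two-term kinetic definition
  `P_diss = [k_off/(k_off+k_assoc)] * [k_return/(k_return+k_bulk)]`. The
  two brackets move oppositely under crowding (slower dissociation per
  step, but more efficient return), and the test suite asserts the
  compensation quantitatively: there are crowding transformations
  (`k_assoc`, `k_return` scaled together) that change `P_diss` by under
  10% while the first bracket alone falls by more than 30%.
* `se_deviation()` converts fitted `k_on` values to relative association
  times `tau_rel = tau_crowder/tau_buffer` and compares them with relative
  viscosities; `|tau_rel - eta_rel| <= 0.15 * eta_rel` is classified
  SE-ideal, an explicit tolerance standing in for what is otherwise a
  visual classification. Relative viscosities are literature values
  shipped as an editable YAML table (`viscosity_table.yaml`), with 13.0
  for the 20% w/v PEG 8K standard condition; the intermediate-concentration
  entries are placeholder interpolations a user should replace with their
  own viscometry.

# What the generators do and do not emulate

The synthetic campaign reproduces the statistical structure the analysis
relies on: binomial band-count noise with the correct fragment identities
and conservation laws, rebinding inflation of late timepoints, Gaussian
instrument noise on traces, and exact functional forms for the
deterministic signals. It does **not** emulate gel-specific artifacts
(background, smearing, label-specific detection efficiency), instrument
dead time, the slow PEG-induced fluorescence phase beyond its biphasic
functional form, or any explicit crowder particles — crowding enters only
through effective parameters (`q`, `p_return`, `rebind_rate`, `eta_rel`).
Passing recovery tests therefore demonstrates the correctness of the
estimators and fitters under the assay's assumed statistics, not the
validity of those assumptions for any particular gel.

# Reproducibility and problem sizes

Every stochastic function takes an explicit integer seed (`rng_seed` in the
config; `seed` arguments elsewhere); identical configuration and seed give
byte-identical serialized outputs, which the suite asserts at the level of
written CSV and JSON. The test and acceptance problem sizes — 10,000–20,000
molecules per walker or population run, 200–500 points per trace, grids of
nine (spacing, q) cells — keep Monte-Carlo standard errors a few times
smaller than the effects being checked while the whole suite runs in a few
seconds.

# Known limitations

* The walker's per-step dissociation probability `q` and return probability
  `p_return` are effective parameters; mapping a crowder concentration onto
  them is left to the user because the experiments establish direction, not
  functional form.
* The population sampler treats rebinding as spatially unstructured
  (arrivals at random intact sites), the minimal mechanism consistent with
  zero-time extrapolation; it does not model preferential rebinding near
  the previous site.
* `P_assoc` and `P_trans` enter the pathway partition from separate
  (trap-on / trap-off) experiments; the partition assumes the trap leaves
  the associative pathway untouched.
* The depletion-layer treatment is dilute-regime only; at 20% w/v a
  semi-dilute correction would shrink `delta`, and no such correction is
  applied.
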