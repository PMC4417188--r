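# glycoslide

Simulation and analysis of facilitated diffusion of DNA glycosylases on
two-site DNA substrates, with and without macromolecular crowding.

DNA repair enzymes such as hUNG and hOGG1 find damaged bases by a search
that mixes 3D diffusion with translocation along the DNA chain — sliding in
loose contact with the DNA surface (*associative* transfer) and microscopic
hopping excursions off the chain (*dissociative* transfer). The gel-based
molecular-clock assay quantifies this with the intramolecular site-transfer
probability on substrates carrying two lesions: from the molar band
fractions of the fragments produced by single-site (AB, BC) and double-site
(A, C) excision,

    P_obs = ([A] + [C] − [AB] − [BC]) / ([A] + [C] + [AB] + [BC])

extrapolated to zero reaction time to remove inflation from independent
enzyme rebinding, and partitioned by a small-molecule active-site trap that
captures enzymes during dissociative excursions:

    P_trans = P_assoc + P_diss,
    P_diss  = [k_off/(k_off + k_assoc)] · [k_return/(k_return + k_bulk)]

The package provides, as plain R functions over data frames:

* **Simulators** (`simulate_walker`, `simulate_population`,
  `simulate_association_trace`, `simulate_dissociation_trace`,
  `simulate_titration`, `simulate_initial_rates`, `simulate_ise_standards`)
  — a sliding/hopping lattice walker with an exact first-passage oracle
  (`first_passage_oracle`), a population sampler that emulates the band
  quantification tables with rebinding, and generators for every other
  input the analysis consumes. All are seeded and byte-reproducible.
* **Transfer estimators** (`compute_ptrans_obs`, `extrapolate_zero_time`,
  `transfer_analysis`, `partition_pathways`, `correct_efficiency`).
* **Kinetic fitters** (`fit_second_order`, `fit_exponentials` with AICc
  model selection, `fit_michaelis_menten` / `relative_params`,
  `fit_titration`, `fit_ise` / `fit_ise_pair`, `kd_kinetic`) — the
  second-order association signal is fitted as
  `Y(t) = Yf − (Yf − Y0)/(k_on·P0·t + 1)`.
* **Crowding physics** (`rg_peg`, `depletion_layer`, `encounter_distance`,
  `pdiss_partition`, `se_deviation`) — the PEG coil-size law
  `R_g = 0.0215·M_w^0.583` nm, dilute-regime depletion layers, and
  Stokes–Einstein deviation of association times
  (`tau_rel = tau_crowder/tau_buffer` vs `eta_rel`).

The methods vignette (`vignettes/crowding-facilitated-diffusion.Rmd`)
documents the model, every tunable parameter, and the numerical choices.

## Worked example

Simulate a site-transfer experiment whose true per-encounter transfer
probability is 0.34 with mild rebinding, then recover it:

```r
library(glycoslide)

cfg <- sim_config(n_molecules = 10000, rebind_rate = 0.002,
                  timepoints = c(15, 30, 45, 60, 75), rng_seed = 5)
tc <- simulate_population(cfg, true_P_trans = 0.34)
transfer_analysis(tc)
#> Site transfer analysis (synthetic, spacing 20 bp, trap off)
#>   P_trans (zero-time) = 0.3455 +/- 0.0057  (slope 7.35e-04 /s)
```

The per-timepoint estimates climb from 0.351 to 0.398 as rebinding converts
singly-cleaved substrates to doubly-cleaved ones; the zero-time intercept
0.346 ± 0.006 recovers the generator truth while the last timepoint alone
would overestimate it by ~17%.

Mechanistic check of the walker against the exact first-passage solve
(saturating trap, spacing 20 bp, q = 0.005):

```r
cfg <- sim_config(dna_length_bp = 400, site1_pos = 150, site2_pos = 170,
                  q = 0.005, trap_on = TRUE, n_molecules = 20000, rng_seed = 3)
simulate_walker(cfg)$p_transfer
#>  estimate        se
#> 0.1385000 0.0024426
first_passage_oracle(spacing = 20, q = 0.005, left_extent = 150)
#> [1] 0.1347707
```

Fit a noiseless biphasic dissociation trace (the crowded stopped-flow
regime: 0.35 and 0.024 s⁻¹ with a 44% slow phase):

```r
tr <- simulate_dissociation_trace(c(0.35, 0.024), c(0.56, 0.44),
                                  times = seq(0, 200, length.out = 500))
f <- fit_exponentials(tr)
f$model          #> "exp2"  (selected by AICc)
f$parameters[c("k_fast", "k_slow")]   #> 0.350 0.024
f$slow_fraction  #> 0.44
```

## The analysis workflow

The `analysis/` directory is a numbered pipeline over the package: stage 1
generates the full synthetic campaign (band tables for buffer-like and
crowded conditions with trap on/off, stopped-flow traces, titrations,
initial-rate tables, ISE standards), stages 2–4 run the transfer,
kinetic-fitting and crowding analyses, and stage 5 consolidates a JSON
report. Each stage prints what it found and writes tables under `results/`:

```sh
Rscript analysis/01_simulate.R --seed 1
Rscript analysis/02_transfer.R
Rscript analysis/03_kinetics.R
Rscript analysis/04_crowding.R
Rscript analysis/05_report.R --seed 1
```

Stage 2, for example, prints the recovered zero-time intercepts
(`P_trans` 0.349 and 0.510 for generator truths 0.34 and 0.50) next to the
inflated last-timepoint estimates, and stage 4 prints the depletion-layer
table and the Stokes–Einstein deviation classification (`tau_rel = 9` vs
`eta_rel = 13` for 20% PEG 8K: negative deviation — faster association
than viscosity alone allows).

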