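# fretrelease

Quantitative toolkit for drug–carrier compatibility and FRET-based release
kinetics of self-assembled polymeric nanoparticles.

Self-assembled carriers (PLGA–PEG micelles and kin) hold poorly water-soluble
drugs by physical association only. In serum, plasma proteins — albumin above
all, with γ-globulin and the lipoproteins — act as competing acceptors, and a
drug that looked stably loaded in buffer can leave the particle in minutes.
Two molecular descriptors govern how fast: the drug's **hydrophobicity**
(distribution coefficient log *D* at pH 7.4) and its **miscibility** with the
matrix polymer (Flory–Huggins interaction parameter χ). `fretrelease` is for
formulation scientists who want to screen drug or prodrug candidates on these
descriptors, analyse dual-channel FRET release assays, and explore the
release mechanism with a transparent kinetic model.

## What the package computes

**Compatibility descriptors.** Group-contribution (Fedors-style) estimates of
the Hildebrand solubility parameter δ (MPa<sup>0.5</sup>) and molar volume
*V* (cm³ mol⁻¹), combined into the Flory–Huggins interaction parameter

> χ = *V* (δ_drug − δ_poly)² / (*R T*)

with smaller χ meaning better drug–matrix miscibility. A (χ, log *D*)
release-zone classifier encodes the design guideline: miscible **or**
strongly hydrophobic drugs release slowly; drugs that are neither release
fast.

**FRET observable.** A donor dye in the particle core and an acceptor-tagged
drug produce FRET only while the drug is particle-associated. The forward
model maps mean per-particle loading to donor- and FRET-channel intensities;
the FRET/donor intensity ratio is linear in loading over the calibrated
range, independent of particle concentration, and invertible through an OLS
calibration line.

**Release kinetics.** Normalized FRET-ratio decays are fitted with a
two-compartment model, y(t) = plateau + f_fast e^(−k_fast t) + f_slow
e^(−k_slow t) — fast pool = interface-bound drug, slow pool = core-embedded
drug — by a deterministic variable-projection-style fit (log-spaced rate
grid, non-negative amplitude solves, Levenberg–Marquardt polish). Half-lives
are read off the fitted curve, and rate-versus-temperature series yield
apparent activation energies by Arrhenius regression.

**Exchange mechanism.** A linear mass-action simulator moves drug between
donor sub-pools (interface/core), a free intermediate, and serum acceptor
pools, with Arrhenius-scaled dissociation rates. Drug descriptors map onto
mechanism parameters (hydrophobicity → dissociation barrier; miscibility →
core-loaded fraction), which reproduces the canonical four-archetype release
ordering CA > C12 > OLA > PLGA2k and the serum-concentration and temperature
dependence of release.

**Synthetic data.** Every stage is testable without instrument data: the
generator produces seeded noisy dual-channel plate-reader traces, calibration
series, condition panels and end-point pool-distribution snapshots, each with
its ground truth attached.

## Worked example

```r
library(fretrelease)

## 1. compatibility descriptors for a C12-tailed dye conjugate vs PLGA
drug    <- molecule_composition("drug_C12", c(CH3 = 1, CH2 = 12, phenyl = 1),
                                supplied_logd = 6)
polymer <- molecule_composition("PLGA", c(CH3 = 1, CH = 1, COO = 1,
                                          CH2 = 1, COO = 1))
characterize_compatibility(drug, polymer, temperature_k = 310.15)
#>       drug polymer delta_drug_mpa05 delta_poly_mpa05 molar_volume_cm3_mol
#> 1 drug_C12    PLGA            17.94            24.09                298.1
#>   temperature_k   chi logd logd_estimated         zone
#> 1         310.1 4.369    6          FALSE intermediate

## 2. simulate its release into 100% serum at 37 C and fit the decay
sys <- archetype_system("C12", medium = "FBS", acceptor_fraction = 1,
                        temperature_c = 37)
tr  <- simulate_exchange(sys, seq(0, 14400, 60), spectral = spectral_params())
fit <- fit_two_compartment(tr$time_s,
                           normalize_ratio_series(tr$fret_ratio, "first_point"))
fit
#> Two-compartment decay fit
#>   fast: f = 0.4458, k = 0.0009737 s^-1 (t1/2 = 711.9 s)
#>   slow: f = 0.06281, k = 0.0006013 s^-1
#>   plateau = 0.4908, rss = 5.928e-06, converged = TRUE
#>   flags: poorly_separated
half_life_of_fit(fit)  # ~752 s, i.e. ~12.5 min
```

The descriptor table says the conjugate is moderately hydrophobic but poorly
miscible with PLGA (χ ≈ 4.4), so it sits between the fast- and slow-release
corners of the guideline; the simulated serum experiment gives a ~12-minute
release half-life, with the plateau reflecting the assay's bleed-through
baseline. A command-line interface covering the same operations ships in
`inst/scripts/fretrelease` (subcommands `chi`, `calibrate`, `fit-release`,
`arrhenius`, `simulate`, `simulate-panel`, `rank`).

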