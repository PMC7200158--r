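# oligocount

Quantitative analyses of DIX-domain self-association for Wnt/β-catenin
signalling studies: how strongly a DIX-type domain self-associates
(from SEC-MALS average masses), what helix a DIX filament forms, and
how many fluorophore-tagged molecules occupy a diffraction-limited TIRF
spot. The package is aimed at structural biologists and single-molecule
microscopists who have an average mass, a helical symmetry, or a short
fluorescence movie and want the corresponding dissociation constant,
filament model, or per-spot copy-number distribution — together with
seeded simulators so every stage can be validated against known ground
truth.

## What it computes

**Isodesmic equilibrium.** For a self-associating protomer measured at
total concentration c_tot with number-average species mass M_avg, the
equal-stepwise-K model sets c_n = m(m/K)^(n−1) for oligomers up to
order N and solves

    Σ n·c_n = c_tot,   M₁·Σ n·c_n / Σ c_n = M_avg,   K_D = m²/c₂

by a guaranteed-unique 1-D root find in x = m/K. `convergence_table()`
tracks K_D as higher-order oligomers are admitted and
`infinite_limit_kd()` gives the closed-form N→∞ limit
K = c_tot(1−x)²/x, x = 1 − M₁/M_avg.

**Helical geometry.** `pitch()` (rise·360/twist),
`protomers_per_turn()`, and `build_double_helix()`, which generates an
idealized antiparallel double-stranded filament (two strands related by
an in-plane two-fold) and exports centroids as a pseudo-atom PDB.

**TIRF copy-number counting.** `tirf_pipeline()` chains rolling-ball
background subtraction, window-5 time averaging, matched-filter spot
detection with a null-calibrated significance test (α = 0.05, PSF
σ = 1 px), optimal-assignment trajectory linking with 4-frame gap
closing, selection of ≥10-frame trajectories, Gaussian-mixture fitting
of start-frame integrated intensities (BIC/AIC selection, 100 seeded EM
replicates), and single-fluorophore calibration g = μ₍₂₎ − μ₍₁₎ from
the two smallest component means.

**Resampling statistics.** Mann-Whitney U (`rank_sum_test()`, exact for
small samples), bootstrap difference-of-means intervals
(`bootstrap_diff_means()`), and ratio of means with bootstrap-
propagated error (`ratio_of_means_bootstrap()`).

**Synthetic data.** `simulate_tirf_stack()` (known copy numbers,
photobleaching, Poisson + read noise), `simulate_mals_series()`, and
`simulate_mgv_fields()` generate every input the analyses need.

## Worked example

```r
library(oligocount)

# a 10 kDa protomer measured at 710 nM total with a 15 kDa
# number-average mass: dissociation constant vs truncation order
convergence_table(710, 10, 15, c(2, 3, 5, 8, 11))
#>   max_order    kd_nM
#> 1         2 236.6667
#> 2         3 671.6504
#> 3         5 907.3820
#> 4         8 944.4788
#> 5        11 946.5544
infinite_limit_kd(15, 10, 710)
#> [1] 946.6667
```

The estimate climbs from 237 nM when only dimers are allowed and
converges near 947 nM (≈0.9 μM) once oligomers of order ~9 and above
are included — truncating the series too early understates how strongly
the domain self-associates.

```r
pitch(helical_symmetry(twist = 48.0, rise = 13.5))
#> [1] 101.25        # Angstrom per helical turn, 7.5 protomers/turn

# copy-number counting on a simulated movie with known truth
sim <- simulate_tirf_stack(tirf_sim_config(seed = 11))
report <- tirf_pipeline(sim$stack, seed = 12)
report$calibration$single_fluor_intensity
#> [1] 103.6379      # counts/fluorophore; simulation truth is 120
report$fraction_within
#> [1] 0.987013      # fraction of spots within 10x of one fluorophore
mean(sim$truth$spots$n <= 10)
#> [1] 0.9866667     # ground-truth fraction
```

The calibrated fluorophore unit lands within ~15% of truth (biased low
by background subtraction and bleaching, as expected for this method),
while the copy-number spread — the fraction of spots within 10× of a
single fluorophore — is recovered almost exactly.

The numbered scripts under `analysis/` run these analyses end to end
(`01_isodesmic_kd.R`, `02_filament_geometry.R`, `03_tirf_copy_number.R`,
`04_severing_statistics.R`) and write their tables under `results/`.

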