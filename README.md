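# flavassembly

Quantitative analysis for flavonoid supramolecular-assembly studies.

Dietary flavonoids (quercetin and its glycosides isoquercitrin and
quercitrin) inhibit many unrelated enzymes at once — classic pan-assay
interference behaviour — and molecular simulation suggests a structural
reason: they self-assemble into ordered π-stacked fibers that physically
impinge on protein dynamics. Turning that hypothesis into numbers takes four
analyses, and this package implements all of them for anyone running, or
emulating, such a study:

1. **Enzyme-panel dose–response fitting.** Four-parameter logistic fits of
   percent inhibition against log₁₀(concentration),
   `y = b + (t − b) / (1 + 10^(h (x₀ − x)))`, with the IC50 read off where
   the fitted curve crosses 50% inhibition and every fit placed in one of
   three categories: IC50 within the assayed range, IC50 extrapolated beyond
   it, or all values at baseline.
2. **Weighted Z-score efficacy ranking.** Per enzyme *i*, successful
   readouts are standardised as `z_i = (log₁₀ IC50 − X̄_i) / s_i`; missing
   readouts are imputed `z = 2`; per compound the score is
   `z̄ = Σ w_i z_i / n_panel` with readout-count weights
   `w_i = N_i / Σ N_i`. Low `z̄` means potent, broad inhibition.
3. **Radius-of-gyration trajectory analysis.** Mass-weighted
   `R_g = sqrt(Σ m_k |r_k − r̄|² / Σ m_k)` time series over tag selections,
   windowed quartile summaries, and Levene / Brown–Forsythe
   variance-heterogeneity tests on duplicate-pooled windows.
4. **Assembly structure and free-energy profiling.** Geometric π-stacking
   detection (centroid distance, interplanar angle, lateral offset),
   molecule-level assembly graphs classified into primary (linear stack),
   secondary (branched), cyclic and singleton topologies; and a
   weighted-ensemble engine with a variation-maximising resampler
   (`V = Σ_ij (d_ij/d0)^α` over a radius-of-gyration distance),
   walker-lineage tracing and `F = −ln p̂` free-energy profiles.

Synthetic-data generators reproduce the statistical structure of the inputs
(a 58-compound × 7-enzyme screen at 10 concentrations spanning 5 nM–100 µM
with two replicates; collapsing molecular configurations; ideal π-stacked
ring fibers; double-well toy dynamics), so the entire pipeline runs and is
tested without any external data.

## Worked example

Simulate the study-design screen, refit it, and rank the compounds:

```r
library(flavassembly)

screen  <- gen_inhibition_panel(default_panel_spec(seed = 1))
fits    <- fit_panel(screen)
round(summarize_categories(fits), 1)
#>     IN_RANGE EXTRAPOLATED     BASELINE
#>         26.1         12.1         61.8

ranking <- rank_compounds(fits)
head(ranking, 3)
#>   compound_id       zbar rank n_repeats_averaged  tied
#> 1       FLV48 0.05975278    1                  1 FALSE
#> 2       FLV38 0.07569584    2                  1 FALSE
#> 3       FLV14 0.09197051    3                  1 FALSE
```

About a quarter of compound × enzyme pairs yield an in-range IC50, an
eighth extrapolate above 100 µM, and the rest sit at baseline; the ranking
orders compounds by the weighted mean of their per-enzyme z-scores (FLV48's
score of 0.060 makes it the panel's broadest inhibitor in this simulated
screen).

Assembly analysis on a synthetic collapsing system and a branched fiber:

```r
traj <- gen_collapse_trajectory(collapse_traj_spec(seed = 1))
rg   <- radius_of_gyration(traj)
distribution_summary(rg, window = c(10, 20))   # equilibrated window, nm
#> $n 100   $min 0.082   $q1 0.089   $median 0.108   $q3 0.141   $max 0.218

fiber <- gen_ring_fiber(fiber_spec(5, branch_points = list(c(3, 2))))
build_assembly_graph(detect_stacking_contacts(fiber),
                     unique(fiber$atoms$molecule_id))
#> <fa_assembly> 7 molecules, 7 contacts, 1 component(s)
#>   component size     class
#> 1         1    7 SECONDARY
```

The collapsed ensemble has compacted from ~1.5 nm to ~0.11 nm median radius
of gyration, and the 5-ring fiber with a 2-ring branch is recovered as a
single 7-molecule component with branched (secondary) topology.

Weighted-ensemble sampling of the double-well toy system:

```r
prop <- make_double_well_propagator(double_well_spec(barrier = 3))
res  <- run_weighted_ensemble(prop, rep(1, 50), revo_params(n_cycles = 200),
                              seed = 1)
res
#> <fa_weresult> 50 walkers x 200 cycles (2 time units/walker, 100 aggregate)
#>   final weight sum deviation: 2.22e-16
profile <- free_energy_profile(res, bins = 25)   # bin_mid, p, F = -ln(p)
```

Total probability is conserved to machine precision across all 200
resampling cycles; the profile's `F` column is the free-energy-like value
in kT units, lowest near the well minima.

## Documentation

The methods vignette (`vignettes/flavonoid-assembly-methods.Rmd`) documents
the models, every tunable threshold with its default and rationale, what
the synthetic generators do and do not emulate, and known limitations.
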