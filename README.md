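# symbioflux

Constraint-based modeling of symbiotic nitrogen fixation in rhizobial
bacteroids, with a statistical framework for scoring how well the model's
predictions agree with transcriptome and proteome data.

## The problem

Inside legume root nodules, rhizobia differentiate into bacteroids that
reduce atmospheric N₂ to ammonium and trade fixed nitrogen for plant
carbon (dicarboxylates such as malate). Genome-scale metabolic
reconstructions of this state can be interrogated with flux balance
analysis (FBA): assuming a metabolic steady state, the flux distribution
*v* is predicted by the linear program

```
maximize   Z = Σᵢ cᵢ · Xᵢ          (production of key metabolites)
subject to S v = 0                 (mass balance)
           αⱼ ≤ vⱼ ≤ βⱼ            (thermodynamic/enzymatic bounds)
```

where the objective **Z** is realized as a drain reaction consuming the
metabolites that sustain nitrogen fixation — glycogen, lysine,
poly-β-hydroxybutyrate, alanine, aspartate and ammonium, optionally
extended with L-valine and L-histidine (`zfix_objective()`), each with
unit coefficient *cᵢ*.

Because a model is only as good as its agreement with data, the package's
second half quantifies model–omics concordance. For the set of genes (or
enzymes) predicted *active* by FBA and the set detected by
high-throughput experiments, the **consistency coefficient**

```
η = |predicted ∩ experimental| / |predicted|
```

ranges from 0 to 1, with a hypergeometric upper-tail p-value for the
overlap and a per-pathway three-way breakdown (predicted only / both /
detected only). A z-score procedure (`zscore_select()`, threshold 1.65 on
standardized mean log-ratios) reproduces the transcriptome selection step
that feeds the experimental set, and a synthetic-data module generates
bacteroid-like toy networks and omics data with known ground truth so the
whole pipeline is testable without any external download.

Who is it for: systems biologists working with GPR-annotated metabolic
reconstructions (tab-separated tables or SBML) who want reproducible FBA
/ FVA / gene-deletion analyses and a quantitative, statistically grounded
answer to "does my model agree with my omics data?"

## Worked example

```r
library(symbioflux)

preset <- make_toy_network("mini_fix")   # bacteroid-like toy network
preset
#> <network_preset> 'mini_fix': 31 reactions, 26 genes; optimum 0.96, 17 essential genes

fit <- solve_fba(preset$model)           # parsimonious FBA
glance(fit)
#> # A tibble: 1 × 5
#>   objective_value status  mode         n_active steady_state_error
#>             <dbl> <chr>   <chr>           <int>              <dbl>
#> 1            0.96 optimal parsimonious       24           7.77e-15

# simulate a proteome that detects each truly-active gene with prob 0.7
sim <- simulate_omics(preset, detection_prob = 0.7, shift = 2, seed = 42)
score_model_vs_omics(preset$model, fit, sim$proteome, preset$pathway_map)
#> <concordance_report> vs 'proteome' (universe: pathways)
#>   eta_genes   = 0.8696 (20 / 23), p = 0.00769
#>   eta_enzymes = 0.7778 (14 / 18), p = 0.0263

ko <- knockout_all(preset$model)         # in-silico single-gene deletions
dplyr::count(ko, phenotype, lethal)
#> # A tibble: 3 × 3
#>   phenotype lethal     n
#>   <chr>     <lgl>  <int>
#> 1 -         FALSE      2
#> 2 -         TRUE      17
#> 3 =         FALSE      7
```

Reading: the network fixes 0.96 objective units at its carbon-limited
optimum; 24 reactions carry flux in the canonical (parsimonious)
optimum. With 70% proteome detection, 20 of the 23 FBA-active genes are
experimentally supported (η = 0.8696), more than expected by chance
(p ≈ 0.008). Knocking out each of the 26 genes one at a time finds 17
lethal genes (the nitrogenase complex, the sole gluconeogenic route,
storage-polymer synthesis, …), two partial-loss genes, and 7 neutral
ones (isozyme pairs and the permanently closed glucose route).

Every result object has `tidy()`/`glance()` methods and an `autoplot()`
(FVA ranges, robustness curves, per-pathway concordance bars, z-score
selections, recovery calibration). `full_run()` chains the whole
pipeline from a YAML config and writes TSV/JSON artifacts plus a
manifest for byte-identical reruns.

## Vignette

`vignettes/symbiotic-fba-concordance.Rmd` documents the model and its
assumptions, the tunable parameters, the synthetic-data design and its
limits, and the numerical choices (solver, tolerances, tie-breaking).
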