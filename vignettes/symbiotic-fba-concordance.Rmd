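---
title: "Methods: constraint-based modeling of nitrogen fixation and model–omics concordance"
author: "symbioflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constraint-based modeling of nitrogen fixation and model-omics concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symbioflux)
```

## The model

A metabolic reconstruction is a list of reactions with signed
stoichiometries over compartmentalized metabolites (`[c]` cytoplasm,
`[e]` external/nodule space), flux bounds, and boolean
gene–protein–reaction (GPR) rules in which `and` encodes a protein
complex and `or` encodes isozymes. Flux balance analysis assumes the
bacteroid operates at a metabolic steady state, `S v = 0`, with each
flux confined to `[α_j, β_j]`; bounds encode irreversibility
(`α_j ≥ 0`) and capacity, with ±1000 arbitrary flux units standing in
for "unconstrained" so every LP stays bounded.

The nitrogen-fixation objective is a *metabolite-production* objective:
a linear combination of target metabolites with unit coefficients, not a
flux already in the network. It is therefore realized as a single
irreversible drain reaction consuming one unit of each target; under
mass balance, the drain's flux equals the net synthesis capacity the
network can sustain, and FBA maximizes it. The default target set is
glycogen, lysine and PHB in the cytoplasm plus exported alanine,
aspartate and ammonium; the extended form adds L-valine and
L-histidine. Their compartment is not dictated by the chemistry of the
drain construction, so it is a parameter
(`zfix_objective(extra_compartment=)`) with `[c]` as the default — the
two amino acids are synthesized cytoplasmically and the drain abstracts
their downstream fate.

Because the targets are consumed *jointly* by one drain, the objective
enforces balanced production: a gene uniquely required for any single
target is predicted essential. This is the intended reading of a
"sustain the symbiosis" objective, and it is what makes, e.g., the sole
gluconeogenic route to glycogen essential in the toy network below.

## Alternate optima, the parsimonious representative, and FVA

The optimal face of an FBA program is rarely a point: parallel routes
carry interchangeable flux, so "the" flux distribution is
solver-dependent. Two mechanisms in the package address this.

* **Parsimonious mode** (default for active-set extraction): after the
  optimum `Z*` is found, a second LP minimizes total absolute flux
  `Σ|v_j|` subject to the same constraints and `v_Z = Z*` (an equality
  pin, so reported fluxes attain the optimum exactly). The split
  `v = p − n`, `p, n ≥ 0` linearizes the absolute values. This picks a
  canonical, reproducible vertex — on a two-route diamond network it
  always selects the shorter route, since the longer one spends more
  total flux for the same yield. Plain mode is retained for comparison;
  on degenerate networks its active set is one arbitrary vertex of the
  optimal face, which is exactly why reported active-set sizes from
  different solvers need not reproduce.

* **Flux variability analysis** fixes the objective at
  `optimum_fraction × Z*` (default 1.0: the optimal face itself) and
  minimizes/maximizes each flux in turn. Reactions whose range is
  numerically zero (`null_variability_core()`, tolerance `1e-6`) carry
  the same flux in *every* optimal solution; this invariant core is the
  robust, solver-independent summary of the optimum.

## Gene deletion and phenotypes

Deleting a gene evaluates every GPR with that gene absent; reactions
whose rule goes false have both bounds set to zero, and FBA is re-run.
The mutant is summarized by the percentage reduction
`100·(1 − Z_mut/Z_wt)` and classified `−` / `=` / `+` with a ±5%
invariance band (the published analysis reports signs only, so the band
width is a package choice, exposed as `tol_percent`). Lethality is
`Z_mut ≤ 1e-6`, the solver noise floor. Under pure LP knockout the `+`
class is unreachable — tightening constraints can never raise a
maximum — so increments can only arise from bound-*widening* experiments
such as `robustness_scan()`, which clamps one reaction to each grid
value and re-solves; the resulting value function is concave
piecewise-linear, a property the tests assert.

## The consistency coefficient

Concordance between model and data is scored on sets. With
`E_iModel`/`G_iModel` the enzymes (reactions) and genes carrying flux
above `1e-6` in the chosen optimum (boundary and objective drains
excluded), and an experimental set from transcriptome/proteome evidence,

η = |predicted ∩ experimental| / |predicted|,

computed separately for genes and enzymes, where "enzyme" is identified
with its catalyzed model reaction. Both sets are first intersected with
a **scoring universe**: by default the union of the supplied pathway
map's members, because model and experiment are only comparable on the
pathways both can see; the whole-model universe is available as an
option. Significance is an upper-tail hypergeometric test of the overlap
in that universe. The universe choice materially affects p-values, which
is why the package exposes it explicitly rather than fixing a
convention, and why published p-values computed under an unstated
universe are not reproduction targets. η is reported to four decimals,
rounded half-up (`round_half_up()`).

The transcriptome branch reproduces the selection procedure upstream of
the experimental set: per-gene mean of replicate normalized log-ratios
(missing values masked), standardization across genes, selection at
`z > 1.65` (strictly one-sided, ≈ upper 5% of a standard normal). The
standard deviation uses the denominator-*N* population form — the
procedure standardizes a fixed population of per-gene means rather than
estimating a sampling variance; the choice is configurable in effect by
pre-scaling, and affects selections only through a factor
`sqrt(N/(N−1))` that is negligible for array-sized gene lists.
Within-array (loess) normalization is consumed, not performed.

## The synthetic-data module

Three generated networks carry analytically known truth:

* `chain` — uptake capped at 5, one conversion, one drain; unique
  optimum 5; the minimal smoke test.
* `diamond` — uptake 10 splitting into a one-step and a two-step route;
  the canonical alternate-optima polytope (branch FVA ranges `[0, 10]`,
  invariant core = uptake + drain only).
* `mini_fix` — ~30 reactions emulating bacteroid physiology: malate
  uptake through a dicarboxylate transporter, a three-subunit
  nitrogenase complex consuming ATP, respiration providing that ATP,
  glycogen/PHB storage, exported alanine/aspartate/ammonium,
  valine/histidine synthesis, a capped myo-inositol sink feeding
  catabolism, isozyme pairs (malic enzyme, alanine dehydrogenase), and
  a permanently closed glucose route that supplies genuinely inactive
  genes. Its optimum is exactly 0.96 (carbon-limited: 12 available
  carbon units against 12.5 consumed per objective unit), and its
  essential set includes the nitrogenase subunits and every
  single-copy step toward any objective metabolite.

Preset truth (optimum, active sets, invariant core, knockout
phenotypes) is **recomputed at generation time** from the model — never
cached on disk — and the test suite re-verifies it against independent
oracles: brute-force polytope-vertex enumeration on the ≤6-reaction
networks, and an external reference LP solver plus an independent GPR
evaluator for the mini_fix knockout scan.

`simulate_omics()` emulates the statistical structure of the two data
channels. Genes active under the parsimonious optimum receive replicate
log-ratios from `Normal(shift, 1)` (shift in units of the noise SD,
default 3 replicates, matching the replicated two-condition design the
z-score procedure assumes); inactive genes from `Normal(0, 1)`. A
background population of non-model genes (default 200) with null
log-ratios is included because microarrays measure the whole
transcriptome and the z-score standardization needs a majority of
unregulated genes to be meaningful — without it, a network whose genes
are mostly active would defeat any relative selection rule. The
proteome channel detects each truly-active gene, and independently each
truly-active enzyme, with probability `detection_prob`.

`end_to_end_recovery()` closes the loop and reports three things: (1) a
detection-calibration curve — the mean gene-η of the model's active set
scored against the simulated proteome over many seeds, whose
expectation is exactly the detection probability because each active
gene is an independent Bernoulli draw; (2) transcriptome recovery —
sensitivity and false-positive rate of the z-selection against the
planted active set, which rises monotonically with the planted shift;
and (3) a knockout confusion table against generated truth. The
calibration deliberately uses the proteome channel alone: merging the
z-selection into the comparison set would add its ~5% null
false-positive rate to every active gene's detection probability and
bias the curve upward by `0.05·(1−p)` — the two channels are therefore
validated separately, and the merged benchmark
(`merge_benchmark()`, a union with the overlap logged) is exercised by
the exact-recovery checks at strong shift.

Default study sizes: calibration at detection probabilities
{0.5, 0.7, 1.0} × 200 seeds, shift-recovery at shifts {1, 2, 4} × 100
seeds — large enough that the binomial CI on a mean η over
200 × 23 active genes has half-width below 0.015, small enough that the
whole experiment runs in seconds on the toy networks.

What the simulation does *not* emulate: dye bias and spatial artifacts
of real arrays, correlated expression within operons, abundance-biased
proteome detection, and genome-scale network structure. Passing tests
therefore demonstrate correctness of the pipeline's statistics and
bookkeeping, not that any particular biological reconstruction is
accurate.

## Numerical choices

* **LP solver.** All problems are solved by a dense two-phase tableau
  simplex implemented in the package: variables are shifted to the
  nonnegative orthant (`w = v − lb`), rows are routed to ≤/≥/= buckets
  with nonnegative right-hand sides, and variables with equal bounds
  (knocked-out reactions) are eliminated before the tableau is built.
  Pricing is Dantzig (most negative reduced cost) with an automatic
  switch to Bland's rule after a pivot budget, which guarantees
  termination on the highly degenerate LPs that knockouts and FVA
  generate. Problems in this package are tens of variables, where a
  dense tableau is both fast (the full mini_fix truth computation —
  FVA plus a whole-genome knockout scan — takes about a second) and
  easy to audit. The suite cross-checks it against vertex enumeration
  and an external reference solver.
* **Tolerances.** Active flux `> 1e-6` (well above the solver's
  feasibility tolerance of `1e-9`); FVA invariance `≤ 1e-6`; lethality
  `≤ 1e-6`; phenotype band ±5%. Solver outputs are clamped into the
  bound box to remove `1e-12`-scale excursions.
* **Degenerate inputs.** Null transformations (`a[c] -> a[c]`) are
  parse errors; infeasible models return a status, never a silent zero;
  an unproducible objective metabolite yields optimum 0 with an empty
  active set; empty predicted sets make η an explicit error rather
  than `NaN`.
* **Determinism.** Parsimonious solves are bit-reproducible; all
  simulation randomness flows from explicit seeds through
  `withr::with_seed`, so identical configurations give byte-identical
  pipeline outputs (the `full_run()` manifest records the config hash
  and seed).

## Known limitations

Single compartment pair by default (extensible, but multi-compartment
transport conventions are the user's responsibility); no
thermodynamic/ΔG bound derivation; no loopless FBA or MILP extensions
(parsimonious mode suppresses, but does not provably eliminate,
futile cycles); gene-level knockout only — no enzyme-complex partial
activity; hypergeometric enrichment without multiple-testing correction
across pathways, since the framework performs two global tests, not a
per-pathway screen.
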