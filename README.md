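# symbflux

Constraint-based metabolic analysis of symbiotic nitrogen fixation in
rhizobial bacteroids.

Bacteroids — the differentiated, non-growing rhizobia inside legume root
nodules — import C4-dicarboxylates (malate, succinate) from the host
plant, respire them microaerobically, and spend the ATP and reductant on
nitrogenase, returning fixed ammonium to the plant. Questions about this
trade ("which genes are required for effective symbiosis?", "which
host-dependent expression changes limit the fixation rate?") are naturally
posed on a genome-scale metabolic reconstruction, but the standard
toolchains are built around growth objectives and single conditions.
`symbflux` provides the bacteroid-specific workflow end to end, in R, with
no external solver dependency.

## What it does

At its core is flux balance analysis with a **symbiosis objective** in
place of biomass: maximise `c'v` subject to steady state `S v = 0` and
bounds `l <= v <= u`, where the objective drains a pseudo-metabolite
aggregating what an effective symbiont must produce (PHB, glycogen,
glutamate, fixed ammonium, cofactor demands), with the composition scaled
so the product's molecular weight is exactly 1 g/mmol — one flux unit is
then 1 g of symbiosis product per gDW per hour, and yields per mmol of
carbon/nitrogen uptake are comparable across reconstructions.

Around that core:

* **Model IO and quality control** — readers/writers for SBML Level 3
  (FBC) and COBRA-style JSON; elemental/charge balance, stoichiometric
  consistency (existence of a strictly positive conserved mass vector),
  and energy-generating-cycle detection.
* **LP toolbox** — a built-in, deterministic bounded-variable simplex;
  FBA, flux variability analysis, shadow prices (rate-limiting substrate
  reports), and joint two-condition 1-norm-minimised flux fitting.
* **Gene analysis** — GPR parsing/evaluation, single-gene deletion
  screening, and symbiotic-gene classification (essential below a 0.05
  mutant/wild-type rate ratio; partial for any other reduction).
* **E-Flux** — condition-specific models from normalized per-gene
  expression tables (`and` = min over subunits, `or` = sum over isozymes,
  `-1` = no data), scaled against a shared cross-condition normaliser.
* **Evolutionary sensitivity analysis** — randomized greedy adoption of
  the high-yield condition's bounds starting from the low-yield condition;
  reactions adopted in nearly all trajectories are the determinants of the
  yield difference.
* **A toy bacteroid generator** — a fully balanced 39-reaction network
  (TCA, respiration, nitrogenase, storage, amino-acid export, symbiosis
  objective, GPRs with isozyme/complex structure) plus matched
  two-condition expression profiles with controllable effect sizes, so the
  entire pipeline is testable without downloads.

## Worked example

```r
library(symbflux)

toy <- generate_toy_bacteroid_model()
m   <- apply_standard_condition(toy$model, toy$condition)

fit <- solve_fba(m)
fit
#> FBA solution (max SK_symbiosis_product)
#>   status:    optimal
#>   objective: 0.131218
#>   reactions with nonzero flux: 30 / 39

compute_symbiosis_yields(m, fit)
#> Symbiosis yields
#>   product flux:   0.1312 g/gDW/h
#>   carbon yield:   0.0143 g/mmol C  (uptake 9.175 mmol C/gDW/h)
#>   nitrogen yield: 0.2749 g/mmol N  (uptake 0.4772 mmol N/gDW/h)
#>   C/N:            0.05201
```

The objective flux (0.131 g product/gDW/h) is what the bacteroid can
deliver under the standard microaerobic condition (malate 1.44, succinate
1.38, O2 1.26 mmol/gDW/h, maintenance ATP fixed at 4); the carbon yield
divides it by total carbon uptake. Shadow prices identify the rate-limiting
substrates — here oxygen first, then myo-inositol:

```r
shadow_prices(m)$rate_limiting[1:2, ]
#>      exchange metabolite      price
#> 8     EX_o2_c       o2_c 0.09185246
#> 15 EX_inost_e    inost_e 0.07873068
```

A single-gene deletion screen classifies the 31 toy genes:

```r
classify_symbiotic_genes(single_gene_deletion(m))
#> Symbiotic-gene classification (31 genes screened)
#>   symbiotic (ratio < 1): 20
#>     essential (ratio < 0.05): 14
#>     partial effect:      6
#>   nonessential:          11
```

Two-condition analysis from expression profiles (the generated scenario
up-regulates the respiratory chain and inositol transport in condition B),
ending with the evolutionary sensitivity analysis from the lower-yield
condition toward the higher one:

```r
profs <- generate_expression_profiles(toy$model)
res <- run_conditions(toy$model, profs, toy$condition,
                      n_runs = 100, seed = 1)
vapply(res$yields, `[[`, 0, "carbon_yield")
#>       A       B
#> 0.00979 0.01429
head(res$determinants, 2)
#>   reaction frequency   mean_gain determinant
#> 1     CYOO      1.00 0.027288394        TRUE
#> 2   INOSTt      0.83 0.000681811       FALSE
```

The respiratory reaction is adopted in every trajectory and contributes
the bulk of the objective gain: it is the bottleneck behind the yield gap.

## Analysing a published reconstruction

All of the above runs unchanged on a genome-scale bacteroid
reconstruction. `analyze_published_model()` wraps the standard-condition
workflow for a downloaded model, reporting parsed model statistics,
symbiosis yields and symbiotic-gene counts:

```r
res <- analyze_published_model("icc541.json")
res$stats; res$yields; res$counts
```

The iCC541 *Sinorhizobium fredii* bacteroid reconstruction this package is
designed around is deposited in its authors' public repository
(`github.com/cacontad/SfrediiScripts`, COBRA JSON); it is not bundled
here. Once downloaded to the repository root (or `~/icc541.json`), the
acceptance test that reproduces its published yields and gene counts runs
automatically with the rest of the suite.

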