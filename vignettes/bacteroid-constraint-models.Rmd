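---
title: "Constraint-based analysis of nitrogen-fixing bacteroids with symbflux"
author: "symbflux authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based analysis of nitrogen-fixing bacteroids with symbflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symbflux)
```

## The model

Rhizobial bacteroids are the differentiated, non-growing form of rhizobia
inside legume nodules. They import C4-dicarboxylates (malate, succinate)
from the host plant, respire them under the microaerobic conditions the
nodule maintains, and spend the resulting ATP and reductant on nitrogenase,
exporting fixed ammonium back to the plant. `symbflux` models this state
with flux balance analysis (FBA): given a stoichiometric matrix $S$ and
flux bounds $l \le v \le u$, it solves

$$\max_v \; c^\top v \quad \text{s.t.} \quad S v = 0,\; l \le v \le u,$$

where the objective $c$ selects not a biomass reaction — growth is switched
off in bacteroids — but a *symbiosis reaction*: a pseudo-reaction consuming
everything an effective symbiont must provide (storage polymers PHB and
glycogen, glutamate, fixed ammonium, phosphate and iron demands) in
proportions given as mmol per gram of symbiosis product. The composition is
rescaled by a single scalar so that the pseudo-product has a molecular
weight of exactly 1 g/mmol; one unit of objective flux then means 1 g of
symbiosis product per gDW per hour, and yields per mmol of carbon or
nitrogen taken up are directly comparable across reconstructions after
`rescale_for_cross_model_comparison()`.

Steady state, a single static bound set, and proportionality of capacity to
transcript abundance (below) are the main assumptions. Thermodynamics
enters only through bound signs; regulation is not modelled.

## Standard nitrogen-fixation condition

`standard_condition()` encodes the bacteroid's nutrient environment:

| parameter | value | unit |
|---|---|---|
| malate uptake | 1.44 | mmol/gDW/h |
| succinate uptake | 1.38 | mmol/gDW/h |
| O2 uptake | 1.26 | mmol/gDW/h |
| ATP maintenance (fixed) | 4 | mmol/gDW/h |
| glutamate uptake (default) | 0.18 | mmol/gDW/h |
| myo-inositol uptake (default) | 0.05 | mmol/gDW/h |
| ions/cofactors | 1000 | mmol/gDW/h (effectively unlimited) |

The glutamate and inositol defaults are package defaults, exposed as
arguments and in the condition YAML: they must be set explicitly when a
specific reconstruction's published condition is to be reproduced. Note an
important interaction: the maintenance flux is *fixed*, so conditions that
remove the ATP supply (for instance closing the O2 exchange) make the model
infeasible rather than merely unproductive — an obligate aerobe cannot pay
its maintenance without respiration. With the maintenance bound freed, the
same model returns a zero optimum.

## Model quality battery

`validate_model()` bundles three checks run before any simulation:

* **Elemental and charge balance** of every internal and transport
  reaction, from the metabolite formulas (generic side groups `R` are a
  pseudo-element and must cancel). Reactions touching metabolites with
  unknown formulas are reported `unchecked`, not balanced.
* **Stoichiometric consistency**: existence of a strictly positive mass
  vector $m$ with $S_\text{int}^\top m = 0$, posed as an LP with $m \ge 1$
  (a scale-invariant closure of $m > 0$). When it fails, a single
  max-support LP identifies exactly the metabolites that cannot carry
  positive conserved mass.
* **Energy-generating cycles**: all exchanges closed, an ATP-dissipation
  reaction added and maximised; any flux above tolerance is a cycle that
  would inflate yields, and the nonzero-flux reactions are reported as a
  witness.

The tolerance for "zero" in all validators is $10^{-6}$.

## The LP engine

No LP backend is assumed: the package carries a bounded-variable two-phase
revised simplex (compiled, dense, explicit basis inverse with periodic
refactorisation). Pivoting is deterministic — Dantzig pricing switching to
Bland's rule after a fixed budget, ratio-test ties broken by smallest
variable index — so repeated solves return identical flux vectors, which
the knockout screen and sensitivity analysis rely on. Pivot tolerance is
$10^{-9}$; phase-1 feasibility is accepted below $10^{-7}$. Duals are read
off the optimal basis; shadow prices are reported so that a positive price
is the objective gain per unit of extra metabolite availability. When the
optimum is primal-degenerate the duals need not be unique; the package
warns and reports the solver's dual, which is how they are used in practice
(flagging rate-limiting substrates, not quantitative pricing).

Flux variability analysis (FVA) reports per-reaction flux ranges subject to
the objective staying within a fraction of its optimum; fraction 0 (the
default used to derive E-Flux envelopes) leaves the objective free. The
joint two-condition fit fixes each condition's objective at its own optimum
(relative tolerance $10^{-6}$) and minimises the summed 1-norm of both flux
vectors with the standard auxiliary-variable linearisation, yielding
parsimonious, comparable distributions.

## Gene deletions

GPR rules are parsed with `and` binding tighter than `or`. A single-gene
deletion disables the reactions whose rule evaluates false, sets their
bounds to zero, and records the mutant/wild-type objective ratio. Genes are
classified *essential* below the 0.05 rate-ratio cutoff, *partial* for any
other reduction beyond a guard band of 0.01 (so LP noise is never labelled
a biological effect), and *nonessential* otherwise; essential plus partial
genes are the symbiotic genes. Both thresholds are arguments.

## E-Flux integration

Reaction activity scores map gene expression through the GPR: `and` takes
the minimum over scored subunits (a complex is limited by its scarcest
subunit), `or` sums scored isozymes (capacities add). The sentinel `-1`
marks missing data and propagates only when no child of a node is scored.

Bounds for each condition scale the baseline FVA envelope (fraction 0) by
the reaction's score divided by a *shared* normaliser — the maximum finite
score over both conditions — so the two condition models sit on one
capacity scale and their yields are comparable. A per-condition normaliser
is available (`normalizer = "per_condition_max"`) for sensitivity checks.
Two deliberate choices:

* a score of exactly 0 closes the reaction, distinct from `-1` (unknown);
* unscored reactions keep the nutrient condition's bounds rather than
  having the FVA envelope imposed: envelope minima/maxima encode fluxes
  *forced* by other reactions at full capacity (the O2 exchange's envelope,
  for instance, forces the uptake the unscaled respiratory chain would
  carry), and imposing them alongside scaled-down bounds is contradictory.
  Scaled reactions do have both bound sides scaled toward zero, the
  symmetric choice for reversible reactions.

## Evolutionary sensitivity analysis

To ask which bound changes explain a yield gap between two conditions, the
analysis starts from the low-yield bounds and repeatedly picks a reaction
uniformly at random among those whose bounds differ, moves both of its
bounds a random fraction $\lambda \sim U(0,1)$ of the way toward the
high-yield bounds (full replacement is a config option), and keeps the move
only if the optimum strictly improves by more than $10^{-6}$ — so neutral
drift through degenerate optima is excluded. A run ends when the objective
is within $10^{-6}$ of the high-condition optimum or after `stall_limit`
consecutive rejections (default 50 times the number of differing
reactions). One master seed spawns per-run seeds as `seed + run - 1`, so
any run can be reproduced in isolation. Reactions accepted in at least 90%
of runs (configurable) are reported as determinants, with their mean
objective gain per acceptance.

Two properties worth knowing. When the two bound sets differ only in the
improving direction, every trajectory's objective is bracketed between the
two optima. When bounds differ in both directions (as with noisy expression
data), a partially adopted mixture can exceed the high-condition optimum;
runs then stop on crossing it. And a serial chain whose members share
identical scaled caps can never be improved by a single-reaction move — a
structural blind spot of any one-reaction-at-a-time greedy adoption, which
is why the toy network keeps each expression-limited route to a single
limiting step.

## The toy bacteroid

`generate_toy_bacteroid_model()` builds a 39-reaction, 36-metabolite
network with real elemental formulas: malate/succinate/glutamate/inositol
uptake, a lumped TCA cycle, one lumped respiratory reaction (P/O = 3)
consuming O2, the canonical nitrogenase
($N_2 + 4\,NADH + 16\,ATP + 16\,H_2O \to 2\,NH_4^+ + H_2 + \dots$, ATP
coefficient configurable), PHB and glycogen storage with a cheap
(inositol-derived) and an expensive (gluconeogenic, ATP-consuming) glycogen
route, ammonium/alanine/aspartate export, a fixed ATP maintenance drain,
and a balanced symbiosis reaction over PHB, glycogen, glutamate, ammonium,
phosphate and iron. Every internal and transport reaction carries a GPR
over synthetic gene ids — including configurable isozyme (`or`) pairs and
complex (`and`) pairs — except the maintenance pseudo-reaction, which is
deliberately the canonical orphan. Generated models are asserted against
the full validation battery and a standard-condition feasibility probe.

Under the standard condition the toy is respiration-limited: O2 and
inositol carry nonzero shadow prices, closing the inositol route costs a
few percent of the optimum, and the knockout screen finds a mixture of
essential (nitrogenase and complex subunits, single-copy TCA genes),
partial, and buffered (isozyme) genes. These proportions emulate the
structure of a genome-scale bacteroid analysis at 1/15th the size; the toy
has no annotation noise, no blocked reactions, no alternative cofactor
pools, and its optima are much less degenerate than a real
reconstruction's, so passing on the toy does not certify behaviour on real
data — it certifies the algorithms.

`generate_expression_profiles()` draws per-gene lognormal expression around
pathway-typical means, multiplies targeted pathways' means in condition B
by scenario fold changes, and marks a configurable fraction of genes
missing (`-1`) in both conditions. Non-planted pathways share a high mean
(and isozyme-pair genes get half of it, so `or`-sums stay on the same
scale) — after shared-max normalisation their relative activities stay near
1, keeping the fixed maintenance payable; the respiratory chain and the
inositol transporter sit lower so the planted fold changes genuinely move
the bottleneck. Defaults are fold 1.5 on the respiratory chain and 1.8 on
inositol transport in condition B, noise $\sigma = 0.08$ on the log scale,
10% missing genes, seed 42. Determinant-recovery properties are asserted on
the noise-free variant of this scenario ($\sigma = 0$, no missing genes):
with per-gene noise *every* scored reaction's bounds differ slightly
between conditions, and the planted pair is no longer the unique ground
truth; under the default noisy scenario the respiratory reaction is still
recovered in every run.

## Problem sizes used in checks

The packaged checks run FBA/FVA/knockout screens on networks of 3–39
reactions, property tests against an exhaustive vertex-enumeration LP
oracle on networks of up to 6 reactions, and sensitivity analyses of 25–200
runs (the analysis itself defaults to 10,000 runs, which is what a full
study would use). These sizes were chosen so the whole battery gives quick
feedback on a laptop while still exercising every code path at the scale
where independent oracles are exact.

## Limitations

* The simplex is dense; it is comfortable at genome scale for single
  solves and screens (hundreds of reactions) but not tuned for
  multi-thousand-reaction pan-models.
* Shadow prices under degeneracy are solver-dependent (warned).
* E-Flux proportionality is a proxy; the package deliberately implements
  no discrete integration variants (iMAT/GIMME) and no loopless or
  quadratic (MOMA) methods.
* The toy generator fixes its network topology; only capacities,
  stoichiometric coefficients, isozyme structure and the inositol route are
  parameterised.
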