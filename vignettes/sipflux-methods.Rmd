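---
title: "Methods: electron-balance and DNA-SIP analytics in sipflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: electron-balance and DNA-SIP analytics in sipflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sipflux)
```

## Scope

`sipflux` implements the quantitative core of a DNA stable-isotope-probing
(DNA-SIP) study of facultative sulfide-oxidizing heterotrophic denitrifiers
(F-SOHDs) in anoxic estuarine sediments:

1. a redox bookkeeping layer (oxidation states, electrons per atom, exact
   rational reaction balancing, standard Gibbs energies);
2. the electron-balance statistics of denitrifying incubations;
3. isopycnic CsCl gradient analytics (density calibration, profile
   normalization, heavy/light demarcation, labelling shifts, heavy-fraction
   enrichment tests);
4. treatment-comparison function assignment with community isotope
   correction;
5. a ground-truthed synthetic data generator;
6. TSV/JSON readers, writers and a pipeline runner.

This vignette documents the model, its parameters, the numerical choices,
and the design decisions that were left open by the source method.

## Electron-balance statistics

All nitrogen and sulfur concentrations enter the statistics on an **atom
basis** (µM of N or S atoms). Molecule-basis measurements (N~2~O, N~2~,
thiosulfate) are converted on read by their atom multiplicity
(`read_timeseries_tsv()`); nothing downstream guesses units.

The completion extent of denitrification over an incubation window is

$$N'_{com} = \frac{(\Delta NO_3 - \Delta NO_2 - \Delta N_2O - \Delta NH_4)
\cdot 5 + \Delta NO_2 \cdot 2 + \Delta N_2O \cdot 4 + \Delta NH_4 \cdot 8}
{C^i_{NO_3} \cdot 5},$$

i.e. electrons actually transferred to nitrogen, relative to the demand of
complete nitrate-to-N~2~ reduction. The per-product coefficients (2, 4, 5, 8
electrons per N) are not free parameters: they are recomputed from oxidation
states by the redox layer and asserted equal in the test suite.

The sulfide electron share is

$$P^S_{den} = \frac{\Delta S^0 \cdot 2 + \Delta S_2O_3^{2-} \cdot 4 +
\Delta SO_3^{2-} \cdot 6 + \Delta SO_4^{2-} \cdot 8}{C^i_{NO_3} \cdot 5},$$

with every sulfur term the **net amount produced** on an S-atom basis
(including the sulfite term, mirroring the other terms). The organic-matter
share uses 4 e^-^ per carbon oxidized to CO~2~ by default (`generic4`), or
per-compound electron contents (acetate 4, propionate 14/3, glucose 4 e^-^/C)
when the OM mix is known.

**Values outside [0, 1] are reported raw with an `overrange` flag, never
clipped.** This matters because the [0, 1] range for $N'_{com}$ is *not* an
invariant: dissimilatory nitrate reduction to ammonium (DNRA) consumes
8 e^-^/N, more than the 5 e^-^/N of the denominator, so a valid ledger with
$3\,\Delta NH_4 > 3\,\Delta NO_2 + \Delta N_2O$ exceeds 1 (a pure-DNRA
ledger attains the supremum 8/5). The provable bound is $[0, 8/5]$;
$[0, 1]$ holds whenever DNRA does not dominate. Likewise, an OM share above
1 usually signals that total OM drawdown (which includes assimilation and
electrons routed to sulfate reduction) over-counts denitrification-directed
electrons; the flag, not silent correction, is the contract.

Net changes are endpoint differences (consumption `max(0, c(t0) - c(t1))`
for NO~3~, sulfide and OM-C; production `max(0, c(t1) - c(t0))` otherwise),
with linear interpolation at unsampled times, replicate means with SEM, and
clamped-to-zero negatives flagged.

## Gradient analytics

Buoyant density is calibrated linearly from refractive index
(`density = 10.8507 · ri − 13.4411` by default; supply a fitted line for a
real instrument). Profiles are normalized per marker to percentages summing
to 100; fractions with density ≥ 1.725 g/mL (the gradient loading density)
are "heavy". The labelling shift between a labelled and an unlabelled
profile is the difference of copy-weighted mean densities — antisymmetric by
construction and zero for identical profiles. Heavy-fraction enrichment is
tested with an equal-variance two-tailed Student's *t* test on replicate
heavy totals; identical groups short-circuit to *t* = 0, *p* = 1 rather
than erroring on zero variance.

## Function assignment

Treatments are coded by a strict token grammar (`12Ci`, `13Ci`, `12Co`,
`13Co`, `N`, `S` joined by `+`; at most one `13*` label). The rules compare
heavy-fraction relative abundances between treatments:

| flag | comparison(s), all must pass |
|---|---|
| chemolithoautotroph | (13Ci+12Co)+N+S > (12Ci+12Co)+N+S **and** 13Ci+N+S > 12Ci+N+S |
| heterotroph | (12Ci+13Co)+N+S > (12Ci+12Co)+N+S **and** (12Ci+13Co)+N > (12Ci+12Co)+N |
| nitrate_reducer_sulfur_oxidizer | +Ci+N+S > +Ci |
| sulfide_oxidizer | +C+N+S > +C+N |
| autotroph_sulfide_oxidizer | (13Ci+12Co)+N+S > both (13Ci+12Co)+N and (12Ci+12Co)+N+S |
| heterotroph_sulfide_oxidizer | (12Ci+13Co)+N+S > both (12Ci+12Co)+N+S and (12Ci+13Co)+N |
| fsohd | heterotroph ∧ heterotroph_sulfide_oxidizer |

"Increase" is operationalized by three conjunctive thresholds
(`decision_thresholds()`): mean difference ≥ 0.5 percentage points, fold
change ≥ 1.2, and a positive difference in ≥ 2/3 of replicate pairings.
The assay design itself never quantifies "increase"; the defaults separate
typical SIP effect sizes (fractions of a point up to tens of points, and
severalfold enrichments) from replicate noise, and every call records the
thresholds and the per-comparison evidence used.

Two comparisons are underdetermined by the assay design and are
configurable:

* the nitrate-reduction rule (+Ci+N+S vs +Ci) defaults to the
  13Ci-labelled heavy fractions (`rule3_label = "13Ci"`), with an unlabelled
  mode;
* the sulfide-oxidation rule (+C+N+S vs +C+N) defaults to the 13Co-labelled
  heavy fractions (`rule4_label = "13Co"`), since sulfide-response contrasts
  are most informative under organic-carbon labelling; 13Ci and unlabelled
  modes exist.

A rule whose treatments are absent is `NA` (not evaluable), never `FALSE`,
and `fsohd` is `NA` when either conjunct is. Calls carry a fixed caveat:
heavy-fraction relative abundances are compositional and do not measure
absolute growth.

## The synthetic generator

`simulate_incubation()` advances guild-specific stoichiometric processes by
explicit Euler steps (default 0.25 h):

| guild | donor → product (e^-^/atom) | acceptor → product (e^-^/atom) |
|---|---|---|
| CHEMOLITHOAUTOTROPH | sulfide → sulfate (8/S), fixes Ci | NO~3~ → N~2~ (5/N) |
| CONVENTIONAL_HD | OM-C → CO~2~ (4/C) | NO~3~ → N~2~ (5/N), or → N~2~O (4/N) when sulfide > 1.25 µM |
| FSOHD_COMPLETE | OM-C (4/C) + sulfide → sulfate (8/S) | NO~3~ → N~2~ (5/N) |
| FSOHD_INCOMPLETE | OM-C (4/C) + sulfide → S^0^ (2/S) | NO~3~ → N~2~ (5/N) |
| DNRA_HETEROTROPH | OM-C (4/C) | NO~3~ → NH~4~ (8/N) |
| SULFATE_REDUCER | OM-C (4/C) | SO~4~ → sulfide (8/S) |
| INERT | — | — |

Every electron released by a donor in a step is consumed by an acceptor in
the same step, so the electron ledger closes exactly and dissolved N and S
atom totals are conserved (biomass N assimilation is off by design, so the
nitrogen ledger closes on dissolved species alone). Pool over-draw is
prevented by proportional down-scaling of the demanding processes, with
automatic step halving (minimum 10^-3^ h) as a second guard; updates are
staged and committed transactionally so a rejected step has no side
effects.

The 1.25 µM free-sulfide threshold on the conventional heterotroph's
nitrous-oxide reductase is the mechanism behind the sulfide–N~2~O contrast:
with 4.83 µM sulfide and no sulfide consumer, denitrification stops at
N~2~O; F-SOHDs remove the sulfide themselves and are unaffected.

Default amendments are the study conditions: nitrate 300 µM N, sulfide
50 µM S, sulfate 750 µM S, ammonium 100 µM N, OM 5 mM C; OM-rich and
OM-limited culture media use C/N 3.52 and 0.70 over 300 µM N. Label atom
purities: 0.985 (13Ci), 0.99 (13Co). Incubations run 72 h with 3-h output
sampling and 3 replicates.

**Noise conventions.** Chemistry noise is additive Gaussian with
σ = 2% of the analyte's *initial* concentration; pools that start at zero
(products) fall back to 2% of the element's initial total, since "2% of
initial" is otherwise undefined for them. qPCR noise is lognormal
(σ = 0.15) with mean-one correction. Truth is always recorded pre-noise.

**Gradients.** A taxon's DNA bands at
ρ = 1.660 + 0.098 · GC + 0.036 · APE g/mL with Gaussian band width
0.006 g/mL, fractionated into 14 fractions over [1.690, 1.760] g/mL
(fraction 1 densest, bottom-first); tail mass is lumped into the terminal
fractions so copy numbers are conserved exactly. Marker genes ride along
with their guild's 16S copies.

**Heavy-abundance tables.** `simulate_heavy_abundance()` generates the
treatment-matrix input of the classifier directly. Each taxon has a
background heavy-fraction share (the unlabelled high-GC tail); a taxon that
assimilates the treatment's ^13^C source is enriched multiplicatively
(`label_fold = 2.5` per responding condition) with an absolute floor of
`effect_pp = 2` percentage points, and F-SOHDs respond a second unit when
sulfide is supplied. The multiplicative form reflects how isotope-labelled
growers dominate heavy DNA severalfold; the additive floor keeps rare
responders above the decision thresholds. Listed taxa deliberately sum to
less than 100%, as in real tables that omit rare taxa.

## Thermodynamics

Reactions hold exact rational coefficients (integer numerator/denominator
pairs); balance checks compute integer residuals over the least common
denominator, so "balanced" means exactly balanced, not balanced to a
tolerance. ΔG° is a stoichiometric sum over a bundled formation-energy
table (standard state: 298.15 K, 1 atm, 1 M, pH 0), with a per-mol-nitrate
normalization and a pH-7 transform
ΔG°′ = ΔG° + ν~H+~ · RT · ln 10^-7^. The bundled acetate-denitrification
reconstruction gives −565.8 kJ per mol nitrate, inside the −579.3 to
−522.9 kJ range reported in the literature for organic-matter-driven
denitrification; this is documented as a plausibility check, not pinned as
a test, because the exact stoichiometries behind that reported range are
not available.

## Problem sizes and runtimes

The test suite and acceptance script use 20-taxon communities, 72-h
incubations at 0.25-h steps (≈ 0.5 s per run), 14-fraction gradients,
1,000-ledger oracle sweeps, a 10,000-case property search on the
completion-extent bounds, and 50 seeded communities for guild-flag
recovery. Everything runs single-threaded in well under the stated budgets
on commodity hardware.

## Limitations

* Guild kinetics are first-order in biomass with fixed uptake rates — no
  Monod saturation, lag phases or temperature dependence.
* The gradient model treats APE as shifting the whole genome uniformly;
  real SIP produces partially labelled DNA mixtures.
* Heavy-fraction relative abundances are compositional; the classifier's
  deltas are not growth rates.
* The pH-7 ΔG transform adjusts proton activity only; ionic strength and
  actual metabolite activities are not modelled.
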