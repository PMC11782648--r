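# sipflux

Electron-balance and DNA stable-isotope-probing (DNA-SIP) analytics for
sulfur-driven denitrification in anoxic sediments, with a ground-truthed
synthetic data generator.

## The scientific problem

In estuarine sediments, nitrate removal is carried out by several competing
metabolisms: conventional heterotrophic denitrifiers (organic carbon as the
electron donor), chemolithoautotrophic sulfur-oxidizing denitrifiers
(sulfide as the donor, CO₂ as the carbon source), and **facultative
sulfide-oxidizing heterotrophic denitrifiers (F-SOHDs)** — heterotrophs that
can additionally burn sulfide when it is present. Separating these guilds
matters because free sulfide above ~1.25 µM inhibits the nitrous-oxide
reductase of conventional denitrifiers, truncating denitrification at the
greenhouse gas N₂O; F-SOHDs both remove that sulfide and finish the
reduction to N₂.

Two quantitative tools identify and weigh these guilds:

1. **Electron-balance statistics** over incubation time series. With all
   pools in µM of N or S atoms, the completion extent of denitrification is

   N′_com = [(ΔNO₃ − ΔNO₂ − ΔN₂O − ΔNH₄)·5 + ΔNO₂·2 + ΔN₂O·4 + ΔNH₄·8] / (Cⁱ_NO₃·5)

   and the share of denitrification electrons contributed by sulfide is

   P^S_den = (ΔS⁰·2 + ΔS₂O₃²⁻·4 + ΔSO₃²⁻·6 + ΔSO₄²⁻·8) / (Cⁱ_NO₃·5),

   where the per-atom electron counts (5 e⁻ for NO₃⁻→N₂, 8 e⁻ for
   sulfide→sulfate, 4 e⁻ per organic carbon→CO₂, …) are derived from
   oxidation states, not hard-coded.

2. **DNA-SIP function assignment.** Parallel microcosms amended with
   combinations of ¹³C-bicarbonate (13Ci), ¹³C-organic matter (13Co),
   nitrate (N) and sulfide (S) are fractionated on CsCl gradients; a taxon
   whose heavy-fraction relative abundance rises only under a particular
   label-by-amendment combination is assigned the corresponding metabolism,
   with unlabelled controls cancelling community-wide amendment responses.
   An F-SOHD is a taxon that is both a heterotroph (responds to 13Co) and a
   heterotrophic sulfide oxidizer (responds *more* under 13Co when sulfide
   is added).

`sipflux` implements both tools, the supporting gradient and thermodynamic
calculations, strict TSV readers/writers, and a stoichiometrically exact
simulator that generates all of these data with known ground truth.

## Worked example

```r
library(sipflux)

## electron balance of a worked ledger (all pools in uM atoms):
## 300 uM nitrate fully consumed; 50 ended as nitrite, 40 as N2O (atom
## basis), 10 as ammonium, the rest as N2
led <- nitrogen_ledger(c_no3_initial = 300, d_no3_consumed = 300,
                       d_no2_produced = 50, d_n2o_produced = 40,
                       d_nh4_produced = 10)
completion_extent(led)
#> [1] 0.8933333        # = 1340/1500

## sulfide's electron share: 45 uM S to sulfate (8 e-/S), 5 uM to S0 (2 e-/S)
sl <- sulfur_ledger(d_sulfide_consumed = 50, d_s0_produced = 5,
                    d_so4_produced = 45)
sulfide_electron_share(sl, c_no3_initial = 300)
#> [1] 0.2466667

## a full synthetic microcosm: 20 taxa, 13C-organic-matter label, all
## amendments, 72 h, 3 noisy replicates
cm  <- make_community(n_taxa = 20, seed = 42)
cfg <- microcosm_config(treatment_key(TRUE, TRUE, TRUE, TRUE, "13Co"),
                        seed = 42)
sim <- simulate_incubation(cm, cfg)
nc  <- net_changes(sim$series, 0, 72)
round(c(d_no3 = nc$nitrogen$d_no3_consumed,
        n_com = completion_extent(nc$nitrogen),
        p_s   = sulfide_electron_share(nc$sulfur, nc$nitrogen$c_no3_initial),
        n2o_pct = n2o_emission_fraction(nc$nitrogen)), 3)
#>   d_no3   n_com     p_s n2o_pct
#> 298.449   0.995   0.071  20.315

## classify the community from its heavy-fraction table
ha    <- simulate_heavy_abundance(cm, seed = 42)
calls <- calls_table(classify_community(ha$table))
sum(calls$fsohd %in% TRUE)
#> [1] 5                # all 5 true F-SOHD taxa recovered, no false calls

## thermodynamics of sulfide-driven denitrification
en <- delta_g_standard(
  reaction_presets()$autotrophic_sulfide_denitrification, species_library())
c(en$dG0, en$dG0_per_nitrate)
#> [1] -3841.000  -480.125   # kJ; per mol nitrate
```

## Analysis workflow

The `analysis/` directory contains the numbered drivers that reproduce the
study's computations end to end, writing TSV tables under `results/`:

| script | writes |
|---|---|
| `analysis/01_simulate_microcosms.R` | per-treatment incubation time series and taxon isotope states |
| `analysis/02_gradient_profiles.R` | CsCl fraction tables and marker labelling shifts |
| `analysis/03_classify_functions.R` | heavy-fraction table, function calls, evidence, guild composition |
| `analysis/04_electron_balance.R` | N′_com, P^S_den, P^OM_den and N₂O fractions per run |
| `analysis/05_thermodynamics.R` | ΔG° / ΔG°′ of the candidate metabolisms |

Run them in order from the repository root:

```sh
Rscript analysis/01_simulate_microcosms.R
Rscript analysis/02_gradient_profiles.R
Rscript analysis/03_classify_functions.R
Rscript analysis/04_electron_balance.R
Rscript analysis/05_thermodynamics.R
```

All computation lives in the package; the scripts are thin, narrated
drivers. Each is seeded, so the `results/` tables are reproducible
bit-for-bit.

## Conventions worth knowing

* Concentrations are µM **atoms** of N or S everywhere inside the package;
  the TSV reader converts molecule-basis rows using an explicit
  `unit_basis` column and refuses ambiguous units.
* Statistics outside [0, 1] (possible for N′_com under DNRA, which carries
  8 e⁻/N) are reported raw with an `overrange` flag — never clipped.
* Gradient fraction 1 is the densest fraction (bottom-first collection);
  fractions at or above 1.725 g/mL are "heavy".
* Classification rules return `NA` when their treatments are absent, and
  every call carries its thresholds and per-comparison evidence.
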