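# nitroflood

Nitrogen budgets and T-RFLP community analysis for seawater-flooded soils.

When low-lying agricultural land is deliberately flooded with seawater
("managed coastal realignment"), the soil turns anoxic within days and its
microbiome reorganizes around anaerobic nitrogen cycling. Microcosm
experiments follow this with three instruments: sealed-core incubations
measuring NH4+ and NOx- fluxes across the soil–water interface, anoxic jar
incubations measuring net ammonification, and porewater depth profiles.
`nitroflood` implements the computational chain that turns those
measurements into a nitrogen mass balance, together with the T-RFLP
fingerprinting and multivariate statistics used to track the community,
and qPCR quantification of marker genes (*amoA*, *nirK*, *nirS*, 16S
rRNA). It is written for biogeochemists and microbial ecologists running
or re-analysing flooding/salinization microcosms.

## The core calculation

Per station and sectioning time point:

* flux: J = (C_end − C_start)·V / (A·t), in mmol m⁻² d⁻¹ (positive =
  efflux); DIN = J(NH4+) + J(NOx−)
* jar rate: OLS slope of porewater NH4+ vs time (admitted when p < 0.05),
  × porosity → nmol cm⁻³ d⁻¹; depth-integrated over 0–20 cm with the
  unmeasured 10–15 cm layer midpoint-interpolated → areal production P
* porewater inventory: Σ C·φ·h, differenced over time → accumulation İ
* **potential denitrification** D = P − J(DIN) − İ (clamped at 0 and
  flagged when negative), **potential NH4+ oxidation** = D + J(NOx−),
  denitrified fraction = D/P

The T-RFLP side: 50–550 bp gating → iterative 1.15×RMS peak-area noise
filtration → single-linkage fragment binning (0.6 bp gap) → relative
abundance → singleton/1% filtering → ln(1 + 100x) → Bray–Curtis, UPGMA,
NMDS, PERMANOVA (exhaustive below 10,000 permutations, Monte-Carlo above),
environmental vectors, OTU sharing counts and abundance modules.

A seeded synthetic-data generator (`generate_scenario()`) produces complete
datasets with known ground truth — a budget that closes exactly, modular
"boom and bust" OTU turnover, qPCR truths — so the whole pipeline is
testable as a parameter-recovery problem.

## Worked example

A miniature dataset whose every number is hand-checkable (collinear jar
series integrating to exactly 10 mmol m⁻² d⁻¹ of production, core fluxes
of 2 + 1 mmol m⁻² d⁻¹, porewater inventory growing 100 → 110 mmol m⁻²
over 10 days):

```r
library(nitroflood)
run_budget(example_budget_dataset())
#> Nitrogen budgets (mmol m-2 d-1):
#>  station time_point production nh4_efflux nox_efflux din_efflux din_sem
#>        S         10         10          2          1          3  0.5774
#>  accumulation denit_raw denit negligible nh4_oxidation denit_fraction
#>             1         6     6      FALSE             7            0.6
#>  incomplete
#>       FALSE
```

Production 10 minus DIN efflux 3 minus accumulation 1 leaves 6 mmol m⁻²
d⁻¹ unaccounted — the potential denitrification; adding the NOx− efflux
gives a potential NH4+ oxidation of 7, and 60% of the produced NH4+ is
inferred lost as gas.

A synthetic community analysed end to end:

```r
sc <- generate_scenario(scenario_config(seed = 1, otu_pool_size = 60,
                                        n_seawater_samples = 0))
cm <- run_community(sc$bundle$peaks[, c("sample_id", "size_bp", "area")],
                    metadata = sc$bundle$metadata,
                    n_perm = 199, n_restarts = 10, seed = 1)
cm$otu_table
#> T-RFLP OTU table (log): 60 samples x 33 OTUs
#>   19 OTUs removed by filtering
cm$permanova
#> PERMANOVA (Monte-Carlo, 199 permutations)
#>        term df     SS      R2      F     p
#>     station  1 0.3717 0.03775  2.632 0.010
#>  time_point  1 1.4260 0.14480 10.100 0.005
#>    Residual 57 8.0500 0.81750     NA    NA
cm$nmds
#> NMDS (k = 2): stress = 0.2231, best of 10 restarts
```

Time point explains the largest share of community variance (R² = 0.14,
p = 0.005 at the 199-permutation resolution) — the generated flooding
signal, recovered.

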