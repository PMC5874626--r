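---
title: "Methods: nitrogen budgets and community fingerprinting in seawater-flooded soils"
author: "nitroflood"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nitrogen budgets and community fingerprinting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitroflood)
```

# Scope

`nitroflood` packages the computational side of a microcosm experiment in
which agricultural soil cores are permanently flooded with seawater and
followed for six months: the benthic nitrogen mass balance derived from core
and jar incubations, the T-RFLP fingerprinting pipeline that turns
capillary-electrophoresis peak tables into an OTU table, the multivariate
statistics run on that table, and qPCR absolute quantification of
nitrogen-cycling marker genes (*amoA*, *nirK*, *nirS*, bacterial 16S rRNA).
Because studies of this kind rarely deposit raw measurement tables, the
package also ships a seeded synthetic-data generator with a fully known
ground truth, so that every downstream stage can be tested end to end as a
parameter-recovery problem.

# The nitrogen mass balance

## Fluxes

A sealed core incubation with headspace volume $V$ (L), cross-section $A$
(m^2^) and duration $t$ (d) yields, for each analyte,

$$ J = \frac{(C_\mathrm{end} - C_\mathrm{start})\, V}{A\, t} \cdot 10^{-3}
\quad [\mathrm{mmol\, m^{-2}\, d^{-1}}], $$

with the sign convention that positive $J$ is an efflux out of the soil.
Influxes are negative values, never errors. The DIN flux is the sum of the
NH~4~^+^ and NO~x~^-^ fluxes of the same core and day
(`compute_flux()`, `compute_din_flux()`).

Replicate cores (n = 3 by default) are averaged per measurement day and the
per-day means combined by a time-weighted mean over the window between
sectionings (`aggregate_fluxes()`). The window for the budget at sectioning
day $T$ is $(T_\mathrm{prev}, T]$, so all flux information between snapshots
is used; the weighting reduces to equal weights for equally spaced days.
The matching of flux days to budget windows is a package choice — the
source experiments do not state one — and is therefore explicit and
window-based rather than nearest-day.

## Jar rates, depth integration, inventories

Anoxic jar incubations of homogenized soil accumulate porewater NH~4~^+^
linearly; `fit_jar_rate()` regresses concentration on time by ordinary
least squares and admits a rate only when the two-sided slope t-test gives
p < 0.05 (configurable `alpha`). Since 1 uM equals 1 nmol per cm^3^ of
porewater, the porewater slope (uM d^-1^) times porosity is the bulk
volumetric rate in nmol cm^-3^ d^-1^. Slopes that fail the gate are
reported as not available with their diagnostics retained; a budget that
depends on them is flagged `incomplete`, never silently dropped.

Layer rates measured at 0–2, 2–5, 5–10 and 15–20 cm are integrated over
0–20 cm (`depth_integrate()`); the unmeasured 10–15 cm layer is linearly
interpolated between the midpoints of its neighbours (7.5, 12.5 and 17.5 cm
are equally spaced, so this equals simple averaging — documented because
other layer geometries would not). The areal rate is
$\sum_l r_l\,h_l \times 0.01$ in mmol m^-2^ d^-1^.

Porewater inventories are $\sum_l C_l\,\phi_l\,h_l \times 10$ in
mmol m^-2^ (`porewater_inventory()`), and the accumulation rate between two
sectionings is the inventory difference per day. The first sectioning uses
the pre-flood profile as its baseline.

## Potential denitrification and NH~4~^+^ oxidation

The mass-balance residual

$$ D_\mathrm{raw} = P - J_\mathrm{DIN} - \dot{I}_{\mathrm{NH_4}} $$

(production minus DIN efflux minus porewater accumulation) is the NH~4~^+^
production not otherwise accounted for, interpreted as nitrogen lost as gas
through coupled nitrification–denitrification. Negative residuals are
clamped to zero and flagged "negligible" while the raw value is retained
for audit. Potential NH~4~^+^ oxidation is the clamped potential
denitrification plus the NO~x~^-^ efflux, and the denitrified fraction is
$D / P$ for $P > 0$. The identity
$P - J_\mathrm{DIN} - \dot{I} - D_\mathrm{raw} = 0$ holds exactly for every
budget the package computes, and is asserted in the tests.

# The T-RFLP pipeline

Peaks are gated to the closed 50–550 bp window. Noise filtration follows
the iterative peak-area procedure: with all peaks initially unclassified,
compute $\sigma$ as the zero-mean RMS of the unclassified areas, promote to
signal every peak with area $> 1.15\,\sigma$, and repeat until a pass
promotes nothing. The procedure converges in at most $n$ promoting passes
(peaks only ever leave the noise set) and is order-invariant; a sample may
legitimately end with zero signal peaks (all areas equal, for instance),
which is flagged. The $\sigma$ estimator is configurable (zero-mean RMS,
the default, or sample SD), as is the factor.

Fragments from all samples are then aligned by single-linkage chaining on
sorted sizes: a new OTU bin opens when the gap to the previous observation
exceeds 0.6 bp. Chains can exceed 0.6 bp total width; each OTU therefore
reports its member-size range alongside its area-weighted centroid.
Same-sample peaks falling into one bin have their areas summed, because
area is the abundance proxy.

Rows are standardized to relative abundance, then OTUs are filtered:
singletons (present in fewer than 2 samples) and OTUs whose overall
abundance falls below 1%. "Overall abundance" is read as the mean
per-sample relative abundance by default; a grand-total share and a
per-sample maximum rule are available, since the phrasing is ambiguous in
the field. Rows are deliberately **not** re-normalized after filtering, so
retained entries keep their original scale. Finally abundances are mapped
through $\ln(1 + 100x)$ — a zero-preserving, monotone log transform on the
percentage scale; the scale factor is configurable.

# Community statistics

Bray–Curtis dissimilarity
$d(a,b) = 1 - 2\sum_i \min(a_i, b_i) / (\sum_i a_i + \sum_i b_i)$
is computed between samples or between OTU abundance profiles
(`bray_curtis()`, delegating to `vegan::vegdist` and cross-checked against
a naive double loop in the tests). Hierarchical clustering is UPGMA via
`stats::hclust(method = "average")`; under exact distance ties hclust's
internal (deterministic) tie-break applies. NMDS minimizes Kruskal stress-1
through `vegan::monoMDS`, taking the best of 20 starts: one metric
(principal-coordinates) start plus seeded random Gaussian configurations;
scores are centred and runs are byte-reproducible under a fixed seed.

PERMANOVA is implemented in the package: the squared distances are
Gower-centred, the total sum of squares partitioned sequentially (Type I)
over the formula terms via cumulative orthonormal projections, and a
pseudo-F formed per term. p-values come from free permutation of the
distance-matrix rows, with the +1-corrected Monte-Carlo estimate by
default and exhaustive enumeration of all $n!$ permutations whenever
$n! \le 10{,}000$. Residual sums of squares at rounding-error scale are
treated as exact within-group fits (F = $\infty$), so perfectly separated
groups attain the enumerated minimum p. `vegan::adonis2` is used as an
independent cross-check in the test suite, never as the implementation,
because it provides neither exhaustive enumeration nor the exact-fit
handling.

Two calibration facts shaped the test design and are worth knowing when
using small designs. First, a free-permutation test on 4 + 4 samples has
only 35 distinct split classes, so the attainable p grid jumps from 0.029
directly past 0.05: any permutation test is conservative there (we measured
a null rejection rate of 0.035 over 4000 simulations). Calibration checks
therefore use 6 + 6 samples, where the grid is fine enough that the
measured null rejection is 0.050. Second, a fraction estimated as a ratio
over a production that has collapsed to ~1% of its earlier peak is not
identifiable at ±0.05 under any realistic noise; the recovery experiments
keep late production at ≥ 20% of peak (see below).

Environmental vector fitting regresses each (centred) variable on the
ordination scores; the reported direction is the unit coefficient vector,
R^2^ the squared multiple correlation, and p a permutation tail
probability obtained by permuting the variable across samples.
`sharing_counts()` tabulates exact Venn cells of OTU presence across
station groups, and `detect_modules()` clusters OTU abundance profiles
(UPGMA on Bray–Curtis) and cuts the tree into k modules (default 4),
renumbered by first appearance along the sample axis — the "boom and bust"
modules typical of flooding experiments.

# qPCR quantification

Standard curves are OLS fits of Cq on log10(copies) over a 10^1^–10^7^
dilution series; the amplification efficiency is $10^{-1/\text{slope}}-1$.
Duplicate Cq values are averaged on the Cq scale (a spread > 0.5 Cq is
flagged), converted to copies per reaction through the curve, and
normalized to copies per gram dry soil by the explicit extraction chain
copies/rxn × (elution / template) / (wet mass × (1 − water content)) —
every factor is an input column, no hidden constants. Values below the
lowest standard are censored ("below quantification") rather than
reported; values above the highest standard are flagged as extrapolated.

# The synthetic-data generator

`generate_scenario()` builds a complete dataset from a seeded
configuration whose defaults are the study conditions: two stations with
contrasting organic matter ("UC" rich, with steep porosity gradients; "C"
poor and homogeneous), six porewater sectioning intervals (0–1, 1–2, 2–5,
5–10, 10–15, 15–20 cm), four jar intervals (0–2, 2–5, 5–10, 15–20 cm —
the 10–15 cm gap is deliberate), sectionings at days 7, 60, 120 and 180
plus a pre-flood state, 13 flux days with 3 replicate cores, and jar
incubations sampled weekly over four weeks.

The budget truth is constructed to close exactly: per station and
sectioning, areal production $P$ (from the layer profile through the same
depth integration the pipeline uses) is split into a denitrified amount
$fP$, porewater accumulation (30% of the remainder by default) and DIN
efflux (the rest, with a time-increasing NO~x~^-^ share). Jar series,
per-core flux incubations and porewater profiles are then generated
consistently with that truth plus configurable instrument noise, so a
noise-free configuration is recovered exactly (to numerical precision) and
the default-noise configuration within stated tolerances. Chloride
profiles are error-function-shaped diffusion fronts relaxing over time —
descriptive plumbing only, no reaction-transport physics is claimed.

The community truth assigns OTUs to a background pool plus co-occurrence
modules occupying disjoint (time point × depth band) windows, with
Dirichlet-distributed abundances (module members up-weighted inside their
window) and per-OTU station/seawater affinities, which gives the
statistics layer a detectable flooding-time signal with known membership.
Electropherograms place one peak per present OTU at its centroid (drawn on
a ≥ 2 bp-spaced grid) with Gaussian size jitter (sd 0.15 bp) and
lognormal area noise, plus a Poisson number of baseline noise peaks.

Two generator choices deserve explanation:

* **Noise-peak areas are a narrow band** (uniform within ±10% of a mean of
  30, emulating spurious calls just above the instrument baseline), not a
  heavy-tailed distribution. The iterative 1.15×RMS filter is scale-free,
  and on heavy-tailed sets (e.g. exponential areas) it cascades: each pass
  lowers the RMS of the remainder and promotes the next tier, so ~90% of
  exponential "noise" ends up classified as signal regardless of its mean.
  A narrow band is the regime in which a 1.15 factor meaningfully
  separates baseline from signal; an exponential option remains available.
* **A peak-calling floor** (`detection_area_min`, default 50 area units)
  censors true-fragment peaks below it, as size-calling software does.
  Without it, trace OTUs inject signal peaks *below* the noise band and
  the filter cascade swallows the band wholesale.

Measurement-noise defaults are set for test power rather than strict
realism (replicate-to-replicate variances are not published for studies of
this kind): 5% relative flux noise across cores, noise-free jars, 1%
relative porewater noise (within flow-injection precision after replicate
averaging — the accumulation term differences cumulated inventories over
60-day windows, which amplifies porewater noise roughly tenfold into the
budget), Cq noise of 0.15 cycles and 0.05 on standards. All randomness
flows from one seed through named substreams, so regenerating one table
never perturbs another and identical configurations are byte-identical.

# Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale, chosen as
the smallest sizes at which each property is informative: the reference
recovery scenario is the full 2-station × 4-sectioning design (~65
samples); regression-gate and PERMANOVA calibrations use 1000 seeded
replicates; binning is checked against its oracle on 200 random instances
of ≤ 30 fragments; OTU recovery uses 100 runs of 12 samples × 50 OTUs.
NMDS uses 20 restarts, 300 iterations and a 1e-7 stress tolerance by
default; the exhaustive-enumeration cap for PERMANOVA is 10,000
permutations; the interpolation tie-break and UPGMA tie-break are as
documented above. Budgets with any unavailable layer rate propagate an
`incomplete` flag.

# Limitations

* The generator's consistency contract is the budget identity, not
  diffusion physics; porewater shapes and Cl^-^ fronts are descriptive.
* T-RFLP cannot resolve taxa sharing a terminal fragment length, and the
  package deliberately offers no taxonomic assignment.
* PERMANOVA uses free permutation only (no strata), sequential sums of
  squares in formula order, and its p-values inherit the discreteness of
  small designs discussed above.
* Potential denitrification is a residual: it aggregates every loss
  pathway (including anammox) and every unmodelled error term; the
  clamping rule encodes the judgement that negative residuals mean
  "negligible", not "impossible".
* Gaseous N~2~/N~2~O is not modelled — the budget infers it by difference.
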