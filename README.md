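# caflnmap

Stratifying cancer-associated fibroblast (CAF) heterogeneity in breast
tumors and metastatic axillary lymph nodes.

Breast-cancer stroma contains four CAF subsets - CAF-S1 to CAF-S4 - defined
by combinatorial levels of five markers (FAP, CD29, alpha-SMA, PDPN or its
IHC surrogate FSP1, and PDGFR-beta). Their balance differs between primary
tumors and invaded lymph nodes and carries prognostic information. This
package is for computational biologists and biostatisticians who need the
bespoke computations of that stratification as tested, reusable code:

* **Decision-tree classification.** Per-marker thresholds are the first
  quartile, median and third quartile of a learning distribution; each
  marker value becomes an ordinal level (Neg < Q1 <= Low < Mdn <= Med < Q3
  <= High), and a record is assigned to the subset whose admissible-level
  profile matches the most markers (ties broken by ordinal distance, then a
  fixed priority). Works on FACS intensities, IHC H-scores
  (H = sum over intensity bins b of b x 100 x fraction(b), range 0-400) and
  tile DAB densities, with quantile transposition across modalities.
* **In-situ CAF maps.** Landmark (affine / thin-plate-spline) registration
  of serial sections, H-DAB colour deconvolution (OD = -log10 I/I0),
  densitometry on 225 um^2 tiles, tile classification, and rendering with
  the fixed palette (S1 red, S2 orange, S3 green, S4 blue, epithelium
  black).
* **Functional-assay quantification.** Fourier-transform traction
  cytometry on an elastic half-space (Boussinesq Green tensor, Tikhonov
  inverse), strain energy SE = 1/2 integral of T.u, collagen-gel
  contraction, spheroid invasion index, track velocity / persistence d/l /
  direction |sin alpha|, SHG collagen density, inverted-Transwell invasion
  statistics with the 1% maximal-distance rule, doubling times and cytokine
  ratios.
* **Survival stratification.** Median splits, Kaplan-Meier, log-rank and
  Breslow-ties Cox regression implemented from first principles (the
  `survival` package serves only as a cross-check in the tests).
* **Synthetic ground truth.** Every input has a generator
  (`simulate_*()`): marker mixtures matching the subset profiles, stained
  serial sections with known tile labels and misalignment, displacement
  fields from known tractions, persistent random walks, invasion
  z-distributions and proportional-hazards cohorts. All generators are
  deterministic given a seed.

## Worked example

Learn thresholds on a balanced reference population, classify a simulated
FACS cohort, and inspect one cell:

```r
library(caflnmap)

ref <- simulate_reference_cells(4000, seed = 2)
th  <- learn_thresholds(ref, markers = caf_panel("FACS"))
data.frame(th)
#>   marker    q1 median    q3
#> 1    FAP 7.937  32.62 131.6
#> 2   CD29 7.995  31.51 124.7
#> 3    SMA 8.186  33.05 130.9
#> 4   PDPN 8.028  31.48 129.4
#> 5 PDGFRB 8.105  31.27 130.2

cells <- simulate_facs_cohort(4000, seed = 3)
calls <- classify_cells(cells, th, caf_profiles("FACS"))
mean(calls$label == cells$true_subset)
#> [1] 0.97975

classify_record(c(FAP = 100, CD29 = 180, SMA = 260, PDPN = 9, PDGFRB = 70),
                th, caf_profiles("FACS"))
#> $label: "CAF-S4"   $match_score: 5   $ambiguous: FALSE
#> $levels: FAP 2 (Med), CD29 3, SMA 3, PDPN 1, PDGFRB 2
```

The quartiles sit near 2^3, 2^5 and 2^7 - the gaps between the generator's
log2 level means 2/4/6/8 - so the learned bands recover the intended
ordinal levels; 98% of cells are assigned their true subset, with the
residual confusion between the profile-adjacent normal-like subsets
CAF-S2/S3. The example cell is FAP-Med, CD29/SMA-High, PDPN-Low,
PDGFRB-Med: the CAF-S4 profile on all five markers.

The full narrative analysis (cohort simulation, classification and PT/LN
enrichment contingency, section mapping, assay metrics, survival
stratification) lives in `analysis/01_simulate_cohorts.R` through
`analysis/05_survival_stratification.R`; each script prints what it found
and writes its tables under `results/analysis/`. `run_demo_cohort()` runs
the same chain end to end into one output directory, byte-reproducibly.

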