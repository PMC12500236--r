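# matriquant

Quantitative analysis of metabolically labeled extracellular matrix (ECM)
proteomes.

## The problem

Tumor tissues engineered on decellularized ECM (dECM) scaffolds mix two
protein pools: the pre-existing scaffold matrix and the matrix newly
synthesized by the seeded cells. Metabolic labeling with an azido sugar
(Ac4GalNAz) tags newly synthesized glycoproteins so they can be
affinity-enriched (desthiobiotin/streptavidin pull-down with competitive
elution), yielding per sample an *input* (bulk ECM extract) and an *eluate*
(enriched newly synthesized ECM) fraction, with *vehicle*-treated tissues
as the non-specific-binding control. `matriquant` is the downstream
statistics for such experiments — for proteomics analysts who have
protein-group LFQ tables (and, optionally, immunofluorescence images) and
need the enrichment QC, differential calls, and ECM accounting.

## What it computes

* **Enrichment QC** (`run_enrichment_qc`): labeled/vehicle fold ratios of
  identified protein groups and total intensities per model, with Grubbs
  outlier screening (α = 0.05) and one-way ANOVA + Tukey HSD across arms;
  species-resolved eluate/input recovery,
  `recovery% = 100 · Σ eluate / Σ input` per species; contaminant
  (actin/tubulin/histone) share of input intensity.
* **Differential statistics** (`run_differential`): total-intensity
  normalization `X_norm = X · Sum_average / Sum_i` per group; prefilter
  (≥ 2 nonzero values in both groups, the remainder kept as a qualitative
  table); log2 transform; optional QRILC imputation of left-censored
  missing values (truncated-normal draws with quantile-regression
  parameter estimates); two-tailed Welch t-tests with permutation-based
  FDR (exhaustive label permutations when ≤ 10,000); geometric-mean fold
  changes (`log2 FC = mean log2 A − mean log2 B`); volcano classes with
  strict thresholds (`log2FC > 1`, `q < 0.05`; boundaries are NS) and the
  p cut-off line at q = 0.05.
* **Matrisome accounting** (`category_summary`, `species_recovery`,
  `contaminant_share`): per-category protein counts and intensity
  proportions, eluate vs input, from a user-supplied matrisome annotation.
* **DAPI-map image quantification** (`run_image_quant`): nuclear-channel
  contrast stretch → threshold → size filtration → disk closing builds a
  binary tissue map; signal channels are averaged inside/outside it and
  normalized by tissue area or a reference channel.
* **Synthetic data** (`simulate_proteome`, `simulate_if_image`): a seeded
  generator whose defaults encode the targeted study conditions
  (5/3 and 5/5 replicate arms, 5.3/9.0-fold detection and 23.4/11.0-fold
  intensity enrichment, 87.5%/30% human/rat recovery, 0.36%/0.81%
  contaminant shares, collagen-depleted / secreted-factor-enriched eluate
  profiles, within/between-model R² of 0.94/0.49), with exact ground truth
  for every stage.

See `vignettes/matriquant-methods.Rmd` for the full model description and
design rationale.

## Worked example

```r
library(matriquant)

cfg <- proteome_sim_config(seed = 1)   # the study-preset defaults
sim <- simulate_proteome(cfg)
sim$table
#> <protein_quant> 2000 proteins x 36 samples
#>   nonzero cells: 66.9%
#>   arms:
#>     dECM-tumor / labeled / eluate: n=5
#>     ...

qc <- run_enrichment_qc(sim$table)
qc$folds
#>   model      detection_fold intensity_fold
#> 1 dECM-tumor           5.28           23.2
#> 2 tumoroid             8.97           10.9
```

The labeled eluates carry ~5.3× more identified protein groups and ~23×
more total intensity than vehicle eluates in the dECM model — the
enrichment the chemistry is supposed to deliver, recovered from the
synthetic data by the same code path a real table would take.

```r
qc$species_recovery[qc$species_recovery$model == "dECM-tumor", ]
#>   species recovery_percent eluate_share_percent
#> 1 human               87.6                98.8
#> 2 rat                 28.7                 1.18
```

Human (cell-derived) protein intensity survives enrichment at ~88% of its
input level while rat (scaffold) protein drops to ~29%, leaving ~1.2% of
eluate intensity of scaffold origin: the pull-down is selective for the
metabolically labeled species.

```r
hum <- filter_proteins(sim$table, species == "human")
el  <- filter_samples(hum, fraction == "eluate", treatment == "labeled")
dr <- run_differential(el,
  group_a = el$samples$sample[el$samples$model == "dECM-tumor"],
  group_b = el$samples$sample[el$samples$model == "tumoroid"],
  normalize_within = "together", impute = TRUE, seed = 1)
dr$class_counts
#> high_in_A high_in_B        NS
#>       443       372       778
dr$p_cutoff
#> [1] 0.0393
```

The cross-model comparison (QRILC-imputed, Welch + permutation FDR) calls
proteins with higher synthesis in the scaffold-based model (`high_in_A`)
and in the scaffold-free tumoroid (`high_in_B`); the volcano's p cut-off
line sits at the largest p with q < 0.05.

```r
img <- simulate_if_image(image_sim_config(seed = 1))
iq  <- run_image_quant(list(field1 = img$image))
dice_coefficient(iq$masks$field1$mask, img$mask)
#> [1] 0.978
iq$report[, c("tissue_area", "red_in", "red_out")]
#>   tissue_area red_in red_out
#> 1       20775  0.796   0.112
```

The DAPI map recovers the true tissue region (Dice 0.98) and the measured
in/out means match the configured signal contrast (0.8 vs 0.1).

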