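---
title: "Methods: quantifying newly synthesized ECM proteomes with matriquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying newly synthesized ECM proteomes with matriquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matriquant)
```

## The problem

Engineered tumor tissues built on decellularized extracellular matrix (dECM)
scaffolds contain two confounded protein pools: the pre-existing scaffold
matrix (here, rat-derived) and the matrix newly synthesized by the seeded
human tumor cells. Metabolic labeling with an azido monosaccharide
(Ac4GalNAz) tags newly synthesized glycoproteins, which are then
affinity-enriched (desthiobiotinylation, streptavidin pull-down, competitive
elution). The proteomic readout is a pair of fractions per sample: the
*input* (bulk ECM extract) and the *eluate* (enriched newly synthesized
ECM), each measured as a label-free quantification (LFQ) table of protein
group intensities, with a parallel *vehicle* (unlabeled) arm controlling for
non-specific binding.

`matriquant` implements the downstream analysis of such experiments:

1. **Enrichment QC** — does labeling enrich? Fold ratios of identified
   protein groups and total intensities, labeled vs vehicle eluates, with
   Grubbs outlier screening and ANOVA/Tukey across arms; species-resolved
   eluate/input recovery; contaminant (actin/tubulin/histone) share of the
   inputs.
2. **Differential statistics** — normalization, detection prefilter, log2
   transform, optional QRILC imputation, Welch t-tests with
   permutation-based FDR, geometric-mean fold changes, volcano
   classification.
3. **Matrisome accounting** — category-wise protein counts and intensity
   proportions, eluate vs input.
4. **Image quantification** — the DAPI-map procedure for immunofluorescence
   intensity statistics inside/outside the tissue area.
5. **Synthetic data** — a generator that emulates the statistical structure
   of the experiment with known ground truth, so every stage above is
   testable without the original raw data.

## Normalization

Total-intensity normalization scales protein `X` in sample `i` of group `K`
by

    X_normalized = X_original * Sum_average / Sum_i

where `Sum_i` is the sample's summed intensity and `Sum_average` the
*arithmetic* mean of the totals over the group's samples (an explicit
choice; a geometric mean would be a plausible alternative but is not what
"average sum" describes). Three groupings cover the analyses: per treatment
arm (labeled-vs-vehicle comparisons), across a selected sample set
(cross-model comparison of labeled eluates), and across all samples
(input-wide normalization). Totals are computed over all proteins present
in the table being normalized: a species-restricted analysis (e.g.
human-only eluates) filters the table *before* normalizing.

Two exact properties follow from the formula and are asserted in the tests:
after normalization every sample total in a group equals the group-average
pre-normalization total, and normalizing twice is the identity. A third
property is worth stating precisely because a stronger version is tempting
but false: multiplying one sample by `c > 0` before normalizing changes the
group-average target itself, so the normalized tables agree only up to that
per-group factor (sample *proportions* are exactly invariant).

## Detection prefilter and Grubbs screening

Proteins with fewer than `k = 2` nonzero values in either comparison group
cannot receive a p value; they are split off as a *qualitative* table
(group means only) rather than dropped, since all-or-nothing detection
(typical for enriched-only proteins) is itself informative. The testable /
qualitative split partitions the input exactly.

Per-sample protein-group counts and intensity totals are screened for
outlier samples with a two-sided single-Grubbs test at `alpha = 0.05`:
`G = max |x - mean| / sd` against
`(n-1)/sqrt(n) * sqrt(t^2 / (n-2+t^2))`, `t = qt(1 - alpha/(2n), n-2)`.
One value per pass, ties toward the lower index; iteration is off by
default (an `iterate` switch exists) since nothing indicates repeated
passes were used in the source workflow.

## Missing values: log2 and QRILC

Zero intensities encode non-detection until the log2 stage, where they
become explicit missing values. LFQ dropout is missing-not-at-random:
low-abundance proteins fall below detection, i.e. the observed sample is
left-censored. QRILC (quantile regression imputation of left-censored
data) exploits this: per sample, with missing fraction `pi`, the observed
quantile at probability `p` sits at probability `pi + (1-pi)p` of the
complete distribution, so regressing observed lower-tail quantiles
(default fit range `p` in (0.001, 0.5), 100 knots) on
`qnorm(pi + (1-pi)p)` estimates the complete distribution's mean and sd.
Missing cells are drawn from that normal truncated *above* at the
estimated censoring point `mu + sigma * qnorm(pi + tune)` (`tune = 0.001`
nudges the truncation probability; draws use the inverse CDF and are
seeded). On hard-censored Gaussian simulations the estimates recover
(mu, sigma) within 5% at 5000 proteins, and imputed values never exceed
the censoring point — both are asserted in the tests.

Imputation is a per-comparison switch. The cross-model comparison of
labeled eluates uses it (both models detect most proteins, missingness is
abundance-driven); the labeled-vs-vehicle comparisons default to
observed-value statistics, because there the missingness is dominated by
the structural absence of proteins from vehicle eluates, which the
qualitative split already handles.

## Welch tests, permutation FDR, fold changes

Per-protein two-tailed Welch t-tests (Satterthwaite df) compare the two
groups; no moderation or fudge factor is applied (`s0 = 0`): the Methods
this reimplements describe a plain Welch test. Multiple testing is
controlled by a permutation-based FDR: group labels are permuted (all
`choose(n, nA)` distinct assignments when at most 10,000 — true for the
study sizes, e.g. 126 at 4 vs 5 — otherwise 10,000 seeded draws), the
pooled null statistics define, at each observed threshold `c`,

    FDR(c) = (mean permutation count at least as extreme as c) /
             (observed count at least as extreme as c)

and each protein's q is the minimum `FDR(c)` over thresholds at or below
its own significance — the smallest FDR at which it is still called.
Extremeness is measured on the Welch *p* scale rather than |t|: with
per-protein Satterthwaite df, equal |t| values are not equally surprising,
and the p scale makes q monotone non-decreasing in p by construction
(asserted after every run). For a single protein with exhaustive
permutations, q reduces to the exact permutation p value (tested against a
brute-force enumeration). The estimator is validated for FDR control on
null simulations rather than for bit-compatibility with any particular
software's variant, whose internal scheme is not recorded.

Fold changes are ratios of geometric means of decimal intensities;
`log2(FC)` equals the difference of mean log2 intensities, so the
computation commutes with back-transforming imputed log2 values (the
package computes in log space; the identity is tested to 1e-12). Volcano
classes use strict inequalities — `log2FC > 1` and `q < 0.05` (or the
mirrored pair) — so boundary values are non-significant, exactly as the
convention prints them. The volcano's p cut-off line sits at the largest
p among proteins with `q < 0.05`. Between-sample reproducibility is
summarized by pairwise Pearson correlation of log2 profiles over
pairwise-complete proteins (pairs sharing fewer than 3 proteins are
flagged, not computed).

## Matrisome and species accounting

Each protein carries a matrisome division and category from a user-supplied
annotation (accession lookup with gene-symbol fallback; unmatched proteins
are non-matrisome — a packaged ~70-entry mini-annotation of well-known ECM
genes serves the tests). Category summaries report protein counts
("identified" = nonzero in at least one sample of the fraction, a
configurable threshold) and intensity proportions of the all-protein total,
averaged per sample; the eluate/input proportion ratio per category
quantifies the enrichment-induced profile shift. Proportions are invariant
to global rescaling (tested).

Species recovery divides pooled eluate intensity by pooled input intensity
per species (×100); a per-sample-mean variant sits behind a flag since the
pooling convention is not recorded in the source workflow. Eluate shares
per species sum to 100%. Contaminant share matches gene symbols against
curated actin/tubulin/histone patterns (`^ACT`, `^TUB`, classic `HIST*`
plus the `H1/H2A/H2B/H3/H4` cluster nomenclature), overridable.

## DAPI-map image quantification

The nuclear (blue) channel is contrast-stretched between its 1st and 99th
percentiles ("saturation balancing"; the source names no method, so the
percentile pair is a parameter), binarized at a fixed threshold (default
0.15 on the stretched 0–1 scale), size-filtered (8-connected components
below 50 px removed), and closed with a disk structuring element (dilation
then erosion, default radius 25 px at the fixture scale of 256×256 px
images). None of these values are published; all are parameters, reported
in the output provenance, and the defaults are validated only against the
package's own synthetic images (Dice ≥ 0.9 against the generating mask
across 20 seeds). Signal channels are averaged inside and outside the mask
(empty regions are NA-flagged); the pixel-count-weighted combination of the
two means equals the global channel mean to 1e-9 (tested). Normalization
modes: by tissue area (equivalently the in-tissue mean) or by a reference
channel's in-tissue mean. Before morphology, the binary mask is monotone
in the threshold (tested); after closing it need not be.

## The synthetic generator

The generator emulates the experiment's statistical structure with exact
ground truth. Its defaults *are* the study conditions this package
targets: 5 labeled / 3 vehicle dECM-tumor eluates and 5/5 tumoroid
eluates (inputs mirror these), 5.3- and 9.0-fold detection enrichment,
23.4- and 11.0-fold intensity enrichment, 87.5% / 30% human/rat recovery,
0.36% / 0.81% contaminant shares, a category profile whose eluate/input
ratios are 0.26 (collagens), 2.0 (regulators and affiliated), 2.9
(proteoglycans) and 9.2 (secreted factors), and replicate correlations of
R² 0.94 within / 0.49 between models.

Mechanisms, per model:

* **Abundance.** Protein log2 abundance = shared effect + model effect +
  replicate noise, with total sd `abundance_sdlog = 2.5` log2 units (about
  four orders of magnitude across the proteome, typical of LFQ) around
  `abundance_meanlog = 23` (intensities near 8×10⁶).
* **Exact truth calibration.** Input category intensity shares, the
  contaminant share, and the rat intensity share (`species_mix` = human
  fraction of input intensity) are rescaled to their configured values
  exactly at the truth level; eluate means are the input means reweighted
  per category to the eluate profile and rescaled per species so pooled
  recovery is exact. The vehicle eluate is a uniform random subset of the
  labeled proteome of size (detectable count)/(detection fold), scaled so
  the total-intensity fold is exact. Configured factors are therefore
  exact in `SyntheticTruth` (an invariant the tests assert), and the
  emitted estimates deviate only through replicate noise and censoring —
  which keeps a 2000-protein run well inside a ±10% recovery band despite
  heavy-tailed intensity sums.
* **Species composition.** The dECM preset's `species_mix = 0.966` is the
  input composition jointly consistent with 87.5%/30% recoveries and a
  1.2% residual rat share of eluate intensity under pooled-sum accounting;
  the tumoroid model is human-only.
* **Dropout.** Soft left-censoring: per sample, dropout probability
  `plogis((threshold - log2 x) / 0.3)` around the sample's own 15th
  intensity percentile — monotone non-increasing in abundance (asserted on
  truth), matching QRILC's left-censoring assumption without a hard edge.
* **Correlation targets.** Within/between-model R² refer to the *emitted*
  data: censoring truncates the lower tail and attenuates Pearson r, so
  the generator derives the latent variance split by numerically inverting
  the attenuation of a bivariate normal observed through logistic
  censoring weights (deterministic grid integration; no simulation
  fitting). The deterministic category/recovery offsets shared between
  models contribute to the shared variance and are subtracted from the
  latent shared component, computed from the configured profile.
* **Contaminants** are named proteins whose gene symbols come from a real
  actin/tubulin/histone pool, so the pattern-based contaminant filter is
  exercised end-to-end.

Synthetic images place soft-edged nuclei (radius 4–7 px) inside a tissue
region built from disc blobs, with configured in/out channel means plus
Gaussian noise (sd 0.02); the ground-truth mask is returned with the image.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: peptide-level effects (shared peptides, protein
inference), intensity-dependent technical variance, batch structure,
inter-protein abundance correlation beyond the shared/model effects,
chromatographic or labeling-efficiency artifacts, and real nuclear
morphology or staining gradients. The replicate noise scale is a free
parameter (derived from the correlation targets by default) because
replicate-level intensity variance is not reported in the source; and the
two printed correlation summaries constrain only a three-component
variance split, not the full covariance.

## Problem sizes and runtime

The validation suite and the acceptance script run the study preset at
2000 proteins — large enough that pooled intensity shares and correlation
summaries stabilize (the tests' tolerance analyses are calibrated there) —
with exhaustive permutations whenever their count is below 10,000. A full
generator + QC + differential + image cycle takes a few seconds on one
core.

## Known limitations

* q values are estimator-specific: FDR-control properties are tested, not
  numeric equality with any external software's permutation variant.
* The DAPI-map defaults (threshold, size cutoff, disk radius) are declared,
  not claimed to match the original unpublished settings.
* Species assignment of ambiguous protein groups follows the first-listed
  accession; alternative conventions would shift species sums slightly.
* `correlation_matrix` is O(samples²·proteins) with pairwise-complete
  handling; it targets replicate-scale sample counts, not hundreds of
  samples.
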