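---
title: "Methods: spatial lipidomics analysis for MALDI-IMS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial lipidomics analysis for MALDI-IMS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lipidims` implements a complete analysis chain for positive-mode MALDI
imaging mass spectrometry (MALDI-IMS) of skeletal tissue sections — from
pixel-resolved peak lists to annotated differential-lipid panels — together
with a seeded synthetic phantom that makes every stage testable without
instrument data. This vignette records the model behind each stage, the
parameters that matter, and the design choices made where the design was
genuinely open.

## The data model

A `PixelSpectrumSet` holds one acquired sample: a peak list
(m/z, optional drift time, intensity) per 50 × 50 µm ablation pixel on a
rectangular grid. Intensities are non-negative ion counts; peak lists are
kept sorted by m/z. Drift time is carried as passthrough metadata and is
never interpreted physically — it only partitions m/z bins when present,
because ion mobility is routinely disabled in sensitivity-critical
acquisitions.

Downstream objects are: a `TargetList` (the shared ion axis), a
`BinnedImage` (pixels × targets), a `FeatureMatrix` (ROIs × targets with a
linear/log2 scale flag and an exclusion log), OPLS/PCA model objects,
per-zone test results, and annotation hit tables.

## Spectral processing

**Peak reduction.** Per pixel, peaks with intensity at or below 100 counts
are removed (strict threshold) and at most the 3,000 most intense peaks are
kept; ties at the boundary keep the lower-m/z peak so the operation is
deterministic. Reduction is idempotent.

**Target-list binning.** All peaks across all pixels (and samples) are
partitioned into half-open bins `[k·w, (k+1)·w)` with origin at zero and
width `w = 0.04` Da, crossed with 100-unit drift bins when drift is
present. Each non-empty bin becomes one target at the intensity-weighted
mean m/z of its members. The half-open, origin-zero convention is a declared
dialect: it is deterministic and matches the "bin window" phrasing of
vendor software without claiming to reproduce its undocumented internals.

**Target consolidation.** A single ion population whose per-pixel mass
error straddles a bin boundary would shear into two low-intensity,
high-variance shard targets. After binning, adjacent targets whose centres
lie closer than half a bin (0.02 Da by default) are therefore merged at
their weighted centre. Genuinely distinct lipid ions are far wider apart
than this at any realistic resolution, while shards hug the boundary within
a few mDa, so the pass is safe; it can be disabled with `merge_within = 0`.

**Re-binning.** Each pixel's peaks are assigned to the nearest target
within one bin width; co-assigned intensities are summed (so assigned
intensity is conserved per pixel), unassignable peaks are dropped and
counted in provenance, and an exactly equidistant peak goes to the
lower-m/z target.

**Lock-mass correction.** For between-sample comparisons a deuterated
internal standard — PC(15:0/18:1)-d7, spiked with the matrix spray — has a
known protonated m/z of 753.6134 computed from its elemental composition
C41H73D7NO8P. Per sample, the most intense signal within ±50 ppm of the
reference in the sample-mean spectrum defines a multiplicative correction
`reference/observed` applied to every m/z of that sample; the ppm shift is
logged. Correction is per sample, not per pixel, because drift is a
property of an acquisition run.

## ROI features and normalization

ROIs are labelled pixel sets: single-pixel sROIs, 10-pixel (5 for small
tissues) lROIs, and off-tissue matrix ROIs containing only the chemical
matrix (DHB) background. Feature extraction averages each target over the
ROI's pixels. The canonical, provenance-recorded order is then:

1. **TIC normalization** — each ROI row divided by its total ion count,
   removing acquisition-scale effects.
2. **Matrix-ion filter** — an ion is excluded iff
   `mean_matrix − 2·SD_matrix > mean_tissue + 2·SD_tissue`, with means and
   population SDs taken over matrix ROIs and over *all pooled* tissue ROIs
   respectively. The filter can never remove an ion whose tissue mean
   reaches its matrix mean. Both intervals are logged per excluded ion.
3. **Log2 scaling** — TIC proportions are rescaled by 1e4 and shifted by a
   pseudocount of 1 before `log2`, avoiding `log(0)` with a documented,
   configurable constant.

Whether the matrix filter runs before or after log scaling is not fixed by
any external constraint; running it on the linear TIC scale was chosen
because the two-sigma interval logic is formulated on intensities, and the
order is enforced and recorded so results are comparable across runs.
Population SD (denominator *n*) is used consistently in this module and in
the scaling steps below; the choice is arbitrary but declared and tested.

**A note on compositional effects.** TIC normalization makes intensities
relative: when a genotype strongly up-regulates a subset of abundant lipids
in a zone, every *unchanged* ion's proportion in that zone falls, and with
enough replication those down-shifts become significant. This is a real
property of TIC-normalized comparisons, the phantom reproduces it, and it
should be kept in mind when reading the down-regulated sets.

## Multivariate modelling

**Pareto scaling** centres each ion and divides by the square root of its
SD — the standard compromise for MS intensities, damping dominant ions
without inflating noise the way unit-variance scaling does. Zero-variance
ions are centred only and flagged.

**PCA** is the singular value decomposition of the Pareto-scaled matrix,
reported as scores, orthonormal loadings and explained-variance
percentages.

**OPLS-DA** is written from scratch in the orthogonal-signal-correction
PLS formulation with a NIPALS inner loop. The two-class label is coded
−1/+1 and centred. For each of `n_orth` orthogonal components the PLS
weight `w ∝ Xᵀy` is computed, the loading component orthogonal to `w` is
extracted, normalised, and its variation deflated from X; a single
predictive PLS component is then fitted to the deflated matrix. With
`n_orth = 0` the predictive component is exactly one-component PLS. The
predictive score is oriented so the class coded +1 has positive mean, which
makes direction labels deterministic. R²Y is reported always; Q² by
leave-one-out refitting, but only for fits of up to 60 observations, above
which it is reported as `NA` rather than dominating runtime.

**S-plot.** For each ion, the covariance `cov(t_pred, x_j)` (denominator
n − 1) and the Pearson correlation are computed against the scaled, centred
matrix that entered the fit. Covariance and correlation share sign by
construction; correlation is bounded by 1.

**Panel selection** thresholds the absolute value of a chosen statistic:
the S-plot covariance (threshold 0.04 by default, the convention for
tissue-contrast panels), the correlation, or the normalised predictive
weight (for `|p1|`-style thresholds — commercial software is ambiguous
about which statistic "p1" denotes, so it is an option rather than a
guess). Covariance is scale-dependent: 0.04 is meaningful on the scale of
the data it was defined for, and should be revisited for data on other
scales (the correlation statistic is the scale-free alternative).
Manual "visual inspection" removals are supported only as an explicit,
logged exclusion list — never automated — so an irreproducible step becomes
auditable. Panels merge by bin-id union with per-ion source provenance,
pairwise overlap counts, and conflict flags.

**Hierarchical clustering** of panel-restricted, column-z-scored data uses
correlation distance with average linkage by default (conventional for
z-scored omics heat maps; both are configurable), clustering ROIs and ions
separately; row clusters cut at the number of tissue classes are exported
for agreement scoring against known labels (adjusted Rand index).

## Zone-wise differential testing

Per growth-plate zone (resting, proliferating, hypertrophic), each ion is
tested with an unpaired two-sided Welch t-test between genotypes on log2
data; "multiple t test" does not specify the variance treatment, and
Welch is the safer default (a pooled-variance option exists). P-values are
Benjamini–Hochberg adjusted *within each zone* — each zone's volcano plot
carries its own q — and the BH step is verified in the test suite against a
brute-force step-up oracle. Fold change is derived from the mean log2
difference, `FC = 2^|Δ|` (a ratio of geometric means) with direction from
the sign of Δ, and an optional 1.5-fold gate applies on top of the q cut.
Ions with zero variance in both groups get p = 1 and a flag.

ROIs are the replication unit, matching how imaging software exports them;
they are pseudo-replicates within animals, so an
`aggregate_replicates = TRUE` option collapses ROIs to per-animal means
before testing. Cross-zone set logic reports all pairwise and triple
intersections of up/down sets plus a per-ion membership pattern table (the
Venn semantics of the per-zone analyses).

## Lipid annotation

Observed targets are matched against a reference library (emulating
LC-MS/MS-derived identifications) across protonated, sodiated,
potassiated, and dehydrated-protonated adducts plus the first ¹³C isotope
peak of each, within 100 ppm — a tolerance sized for multi-session MALDI
calibration drift, not instrument resolution. Charge-carrier deltas are the
standard tabulated cation-minus-electron masses (proton 1.007276, Na⁺
22.989218, K⁺ 38.963158) recorded to six decimals; dehydration is modelled
only in combination with protonation. One observed ion may keep several
tier-assigned hypotheses; nothing forces uniqueness.

Hits are scored into confidence tiers: (i) manually annotated; (ii)
supported by both spectral databases; (iii) a highly scored hit in one
database only; (iv) excluded, with explicit reasons — low database score,
an odd total of fatty-acyl carbons (biologically implausible in mammals),
or an implausible adduct stack. The "highly scored" criterion is carried
as a boolean evidence flag in the library rather than a numeric cutoff.
A shorthand-nomenclature parser handles full sn-position notation,
totals-only shorthand, lyso, ether/plasmanyl, plasmenyl, sphingoid-base and
deuterium-labelled names. An m/z-only consensus-binning step (0.2-m/z
half-open bins, ambiguity flags) reproduces how retention-time-free
libraries are condensed for imaging annotation.

## The synthetic phantom

The generator emulates the statistical structure the analysis assumes, not
the anatomy. The grid (64 × 64 pixels by default) is split into horizontal
bands: an off-tissue matrix band (a quarter of the rows, so the background
filter always has matrix-only pixels), marrow, cortical bone, articular
cartilage, and the growth plate as three adjacent zone bands. The default
lipid panel plants class-typical enrichments — LPC/PC in the growth plate,
ether-PC in marrow, SM in articular cartilage, PE in cortical bone —
2.5 log2 units above a baseline of 2¹⁰ counts, plus spatially flat species
and matrix-only ions that are maximal off tissue but weakly present
everywhere (as a sprayed matrix is). A configurable subset of growth-plate
lipids carries multiplicative KO-vs-WT effects drawn from 1.5–3× in every
zone.

Each lipid is emitted as its adduct ions (intensity split by the adduct
weights, default 0.60/0.20/0.15/0.05 for H/Na/K/dehydrated) plus a ¹³C
partner of the protonated ion at a fixed 0.3 fraction — enough to exercise
isotope-aware matching without a full isotope-pattern model. Intensity
noise is multiplicative log-normal (sdlog 0.35 by default) with a small
additive baseline; m/z jitter is Gaussian per pixel (5 ppm), and a
per-sample calibration shift exercises the lock mass. Within-tissue
biological variance is not quantified anywhere authoritative, so it is an
exposed parameter, not an asserted constant. Neutral masses are drawn from
class-typical ranges under a global constraint that no two library ions of
any adduct form fall within 150 ppm of each other, keeping every planted
ion unambiguous at the 100-ppm annotation tolerance; matrix-ion masses stay
below every tissue-lipid adduct ion so background and biology can never
share a bin.

What the phantom does *not* emulate: realistic isotope envelopes, chemical
noise continua, ion-mobility physics, spatial intensity gradients within a
tissue, or histology. Passing tests therefore demonstrate the correctness
and calibration of the *pipeline* under its stated assumptions — they do
not certify performance on real spectra, where peak shape, isobaric
interference and section artefacts add failure modes this model excludes.

A companion ROI-level generator (`generate_roi_phantom()`) draws log2
feature matrices directly — the same intensity model after ROI averaging —
and is used for statistical calibration at scale (error-rate and power
studies), where simulating pixels would add nothing but runtime.

## Problem sizes and numerical conventions

The validation suite runs phantoms of 28 × 24 to 48 × 48 pixels with
17–300 lipids, null FDR calibration over 100 seeds and recovery over 20
seeds of 200-ion, 10-ROI-per-group designs — sizes chosen so the full suite
completes in about a minute while keeping every estimate's Monte-Carlo
error well inside the margins being asserted. Other conventions: SD is the
population SD wherever a convention had to be fixed; covariance and
correlation use n − 1; q-values of zero are floored at 1e-300 before
`−log10`; all seeds are explicit and every pipeline output is
byte-reproducible under a fixed seed (file digests are compared in the
tests); the FDR variant is BH and is configurable.

## Known limitations

ROI-level inference treats pseudo-replicates as independent unless
aggregation is requested; no mixed-effects or permutation machinery is
included. The OPLS implementation fits a single predictive component (the
two-class case needs no more). MS2 spectral evidence is represented only as
library flags. Negative-ion mode, profile spectra and vendor raw files are
out of scope; imzML (continuous and processed, 64-bit) and a tabular text
dialect are the interchange formats.
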