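# lipidims

Spatial lipidomics analysis for MALDI imaging mass spectrometry
(MALDI-IMS), built for skeletal tissue studies such as mouse knee joints:
mapping which lipid classes occupy which tissue compartment (bone marrow,
cortical bone, articular cartilage, growth-plate zones) and how a genotype
shifts the lipid landscape of the growth plate.

The package takes pixel-resolved MS1 peak lists through the full analysis
chain a practitioner would otherwise assemble from vendor software and ad
hoc scripts:

* **Spectral processing** — per-pixel peak reduction (top 3,000 peaks with
  intensity > 100), shared target-list binning (half-open 0.04-Da m/z bins,
  optional drift-time crossing, boundary-shard consolidation), re-binning of
  all samples onto one ion axis, and per-sample lock-mass correction against
  a spiked deuterated internal standard, PC(15:0/18:1)-d7, whose protonated
  ion sits at m/z 753.6134.
* **ROI features** — region-of-interest extraction, TIC normalization, a
  two-sigma matrix-ion background filter
  (`mean_matrix − 2·SD > mean_tissue + 2·SD` excludes an ion), and log2
  scaling.
* **Multivariate modelling** — PCA and a from-scratch OPLS-DA (orthogonal
  signal correction + NIPALS PLS) on Pareto-scaled data; S-plot statistics
  `cov(t, x_j)` vs `corr(t, x_j)` per ion; threshold-based differential-ion
  panels with auditable post-hoc exclusions; panel merging; hierarchical
  clustering of z-scored panels.
* **Differential statistics** — per-zone Welch t-tests between genotypes,
  Benjamini–Hochberg q-values within each zone, fold change `2^|Δlog2|`
  with an optional 1.5-fold gate, volcano tables and cross-zone Venn
  summaries.
* **Annotation** — adduct- and isotope-aware matching (H/Na/K/−H₂O adducts
  and ¹³C partners) against an LC-MS/MS-style lipid library at 100 ppm, with
  tiered confidence scoring and a LIPID MAPS shorthand parser.
* **Synthetic phantoms** — a seeded generator that plants tissue-specific
  lipid enrichments, matrix background, adduct mixtures, an internal
  standard, noise and genotype effects, with a ground-truth table for
  validating every stage.

## Worked example

Simulate a joint-section phantom, process it, and pull the growth-plate vs
articular-cartilage lipid panel:

```r
library(lipidims)

spec    <- phantom_spec(grid_shape = c(48, 48),
                        lipid_panel = make_lipid_panel(seed = 7), seed = 7)
phantom <- generate_phantom(spec)
phantom$spectra
#> PixelSpectrumSet: 2304 pixels, 549504 peaks, sample 'phantom'

ps  <- reduce_peaks(phantom$spectra, top_n = 3000, min_intensity = 100)
tl  <- build_target_list(ps, mz_bin = 0.04)      # 301 targets
img <- rebin_to_targets(ps, tl)
rois <- auto_rois(ps$pixels, n_per_region = 4, size = 10, n_matrix = 4,
                  seed = 8)
fm  <- preprocess_features(img, rois)            # TIC -> matrix filter -> log2
fm
#> FeatureMatrix: 28 ROIs x 251 ions (log2 scale, 50 excluded)
```

The 50 excluded ions are exactly the binned adduct forms of the planted
matrix-only (DHB-like) species — the background filter removes them without
touching tissue lipids. A supervised contrast between the two cartilage
compartments:

```r
gp <- fm$rois$tissue %in% c("growth_plate", "articular_cartilage")
m  <- fit_oplsda(fm$values[gp, ], fm$rois$tissue[gp], n_orth = 1,
                 positive_class = "growth_plate")
sprintf("R2Y = %.3f, Q2 = %.3f", m$r2y, m$q2)
#> "R2Y = 1.000, Q2 = 0.999"

panel <- select_panel(m, stat = "corr", threshold = 0.8,
                      contrast = "gp_vs_ac")     # 100 ions
lib   <- generate_library(spec, decoys = 25)
hits  <- score_tiers(match_ions(tl[tl$bin_id %in% panel$bin_id, ], lib,
                                tolerance = 100))
head(hits[, c("bin_id", "lipid", "adduct", "ppm_error", "tier")], 3)
#>    bin_id        lipid adduct     ppm_error tier
#> 1 t_00220 SM(38:0)#029    M+H -0.0009909504    i
#> 2 t_00216 SM(44:1)#028    M+K  0.0015234437    i
#> 3 t_00236 SM(38:0)#029   M+Na  0.0080756779    i
```

The model separates the compartments essentially perfectly (R²Y/Q² ≈ 1 —
this is a phantom with planted enrichments), and the panel's top hits
annotate to the sphingomyelin and lysophosphatidylcholine species the
generator enriched in articular cartilage and the growth plate, at
sub-ppm mass error, tier i (manual-ID grade evidence in the simulated
library).

Both study designs also run end to end:

```r
res <- run_atlas(run_config("atlas", out_dir = "out_atlas", seed = 1))
res <- run_genotype_contrast(run_config("genotype_contrast",
                                        out_dir = "out_ko", seed = 1))
```

writing feature matrices, S-plot tables, panels, per-zone volcano tables,
Venn membership tables, annotation tables and a JSON-lines provenance log
as CSV/JSONL. A thin CLI wrapper lives at `inst/scripts/ims`
(`ims simulate`, `ims atlas`, `ims contrast`).

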