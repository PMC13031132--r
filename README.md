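# zonemap

Spatial single-cell proteomics along porto–central tissue trajectories.

Hepatocyte function varies systematically along the axis from the portal to
the central vein of the liver lobule ("liver zonation"). Deep Visual
Proteomics workflows image a tissue section, segment single cells, excise
them by laser microdissection and measure each cell's proteome by
ultrasensitive DIA mass spectrometry. `zonemap` implements the computational
spine of such a study:

- **Strategic cell selection.** Central and portal veins are detected as
  signal voids in the cell-boundary channel (Gaussian blur, morphological
  dilation, histogram-minimum threshold) and typed by pericentral/periportal
  marker expression (GS / ASS1). Cells between a vein pair (within a 65°
  cone around the axis) are sampled by **farthest-first traversal**, the
  greedy 2-approximation to max-min dispersion, so up to 44 cells cover the
  trajectory uniformly. Each cell gets a spatial ratio
  `S = d_central / (d_central + d_portal)` ∈ [0, 1] (0 = central vein).
  Cutting contours are simplified (≥90% vertex reduction, area-conserving)
  and exported as LMD-style XML with three calibration points.
- **Continuous gradient inference.** Per protein, after Tukey-fence outlier
  removal and robust scaling (median/IQR), a random-intercept linear mixed
  model is fitted:

  y_ij = β₀ + β₁·S_ij + u_i + ε_ij,  u_i ~ N(0, σ_u²), ε_ij ~ N(0, σ²)

  with cell *j* of patient *i*. The fixed slope β₁ — the **zonation
  coefficient** — is tested against zero by a Wald test (z = β₁ / SE(β₁)),
  with Benjamini–Hochberg Q values over all proteins. β₁ < 0 means
  enrichment towards the central vein; |β₁| > 1 with Q < 0.05 is "strongly
  zonated". Between conditions (e.g. healthy vs desmoplastic tissue),
  Δβ₁ is Wald-tested with SE(Δβ₁) = √(SE_A² + SE_B²); |Δβ₁| > 1 and
  Q < 0.05 calls a **zonation loss**.
- **Quality control.** Sample exclusion at 1.5 s.d. below / 3 s.d. above
  the median protein-identification count, ≥70% protein completeness,
  within-patient Z-scoring, rank-based cell-type contamination scores
  (marker panels: intensity > 1×10⁸ and ≥5-fold over every other cell
  type, top 20), and a PCA check that PC1 tracks S (Spearman).
- **Discrete comparator.** 20 equal-width spatial bins, bin Z-scores,
  heatmap ordering by trajectory expression difference, per-protein one-way
  ANOVA with BH correction, pathway median-Z profiles, and a per-protein
  comparison of the continuous and binned significance scales.
- **DIA window design.** 60 variable-width isolation windows over
  380–980 m/z with edges at empirical quantiles of a precursor m/z list,
  so per-window precursor counts differ by at most one.
- **Synthetic fixtures.** Generators for zonated two-vein tissue scenes
  (four channels + polygonal cells) and proteome matrices drawn from the
  same mixed model with logistic intensity-dependent (MNAR) dropout and
  known ground truth, so the whole pipeline is testable without external
  data.

## Worked example

```r
library(zonemap)

# a synthetic two-vein scene, then the full selection workflow
tis <- generate_tissue(tissue_spec(seed = 1))
sel <- run_select(zonemap_config(out_dir = "out"), tissue = tis)
#> detected 2 vein(s): central, portal
#> trajectory: axis 400.0 px, 314 cells in ROI
#> selected 44 cells (k = 44)
head(sel$table[, c("cell_id", "d_central", "d_portal", "S")], 4)
#>     cell_id d_central d_portal         S
#> 1 cell_0007  128.3307 359.9737 0.2628088
#> 2 cell_0438  363.9732 124.5873 0.7449910
#> 3 cell_0423  151.0500 317.9544 0.3220651
#> 4 cell_0023  332.4648 144.4692 0.6970876

# a synthetic cohort (14 patients x 44 cells), then gradient mapping
sim <- generate_proteome(proteome_spec(n_proteins = 300, seed = 1))
res <- run_zonation(zonemap_config(out_dir = "out"), im = sim$matrix)
#> sample QC: 576 of 616 samples kept (median 254 ids, sd 6.3)
#> completeness >= 70%: 300 of 300 proteins kept
#> gradients: 300 fits, 96 significant, 71 strong
head(res$fits[order(res$fits$Q),
              c("protein_id", "beta1", "se_beta1", "Q", "direction", "strong")], 4)
#>    protein_id beta1 se_beta1 Q direction strong
#> 46  PROT_0046  1.76   0.0460 0    portal   TRUE
#> 53  PROT_0053 -1.62   0.0405 0   central   TRUE
#> 68  PROT_0068  1.74   0.0444 0    portal   TRUE
#> 74  PROT_0074  1.85   0.0467 0    portal   TRUE
```

The selection messages report the vein pair, the cone ROI size and the
selected cell count; `sel$table` lists each chosen cell with its anchor
distances (pixels) and spatial ratio. In the zonation run, 40 of the 616
simulated shapes fall outside the identification-count fences; the fitted
zonation coefficients recover the designed gradients (e.g. PROT_0046 rises
towards the portal vein at 1.76 normalized units per unit S, Q ≈ 0), and
the 30% of proteins simulated with a gradient are the ones called
significant. `res$comparison$rho` gives the Spearman agreement between the
continuous and 20-bin ANOVA significance scales on the same data.

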