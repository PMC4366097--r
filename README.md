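# noecest

Analysis of NOE-mediated CEST MRI in glioblastoma, with a seeded digital
phantom for end-to-end validation.

Nuclear Overhauser enhancement (NOE) imaging is a chemical exchange
saturation transfer (CEST) contrast originating from mobile macromolecular
protons upfield of water (−2 to −5 ppm). Saturating at an offset Δω and
normalizing the water signal by the unsaturated image gives the Z-spectrum
Z(Δω) = M/M₀; the contrast is the asymmetry at the NOE-dominated readout,

    MTR_asym(3.3 ppm) = Z(−3.3 ppm) − Z(+3.3 ppm),

in percent, so strong NOE effects are negative and *weak* NOE shows as
*high* values. The scientific question the toolchain serves: does this
contrast track tumor cellularity — as judged against the apparent
diffusion coefficient (ADC) voxelwise inside the contrast-enhancing (CE-T1)
tumor and the T2 peritumoral edema, and against cell densities of
stereotactic biopsy specimens read out over 3×3×3-voxel neighborhoods.

The package is aimed at imaging scientists who need a tested,
reproducible implementation of this pipeline:

- **Z-spectrum chain** — M₀ normalization with masking, B0 deviation
  mapping by natural-cubic-spline minimum search on a 0.001-ppm grid, B0
  correction by spline re-evaluation (never extrapolated), MTR_asym
  readout at ±10/3 ppm (the grid nodes nearest 3.3 ppm on the 13-offset
  protocol), display windowing to [−10%, +5%].
- **Region statistics** — SWI/necrosis exclusions, voxelwise pairing with
  ADC, Spearman correlation (mid-ranks, t-approximation), Bonett–Wright
  95% confidence intervals, and association classification
  (none ≤ 0.15 < weak < 0.40 ≤ moderate < 0.65 ≤ strong, insignificant if
  p > α), plus cohort tallies.
- **Biopsy module** — world↔voxel mapping, 3×3×3 neighborhood means,
  Spearman + least-squares regression of cell density on each contrast.
- **Digital phantom** — concentric-ellipsoid glioblastoma (necrotic core ⊂
  CE rim ⊂ edema in NAWM with a CSF shell), multi-pool Lorentzian
  Z-spectra per tissue class, a smooth ±0.3 ppm B0 field, Rician noise,
  and cellularity/ADC fields coupled to the NOE amplitude through a
  Gaussian copula with configurable Spearman correlations — so every
  correlation the pipeline must detect can be dialed in and recovered.
- **Pipeline** — `run_pipeline()` ties simulate → process → correlate →
  biopsy into one seeded, fully reproducible run with per-stage voxel
  accounting, NIfTI/CSV/JSON outputs and a markdown report; a thin CLI
  lives in `inst/cli/noecest`.

## Worked example

```r
library(noecest)

# 1. Simulate a subject: digital phantom + 7T-style CEST acquisition
phantom <- build_phantom(phantom_config(seed = 42))
acq     <- simulate_acquisition(phantom, acquisition_params(), seed = 43)

# 2. Process the Z-spectra: normalize, map and correct B0, read out MTR_asym
z    <- normalize_zspectrum(acq)
b0   <- estimate_b0(z)
zcor <- correct_b0(z, b0)
mtr  <- compute_mtr_asym(zcor)
print(mtr)
#> MTR_asym map at 3.33 ppm: 23008 voxels, -12.42% .. 5.05% (window -10..5)

# 3. Voxelwise MTR_asym vs ADC inside the cleaned ROIs
lab   <- phantom$label_map
rois  <- apply_exclusions(roi_mask_set(lab == 3, lab == 2,
                                       phantom$swi_mask, lab == 4))
pairs <- extract_pairs(mtr, phantom$adc_map, rois)
print(correlate_rois(pairs), digits = 3)
#>           roi   r_sp        p n_voxels   ci_lo  ci_hi              class
#> 1 ce_t1_tumor 0.0189 5.33e-01     1093 -0.0405 0.0781 none-insignificant
#> 2    t2_edema 0.0735 4.79e-05     3056  0.0381 0.1087    none-negligible

# 4. Classification bookkeeping on the bundled reference cohort
summarize_cohort(reference_cohort_correlations())$tallies
#>           roi  n positive negative none
#> 1 ce_t1_tumor 15        2        2   11
#> 2    t2_edema 15        8        0    7
```

Reading the numbers: the CE-T1 tumor row is null (the phantom couples ADC
to the NOE contrast only in edema by default), while the edema row is
significantly positive but attenuated by acquisition noise from the
configured rank correlation of 0.25 to ≈ 0.07 — weak-but-significant, the
regime the cohort bookkeeping in step 4 tallies: 8 of 15 reference
patients positive in edema, 11 of 15 with no association in CE-T1 tumor.

A complete seeded run with outputs on disk:

```r
run_pipeline(run_config(seed = 1), out_dir = "results/run1")
render_report("results/run1")   # report.md + scatterplots
```

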