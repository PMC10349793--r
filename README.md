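# duodose

Healthy-liver dosimetry for holmium-166 (¹⁶⁶Ho) microsphere liver
radioembolization from a simultaneous ¹⁶⁶Ho/⁹⁹ᵐTc dual-isotope SPECT
acquisition.

Radioembolization dosimetry needs an accurate healthy-liver volume of
interest (VOI). The clinical standard — manual segmentation on a
contrast-enhanced CT followed by rigid registration onto the SPECT — is
slow and error-prone. Because [⁹⁹ᵐTc]-stannous-phytate accumulates in
Kupffer cells, present only in healthy liver parenchyma (and spleen),
the ⁹⁹ᵐTc image from a dual-isotope acquisition delineates healthy
tissue physiologically, intrinsically co-registered with the ¹⁶⁶Ho
image, and can be segmented automatically. `duodose` is aimed at
nuclear-medicine physicists and imaging researchers evaluating that
workflow.

The package implements, end to end:

- **Automatic segmentation** — after spleen removal, the ⁹⁹ᵐTc image is
  thresholded at 40% of the maximum of a Gaussian-smoothed copy
  (`automaticHealthyMask()`); the manual-reference construction
  (liver − tumors > 1 cm − necrosis) is `referenceHealthyMask()`.
- **Voxel dosimetry** — local deposition:
  *D* [Gy] = 15.87 [mJ/MBq] · *C* [MBq/ml] / ρ [g/ml], with counts
  scaled to concentration inside an automatic CT body mask so the
  integrated activity equals the administered activity
  (`countsToConcentration()`, `doseFromConcentration()`), and ρ = 1.06
  g/ml. Energy is conserved exactly by construction.
- **DVH metrics** — mean dose, cumulative DVH, D70 (30th percentile of
  voxel doses) and V50 (`meanDose()`, `cumulativeDvh()`, `dMetric()`,
  `vMetric()`).
- **Agreement statistics** — Sørensen–Dice, symmetric surface Hausdorff
  distance (cm), volume difference, Bland–Altman with coefficient of
  reproducibility 1.96·SD, Pearson correlation, paired t-test, and a
  dose–hepatotoxicity summary by worst grade (`diceCoefficient()`,
  `hausdorffDistance()`, `blandAltman()`, `toxicitySummary()`, ...).
- **A synthetic phantom** with known ground truth — ellipsoid liver and
  spleen, Tc-cold tumors with necrotic cores, Gaussian PSF blur, Poisson
  count noise, and a rigid misregistration emulating the manual arm's
  registration error (`phantomSpec()`, `makePhantom()`,
  `simulateSpect()`, `perturbMask()`).

Volumes are handled as S4 `VoxelGrid`/`BinaryMask` objects with physical
spacing and origin, read and written as NIfTI-1 (`readVolume()`,
`writeVolume()`). A thin command-line front end lives at
`inst/scripts/duodose` (subcommands `phantom`, `segment`, `dose`,
`run`).

## Worked example

A full two-arm comparison on the default phantom (64³ grid, 4.8 mm
voxels, 5400 MBq ¹⁶⁶Ho, PSF 10 mm, 10⁷ counts per isotope, manual arm
misregistered by (8, 4, 12) mm + 3°):

```r
library(duodose)
rep <- runComparison(phantomSpec(seed = 7L))

rep$agreement$dice            # 0.8072
rep$agreement$hausdorff_cm    # 1.98
rep$manual$mean_dose_gy       # 34.78
rep$automatic$mean_dose_gy    # 38.92
rep$true_mean_dose_gy         # 41.35 (analytic phantom truth)
rep$dice_vs_truth             # 0.9864
```

The automatic mask overlaps the true healthy liver at Dice 0.986 and
recovers its mean dose to within a few percent; the "manual" arm —
deliberately misregistered, as clinical manual registration is —
overlaps the automatic mask at Dice 0.81 and underestimates the mean
dose, illustrating why registration error, not the threshold method, is
the dominant error source. The Bland–Altman summary prints its limits
of agreement directly:

```r
blandAltman(c(20, 22, 24, 19, 25), c(18, 20, 22, 18, 22))
#> Bland-Altman (n = 5): mean difference 2.000 +/- 1.386 (CoR),
#>   limits of agreement [0.614, 3.386]
```

Cohorts of runs aggregate the paired per-run mean dose, D70 and V50
into Bland–Altman, Pearson and paired t-test blocks with
`runCohort()`; `vignettes/dual-isotope-dosimetry.Rmd` documents the
model, parameters and phantom in detail.

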