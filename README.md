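# petharm — data-driven resolution harmonization for brain PET

Multicenter FDG-PET studies pool images acquired on scanners with different
effective spatial resolutions (typically 4.5–6 mm FWHM). Without resolution
matching, voxelwise and regional analyses confound scanner hardware with
biology. The classical fix — derive a per-scanner smoothing filter from
phantom scans — is unavailable in most retrospective archives.

`petharm` estimates the harmonizing filter from the study images alone.
Given spatially and intensity normalized volumes from a *reference* scanner
and a *test* scanner, it finds the anisotropic Gaussian filter

    Θ* = (FWHM_XY, FWHM_Z) = argmax_Θ SSIM( I_ref , G(Θ) ∗ I_test )

where `I_ref` and `I_test` are the cohort-average images, `G(Θ)` is a
separable 3D Gaussian (one in-plane width, one axial width, in mm), and
SSIM is the mean 3D structural similarity index. The optimum is located by
an exhaustive 0.5 mm grid search followed by bounded Nelder–Mead
refinement. Ground-truth filters for validation come from the quadratic
combination rule `FWHM_filter² = FWHM_target² − FWHM_scanner²`, applied per
direction.

The package also ships a digital brain-phantom simulator (gray/white
contrast 4:1, subject variability, noise, residual misregistration, scanner
blur) and a validation harness that scores estimated filters against the
quadrature rule across a full cross-scanner matrix — so the entire protocol
is testable without any patient data.

## Worked example

Simulate two 20-subject cohorts from one phantom — a "Discovery-like"
scanner (5.5 mm XY / 6.0 mm Z) and an "HR+-like" scanner (6.0 / 6.0 mm) —
then harmonize the Discovery cohort to the HR+ cohort at an 8 mm target:

```r
library(petharm)

ph <- make_phantom(c(48, 58, 48), c(2, 2, 2))
spec_a <- synthetic_cohort_spec(scanner = c(5.5, 6.0), n_subjects = 20,
                                shape = c(48, 58, 48), spacing = c(2, 2, 2), seed = 11)
spec_b <- synthetic_cohort_spec(scanner = c(6.0, 6.0), n_subjects = 20,
                                shape = c(48, 58, 48), spacing = c(2, 2, 2), seed = 22)
test_avg <- average_cohort(simulate_cohort(spec_a, ph))$mean_volume
ref_avg  <- average_cohort(simulate_cohort(spec_b, ph))$mean_volume

ref_prep <- prepare_reference(ref_avg, scanner_profile("HR+", 6, 6), 8)
res <- estimate_filter(ref_prep, test_avg, upper_bound = 10)
res
#> <optimization_result> FWHM_XY = 5.832 mm, FWHM_Z = 5.353 mm (SSIM 0.991452)
#>   492 objective evaluations; converged: TRUE; boundary: FALSE
```

The quadrature ground truth is `sqrt(8² − 5.5²) = 5.809` mm in-plane and
`sqrt(8² − 6²) = 5.292` mm axially: the data-driven estimate lands within
0.07 mm of both despite 5% subject variability, 5% noise and 0.5 mm
registration jitter. Applying `apply_harmonization(volumes, res$theta)`
then brings every test volume to the reference resolution.

Real data enter through `read_volume()`/`write_volume()` (NIfTI-1, `.nii`
or `.nii.gz`, assumed already spatially normalized to a common template
grid).

## Command line

A thin wrapper over the same functions:

```sh
exec/petharm estimate --ref ref1.nii.gz,ref2.nii.gz --test t1.nii.gz,t2.nii.gz \
                      --target 8 --out report.json
exec/petharm apply    --in t1.nii.gz,t2.nii.gz --fwhm-xy 5.83 --fwhm-z 5.35 --out-dir harmonized/
exec/petharm simulate --config cohort.yaml --out-dir cohort/
exec/petharm validate --config validation.yaml --out-dir results/
exec/petharm ssim-map --ref ref.nii.gz --test t.nii.gz --xy-grid 0,1,2,3 --z-grid 0,1,2,3 --out surface.csv
```

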