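# pat3d

Quantifying pericardial adipose tissue (PAT) — the fat surrounding the
heart — from short-axis cardiac image stacks. PAT, and in particular its
atrial component, is an independent predictor of atrial fibrillation, so a
reproducible, non-invasive measure of local cardiac fat stores is of direct
clinical interest. `pat3d` implements the semi-automated pipeline used to
validate such a measure against reference (autopsy) fat mass, plus the
method-comparison statistics for that validation, and a digital phantom
with analytically known fat volumes for end-to-end verification.

The pipeline is:

1. **Mark** fat regions on each end-diastolic short-axis slice
   (polygon tracing, intensity thresholding within an ROI, seeded region
   growing — `apply_roi_set()`, `threshold_within_roi()`, `region_grow()`).
2. **Model** the marked regions in 3D by linear interpolation of pixel
   values between consecutive slices: for a pixel column with values
   *a*, *b* on adjacent slices, the value at fractional position
   *t* ∈ [0, 1] is (1 − *t*)·*a* + *t*·*b*
   (`interpolate_between_slices()`, `binarize()`).
3. **Quantify** compartment volumes on the model and convert to mass with
   the adipose density constant ρ = 0.9 g/mL. Atrial fat lies above the
   mitral valve hinge and below the right pulmonary artery; ventricular fat
   runs from the hinge down to the apex
   (`split_compartments()`, `quantify_fat()`).
4. **Validate** against reference measurements with the single-measures
   two-way random-effects intraclass correlation (consistency and absolute
   forms) and Bland–Altman bias with limits of agreement *bias* ± *k*·SD of
   the paired differences (`icc()`, `bland_altman()`, `agreement_report()`).

A paired autopsy/CMR validation table (nine sheep, atrial/ventricular/total
PAT mass in grams) ships with the package, and `generate_phantom()` builds
synthetic stacks — an ellipsoidal heart with an irregular bright fat shell
and patchy atrial deposits at 6 mm slices — whose true fat volumes are known
analytically or by fine-grid voxelization.

## Worked example

```r
library(pat3d)

# validation statistics from the packaged paired table
tab <- read_paired_table(pat_example("sheep_pat_autopsy_cmr.csv"))
rep <- agreement_report(tab, k = 2)
dplyr::select(rep, quantity, mean_autopsy_g, mean_cmr_g, bias,
              loa_half_width, icc_consistency)
#>   quantity    mean_autopsy_g mean_cmr_g  bias loa_half_width icc_consistency
#> 1 atrial                29.1       36.8  7.67           11.4           0.811
#> 2 total                260.        286.  26.3           23.1           0.988
#> 3 ventricular          231.        250.  18.7           19.6           0.990
```

Imaging over-estimates autopsy mass systematically (bias 26 g for total
PAT — autopsy cannot retrieve every gram of adherent fat), while the
consistency ICC exceeds 0.80 for every compartment; `autoplot(tab)` draws
the per-compartment Bland–Altman panels.

```r
# end-to-end on a synthetic stack with known truth
ph <- generate_phantom(phantom_spec(seed = 7))
mask_stack_volume(ph$truth_masks)    # recovered total volume, mL
#> [1] 88.4385
ph$truth$total_volume_ml             # fine-grid truth, mL
#> [1] 89.767

quantify_fat(ph$truth_masks,
             compartment_bounds(ph$truth$mitral_hinge_slice))
#>   atrial_volume_ml ventricular_volume_ml total_volume_ml atrial_mass_g ...
#> 1            21.79                 60.55           82.34         19.61 ...
```

The 1.5% shortfall on the whole stack is the slice-sampling discretization
error at 6 mm slices, bounded by `A_max * dz` (largest slice area times
slice spacing). The compartment totals are smaller again because each
compartment is modelled from its own slices only, so the interval bridging
the hinge boundary contributes to neither — the same `A_max * dz` bound
covers it.

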