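# petmtv

Segmentation-threshold comparison for FDG-PET volumetric response assessment
in lymphoma.

## The problem

Metabolic tumor volume (MTV) and total lesion glycolysis (TLG) from
[¹⁸F]FDG-PET are increasingly used for prognostication in Hodgkin lymphoma,
but their values depend heavily on how lesions are delineated. Four threshold
rules are in common clinical use, and they disagree most on heterogeneous or
low-uptake lesions:

| method | voxel inclusion rule |
|--------|----------------------|
| **V41%**   | SUV ≥ 0.41 · SUVmax, with SUVmax taken within the lesion's own site |
| **V2.5**   | SUV ≥ 2.5 (absolute) |
| **Vliver** | lesion eligible if SUVmax / SUVmean(liver) > 1.5; voxels at SUV ≥ 1.5 · SUVmean(liver) |
| **AM**     | adaptive: SUV ≥ 0.15 · I(mean) + SUVmean(liver), where I(mean) is the mean SUV inside the 70 %-of-Imax isocontour |

All four grow a 26-connected component from an operator seed inside a search
VOI. From each mask the package extracts SUVmax, SUVmean, SUVpeak (mean over
a 1 mL sphere around the hottest voxel), MTV (mL) and TLG = MTV · SUVmean,
tracks their percentage change across baseline (PET1), interim (PET2) and
end-of-therapy (PET3) scans, assigns Deauville 5-point scores against
mediastinal blood-pool and liver references, and compares the methods with
Pearson correlation + linear regression, Bland–Altman limits of agreement,
and univariable logistic regression of the dichotomized Deauville outcome on
each metric.

Because clinical scans cannot be redistributed, the package ships a digital
phantom generator that renders multi-timepoint cohorts — lesions of known
volume and uptake (optionally radially graded), liver and mediastinal
reference regions, Gaussian point-spread blur and additive noise, and a
programmable therapy-response model — so every stage of the pipeline can be
validated against known ground truth.

## Worked example

Delineate one heterogeneous 10 mm lesion (peak SUV 8, rim SUV 4, 6 mm PSF,
noise SD 0.1) with all four methods:

```r
library(petmtv)
spec <- phantom_spec(
  grid_shape = c(48, 48, 36), voxel_spacing = 2, background_suv = 0.5,
  liver_region = voi_sphere(c(19, 19, 36), 10, label = "liver"), liver_suv = 2,
  mediastinum_region = voi_sphere(c(77, 19, 36), 7, label = "mbp"),
  mediastinum_suv = 1.2,
  lesions = list(lesion_spec(c(58, 67, 36), radius = 10, uptake = 8,
                             heterogeneity_amp = 4, label = "nodal")),
  psf_fwhm = 6, noise_sigma = 0.1, rng_seed = 42)
ph <- generate_phantom(spec)
liver <- reference_mean(ph$volume, voi_sphere(c(19, 19, 36), 10))
q <- query_from_voi(ph$volume, voi_sphere(c(58, 67, 36), 18), label = "nodal")
for (m in SEGMENTATION_METHODS) {
  seg <- segment_lesion(ph$volume, q, m, liver_mean = liver)
  met <- extract_metrics(ph$volume, seg)
  cat(sprintf("%-7s threshold %.2f  MTV %5.2f mL  SUVmean %.2f  TLG %6.2f\n",
              m, seg$applied_threshold, met$mtv_ml, met$suvmean, met$tlg))
}
```

```
v41     threshold 2.62  MTV  3.47 mL  SUVmean 4.12  TLG  14.29
v25     threshold 2.50  MTV  3.71 mL  SUVmean 4.02  TLG  14.91
vliver  threshold 2.33  MTV  4.08 mL  SUVmean 3.87  TLG  15.79
am      threshold 2.34  MTV  4.06 mL  SUVmean 3.88  TLG  15.74
```

The true lesion volume is 4.19 mL. The measured liver SUVmean is 1.55 (below
the nominal 2.0 because the point-spread function mixes in surrounding
background), so Vliver and AM land on similar, slightly permissive
thresholds and recover nearly the full volume, V2.5 sits in between, and
V41% — anchored to the blurred lesion peak — cuts away the faint rim and
under-segments the most. On a cohort of such lesions this is exactly the
behaviour that separates relative from absolute thresholds.

A whole synthetic study (cohort simulation, segmentation with all four
methods, metric extraction, Deauville scoring, agreement and regression
tables, plots, checksummed manifest) is one call:

```r
res <- run_full_study(run_config(out_dir = "study", n_patients = 20, seed = 1))
head(res$agreement)   # pair x parameter x timepoint: rho, p, bias, LoA
head(res$ds_regression)
```

A thin command-line wrapper with verbs `simulate`, `segment`, `compare` and
`run-all` is installed at `inst/scripts/petmtv`.

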