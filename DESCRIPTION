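Package: petmtv
Title: PET Metabolic Tumor Volume Segmentation and Threshold Method Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for delineating FDG-PET lesions on SUV volumes with four
    threshold rules (41% of lesion SUVmax, absolute SUV 2.5, 1.5 x liver
    SUVmean, and an adaptive background-corrected threshold), extracting
    SUVmax, SUVmean, SUVpeak, metabolic tumor volume (MTV) and total lesion
    glycolysis (TLG), scoring treatment response on the Deauville 5-point
    scale, and comparing the methods with Pearson correlation, linear
    regression, Bland-Altman agreement and univariable logistic regression
    against response. Includes a digital phantom generator that builds
    synthetic multi-timepoint PET cohorts with known ground truth so the whole
    pipeline can be exercised and validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
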