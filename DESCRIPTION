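Package: batwfi
Title: Water-Fat MRI Simulation and Fat-Fraction Quantification for Brown
    and White Adipose Tissue Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Digital-phantom simulation and analysis of chemical-shift-encoded
    gradient-echo (water-fat) MRI for quantifying brown adipose tissue (BAT)
    within white adipose tissue (WAT). Builds fine-grid ground-truth tube
    phantoms with controlled BAT/WAT mixtures, forward-simulates multiecho
    acquisitions with partial-volume averaging and complex noise, estimates
    proton density fat fraction (PDFF) maps by T2*-corrected multipeak
    variable-projection fitting (and by an uncorrected single-peak fit),
    and computes VOI statistics, PDFF histograms and threshold volumetry
    (volume of tissue with PDFF below a cutoff).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
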