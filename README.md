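# batwfi

Water–fat MRI simulation and fat-fraction quantification for brown and
white adipose tissue phantoms.

## What this is for

Brown adipose tissue (BAT) stores lipid in small multilocular droplets
inside water- and mitochondria-rich cells, so its proton density fat
fraction (PDFF) is much lower than that of white adipose tissue (WAT).
Chemical-shift-encoded (Dixon / water–fat) MRI can therefore flag BAT-like
tissue inside a fat depot and estimate how much of the depot it occupies.
`batwfi` implements that measurement chain end to end, in silico, for
researchers validating PDFF-based BAT metrics:

* **digital phantoms** — cylindrical sample tubes with controlled BAT/WAT
  mixtures (clumped or layered packing, per-cell tissue heterogeneity,
  smooth B0 field map) in a gadolinium-doped water box;
* **acquisition simulation** — two multiecho gradient-echo protocols (a
  six-echo "quantitative" low-resolution protocol, TE = 1.5 + n·1.3 ms at
  1.1×1.1×2.2 mm³, and a four-echo high-resolution protocol,
  TE = 3.8…6.8 ms at 0.5×0.5×2.2 mm³) in two orthogonal orientations, with
  partial volume arising from complex voxel averaging and circular complex
  Gaussian noise;
* **PDFF estimation** — per-voxel inversion of the signal model

  `s(TE) = (ρ_W + ρ_F Σ_p α_p e^{i2πΔf_p TE}) · e^{i2πψTE} · e^{−R₂*TE}`

  by variable projection (amplitudes solved linearly at each candidate
  (ψ, R₂*); coarse grid plus bounded refinement), either T2*-corrected with
  a six-peak lipid spectrum (`fitQuantitative()`) or uncorrected with a
  single peak and R₂* = 0 (`fitUncorrected()`), plus water–fat swap
  resolution (`swapCheck()`);
* **BAT metrics** — VOI statistics, PDFF histograms, and threshold
  volumetry: `VOL(PDFF ≤ t)` = count of VOI voxels at or below the
  threshold × voxel volume, with aggregation (mean ± SD, min/max envelope)
  over the four acquisitions.

All volumes read and write NIfTI-1 (+ JSON sidecars); configuration is
YAML; everything is deterministic per master seed.

## Worked example

```r
library(batwfi)

cfg <- experimentConfig(3, seed = 7, profile = "small")  # mixture replica
rep <- runExperiment(cfg)
round(sapply(rep$tubes, function(tb) tb$aggregate$meanOfMeans), 1)
#> tube1 tube2 tube3
#>  41.0  54.0  90.7
round(sapply(rep$tubes, function(tb) tb$volAtThresholdMean), 3)
#> tube1 tube2 tube3
#> 0.099 0.064 0.000
```

Tube 1 (60 % BAT / 40 % WAT) shows the lowest VOI-mean PDFF and the
largest volume of tissue with PDFF ≤ 50 % — the BAT-like compartment;
tube 2 (40/60) is intermediate, and the pure-WAT tube 3 contributes
essentially no volume below the threshold. The same pipeline at full
geometry (`profile = "paper"`) uses 0.6 cm³ analyzed VOIs over eight
central slices.

A command-line wrapper is installed at `inst/cli/batwfi`:

```sh
Rscript inst/cli/batwfi experiment --id 3 --seed 7 --out run/
Rscript inst/cli/batwfi simulate --id 1 --seed 1 --out sim/
Rscript inst/cli/batwfi fit --input sim/quantitative_lowres.coronal \
    --method quantitative --out fits/quant
Rscript inst/cli/batwfi analyze --pdff fits/quant_pdff.nii --mask mask.nii --out out/
```

See `vignettes/waterfat-phantom-methods.Rmd` for the model, parameter
choices and the limits of what the simulations establish.

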