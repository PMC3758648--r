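# specmicro

Characterization and comparison of hyperspectral fluorescence microscopy
systems.

Hyperspectral microscopes record an emission spectrum at every pixel
(an *X × Y × λ* cube), which makes it possible to separate a weak
fluorescent label — say GFP-expressing cells — from strong, spectrally
overlapping tissue autofluorescence by linear spectral unmixing. How well
this works depends heavily on acquisition settings: pinhole diameter,
illumination intensity, detector gain, exposure history. `specmicro`
implements a quantitative workflow for measuring that dependence and for
comparing systems (e.g. a widefield AOTF/EMCCD instrument against a
confocal grating/PMT instrument) on a common footing:

- **Flat spectral correction** — the wavelength-dependent transmission of a
  tunable-filter system is measured from dark/bright calibration images and
  a traceable lamp spectrum as a transfer function
  *TF(λ) = (I_bright(λ) − I_dark(λ)) / I_lamp(λ)*; raw data are corrected
  per pixel as *I_corr(λ) = max(0, I_raw(λ) − I_dark(λ)) · CC(λ)* with
  *CC = 1/TF*.
- **Endmember libraries** — pure GFP / Hoechst / autofluorescence spectra
  extracted from single-fluorophore control cubes by thresholding the total
  emission image and pixel-averaging inside the ROI.
- **Linear unmixing** — per-pixel least squares *min_a ‖x − S a‖²*
  (unconstrained OLS, or NNLS for nonnegative abundances), with per-pixel
  RMS reconstruction error and the percent RMS error
  *100 · RMS_error / RMS_signal* in both image-averaged and pixelwise
  conventions.
- **Noise characterization** — per-pixel per-band SNR *μ/σ* across
  sequential replicate images, composite and per-band summaries, SNR of
  unmixed abundance images, and ROI coefficients of variation.
- **Photobleaching analysis** — per-endmember decay curves normalized to
  the initial intensity, mono-exponential rate fits, and unmixing error as
  a function of illumination time.
- **Theoretical sensitivity studies** — a known endmember spectrum is added
  (post-acquisition) to a control image at graded peak intensities; the
  unmixed response slope measures sensitivity, and a nearest-rank quantile
  threshold on the zero-added abundance distribution measures specificity
  as false-positive pixel counts.
- **A synthetic acquisition simulator** — Gaussian endmembers, geometric
  scenes, and detector models (Poisson photons, multiplicative excess
  noise, Gaussian read noise, offset, quantization/clipping) with
  `widefield` and `confocal` presets, so the entire pipeline is testable
  without instrument data.

## Worked example

Simulate five replicate confocal acquisitions of a mixed scene, measure the
noise, and unmix:

```r
library(specmicro)

p      <- preset("confocal")
lib    <- preset_library(p)                      # GFP, Hoechst, AF on 462-648 nm
scene  <- render_scene(preset_scene(p, c(48, 48)), lib)
series <- acquire(scene$cube, p$detector, n_replicates = 5, seed = 7)

composite_snr(snr_map(series))
#> [1] 8.929125

res <- unmix(series$cubes[[1]], lib)
percent_rms_error(res, "image_averaged")
#> [1] 9.522953
```

The composite SNR (≈ 8.9) is the mean of per-pixel, per-band μ/σ values
over the field of view and all 32 bands — the single-number noise summary
for this acquisition setting. The percent RMS error (≈ 9.5 %) says the
unmixing residual is about a tenth of the RMS signal. Re-running with
`preset("widefield")` gives a composite SNR near 1.6 and a percent RMS
error near 58 %, reproducing the qualitative contrast between the two
system families: the EMCCD preset collects fewer photons per band, carries
excess multiplication noise, and pays for it in unmixing accuracy.

A spike-in sensitivity study on a noise-free autofluorescence control
responds ideally:

```r
sens <- run_sensitivity(control, lib, spikein_spec("GFP"))
sens$slope        # 1.000000 — one abundance unit per unit of added peak intensity
sens$threshold    # 98.5% nearest-rank quantile of the zero-added ROI abundances
```

The end-to-end driver chains every stage for one or both presets and
returns a single report:

```r
report <- characterize(c("widefield", "confocal"), seed = 1)
write_report_json(report, "report.json")
```

A thin command-line wrapper with subcommands (`simulate`, `unmix`, `snr`,
`sensitivity`, `characterize`) is installed at
`system.file("cli/specmicro", package = "specmicro")`.

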