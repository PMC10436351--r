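# iscatsim

First-principles simulation of mass photometry (MP): the label-free optical
technique that weighs single biomolecules by the interferometric contrast
they create when landing on a microscope cover glass. `iscatsim` is aimed at
people building or analyzing interferometric scattering instruments and at
anyone who wants a quantitative, end-to-end sandbox for the measurement —
from Maxwell-level image formation down to the mass histogram.

The package covers:

* **Image formation** — Fourier-optics rendering of the interferometric
  point-spread function of a molecule at the glass–water interface:
  Fresnel reference reflection, dipole-at-interface scattering including
  supercritical-angle emission, a partially transmissive back-focal-plane
  (BFP) attenuation mask with optional phase, high-NA aplanatic collection,
  defocus (Gouy-phase) tuning, and index-mismatch aberration of elevated
  emitters. The ratiometric contrast `C = (I_det − I_bkg)/I_bkg` is the
  central observable; in the small-signal regime
  `C = 2(|s|/|r|)cos φ + (|s|/|r|)²`.
* **Molecules** — Rayleigh spheres via Clausius–Mossotti,
  `α = 3V (n_p² − n_m²)/(n_p² + 2n_m²)`, and atomistic 3×3 polarizability
  tensors from PDB structures via a coupled-dipole model, with uniform
  SO(3) orientation sampling and polarization projection.
* **Backgrounds** — correlated cover-glass roughness (±0.8 nm over
  ~100 nm) and its masked speckle image.
* **Landing assays** — Poisson landing schedules, photon-count movies with
  shot noise, detector binning, TIFF/CSV export.
* **Analysis** — sliding-window ratiometric frames, significance- and
  radial-symmetry-based event detection, subpixel PSF fitting
  (theoretical or experimental model), pixel-wise local reflectivity
  correction, Gaussian mass-peak fitting and contrast-to-mass calibration.
* **Photon budget** — closed-form `SNR = √(2 N_sca)` chain with collection
  efficiency μ, BFP area, interface enhancement γ, detection-limit mass
  `m_q`, quantum Cramér–Rao mass resolution `σ_m`, and an excess-noise
  model with its finite SNR ceiling.

## Worked example

Contrast of the Hsp16.5 24-mer (modelled as a 5.6 nm sphere of index
1.480) at 445 nm through a 1% mask, maximized over defocus:

```r
library(iscatsim)

cfg  <- optical_config(d_px = 57e-9, n_pix = 70, mask_phase = 0,
                       mask_transmission = 0.01)
hsp  <- scatterer_response(sphere_polarizability(sphere_scatterer(5.6e-9, 1.480)))
sw   <- axial_contrast_sweep(cfg, hsp, c(-2e-6, 2e-6), dz = 57e-9, n_az = 2)
cat(sprintf("peak contrast %.2f%% at %.0f nm defocus\n",
            100 * abs(sw$c_opt), 1e9 * abs(sw$z_opt)))
#> peak contrast 0.61% at 182 nm defocus
```

A 0.61% contrast means the molecule changes the detected intensity at its
brightest pixel by about 6 parts in a thousand relative to the bare
interface reflection, and the optimum sits ~180 nm above nominal focus
because defocus tunes the phase between scattered and reflected light.

The analytic photon budget at the standard operating point:

```r
p <- snr_parameters(mu = 0.40, gamma = 1.58, a_bfp = 50e-6,
                    i_illu = 1e9, dt = 0.1, m = 66)   # 0.1 MW/cm^2, 100 ms
shot_noise_snr(p)          #> 20.8     single-molecule SNR for 66 kDa
detection_limit_mass(p, 3) #> 9.52     smallest mass (kDa) detectable at SNR 3
qcrlb_resolution(p)        #> 2.24     quantum-limited mass resolution (kDa)
```

A full landing assay — speckled background, shot noise, detection, fitting,
correction, calibration — is assembled in a dozen lines; see the vignette
(`vignettes/mass-photometry-simulation.Rmd`) for the complete walkthrough
and the model's assumptions.

## Command line

A thin CLI over the same functions ships in `inst/exec/iscatsim-cli`:

```sh
Rscript "$(Rscript -e 'cat(system.file("exec", "iscatsim-cli", package = "iscatsim"))')" \
  snr-budget --excess-kda 5
```

Subcommands: `simulate-psf` (PSF/defocus sweep to TIFF + YAML) and
`snr-budget` (budget scalars to JSON).
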