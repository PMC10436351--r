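---
title: "Simulating mass photometry from first principles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating mass photometry from first principles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iscatsim)
```

Mass photometry infers the mass of single biomolecules from the
interferometric contrast they generate when landing on a microscope cover
glass: light scattered by the molecule interferes with the weak reflection
from the glass–water interface, and the relative intensity change — the
*ratiometric contrast* `C = (I_det − I_bkg)/I_bkg` — scales linearly with the
molecule's excess polarizability and hence, to good approximation, with its
mass. `iscatsim` builds this measurement from first principles: a
Fourier-optics model of the imaging system, molecular polarizability models,
the static speckle background of real cover glass, a landing-assay movie
generator with shot noise, the ratiometric detection-and-calibration
pipeline used on such movies, and a closed-form photon budget for what the
technique can ultimately resolve.

## The imaging model

The simulated instrument is a widefield interferometric scattering
microscope: plane-wave illumination through an index-matched oil objective,
a glass–water interface as the sample support, and a partially transmissive
attenuation mask in the back focal plane (BFP) that dims the reflected
reference beam (power transmission `|tau|^2`, typically 1%, inside a cutoff
of effective NA 0.58) so that the scattered light is relatively enhanced by
`1/|tau|`.

Image formation is computed in the angular spectrum domain. The reference
field is the normal-incidence Fresnel reflection `r = (n_g − n_m)/(n_g +
n_m)` (|r|² ≈ 0.4% for borosilicate/water), attenuated and phase-shifted by
the mask. The scattered field of a molecule is modelled as a point dipole at
the interface, driven by the transmitted illumination; its angular spectrum
on the glass side comes from the exact dipole-near-interface transmission
formulas, which include the supercritical-angle ("forbidden") light that
makes a dipole near a denser medium considerably brighter than in bulk. The
detector field is assembled with the energy-conserving aplanatic pupil
weighting `F(θ)/sqrt(cos θ)` (we verified the alternative ideal-4f `1/cos`
weighting violates the collected-power budget), band-limited by the NA,
masked, and Fourier-transformed to the image plane. Circular polarization is
simulated as the average over azimuthally distributed linear polarizations.

Two conventions in this model are genuinely ambiguous in the literature and
are therefore explicit package choices:

* **Polarizability convention.** We quote excess polarizabilities in the
  "volume" convention `alpha = 3V (n_p² − n_m²)/(n_p² + 2 n_m²)` (Å³), in
  which the scattering cross-section is `k⁴ alpha²/6π`.
* **Which wavenumber drives the scattering amplitude.** The far-field
  scattering prefactor is `k² alpha/4π`; whether `k` carries the medium
  index amounts to a factor `n_m²` in amplitude and depends on how the
  scattering coefficient is introduced. The imaging default is the vacuum
  wavenumber (`k_convention = "vacuum"`), which together with the
  Clausius–Mossotti sphere model reproduces the measured-scale contrast of
  the Hsp16.5 benchmark below; the medium-`k` convention is available as a
  config switch.

Defocus matters: moving the sample by `dz` advances the reference by `2 k_g
dz` but each scattered plane wave by `k_g dz (1 + cos θ)`, so defocus tunes
the Gouy-type phase between the two. With a plain attenuation mask the
contrast is maximal roughly 190 nm from the nominal focus; adding a π/2 mask
phase re-phases the fields so the optimum returns to the focal plane, which
is the configuration used for landing assays.

Worked benchmark (the package's standard check): a sphere of radius 5.6 nm
and index 1.480 — the size and refractive index used for the Hsp16.5 24-mer
(396 kDa) — imaged at 445 nm with a 1.42 NA objective and a 1% mask gives a
peak ratiometric contrast of 0.61% at 182 nm defocus on the 57 nm / 70 px
grid (`axial_contrast_sweep()` reproduces both numbers; the acceptance
script recomputes them on every run).

The scatterer sits at the interface plane by default (`height = 0`, the
contact limit of a point scatterer); an elevated emitter picks up the exact
water-path phase `exp(i k_m cosθ_w h)` per angular component, which is the
index-mismatch (Gibson–Lanni-type) aberration term for an emitter at depth
`h` and also attenuates its evanescent components.

## Molecular models

**Spheres.** `sphere_polarizability()` is the Clausius–Mossotti form above;
it vanishes at index matching and scales with volume.

**Atomic structures.** `tensor_from_structure()` implements a coupled-dipole
model: every atom carries an isotropic excess polarizability; the induced
dipoles interact through the bare point-dipole tensor `(3 r̂r̂ − I)/(4π r³)`
over all pairwise distances (a hard 0.8 Å distance floor guards
conditioning), and the self-consistent total moment per unit field is the
molecular 3×3 tensor. The per-element table ships as a swappable config file
(`extdata/atomic_polarizabilities.csv`): relative magnitudes follow atomic
polarizability data (ionic values for bound metals), and the absolute scale
is calibrated so an average protein elemental composition ("averagine",
heavy atoms only) yields 724 Å³ of excess polarizability per kDa — the
mass–polarizability slope of folded proteins that also anchors the photon
budget. Structure masses are computed from the atoms actually present, so a
PDB entry missing hydrogens or disordered residues weighs what its atoms
weigh. Above a configurable atom count the solve (O((3N)³)) coarse-grains to
one site per residue carrying the summed polarizability.

Orientation handling follows the intrinsic z-y-x Euler convention `R = R_z
R_y R_x`; `sample_orientation()` draws uniform (Haar) rotations via unit
quaternions. Under linear polarization along `ê` the driven response is
`êᵀ α ê`; under circular polarization it is the azimuthal average
`(α_xx + α_yy)/2`, which is why circularly polarized mass photometry is
nearly insensitive to molecular shape and orientation while linearly
polarized measurements of anisotropic molecules are not.

## Cover-glass roughness and speckle

Real cover glass is rough on the scale of ±0.8 nm height over ~100 nm
lateral correlation lengths. `generate_height_map()` draws uniform white
noise, low-pass filters it in frequency space (Gaussian filter whose
filtered-noise autocorrelation FWHM equals the requested correlation
length), and peak-normalizes to the height bound (the quoted roughness is a
bound, not an RMS). The reflected reference then carries the phase map
`psi = 2 k₀ n_g Δh` (round-trip path in glass; an optional term adds the
transmission-path contribution, off by default because the coverslip phase
contribution to protein contrast is not separately constrained). Imaged
through the mask, the phase structure — mostly outside the mask cutoff and
therefore unattenuated — produces the static speckle background whose
contrast dwarfs any single protein; with a π/2 mask the first-order speckle
field is co-phased with the shifted reference, so speckle modulates mainly
the local reference *amplitude*. That observation is what makes the local
reflectivity correction below work.

## Landing assays and the analysis pipeline

`simulate_movie()` renders photon-count movies: the static speckle
background plus, from each landing frame onward, the molecule's
interferometric PSF at its (subpixel, uniformly distributed) position —
landings arrive as a Poisson process in time — with independent per-pixel
Poisson shot noise. Landed molecules persist and become part of the
background. One RNG stream per movie makes runs bit-reproducible. Movies use
the π/2-phase mask, in-focus configuration; event fields are rendered for a
single linear polarization (for isotropic sphere scatterers the circular
average changes only the weak cross-polarized rings, not the fitted
contrast). Detector binning (`bin_detector()`) sums counts exactly.

The analysis chain mirrors what is run on experimental movies:

1. **Ratiometric frames** (`ratiometric_stack()`): sliding windows average
   `n_avg` frames into two half-stacks and output `(Ī₂ − Ī₁)/Ī₁`. Static
   structure cancels exactly; a landing fades in and out across
   `2 n_avg` consecutive ratiometric frames with a triangular envelope, with
   full amplitude when the landing falls exactly between the half-stacks.
   With stacks of exactly `n_avg` frames the pixel series
   `[100, 100, 110, 110, 110, 110]` at `n_avg = 2` gives a first
   ratiometric value of +0.10.
2. **Local reflectivity correction** (`correct_ratio_stack()`): each frame is
   multiplied by `sqrt(I_bkg(x)/I_flat)` pixel-wise. Because speckle
   modulates mainly the local reference amplitude, this removes the
   `1/|r_local|` dependence of the contrast *and* restores the distorted PSF
   shape before fitting; it also makes the ratiometric shot noise uniform
   across the field. The event-level variant
   (`reflectivity_correction()`), which rescales only the fitted contrast,
   is retained for comparison; the residual broadening left by the local
   *phase* of the speckle is physical and is not corrected.
3. **Detection** (`detect_events()`): candidates must stand `min_snr` (5 by
   default) sigma above the per-pixel ratiometric noise propagated from the
   background photon counts, be local maxima, pass a radial-symmetry score
   (correlation of the patch with its angular average, threshold 0.4 — the
   criterion is qualitative in the field; the statistic is ours), survive
   non-maximum suppression within 5 px (Airy-ring duplicates), and persist
   for ≥ 2 ratiometric frames (single-frame shot-noise outliers are
   rejected). Events peaking at the first or last ratiometric frame are
   dropped as truncated.
4. **Contrast fitting** (`fit_event_contrast()`): least-squares amplitude +
   subpixel position fit of a PSF model (theoretical, from the same optical
   model; or experimental, built by `build_experimental_psf()` from aligned,
   outlier-rejected event patches) on a 7×7 patch.
5. **Histogram and calibration** (`fit_mass_peaks()`, `calibrate_mass()`):
   peaks are seeded at the modes of a Gaussian KDE (bandwidth 2 kDa on the
   mass scale) and fitted by iteratively trimmed normal moments (±2.5σ,
   robust against neighbouring peaks); a least-squares line through
   calibrant peak contrasts versus known mass converts contrast to mass.
   Following the practice of calibrating on low-noise data, the calibration
   contrasts are computed from noise-free renders of the calibrant spheres.

On the standard benchmark movie (128×128 px at 70 nm, 0.1% mask,
0.25 MW/cm² illumination scale, 10⁶ photons/pixel/frame, `n_avg` 10 — 10⁷
photoelectrons per pixel per half-stack — and ~340 BSA-monomer landings on a
seeded rough surface) the pipeline recovers the monomer peak at 66 kDa with
σ ≈ 2 kDa after the pixel-wise correction; without any correction the
roughness broadens the peak several-fold. The acceptance script reruns this
end to end.

## The photon budget

The closed-form budget predicts performance from experimental parameters.
Detected scattered photons per pixel and exposure:

```
N_sca = (I_illu Δt λ / hc) · OT · QE · μ · γ · (k_m⁴ (δα m)² / 6π) ·
        A_BFP d_px² / (λ² f_obj²)
```

with collection efficiency `μ = asin(min(NA/n_i, 1))/π`, accessible BFP area
`A_BFP = π f_obj² (n_i n_m/n_g)²` (≈ 50 mm² for a 3 mm objective), the
interface enhancement `γ` (below), the mass–polarizability slope `δα = 724
Å³/kDa`, and the last factor concentrating the collected light onto the
brightest pixel. Reflected photons are `N_ref = (I_illu Δt λ/hc) · OT · QE ·
|r|² |τ|² d_px²`. The ratiometric signal amplitude `2√(N_sca N_ref)` against
the shot noise `√(2 N_ref)` of two compared half-stacks gives

```
SNR = √(2 N_sca)
```

(the factor 2 from the interferometric cross term, the 1/√2 from comparing
two frame sets). Because SNR is linear in mass, the detection limit is `m_q
= m·q/SNR(m)` and the quantum Cramér–Rao bound on mass resolution is `σ_m =
m/(√2 SNR(m))` — equivalently, σ_m equals the mass that reaches SNR = 1/√2,
an identity the tests verify to 1e−10. At the standard operating point (0.1
MW/cm², 100 ms, 445 nm, 66 kDa, and the rounded factors μ = 0.40, γ = 1.58,
A_BFP = 50 mm², |r|² = 0.004, |τ|² = 0.02, OT = 0.8, QE = 0.7, d_px = 80 nm)
this chain yields SNR ≈ 20.8, m_{q=3} ≈ 9.5 kDa and σ_m ≈ 2.2 kDa.

**Excess noise.** Experimental images show a dynamic, speckle-like
background that temporal averaging does not remove, with contrast equivalent
to a ≈5 kDa protein; its origin is unexplained and we model it only
analytically. Expressed as a mass-equivalent contrast floor it adds in
quadrature: `1/SNR_exc² = 1/SNR_shot² + (σ_exc/m)²`, recovering shot-noise
behaviour at σ_exc = 0 and saturating at the ceiling `m/σ_exc` (13.2 for 66
kDa over 5 kDa) as photon flux grows; at 0.85 MW/cm² and 100 ms the combined
SNR is ≈12.9. Whether the excess term enters before or after the √2
ratiometric factor is fixed by this ceiling: the mass-equivalent formulation
reproduces it exactly, so no extra √2 appears.

**Interface enhancement γ.** `gamma_interface()` integrates the emission
pattern of an illumination-driven (in-plane) dipole at the water–glass
interface over the collection cone — using the same pattern code as the
imaging engine, so budget and images cannot diverge — and normalizes by the
bulk-water dipole power times μ. This yields 1.11/1.23/1.55/1.60/1.62 at NA
1.2/1.3/1.4/1.42/1.5 against the reference values 1.14/1.21/1.53/1.58/1.67:
four of five within ±0.05, while NA 1.5 sits 0.051 low — alternative
normalizations (3D orientation averages, solid-angle denominators, aplanatic
weightings) fit strictly worse, so we keep the physical model and also ship
the tabulated values as `method = "table"`.

The Eq-style shorthand `SNR = κ m √(I Δt/λ⁵)` is available through
`kappa_constant()`; κ is always computed from the current parameter set at
call time, never hard-coded, so a unit error anywhere in the chain surfaces
as a mismatch with the full evaluation (a property test sweeps random
parameter sets at 1e−9 tolerance).

## Numerical choices

* Grids: landing assays use 128×128 px at 70 nm (field of view ~80 µm²);
  single-PSF benchmarks use 70 px at 57 nm. The scattered-field spectrum is
  evaluated on a zero-padded grid sized so the pupil diameter is sampled by
  ≥256 points (≥64 for the small PSF-model patches), keeping the mask edge
  and the critical-angle structure smooth; a Bluestein chirp-z transform
  (`czt()`, `to_bfp()`) provides arbitrarily fine pupil sampling for
  BFP-plane inspection.
* `propagate()` applies the exact angular-spectrum phase; evanescent
  components decay for either propagation direction (the operator is kept
  contractive rather than amplifying evanescent waves backwards), and
  distances whose steepest 99.9%-energy ray would walk beyond half the
  field of view are refused (periodic wrap-around).
* The benchmark movie sizes above (450 frames, ~340 events) hold the full
  analysis in a few minutes on one core; all simulation sizes are
  parameters.
* Axial sweeps refine the coarse arg-max on a 10× finer local grid;
  contrast extrema are reported signed, with benchmark comparisons quoting
  the magnitude.

## What the synthetic data do and do not show

The generator reproduces plane-wave illumination, mask attenuation and
phase, interface-enhanced dipole scattering, correlated glass roughness,
Poisson shot noise, Poisson landing statistics and uniform orientations. It
deliberately omits: scanned/speckle-free illumination (real instruments
scan to suppress illumination speckle), Brownian-motion blurring of
incompletely bound particles, desorption, camera read noise,
full-well saturation, drift and autofocus, illumination inhomogeneity (a
flat-field map can be supplied), frame-split landings, and any generative
model of the unexplained dynamic excess background (analytic only, see
above). Passing tests therefore validate the optical and statistical model
and the pipeline's correctness on that model — not instrument-specific
artefacts of real recordings.

## Known limitations

* The coupled-dipole atomic model uses bare dipoles with a distance floor;
  damped/screened (Thole-style) interactions are not implemented, and the
  absolute atomic-polarizability scale is calibrated to the protein
  mass–polarizability slope rather than derived ab initio. The table is a
  config file precisely so it can be swapped.
* γ at NA 1.5 deviates by 0.051 from the reference table (see above).
* The sphere-model contrast depends on the `k_convention` choice (factor
  n_m² in amplitude); both conventions are exposed, and the default is the
  one consistent with the package's quoted polarizability scale.
* Tensor scatterers enter the imaging engine through their effective scalar
  response (`êᵀαê` or the circular average); full vectorial tensor imaging
  (polarization mixing in the PSF) is not modelled.
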