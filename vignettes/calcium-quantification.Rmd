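---
title: "Quantifying intracellular calcium stores from cryo-imaging data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intracellular calcium stores from cryo-imaging data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calciq)
```

## The problem

Coccolithophores such as *Emiliania huxleyi* precipitate one calcite
coccolith per hour, a flux that requires on the order of 22.5 fmol of Ca²⁺
per coccolith to pass through the coccolith vesicle. Free cytosolic calcium
is held at sub-micromolar levels, so a substantial intermediate store must
exist. Cryo-imaging of vitrified cells can find and quantify such a store,
but each modality measures concentration only indirectly: backscatter
contrast, X-ray absorbance, or spectral fingerprints. `calciq` implements
those indirect chains as explicit, testable models, and ships a phantom
generator so that every chain can be verified by planting a known
concentration and recovering it.

## Backscatter quantification

The energy-selective backscatter (EsB) signal increases with the mean
atomic number of the material in the interaction volume. We model the
detector as affine in the effective backscatter coefficient,
$\mathrm{grey} = a\,\eta_\mathrm{eff} + b$, and calibrate $a, b$ per stack
from internal standards — regions of known composition inside the same
image: lipid bodies (treated as linear hydrocarbon, CH₂), the seawater
culture medium, and coccolith calcite. For each standard
$\eta_\mathrm{eff} = \sum_i \eta_i c_i$ over elemental weight fractions,
with atomic coefficients from the cubic polynomial fit to Heinrich's
backscatter measurements,
$\eta(Z) = -0.0254 + 1.6\cdot10^{-2}Z - 1.86\cdot10^{-4}Z^2 +
8.3\cdot10^{-7}Z^3$, taken as energy-independent for the light elements
that dominate biological material. Two numerical notes:

- the polynomial is slightly negative at $Z = 1$; `heinrich_eta()` floors
  it (default $10^{-3}$) so that $\eta$ stays in $(0,1)$ and strictly
  increasing, and the coefficients are an exposed argument so an
  alternative fit can be swapped in;
- with two standards the calibration line is exact; with more it is the
  least-squares line (`stats::lm`), and the residual norm is reported so a
  bad standard is visible.

The inverse step assumes the unknown body is a concentrated
calcium/phosphate electrolyte with a fixed Ca:P atomic ratio of 1:2,
motivated by the elemental analysis of the store (polyphosphate-bound
calcium). Phosphorus is carried as metaphosphate chain units (PO₃, the
polyphosphate repeat; orthophosphate is a configuration switch) and no
counterions are added — the charge imbalance is tolerated in the density
model, since the dominant cation is the calcium being quantified.
$\eta_\mathrm{eff}$ is strictly increasing in the Ca mass fraction, so the
inversion is a bisection to $10^{-9}$ in mass fraction, unconditionally
robust. Molarity then follows from the density mixing rule
$1/\rho_s = c_w/\rho_w + \sum_i c_i/\rho_i$ with ion densities computed
from tabulated ionic radii (Shannon radii for monatomic ions; an effective
210 pm radius for the PO₃ unit, both shipped as editable CSV). The same
rule applied to pure calcite ($\rho = 2.71$ g/cm³, $M = 100.09$ g/mol)
gives 27.08 M — the "27 M" calcite reference used throughout.

Dispersion is propagated by a first-order delta method: the grey standard
deviation of the region divided by the calibration slope, times the
numerically differentiated inverse map. This is a per-voxel spread, not a
standard error of the regional mean; it is reported because single-valued
concentration estimates hide how heterogeneous the raw signal is.

## Soft X-ray quantification

Flat-field normalization gives optical density $OD = -\ln(I/I_0)$; pixels
with non-positive measured intensity are marked invalid (`NA`) rather than
clamped, and are excluded from region statistics. Calcium localization
subtracts the below-edge OD (342 eV) from the on-edge OD (353.2 eV, the
second white line of the Ca L₂,₃-edge): all energy-independent absorption
(carbon, oxygen, water) cancels, leaving a map proportional to the areal
Ca density. Concentration uses the region-mean areal density ratio against
the calcite internal standard,
$c = c_\mathrm{cal}\,(\overline{\Delta OD}/\bar L)\,/\,
(\overline{\Delta OD}_\mathrm{cal}/\bar L_\mathrm{cal})$, with chord
lengths $L$ measured on the 3-D segmentation mask along the viewing axis
(zero-tilt by default, the axis is an argument). A single scalar per region
was chosen over per-pixel division because per-pixel ratios amplify noise
at thin chords; the regional ratio is exact for a homogeneous body.
Projection pixels whose beam path crosses both the body and the calibration
region are excluded from both footprints.

Registration is translation-only phase correlation. Two frames straddling
the absorption edge differ strongly in content (the Ca-bearing bodies
appear only on-edge), which makes direct pairwise registration of the two
frames fragile under noise; energy scans are therefore aligned with a
running reference — each frame registered to its predecessor, shifts
accumulated — where consecutive frames differ only marginally. This is the
default inside `xray_quantify_body()` whenever more than two frames are
supplied; a fixed middle-frame reference remains available in
`align_energy_stack()`. Shifts are integer-pixel and applied circularly, so
alignment is exactly invertible and the same shift list can be transferred
to a simultaneously acquired channel.

The phenomenological L-edge absorbance model (`ca_ledge_mu()`) is an arctan
edge step plus Gaussian white lines at 349.3 and 353.2 eV, with the
calcite crystal-field peaks (347.9, 351.3 eV) present only for
crystalline phases, all scaled linearly with molarity
($\kappa = 7\times10^{-5}$ OD per M·nm at the step). It is deliberately
*not* a tabulated cross-section database: the pipeline needs a
self-consistent forward/inverse pair with the correct structure (edge step,
white lines, linear Ca scaling, energy-independent background), not
beamline-accurate optics. Consequently the closed-loop recoveries validate
the analysis chain, not any absolute cross-section.

## XANES linear-combination fitting

Preprocessing follows standard practice: repeated scans are averaged
pointwise; the edge energy $E_0$ is the third peak of the first derivative
(Savitzky–Golay derivative on a uniform resampling, 1 eV window, peaks
prominence-filtered at 5% of the derivative range, falling back to the
global derivative maximum with a warning when fewer than three peaks
exist); normalization fits a linear pre-edge over $[E_0-25, E_0-13]$ eV
and a quadratic post-edge over $[E_0+26, E_0+90]$ eV, divides by the edge
step at $E_0$ and flattens the post-edge to fluctuate about 1. This makes
the result invariant to affine transforms of the raw intensity, which the
tests check exactly.

The fit itself minimizes the squared misfit of a target spectrum against a
non-negative, sum-to-one combination of reference spectra. The simplex
constraint is on by default: the fractional "relative contribution" read
off such fits presumes it, and it is a configuration switch for the
unconstrained variant. Because reference sets are small, the constrained
optimum is found exactly: the equality-constrained least-squares problem is
solved on every support subset via its KKT system and the feasible solution
with the smallest residual wins (ties to the smaller support). This is
deterministic and needs no starting point or tolerance tuning. The fit
window defaults to $[E_0-20, E_0+60]$ eV — a conventional XANES span;
the LCF window is exposed because no single value is canonical.
`compare_reference_sets()` ranks candidate reference sets by residual with
ties broken toward fewer references, which is how "adding an ACC reference
improves the fit" is made into a testable statement.

## Fourier shell correlation

`fsc()` computes the shell-wise normalized cross-correlation of the Fourier
coefficients of two independently reconstructed volumes (even/odd split),
over concentric shells up to Nyquist; non-cubic volumes are zero-padded.
Resolution is the first crossing of the 0.25 threshold (lowest frequency
where the curve drops below it), located by linear interpolation between
bracketing shells, and reported as half pitch, $1/(2 f_c)$. When the curve
never crosses, the sampling-limited value (two voxels) is returned with an
explicit flag rather than a fabricated crossing. The threshold is a plain
0.25 — not the 0.25-bit information criterion.

## The phantom generator

`make_cell_phantom()` builds a labelled ellipsoidal cell (default 64³
voxels at 40 nm) with nucleus, chloroplast, lipid body, a forming-coccolith
calcite annulus, a Ca–P body and an optional dilute "cloud" shell around
it. The defaults are the study conditions this package targets: a body of
exactly 1.5 µm³ (the body is the set of voxels nearest its centre whose
count matches the target volume, so the planted volume is exact to one
voxel) at 10 M Ca, a cloud at 1.5 M, calcite at its physical 27.08 M,
and a seawater medium containing 10 mM CaCl₂ (shipped as an editable YAML
recipe). The body's composition is built by inverting the electrolyte model
at the requested molarity, so the BSE forward render and the BSE inversion
share no code path with the planted value itself.

The EsB render is exactly affine in $\eta_\mathrm{eff}$ plus Gaussian grey
noise; the X-ray render integrates the L-edge model along an axis with
Gaussian or Poisson noise and optional integer per-frame drift (the first
frame is the drift reference); the K-edge generator mixes three synthetic
reference curves on the simplex. All renders are deterministic under a
fixed seed.

What the phantom does *not* emulate — and hence what passing tests do not
show about real data: detector nonlinearity and charging, beam damage,
partial-volume and point-spread blurring, segmentation error (masks are
ground truth here), missing-wedge artefacts, and real cross-section
energy dependence of the non-Ca matrix. The closed loops demonstrate that
the analysis chains are unbiased and correctly calibrated when their
modelling assumptions hold; they cannot certify the assumptions themselves.

## Problem sizes and noise levels used in the checks

The shipped tests and the acceptance script run: the BSE loop on the 64³
phantom with 5% grey noise over 20 seeds (recovered mean within 5% of
10 M; noise-free recovery exact); the X-ray loop at 13.4 M with a
13-frame scan (342 eV anchor plus 347.7–353.2 eV in 0.5 eV steps), 1%
intensity noise and ±2 px frame drift over 10 seeds (mean within 10%);
LCF with weights (0.5, 0.3, 0.2) and 1% noise over 50 seeds (mean
absolute weight error well below 0.03); and FSC on 24³ noise volumes plus
the reference curve crossing 0.25 at 0.0096 nm⁻¹ (52 nm half pitch).
These sizes keep the whole suite around ten seconds while leaving every
recovery comfortably inside its tolerance; all of them scale up by changing
`phantom_config()` arguments only.

## Known limitations

- The electrolyte density model treats ions as close-packed spheres at
  their ionic radii; it is a first-order approximation adequate for the
  molar-range concentrations targeted here, and the radius table is data,
  not code.
- Registration is integer-pixel and translation-only (the acquisition
  protocol it mirrors also restricted alignment to translations); subpixel
  drift appears as residual blur, not as a shift error.
- Two-frame difference maps without a connecting scan rely on shared
  contrast between the frames; with heavy noise, provide the full scan so
  the running-reference alignment can be used.
- The calcite calibration constant defaults to the conventional 27 M;
  closed-loop exactness tests calibrate against the phantom's exact value
  (27.08 M), a 0.3% difference that is invisible at the stated
  tolerances but worth knowing about.
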