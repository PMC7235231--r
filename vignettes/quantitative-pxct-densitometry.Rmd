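---
title: "Quantitative PXCT densitometry: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative PXCT densitometry: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Ptychographic X-ray computed tomography (PXCT) reconstructs the real part of
the X-ray refractive index, $n(\mathbf r) = 1 - \delta(\mathbf r) +
i\beta(\mathbf r)$, in three dimensions at tens-of-nanometre voxels. Away
from absorption edges $\delta$ is proportional to electron density, which in
turn is proportional to mass density through a composition-dependent factor.
This makes PXCT a *non-destructive densitometer*: inside an intact rock
fragment, one can measure the density of a micrometric fossil filament, of
the mineral crystals replacing it, and of the matrix around it — and from
those densities identify the materials.

`pxct` implements that analysis chain for silicified microfossil specimens
(kerogenous filaments, iron-oxide crystals and voids in a quartz matrix),
together with a synthetic phantom generator providing ground truth, so that
every stage is testable without beamline data.

# The physical model

Electron density from the phase volume:

$$ n_e(\mathbf r) = \frac{2\pi\,\delta(\mathbf r)}{\lambda^2 r_0}, $$

with $\lambda$ the wavelength and $r_0$ the classical electron radius.
Internally $\lambda$ and $r_0$ are held in Ångström so $n_e$ comes out in
e/Å³. Mass density follows from the molar mass per electron:

$$ \rho = \frac{n_e\,A}{N_A\,Z}, $$

where $A$ is the molar mass of the assumed composition and $Z$ its electron
count. The $A/Z$ ratio is ≈2 for light minerals (SiO₂: 2.00; Fe₂O₃, Fe₃O₄:
2.10) and lower for hydrogen-rich organics; the bundled model kerogen
composition C₁₇₅H₁₀₂O₉N₄S₂ gives 1.92. Both conversions are exact affine
maps, so a fitted Gaussian width propagates linearly into a density
uncertainty. Compositions are parsed against a fixed IUPAC-2021
standard-atomic-weight table bundled with the package, making $A/Z$
reproducible to the printed rounding.

Every conversion has an exact inverse (used by the phantom generator), and
the package's tests check the full $\rho \to n_e \to \delta \to n_e \to
\rho$ round trip to $10^{-10}$ relative.

# The analysis pipeline

`run_pipeline()` executes, in order:

1. **Input** — a simulated phantom or an NRRD phase volume.
2. **Tomography leg (optional)** — parallel-beam forward projection,
   per-projection constant+linear phase-ramp corruption and least-squares
   removal over the air margin, filtered back projection, and even/odd-split
   Fourier shell correlation for resolution.
3. **Electron density** — voxelwise $\delta \to n_e$.
4. **Segmentation** — pure intensity thresholding (no filtering, preserving
   the original density information). Thresholds are user-set or derived
   automatically.
5. **Partial-volume erosion** — each phase mask is shrunk by 3 voxels with a
   Euclidean ball (distance-transform thresholding).
6. **Histograms and Gaussian fits** — per-phase electron-density histograms,
   one Gaussian per phase; the whole-volume decomposition uses one Gaussian
   per expected phase.
7. **Air normalization** — the air component's center is subtracted from all
   centers, anchoring zero electron density.
8. **Densities, matching, classification** — centers map to g/cm³ under the
   per-phase composition hypotheses; candidates are ranked by $|\rho -
   \rho_{\mathrm{ref}}|$; carbonaceous phases are classified against the
   thermally-mature-kerogen window.

## Why erode by 3 voxels?

A voxel straddling a material interface records a mixture of the two
materials — the partial-volume effect. Boundary voxels therefore bias
per-phase statistics toward the neighbouring material, and the package's
regression tests show that bias directly (a thin-walled kerogen sheath's
fitted center moves toward the quartz value without erosion, and the bias
strictly shrinks with a 3-voxel erosion).

The depth comes from a continuum argument: a spherical particle of radius
$R$ has more voxels in its volume than on its surface when
$\tfrac{4\pi}{3}R^3/l^3 > 4\pi R^2/l^2$, i.e. $R > 3l$ for voxel width $l$.
`min_shrink_voxels()` returns this continuum solution (3), and
`discrete_shrink_oracle()` checks it by brute force on digitized spheres.
The discrete crossing depends on the boundary-connectivity convention used
to count "surface" voxels: comparing all sphere voxels against its
26-connected boundary shell puts the crossing at $R = 2$, bracketing the
continuum value from below (a 6-connected interior-versus-surface variant
crosses at 5 instead). The continuum value 3 is kept as the conservative
default erosion depth.

## Segmentation thresholds

The reference workflow sets thresholds manually. The automatic mode here
clusters the whole-volume histogram with a deterministic weighted 1-D
k-means (one class per expected phase) and cuts at class midpoints. This was
chosen over picking the K highest histogram peaks after observing that
partial-volume "bridges" between abundant phases can out-rank the genuine
peak of a scarce phase (iron-oxide crystals occupy well under 1% of the
volume); a clustering objective is insensitive to that failure mode. The
per-phase Gaussian fits after erosion, not the threshold positions, carry
the quantitative weight.

## Gaussian fitting

Fits are least squares on binned counts (sum of Gaussians, bounded
quasi-Newton, deterministic initialization from separated local maxima) —
matching the histogram-curve-fitting workflow of the reference analysis —
rather than an EM mixture fit on voxel values. Freedman–Diaconis binning is
the default; a fixed bin count can be forced. Degenerate cases are handled
explicitly: constant (noiseless) phases produce single-bin histograms and
fall back to voxel moments; overlapping components trigger a degeneracy
warning; a fit that fails to improve on its initialization is an error, not
a silent result.

Fitted widths are reported as the 1σ uncertainty of the density estimate
(the width of the distribution taken as the standard deviation), and
uncertainty propagation through $A/Z$ is exact.

# The synthetic phantom: the stated world

The generator mirrors the target acquisition: 28.53 nm voxels at 6.2 keV,
so a 35-voxel-diameter tube is a 1.0 µm filament. The canonical
four-phase scene (`gunflint_phantom_spec()`) holds, in a quartz pillar
(ρ = 2.66 g/cm³) surrounded by air:

* two kerogenous tubes (ρ = 1.50 g/cm³, composition C₁₇₅H₁₀₂O₉N₄S₂,
  diameters ~1 µm and ~0.7 µm), one with 20% peak-to-peak periodic radius
  modulation emulating septation-like constrictions;
* maghemite crystals (ρ = 4.87 g/cm³) with octahedral (L1-ball) and cubic
  (L∞-ball) habits;
* an ellipsoidal void inside the kerogen, emulating thermal-cracking
  porosity;
* an isotropic Gaussian PSF of FWHM 2 voxels (the partial-volume effect);
* additive i.i.d. Gaussian noise with σ = 2% of the matrix δ.

Hollow tube walls can carry seeded random angular gaps (a stand-in for the
qualitative "saw-tooth", discontinuous wall morphology of permineralized
sheaths; no quantitative roughness statistics exist to calibrate against,
so the gap fraction is an explicit, documented free parameter). All
randomness — wall gaps and noise — derives from the spec's single seed;
identical specs produce bit-identical volumes.

What a green phantom test does **not** establish: the noise is not
photon-accurate (no coherent-imaging statistics through a ptychographic
reconstruction), projections are born aligned (no registration errors), the
PSF is exactly Gaussian and isotropic, and phase boundaries are sharp below
the PSF. Recovery results on the phantom therefore validate the *analysis*,
not the beamline.

## Tomography-leg calibrations

Two parameters of the simulated acquisition are not stated anywhere and
were fixed once, by calibration against the stated world:

* **Projection noise.** The phantom states volume noise of 2% of the matrix
  δ. Per-projection noise is parameterized as a fraction of (matrix δ ×
  pillar diameter), and the default fraction 0.006 was calibrated so the
  FBP reconstruction carries ~2% of the matrix δ as noise in the matrix
  interior (the measured relation is linear: volume noise ≈ 3.4 × the
  projection fraction).
* **Angle count.** The canonical FSC experiment scales the reference
  acquisition's angular sampling density (1100 projections for a ~770-pixel
  detector width) to the phantom width — 137 angles at 96 voxels.

The quantification stage analyzes only the inscribed cylinder of an FBP
reconstruction: voxels outside the reconstruction circle receive partial
angular coverage and carry a positive haze that would otherwise contaminate
the air phase and, through air normalization, every density.

# Tomography

"Modified" filtered back projection in the reference workflow is not
specified further; the package implements textbook parallel-beam FBP
(band-limited Ram–Lak ramp filter from its real-space kernel, optional Hann
apodization, slice-by-slice bilinear backprojection), and checks itself
against analytic oracles — chord-length profiles of a uniform disc and
interior-mean recovery — rather than against beamline output. Conventions:
rotation about z, angle 0 projects along +y, voxel centers at integer
coordinates, projections in δ·nm.

Per-projection phase ramps ($a + bs + cz$) are removed by least squares
over air-only pixels, with the air mask derived from the pillar radius or
supplied explicitly. On noiseless data plane recovery is exact; under noise
the residual coefficients shrink as $1/\sqrt{\text{mask size}}$.

# Resolution by Fourier shell correlation

The projections are split into even/odd angular halves, each half is
reconstructed independently, and the two tomograms are correlated per
Fourier shell (one frequency voxel wide, raised-cosine spherical real-space
mask on by default to suppress box-edge correlation). The resolution is
read where the FSC first drops below the half-bit information threshold

$$ T(n) = \frac{0.2071 + 1.9102/\sqrt{n}}{1.2071 + 0.9102/\sqrt{n}}, $$

with $n$ the raw voxel count of the shell (masking is not folded into
$n$); $T \to 0.1716$ for large shells.

**Convention.** The package reports *half-period* resolution, $d = 1/(2
f^*)$ with $f^*$ the crossing frequency in cycles/nm. Under this convention
the sampling (Nyquist) floor is one voxel width — e.g. 28.53 nm — while
under the full-period convention ($d = 1/f^*$) the same floor reads as two
voxel widths. Published half-period values just below two voxel widths only
make sense in the half-period convention, which is why it is used here; the
acceptance tests assert the sampling floor in both forms ($1/(2f^*) \ge l$
and $1/f^* \ge 2l$) so the physical statement is convention-proof. If the
FSC never crosses the threshold the result is flagged Nyquist-limited; a
curve starting below threshold is flagged degenerate rather than raised as
an error.

# Filament morphometrics

Diameter homogeneity along a filament is a morphometric line of evidence
for biogenicity (cellular filaments hold a near-constant diameter over
their full three-dimensional extent; mineral veins and cracks do not).
`filament_diameter_profile()` traces the mask's centerline as slab
centroids along its principal axis and reads the local diameter as twice
the Euclidean distance transform maximum per slab. This is a deliberate
simplification of full 3-D skeletonization (no such primitive exists in
the installed package set): it is accurate for tubular, singly-connected,
moderately curved masks — the case it is used and tested for — and refuses
service on disconnected or non-filament-shaped masks (axial extent must
exceed four local radii). On a digitized 1 µm tube it recovers the
diameter within ~3% and a CV < 0.01; with 20% constrictions the CV rises
to ~0.07 while the mean is preserved within ~2%.

# Numerical choices

* Erosion uses the exact Euclidean distance transform
  (Felzenszwalb–Huttenlocher), not an iterated cubic structuring element:
  "in every direction" is read as isotropic.
* The PSF convolution runs in Fourier space on a volume padded by constant
  extension with the air value; an interior-supported phantom conserves
  total δ to $10^{-6}$ relative.
* The air component is identified as the lowest-center component by
  default and is overridable; if the air phase is lost (e.g. over-eroded),
  normalization is skipped and flagged rather than silently anchored to a
  non-air phase.
* Ties in candidate matching break lexicographically by name, making the
  ranking a total order independent of input order.
* Reports are serialized without timestamps; identical configuration and
  seed reproduce byte-identical JSON.

# Reference values bundled

The candidate table ships quartz 2.66, hematite 5.24, magnetite 5.18,
maghemite 4.87 g/cm³, and a mature-kerogen reference band 1.25–1.40 g/cm³.
The carbonaceous classifier instead uses the wider thermal-maturity window
1.19–1.77 g/cm³ (boundaries inclusive; >2 g/cm³ classified as
graphitic/amorphous). The band and the window come from different reference
contexts and are deliberately **not** reconciled: the table row is a
candidate-matching reference, the window a maturity classification.

# Known limitations

* Ptychographic phase retrieval, projection alignment and the absorption
  channel β are out of scope; the tomography leg starts from ideal aligned
  phase projections.
* Volume I/O is NRRD only (raw and ascii encodings); no TIFF stack support
  in the current R dependency set.
* The gap-fraction wall model and the noise model are stand-ins for
  qualitative observations, not fitted to data.
* Densities assume the hypothesized composition; a wrong hypothesis scales
  the density by the ratio of the $A/Z$ values (tested explicitly).
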