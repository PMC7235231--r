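# pxct — quantitative densitometry for ptychographic X-ray tomography

`pxct` is an R package for the quantitative analysis of ptychographic X-ray
computed tomography (PXCT) phase volumes of mineralized specimens — in
particular silicified microfossils, where the questions are: *what is this
micrometric structure made of, how dense is it, and is its morphology
consistent with a biological origin?*

PXCT delivers a 3-D map of the refractive-index decrement δ. Away from
absorption edges δ is proportional to electron density,

    n_e(r) = 2π δ(r) / (λ² r₀),

and electron density converts to mass density through the molar mass per
electron of an assumed composition,

    ρ = n_e · A / (N_A · Z),

with A/Z ≈ 2.00 for quartz, 2.10 for the iron oxides Fe₂O₃/Fe₃O₄, and 1.92
for a model thermally-mature kerogen C₁₇₅H₁₀₂O₉N₄S₂. Because different iron
oxides differ in density (hematite 5.24, magnetite 5.18, maghemite
4.87 g/cm³), a well-calibrated density measurement identifies the mineral;
because mature kerogen (1.19–1.77 g/cm³) is much lighter than graphitic or
amorphous carbon (>2 g/cm³), it also constrains the carbonaceous phase.

The package implements the full chain:

* **physics** — formula parsing against a bundled IUPAC atomic-weight
  table, δ ↔ electron density ↔ mass density conversions (exact inverses),
  mineral-candidate ranking, kerogen-maturity classification;
* **phantom** — a seeded synthetic-specimen generator (quartz pillar,
  kerogenous tubes with constrictions and wall gaps, octahedral/cubic
  iron-oxide crystals, voids, Gaussian PSF, additive noise) with full
  ground truth;
* **tomo** — parallel-beam forward projection, per-projection phase-ramp
  removal, filtered back projection (Ram–Lak / Hann), even/odd splitting;
* **resolution** — Fourier shell correlation with the half-bit threshold
  and half-period resolution estimation;
* **quantify** — threshold segmentation, 3-voxel partial-volume erosion
  (with the continuum derivation and a brute-force discrete oracle),
  histogram extraction, Gaussian decomposition with air normalization,
  per-phase density estimation, filament-diameter morphometrics;
* **pipeline** — `run_config()` / `run_pipeline()` orchestration, NRRD
  volume I/O, CSV/JSON artifacts, deterministic reports, and a thin CLI
  (`inst/cli/pxct`).

## Worked example

Simulate the canonical four-phase specimen (128³ voxels at 28.53 nm,
6.2 keV; quartz matrix, two kerogen filaments, maghemite crystals, a void;
PSF FWHM 2 voxels, noise 2% of the matrix δ) and run the full
quantification:

```r
library(pxct)
cfg <- run_config(phantom = gunflint_phantom_spec(seed = 3), seed = 3)
rep <- run_pipeline(cfg)
print(rep)
```

```
PXCT quantitative densitometry report
  air offset: 2.2232e-05 e/A^3
  air        n_e = 0.0000 e/A^3 (397080 vox, no material hypothesis)
  kerogen    rho = 1.500 +/- 0.051 g/cm^3 (n_e 0.4698 e/A^3, 111493 vox)  -> mature kerogen [mature_kerogen]
  matrix     rho = 2.660 +/- 0.053 g/cm^3 (n_e 0.7999 e/A^3, 823416 vox)  -> quartz (within 1 sigma)
  iron_oxide rho = 4.869 +/- 0.055 g/cm^3 (n_e 1.3956 e/A^3, 4504 vox)  -> maghemite (within 1 sigma)
```

Reading the report: each phase's electron-density histogram (after 3-voxel
erosion of its mask, which removes partial-volume boundary voxels) was
fitted with a Gaussian; centers were shifted so the air phase sits at zero;
centers ± 1σ were converted to mass densities under each phase's
composition hypothesis. All three material densities land on their ground
truth (1.50, 2.66, 4.87 g/cm³) to within 0.1%, and the iron-oxide phase
matches maghemite — not hematite or magnetite — within 1σ, reproducing the
density-based mineral discrimination this kind of analysis is for.

Filament morphometrics on a clean synthetic filament (1 µm nominal
diameter, 20% periodic constrictions):

```r
mat <- gunflint_materials()
spec <- phantom_spec(shape = c(80, 80, 120), inclusions = list(
  tube_inclusion(center = c(39.5, 39.5, 59.5), material = mat$kerogen,
                 radius = 17.5, constriction_period = 40,
                 constriction_amplitude = 0.2)),
  psf_fwhm_vox = 0, noise_sigma_frac = 0, pillar_radius_vox = 35, seed = 1)
m <- phase_mask(build_phantom(spec)$labels$data == 2, "filament", 28.53)
filament_diameter_profile(m)[c("mean_nm", "cv")]
#> $mean_nm  947.2
#> $cv       0.068
```

A near-constant diameter (low CV) along the full 3-D extent is the
morphometric signature of a cellular filament.

## Acceptance script

`scripts/acceptance.R` recomputes the package's headline quantities from
scratch using only the installed package: the A/Z ratios of the kerogen
model composition, quartz and the iron oxides, and the fitted matrix-phase
Gaussian width (in g/cm³) averaged over ten 128³ quartz-matrix phantoms
under the stated PSF and noise. Run it from the repository root:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Further reading

The methods vignette
(`vignettes/quantitative-pxct-densitometry.Rmd`) documents the model and
its assumptions, the shrink-rule derivation, all calibrated defaults, the
FSC resolution convention, and known limitations.
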