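# Shared fixture builders. Everything is generated in code at test time.

# a small cylinder volume: uniform delta disc replicated over z slices
cylinder_volume <- function(n = 64, radius = 20, nz = 8, delta = 1.4e-5,
                            voxel = 28.53) {
  ax <- seq_len(n) - (n + 1) / 2
  circ <- outer(ax^2, ax^2, "+") <= radius^2
  volume3d(array(rep(circ * delta, nz), dim = c(n, n, nz)), voxel, "delta")
}

# digitized sphere mask centered in an n^3 box
sphere_mask <- function(n, radius) {
  ax <- seq_len(n) - (n + 1) / 2
  outer(outer(ax^2, ax^2, "+"), ax^2, "+") <= radius^2
}

# a straight solid kerogen tube phantom along z
tube_phantom_spec <- function(shape = c(80, 80, 120), radius = 17.5, ...,
                              psf_fwhm_vox = 0, noise_sigma_frac = 0,
                              seed = 1) {
  mat <- gunflint_materials()
  phantom_spec(
    shape = shape,
    inclusions = list(tube_inclusion(
      center = (shape - 1) / 2, material = mat$kerogen, radius = radius, ...)),
    psf_fwhm_vox = psf_fwhm_vox, noise_sigma_frac = noise_sigma_frac,
    pillar_radius_vox = 0.44 * shape[1], seed = seed)
}

# quartz n_e at the reference density, e/A^3 (used all over)
quartz_ne <- function() electron_density_from_mass_density(2.66, "SiO2")
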