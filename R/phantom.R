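#' Materials for phantom construction
#'
#' A material pairs a name with a chemical composition and a nominal mass
#' density. Air is represented with zero density (its electron density is
#' ~3 orders of magnitude below solids and indistinguishable from vacuum at
#' the densities of interest).
#'
#' @param name material name.
#' @param formula chemical formula string (ignored for `rho = 0`).
#' @param rho_g_cm3 mass density, g/cm^3 (>= 0).
#' @return object of class `pxct_material`.
#' @export
#' @examples
#' material("quartz", "SiO2", 2.66)
material <- function(name, formula, rho_g_cm3) {
  stopifnot(is.character(name), rho_g_cm3 >= 0)
  comp <- if (rho_g_cm3 > 0) .as_composition(formula) else NULL
  structure(list(name = name, composition = comp, rho_g_cm3 = rho_g_cm3),
            class = "pxct_material")
}

#' Default material set for the silicified-microfossil scene
#'
#' Quartz matrix, model mature kerogen (composition C175H102O9N4S2, density
#' in the mature band), maghemite crystals, and air/void.
#'
#' @param kerogen_rho kerogen mass density, g/cm^3 (default 1.50, a mature
#'   value within 1.19-1.77).
#' @return named list of [material()] objects.
#' @export
gunflint_materials <- function(kerogen_rho = 1.50) {
  list(
    air       = material("air", NULL, 0),
    quartz    = material("quartz", "SiO2", 2.66),
    kerogen   = material("kerogen", "C175H102O9N4S2", kerogen_rho),
    maghemite = material("maghemite", "Fe2O3", 4.87),
    void      = material("void", NULL, 0)
  )
}

# ---- inclusion constructors -------------------------------------------------

#' Phantom inclusions
#'
#' Geometric primitives painted into the phantom in list order (later
#' inclusions overwrite earlier ones, so a void listed after its host tube
#' carves into it). Coordinates and lengths are in voxels; `center` is in
#' 0-based voxel units (voxel centers at integer coordinates).
#'
#' `tube_inclusion` models a filament: a (possibly hollow) cylinder along an
#' arbitrary axis with optional periodic radius modulation (constrictions
#' reminiscent of cell septation) and, for hollow walls, seeded random
#' angular gaps producing the discontinuous saw-tooth wall texture seen in
#' permineralized sheaths.
#'
#' @param center numeric length-3 center, voxels.
#' @param material a [material()].
#' @param axis tube axis direction (any length-3 vector, normalized
#'   internally).
#' @param radius outer tube radius, voxels.
#' @param length tube length, voxels (`Inf` spans the volume).
#' @param wall_thickness `NULL` for a solid rod, otherwise wall thickness in
#'   voxels (hollow sheath).
#' @param constriction_period period of radius modulation along the axis,
#'   voxels; 0 disables.
#' @param constriction_amplitude peak-to-peak radius modulation as a fraction
#'   of `radius` (in [0, 1)); the modulation is symmetric so the mean
#'   diameter is preserved.
#' @param wall_gap_fraction for hollow tubes, fraction of wall surface
#'   patches removed at random (seeded by the phantom spec), in [0, 1).
#' @return object of class `pxct_inclusion`.
#' @export
tube_inclusion <- function(center, material, axis = c(0, 0, 1), radius,
                           length = Inf, wall_thickness = NULL,
                           constriction_period = 0,
                           constriction_amplitude = 0,
                           wall_gap_fraction = 0) {
  stopifnot(radius > 0, constriction_amplitude >= 0,
            constriction_amplitude < 1,
            wall_gap_fraction >= 0, wall_gap_fraction < 1)
  if (constriction_amplitude * radius >= radius)
    stop("constriction amplitude must be smaller than the radius")
  structure(list(kind = "tube", center = center, material = material,
                 axis = axis / sqrt(sum(axis^2)), radius = radius,
                 length = length, wall_thickness = wall_thickness,
                 constriction_period = constriction_period,
                 constriction_amplitude = constriction_amplitude,
                 wall_gap_fraction = wall_gap_fraction),
            class = "pxct_inclusion")
}

#' @rdname tube_inclusion
#' @param half_size for `crystal_inclusion`: half-diagonal (octahedron, an L1
#'   ball) or half-edge (cube, an L-infinity ball), voxels.
#' @param kind crystal habit: `"octahedron"` or `"cube"`.
#' @param rotation optional 3x3 rotation matrix for crystal orientation
#'   (default axis-aligned).
#' @export
crystal_inclusion <- function(center, material, half_size,
                              kind = c("octahedron", "cube"),
                              rotation = NULL) {
  kind <- match.arg(kind)
  stopifnot(half_size > 0)
  if (!is.null(rotation))
    stopifnot(is.matrix(rotation), all(dim(rotation) == c(3, 3)))
  structure(list(kind = kind, center = center, material = material,
                 half_size = half_size, rotation = rotation),
            class = "pxct_inclusion")
}

#' @rdname tube_inclusion
#' @param semiaxes for `ellipsoid_inclusion`: length-3 semi-axis lengths,
#'   voxels. Used with a zero-density material this models the cracks/voids
#'   left by thermal cracking of mature kerogen.
#' @export
ellipsoid_inclusion <- function(center, material, semiaxes,
                                rotation = NULL) {
  stopifnot(length(semiaxes) == 3, all(semiaxes > 0))
  structure(list(kind = "ellipsoid_void", center = center,
                 material = material, semiaxes = semiaxes,
                 rotation = rotation),
            class = "pxct_inclusion")
}

#' @rdname tube_inclusion
#' @export
sphere_inclusion <- function(center, material, radius) {
  stopifnot(radius > 0)
  structure(list(kind = "sphere", center = center, material = material,
                 radius = radius),
            class = "pxct_inclusion")
}

# ---- phantom spec -----------------------------------------------------------

#' Declarative phantom specification
#'
#' Describes a synthetic specimen: a cylindrical pillar of matrix material
#' surrounded by air, a list of inclusions, the imaging point-spread function
#' and additive noise level, and a seed that fully determines the output.
#' Defaults mirror the acquisition geometry this package targets: 28.53 nm
#' voxels at 6.2 keV, so a tube of diameter 35 voxels is a ~1 um filament.
#'
#' @param shape integer length-3 volume dimensions, voxels.
#' @param beam a [beam_geometry()].
#' @param matrix_material [material()] filling the pillar.
#' @param inclusions list of inclusion objects (see [tube_inclusion()]).
#' @param psf_fwhm_vox isotropic Gaussian PSF full width at half maximum,
#'   voxels (>= 0, 0 = ideal imaging).
#' @param noise_sigma_frac additive Gaussian noise sigma as a fraction of the
#'   matrix delta (>= 0).
#' @param pillar_radius_vox radius of the specimen pillar; voxels outside
#'   (in x-y) are air. `NULL` defaults to 45% of the smaller lateral extent.
#' @param seed integer seed controlling wall gaps and noise.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128, 128, 128),
                         beam = beam_geometry(),
                         matrix_material = gunflint_materials()$quartz,
                         inclusions = list(),
                         psf_fwhm_vox = 2,
                         noise_sigma_frac = 0.02,
                         pillar_radius_vox = NULL,
                         seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape > 0),
            inherits(beam, "beam_geometry"),
            inherits(matrix_material, "pxct_material"),
            psf_fwhm_vox >= 0, noise_sigma_frac >= 0)
  if (is.null(pillar_radius_vox))
    pillar_radius_vox <- 0.45 * min(shape[1:2])
  stopifnot(pillar_radius_vox > 0,
            pillar_radius_vox <= min(shape[1:2]) / 2)
  for (inc in inclusions)
    stopifnot(inherits(inc, "pxct_inclusion"))
  structure(list(shape = shape, beam = beam,
                 matrix_material = matrix_material,
                 inclusions = inclusions,
                 psf_fwhm_vox = psf_fwhm_vox,
                 noise_sigma_frac = noise_sigma_frac,
                 pillar_radius_vox = pillar_radius_vox,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# run expr with a private RNG stream; global .Random.seed untouched
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# voxel coordinate grids (0-based, voxel centers at integers)
.coord_grids <- function(shape) {
  x <- seq_len(shape[1]) - 1
  y <- seq_len(shape[2]) - 1
  z <- seq_len(shape[3]) - 1
  list(
    X = array(rep(x, times = shape[2] * shape[3]), dim = shape),
    Y = array(rep(rep(y, each = shape[1]), times = shape[3]), dim = shape),
    Z = array(rep(z, each = shape[1] * shape[2]), dim = shape)
  )
}

.inclusion_mask <- function(inc, g, shape) {
  dx <- g$X - inc$center[1]
  dy <- g$Y - inc$center[2]
  dz <- g$Z - inc$center[3]
  if (!is.null(inc$rotation)) {
    R <- inc$rotation
    rx <- R[1, 1] * dx + R[1, 2] * dy + R[1, 3] * dz
    ry <- R[2, 1] * dx + R[2, 2] * dy + R[2, 3] * dz
    rz <- R[3, 1] * dx + R[3, 2] * dy + R[3, 3] * dz
    dx <- rx; dy <- ry; dz <- rz
  }
  switch(inc$kind,
    sphere = dx^2 + dy^2 + dz^2 <= inc$radius^2,
    cube = pmax(abs(dx), abs(dy), abs(dz)) <= inc$half_size,
    octahedron = abs(dx) + abs(dy) + abs(dz) <= inc$half_size,
    ellipsoid_void = (dx / inc$semiaxes[1])^2 + (dy / inc$semiaxes[2])^2 +
      (dz / inc$semiaxes[3])^2 <= 1,
    tube = .tube_mask(inc, dx, dy, dz),
    stop("unknown inclusion kind: ", inc$kind)
  )
}

.tube_mask <- function(inc, dx, dy, dz) {
  a <- inc$axis
  t <- dx * a[1] + dy * a[2] + dz * a[3]          # axial coordinate
  px <- dx - t * a[1]; py <- dy - t * a[2]; pz <- dz - t * a[3]
  r2 <- px^2 + py^2 + pz^2
  rloc <- inc$radius
  if (inc$constriction_period > 0 && inc$constriction_amplitude > 0)
    rloc <- inc$radius *
      (1 + inc$constriction_amplitude / 2 *
         sin(2 * pi * t / inc$constriction_period))
  inside <- r2 <= rloc^2 & abs(t) <= inc$length / 2
  if (!is.null(inc$wall_thickness)) {
    wall <- inside & r2 > pmax(rloc - inc$wall_thickness, 0)^2
    if (inc$wall_gap_fraction > 0) {
      # remove random surface patches: 16 angular sectors x axial bands
      nsec <- 16L
      band_len <- max(4, inc$radius)
      # angular coordinate around the axis
      ref <- if (abs(a[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      u <- ref - sum(ref * a) * a; u <- u / sqrt(sum(u^2))
      v <- c(a[2] * u[3] - a[3] * u[2], a[3] * u[1] - a[1] * u[3],
             a[1] * u[2] - a[2] * u[1])
      phi <- atan2(px * v[1] + py * v[2] + pz * v[3],
                   px * u[1] + py * u[2] + pz * u[3])
      sec <- pmin(floor((phi + pi) / (2 * pi) * nsec), nsec - 1)
      band <- floor((t - min(t[wall], 0)) / band_len)
      band <- band - min(band[wall], 0)
      nb <- max(band[wall]) + 1
      drop <- matrix(stats::runif(nb * nsec) < inc$wall_gap_fraction,
                     nrow = nb)
      gap <- wall & drop[cbind(band + 1, sec + 1)]
      wall <- wall & !gap
    }
    inside <- wall
  }
  inside
}

#' Build a labeled phantom volume with ground truth
#'
#' Paints the specification into a label volume: label 0 is air (outside the
#' pillar), label 1 the matrix, and labels 2, 3, ... the inclusions in list
#' order (painter's algorithm — later inclusions overwrite earlier ones).
#' Randomized features (wall gaps) are drawn from the spec's seed, so the
#' output is a pure function of the spec.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements
#'   \describe{
#'     \item{labels}{[volume3d()] label channel}
#'     \item{materials}{named-by-label list of [material()]s}
#'     \item{truth}{per-label masks, true densities (rho, n_e, delta) and
#'       volume fractions}
#'   }
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  g <- .coord_grids(shape)
  cx <- (shape[1] - 1) / 2; cy <- (shape[2] - 1) / 2
  pillar <- (g$X - cx)^2 + (g$Y - cy)^2 <= spec$pillar_radius_vox^2

  lab <- array(0L, dim = shape)
  lab[pillar] <- 1L

  # bounds check (finite-extent inclusions must fit inside the volume)
  for (i in seq_along(spec$inclusions)) {
    inc <- spec$inclusions[[i]]
    ext <- switch(inc$kind,
      sphere = rep(inc$radius, 3),
      cube = rep(inc$half_size * if (is.null(inc$rotation)) 1 else sqrt(3), 3),
      octahedron = rep(inc$half_size, 3),
      ellipsoid_void = rep(max(inc$semiaxes), 3),
      tube = rep(inc$radius * (1 + inc$constriction_amplitude / 2), 3))
    ok <- all(inc$center - ext >= -0.5 | inc$kind == "tube") &&
      all(inc$center >= -0.5) && all(inc$center <= shape - 0.5)
    if (inc$kind != "tube")
      ok <- ok && all(inc$center - ext >= -0.5) &&
        all(inc$center + ext <= shape - 0.5)
    if (!ok)
      stop("inclusion ", i, " (", inc$kind, ") extends outside the volume")
  }

  masks <- .with_seed(spec$seed, {
    lapply(spec$inclusions, .inclusion_mask, g = g, shape = shape)
  })
  for (i in seq_along(masks)) lab[masks[[i]]] <- i + 1L

  materials <- c(list(gunflint_materials()$air, spec$matrix_material),
                 lapply(spec$inclusions, `[[`, "material"))
  names(materials) <- as.character(seq_along(materials) - 1L)

  truth_masks <- lapply(seq_along(materials) - 1L, function(l) lab == l)
  names(truth_masks) <- vapply(materials, `[[`, "", "name")
  nvox <- prod(shape)
  truth <- list(
    masks = truth_masks,
    rho = vapply(materials, `[[`, numeric(1), "rho_g_cm3"),
    n_e = vapply(materials, function(m)
      if (m$rho_g_cm3 > 0)
        electron_density_from_mass_density(m$rho_g_cm3, m$composition)
      else 0, numeric(1)),
    volume_fractions = vapply(truth_masks, function(m) sum(m) / nvox,
                              numeric(1))
  )
  truth$delta <- delta_from_electron_density(truth$n_e, spec$beam)

  list(labels = volume3d(lab, spec$beam$voxel_size_nm, "label"),
       materials = materials, truth = truth)
}

#' Convert a label volume to a refractive-index decrement map
#'
#' Each voxel takes the delta of its material at the given beam energy
#' (computed from the material density and composition), producing the
#' piecewise-constant ideal phase volume.
#'
#' @param labels label-channel [volume3d()].
#' @param materials list of [material()]s named by label value (as produced
#'   by [build_phantom()]).
#' @param beam a [beam_geometry()].
#' @return delta-channel [volume3d()].
#' @export
assign_densities <- function(labels, materials, beam) {
  stopifnot(inherits(labels, "volume3d"), labels$channel == "label")
  present <- sort(unique(as.vector(labels$data)))
  missing <- setdiff(as.character(present), names(materials))
  if (length(missing))
    stop("no material mapped for label(s): ", paste(missing, collapse = ", "))
  deltas <- vapply(materials, function(m) {
    if (m$rho_g_cm3 == 0) 0
    else delta_from_mass_density(m$rho_g_cm3, m$composition, beam)
  }, numeric(1))
  lut <- stats::setNames(deltas, names(materials))
  out <- array(lut[as.character(labels$data)], dim = dim(labels$data))
  volume3d(out, labels$voxel_size_nm, "delta")
}

#' Apply an isotropic Gaussian point-spread function
#'
#' Models the finite imaging resolution responsible for the partial-volume
#' effect: voxels near material interfaces take intermediate values. The
#' convolution is performed in Fourier space on a volume padded by constant
#' extension with the air value, so an interior-supported phantom conserves
#' its total delta.
#'
#' @param vol a [volume3d()] (delta or electron-density channel).
#' @param fwhm_vox Gaussian FWHM in voxels (>= 0; 0 returns the input).
#' @param air_value pad value used for constant extension (default 0).
#' @return blurred [volume3d()], same channel.
#' @export
apply_psf <- function(vol, fwhm_vox, air_value = 0) {
  stopifnot(inherits(vol, "volume3d"))
  if (fwhm_vox < 0) stop("PSF FWHM must be non-negative")
  if (fwhm_vox == 0) return(vol)
  sigma <- fwhm_vox / (2 * sqrt(2 * log(2)))
  pad <- ceiling(4 * sigma)
  d <- dim(vol$data)
  dp <- d + 2L * pad
  big <- array(air_value, dim = dp)
  big[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <-
    vol$data
  # replicate edge planes so constant extension holds beyond the pad too
  kern1 <- function(n) {
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    k <- exp(-x^2 / (2 * sigma^2))
    k / sum(k)
  }
  K <- outer(outer(kern1(dp[1]), kern1(dp[2])), kern1(dp[3]))
  dim(K) <- dp
  sm <- Re(stats::fft(stats::fft(big) * stats::fft(K), inverse = TRUE)) /
    prod(dp)
  out <- sm[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])]
  volume3d(out, vol$voxel_size_nm, vol$channel)
}

#' Add i.i.d. Gaussian noise
#'
#' Emulates reconstruction noise in the phase volume. Deterministic given the
#' seed; the global RNG state is left untouched.
#'
#' @param vol a [volume3d()].
#' @param sigma noise standard deviation in the volume's units (>= 0).
#' @param seed integer seed.
#' @return noisy [volume3d()].
#' @export
add_noise <- function(vol, sigma, seed = 1L) {
  stopifnot(inherits(vol, "volume3d"), sigma >= 0)
  if (sigma == 0) return(vol)
  noise <- .with_seed(seed, stats::rnorm(length(vol$data), sd = sigma))
  volume3d(vol$data + array(noise, dim = dim(vol$data)),
           vol$voxel_size_nm, vol$channel)
}

#' Canonical four-phase microfossil phantom
#'
#' The in-silico stand-in for an iron-mineralized filamentous microfossil
#' pillar: quartz matrix, two kerogenous filaments of ~1 um diameter (35
#' voxels at 28.53 nm) with periodic constrictions, maghemite crystals with
#' octahedral and cubic habits, a thermal-cracking void inside the kerogen,
#' and surrounding air.
#'
#' @param shape volume dimensions (default 128^3).
#' @param kerogen_rho kerogen density, g/cm^3.
#' @param psf_fwhm_vox,noise_sigma_frac,seed passed to [phantom_spec()].
#' @return a [phantom_spec()].
#' @export
gunflint_phantom_spec <- function(shape = c(128, 128, 128),
                                  kerogen_rho = 1.50,
                                  psf_fwhm_vox = 2,
                                  noise_sigma_frac = 0.02,
                                  seed = 1L) {
  mat <- gunflint_materials(kerogen_rho)
  c0 <- (shape - 1) / 2
  sc <- shape[1] / 128   # scale positions for other volume sizes
  inclusions <- list(
    tube_inclusion(center = c0 + c(-20, 0, 0) * sc, material = mat$kerogen,
                   axis = c(0, 0.15, 1), radius = 17.5 * sc,
                   constriction_period = 40 * sc,
                   constriction_amplitude = 0.2),
    tube_inclusion(center = c0 + c(24, 18, 0) * sc, material = mat$kerogen,
                   axis = c(0.1, -0.1, 1), radius = 12 * sc),
    crystal_inclusion(center = c0 + c(24, -24, 26) * sc,
                      material = mat$maghemite, half_size = 16 * sc,
                      kind = "octahedron"),
    crystal_inclusion(center = c0 + c(20, -20, -30) * sc,
                      material = mat$maghemite, half_size = 10 * sc,
                      kind = "cube"),
    ellipsoid_inclusion(center = c0 + c(-20, 0, 20) * sc,
                        material = mat$void,
                        semiaxes = c(6, 4, 10) * sc)
  )
  phantom_spec(shape = shape, matrix_material = mat$quartz,
               inclusions = inclusions, psf_fwhm_vox = psf_fwhm_vox,
               noise_sigma_frac = noise_sigma_frac, seed = seed)
}

#' Simulate the imaged phase volume for a phantom
#'
#' Chains [build_phantom()], [assign_densities()], [apply_psf()] and
#' [add_noise()] (noise sigma = `noise_sigma_frac` times the matrix delta),
#' returning the ideal and degraded delta volumes with ground truth.
#'
#' @param spec a [phantom_spec()].
#' @return list `labels`, `materials`, `truth`, `delta_ideal`, `delta`
#'   (PSF + noise applied).
#' @export
simulate_phantom <- function(spec) {
  ph <- build_phantom(spec)
  ideal <- assign_densities(ph$labels, ph$materials, spec$beam)
  degraded <- apply_psf(ideal, spec$psf_fwhm_vox)
  matrix_delta <- delta_from_mass_density(spec$matrix_material$rho_g_cm3,
                                          spec$matrix_material$composition,
                                          spec$beam)
  degraded <- add_noise(degraded, spec$noise_sigma_frac * matrix_delta,
                        seed = spec$seed + 1L)
  c(ph, list(delta_ideal = ideal, delta = degraded))
}
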