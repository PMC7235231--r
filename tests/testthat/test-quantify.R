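test_that("threshold segmentation partitions the volume exactly", {
  set.seed(21)
  vol <- volume3d(array(stats::runif(20^3), c(20, 20, 20)), 10,
                  "electron_density")
  masks <- threshold_segment(vol, c(0.3, 0.7))
  expect_length(masks, 3)
  total <- Reduce(`+`, lapply(masks, function(m) m$mask * 1L))
  expect_true(all(total == 1))                        # exact partition
  expect_true(all(vol$data[masks[[1]]$mask] < 0.3))
  expect_true(all(vol$data[masks[[2]]$mask] >= 0.3 &
                    vol$data[masks[[2]]$mask] < 0.7))
  expect_error(threshold_segment(vol, c(0.7, 0.3)), "increasing")
  # no thresholds: single whole-volume mask
  one <- threshold_segment(vol)
  expect_length(one, 1)
  expect_identical(one[[1]]$n_voxels, 8000L)
})

test_that("shrink rule: continuum solution is 3, discrete oracle brackets it", {
  expect_identical(min_shrink_voxels(), 3L)
  oracle <- discrete_shrink_oracle(1:10)
  expect_gte(oracle$radius, 2)
  expect_lte(oracle$radius, 4)
  # default pipeline wiring uses the continuum value
  expect_identical(formals(erode_mask)$depth, quote(min_shrink_voxels()))
  expect_identical(formals(run_config)$erosion_depth,
                   quote(min_shrink_voxels()))
})

test_that("erosion is anti-extensive, decreasing in depth, and isotropic", {
  m <- phase_mask(sphere_mask(25, 10), "sphere", 10)
  e0 <- erode_mask(m, 0)
  expect_identical(e0$mask, m$mask)
  e3 <- erode_mask(m, 3)
  expect_true(all(m$mask[e3$mask]))                   # output subset of input
  # voxel count close to a radius-7 sphere
  expect_equal(e3$n_voxels / sum(sphere_mask(25, 7)), 1, tolerance = 0.05)
  # decreasing in depth
  counts <- vapply(0:5, function(d) erode_mask(m, d)$n_voxels, integer(1))
  expect_true(all(diff(counts) < 0))
  # full-volume mask: erosion bites in from the array border
  full <- phase_mask(array(TRUE, c(12, 12, 12)), "full", 10)
  ef <- erode_mask(full, 3)
  idx <- which(ef$mask, arr.ind = TRUE)
  expect_true(all(idx >= 4 & idx <= 9))
})

test_that("over-eroded masks are empty and flagged, not an error", {
  spec <- tube_phantom_spec(shape = c(32, 32, 48), radius = 3)
  ph <- build_phantom(spec)
  m <- phase_mask(ph$labels$data == 2, "thin", 28.53)
  e <- erode_mask(m, 3)
  expect_true(e$empty)
  expect_identical(e$n_voxels, 0L)
})

test_that("histogram extraction preserves counts and means", {
  vol <- volume3d(array(1.5, c(10, 10, 10)), 10, "electron_density")
  m <- phase_mask(array(TRUE, c(10, 10, 10)), "all", 10)
  h <- extract_histogram(vol, m, bins = 8)
  expect_identical(sum(h$counts), 1000L)
  expect_identical(sum(h$counts > 0), 1L)            # constant -> one bin

  set.seed(33)
  noisy <- volume3d(array(1.5 + stats::rnorm(1000, sd = 0.05),
                          c(10, 10, 10)), 10, "electron_density")
  h2 <- extract_histogram(noisy, m)
  hist_mean <- sum(h2$mids * h2$counts) / sum(h2$counts)
  expect_lt(abs(hist_mean - mean(noisy$data)), mean(diff(h2$breaks)))
  empty <- phase_mask(array(FALSE, c(10, 10, 10)), "none", 10)
  expect_error(extract_histogram(vol, empty), "empty")
})

test_that("Gaussian fitting recovers an exact single component", {
  # exact Gaussian histogram (counts evaluated from the curve, no sampling):
  # center must come back to within 0.1% of sigma
  mids <- seq(0.70, 0.90, length.out = 201)
  bw <- mids[2] - mids[1]
  h <- structure(list(
    breaks = c(mids - bw / 2, max(mids) + bw / 2), mids = mids,
    counts = 1e5 * bw * stats::dnorm(mids, 0.8, 0.016),
    units = "electron_density", label = "exact",
    components = NULL, residual = NA_real_), class = "histogram_model")
  fit <- fit_gaussians(h, 1)
  expect_lt(abs(fit$components$center - 0.8), 0.001 * 0.016)
  expect_equal(fit$components$sigma, 0.016, tolerance = 0.005)

  # sampled version: center within a few sigma/sqrt(n)
  set.seed(44)
  x <- stats::rnorm(2e5, mean = 0.8, sd = 0.016)
  vol <- volume3d(array(x[1:195112], c(58, 58, 58)), 10, "electron_density")
  m <- phase_mask(array(TRUE, dim(vol$data)), "all", 10)
  hs <- fit_gaussians(extract_histogram(vol, m), 1)
  expect_equal(hs$components$center, 0.8, tolerance = 5 * 0.016 / sqrt(2e5))
  expect_equal(hs$components$sigma, 0.016, tolerance = 0.02)
})

test_that("four-phase mixture: all centers recovered within 1%", {
  # air, kerogen, quartz, maghemite at their true electron densities
  true_ne <- c(0,
               electron_density_from_mass_density(1.50, "C175H102O9N4S2"),
               quartz_ne(),
               electron_density_from_mass_density(4.87, "Fe2O3"))
  set.seed(55)
  counts <- c(3e5, 1e5, 8e5, 5e4)
  vals <- unlist(mapply(function(mu, n) stats::rnorm(n, mu, 0.018),
                        true_ne, counts))
  n <- length(vals)
  vol <- volume3d(array(vals, c(n, 1, 1)), 10, "electron_density")
  m <- phase_mask(array(TRUE, c(n, 1, 1)), "all", 10)
  h <- fit_gaussians(extract_histogram(vol, m, bins = 400), 4)
  got <- sort(h$components$center)
  expect_equal(got[1], 0, tolerance = 0.01 * max(true_ne))
  for (i in 2:4)
    expect_equal(got[i], sort(true_ne)[i], tolerance = 0.01)
  # deterministic: same inputs, same fit
  h2 <- fit_gaussians(extract_histogram(vol, m, bins = 400), 4)
  expect_identical(h$components, h2$components)
})

test_that("overlapping identical components trigger the degeneracy warning", {
  set.seed(66)
  vals <- stats::rnorm(5e4, 1, 0.05)
  vol <- volume3d(array(vals, c(length(vals), 1, 1)), 10, "electron_density")
  m <- phase_mask(array(TRUE, dim(vol$data)), "all", 10)
  h <- extract_histogram(vol, m, bins = 100)
  expect_warning(fit_gaussians(h, 2, init = c(0.99, 1.01)), "degenerate")
})

test_that("air normalization anchors the density scale", {
  comp <- data.frame(center = c(0.02, 0.49, 0.82), sigma = rep(0.01, 3))
  out <- air_normalize(comp)
  expect_equal(out$offset, 0.02)
  expect_equal(out$components$center, c(0, 0.47, 0.80))
  # already-zero air is the identity
  out0 <- air_normalize(out$components)
  expect_equal(out0$offset, 0)
  # a global offset does not change the final densities
  shifted <- comp
  shifted$center <- shifted$center + 0.37
  expect_equal(air_normalize(shifted)$components$center,
               out$components$center, tolerance = 1e-12)
})

test_that("ramp-induced offsets cancel after air normalization end-to-end", {
  spec <- phantom_spec(shape = c(64, 64, 64), inclusions = list(),
                       psf_fwhm_vox = 2, noise_sigma_frac = 0.02,
                       pillar_radius_vox = 24, seed = 12)
  sim <- pxct:::simulate_phantom(spec)
  # a residual constant phase offset survives into the volume
  offset_delta <- 2e-6
  ne <- volume3d(electron_density_from_delta(sim$delta$data + offset_delta,
                                             spec$beam),
                 28.53, "electron_density")
  masks <- threshold_segment(ne, mean(range(ne$data)),
                             labels = c("air", "matrix"))
  comp <- do.call(rbind, lapply(masks, function(m) {
    fit_gaussians(extract_histogram(ne, erode_mask(m, 3)), 1)$components
  }))
  normed <- air_normalize(comp)$components
  rho <- mass_density_from_electron_density(normed$center[2], "SiO2")
  expect_equal(rho, 2.66, tolerance = 0.01)
})

test_that("phase density estimates map components through A/Z correctly", {
  est <- estimate_phase_density(quartz_ne(), 0.016, "SiO2")
  expect_equal(est$mass_density, 2.66, tolerance = 1e-10)
  est2 <- estimate_phase_density(quartz_ne(), 0.032, "SiO2")
  expect_equal(est2$mass_density_sigma, 2 * est$mass_density_sigma,
               tolerance = 1e-12)
  # hypothesis matters: kerogen A/Z vs quartz A/Z
  ne_k <- electron_density_from_mass_density(1.50, "C175H102O9N4S2")
  wrong <- estimate_phase_density(ne_k, 0.01, "SiO2")
  right <- estimate_phase_density(ne_k, 0.01, "C175H102O9N4S2")
  expect_equal(wrong$mass_density / right$mass_density,
               a_over_z("SiO2") / a_over_z("C175H102O9N4S2"),
               tolerance = 1e-10)
})

test_that("filament diameter profile: solid and constricted tubes", {
  m <- phase_mask(build_phantom(tube_phantom_spec())$labels$data == 2,
                  "ker", 28.53)
  pr <- filament_diameter_profile(m)
  expect_equal(pr$mean_nm, 35 * 28.53, tolerance = 0.05)
  expect_lt(pr$cv, 0.1)

  mc <- phase_mask(build_phantom(tube_phantom_spec(
    constriction_period = 40, constriction_amplitude = 0.2))$labels$data == 2,
    "ker", 28.53)
  prc <- filament_diameter_profile(mc)
  expect_gt(prc$cv, 0.04)                      # modulation shows up in CV
  expect_equal(prc$mean_nm, pr$mean_nm, tolerance = 0.05)  # mean preserved

  expect_error(filament_diameter_profile(
    phase_mask(array(FALSE, c(8, 8, 8)), "none", 10)), "empty")
})

test_that("filament profile rejects non-filament masks", {
  sp <- phase_mask(sphere_mask(31, 10), "sphere", 28.53)
  expect_error(filament_diameter_profile(sp), "filament|degenerate")
  two <- sphere_mask(41, 5)
  two[2:4, 2:4, 2:4] <- TRUE                    # a second, distant blob
  expect_error(filament_diameter_profile(phase_mask(two, "two", 28.53)),
               "connected")
})

test_that("3-voxel erosion strictly reduces partial-volume bias", {
  # thin-walled kerogen sheath in quartz: boundary voxels mix toward the
  # matrix; erosion must shrink that bias
  mat <- gunflint_materials()
  spec <- phantom_spec(shape = c(96, 96, 96), inclusions = list(
    tube_inclusion(center = c(47.5, 47.5, 47.5), material = mat$kerogen,
                   radius = 14, wall_thickness = 8)),
    psf_fwhm_vox = 2, noise_sigma_frac = 0.01, pillar_radius_vox = 42,
    seed = 4)
  sim <- pxct:::simulate_phantom(spec)
  ne <- volume3d(electron_density_from_delta(sim$delta$data, spec$beam),
                 28.53, "electron_density")
  km <- phase_mask(sim$labels$data == 2, "kerogen", 28.53)
  true_ne <- unname(sim$truth$n_e[3])
  bias_at <- function(depth) {
    h <- fit_gaussians(extract_histogram(ne, erode_mask(km, depth)), 1)
    abs(h$components$center - true_ne)
  }
  expect_lt(bias_at(3), bias_at(0))
  # and the uneroded center is biased toward the matrix value
  h0 <- fit_gaussians(extract_histogram(ne, km), 1)
  expect_gt(h0$components$center, true_ne)
})
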