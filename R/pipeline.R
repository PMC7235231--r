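#' Pipeline run configuration
#'
#' Bundles every knob of the end-to-end analysis: the input (a phantom spec
#' or a volume file), the optional tomography simulation leg, FSC resolution
#' estimation, segmentation, erosion depth, Gaussian decomposition, material
#' hypotheses and candidate matching.
#'
#' @param phantom a [phantom_spec()] (ignored when `input_path` given).
#' @param input_path optional NRRD volume to analyze instead of a phantom.
#' @param tomography simulate the acquisition: forward project, (optionally
#'   ramp-corrupt/correct), add projection noise, FBP-reconstruct, and run
#'   the rest of the pipeline on the reconstruction.
#' @param n_angles,filter tomography settings (see [fbp_reconstruct()]).
#' @param projection_noise_frac per-projection Gaussian noise sigma as a
#'   fraction of the matrix delta times the pillar diameter (a typical
#'   specimen path length); 0 disables. The default 0.006 is calibrated so
#'   the FBP reconstruction carries ~2% of the matrix delta as noise,
#'   matching the phantom's stated volume-noise level.
#' @param simulate_ramps add seeded per-projection constant+linear phase
#'   ramps before correction, exercising the ramp-removal stage.
#' @param do_fsc estimate resolution by even/odd split FSC (requires
#'   `tomography = TRUE`).
#' @param thresholds segmentation cut points in e/Angstrom^3, or `NULL` to
#'   derive them from crossings of a Gaussian decomposition of the
#'   whole-volume histogram.
#' @param n_phases number of material phases (air included).
#' @param erosion_depth partial-volume erosion depth, voxels.
#' @param hypotheses character vector of composition formulas per phase in
#'   ascending-density order (`NA` for air/void phases, which get no mass
#'   density).
#' @param phase_names optional phase names, ascending-density order.
#' @param candidates mineral candidate table (data.frame) or path to a CSV.
#' @param k_sigma candidate consistency threshold, in sigma.
#' @param out_dir directory for artifacts (histograms CSV, FSC CSV, report
#'   JSON, masks); `NULL` writes nothing.
#' @param seed integer master seed for all stochastic stages.
#' @return object of class `run_config`.
#' @export
run_config <- function(phantom = gunflint_phantom_spec(),
                       input_path = NULL,
                       tomography = FALSE,
                       n_angles = 180,
                       filter = "ram-lak",
                       projection_noise_frac = 0.006,
                       simulate_ramps = FALSE,
                       do_fsc = FALSE,
                       thresholds = NULL,
                       n_phases = 4,
                       erosion_depth = min_shrink_voxels(),
                       hypotheses = c(NA, "C175H102O9N4S2", "SiO2", "Fe2O3"),
                       phase_names = c("air", "kerogen", "matrix",
                                       "iron_oxide"),
                       candidates = NULL,
                       k_sigma = 1,
                       out_dir = NULL,
                       seed = 1L) {
  if (do_fsc && !tomography)
    stop("FSC resolution estimation requires tomography = TRUE")
  stopifnot(n_phases >= 1, length(hypotheses) == n_phases,
            length(phase_names) == n_phases, erosion_depth >= 0)
  if (!is.null(input_path) && !file.exists(input_path))
    stop("input volume does not exist: ", input_path)
  if (is.character(candidates)) candidates <- mineral_candidates(candidates)
  structure(list(phantom = phantom, input_path = input_path,
                 tomography = tomography, n_angles = n_angles,
                 filter = filter,
                 projection_noise_frac = projection_noise_frac,
                 simulate_ramps = simulate_ramps, do_fsc = do_fsc,
                 thresholds = thresholds, n_phases = n_phases,
                 erosion_depth = erosion_depth, hypotheses = hypotheses,
                 phase_names = phase_names, candidates = candidates,
                 k_sigma = k_sigma, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

# stable hash of the semantically meaningful configuration
.config_hash <- function(config) {
  x <- config[setdiff(names(config), "out_dir")]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(x), collapse = "\n"), tmp)
  unname(tools::md5sum(tmp))
}

# deterministic weighted 1D k-means (Lloyd) on histogram bins; robust to
# hugely imbalanced phase fractions where raw peak height fails
.kmeans_thresholds <- function(h, k) {
  x <- h$mids
  w <- as.numeric(h$counts)
  ctr <- seq(min(x), max(x), length.out = k + 2)[seq_len(k) + 1]
  for (it in seq_len(500)) {
    bounds <- (ctr[-1] + ctr[-k]) / 2
    grp <- findInterval(x, bounds) + 1
    new_ctr <- vapply(seq_len(k), function(j) {
      sel <- grp == j
      if (!any(sel) || sum(w[sel]) == 0) ctr[j]
      else sum(w[sel] * x[sel]) / sum(w[sel])
    }, numeric(1))
    if (max(abs(new_ctr - ctr)) < 1e-12) break
    ctr <- sort(new_ctr)
  }
  (ctr[-1] + ctr[-k]) / 2
}

# thresholds from crossings of adjacent fitted Gaussians (fall back to the
# midpoint when the analytic crossing is outside the bracket)
.component_crossings <- function(comp) {
  k <- nrow(comp)
  vapply(seq_len(k - 1), function(i) {
    c1 <- comp$center[i]; s1 <- comp$sigma[i]; a1 <- comp$amplitude[i]
    c2 <- comp$center[i + 1]; s2 <- comp$sigma[i + 1]; a2 <- comp$amplitude[i + 1]
    f <- function(x) {
      a1 * exp(-(x - c1)^2 / (2 * s1^2)) - a2 * exp(-(x - c2)^2 / (2 * s2^2))
    }
    mid <- (c1 + c2) / 2
    out <- tryCatch({
      if (f(c1) > 0 && f(c2) < 0)
        stats::uniroot(f, c(c1, c2))$root
      else mid
    }, error = function(e) mid)
    out
  }, numeric(1))
}

#' Run the full quantitative densitometry pipeline
#'
#' Executes phantom simulation (or volume loading), the optional tomography
#' leg (forward projection, ramp removal, FBP, even/odd FSC), conversion to
#' electron density, threshold segmentation, partial-volume erosion,
#' per-phase histogram extraction, Gaussian fitting, air normalization,
#' mass-density estimation under the configured hypotheses, mineral
#' candidate matching, and carbonaceous classification.
#'
#' @param config a [run_config()].
#' @return object of class `pxct_report` (see Details), invisibly also
#'   written to `config$out_dir` when set.
#'
#' @details The report carries, per phase: the fitted electron-density
#' component (air-normalized), the mass-density estimate with 1-sigma
#' uncertainty, the ranked candidate matches, and for carbonaceous
#' hypotheses the density classification. Global entries: the air offset,
#' FSC resolution (when enabled), the config hash, seed and stage log.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- character()
  t0 <- Sys.time()
  note <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, sprintf("[%6.1fs] %s",
                           as.numeric(Sys.time() - t0, units = "secs"), msg))
  }
  flags <- character()

  # ---- input ----------------------------------------------------------------
  truth <- NULL
  if (!is.null(config$input_path)) {
    vol <- read_volume(config$input_path)
    beam <- beam_geometry(voxel_size_nm = vol$voxel_size_nm)
    pillar_radius <- 0.45 * min(dim(vol$data)[1:2])
    note("loaded volume %s (%s)", config$input_path,
         paste(dim(vol$data), collapse = "x"))
  } else {
    spec <- config$phantom
    beam <- spec$beam
    pillar_radius <- spec$pillar_radius_vox
    sim <- simulate_phantom(spec)
    vol <- sim$delta
    truth <- sim$truth
    note("simulated phantom %s, %d inclusions, PSF %.3g vox, noise %.3g",
         paste(spec$shape, collapse = "x"), length(spec$inclusions),
         spec$psf_fwhm_vox, spec$noise_sigma_frac)
  }

  # ---- tomography leg -------------------------------------------------------
  fsc_res <- NULL
  if (config$tomography) {
    proj <- forward_project(vol, n_angles = config$n_angles)
    note("forward projected %d angles", config$n_angles)
    if (config$simulate_ramps) {
      rm_mod <- .with_seed(config$seed + 11L, ramp_model(
        offset = stats::rnorm(config$n_angles, sd = 50),
        slope_s = stats::rnorm(config$n_angles, sd = 0.5),
        slope_z = stats::rnorm(config$n_angles, sd = 0.5)))
      proj <- add_ramp(proj, rm_mod)
      note("added simulated phase ramps")
    }
    if (config$projection_noise_frac > 0) {
      matrix_delta <- if (!is.null(truth)) unname(truth$delta[2])
        else stats::quantile(vol$data, 0.75, names = FALSE)
      sigma <- config$projection_noise_frac * matrix_delta *
        2 * pillar_radius * beam$voxel_size_nm
      proj <- add_projection_noise(proj, sigma, seed = config$seed + 7L)
      note("added projection noise sigma = %.3g delta*nm", sigma)
    }
    rc <- remove_ramp(proj, pillar_radius_vox = pillar_radius)
    proj <- rc$projections
    note("removed per-projection phase ramps")
    if (config$do_fsc) {
      halves <- split_even_odd(proj)
      recA <- fbp_reconstruct(halves$even, filter = config$filter)
      recB <- fbp_reconstruct(halves$odd, filter = config$filter)
      curve <- fsc(recA, recB)
      fsc_res <- c(resolution_estimate(curve), list(curve = curve))
      note("even/odd FSC: resolution %.4g nm%s", fsc_res$resolution_nm,
           if (fsc_res$nyquist_limited) " (Nyquist-limited)" else "")
    }
    vol <- fbp_reconstruct(proj, filter = config$filter)
    note("FBP reconstruction (%s filter)", config$filter)
  }

  # ---- electron density and segmentation ------------------------------------
  ne_vol <- volume3d(electron_density_from_delta(vol$data, beam),
                     vol$voxel_size_nm, "electron_density")
  # quantify only inside the reconstructed field of view: voxels beyond the
  # inscribed cylinder get partial angular coverage in FBP and carry haze
  d <- dim(ne_vol$data)
  if (config$tomography) {
    cx <- (d[1] - 1) / 2; cy <- (d[2] - 1) / 2
    r2 <- outer((seq_len(d[1]) - 1 - cx)^2, (seq_len(d[2]) - 1 - cy)^2, "+")
    fov <- array(rep(r2 <= (min(d[1:2]) / 2 - 2)^2, d[3]), dim = d)
    note("restricting analysis to the reconstruction circle")
  } else {
    fov <- array(TRUE, dim = d)
  }
  if (is.null(config$thresholds)) {
    whole <- phase_mask(fov, "volume", ne_vol$voxel_size_nm)
    h_all <- extract_histogram(ne_vol, whole, bins = 512)
    thresholds <- .kmeans_thresholds(h_all, config$n_phases)
    note("auto thresholds (%d-class histogram clustering): %s",
         config$n_phases, paste(signif(thresholds, 4), collapse = ", "))
  } else {
    thresholds <- config$thresholds
    note("user thresholds: %s", paste(signif(thresholds, 4), collapse = ", "))
  }
  masks <- threshold_segment(ne_vol, thresholds, labels = config$phase_names)
  if (config$tomography)
    masks <- lapply(masks, function(m)
      phase_mask(m$mask & fov, m$label, m$voxel_size_nm))

  # ---- erosion, histograms, fits --------------------------------------------
  phases <- vector("list", config$n_phases)
  names(phases) <- config$phase_names
  air_center_raw <- NA_real_
  for (i in seq_len(config$n_phases)) {
    em <- erode_mask(masks[[i]], config$erosion_depth)
    if (em$n_voxels < 100) {
      flags <- c(flags, sprintf(
        "phase '%s' has %d voxels after %d-voxel erosion; too few to fit",
        em$label, em$n_voxels, config$erosion_depth))
      phases[[i]] <- list(mask = em, histogram = NULL, fit = NULL)
      next
    }
    h <- extract_histogram(ne_vol, em)
    if (sum(h$counts > 0) >= 3) {
      h <- fit_gaussians(h, n_components = 1)
    } else {
      # degenerate histogram (noiseless piecewise-constant volume): fall
      # back to voxel moments of the eroded phase
      vals <- ne_vol$data[em$mask]
      h$components <- data.frame(center = mean(vals),
                                 sigma = max(stats::sd(vals), 1e-12),
                                 amplitude = max(h$counts))
      flags <- c(flags, sprintf(
        "phase '%s' histogram degenerate; used moment estimates", em$label))
    }
    phases[[i]] <- list(mask = em, histogram = h, fit = h$components)
    if (i == 1) air_center_raw <- h$components$center[1]
  }
  note("segmented, eroded by %d, fitted %d phases", config$erosion_depth,
       sum(!vapply(phases, function(p) is.null(p$fit), logical(1))))

  # ---- air normalization ----------------------------------------------------
  fitted_idx <- which(!vapply(phases, function(p) is.null(p$fit), logical(1)))
  centers <- data.frame(
    phase = config$phase_names[fitted_idx],
    center = vapply(fitted_idx, function(i) phases[[i]]$fit$center, numeric(1)),
    sigma = vapply(fitted_idx, function(i) phases[[i]]$fit$sigma, numeric(1))
  )
  if (1 %in% fitted_idx) {
    norm <- air_normalize(centers, air_index = which(fitted_idx == 1))
    centers <- norm$components
    note("air normalization: offset %.5g e/A^3", norm$offset)
  } else {
    norm <- list(offset = 0, components = centers)
    flags <- c(flags, "air phase not fitted; no air normalization applied")
  }

  # ---- densities, matching, classification ----------------------------------
  results <- list()
  for (r in seq_len(nrow(centers))) {
    i <- fitted_idx[r]
    hyp <- config$hypotheses[i]
    entry <- list(phase = centers$phase[r],
                  n_voxels = phases[[i]]$mask$n_voxels,
                  electron_density = centers$center[r],
                  electron_density_sigma = centers$sigma[r])
    if (!is.na(hyp)) {
      est <- density_estimate(centers$center[r], centers$sigma[r], hyp)
      cand <- config$candidates
      if (is.null(cand)) cand <- mineral_candidates()
      matches <- match_candidates(est, cand, k_sigma = config$k_sigma)
      entry$composition <- hyp
      entry$mass_density <- est$mass_density
      entry$mass_density_sigma <- est$mass_density_sigma
      entry$top_candidate <- matches$name[1]
      entry$top_within_k_sigma <- matches$within_k_sigma[1]
      entry$matches <- matches
      if ("C" %in% names(.as_composition(hyp)$formula))
        entry$carbonaceous_class <- classify_carbonaceous(est)
    }
    results[[centers$phase[r]]] <- entry
  }

  report <- structure(list(
    phases = results,
    air_offset = norm$offset,
    thresholds = thresholds,
    fsc = if (!is.null(fsc_res))
      fsc_res[c("resolution_nm", "crossing_frequency_nm",
                "nyquist_limited", "degenerate")] else NULL,
    flags = flags,
    provenance = list(config_hash = .config_hash(config),
                      seed = config$seed,
                      package_version = as.character(
                        utils::packageVersion("pxct"))),
    log = log
  ), class = "pxct_report")
  attr(report, "volumes") <- list(ne = ne_vol, truth = truth)
  attr(report, "fsc_curve") <- if (!is.null(fsc_res)) fsc_res$curve else NULL
  attr(report, "phases_full") <- phases

  if (!is.null(config$out_dir)) .write_artifacts(report, config)
  report
}

.write_artifacts <- function(report, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_report(report, file.path(config$out_dir, "report.json"))
  phases <- attr(report, "phases_full")
  for (nm in names(phases)) {
    h <- phases[[nm]]$histogram
    if (is.null(h)) next
    utils::write.csv(data.frame(mid = h$mids, count = h$counts),
                     file.path(config$out_dir,
                               paste0("histogram_", nm, ".csv")),
                     row.names = FALSE)
  }
  curve <- attr(report, "fsc_curve")
  if (!is.null(curve))
    write_fsc_csv(curve, file.path(config$out_dir, "fsc.csv"))
  invisible(config$out_dir)
}

#' Serialize a report to JSON
#'
#' Deterministic (no timestamps), so identical config + seed reproduce a
#' byte-identical file.
#'
#' @param report a `pxct_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "pxct_report"))
  x <- unclass(report)
  x$log <- NULL  # timing lines are not part of the reproducible payload
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "rows", na = "null")
  invisible(path)
}

#' @export
print.pxct_report <- function(x, ...) {
  cat("PXCT quantitative densitometry report\n")
  cat(sprintf("  air offset: %.5g e/A^3\n", x$air_offset))
  for (p in x$phases) {
    if (!is.null(p$mass_density)) {
      cat(sprintf("  %-10s rho = %.3f +/- %.3f g/cm^3 (n_e %.4f e/A^3, %d vox)",
                  p$phase, p$mass_density, p$mass_density_sigma,
                  p$electron_density, p$n_voxels))
      cat(sprintf("  -> %s%s", p$top_candidate,
                  if (isTRUE(p$top_within_k_sigma)) " (within 1 sigma)" else ""))
      if (!is.null(p$carbonaceous_class))
        cat(" [", p$carbonaceous_class, "]", sep = "")
      cat("\n")
    } else {
      cat(sprintf("  %-10s n_e = %.4f e/A^3 (%d vox, no material hypothesis)\n",
                  p$phase, p$electron_density, p$n_voxels))
    }
  }
  if (!is.null(x$fsc))
    cat(sprintf("  FSC half-period resolution: %.4g nm%s\n",
                x$fsc$resolution_nm,
                if (isTRUE(x$fsc$nyquist_limited)) " (Nyquist-limited)" else ""))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
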