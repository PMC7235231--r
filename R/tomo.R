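#' An angle-ordered stack of parallel-beam projections
#'
#' Projection images are line integrals of the refractive-index decrement
#' (units delta*nm), one image per rotation angle, stored as an
#' `(n_s, n_z, n_angles)` array: detector coordinate s runs across the
#' rotation plane, z along the rotation axis.
#'
#' @param data numeric array `(n_s, n_z, n_angles)`.
#' @param angles_deg strictly increasing angles in `[0, 180)`, degrees.
#' @param pixel_size_nm detector pixel size, nm.
#' @return object of class `projection_set`.
#' @export
projection_set <- function(data, angles_deg, pixel_size_nm) {
  stopifnot(is.array(data), length(dim(data)) == 3,
            dim(data)[3] == length(angles_deg),
            all(diff(angles_deg) > 0),
            all(angles_deg >= 0), all(angles_deg < 180),
            pixel_size_nm > 0)
  structure(list(data = data, angles_deg = angles_deg,
                 pixel_size_nm = pixel_size_nm),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("projection_set: %d projections of %d x %d px (%.4g nm), %.4g-%.4g deg\n",
              d[3], d[1], d[2], x$pixel_size_nm,
              min(x$angles_deg), max(x$angles_deg)))
  invisible(x)
}

#' Forward project a volume (parallel-beam Radon transform)
#'
#' Computes line integrals of the volume through the rotation plane (rotation
#' about the z axis; angle 0 projects along +y), with bilinear interpolation
#' and unit step along each ray. The projection values are scaled by the
#' voxel size, giving delta*nm — the phase-proportional quantity a beamline
#' projection carries.
#'
#' @param vol a [volume3d()] (delta channel).
#' @param angles_deg projection angles in degrees, strictly increasing in
#'   `[0, 180)`. Default: `n_angles` equally spaced over 180 degrees.
#' @param n_angles used when `angles_deg` is `NULL`.
#' @return a [projection_set()].
#' @export
forward_project <- function(vol, angles_deg = NULL, n_angles = 180) {
  stopifnot(inherits(vol, "volume3d"))
  if (is.null(angles_deg))
    angles_deg <- seq(0, 180, length.out = n_angles + 1)[seq_len(n_angles)]
  if (length(angles_deg) == 0) stop("empty angle list")
  d <- dim(vol$data)
  if (d[1] != d[2])
    stop("volume must be square in the rotation (x-y) plane; pad first")
  raw <- .cpp_forward_project(as.numeric(vol$data), as.integer(d),
                              angles_deg * pi / 180)
  projection_set(raw * vol$voxel_size_nm, angles_deg, vol$voxel_size_nm)
}

#' Per-projection constant + linear phase ramps
#'
#' Phase projections from ptychographic reconstructions carry an arbitrary
#' constant offset and linear phase terms per projection; these are modeled
#' as `a + b*s + c*z` (s, z in 0-based pixel units) and removed by
#' least-squares fitting over air-only pixels.
#'
#' @param offset,slope_s,slope_z coefficients, each length 1 or one per
#'   projection. Units: delta*nm (per pixel for the slopes).
#' @return object of class `ramp_model` (a data.frame, one row per
#'   projection once applied).
#' @export
ramp_model <- function(offset = 0, slope_s = 0, slope_z = 0) {
  stopifnot(all(is.finite(c(offset, slope_s, slope_z))))
  structure(list(offset = offset, slope_s = slope_s, slope_z = slope_z),
            class = "ramp_model")
}

.ramp_plane <- function(ns, nz, a, b, cc) {
  outer(0:(ns - 1) * b + a, rep(1, nz)) + outer(rep(1, ns), 0:(nz - 1) * cc)
}

#' @rdname ramp_model
#' @param p a [projection_set()].
#' @param model a [ramp_model()].
#' @export
add_ramp <- function(p, model) {
  stopifnot(inherits(p, "projection_set"), inherits(model, "ramp_model"))
  d <- dim(p$data)
  na <- d[3]
  a <- rep_len(model$offset, na)
  b <- rep_len(model$slope_s, na)
  cc <- rep_len(model$slope_z, na)
  out <- p$data
  for (i in seq_len(na))
    out[, , i] <- out[, , i] + .ramp_plane(d[1], d[2], a[i], b[i], cc[i])
  projection_set(out, p$angles_deg, p$pixel_size_nm)
}

#' Remove constant and linear phase components
#'
#' Fits `a + b*s + c*z` by least squares over the air-only margin of each
#' projection and subtracts the fitted plane, so air integrates to zero
#' phase. The air mask is either supplied or derived from the specimen
#' pillar radius (detector columns whose rays miss the pillar).
#'
#' @param p a [projection_set()].
#' @param air_mask logical `(n_s, n_z)` matrix marking air-only pixels, or
#'   `NULL` to derive it from `pillar_radius_vox`.
#' @param pillar_radius_vox pillar radius in voxels (same grid as the
#'   detector); used when `air_mask` is `NULL`.
#' @param margin_vox extra clearance added to the pillar radius.
#' @return list with `projections` (corrected [projection_set()]) and
#'   `ramps` (data.frame of fitted coefficients per projection).
#' @export
remove_ramp <- function(p, air_mask = NULL, pillar_radius_vox = NULL,
                        margin_vox = 2) {
  stopifnot(inherits(p, "projection_set"))
  d <- dim(p$data)
  if (is.null(air_mask)) {
    if (is.null(pillar_radius_vox))
      stop("supply either air_mask or pillar_radius_vox")
    cs <- (d[1] - 1) / 2
    air_cols <- abs(seq_len(d[1]) - 1 - cs) > pillar_radius_vox + margin_vox
    air_mask <- matrix(air_cols, nrow = d[1], ncol = d[2])
  }
  stopifnot(is.logical(air_mask), all(dim(air_mask) == d[1:2]))
  if (!any(air_mask)) stop("air mask is empty")
  s_idx <- matrix(0:(d[1] - 1), nrow = d[1], ncol = d[2])
  z_idx <- matrix(0:(d[2] - 1), nrow = d[1], ncol = d[2], byrow = TRUE)
  X <- cbind(1, s_idx[air_mask], z_idx[air_mask])
  XtXi <- solve(crossprod(X))
  out <- p$data
  coefs <- matrix(NA_real_, nrow = d[3], ncol = 3,
                  dimnames = list(NULL, c("offset", "slope_s", "slope_z")))
  for (i in seq_len(d[3])) {
    beta <- XtXi %*% crossprod(X, p$data[, , i][air_mask])
    coefs[i, ] <- beta
    out[, , i] <- out[, , i] -
      .ramp_plane(d[1], d[2], beta[1], beta[2], beta[3])
  }
  list(projections = projection_set(out, p$angles_deg, p$pixel_size_nm),
       ramps = as.data.frame(coefs))
}

# frequency response of the discrete Ram-Lak (ramp) filter of length L,
# built from the band-limited real-space kernel (sample spacing 1)
.ramp_filter <- function(L, type = c("ram-lak", "hann")) {
  type <- match.arg(type)
  shift <- c(0:(L / 2 - 1), -(L / 2):-1)
  h <- numeric(L)
  h[shift == 0] <- 0.25
  odd <- shift %% 2 != 0
  h[odd] <- -1 / (pi^2 * shift[odd]^2)
  H <- Re(stats::fft(h))
  if (type == "hann") {
    f <- abs(shift) / L            # cycles/sample, in [0, 0.5]
    H <- H * (0.5 * (1 + cos(2 * pi * f)))
  }
  H
}

#' Filtered back projection reconstruction
#'
#' Slice-by-slice parallel-beam FBP: each projection row is convolved with
#' the band-limited ramp filter (optionally apodized with a Hann window to
#' trade resolution for noise), then smeared back across the slice at its
#' angle. Output voxel size equals the detector pixel size; output values
#' are delta.
#'
#' @param p a (ramp-corrected) [projection_set()].
#' @param filter `"ram-lak"` (sharpest) or `"hann"` (noise-suppressing).
#' @return a delta-channel [volume3d()] of size `(n_s, n_s, n_z)`.
#' @export
fbp_reconstruct <- function(p, filter = c("ram-lak", "hann")) {
  filter <- match.arg(filter)
  stopifnot(inherits(p, "projection_set"))
  d <- dim(p$data)
  na <- d[3]
  if (na < 2) stop("FBP needs at least 2 projection angles")
  # work in voxel units so the discrete filter normalization applies
  proj <- p$data / p$pixel_size_nm
  L <- 2^ceiling(log2(2 * d[1]))
  H <- .ramp_filter(L, filter)
  filt <- array(0, dim = d)
  for (i in seq_len(na)) {
    pad <- matrix(0, nrow = L, ncol = d[2])
    pad[seq_len(d[1]), ] <- proj[, , i]
    sm <- Re(stats::mvfft(stats::mvfft(pad) * H, inverse = TRUE)) / L
    filt[, , i] <- sm[seq_len(d[1]), ]
  }
  bp <- .cpp_backproject(as.numeric(filt), as.integer(d),
                         p$angles_deg * pi / 180)
  rec <- bp * pi / na
  volume3d(rec, p$pixel_size_nm, "delta")
}

#' Split projections into independent even/odd half datasets
#'
#' Alternating angular projections form two independent datasets with double
#' angular spacing; reconstructing each and correlating them in Fourier
#' shells yields an unbiased resolution estimate. With an odd number of
#' projections (e.g. 653) the halves hold 327 and 326.
#'
#' @param p a [projection_set()] with at least 4 angles.
#' @return list with elements `even` (angles at positions 1, 3, ... —
#'   0-based even indices) and `odd` (positions 2, 4, ...).
#' @export
split_even_odd <- function(p) {
  stopifnot(inherits(p, "projection_set"))
  na <- dim(p$data)[3]
  if (na < 4) stop("need at least 4 projections to split")
  ie <- seq(1, na, by = 2)
  io <- seq(2, na, by = 2)
  list(
    even = projection_set(p$data[, , ie, drop = FALSE], p$angles_deg[ie],
                          p$pixel_size_nm),
    odd = projection_set(p$data[, , io, drop = FALSE], p$angles_deg[io],
                         p$pixel_size_nm)
  )
}

#' Add Gaussian noise to projections
#'
#' Deterministic given the seed; used to emulate per-projection measurement
#' noise so even/odd half tomograms carry independent noise realizations.
#'
#' @param p a [projection_set()].
#' @param sigma noise sd in projection units (delta*nm).
#' @param seed integer seed.
#' @return noisy [projection_set()].
#' @export
add_projection_noise <- function(p, sigma, seed = 1L) {
  stopifnot(inherits(p, "projection_set"), sigma >= 0)
  if (sigma == 0) return(p)
  noise <- .with_seed(seed, stats::rnorm(length(p$data), sd = sigma))
  projection_set(p$data + array(noise, dim = dim(p$data)),
                 p$angles_deg, p$pixel_size_nm)
}

#' Read / write projection sets
#'
#' Stored as an NRRD raster (see [write_volume()] for encodings) plus a JSON
#' sidecar carrying the angles and detector pixel size.
#'
#' @param p a [projection_set()].
#' @param path output `.nrrd` path; the sidecar is `path` + `.json`.
#' @param encoding passed to the NRRD writer.
#' @return `write_projections`: `path` invisibly; `read_projections`: a
#'   [projection_set()].
#' @export
write_projections <- function(p, path, encoding = "raw") {
  stopifnot(inherits(p, "projection_set"))
  vol <- volume3d(p$data, p$pixel_size_nm, "delta")
  write_volume(vol, path, encoding = encoding)
  jsonlite::write_json(list(angles_deg = p$angles_deg,
                            pixel_size_nm = p$pixel_size_nm),
                       paste0(path, ".json"), digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_projections
#' @export
read_projections <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing sidecar JSON: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  vol <- read_volume(path)
  projection_set(vol$data, meta$angles_deg, meta$pixel_size_nm)
}
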