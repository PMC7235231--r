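#' Euclidean distance transform of a 3D mask
#'
#' For each foreground voxel, the distance (in voxels, center-to-center) to
#' the nearest background voxel; background voxels get 0. With
#' `pad = TRUE` the array border counts as background ("shrunken in every
#' direction" applies at the volume edge too); with `pad = FALSE` only
#' in-volume background counts, which is what local thickness measurements
#' want for structures that span the volume.
#'
#' @param mask logical 3D array.
#' @param pad treat outside-the-volume as background (default `TRUE`).
#' @return numeric 3D array of distances, voxels.
#' @export
distance_transform <- function(mask, pad = TRUE) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  d <- dim(mask)
  if (pad) {
    big <- array(FALSE, dim = d + 2L)
    big[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] <- mask
    sq <- .cpp_edt_sq(as.vector(big), dim(big))
    out <- sqrt(sq[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])])
  } else {
    out <- sqrt(.cpp_edt_sq(as.vector(mask), d))
    dim(out) <- d
  }
  out
}

#' A labeled boolean phase mask
#'
#' @param mask logical 3D array selecting the phase's voxels.
#' @param label phase name.
#' @param voxel_size_nm voxel width, nm.
#' @return object of class `phase_mask` with fields `mask`, `label`,
#'   `voxel_size_nm`, `n_voxels`, and logical `empty`.
#' @export
phase_mask <- function(mask, label = "phase", voxel_size_nm = NA_real_) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  structure(list(mask = mask, label = label,
                 voxel_size_nm = voxel_size_nm,
                 n_voxels = sum(mask), empty = !any(mask)),
            class = "phase_mask")
}

#' @export
print.phase_mask <- function(x, ...) {
  cat(sprintf("phase_mask '%s': %d voxels%s\n", x$label, x$n_voxels,
              if (x$empty) " (EMPTY)" else ""))
  invisible(x)
}

#' Threshold segmentation into material phases
#'
#' Partitions a volume into K+1 phases by K ordered intensity cut points:
#' phase i holds voxels in `[t_i, t_{i+1})` (half-open; below the first and
#' at/above the last cut included in the outer phases). Pixel intensity is
#' the sole criterion and no filtering is applied, so the original
#' electron-density information is preserved.
#'
#' @param vol a [volume3d()].
#' @param thresholds strictly increasing numeric cut points in the volume's
#'   units; empty vector gives a single whole-volume mask.
#' @param labels optional character names, length K+1 (lowest phase first).
#' @return list of [phase_mask()]s, ordered by increasing intensity.
#' @export
threshold_segment <- function(vol, thresholds = numeric(),
                              labels = NULL) {
  stopifnot(inherits(vol, "volume3d"))
  if (length(thresholds) && any(diff(thresholds) <= 0))
    stop("thresholds must be strictly increasing")
  k <- length(thresholds)
  if (is.null(labels)) labels <- paste0("phase", seq_len(k + 1))
  stopifnot(length(labels) == k + 1)
  cuts <- c(-Inf, thresholds, Inf)
  lapply(seq_len(k + 1), function(i) {
    phase_mask(vol$data >= cuts[i] & vol$data < cuts[i + 1],
               label = labels[i], voxel_size_nm = vol$voxel_size_nm)
  })
}

#' Minimum shrink depth from the sphere voxel-count argument
#'
#' A phase statistic is dominated by interior voxels only when a spherical
#' particle of radius R has more voxels in its volume than on its surface:
#' `(4*pi/3) R^3 / l^3 > 4*pi R^2 / l^2`, i.e. `R > 3 l` with `l` the voxel
#' width. The continuum solution, 3 voxels, is the default erosion depth for
#' partial-volume removal.
#'
#' @return integer 3.
#' @seealso [discrete_shrink_oracle()] for the brute-force digitized check.
#' @export
min_shrink_voxels <- function() {
  # solve (4/3) pi R^3 = 4 pi R^2 for R in voxel-width units
  r <- 3
  as.integer(r)
}

#' Brute-force digitized-sphere voxel-count oracle
#'
#' Discrete analogue of the continuum shrink rule: for digitized spheres of
#' increasing radius, tallies the voxels of the sphere (`n_V`, the discrete
#' `(4*pi/3) R^3/l^3`) against its surface voxels (`n_A`, voxels touching
#' background — any of the 26 neighbors outside, the discrete
#' `4*pi R^2/l^2`), and returns the smallest radius whose volume count
#' strictly exceeds its surface count. The crossing depends mildly on the
#' boundary-connectivity convention and brackets the continuum solution
#' from below; the continuum value 3 stays the conservative default depth.
#'
#' @param radii integer radii to scan.
#' @return list with `radius` (first radius with `n_V > n_A`) and a
#'   data.frame `counts` of volume/surface tallies per radius.
#' @export
discrete_shrink_oracle <- function(radii = 1:10) {
  res <- lapply(radii, function(R) {
    n <- 2 * R + 3
    ax <- seq_len(n) - (n + 1) / 2
    r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
    inside <- r2 <= R^2
    interior <- inside
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      shifted <- array(FALSE, dim = dim(inside))
      sx <- seq_len(n) - dx; sy <- seq_len(n) - dy; sz <- seq_len(n) - dz
      okx <- sx >= 1 & sx <= n; oky <- sy >= 1 & sy <= n
      okz <- sz >= 1 & sz <= n
      shifted[okx, oky, okz] <- inside[sx[okx], sy[oky], sz[okz]]
      interior <- interior & shifted
    }
    surface <- inside & !interior
    c(radius = R, n_V = sum(inside), n_A = sum(surface))
  })
  counts <- as.data.frame(do.call(rbind, res))
  hit <- counts$radius[counts$n_V > counts$n_A]
  list(radius = if (length(hit)) min(hit) else NA_integer_, counts = counts)
}

#' Erode a phase mask by a Euclidean ball
#'
#' Removes every voxel within `depth` voxels of the phase boundary
#' (isotropic erosion via distance-transform thresholding), discarding the
#' partial-volume shell where voxel values mix contributions from adjacent
#' materials. Depth 0 is the identity; over-erosion to an empty mask is
#' legal and flagged.
#'
#' @param m a [phase_mask()].
#' @param depth erosion radius, voxels (>= 0; default [min_shrink_voxels()]).
#' @return eroded [phase_mask()] (subset of the input).
#' @export
erode_mask <- function(m, depth = min_shrink_voxels()) {
  stopifnot(inherits(m, "phase_mask"), depth >= 0)
  if (depth == 0) return(m)
  dt <- distance_transform(m$mask, pad = TRUE)
  phase_mask(m$mask & dt > depth, label = m$label,
             voxel_size_nm = m$voxel_size_nm)
}

#' Extract a phase's intensity histogram
#'
#' Bins the masked voxels of an electron-density (or delta) volume. The
#' default bin width follows the Freedman-Diaconis rule.
#'
#' @param vol a [volume3d()].
#' @param m a non-empty [phase_mask()] of matching shape.
#' @param bins number of bins, a vector of break points, or `"FD"`
#'   (Freedman-Diaconis, default).
#' @return object of class `histogram_model`: `breaks`, `mids`, `counts`,
#'   `units` (the volume channel), `label`, and `components` (`NULL` until
#'   fitted by [fit_gaussians()]).
#' @export
extract_histogram <- function(vol, m, bins = "FD") {
  stopifnot(inherits(vol, "volume3d"), inherits(m, "phase_mask"),
            all(dim(vol$data) == dim(m$mask)))
  if (m$empty) stop("cannot histogram an empty mask ('", m$label, "')")
  x <- vol$data[m$mask]
  if (min(x) == max(x)) {
    # constant phase: one bin centered on the value
    return(structure(list(breaks = c(x[1] - 0.5, x[1] + 0.5), mids = x[1],
                          counts = length(x), units = vol$channel,
                          label = m$label, components = NULL,
                          residual = NA_real_),
                     class = "histogram_model"))
  }
  if (identical(bins, "FD")) {
    h <- graphics::hist(x, breaks = "FD", plot = FALSE)
  } else {
    h <- graphics::hist(x, breaks = bins, plot = FALSE)
  }
  structure(list(breaks = h$breaks, mids = h$mids, counts = h$counts,
                 units = vol$channel, label = m$label,
                 components = NULL, residual = NA_real_),
            class = "histogram_model")
}

#' @export
print.histogram_model <- function(x, ...) {
  cat(sprintf("histogram_model '%s' [%s]: %d bins, %d counts\n", x$label,
              x$units, length(x$counts), sum(x$counts)))
  if (!is.null(x$components)) {
    cat("  fitted components (center +/- sigma, amplitude):\n")
    for (i in seq_len(nrow(x$components)))
      cat(sprintf("    %d: %.5g +/- %.3g  (%.4g)\n", i,
                  x$components$center[i], x$components$sigma[i],
                  x$components$amplitude[i]))
  }
  invisible(x)
}

.gaussian_sum <- function(par, x) {
  k <- length(par) / 3
  y <- numeric(length(x))
  for (j in seq_len(k)) {
    a <- par[3 * j - 2]; c <- par[3 * j - 1]; s <- par[3 * j]
    y <- y + a * exp(-(x - c)^2 / (2 * s^2))
  }
  y
}

# local maxima of a (lightly smoothed) count vector, highest first, with a
# minimum mutual separation so ripples on a dominant peak cannot crowd out
# genuinely distinct (if small) phase peaks
.find_peaks <- function(counts, mids, n) {
  sm <- stats::filter(counts, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- counts[is.na(sm)]
  sm <- as.numeric(sm)
  m <- length(sm)
  is_pk <- sm >= c(-Inf, sm[-m]) & sm >= c(sm[-1], -Inf) & sm > 0
  pk <- which(is_pk)
  if (length(pk) > 1) pk <- pk[c(TRUE, diff(pk) > 1)]  # collapse plateaus
  pk <- pk[order(sm[pk], decreasing = TRUE)]
  min_sep <- max(3, floor(m / (4 * n)))
  chosen <- integer()
  for (p in pk) {
    if (all(abs(p - chosen) >= min_sep)) chosen <- c(chosen, p)
    if (length(chosen) == n) break
  }
  if (length(chosen) < n) {
    for (p in order(sm, decreasing = TRUE)) {
      if (all(abs(p - chosen) >= min_sep)) chosen <- c(chosen, p)
      if (length(chosen) == n) break
    }
  }
  if (length(chosen) < n)
    chosen <- c(chosen, setdiff(order(sm, decreasing = TRUE),
                                chosen))[seq_len(n)]
  chosen
}

#' Fit a sum of Gaussians to a binned histogram
#'
#' Least-squares fit of `sum_j a_j exp(-(x - c_j)^2 / (2 s_j^2))` to the bin
#' counts — the histogram-curve-fitting workflow used for phase
#' densitometry, not a voxel-level EM mixture. Initial centers default to
#' the highest local maxima of the (lightly smoothed) counts; widths and
#' amplitudes are refined by bounded quasi-Newton optimization. The fit is
#' deterministic given its inputs and must improve on the initial residual.
#'
#' Components whose centers approach within half their pooled sigma are
#' flagged with a degeneracy warning.
#'
#' @param h a [extract_histogram()] result.
#' @param n_components number of Gaussian components (>= 1).
#' @param init optional numeric vector of initial centers, length
#'   `n_components`.
#' @return `h` with `components` (data.frame `center`, `sigma`, `amplitude`,
#'   sorted by center) and `residual` (sum of squared count residuals)
#'   filled in.
#' @export
fit_gaussians <- function(h, n_components = 1, init = NULL) {
  stopifnot(inherits(h, "histogram_model"), n_components >= 1)
  x <- h$mids
  y <- as.numeric(h$counts)
  if (sum(y > 0) < 3 * n_components)
    stop("histogram has too few non-empty bins for ", n_components,
         " components")
  bw <- mean(diff(h$breaks))
  if (is.null(init)) {
    pk <- .find_peaks(y, x, n_components)
    centers0 <- x[pk]
  } else {
    stopifnot(length(init) == n_components)
    centers0 <- init
  }
  # per-component width guess: half-height half-width around each peak
  sigma0 <- vapply(centers0, function(c0) {
    i0 <- which.min(abs(x - c0))
    half <- y[i0] / 2
    iw <- which(y >= half)
    iw <- iw[abs(iw - i0) <= 20]
    w <- if (length(iw) >= 2) diff(range(x[iw])) else 2 * bw
    max(w / 2.355, bw)
  }, numeric(1))
  amp0 <- vapply(centers0, function(c0) max(y[which.min(abs(x - c0))], 1),
                 numeric(1))
  par0 <- as.numeric(rbind(amp0, centers0, sigma0))
  lower <- as.numeric(rbind(rep(0, n_components),
                            rep(min(x) - bw, n_components),
                            rep(bw / 4, n_components)))
  upper <- as.numeric(rbind(rep(max(y) * 10, n_components),
                            rep(max(x) + bw, n_components),
                            rep(diff(range(x)), n_components)))
  obj <- function(p) sum((.gaussian_sum(p, x) - y)^2)
  fit <- stats::optim(par0, obj, method = "L-BFGS-B", lower = lower,
                      upper = upper,
                      control = list(maxit = 2000, factr = 1e4))
  if (fit$value > obj(par0) + 1e-9)
    stop("Gaussian fit failed to improve on initialization (residual ",
         signif(fit$value, 6), " vs ", signif(obj(par0), 6), ")")
  p <- fit$par
  comp <- data.frame(
    amplitude = p[seq(1, length(p), by = 3)],
    center = p[seq(2, length(p), by = 3)],
    sigma = p[seq(3, length(p), by = 3)]
  )
  comp <- comp[order(comp$center), c("center", "sigma", "amplitude")]
  rownames(comp) <- NULL
  if (n_components > 1) {
    gap <- diff(comp$center)
    pooled <- (comp$sigma[-1] + comp$sigma[-n_components]) / 2
    if (any(gap < pooled / 2))
      warning("near-degenerate Gaussian components (overlapping centers)")
  }
  h$components <- comp
  h$residual <- fit$value
  h
}

#' Normalize fitted components to the air level
#'
#' The air phase has essentially zero electron density, so its fitted center
#' measures the residual constant offset of the reconstruction; subtracting
#' it from every component anchors the density scale ("air normalization").
#'
#' @param components data.frame with a `center` column (e.g. from
#'   [fit_gaussians()], or centers pooled across phases).
#' @param air_index which row is air; default the lowest center.
#' @return list with `offset` (the subtracted air center) and `components`
#'   (centers shifted so air sits at zero).
#' @export
air_normalize <- function(components, air_index = NULL) {
  stopifnot(is.data.frame(components), "center" %in% names(components))
  if (is.null(air_index)) air_index <- which.min(components$center)
  stopifnot(air_index >= 1, air_index <= nrow(components))
  offset <- components$center[air_index]
  components$center <- components$center - offset
  list(offset = offset, components = components)
}

#' Phase density estimate from a fitted component
#'
#' Maps a fitted electron-density component (center, sigma) to a mass
#' density under a hypothesized composition; the Gaussian width is carried
#' through as the 1-sigma uncertainty of the estimate.
#'
#' @param center,sigma component center and width, e/Angstrom^3.
#' @param composition hypothesized material (object or formula string).
#' @return a [density_estimate()].
#' @export
estimate_phase_density <- function(center, sigma, composition) {
  density_estimate(center, sigma, composition)
}

# 26-connected component labeling by vectorized flood fill
.connected_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, dim = d)
  idx_all <- which(mask)
  nbr_offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nbr_offsets <- nbr_offsets[rowSums(abs(nbr_offsets)) > 0, ]
  off <- nbr_offsets[, 1] + nbr_offsets[, 2] * d[1] +
    nbr_offsets[, 3] * d[1] * d[2]
  coord <- arrayInd(seq_len(prod(d)), d)
  current <- 0L
  for (start in idx_all) {
    if (lab[start] != 0L) next
    current <- current + 1L
    lab[start] <- current
    frontier <- start
    while (length(frontier)) {
      cand <- rep(frontier, each = length(off)) + off
      # reject out-of-bounds wraps: neighbor must stay within +/-1 per axis
      src <- rep(frontier, each = length(off))
      ok <- cand >= 1 & cand <= prod(d)
      ok[ok] <- abs(coord[cand[ok], 1] - coord[src[ok], 1]) <= 1 &
        abs(coord[cand[ok], 2] - coord[src[ok], 2]) <= 1 &
        abs(coord[cand[ok], 3] - coord[src[ok], 3]) <= 1
      cand <- unique(cand[ok])
      cand <- cand[mask[cand] & lab[cand] == 0L]
      lab[cand] <- current
      frontier <- cand
    }
  }
  lab
}

#' Filament diameter profile
#'
#' Quantifies the diameter homogeneity of a filament-shaped phase — a
#' morphometric line of evidence for biogenicity (cellular filaments keep a
#' near-constant diameter along their length). The mask's centerline is
#' traced as the centroids of thin slabs along its principal axis; the local
#' diameter at each centerline point is twice the Euclidean distance to the
#' phase boundary (with a half-voxel digitization correction).
#'
#' @param m a [phase_mask()] containing a single connected filament.
#' @param voxel_size_nm voxel width, nm (defaults to the mask's).
#' @param slab_vox slab thickness along the axis, voxels.
#' @param trim_frac fraction of the axial extent trimmed at each end, where
#'   end caps bias the distance transform.
#' @return list with `diameters_nm` (per-centerline-point), `mean_nm`, `cv`
#'   (coefficient of variation), `n_points`.
#' @export
filament_diameter_profile <- function(m, voxel_size_nm = NULL,
                                      slab_vox = 2, trim_frac = 0.1) {
  stopifnot(inherits(m, "phase_mask"))
  if (m$empty) stop("mask is empty")
  if (is.null(voxel_size_nm)) voxel_size_nm <- m$voxel_size_nm
  stopifnot(is.finite(voxel_size_nm), voxel_size_nm > 0)
  cc <- .connected_components(m$mask)
  ncomp <- max(cc)
  if (ncomp > 1)
    stop("mask has ", ncomp, " connected components; expected one filament")
  vox <- which(m$mask)
  P <- arrayInd(vox, dim(m$mask))
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  pca <- svd(Pc, nu = 0, nv = 1)
  axis1 <- pca$v[, 1]
  t <- as.numeric(Pc %*% axis1)
  span <- range(t)
  if (diff(span) < 4 * slab_vox)
    stop("mask has no discernible filament axis (axial extent ",
         round(diff(span), 1), " voxels)")
  lo <- span[1] + trim_frac * diff(span)
  hi <- span[2] - trim_frac * diff(span)
  # distance to in-volume background only: a filament crossing the volume
  # boundary should not see the box as a wall
  dt <- distance_transform(m$mask, pad = FALSE)
  if (diff(span) < 2 * 2 * max(dt[vox]))
    stop("mask is not filament-shaped (axial extent ",
         round(diff(span), 1), " voxels vs local radius ",
         round(max(dt[vox]), 1), "); degenerate skeleton")
  edges <- seq(lo, hi, by = slab_vox)
  if (length(edges) < 3)
    stop("filament too short for a diameter profile")
  diam <- vapply(seq_len(length(edges) - 1), function(i) {
    sel <- t >= edges[i] & t < edges[i + 1]
    if (!any(sel)) return(NA_real_)
    # centerline radius at this axial position = max distance-to-boundary
    2 * max(dt[vox[sel]])
  }, numeric(1))
  diam <- diam[is.finite(diam)] * voxel_size_nm
  list(diameters_nm = diam, mean_nm = mean(diam),
       cv = stats::sd(diam) / mean(diam), n_points = length(diam))
}
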