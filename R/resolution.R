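#' Fourier shell correlation between two volumes
#'
#' Correlates two independent reconstructions of the same object per
#' concentric spatial-frequency shell:
#' `FSC(s) = Re sum(F_A * conj(F_B)) / sqrt(sum|F_A|^2 * sum|F_B|^2)`.
#' Shells are one frequency voxel wide. A raised-cosine spherical mask is
#' applied in real space by default to suppress spurious correlation from
#' the shared box edges.
#'
#' @param volA,volB [volume3d()]s of identical shape and voxel size.
#' @param mask `TRUE` (default) for the raised-cosine sphere, `FALSE` for
#'   none, or a numeric array of weights matching the volumes.
#' @return object of class `fsc_result`: a data.frame-like list with
#'   `frequency_nm` (shell centers, cycles/nm), `fsc`, `n_eff` (voxels per
#'   shell), `threshold` (half-bit curve), plus `voxel_size_nm`.
#' @export
fsc <- function(volA, volB, mask = TRUE) {
  stopifnot(inherits(volA, "volume3d"), inherits(volB, "volume3d"))
  if (!all(dim(volA$data) == dim(volB$data)))
    stop("volumes must have identical shapes")
  if (volA$voxel_size_nm != volB$voxel_size_nm)
    stop("volumes must have identical voxel sizes")
  d <- dim(volA$data)
  A <- volA$data
  B <- volB$data
  if (isTRUE(mask)) {
    w <- .soft_spherical_mask(d)
    A <- A * w; B <- B * w
  } else if (is.array(mask)) {
    stopifnot(all(dim(mask) == d))
    A <- A * mask; B <- B * mask
  }
  FA <- stats::fft(A)
  FB <- stats::fft(B)

  # shell index: nearest integer radius in units of the largest axis's
  # frequency step, so shells are one frequency voxel wide
  L <- max(d)
  fr <- lapply(d, function(n) {
    k <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))[seq_len(n)]
    k / n  # cycles per voxel
  })
  R2 <- outer(outer(fr[[1]]^2, fr[[2]]^2, "+"), fr[[3]]^2, "+")
  shell <- as.integer(round(sqrt(R2) * L))
  nmax <- L %/% 2   # up to Nyquist
  keep <- shell <= nmax
  sh <- shell[keep] + 1L

  num <- Re(FA * Conj(FB))[keep]
  pa <- (Mod(FA)^2)[keep]
  pb <- (Mod(FB)^2)[keep]
  s_num <- tapply(num, sh, sum)
  s_pa <- tapply(pa, sh, sum)
  s_pb <- tapply(pb, sh, sum)
  n_eff <- as.integer(table(sh))
  corr <- as.numeric(s_num / sqrt(s_pa * s_pb))
  freq <- (as.integer(names(s_num)) - 1L) / (L * volA$voxel_size_nm)

  structure(list(frequency_nm = freq, fsc = corr, n_eff = n_eff,
                 threshold = half_bit_threshold(n_eff),
                 voxel_size_nm = volA$voxel_size_nm),
            class = "fsc_result")
}

.soft_spherical_mask <- function(d, edge_frac = 0.1) {
  ctr <- (d - 1) / 2
  rmax <- min(d) / 2 - 1
  redge <- rmax * (1 - edge_frac)
  x <- (seq_len(d[1]) - 1 - ctr[1])^2
  y <- (seq_len(d[2]) - 1 - ctr[2])^2
  z <- (seq_len(d[3]) - 1 - ctr[3])^2
  r <- sqrt(outer(outer(x, y, "+"), z, "+"))
  w <- array(0, dim = d)
  w[r <= redge] <- 1
  tr <- r > redge & r <= rmax
  w[tr] <- 0.5 * (1 + cos(pi * (r[tr] - redge) / (rmax - redge)))
  w
}

#' @export
print.fsc_result <- function(x, ...) {
  cat(sprintf("FSC over %d shells to Nyquist (%.4g 1/nm)\n",
              length(x$fsc), max(x$frequency_nm)))
  invisible(x)
}

#' @export
as.data.frame.fsc_result <- function(x, ...) {
  data.frame(frequency_nm = x$frequency_nm, fsc = x$fsc,
             threshold = x$threshold, n_eff = x$n_eff)
}

#' Half-bit significance threshold
#'
#' The van Heel-Schatz half-bit information threshold per shell,
#' `T = (0.2071 + 1.9102/sqrt(n)) / (1.2071 + 0.9102/sqrt(n))`, where `n`
#' is the number of independent Fourier voxels in the shell. It tends to
#' 0.2071/1.2071 ~ 0.1716 for large shells.
#'
#' @param n_per_shell integer vector of voxels per shell (>= 1).
#' @return numeric threshold vector.
#' @export
half_bit_threshold <- function(n_per_shell) {
  stopifnot(all(n_per_shell >= 1))
  sq <- sqrt(n_per_shell)
  (0.2071 + 1.9102 / sq) / (1.2071 + 0.9102 / sq)
}

#' Half-period resolution from an FSC curve
#'
#' Finds the first frequency at which the FSC drops below the half-bit
#' threshold (linear interpolation between the bracketing shells) and
#' reports the half-period resolution `1/(2 f*)` in nm. If the FSC never
#' drops below the threshold the result is the Nyquist-limited value with
#' `nyquist_limited = TRUE`; if it starts below the threshold the result is
#' flagged `degenerate`.
#'
#' @param fsc_result an [fsc()] result.
#' @return list with `resolution_nm`, `crossing_frequency_nm`,
#'   `nyquist_limited`, `degenerate`.
#' @export
resolution_estimate <- function(fsc_result) {
  stopifnot(inherits(fsc_result, "fsc_result"))
  f <- fsc_result$frequency_nm
  dcurve <- fsc_result$fsc - fsc_result$threshold
  nyq <- 1 / (2 * fsc_result$voxel_size_nm)
  # skip the DC shell; find first sign change + -> -
  idx <- which(dcurve[-1] < 0) + 1L
  if (dcurve[2] < 0 && length(dcurve) > 1) {
    return(list(resolution_nm = NA_real_, crossing_frequency_nm = NA_real_,
                nyquist_limited = FALSE, degenerate = TRUE))
  }
  if (length(idx) == 0) {
    return(list(resolution_nm = 1 / (2 * nyq), crossing_frequency_nm = nyq,
                nyquist_limited = TRUE, degenerate = FALSE))
  }
  i <- idx[1]
  f_star <- f[i - 1] + (f[i] - f[i - 1]) *
    dcurve[i - 1] / (dcurve[i - 1] - dcurve[i])
  list(resolution_nm = 1 / (2 * f_star), crossing_frequency_nm = f_star,
       nyquist_limited = FALSE, degenerate = FALSE)
}

#' Write an FSC curve as CSV
#'
#' Columns: `frequency_nm` (cycles/nm), `fsc`, `threshold`, `n_eff`.
#'
#' @param fsc_result an [fsc()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_fsc_csv <- function(fsc_result, path) {
  utils::write.csv(as.data.frame(fsc_result), path, row.names = FALSE)
  invisible(path)
}
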