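#' A 3D scalar volume with voxel-size metadata
#'
#' The pipeline's central container: a 3D numeric array plus the physical
#' voxel width and a channel tag saying what the scalars mean (`label`,
#' `delta`, `electron_density` or `mass_density`).
#'
#' @param data a 3D numeric array.
#' @param voxel_size_nm isotropic voxel width, nm (> 0).
#' @param channel one of `"label"`, `"delta"`, `"electron_density"`,
#'   `"mass_density"`.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(data, voxel_size_nm,
                     channel = c("delta", "label", "electron_density",
                                 "mass_density")) {
  channel <- match.arg(channel)
  stopifnot(is.array(data), length(dim(data)) == 3,
            is.numeric(voxel_size_nm), length(voxel_size_nm) == 1,
            voxel_size_nm > 0)
  if (channel == "label") {
    if (any(data < 0) || any(data != round(data)))
      stop("label channel must hold non-negative integers")
  } else if (!all(is.finite(data))) {
    stop("volume contains non-finite values")
  }
  structure(list(data = data, voxel_size_nm = voxel_size_nm,
                 channel = channel),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("volume3d [%s]: %d x %d x %d voxels at %.4g nm (%.3g x %.3g x %.3g um)\n",
              x$channel, d[1], d[2], d[3], x$voxel_size_nm,
              d[1] * x$voxel_size_nm / 1e3, d[2] * x$voxel_size_nm / 1e3,
              d[3] * x$voxel_size_nm / 1e3))
  cat(sprintf("  range [%.6g, %.6g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$data)

#' Read / write volumes as NRRD
#'
#' NRRD ("nearly raw raster data") stores a small text header (dimension,
#' sizes, element type, encoding, voxel spacing) followed by the raster.
#' Both `raw` (little-endian IEEE float) and text `ascii` encodings are
#' supported; the latter keeps small fixtures human-readable. The voxel size
#' is taken from `space directions` or `spacings` and must be present —
#' a missing voxel size is an error, never a silent default.
#'
#' @param path file path (conventionally `.nrrd`).
#' @return `read_volume`: a [volume3d()]. `write_volume`: `path`, invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD000[1-5]$", magic))
    stop("not an NRRD file (bad magic): ", path)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("truncated NRRD header in ", path)
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(kv) == 3) hdr[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  sizes <- as.integer(strsplit(hdr$sizes, "\\s+")[[1]])
  if (is.null(hdr$dimension) || as.integer(hdr$dimension) != 3 ||
      length(sizes) != 3)
    stop("expected a 3-dimensional NRRD, got dimension ",
         hdr$dimension %||% "?")
  voxel <- .nrrd_voxel_size(hdr)
  type <- hdr$type
  enc <- tolower(hdr$encoding %||% "raw")
  n <- prod(sizes)
  vals <- switch(enc,
    raw = {
      sz <- switch(type, float = 4L, double = 8L,
                   stop("unsupported NRRD type for raw encoding: ", type))
      endian <- if (!is.null(hdr$endian) && hdr$endian == "big") "big" else "little"
      readBin(con, what = "numeric", n = n, size = sz, endian = endian)
    },
    ascii = ,
    text = ,
    txt = scan(con, what = double(), n = n, quiet = TRUE),
    stop("unsupported NRRD encoding: ", enc)
  )
  if (length(vals) != n) stop("NRRD data truncated: got ", length(vals),
                              " of ", n, " values")
  channel <- hdr[["pxct channel"]] %||% hdr[["channel"]] %||% "delta"
  volume3d(array(vals, dim = sizes), voxel_size_nm = voxel, channel = channel)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.nrrd_voxel_size <- function(hdr) {
  if (!is.null(hdr[["space directions"]])) {
    vecs <- regmatches(hdr[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", hdr[["space directions"]]))[[1]]
    mats <- lapply(vecs, function(v)
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]))
    sp <- vapply(mats, function(v) sqrt(sum(v^2)), numeric(1))
  } else if (!is.null(hdr$spacings)) {
    sp <- as.numeric(strsplit(hdr$spacings, "\\s+")[[1]])
  } else {
    stop("NRRD header carries no voxel size (no 'space directions' or 'spacings')")
  }
  if (length(unique(round(sp, 9))) != 1)
    stop("anisotropic voxels are not supported (spacings: ",
         paste(sp, collapse = ", "), ")")
  sp[1]
}

#' @rdname read_volume
#' @param vol a [volume3d()].
#' @param encoding `"raw"` (32-bit float, little-endian) or `"ascii"`.
#' @export
write_volume <- function(vol, path, encoding = c("raw", "ascii")) {
  stopifnot(inherits(vol, "volume3d"))
  encoding <- match.arg(encoding)
  d <- dim(vol$data)
  s <- vol$voxel_size_nm
  hdr <- c(
    "NRRD0004",
    "type: float",
    "dimension: 3",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    sprintf("encoding: %s", encoding),
    if (encoding == "raw") "endian: little",
    "space dimension: 3",
    sprintf("space directions: (%.10g,0,0) (0,%.10g,0) (0,0,%.10g)", s, s, s),
    'space units: "nm" "nm" "nm"',
    sprintf("pxct channel:=%s", vol$channel),
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (encoding == "raw") {
    writeBin(as.numeric(vol$data), con, size = 4L, endian = "little")
  } else {
    writeLines(paste(format(as.numeric(vol$data), digits = 9, trim = TRUE,
                            scientific = TRUE),
                     collapse = " "), con)
  }
  invisible(path)
}
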