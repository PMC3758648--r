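# File formats: multi-page TIFF cubes, ENVI hdr/raw cubes, spectral
# library CSV, lamp spectrum CSV, and plain-text series manifests.

#' Write a cube as a multi-page TIFF
#'
#' One page per band, band order = axis order, 16-bit integer samples.
#' TIFF output is reserved for integer-valued data in 0..65535 (raw
#' acquisitions, rounded abundance images); real-valued corrected cubes
#' belong in ENVI float storage ([write_envi()]), which preserves them
#' exactly. The wavelength axis is not embedded; pair the file with
#' [write_series_manifest()] or supply the axis on read.
#'
#' @param cube A `spectral_cube` with integer intensities <= 65535.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cube_tiff <- function(cube, path) {
  stopifnot(inherits(cube, "spectral_cube"))
  d <- dim(cube$data)
  integral <- max(cube$data) <= 65535 &&
    isTRUE(all.equal(cube$data, round(cube$data), tolerance = 1e-9))
  if (!integral) {
    stop("TIFF storage holds 16-bit integers; this cube has real-valued ",
         "or out-of-range intensities -- use write_envi() for float data")
  }
  pages <- lapply(seq_len(d[3]), function(b) cube$data[, , b] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a multi-page TIFF cube
#'
#' @param path TIFF file, one page per band.
#' @param axis `wavelength_axis` matching the page count.
#' @param bit_depth Detector bit depth to record.
#' @param corrected Mark the cube as corrected (not bounded by the raw
#'   ceiling).
#' @return A `spectral_cube`.
#' @export
read_cube_tiff <- function(path, axis, bit_depth = 16, corrected = FALSE) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != n_bands(axis)) {
    stop("TIFF has ", length(pages), " pages but the axis has ",
         n_bands(axis), " bands")
  }
  d <- dim(pages[[1]])
  data <- array(unlist(pages), dim = c(d[1], d[2], length(pages)))
  spectral_cube(data, axis, bit_depth = bit_depth,
                meta = list(corrected = corrected, source = path))
}

envi_data_types <- c(`4` = "double", `12` = "integer") # float32, uint16

#' Write a cube in ENVI format
#'
#' Produces a text `.hdr` header (samples, lines, bands, band-sequential
#' interleave, wavelength list) and a raw little-endian binary file.
#' Integer cubes are stored as unsigned 16-bit (ENVI data type 12), others
#' as 32-bit float (type 4).
#'
#' @param cube A `spectral_cube`.
#' @param path_base Path without extension; `.hdr` and `.raw` are appended.
#' @return `path_base`, invisibly.
#' @export
write_envi <- function(cube, path_base) {
  stopifnot(inherits(cube, "spectral_cube"))
  d <- dim(cube$data)
  integral <- max(cube$data) <= 65535 &&
    isTRUE(all.equal(cube$data, round(cube$data), tolerance = 1e-9))
  dtype <- if (integral) 12L else 4L
  hdr <- c(
    "ENVI",
    "file type = ENVI Standard",
    paste0("samples = ", d[2]),
    paste0("lines = ", d[1]),
    paste0("bands = ", d[3]),
    "header offset = 0",
    paste0("data type = ", dtype),
    "interleave = bsq",
    "byte order = 0",
    paste0("wavelength units = nm"),
    paste0("wavelength = { ", paste(cube$axis$centers, collapse = ", "), " }")
  )
  writeLines(hdr, paste0(path_base, ".hdr"))
  con <- file(paste0(path_base, ".raw"), "wb")
  on.exit(close(con))
  # bsq: per band, pixels in row-major (line by line) order
  for (b in seq_len(d[3])) {
    plane <- t(cube$data[, , b])
    if (dtype == 12L) {
      writeBin(as.integer(round(plane)), con, size = 2, endian = "little")
    } else {
      writeBin(as.numeric(plane), con, size = 4, endian = "little")
    }
  }
  invisible(path_base)
}

parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE)
  txt <- paste(lines, collapse = "\n")
  get1 <- function(key) {
    m <- regmatches(txt, regexec(paste0(key, "\\s*=\\s*([^\n{]+)"), txt))[[1]]
    if (length(m) < 2) stop("ENVI header missing field: ", key)
    trimws(m[2])
  }
  wl <- regmatches(txt, regexec("wavelength\\s*=\\s*\\{([^}]*)\\}", txt))[[1]]
  if (length(wl) < 2) stop("ENVI header missing wavelength list")
  list(
    samples = as.integer(get1("samples")),
    lines = as.integer(get1("lines")),
    bands = as.integer(get1("bands")),
    data_type = as.integer(get1("data type")),
    interleave = tolower(get1("interleave")),
    wavelength = as.numeric(strsplit(wl[2], ",")[[1]])
  )
}

#' Read an ENVI cube
#'
#' Supports band-sequential (bsq) little-endian files of data type 4
#' (float32) or 12 (uint16) with a wavelength list in the header.
#'
#' @param path_base Path without extension, or the `.hdr` path.
#' @param bit_depth Detector bit depth to record (default 16).
#' @param corrected Mark the cube as corrected.
#' @return A `spectral_cube`.
#' @export
read_envi <- function(path_base, bit_depth = 16, corrected = FALSE) {
  hdr_path <- if (grepl("\\.hdr$", path_base)) path_base else paste0(path_base, ".hdr")
  raw_path <- sub("\\.hdr$", ".raw", hdr_path)
  if (!grepl("\\.raw$", raw_path)) raw_path <- paste0(path_base, ".raw")
  h <- parse_envi_header(hdr_path)
  if (h$interleave != "bsq") stop("only bsq interleave is supported")
  if (!h$data_type %in% c(4L, 12L)) {
    stop("unsupported ENVI data type ", h$data_type, " (supported: 4, 12)")
  }
  n <- h$samples * h$lines * h$bands
  con <- file(raw_path, "rb")
  on.exit(close(con))
  vals <- if (h$data_type == 4L) {
    readBin(con, "numeric", n = n, size = 4, endian = "little")
  } else {
    readBin(con, "integer", n = n, size = 2, signed = FALSE, endian = "little")
  }
  data <- array(NA_real_, dim = c(h$lines, h$samples, h$bands))
  per_band <- h$samples * h$lines
  for (b in seq_len(h$bands)) {
    plane <- matrix(vals[((b - 1) * per_band + 1):(b * per_band)],
                    nrow = h$samples, ncol = h$lines)
    data[, , b] <- t(plane)
  }
  wl <- h$wavelength
  step <- if (length(wl) > 1) wl[2] - wl[1] else 1
  axis <- make_wavelength_axis(wl[1], wl[length(wl)], step)
  spectral_cube(data, axis, bit_depth = bit_depth,
                meta = list(corrected = corrected, source = hdr_path))
}

#' Write a spectral library as CSV
#'
#' First column `wavelength_nm`, one column per endmember.
#'
#' @param library A `spectral_library`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_library_csv <- function(library, path) {
  stopifnot(inherits(library, "spectral_library"))
  df <- data.frame(wavelength_nm = library$axis$centers, library$spectra,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a spectral library from CSV
#'
#' @param path CSV with first column `wavelength_nm` and one column per
#'   endmember. The wavelength column must be evenly spaced.
#' @param normalization Normalization applied on load (default `"raw"`).
#' @return A `spectral_library`.
#' @export
read_library_csv <- function(path, normalization = "raw") {
  df <- utils::read.csv(path, check.names = FALSE)
  wl <- df[[1]]
  step <- if (length(wl) > 1) wl[2] - wl[1] else 1
  axis <- make_wavelength_axis(wl[1], wl[length(wl)], step)
  build_library(as.matrix(df[-1]), axis, normalization = normalization)
}

#' Read a lamp spectrum and interpolate it onto an axis
#'
#' @param path Two-column CSV (wavelength_nm, irradiance).
#' @param axis Optional `wavelength_axis`; when given, irradiance is
#'   linearly interpolated onto the band centers and the interpolation is
#'   flagged in the attached attribute `interpolated`.
#' @return A data frame (no axis) or a numeric per-band vector (with axis).
#' @export
read_lamp_spectrum <- function(path, axis = NULL) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2) stop("lamp spectrum CSV needs two columns")
  if (is.null(axis)) {
    return(df)
  }
  out <- stats::approx(df[[1]], df[[2]], xout = axis$centers)$y
  if (anyNA(out)) {
    stop("lamp spectrum does not cover the full wavelength axis")
  }
  attr(out, "interpolated") <- TRUE
  out
}

#' Write a plain-text manifest for an acquisition series
#'
#' Key-value text file listing the member files (ENVI base paths or TIFF
#' files), the series kind, and acquisition times for a timeseries.
#'
#' @param series An `acquisition_series`.
#' @param dir Output directory (created if needed).
#' @param basename File name stem for the members.
#' @param format `"envi"` or `"tiff"`.
#' @return Manifest path, invisibly.
#' @export
write_series_manifest <- function(series, dir, basename = "cube",
                                  format = c("envi", "tiff")) {
  format <- match.arg(format)
  stopifnot(inherits(series, "acquisition_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(series$cubes))
  for (i in seq_along(series$cubes)) {
    stem <- file.path(dir, sprintf("%s_%03d", basename, i))
    if (format == "envi") {
      write_envi(series$cubes[[i]], stem)
      files[i] <- paste0(basename(stem), "")
    } else {
      write_cube_tiff(series$cubes[[i]], paste0(stem, ".tif"))
      files[i] <- paste0(basename(stem), ".tif")
    }
  }
  ax <- series$cubes[[1]]$axis
  lines <- c(
    paste0("kind = ", series$kind),
    paste0("format = ", format),
    paste0("bit_depth = ", series$cubes[[1]]$bit_depth),
    paste0("axis = ", ax$start_nm, ":", ax$stop_nm, ":", ax$step_nm),
    if (!is.null(series$times_s)) {
      paste0("times_s = ", paste(series$times_s, collapse = ","))
    },
    paste0("file = ", files)
  )
  manifest <- file.path(dir, "manifest.txt")
  writeLines(lines, manifest)
  invisible(manifest)
}

#' Read an acquisition series from a manifest
#'
#' @param manifest Path written by [write_series_manifest()].
#' @return An `acquisition_series`.
#' @export
read_series_manifest <- function(manifest) {
  dir <- dirname(manifest)
  lines <- readLines(manifest, warn = FALSE)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[[`, character(1), 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))
  get1 <- function(key) {
    v <- vals[keys == key]
    if (!length(v)) stop("manifest missing key: ", key)
    v[1]
  }
  kind <- get1("kind")
  fmt <- get1("format")
  bit_depth <- as.integer(get1("bit_depth"))
  ax_parts <- as.numeric(strsplit(get1("axis"), ":")[[1]])
  axis <- make_wavelength_axis(ax_parts[1], ax_parts[2], ax_parts[3])
  times <- if ("times_s" %in% keys) {
    as.numeric(strsplit(get1("times_s"), ",")[[1]])
  }
  files <- vals[keys == "file"]
  cubes <- lapply(files, function(f) {
    if (fmt == "envi") {
      read_envi(file.path(dir, f), bit_depth = bit_depth)
    } else {
      read_cube_tiff(file.path(dir, f), axis, bit_depth = bit_depth)
    }
  })
  acquisition_series(cubes, kind, times_s = times)
}
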