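# Synthetic acquisition simulator: Gaussian endmembers, geometric scenes,
# and detector noise models with the statistical structure of
# widefield-EMCCD and confocal-PMT hyperspectral systems.

#' Describe a Gaussian emission endmember
#'
#' Fluorophore emission is emulated as a single Gaussian in wavelength,
#' parameterized by peak position, full width at half maximum, and a
#' dimensionless relative brightness. Real tissue autofluorescence is a
#' multi-fluorophore mixture; a single Gaussian captures what matters for
#' unmixing studies -- peak position and spectral overlap.
#'
#' @param name Endmember label.
#' @param peak_nm Emission peak (nm).
#' @param width_nm Full width at half maximum (nm), positive.
#' @param relative_brightness Dimensionless scale, positive.
#' @return An `endmember_model`.
#' @export
endmember_model <- function(name, peak_nm, width_nm, relative_brightness = 1) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  if (width_nm <= 0) stop("width_nm must be positive")
  if (relative_brightness <= 0) stop("relative_brightness must be positive")
  structure(
    list(
      name = name, peak_nm = peak_nm, width_nm = width_nm,
      relative_brightness = relative_brightness
    ),
    class = "endmember_model"
  )
}

#' Sample a Gaussian endmember on a wavelength axis
#'
#' Evaluates `relative_brightness * exp(-4 ln 2 (lambda - peak)^2 / FWHM^2)`
#' at the band centers, so the value at `peak_nm` (if sampled) equals the
#' relative brightness and the value at `peak_nm +/- FWHM/2` equals half of
#' it.
#'
#' @param model An `endmember_model`.
#' @param axis A `wavelength_axis`.
#' @return Numeric spectrum vector, one value per band.
#' @export
gaussian_endmember <- function(model, axis) {
  stopifnot(inherits(model, "endmember_model"), inherits(axis, "wavelength_axis"))
  lam <- axis$centers
  model$relative_brightness *
    exp(-4 * log(2) * (lam - model$peak_nm)^2 / model$width_nm^2)
}

#' Describe a synthetic scene
#'
#' A scene places geometric objects -- full-frame backgrounds, disks, and
#' annuli -- each carrying one endmember at a fixed abundance level.
#' Overlapping objects add linearly, matching the mixing model the unmixing
#' stage assumes.
#'
#' @param shape Image dimensions `c(rows, cols)`.
#' @param objects List of objects, each a list with fields `endmember`
#'   (name), `shape` (`"background"`, `"disk"` or `"annulus"`), `level`
#'   (abundance, >= 0), and for disks/annuli `center = c(row, col)` plus
#'   `radius` (disk) or `inner`/`outer` radii (annulus).
#' @return A `scene_spec`.
#' @export
scene_spec <- function(shape, objects = list()) {
  stopifnot(length(shape) == 2, all(shape >= 1))
  for (ob in objects) {
    if (is.null(ob$endmember) || is.null(ob$shape) || is.null(ob$level)) {
      stop("each scene object needs endmember, shape and level fields")
    }
    if (ob$level < 0) stop("abundance levels must be >= 0")
  }
  structure(list(shape = as.integer(shape), objects = objects),
            class = "scene_spec")
}

object_mask <- function(ob, shape) {
  switch(ob$shape,
    background = matrix(TRUE, shape[1], shape[2]),
    disk = {
      rr <- row(matrix(0, shape[1], shape[2])) - ob$center[1]
      cc <- col(matrix(0, shape[1], shape[2])) - ob$center[2]
      rr^2 + cc^2 <= ob$radius^2
    },
    annulus = {
      rr <- row(matrix(0, shape[1], shape[2])) - ob$center[1]
      cc <- col(matrix(0, shape[1], shape[2])) - ob$center[2]
      d2 <- rr^2 + cc^2
      d2 <= ob$outer^2 & d2 >= ob$inner^2
    },
    stop("unknown scene object shape: ", ob$shape)
  )
}

#' Render a scene into ground-truth abundances and a noise-free cube
#'
#' @param spec A `scene_spec`.
#' @param library A `spectral_library` containing every endmember the scene
#'   references.
#' @return List with `abundances` (rows x cols x endmember array, named) and
#'   `cube` (noise-free `spectral_cube` equal to the abundance-weighted sum
#'   of library spectra at every pixel).
#' @export
render_scene <- function(spec, library) {
  stopifnot(inherits(spec, "scene_spec"), inherits(library, "spectral_library"))
  shape <- spec$shape
  k <- length(library$names)
  ab <- array(0, dim = c(shape[1], shape[2], k),
              dimnames = list(NULL, NULL, library$names))
  for (ob in spec$objects) {
    if (!ob$endmember %in% library$names) {
      stop("scene references unknown endmember: ", ob$endmember)
    }
    m <- object_mask(ob, shape)
    plane <- ab[, , ob$endmember]
    plane[m] <- plane[m] + ob$level
    ab[, , ob$endmember] <- plane
  }
  cube <- reconstruct(ab, library)
  list(abundances = ab, cube = cube)
}

#' Describe a detector noise model
#'
#' One abstraction covers both detector families: a Poisson photon branch
#' scaled by `illumination_scale` (which stands in for lamp percentage,
#' laser percentage, and pinhole transmission alike), multiplicative gain
#' with an excess noise factor `F` (EM-register or PMT multiplication
#' noise, modeled as variance `F^2 gain^2 mean` on the photon branch),
#' additive Gaussian read noise, a fixed offset, and quantization/clipping
#' to the detector bit depth.
#'
#' @param kind `"emccd"` or `"pmt"`.
#' @param gain Detector gain (arbitrary units, > 0).
#' @param read_noise Read noise, counts RMS (>= 0).
#' @param excess_noise_factor Multiplicative-noise factor F (>= 1).
#' @param offset Dark offset, counts.
#' @param bit_depth Detector bit depth, 8..16.
#' @param illumination_scale Dimensionless illumination multiplier (>= 0).
#' @return A `detector_model`.
#' @export
detector_model <- function(kind = c("emccd", "pmt"), gain = 1, read_noise = 0,
                           excess_noise_factor = 1, offset = 0,
                           bit_depth = 12, illumination_scale = 1) {
  kind <- match.arg(kind)
  if (gain <= 0) stop("gain must be positive")
  if (read_noise < 0) stop("read_noise must be >= 0")
  if (excess_noise_factor < 1) stop("excess_noise_factor must be >= 1")
  if (!(bit_depth %in% 8:16)) stop("bit_depth must be in 8..16")
  if (illumination_scale < 0) stop("illumination_scale must be >= 0")
  structure(
    list(
      kind = kind, gain = gain, read_noise = read_noise,
      excess_noise_factor = excess_noise_factor, offset = offset,
      bit_depth = bit_depth, illumination_scale = illumination_scale
    ),
    class = "detector_model"
  )
}

detect_once <- function(signal, detector) {
  m <- detector$illumination_scale * signal
  n <- length(m)
  photons <- stats::rpois(n, m)
  f2 <- detector$excess_noise_factor^2
  if (f2 > 1) {
    # excess multiplicative noise: adds (F^2 - 1) * mean to the photon variance
    photons <- photons + stats::rnorm(n, 0, sqrt((f2 - 1) * m))
  }
  out <- detector$gain * photons
  if (detector$read_noise > 0) {
    out <- out + stats::rnorm(n, 0, detector$read_noise)
  }
  out <- round(out + detector$offset)
  pmin(pmax(out, 0), 2^detector$bit_depth - 1)
}

#' Simulate replicate acquisitions of a static scene
#'
#' Each replicate applies the full detector chain to the noise-free signal:
#' `clip(round(gain * excess(Poisson(illumination_scale * signal)) +
#' N(0, read_noise) + offset), 0, 2^bit_depth - 1)`. Replicates are i.i.d.
#' and the whole series is reproducible for a fixed seed.
#'
#' @param noise_free Noise-free `spectral_cube` (e.g. from [render_scene()]).
#' @param detector A `detector_model`.
#' @param n_replicates Number of sequential images (>= 1).
#' @param seed RNG seed (or `NULL` to use the current stream).
#' @return An `acquisition_series` of kind `"replicate"` (a single cube is
#'   returned with `check = FALSE`; replicate statistics need >= 2).
#' @export
acquire <- function(noise_free, detector, n_replicates = 5, seed = NULL) {
  stopifnot(inherits(noise_free, "spectral_cube"),
            inherits(detector, "detector_model"), n_replicates >= 1)
  d <- dim(noise_free$data)
  cubes <- with_seed(seed, lapply(seq_len(n_replicates), function(i) {
    vals <- detect_once(as.vector(noise_free$data), detector)
    spectral_cube(array(vals, d), noise_free$axis,
                  bit_depth = detector$bit_depth,
                  meta = list(detector = detector$kind, replicate = i))
  }))
  acquisition_series(cubes, "replicate", check = n_replicates >= 2)
}

#' Simulate a photobleaching time series
#'
#' Each endmember's abundance map decays mono-exponentially,
#' `A_k(t) = A_k(0) exp(-rate_k t)`, before spectral mixing and detection.
#' Mono-exponential kinetics are the minimal model supporting differential
#' photobleaching and decay-rate recovery.
#'
#' @param abundances Ground-truth abundance array (rows x cols x endmember,
#'   dimnames naming the endmembers) as produced by [render_scene()].
#' @param library `spectral_library` providing the endmember spectra.
#' @param rates Named per-endmember decay constants (1/s), >= 0. Endmembers
#'   without an entry do not bleach.
#' @param times_s Strictly increasing acquisition times (s).
#' @param detector A `detector_model`, or `NULL` for noise-free output.
#' @param seed RNG seed.
#' @return An `acquisition_series` of kind `"timeseries"`.
#' @export
simulate_bleaching <- function(abundances, library, rates, times_s,
                               detector = NULL, seed = NULL) {
  stopifnot(is.array(abundances), length(dim(abundances)) == 3)
  nm <- dimnames(abundances)[[3]]
  if (is.null(nm)) stop("abundance array must carry endmember dimnames")
  if (any(rates < 0)) stop("decay rates must be >= 0")
  if (length(times_s) < 1 || (length(times_s) > 1 && any(diff(times_s) <= 0))) {
    stop("times_s must be strictly increasing")
  }
  k <- vapply(nm, function(x) if (x %in% names(rates)) rates[[x]] else 0,
              numeric(1))
  with_seed(seed, {
    cubes <- lapply(times_s, function(t) {
      ab_t <- sweep(abundances, 3, exp(-k * t), `*`)
      cube <- reconstruct(ab_t, library)
      if (is.null(detector)) {
        cube
      } else {
        d <- dim(cube$data)
        vals <- detect_once(as.vector(cube$data), detector)
        spectral_cube(array(vals, d), cube$axis,
                      bit_depth = detector$bit_depth,
                      meta = list(detector = detector$kind, time_s = t))
      }
    })
    acquisition_series(cubes, "timeseries", times_s = times_s)
  })
}

#' Simulator presets for the two system families
#'
#' Returns a detector model, endmember triple, and default scene emulating
#' either a widefield AOTF/EMCCD system or a confocal grating/PMT system.
#' GFP (peak 510 nm) and Hoechst (peak 461 nm) are shared between presets;
#' the bulk autofluorescence peak shifts with the excitation used by each
#' system family (505 nm widefield, 545 nm confocal). Detector constants
#' put raw-image composite SNR in the characteristic regimes of the two
#' families (roughly 5-30 for the confocal preset and 1.5-5 for the
#' widefield preset at the default scene brightness): the widefield preset
#' has lower photon flux per band, EM excess noise, and a large offset from
#' nonspecific background; the confocal preset is closer to shot-limited.
#'
#' @param system `"widefield"` or `"confocal"`.
#' @return List with `system`, `detector` (`detector_model`), `endmembers`
#'   (list of `endmember_model`: gfp, hoechst, af), and `scene_levels`
#'   (default abundance levels used by [preset_scene()]).
#' @export
preset <- function(system = c("widefield", "confocal")) {
  system <- match.arg(system)
  if (system == "widefield") {
    detector <- detector_model(
      kind = "emccd", gain = 20, read_noise = 150,
      excess_noise_factor = sqrt(2), offset = 100, bit_depth = 16,
      illumination_scale = 0.05
    )
    af_peak <- 505
  } else {
    detector <- detector_model(
      kind = "pmt", gain = 1, read_noise = 2,
      excess_noise_factor = 1.3, offset = 5, bit_depth = 12,
      illumination_scale = 1
    )
    af_peak <- 545
  }
  list(
    system = system,
    detector = detector,
    endmembers = list(
      gfp = endmember_model("GFP", peak_nm = 510, width_nm = 40),
      hoechst = endmember_model("Hoechst", peak_nm = 461, width_nm = 60),
      af = endmember_model("AF", peak_nm = af_peak, width_nm = 90,
                           relative_brightness = 1)
    ),
    scene_levels = c(GFP = 400, Hoechst = 600, AF = 150)
  )
}

#' Build the preset spectral library on an axis
#'
#' @param p A preset from [preset()].
#' @param axis Wavelength axis (default 462-648 nm / 6 nm).
#' @param normalization Library normalization (default `"peak1"`).
#' @return A `spectral_library` with endmembers GFP, Hoechst, AF.
#' @export
preset_library <- function(p, axis = make_wavelength_axis(462, 648, 6),
                           normalization = "peak1") {
  spectra <- lapply(p$endmembers, gaussian_endmember, axis = axis)
  names(spectra) <- vapply(p$endmembers, `[[`, character(1), "name")
  build_library(spectra, axis, normalization = normalization)
}

#' Default preset scene
#'
#' A field of view with full-frame autofluorescence background, a large
#' Hoechst-stained disk (nuclei-dense region), and a small GFP disk
#' (a single labeled cell) overlapping the Hoechst region -- the spatial
#' motif of labeled cells inside stained, autofluorescent tissue.
#'
#' @param p A preset from [preset()].
#' @param shape Image dimensions `c(rows, cols)`.
#' @return A `scene_spec`.
#' @export
preset_scene <- function(p, shape = c(64, 64)) {
  lv <- p$scene_levels
  r <- shape[1]; c <- shape[2]
  scene_spec(shape, list(
    list(endmember = "AF", shape = "background", level = unname(lv["AF"])),
    list(endmember = "Hoechst", shape = "disk",
         center = round(c(0.38 * r, 0.42 * c)), radius = round(0.22 * min(r, c)),
         level = unname(lv["Hoechst"])),
    list(endmember = "GFP", shape = "disk",
         center = round(c(0.65 * r, 0.68 * c)), radius = round(0.10 * min(r, c)),
         level = unname(lv["GFP"]))
  ))
}
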