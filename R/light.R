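#' Savitzky-Golay smoothing of a spectrum
#'
#' Linear (polynomial order 1) Savitzky-Golay filter: each point is
#' replaced by the value at its own wavelength of a local least-squares
#' straight-line fit over a window. The window is given in nm and
#' converted to an odd number of grid points. At the spectrum edges the
#' window shrinks to fit, so constant and straight-line spectra are
#' preserved exactly everywhere.
#'
#' @param value spectral values on a uniform wavelength grid
#' @param wavelength wavelength grid in nm (uniform spacing assumed for
#'   the nm-to-points conversion)
#' @param window_nm filter window width in nm (default 15)
#' @param passes number of filter passes (default 2)
#' @return smoothed values, same length as the input.
#' @export
smooth_spectrum <- function(value, wavelength, window_nm = 15, passes = 2) {
  n <- length(value)
  if (length(wavelength) != n) stopf("wavelength and value length differ")
  if (n < 3) stopf("spectrum too short to smooth")
  dl <- mean(diff(wavelength))
  pts <- max(3, round(window_nm / dl))
  if (pts %% 2 == 0) pts <- pts + 1
  if (pts > n) stopf("window of %d points wider than the spectrum (%d)", pts, n)
  hw <- (pts - 1) %/% 2
  for (p in seq_len(passes)) {
    value <- vapply(seq_len(n), function(i) {
      idx <- max(1, i - hw):min(n, i + hw)
      x <- wavelength[idx] - wavelength[i]
      xm <- mean(x)
      sxx <- sum((x - xm)^2)
      ym <- mean(value[idx])
      if (sxx == 0) return(ym)
      b <- sum((x - xm) * (value[idx] - ym)) / sxx
      ym - b * xm # fit evaluated at x = 0
    }, numeric(1))
  }
  value
}

#' Normalize a spectral stack to the interface spectrum
#'
#' Divides every depth's spectrum wavelength-wise by the spectrum at the
#' reference depth (the mat-salt interface by default), so values
#' represent the fraction of light at the interface. Idempotent.
#'
#' @param stack a [spectral_stack()]
#' @param reference_depth reference depth in mm (default 0); the nearest
#'   grid depth within half a depth step is used
#' @return a normalized [spectral_stack()].
#' @export
normalize_stack <- function(stack, reference_depth = 0) {
  stopifnot(inherits(stack, "spectral_stack"))
  i <- which.min(abs(stack$depth - reference_depth))
  step <- if (length(stack$depth) > 1) min(diff(stack$depth)) else Inf
  if (abs(stack$depth[i] - reference_depth) > step / 2 + 1e-9) {
    stopf("no grid depth within half a step of the reference depth %g mm",
          reference_depth)
  }
  ref <- stack$irradiance[, i]
  if (any(ref <= 0)) stopf("zero or negative irradiance at the reference depth")
  spectral_stack(stack$wavelength, stack$depth,
                 sweep(stack$irradiance, 1, ref, "/"),
                 normalized = TRUE)
}

#' Spectral attenuation coefficients between consecutive depths
#'
#' The attenuation spectrum between consecutive depths is the negative
#' gradient of the log-transformed spectra:
#' `alpha(lambda, z_mid) = -(ln E(lambda, z2) - ln E(lambda, z1)) / (z2 - z1)`,
#' in mm^-1, located at interval midpoints.
#'
#' @param stack a [spectral_stack()] with at least 2 depths
#' @return an `attenuation_stack`: list with `wavelength`, `depth`
#'   (midpoints, one fewer than the source stack) and `attenuation`
#'   matrix (wavelength x depth).
#' @export
attenuation_spectra <- function(stack) {
  stopifnot(inherits(stack, "spectral_stack"))
  if (length(stack$depth) < 2) stopf("need at least 2 depths")
  if (any(stack$irradiance <= 0)) stopf("non-positive irradiance; cannot log")
  lg <- log(stack$irradiance)
  dz <- diff(stack$depth)
  att <- -sweep(lg[, -1, drop = FALSE] - lg[, -ncol(lg), drop = FALSE],
                2, dz, "/")
  mid <- (stack$depth[-1] + stack$depth[-length(stack$depth)]) / 2
  structure(list(wavelength = stack$wavelength, depth = mid,
                 attenuation = att),
            class = "attenuation_stack")
}

#' @export
print.attenuation_stack <- function(x, ...) {
  cat(sprintf("<attenuation_stack> %d wavelengths x %d depth intervals\n",
              length(x$wavelength), length(x$depth)))
  invisible(x)
}

#' Pigment absorption band definition
#'
#' @param pigment pigment name
#' @param peak peak absorption wavelength in nm; defaults for the
#'   diagnostic pigments are chl_a 674, phycocyanin 624, bchl_c 745,
#'   bchl_a 845 and 902
#' @param window_half_width half-width of the quantification window in nm
#'   (default 5, i.e. a 10-nm window)
#' @return a `band_definition` list.
#' @export
band_definition <- function(pigment, peak, window_half_width = 5) {
  structure(list(pigment = pigment, peak = peak,
                 window_half_width = window_half_width),
            class = "band_definition")
}

#' The five diagnostic pigment bands
#'
#' @param window_half_width half-width in nm passed to each band
#' @return a named list of [band_definition()] objects for chlorophyll a
#'   (674 nm), phycocyanin (624 nm), bacteriochlorophyll c (745 nm) and
#'   bacteriochlorophyll a (845 and 902 nm).
#' @export
default_bands <- function(window_half_width = 5) {
  peaks <- c(chl_a = 674, phycocyanin = 624, bchl_c = 745,
             bchl_a_845 = 845, bchl_a_902 = 902)
  stats::setNames(lapply(names(peaks), function(nm) {
    band_definition(nm, peaks[[nm]], window_half_width)
  }), names(peaks))
}

#' Pigment abundance from the attenuation spectra
#'
#' At each depth the pigment abundance is estimated as the area enclosed
#' between the attenuation curve and the straight chord connecting the
#' window endpoints, over a 10-nm window centred on the pigment's peak
#' absorption wavelength. Only a positive (convex-peak) enclosed area
#' counts; windows where the curve does not rise above the chord score 0.
#' The chord baseline removes any spectrally linear matrix attenuation.
#'
#' @param att an `attenuation_stack` from [attenuation_spectra()]
#' @param band a [band_definition()]
#' @return data.frame with `depth_mm` and `abundance` (mm^-1 nm) plus the
#'   band stored in the `band` attribute.
#' @export
pigment_abundance <- function(att, band) {
  stopifnot(inherits(att, "attenuation_stack"),
            inherits(band, "band_definition"))
  lo <- band$peak - band$window_half_width
  hi <- band$peak + band$window_half_width
  if (lo < min(att$wavelength) || hi > max(att$wavelength)) {
    stopf("band window [%g, %g] nm outside the wavelength grid", lo, hi)
  }
  idx <- which(att$wavelength >= lo - 1e-9 & att$wavelength <= hi + 1e-9)
  if (length(idx) < 3) stopf("band window covers fewer than 3 wavelengths")
  lam <- att$wavelength[idx]
  abundance <- vapply(seq_along(att$depth), function(j) {
    a <- att$attenuation[idx, j]
    chord <- a[1] + (a[length(a)] - a[1]) *
      (lam - lam[1]) / (lam[length(lam)] - lam[1])
    area <- trapz(lam, a - chord)
    if (area > 0) area else 0
  }, numeric(1))
  structure(data.frame(depth_mm = att$depth, abundance = abundance),
            band = band, unit = "mm-1 nm",
            class = c("pigment_profile", "data.frame"))
}

#' Integrated UV, PAR and NIR intensity profiles
#'
#' Trapezoidal integral of the irradiance over the three spectral
#' channels, per depth: UV 200-400 nm, photosynthetically active
#' radiation (PAR) 400-700 nm, near infrared (NIR) 750-950 nm. Channels
#' with no overlap with the wavelength grid are reported as `NA` (not
#' fabricated); if no channel overlaps, an error is raised.
#'
#' @param stack a [spectral_stack()]
#' @param normalize if `TRUE` (default), divide each channel by its value
#'   at the depth nearest 0 mm (the interface)
#' @param channels named list of length-2 wavelength ranges (nm)
#' @return data.frame with `depth_mm` and one column per channel.
#' @export
channel_profiles <- function(stack, normalize = TRUE,
                             channels = list(uv = c(200, 400),
                                             par = c(400, 700),
                                             nir = c(750, 950))) {
  stopifnot(inherits(stack, "spectral_stack"))
  lam <- stack$wavelength
  vals <- lapply(channels, function(rng) {
    idx <- which(lam >= rng[1] & lam <= rng[2])
    if (length(idx) < 2) return(rep(NA_real_, length(stack$depth)))
    vapply(seq_along(stack$depth), function(j) {
      trapz(lam[idx], stack$irradiance[idx, j])
    }, numeric(1))
  })
  if (all(vapply(vals, function(v) all(is.na(v)), logical(1)))) {
    stopf("wavelength grid overlaps none of the requested channels")
  }
  if (normalize) {
    i0 <- which.min(abs(stack$depth))
    vals <- lapply(vals, function(v) v / v[i0])
  }
  out <- data.frame(depth_mm = stack$depth)
  for (nm in names(vals)) out[[nm]] <- vals[[nm]]
  structure(out, normalized = normalize,
            class = c("channel_profiles", "data.frame"))
}

#' Depth at which a channel is attenuated to a given fraction
#'
#' First depth at which the relative intensity falls to or below the
#' target fraction, with log-linear interpolation between the bracketing
#' grid points (light decays close to exponentially, so interpolation is
#' done on the log of intensity). Only depths at or below the surface
#' reference (0 mm) are considered.
#'
#' @param profile data.frame with `depth_mm` and a relative-intensity
#'   column (surface value 1), e.g. one channel of [channel_profiles()]
#' @param fraction target fraction in (0, 1]
#' @param channel column name holding the intensity (default `"par"`)
#' @return depth in mm; `Inf` if the profile never reaches the fraction
#'   within its depth range (the documented beyond-range sentinel).
#' @export
#' @examples
#' z <- seq(0, 6, 0.4)
#' pr <- data.frame(depth_mm = z, par = exp(-log(100) / 3.5 * z))
#' attenuation_depth(pr, 0.01) # 3.5 mm
attenuation_depth <- function(profile, fraction, channel = "par") {
  if (fraction <= 0 || fraction > 1) stopf("fraction must be in (0, 1]")
  keep <- profile$depth_mm >= 0
  z <- profile$depth_mm[keep]
  v <- profile[[channel]][keep]
  if (length(z) == 0) stopf("profile has no depths at or below the surface")
  if (fraction >= v[1]) return(z[1])
  below <- which(v <= fraction)
  if (length(below) == 0) return(Inf)
  i <- below[1]
  if (i == 1) return(z[1])
  # log-linear interpolation between the bracketing points
  lf <- log(fraction)
  l1 <- log(v[i - 1]); l2 <- log(v[i])
  z[i - 1] + (lf - l1) / (l2 - l1) * (z[i] - z[i - 1])
}
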