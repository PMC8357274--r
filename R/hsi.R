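#' Hyperspectral reflectance cube
#'
#' A 3-D array of reflectance spectra over an image: rows x columns x
#' wavelengths, with the column axis oriented along depth when a
#' vertically sliced core is imaged. Spatial resolution metadata is
#' carried through but not used in computation.
#'
#' @param reflectance 3-D array (x, y, lambda), strictly positive
#' @param wavelength wavelength grid in nm, length `dim(reflectance)[3]`
#' @param pixel_size_um spatial resolution metadata (default 60 um/pixel)
#' @return an `hsi_cube` list.
#' @export
hsi_cube <- function(reflectance, wavelength, pixel_size_um = 60) {
  reflectance <- as.array(reflectance)
  if (length(dim(reflectance)) != 3) stopf("reflectance must be a 3-D array")
  if (dim(reflectance)[3] != length(wavelength)) {
    stopf("third dimension must match the wavelength grid")
  }
  if (any(reflectance <= 0)) stopf("reflectance must be strictly positive")
  if (any(diff(wavelength) <= 0)) stopf("wavelength grid must be increasing")
  structure(list(reflectance = reflectance,
                 wavelength = as.numeric(wavelength),
                 pixel_size_um = pixel_size_um),
            class = "hsi_cube")
}

#' Second-derivative pigment abundance map from a hyperspectral cube
#'
#' Simplified second-derivative spectral analysis: each pixel's spectrum
#' is Savitzky-Golay smoothed ([smooth_spectrum()]), its second
#' derivative with respect to wavelength is taken by central differences,
#' and the maximum of the second derivative within the pigment's band
#' window is reported. An absorption dip in reflectance has positive
#' curvature at its centre, so the map is the positive-curvature
#' magnitude (floored at 0); it grows monotonically with dip strength.
#'
#' @param cube an [hsi_cube()]
#' @param band a [band_definition()]; the window searched is the peak
#'   +/- `window_half_width`
#' @param window_nm,passes smoothing parameters, see [smooth_spectrum()]
#' @return matrix (x, y) of band curvature amplitudes (per nm^2).
#' @export
hyperspectral_pigment_map <- function(cube, band, window_nm = 15,
                                      passes = 2) {
  stopifnot(inherits(cube, "hsi_cube"), inherits(band, "band_definition"))
  lam <- cube$wavelength
  lo <- band$peak - band$window_half_width
  hi <- band$peak + band$window_half_width
  if (lo < min(lam) || hi > max(lam)) {
    stopf("band window [%g, %g] nm outside the cube's wavelength grid",
          lo, hi)
  }
  nl <- length(lam)
  win <- which(lam >= lo - 1e-9 & lam <= hi + 1e-9)
  # central second differences need interior points
  win <- win[win > 1 & win < nl]
  if (length(win) == 0) stopf("band window has no interior wavelengths")
  d <- dim(cube$reflectance)
  out <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      s <- smooth_spectrum(cube$reflectance[i, j, ], lam,
                           window_nm = window_nm, passes = passes)
      d2 <- (s[win + 1] - 2 * s[win] + s[win - 1]) /
        ((lam[win + 1] - lam[win]) * (lam[win] - lam[win - 1]))
      out[i, j] <- max(c(d2, 0))
    }
  }
  out
}
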