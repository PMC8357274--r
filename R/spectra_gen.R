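#' Depth-resolved irradiance spectra
#'
#' Container for scalar-irradiance spectra E(lambda, z) measured (or
#' simulated) at a series of depths. Depth 0 mm is the mat-salt
#' interface; the salt crust occupies negative depths.
#'
#' @param wavelength strictly increasing wavelength grid in nm
#' @param depth strictly increasing depth grid in mm
#' @param irradiance matrix (wavelength x depth) of positive irradiances,
#'   arbitrary linear units
#' @param normalized logical flag: has the stack been normalized to the
#'   interface spectrum?
#' @return a `spectral_stack` list.
#' @export
spectral_stack <- function(wavelength, depth, irradiance, normalized = FALSE) {
  wavelength <- as.numeric(wavelength)
  depth <- as.numeric(depth)
  if (length(wavelength) == 0) stopf("empty wavelength grid")
  if (any(diff(wavelength) <= 0)) stopf("wavelength grid must be strictly increasing")
  if (length(depth) > 1 && any(diff(depth) <= 0)) {
    stopf("depth grid must be strictly increasing")
  }
  irradiance <- as.matrix(irradiance)
  if (nrow(irradiance) != length(wavelength) ||
      ncol(irradiance) != length(depth)) {
    stopf("irradiance must be a %d x %d matrix (wavelength x depth)",
          length(wavelength), length(depth))
  }
  if (any(irradiance <= 0)) stopf("irradiance must be strictly positive")
  structure(list(wavelength = wavelength, depth = depth,
                 irradiance = irradiance, normalized = normalized),
            class = "spectral_stack")
}

#' @export
print.spectral_stack <- function(x, ...) {
  cat(sprintf("<spectral_stack> %d wavelengths (%g..%g nm) x %d depths (%g..%g mm)%s\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              length(x$depth), min(x$depth), max(x$depth),
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Halogen-lamp-like incident spectrum
#'
#' Smooth blackbody-shaped spectral distribution (default 3200 K, typical
#' of a halogen light source), normalized to a maximum of 1 over the
#' given grid.
#'
#' @param wavelength wavelength grid in nm
#' @param temperature colour temperature in K
#' @return numeric vector of relative spectral irradiance.
#' @export
incident_spectrum <- function(wavelength, temperature = 3200) {
  lam <- wavelength * 1e-9
  hc_over_k <- 1.43877e-2 # m K
  e <- lam^-5 / expm1(hc_over_k / (lam * temperature))
  e / max(e)
}

#' Generate a synthetic irradiance spectral stack
#'
#' Builds E(lambda, z) = E(lambda, 0^-) * exp(-tau(lambda, z)) where the
#' optical depth tau accumulates the salt-crust attenuation (uniform in
#' lambda, negative depths), the per-layer matrix attenuation, and the
#' Gaussian pigment bands of the scenario (Gaussian in lambda and in
#' depth; band integrals over depth are evaluated in closed form). The
#' incident spectrum enters at the top of the salt crust.
#'
#' @param scenario a [mat_scenario()]
#' @param wavelengths monotone wavelength grid in nm
#' @param depth_step depth step in mm (default 0.4, the measurement
#'   interval of the profiling setup)
#' @param surface_spectrum incident spectral irradiance at the top of the
#'   salt crust: a numeric vector on `wavelengths` or a function of
#'   wavelength; defaults to [incident_spectrum()]
#' @param noise_sd override for the additive irradiance noise sd
#'   (truncated so irradiance stays positive); defaults to the scenario's
#' @return a [spectral_stack()] spanning the salt crust (negative depths)
#'   and the mat.
#' @export
generate_spectral_stack <- function(scenario,
                                    wavelengths = seq(200, 950, by = 1),
                                    depth_step = 0.4,
                                    surface_spectrum = incident_spectrum,
                                    noise_sd = NULL) {
  stopifnot(inherits(scenario, "mat_scenario"))
  if (length(wavelengths) == 0) stopf("empty wavelength grid")
  if (depth_step <= 0) stopf("depth_step must be > 0")
  wavelengths <- as.numeric(wavelengths)
  if (any(diff(wavelengths) <= 0)) stopf("wavelength grid must be monotone increasing")

  salt_th <- scenario$salt$thickness_mm %||% 0
  salt_k <- scenario$salt$attenuation %||% 0
  bounds <- scenario$layer_boundaries
  z_bot <- bounds[length(bounds)]
  z <- seq(-salt_th, z_bot, by = depth_step)
  if (abs(z[length(z)] - z_bot) > 1e-9) z <- c(z, z_bot)

  e0 <- if (is.function(surface_spectrum)) surface_spectrum(wavelengths)
        else as.numeric(surface_spectrum)
  if (length(e0) != length(wavelengths) || any(e0 <= 0)) {
    stopf("surface spectrum must be positive and match the wavelength grid")
  }

  # optical depth of the matrix (lambda-independent), per depth
  tau_matrix <- vapply(z, function(zi) {
    salt_part <- salt_k * overlap_len(-salt_th, zi, -salt_th, 0)
    mat_part <- sum(scenario$matrix_attenuation *
                      overlap_len(0, max(zi, 0), bounds[-length(bounds)],
                                  bounds[-1]))
    salt_part + mat_part
  }, numeric(1))

  # pigment bands: Gaussian in lambda, closed-form depth integral over [0, z]
  tau_bands <- matrix(0, length(wavelengths), length(z))
  for (b in scenario$pigment_bands) {
    lam_shape <- exp(-(wavelengths - b$center_wavelength)^2 /
                       (2 * b$bandwidth_sigma^2))
    zi <- pmax(z, 0)
    depth_int <- b$depth_sigma * sqrt(2 * pi) *
      (stats::pnorm((zi - b$depth_center) / b$depth_sigma) -
         stats::pnorm((0 - b$depth_center) / b$depth_sigma))
    tau_bands <- tau_bands + b$peak_attenuation * outer(lam_shape, depth_int)
  }

  e <- outer(e0, exp(-tau_matrix)) * exp(-tau_bands)

  sd_i <- noise_sd %||% (scenario$noise_sd$irradiance %||% 0)
  if (sd_i > 0) {
    floor_e <- 1e-12 * max(e)
    e <- with_local_seed(scenario$seed, {
      pmax(e + matrix(stats::rnorm(length(e), sd = sd_i), nrow(e)), floor_e)
    })
  }
  spectral_stack(wavelengths, z, e, normalized = FALSE)
}
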