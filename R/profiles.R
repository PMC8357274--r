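#' Depth profile of a measured or simulated quantity
#'
#' The basic container for microsensor data: one quantity (`O2`, `H2S`,
#' `pH` or `Stot`) on a strictly increasing depth grid. Depths are in mm
#' with the mat surface at 0 and positive values downward; concentrations
#' are in mol m^-3 (equivalently mmol L^-1); pH is unitless.
#'
#' @param depth_mm numeric, strictly increasing depths in mm
#' @param value numeric, same length as `depth_mm`
#' @param quantity one of `"O2"`, `"H2S"`, `"pH"`, `"Stot"` or another label
#' @param condition illumination condition, `"light"` or `"dark"`
#' @param unit unit string; defaults to `"mol m-3"` (`""` for pH)
#' @param salinity_context percent (w/v) salinity of the porewater, optional
#' @param replicate_id optional replicate label
#' @return a `depth_profile`: a data.frame with columns `depth_mm` and
#'   `value` and metadata attributes.
#' @export
depth_profile <- function(depth_mm, value,
                          quantity = "O2",
                          condition = c("light", "dark"),
                          unit = NULL,
                          salinity_context = NA_real_,
                          replicate_id = NA_character_) {
  condition <- match.arg(condition)
  depth_mm <- as.numeric(depth_mm)
  value <- as.numeric(value)
  if (length(depth_mm) != length(value)) {
    stopf("depth_mm and value must have equal length")
  }
  if (any(diff(depth_mm) <= 0)) {
    stopf("depth grid must be strictly increasing")
  }
  if (is.null(unit)) unit <- if (identical(quantity, "pH")) "" else "mol m-3"
  if (identical(quantity, "pH") && any(value < 0 | value > 14)) {
    stopf("pH values outside [0, 14]")
  }
  x <- data.frame(depth_mm = depth_mm, value = value)
  structure(x,
            quantity = quantity, condition = condition, unit = unit,
            salinity_context = salinity_context, replicate_id = replicate_id,
            class = c("depth_profile", "data.frame"))
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("<depth_profile> %s (%s), %d depths %.3g..%.3g mm [%s]\n",
              attr(x, "quantity"), attr(x, "condition"), nrow(x),
              min(x$depth_mm), max(x$depth_mm), attr(x, "unit")))
  invisible(x)
}

#' Solute diffusivity specification
#'
#' Bundles the free-solution molecular diffusivity with the porosity
#' correction used to obtain the effective sediment diffusivity. The
#' default correction is `D_eff = porosity * d0`; an alternative tortuosity
#' form `D_eff = d0 / (1 + 3 * (1 - porosity))` is available as
#' `"tortuosity"`.
#'
#' @param solute solute label (e.g. `"O2"`, `"Stot"`)
#' @param d0 molecular diffusivity in m^2 s^-1; must be > 0
#' @param porosity volume fraction of porewater, in (0, 1]
#' @param correction `"porosity"` (default) or `"tortuosity"`
#' @return a `diffusion_spec` list.
#' @export
#' @examples
#' diffusion_spec("O2", 1.5e-9, porosity = 0.3)
diffusion_spec <- function(solute, d0, porosity = 0.3,
                           correction = c("porosity", "tortuosity")) {
  correction <- match.arg(correction)
  if (!is.numeric(d0) || d0 <= 0) stopf("d0 must be > 0")
  if (porosity <= 0 || porosity > 1) stopf("porosity must be in (0, 1]")
  structure(list(solute = solute, d0 = d0, porosity = porosity,
                 correction = correction),
            class = "diffusion_spec")
}

#' Effective diffusivity after porosity correction
#'
#' @param spec a [diffusion_spec()]
#' @return effective diffusivity in m^2 s^-1.
#' @export
effective_diffusivity <- function(spec) {
  stopifnot(inherits(spec, "diffusion_spec"))
  switch(spec$correction,
         porosity = spec$porosity * spec$d0,
         tortuosity = spec$d0 / (1 + 3 * (1 - spec$porosity)))
}

#' Total-sulfur diffusivity from the oxygen diffusivity
#'
#' The diffusivity of total sulfide is taken as a fixed fraction of the
#' oxygen diffusivity, `D_Stot = 0.64 * D_O2`.
#'
#' @param d_o2 oxygen diffusivity in m^2 s^-1; must be > 0
#' @return total-sulfur diffusivity in m^2 s^-1.
#' @export
#' @examples
#' stot_diffusivity(1.5e-9) # 9.6e-10, ~1e-9 at one significant figure
stot_diffusivity <- function(d_o2) {
  if (!is.numeric(d_o2) || any(d_o2 <= 0)) stopf("d_o2 must be > 0")
  0.64 * d_o2
}

new_flux_profile <- function(depth_mm, flux, quantity, condition) {
  structure(data.frame(depth_mm = depth_mm, flux = flux),
            quantity = quantity, condition = condition,
            unit = "mol m-2 s-1",
            class = c("flux_profile", "data.frame"))
}

new_rate_profile <- function(depth_mm, rate, quantity, condition,
                             interval_edges = NULL) {
  structure(data.frame(depth_mm = depth_mm, rate = rate),
            quantity = quantity, condition = condition,
            unit = "mol m-3 s-1", interval_edges = interval_edges,
            class = c("rate_profile", "data.frame"))
}

#' Volumetric rate profile on a depth grid
#'
#' Constructor for piecewise rate profiles, e.g. a known ground truth for
#' synthetic tracer cores. Rates are in mol m^-3 s^-1 with production
#' positive and consumption negative.
#'
#' @param depth_mm depth grid in mm (midpoints of the intervals the rates
#'   apply to)
#' @param rate rates in mol m^-3 s^-1
#' @param quantity quantity label the rates refer to
#' @param condition illumination condition label
#' @param interval_edges optional vector of interval edges (length
#'   `length(depth_mm) + 1`) recording the supports of each rate value
#' @return a `rate_profile` data.frame.
#' @export
rate_profile <- function(depth_mm, rate, quantity = "SRR",
                         condition = "dark", interval_edges = NULL) {
  if (length(depth_mm) != length(rate)) stopf("depth and rate length differ")
  if (any(!is.finite(rate))) stopf("rates must be finite")
  new_rate_profile(as.numeric(depth_mm), as.numeric(rate), quantity,
                   condition, interval_edges)
}
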