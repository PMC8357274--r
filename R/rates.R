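#' Total sulfide from H2S and pH
#'
#' Computes total sulfide S_tot = H2S + HS^- from the measured H2S
#' profile and pH via the first dissociation equilibrium:
#' `S_tot(z) = H2S(z) * (1 + 10^(pH(z) - pK1))`. The second dissociation
#' is negligible at porewater pH. Hypersaline activity corrections are
#' not applied; the output records the pK1 used.
#'
#' @param h2s a [depth_profile()] of H2S (mol m^-3)
#' @param ph a [depth_profile()] of pH
#' @param pk1 first dissociation constant of H2S (default 7.0)
#' @param interpolate if `TRUE`, linearly interpolate both inputs onto
#'   the union of their depth grids; if `FALSE` (default) mismatched
#'   grids are an error
#' @return a [depth_profile()] of S_tot in mol m^-3.
#' @export
total_sulfide <- function(h2s, ph, pk1 = 7.0, interpolate = FALSE) {
  stopifnot(inherits(h2s, "depth_profile"), inherits(ph, "depth_profile"))
  if (!isTRUE(all.equal(h2s$depth_mm, ph$depth_mm))) {
    if (!interpolate) {
      stopf("H2S and pH are on different depth grids; set interpolate = TRUE")
    }
    grid <- sort(union(h2s$depth_mm, ph$depth_mm))
    grid <- grid[grid >= max(min(h2s$depth_mm), min(ph$depth_mm)) &
                   grid <= min(max(h2s$depth_mm), max(ph$depth_mm))]
    h2s_v <- stats::approx(h2s$depth_mm, h2s$value, grid)$y
    ph_v <- stats::approx(ph$depth_mm, ph$value, grid)$y
  } else {
    grid <- h2s$depth_mm
    h2s_v <- h2s$value
    ph_v <- ph$value
  }
  stot <- h2s_v * (1 + 10^(ph_v - pk1))
  out <- depth_profile(grid, stot, quantity = "Stot",
                       condition = attr(h2s, "condition"),
                       salinity_context = attr(h2s, "salinity_context"))
  attr(out, "pk1") <- pk1
  attr(out, "activity_corrected") <- FALSE
  out
}

#' Optional pre-differentiation smoothing of a profile
#'
#' Moving local linear fit (window in points, shrunk at the edges).
#' Double differencing amplifies sensor noise, so smoothing can help on
#' measured profiles; it is off by default so analytic tests stay exact.
#' @noRd
smooth_profile_values <- function(depth, value, window_pts) {
  n <- length(value)
  hw <- (window_pts - 1) %/% 2
  vapply(seq_len(n), function(i) {
    idx <- max(1, i - hw):min(n, i + hw)
    if (length(idx) < 3) return(value[i])
    x <- depth[idx] - depth[i]
    fit <- stats::lm.fit(cbind(1, x), value[idx])
    fit$coefficients[1]
  }, numeric(1))
}

#' Diffusive flux from a concentration profile
#'
#' Fick's first law with the porosity-corrected diffusivity:
#' `J = -D_eff * dC/dz`, with depth converted from mm to m internally.
#' Positive flux is downward (toward greater depth).
#'
#' @param profile a [depth_profile()] of concentration (mol m^-3)
#' @param spec a [diffusion_spec()]
#' @param mode `"finite_difference"`: one flux per consecutive depth
#'   interval, located at the interval midpoint; `"fitted_slope"`: slope
#'   of a moving local linear fit (window `window_pts`), one flux per
#'   depth point
#' @param window_pts window (points) for `"fitted_slope"`; also used for
#'   optional pre-smoothing
#' @param smooth if `TRUE`, smooth the profile with a moving linear fit
#'   before differencing (off by default)
#' @return a `flux_profile` data.frame with columns `depth_mm` and `flux`
#'   (mol m^-2 s^-1).
#' @export
#' @examples
#' p <- depth_profile(seq(0, 2, 0.5), 0.25 - 0.1 * seq(0, 2, 0.5))
#' diffusive_flux(p, diffusion_spec("O2", 1.5e-9, 0.3))
diffusive_flux <- function(profile, spec,
                           mode = c("finite_difference", "fitted_slope"),
                           window_pts = 3, smooth = FALSE) {
  stopifnot(inherits(profile, "depth_profile"),
            inherits(spec, "diffusion_spec"))
  mode <- match.arg(mode)
  z <- profile$depth_mm
  v <- profile$value
  if (length(z) < 2) stopf("need at least 2 depth points to compute a flux")
  if (anyDuplicated(z)) stopf("duplicate depths in profile")
  if (smooth) v <- smooth_profile_values(z, v, window_pts)
  d_eff <- effective_diffusivity(spec)
  z_m <- mm_to_m(z)
  if (mode == "finite_difference") {
    flux <- -d_eff * diff(v) / diff(z_m)
    mid <- (z[-1] + z[-length(z)]) / 2
    new_flux_profile(mid, flux, attr(profile, "quantity"),
                     attr(profile, "condition"))
  } else {
    n <- length(z)
    hw <- (window_pts - 1) %/% 2
    slope <- vapply(seq_len(n), function(i) {
      idx <- max(1, i - hw):min(n, i + hw)
      if (length(idx) < 2) return(NA_real_)
      stats::lm.fit(cbind(1, z_m[idx]), v[idx])$coefficients[2]
    }, numeric(1))
    new_flux_profile(z, -d_eff * slope, attr(profile, "quantity"),
                     attr(profile, "condition"))
  }
}

#' Local volumetric conversion rates from the flux divergence
#'
#' At steady state the net local production rate is the depth derivative
#' (1-D divergence) of the diffusive flux: `R(z) = dJ/dz`, discretised on
#' the midpoints of consecutive flux intervals. With depth and flux both
#' positive downward, flux diverging away from a depth means production
#' there (positive rate); converging flux means consumption (negative).
#'
#' @param flux a `flux_profile` from [diffusive_flux()]
#' @return a `rate_profile` with rates in mol m^-3 s^-1 located at the
#'   flux-interval midpoints; the `interval_edges` attribute records the
#'   flux depths bounding each rate, which [areal_rate()] uses for exact
#'   conservation.
#' @export
local_rates <- function(flux) {
  stopifnot(inherits(flux, "flux_profile"))
  z <- flux$depth_mm
  if (length(z) < 2) stopf("need at least 2 flux points to compute rates")
  rate <- diff(flux$flux) / diff(mm_to_m(z))
  mid <- (z[-1] + z[-length(z)]) / 2
  new_rate_profile(mid, rate, attr(flux, "quantity"),
                   attr(flux, "condition"), interval_edges = z)
}

#' Areal rate over a depth zone
#'
#' Integrates the volumetric rate profile over a depth zone, in
#' mol m^-2 s^-1. Each rate value is treated as constant over its source
#' interval (the flux depths it was differenced between), which makes the
#' integral over any zone aligned with those intervals exactly equal to
#' the flux difference across it (discrete conservation). A trapezoid
#' rule on the midpoint grid is available as an alternative.
#'
#' @param rates a `rate_profile`
#' @param zone numeric length-2 depth interval in mm; defaults to the
#'   full span of the profile
#' @param sign `"net"` (default): integrate rates as they are;
#'   `"production"`: only positive rates; `"consumption"`: only negative
#'   rates, reported as a positive magnitude
#' @param method `"interval"` (default, conservative) or `"trapezoid"`
#' @return areal rate in mol m^-2 s^-1.
#' @export
areal_rate <- function(rates, zone = NULL,
                       sign = c("net", "production", "consumption"),
                       method = c("interval", "trapezoid")) {
  stopifnot(inherits(rates, "rate_profile"))
  sign <- match.arg(sign)
  method <- match.arg(method)
  edges <- attr(rates, "interval_edges")
  if (is.null(edges)) {
    mids <- rates$depth_mm
    edges <- c(mids[1] - (mids[2] - mids[1]) / 2,
               (mids[-1] + mids[-length(mids)]) / 2,
               mids[length(mids)] +
                 (mids[length(mids)] - mids[length(mids) - 1]) / 2)
  }
  zone <- zone %||% range(edges)
  if (length(zone) != 2 || zone[2] <= zone[1]) stopf("empty zone")
  r <- switch(sign,
              net = rates$rate,
              production = pmax(rates$rate, 0),
              consumption = pmin(rates$rate, 0))
  if (method == "interval") {
    w <- overlap_len(zone[1], zone[2], edges[-length(edges)], edges[-1])
    if (sum(w) == 0) stopf("zone [%g, %g] mm does not overlap the profile",
                           zone[1], zone[2])
    res <- sum(r * mm_to_m(w))
  } else {
    keep <- rates$depth_mm >= zone[1] & rates$depth_mm <= zone[2]
    if (sum(keep) < 2) stopf("zone contains fewer than 2 rate points")
    res <- trapz(mm_to_m(rates$depth_mm[keep]), r[keep])
  }
  if (sign == "consumption") res <- abs(res)
  res
}

#' Average volumetric rate over the oxic zone
#'
#' Mean of the rate profile over the depths where the oxygen
#' concentration exceeds a threshold, the convention used for
#' depth-averaged volumetric photosynthesis and respiration. The mean is
#' length-weighted over the rate intervals whose midpoint O2 (linearly
#' interpolated) passes the mask.
#'
#' @param rates a `rate_profile`
#' @param o2 a [depth_profile()] of O2 overlapping the rate profile
#' @param threshold oxic threshold in mol m^-3 (default 0; set to the
#'   sensor detection limit if desired)
#' @return mean rate in mol m^-3 s^-1.
#' @export
avg_volumetric <- function(rates, o2, threshold = 0) {
  stopifnot(inherits(rates, "rate_profile"), inherits(o2, "depth_profile"))
  o2_at <- stats::approx(o2$depth_mm, o2$value, rates$depth_mm,
                         rule = 1)$y
  mask <- !is.na(o2_at) & o2_at > threshold
  if (!any(mask)) {
    stopf("no depth satisfies O2 > %g mol m-3 within the rate profile",
          threshold)
  }
  edges <- attr(rates, "interval_edges")
  w <- if (is.null(edges)) rep(1, nrow(rates)) else diff(edges)
  sum(rates$rate[mask] * w[mask]) / sum(w[mask])
}

#' Upward sulfide flux at the top of the sulfide gradient
#'
#' Magnitude of the diffusive total-sulfide flux into the oxic zone,
#' estimated from a linear fit over a depth window starting at the lower
#' boundary of the oxic zone (where the upward sulfide gradient begins).
#'
#' @param stot a [depth_profile()] of total sulfide
#' @param spec a [diffusion_spec()] for total sulfur
#' @param oxic_lower_bound depth (mm) of the bottom of the oxic zone
#' @param window_mm fit window below `oxic_lower_bound` (default 1 mm)
#' @return upward flux magnitude in mol m^-2 s^-1, with a `direction`
#'   attribute (`"upward"` when sulfide increases with depth).
#' @export
interfacial_sulfide_flux <- function(stot, spec, oxic_lower_bound,
                                     window_mm = 1) {
  stopifnot(inherits(stot, "depth_profile"), inherits(spec, "diffusion_spec"))
  keep <- stot$depth_mm >= oxic_lower_bound &
    stot$depth_mm <= oxic_lower_bound + window_mm
  if (sum(keep) < 2) {
    stopf("fit window [%g, %g] mm contains fewer than 2 points",
          oxic_lower_bound, oxic_lower_bound + window_mm)
  }
  z_m <- mm_to_m(stot$depth_mm[keep])
  slope <- stats::lm.fit(cbind(1, z_m), stot$value[keep])$coefficients[2]
  d_eff <- effective_diffusivity(spec)
  res <- d_eff * abs(slope)
  attr(res, "direction") <- if (slope > 0) "upward" else "downward"
  res
}

#' Standing pool of a solute over a depth zone
#'
#' @param profile a [depth_profile()] of concentration
#' @param zone numeric length-2 depth interval in mm (default: full span)
#' @param mode `"depth_averaged"` (trapezoidal mean, mol m^-3) or
#'   `"depth_integrated"` (trapezoidal integral, mol m^-2)
#' @return the pool in the units of the chosen mode.
#' @export
pool <- function(profile, zone = NULL,
                 mode = c("depth_averaged", "depth_integrated")) {
  stopifnot(inherits(profile, "depth_profile"))
  mode <- match.arg(mode)
  zone <- zone %||% range(profile$depth_mm)
  if (length(zone) != 2 || zone[2] <= zone[1]) stopf("empty zone")
  keep <- profile$depth_mm >= zone[1] & profile$depth_mm <= zone[2]
  if (sum(keep) < 2) stopf("zone contains fewer than 2 profile points")
  z <- profile$depth_mm[keep]
  v <- profile$value[keep]
  integral <- trapz(mm_to_m(z), v)
  switch(mode,
         depth_averaged = integral / mm_to_m(z[length(z)] - z[1]),
         depth_integrated = integral)
}

#' Turnover time of a standing pool
#'
#' @param pool standing pool in mol m^-3 (or mol m^-2 against an areal
#'   rate)
#' @param rate production or consumption rate in matching units per s
#'   (> 0)
#' @return turnover time in seconds.
#' @export
#' @examples
#' turnover_days(turnover_time(0.2, 2.4e-6)) # ~0.96 day
turnover_time <- function(pool, rate) {
  if (!is.numeric(rate) || rate <= 0) {
    stopf("turnover is undefined for rate <= 0")
  }
  pool / rate
}

#' @rdname turnover_time
#' @param seconds a time in seconds
#' @return `turnover_days()`: the time in days.
#' @export
turnover_days <- function(seconds) seconds / SECONDS_PER_DAY

#' Ratio of two rates
#'
#' @param numerator,denominator rates in matching units; denominator > 0
#' @return the plain ratio; format with [fold_format()] for the
#'   conventional "n-fold" string.
#' @export
#' @examples
#' fold_format(fold_change(1.9e-7, 2.1e-8)) # "9-fold"
fold_change <- function(numerator, denominator) {
  if (!is.numeric(denominator) || denominator <= 0) {
    stopf("fold change is undefined for denominator <= 0")
  }
  numerator / denominator
}
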