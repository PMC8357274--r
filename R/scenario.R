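#' Gaussian pigment absorption band
#'
#' Describes one photopigment as a Gaussian absorption band in wavelength
#' and a Gaussian abundance distribution in depth. Diagnostic centres used
#' throughout are chlorophyll a at 674 nm, phycocyanin at 624 nm,
#' bacteriochlorophyll c at 745 nm and bacteriochlorophyll a at 845 and
#' 902 nm.
#'
#' @param name pigment label
#' @param center_wavelength band centre in nm, within the instrument
#'   range \[200, 950\]
#' @param bandwidth_sigma Gaussian sigma of the band in nm (> 0)
#' @param peak_attenuation attenuation at band centre and depth centre,
#'   in mm^-1 (>= 0)
#' @param depth_center depth of maximum pigment abundance in mm
#' @param depth_sigma Gaussian sigma of the depth distribution in mm (> 0)
#' @return a `pigment_band` list.
#' @export
pigment_band <- function(name, center_wavelength, bandwidth_sigma,
                         peak_attenuation, depth_center, depth_sigma) {
  if (center_wavelength < 200 || center_wavelength > 950) {
    stopf("center_wavelength %s nm outside instrument range [200, 950]",
          center_wavelength)
  }
  if (bandwidth_sigma <= 0 || depth_sigma <= 0) stopf("sigma values must be > 0")
  if (peak_attenuation < 0) stopf("peak_attenuation must be >= 0")
  structure(list(name = name,
                 center_wavelength = center_wavelength,
                 bandwidth_sigma = bandwidth_sigma,
                 peak_attenuation = peak_attenuation,
                 depth_center = depth_center,
                 depth_sigma = depth_sigma),
            class = "pigment_band")
}

#' Synthetic mat scenario with known ground truth
#'
#' A scenario fixes everything the synthetic generators need: layer
#' geometry, per-solute piecewise-constant volumetric rates and boundary
#' conditions for the steady-state reaction-diffusion solver, per-layer
#' matrix light attenuation and pigment bands for the spectral generator,
#' the sulfate-reduction truth for tracer cores, and noise levels plus a
#' seed. With all noise set to 0 and the same seed, every generator is
#' bit-reproducible.
#'
#' @param layer_boundaries strictly increasing depths in mm; the first
#'   entry is 0 (the mat surface), so `n` layers need `n + 1` boundaries
#' @param rates named list; one numeric vector of per-layer volumetric
#'   rates (mol m^-3 s^-1, production positive) per solute label
#' @param diffusivity named list of molecular diffusivities (m^2 s^-1)
#'   per solute label
#' @param porosity porewater volume fraction in (0, 1]
#' @param correction porosity-correction rule, see [diffusion_spec()]
#' @param boundary_conditions named list per solute; each element is a
#'   list with `top` and `bottom`, each either `list(type =
#'   "concentration", value = <mol m-3>)` or `list(type = "zero_flux")`
#' @param pigment_bands list of [pigment_band()] objects
#' @param matrix_attenuation per-layer scalar attenuation in mm^-1
#'   (length 1 is recycled to all layers)
#' @param salt list with `thickness_mm` and `attenuation` (mm^-1) for the
#'   overlying salt crust; the crust occupies negative depths above the
#'   mat-salt interface at 0 mm
#' @param srr_truth a [rate_profile()] giving the true sulfate-reduction
#'   rate per tracer-core section (its `interval_edges` attribute defines
#'   the sectioning)
#' @param tracer list of tracer-incubation context: `sulfate_mol_m3`,
#'   `porosity`, `incubation_time_s`, `total_activity_kBq`
#' @param community list with `layers`, `taxon_profiles` (matrix taxa x
#'   layers of proportions) and `total_cells` per layer
#' @param noise_sd list of noise levels: `concentration` (additive sd,
#'   mol m^-3), `irradiance` (additive sd, truncated at zero), and
#'   `activity_sdlog` (sdlog of the multiplicative log-normal noise on
#'   tracer activities)
#' @param seed integer seed used by all generators
#' @return a `mat_scenario` list.
#' @seealso [example_scenario()] for a fully parameterised hypersaline
#'   mat, [solve_steady_state()], [generate_spectral_stack()],
#'   [generate_tracer_cores()], [generate_community()]
#' @export
mat_scenario <- function(layer_boundaries,
                         rates = list(),
                         diffusivity = list(),
                         porosity = 0.3,
                         correction = "porosity",
                         boundary_conditions = list(),
                         pigment_bands = list(),
                         matrix_attenuation = 0,
                         salt = list(thickness_mm = 0, attenuation = 0),
                         srr_truth = NULL,
                         tracer = list(),
                         community = NULL,
                         noise_sd = list(concentration = 0,
                                         irradiance = 0,
                                         activity_sdlog = 0),
                         seed = 1L) {
  if (any(diff(layer_boundaries) <= 0)) {
    stopf("layer_boundaries must be strictly increasing")
  }
  if (porosity <= 0 || porosity > 1) stopf("porosity must be in (0, 1]")
  if (length(diffusivity) && any(unlist(diffusivity) <= 0)) {
    stopf("diffusivities must be > 0")
  }
  n_layers <- length(layer_boundaries) - 1
  matrix_attenuation <- rep_len(as.numeric(matrix_attenuation), n_layers)
  if (any(matrix_attenuation < 0)) stopf("matrix_attenuation must be >= 0")
  for (s in names(rates)) {
    if (length(rates[[s]]) != n_layers) {
      stopf("rates for '%s' must have one value per layer (%d)", s, n_layers)
    }
  }
  structure(list(layer_boundaries = as.numeric(layer_boundaries),
                 rates = rates,
                 diffusivity = diffusivity,
                 porosity = porosity,
                 correction = correction,
                 boundary_conditions = boundary_conditions,
                 pigment_bands = pigment_bands,
                 matrix_attenuation = matrix_attenuation,
                 salt = salt,
                 srr_truth = srr_truth,
                 tracer = tracer,
                 community = community,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "mat_scenario")
}

#' @export
print.mat_scenario <- function(x, ...) {
  cat(sprintf("<mat_scenario> %d layers over %g..%g mm, solutes: %s\n",
              length(x$layer_boundaries) - 1, min(x$layer_boundaries),
              max(x$layer_boundaries),
              paste(names(x$rates), collapse = ", ")))
  invisible(x)
}

#' Default hypersaline mat scenario
#'
#' A five-layer mat (orange, green, brown, black, gray) over 6 mm under a
#' 2-mm salt crust, parameterised to the conditions of a flooded sabkha
#' mat: oxygenic photosynthesis peaking near 2 and 4 mm depth, sulfide
#' supplied from the underlying sediment and consumed in the anoxygenic
#' photic zone, matrix attenuation such that PAR falls to 1 % of the
#' surface level at 3.5 mm, a nearly transparent salt crust (~1 % total
#' loss), the five diagnostic pigment bands, a sulfate-reduction truth
#' peaking at ~7 mm with a 3-cm average of ~2.4e-6 mol m^-3 s^-1, and a
#' five-layer community in which archaea dominate the black layer.
#'
#' @param seed integer seed
#' @param noise one of `"default"` (realistic sensor/counting noise) or
#'   `"none"` (exact ground truth)
#' @return a [mat_scenario()].
#' @export
example_scenario <- function(seed = 1L, noise = c("default", "none")) {
  noise <- match.arg(noise)
  bounds <- c(0, 1, 2, 3.5, 4.5, 6)

  rates <- list(
    # mol m-3 s-1 per layer, production positive; O2 rate magnitudes match
    # the flooded-mat volumetric budget (photosynthesis a few 1e-4, dark
    # respiration ~1e-4) and are balanced so concentrations stay
    # non-negative with the stated boundary conditions
    O2_light = c(-1.0e-4, 2.2e-4, -0.8e-4, 1.0e-4, -5.587e-5),
    O2_dark  = c(-1.8e-4, 0, 0, 0, 0),
    Stot_light = c(-0.6e-5, -0.4e-5, -0.6e-5, 0.2e-5, 1.2e-5),
    Stot_dark  = c(-1.2e-5, -0.4e-5, -0.2e-5, 0.4e-5, 1.2e-5)
  )
  diffusivity <- list(O2_light = 1.5e-9, O2_dark = 1.5e-9,
                      Stot_light = stot_diffusivity(1.5e-9),
                      Stot_dark = stot_diffusivity(1.5e-9))
  bc_conc <- function(v) list(type = "concentration", value = v)
  boundary_conditions <- list(
    O2_light = list(top = bc_conc(0.2), bottom = list(type = "zero_flux")),
    O2_dark  = list(top = bc_conc(0.2), bottom = list(type = "zero_flux")),
    Stot_light = list(top = bc_conc(0), bottom = bc_conc(0.35)),
    Stot_dark  = list(top = bc_conc(0), bottom = bc_conc(0.35))
  )

  bands <- list(
    pigment_band("chl_a",       674,  8, 1.2, 1.5, 0.5),
    pigment_band("phycocyanin", 624, 10, 0.8, 1.8, 0.5),
    pigment_band("bchl_a_845",  845, 12, 0.6, 3.5, 0.6),
    pigment_band("bchl_a_902",  902, 12, 0.5, 3.5, 0.6),
    pigment_band("bchl_c",      745, 10, 0.6, 4.5, 0.6)
  )

  # PAR to 1 % of the surface level within 3.5 mm -> k = ln(100)/3.5
  k_mat <- log(100) / 3.5
  # ~1 % total transmission loss across the 2-mm crust
  salt <- list(thickness_mm = 2, attenuation = -log(0.99) / 2)

  # sulfate reduction truth per canonical core section (mm edges)
  srr_edges <- c(0, 3.2, 11.2, 19.2, 27.2, 30)
  srr_rates <- c(0.5e-6, 4.4e-6, 2.6e-6, 1.4e-6, 0.9e-6)
  srr_truth <- rate_profile(depth_mm = (srr_edges[-1] + srr_edges[-6]) / 2,
                            rate = srr_rates, quantity = "SRR",
                            interval_edges = srr_edges)

  taxa <- c("Cyanobacteria", "Chloroflexi", "Halobacteriales",
            "Deltaproteobacteria", "Chromatiales", "Rhodovibrio",
            "Salinibacter", "other")
  profiles <- cbind(
    orange = c(0.100, 0.150, 0.200, 0.030, 0.050, 0.120, 0.150, 0.200),
    green  = c(0.250, 0.200, 0.100, 0.040, 0.060, 0.100, 0.100, 0.150),
    brown  = c(0.080, 0.250, 0.150, 0.080, 0.080, 0.100, 0.080, 0.180),
    black  = c(0.010, 0.080, 0.560, 0.100, 0.050, 0.050, 0.050, 0.100),
    gray   = c(0.005, 0.050, 0.400, 0.150, 0.080, 0.050, 0.065, 0.200)
  )
  rownames(profiles) <- taxa
  community <- list(
    layers = colnames(profiles),
    taxon_profiles = profiles,
    total_cells = c(orange = 1.4e10, green = 1.6e10, brown = 1.2e10,
                    black = 4.3e9, gray = 3.5e9)
  )

  noise_sd <- if (noise == "none") {
    list(concentration = 0, irradiance = 0, activity_sdlog = 0)
  } else {
    # irradiance noise is absolute on a unit-peak incident spectrum;
    # 1e-5 is the quantisation floor of a 16-bit spectrometer ADC
    list(concentration = 0.001, irradiance = 1e-5, activity_sdlog = 0.10)
  }

  mat_scenario(
    layer_boundaries = bounds,
    rates = rates,
    diffusivity = diffusivity,
    porosity = 0.3,
    boundary_conditions = boundary_conditions,
    pigment_bands = bands,
    matrix_attenuation = k_mat,
    salt = salt,
    srr_truth = srr_truth,
    tracer = list(sulfate_mol_m3 = 300, porosity = 0.35,
                  incubation_time_s = 6.5 * 3600,
                  total_activity_kBq = 200),
    community = community,
    noise_sd = noise_sd,
    seed = seed
  )
}

#' Read a scenario from a YAML configuration file
#'
#' The file mirrors the arguments of [mat_scenario()]; pigment bands are
#' given as a list of mappings with the [pigment_band()] fields, and the
#' sulfate-reduction truth as `srr_truth: {edges_mm: [...], rates: [...]}`.
#'
#' @param path path to the YAML file
#' @return a [mat_scenario()].
#' @export
scenario_from_yaml <- function(path) {
  if (!file.exists(path)) stopf("scenario file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  bands <- lapply(cfg$pigment_bands, function(b) do.call(pigment_band, b))
  srr <- NULL
  if (!is.null(cfg$srr_truth)) {
    edges <- as.numeric(cfg$srr_truth$edges_mm)
    srr <- rate_profile(depth_mm = (edges[-1] + edges[-length(edges)]) / 2,
                        rate = as.numeric(cfg$srr_truth$rates),
                        quantity = "SRR", interval_edges = edges)
  }
  comm <- NULL
  if (!is.null(cfg$community)) {
    m <- do.call(cbind, lapply(cfg$community$taxon_profiles, as.numeric))
    rownames(m) <- cfg$community$taxa
    comm <- list(layers = colnames(m), taxon_profiles = m,
                 total_cells = stats::setNames(
                   as.numeric(cfg$community$total_cells), colnames(m)))
  }
  mat_scenario(
    layer_boundaries = as.numeric(cfg$layer_boundaries),
    rates = lapply(cfg$rates, as.numeric),
    diffusivity = cfg$diffusivity,
    porosity = cfg$porosity %||% 0.3,
    correction = cfg$correction %||% "porosity",
    boundary_conditions = cfg$boundary_conditions,
    pigment_bands = bands,
    matrix_attenuation = cfg$matrix_attenuation %||% 0,
    salt = cfg$salt %||% list(thickness_mm = 0, attenuation = 0),
    srr_truth = srr,
    tracer = cfg$tracer %||% list(),
    community = comm,
    noise_sd = cfg$noise_sd %||% list(concentration = 0, irradiance = 0,
                                      activity_sdlog = 0),
    seed = cfg$seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
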