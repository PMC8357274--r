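#' Tracer sample sheet constructor
#'
#' One row per syringe-core depth section of a 35S-sulfate incubation:
#' recovered total-reducible-inorganic-sulfur (TRIS) activity `a`,
#' residual sulfate activity `A`, and the incubation context needed by
#' [compute_srr()].
#'
#' @param core_id core label
#' @param section_top,section_bottom section edges in mm (bottom > top)
#' @param section_volume_ml section volume in ml
#' @param tris_kBq TRIS activity a in kBq (>= 0)
#' @param sulfate_residual_kBq residual sulfate activity A in kBq (>= 0)
#' @param sulfate_mol_m3 porewater sulfate concentration in mol m^-3
#' @param porosity porewater volume fraction
#' @param incubation_time_s incubation time in s (> 0 for non-blanks)
#' @param is_blank logical: instantaneous-kill blank?
#' @return a `tracer_samples` data.frame.
#' @export
tracer_samples <- function(core_id, section_top, section_bottom,
                           section_volume_ml, tris_kBq, sulfate_residual_kBq,
                           sulfate_mol_m3, porosity, incubation_time_s,
                           is_blank = FALSE) {
  x <- data.frame(core_id = core_id, section_top = section_top,
                  section_bottom = section_bottom,
                  section_volume_ml = section_volume_ml,
                  tris_kBq = tris_kBq,
                  sulfate_residual_kBq = sulfate_residual_kBq,
                  sulfate_mol_m3 = sulfate_mol_m3, porosity = porosity,
                  incubation_time_s = incubation_time_s, is_blank = is_blank)
  if (any(x$tris_kBq < 0) || any(x$sulfate_residual_kBq < 0)) {
    stopf("activities must be >= 0")
  }
  if (any(x$section_bottom <= x$section_top)) {
    stopf("section_bottom must exceed section_top")
  }
  if (any(!x$is_blank & x$incubation_time_s <= 0)) {
    stopf("incubation_time_s must be > 0 for non-blank samples")
  }
  class(x) <- c("tracer_samples", "data.frame")
  x
}

#' Generate synthetic 35S tracer cores from a known rate profile
#'
#' For each depth section the TRIS activity is set by inverting the
#' radiotracer rate equation (see [compute_srr()]) so that at zero noise
#' the computed rate reproduces the true rate exactly; the residual
#' sulfate activity is the remainder of the injected tracer, so
#' `a + A` equals the injected activity. Replicate noise is multiplicative
#' log-normal on the TRIS fraction.
#'
#' @param scenario a [mat_scenario()]; supplies tracer context
#'   (`sulfate_mol_m3`, `porosity`) and the noise level
#' @param true_srr a [rate_profile()] with `interval_edges` defining the
#'   sectioning; defaults to the scenario's `srr_truth`
#' @param incubation_time_s incubation time in s (default 6.5 h)
#' @param total_activity_kBq injected tracer activity per core (default
#'   200 kBq)
#' @param n_replicates number of replicate cores
#' @param seed seed (defaults to the scenario seed)
#' @param fractionation isotope fractionation correction (default 1.06)
#' @return a `tracer_samples` data.frame with one row per core section.
#' @export
generate_tracer_cores <- function(scenario, true_srr = NULL,
                                  incubation_time_s = NULL,
                                  total_activity_kBq = NULL,
                                  n_replicates = 3, seed = NULL,
                                  fractionation = 1.06) {
  stopifnot(inherits(scenario, "mat_scenario"))
  true_srr <- true_srr %||% scenario$srr_truth
  if (is.null(true_srr)) stopf("no sulfate-reduction truth available")
  incubation_time_s <- incubation_time_s %||%
    (scenario$tracer$incubation_time_s %||% 23400)
  total_activity_kBq <- total_activity_kBq %||%
    (scenario$tracer$total_activity_kBq %||% 200)
  if (incubation_time_s <= 0) stopf("incubation_time_s must be > 0")
  if (total_activity_kBq <= 0) stopf("total_activity_kBq must be > 0")
  sulfate <- scenario$tracer$sulfate_mol_m3 %||% 300
  phi <- scenario$tracer$porosity %||% scenario$porosity
  sdlog <- scenario$noise_sd$activity_sdlog %||% 0
  seed <- seed %||% scenario$seed

  edges <- attr(true_srr, "interval_edges")
  if (is.null(edges)) {
    stopf("true_srr must carry interval_edges defining the sectioning")
  }
  thick <- diff(edges)
  # TRIS fraction that makes compute_srr() return the true rate exactly
  frac <- true_srr$rate * incubation_time_s / (sulfate * phi * fractionation)
  if (any(frac > 1)) {
    stopf(paste0("true rate implies TRIS activity above the injected ",
                 "tracer (fraction %.3g > 1): tracer exhaustion, unphysical"),
          max(frac))
  }

  with_local_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(n_replicates), function(rep_i) {
      f <- frac
      if (sdlog > 0) {
        f <- pmin(f * stats::rlnorm(length(f), sdlog = sdlog), 1)
      }
      a <- f * total_activity_kBq
      tracer_samples(core_id = sprintf("core_%02d", rep_i),
                     section_top = edges[-length(edges)],
                     section_bottom = edges[-1],
                     section_volume_ml = 0.125 * thick,
                     tris_kBq = a,
                     sulfate_residual_kBq = total_activity_kBq - a,
                     sulfate_mol_m3 = sulfate, porosity = phi,
                     incubation_time_s = incubation_time_s,
                     is_blank = FALSE)
    }))
    class(out) <- c("tracer_samples", "data.frame")
    out
  })
}

#' Generate a synthetic layered community table
#'
#' Draws multinomial amplicon read counts per layer from known taxon
#' proportions and pairs them with total cell counts, providing ground
#' truth for absolute-abundance scaling.
#'
#' @param layer_labels layer names (columns)
#' @param taxon_profiles matrix (taxa x layers) of per-layer proportions,
#'   each column summing to 1 within 1e-9, all entries >= 0
#' @param total_counts_per_layer total cells per g wet weight, per layer
#' @param read_depth multinomial reads per layer (> 0)
#' @param seed integer seed
#' @return list with `read_counts` (taxa x layers), `rel_abundance`
#'   (columns summing to 1) and `total_cells`.
#' @export
generate_community <- function(layer_labels, taxon_profiles,
                               total_counts_per_layer,
                               read_depth = 1e5, seed = 1L) {
  taxon_profiles <- as.matrix(taxon_profiles)
  if (any(taxon_profiles < 0)) stopf("negative taxon proportions")
  sums <- colSums(taxon_profiles)
  if (any(abs(sums - 1) > 1e-9)) {
    stopf("per-layer proportions must sum to 1 (max deviation %.2g)",
          max(abs(sums - 1)))
  }
  if (read_depth <= 0) stopf("read_depth must be > 0")
  if (ncol(taxon_profiles) != length(layer_labels) ||
      length(total_counts_per_layer) != length(layer_labels)) {
    stopf("layer_labels, taxon_profiles columns and total counts must align")
  }
  counts <- with_local_seed(seed, {
    matrix(vapply(seq_along(layer_labels), function(j) {
      as.numeric(stats::rmultinom(1, size = read_depth,
                                  prob = taxon_profiles[, j]))
    }, numeric(nrow(taxon_profiles))), nrow = nrow(taxon_profiles),
    dimnames = list(rownames(taxon_profiles), layer_labels))
  })
  rel <- sweep(counts, 2, colSums(counts), "/")
  list(read_counts = counts, rel_abundance = rel,
       total_cells = stats::setNames(as.numeric(total_counts_per_layer),
                                     layer_labels))
}
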