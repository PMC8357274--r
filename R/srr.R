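#' Sulfate reduction rate from a 35S tracer sample
#'
#' Standard single-step radiotracer rate equation:
#' `SRR = [SO4] * porosity * (a / (a + A)) * fractionation / t`
#' where `a` is the recovered TRIS activity, `A` the residual sulfate
#' activity, and 1.06 the isotope fractionation correction. The porosity
#' factor converts the porewater-based sulfate concentration to a rate
#' per volume of whole sediment (mol m^-3 sediment s^-1).
#'
#' @param samples a [tracer_samples()] data.frame (non-blank rows)
#' @param fractionation isotope fractionation correction (default 1.06)
#' @return an `srr_results` data.frame with `core_id`, `section_top`,
#'   `section_bottom`, `depth_mid` (mm), `rate` (mol m^-3 s^-1) and a
#'   `below_mdl` flag (`NA` until [censor_rates()] is applied).
#' @export
#' @examples
#' s <- tracer_samples("c1", 0, 3.2, 0.4, tris_kBq = 0.2,
#'                     sulfate_residual_kBq = 199.8, sulfate_mol_m3 = 300,
#'                     porosity = 0.35, incubation_time_s = 23400)
#' compute_srr(s)$rate # 300 * 0.35 * 1e-3 * 1.06 / 23400
compute_srr <- function(samples, fractionation = 1.06) {
  stopifnot(inherits(samples, "data.frame"))
  if (any(samples$is_blank)) {
    stopf("blank samples passed to compute_srr(); use detection_limit()")
  }
  tot <- samples$tris_kBq + samples$sulfate_residual_kBq
  if (any(tot <= 0)) stopf("a + A must be > 0: no recovered activity")
  rate <- samples$sulfate_mol_m3 * samples$porosity *
    (samples$tris_kBq / tot) * fractionation / samples$incubation_time_s
  structure(data.frame(core_id = samples$core_id,
                       section_top = samples$section_top,
                       section_bottom = samples$section_bottom,
                       depth_mid = (samples$section_top +
                                      samples$section_bottom) / 2,
                       rate = rate,
                       below_mdl = NA),
            unit = "mol m-3 s-1",
            class = c("srr_results", "data.frame"))
}

#' Minimum detection limit from blanks
#'
#' Apparent rates are computed for each blank with the same rate
#' equation and the supplied incubation context; the MDL is their mean
#' plus `k` standard deviations (default 3).
#'
#' @param blanks a [tracer_samples()] data.frame of at least 2 blanks
#' @param sulfate_mol_m3,porosity,incubation_time_s context parameters of
#'   the real incubations; default to the blanks' own columns
#' @param k standard-deviation multiplier (default 3)
#' @param fractionation isotope fractionation correction
#' @return MDL in mol m^-3 s^-1.
#' @export
detection_limit <- function(blanks, sulfate_mol_m3 = NULL, porosity = NULL,
                            incubation_time_s = NULL, k = 3,
                            fractionation = 1.06) {
  stopifnot(inherits(blanks, "data.frame"))
  if (nrow(blanks) < 2) stopf("need at least 2 blanks for a detection limit")
  sulfate <- sulfate_mol_m3 %||% blanks$sulfate_mol_m3
  phi <- porosity %||% blanks$porosity
  tt <- incubation_time_s %||% blanks$incubation_time_s
  tot <- blanks$tris_kBq + blanks$sulfate_residual_kBq
  if (any(tot <= 0)) stopf("a + A must be > 0 in blanks")
  apparent <- sulfate * phi * (blanks$tris_kBq / tot) * fractionation / tt
  mean(apparent) + k * stats::sd(apparent)
}

#' Flag rates below the detection limit
#'
#' Censored values are retained, not zeroed; only the flag is set.
#'
#' @param results an `srr_results` data.frame from [compute_srr()]
#' @param mdl detection limit in mol m^-3 s^-1 (>= 0)
#' @return `results` with `below_mdl` set; the number flagged is
#'   reported in the `n_below_mdl` attribute.
#' @export
censor_rates <- function(results, mdl) {
  stopifnot(inherits(results, "data.frame"))
  if (!is.numeric(mdl) || mdl < 0) stopf("mdl must be >= 0")
  results$below_mdl <- results$rate < mdl
  attr(results, "mdl") <- mdl
  attr(results, "n_below_mdl") <- sum(results$below_mdl)
  results
}

#' Depth-aggregated sulfate reduction rates
#'
#' Volume(length)-weighted mean rate over the mat (`[0, mat_bottom]`) and
#' over the full measured horizon (`[0, horizon]`, default 30 mm), with
#' sections partially overlapping a zone weighted by their overlap
#' length. Sections of each core must tile `[0, horizon]` without gaps or
#' overlaps; replicate cores are aggregated together.
#'
#' @param results an `srr_results` data.frame
#' @param mat_bottom bottom of the mat in mm
#' @param horizon aggregation horizon in mm (default 30)
#' @param tol tiling tolerance in mm
#' @return list with `mat_avg` and `horizon_avg` (mol m^-3 s^-1), plus
#'   `n_cores`.
#' @export
depth_aggregate <- function(results, mat_bottom, horizon = 30, tol = 1e-6) {
  stopifnot(inherits(results, "data.frame"))
  for (core in unique(results$core_id)) {
    sec <- results[results$core_id == core, ]
    sec <- sec[order(sec$section_top), ]
    edges_ok <- abs(sec$section_top[1]) <= tol &&
      sec$section_bottom[nrow(sec)] >= horizon - tol &&
      all(abs(sec$section_top[-1] - sec$section_bottom[-nrow(sec)]) <= tol)
    if (!edges_ok) {
      bad <- which(abs(sec$section_top[-1] -
                         sec$section_bottom[-nrow(sec)]) > tol)
      stopf(paste0("core '%s': sections do not tile [0, %g] mm ",
                   "(offending section boundaries after rows: %s)"),
            core, horizon,
            if (length(bad)) paste(bad, collapse = ", ") else "ends")
    }
  }
  wmean <- function(zone_hi) {
    w <- overlap_len(0, zone_hi, results$section_top, results$section_bottom)
    if (sum(w) == 0) stopf("no section overlaps [0, %g] mm", zone_hi)
    sum(results$rate * w) / sum(w)
  }
  list(mat_avg = wmean(mat_bottom), horizon_avg = wmean(horizon),
       n_cores = length(unique(results$core_id)))
}
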