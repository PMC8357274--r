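#' Per-layer community with total cell counts
#'
#' Relative taxon abundances of one mat-layer sample paired with the
#' total microscopy cell count of that layer, the two ingredients of
#' absolute-abundance scaling.
#'
#' @param patch_id mat patch (replicate) label
#' @param layer layer label, one of orange, green, brown, black, gray
#'   (top to bottom)
#' @param taxon_abundances named numeric vector of relative abundances,
#'   >= 0 and summing to 1 within 1e-6
#' @param total_cells total cells per g wet weight (>= 0)
#' @return a `layer_community` list with a `layer_index` (0-4).
#' @export
layer_community <- function(patch_id, layer, taxon_abundances, total_cells) {
  layers <- c("orange", "green", "brown", "black", "gray")
  if (!layer %in% layers) {
    stopf("unknown layer '%s' (expected one of %s)", layer,
          paste(layers, collapse = ", "))
  }
  if (is.null(names(taxon_abundances))) stopf("taxon abundances must be named")
  if (any(taxon_abundances < 0)) stopf("negative abundances")
  if (abs(sum(taxon_abundances) - 1) > 1e-6) {
    stopf("abundances sum to %.8f, not 1", sum(taxon_abundances))
  }
  if (total_cells < 0) stopf("total_cells must be >= 0")
  structure(list(patch_id = patch_id, layer = layer,
                 layer_index = match(layer, layers) - 1L,
                 taxon_abundances = taxon_abundances,
                 total_cells = total_cells),
            class = "layer_community")
}

#' Scale relative abundances to absolute cell densities
#'
#' Absolute per-taxon cell densities are the elementwise product of the
#' relative sequence abundance and the total cell count:
#' `cells_taxon = rel_abundance_taxon * total_cells`.
#'
#' @param layer a [layer_community()]
#' @param renormalize if `TRUE`, abundances deviating from unit sum by up
#'   to 1e-3 are renormalized; by default any deviation above 1e-3 is an
#'   error (and below that the raw values are used)
#' @return named numeric vector of cells per g wet weight, summing to
#'   `total_cells`.
#' @export
scale_abundances <- function(layer, renormalize = FALSE) {
  stopifnot(inherits(layer, "layer_community"))
  ab <- layer$taxon_abundances
  s <- sum(ab)
  if (s == 0) stopf("all-zero abundances")
  if (abs(s - 1) > 1e-3 && !renormalize) {
    stopf("abundance sum %.6f deviates from 1 by more than 1e-3; set renormalize = TRUE", s)
  }
  if (renormalize) ab <- ab / s
  ab * layer$total_cells
}

#' Taxon-to-guild map
#'
#' @param mapping named character vector taxon -> guild; guilds must be
#'   from the controlled vocabulary `cyanobacteria`, `SRB`, `SOB`,
#'   `other`
#' @param provenance free-text note on where the rules come from
#' @return a `guild_map` list.
#' @export
guild_map <- function(mapping, provenance = "") {
  guilds <- c("cyanobacteria", "SRB", "SOB", "other")
  if (!all(mapping %in% guilds)) {
    stopf("guild labels must be from: %s", paste(guilds, collapse = ", "))
  }
  structure(list(mapping = mapping, provenance = provenance),
            class = "guild_map")
}

#' Default guild map for the mat community
#'
#' Cyanobacteria are the photoautotrophs, Deltaproteobacteria the
#' sulfate reducers, Chromatiales the sulfur oxidizers; everything else
#' is grouped as other.
#' @return a [guild_map()].
#' @export
default_guild_map <- function() {
  guild_map(c(Cyanobacteria = "cyanobacteria",
              Deltaproteobacteria = "SRB",
              Chromatiales = "SOB"),
            provenance = "photoautotrophs = Cyanobacteria; SRB = Deltaproteobacteria; SOB = Chromatiales")
}

#' Guild cell densities per layer
#'
#' Scales every layer sample to absolute abundances
#' ([scale_abundances()]), sums by guild, and averages replicate samples
#' of the same layer (scale-then-average). Taxa missing from the guild
#' map are assigned to `other` and counted in the `n_unmapped_taxa`
#' attribute.
#'
#' @param layers list of [layer_community()] objects
#' @param guilds a [guild_map()]
#' @return data.frame with `layer`, `n` (replicates) and one column per
#'   guild (cells per g).
#' @export
guild_summary <- function(layers, guilds = default_guild_map()) {
  stopifnot(inherits(guilds, "guild_map"))
  guild_levels <- c("cyanobacteria", "SRB", "SOB", "other")
  unmapped <- character(0)
  per_sample <- lapply(layers, function(ly) {
    cells <- scale_abundances(ly)
    g <- guilds$mapping[names(cells)]
    miss <- is.na(g)
    unmapped <<- union(unmapped, names(cells)[miss])
    g[miss] <- "other"
    sums <- vapply(guild_levels, function(gl) sum(cells[g == gl]), numeric(1))
    c(list(layer = ly$layer), as.list(sums))
  })
  df <- do.call(rbind, lapply(per_sample, as.data.frame))
  agg <- stats::aggregate(df[guild_levels], by = list(layer = df$layer), mean)
  n <- stats::aggregate(list(n = df$layer), by = list(layer = df$layer), length)
  out <- merge(n, agg, by = "layer")
  layer_order <- c("orange", "green", "brown", "black", "gray")
  out <- out[order(match(out$layer, layer_order)), ]
  rownames(out) <- NULL
  attr(out, "n_unmapped_taxa") <- length(unmapped)
  attr(out, "unmapped_taxa") <- unmapped
  out
}

#' Cell-count contrast between groups of layers
#'
#' Ratio of summary total cell counts between two groups of layers, e.g.
#' the upper (orange, green, brown) versus lower (black, gray) layers.
#' The summary is either the midpoint of the min-max range of the
#' group's per-sample totals or their mean.
#'
#' @param layers list of [layer_community()] objects
#' @param group_a,group_b character vectors of layer labels (numerator /
#'   denominator)
#' @param statistic `"midpoint_ratio"` (default) or `"mean_ratio"`
#' @return the ratio; format with [fold_format()].
#' @export
layer_contrast <- function(layers, group_a, group_b,
                           statistic = c("midpoint_ratio", "mean_ratio")) {
  statistic <- match.arg(statistic)
  totals <- vapply(layers, function(ly) ly$total_cells, numeric(1))
  labels <- vapply(layers, function(ly) ly$layer, character(1))
  ta <- totals[labels %in% group_a]
  tb <- totals[labels %in% group_b]
  if (length(ta) == 0 || length(tb) == 0) stopf("both groups must be non-empty")
  summ <- function(x) switch(statistic,
                             midpoint_ratio = (min(x) + max(x)) / 2,
                             mean_ratio = mean(x))
  denom <- summ(tb)
  if (denom == 0) stopf("zero denominator group summary")
  summ(ta) / denom
}
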