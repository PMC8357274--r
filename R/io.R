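## TSV dialect: UTF-8, tab-separated, header row, '.' decimal.
## Numbers are written with %.17g so write -> read round trips are exact.

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

write_tsv_raw <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (j in which(num)) out[[j]] <- fmt_num(df[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stopf("malformed header in '%s': missing column(s) %s", path,
          paste(missing, collapse = ", "))
  }
}

#' Write and read depth-profile TSV files
#'
#' Columns: `depth_mm`, `value`, `unit`, `quantity`, `condition`,
#' `replicate`. Numbers are written at full double precision so the
#' round trip is exact.
#'
#' @param profile a [depth_profile()]
#' @param path file path
#' @return `write_profile_tsv()` returns `path` invisibly;
#'   `read_profile_tsv()` returns a [depth_profile()].
#' @export
write_profile_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "depth_profile"))
  df <- data.frame(depth_mm = profile$depth_mm, value = profile$value,
                   unit = attr(profile, "unit"),
                   quantity = attr(profile, "quantity"),
                   condition = attr(profile, "condition"),
                   replicate = attr(profile, "replicate_id"))
  write_tsv_raw(df, path)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @param expected_unit if non-`NULL`, reading a file whose unit column
#'   disagrees is an error naming the expected unit
#' @export
read_profile_tsv <- function(path, expected_unit = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", dec = ".", check.names = FALSE)
  require_columns(df, c("depth_mm", "value", "quantity", "condition"), path)
  unit <- if ("unit" %in% names(df)) as.character(df$unit[1]) else NULL
  if (!is.null(expected_unit) && !identical(unit, expected_unit)) {
    stopf("unit mismatch in '%s': expected '%s', found '%s'", path,
          expected_unit, unit %||% "<none>")
  }
  depth_profile(df$depth_mm, df$value, quantity = as.character(df$quantity[1]),
                condition = as.character(df$condition[1]),
                unit = unit,
                replicate_id = if ("replicate" %in% names(df)) {
                  as.character(df$replicate[1])
                } else NA_character_)
}

#' Write and read spectral stacks as wide TSV matrices
#'
#' First column `wavelength_nm`; remaining column names are depths in
#' mm. A `# normalized: true/false` comment line records the
#' normalization flag.
#'
#' @param stack a [spectral_stack()]
#' @param path file path
#' @return `write_spectral_stack()` returns `path` invisibly;
#'   `read_spectral_stack()` a [spectral_stack()].
#' @export
write_spectral_stack <- function(stack, path) {
  stopifnot(inherits(stack, "spectral_stack"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# normalized: %s",
                     if (stack$normalized) "true" else "false"), con)
  writeLines(paste(c("wavelength_nm", fmt_num(stack$depth)),
                   collapse = "\t"), con)
  body <- cbind(fmt_num(stack$wavelength),
                matrix(fmt_num(stack$irradiance), nrow(stack$irradiance)))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_spectral_stack
#' @export
read_spectral_stack <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  first <- readLines(path, n = 1)
  normalized <- grepl("normalized: true", first)
  df <- utils::read.delim(path, sep = "\t", skip = 1, check.names = FALSE)
  if (names(df)[1] != "wavelength_nm") {
    stopf("malformed header in '%s': first column must be wavelength_nm", path)
  }
  depth <- as.numeric(names(df)[-1])
  if (any(is.na(depth))) {
    stopf("malformed header in '%s': depth column names must be numeric mm",
          path)
  }
  spectral_stack(df$wavelength_nm, depth,
                 as.matrix(df[, -1, drop = FALSE]), normalized = normalized)
}

#' Write a tracer sample sheet / SRR results table
#'
#' @param x a [tracer_samples()] or `srr_results` data.frame
#' @param path file path
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(x, path) {
  write_tsv_raw(as.data.frame(x), path)
  invisible(path)
}

#' Read a tracer sample sheet TSV
#'
#' @param path file path to a TSV with the [tracer_samples()] columns
#' @return a `tracer_samples` data.frame.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", dec = ".")
  require_columns(df, c("core_id", "section_top", "section_bottom",
                        "tris_kBq", "sulfate_residual_kBq",
                        "sulfate_mol_m3", "porosity",
                        "incubation_time_s"), path)
  if (is.null(df$is_blank)) df$is_blank <- FALSE
  if (is.null(df$section_volume_ml)) {
    df$section_volume_ml <- 0.125 * (df$section_bottom - df$section_top)
  }
  tracer_samples(df$core_id, df$section_top, df$section_bottom,
                 df$section_volume_ml, df$tris_kBq,
                 df$sulfate_residual_kBq, df$sulfate_mol_m3, df$porosity,
                 df$incubation_time_s, as.logical(df$is_blank))
}

#' Write a summary rate table
#'
#' One row per process and condition with areal (mol m^-2 s^-1) and
#' average volumetric (mol m^-3 s^-1) columns, mirroring the
#' conventional presentation of mat rate budgets.
#'
#' @param rates data.frame with columns `process`, `condition`, `areal`,
#'   `avg_volumetric`
#' @param path file path
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(rates, path) {
  require_columns(rates, c("process", "condition", "areal",
                           "avg_volumetric"), "<rate table>")
  write_tsv_raw(rates, path)
  invisible(path)
}
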