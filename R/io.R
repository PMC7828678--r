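# CSV schemas used at the package boundary. All tables are plain CSV with
# validated headers; unknown extra columns are preserved on read.

.check_columns <- function(df, required, what, path) {
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("%s '%s' is missing column(s): %s", what, path,
                 paste(miss, collapse = ", ")), call. = FALSE)
}

#' Read / write a biodistribution table
#'
#' Schema: `conjugate`, `time_h`, `organ`, `animal_id`, `pct_ia_per_g`
#' (plus optional columns such as `dar` or `organ_mass_g`, preserved
#' as-is). Values are %IA per gram, decay-corrected to injection time.
#'
#' @param path CSV file path.
#' @return `read_biodistribution`: the validated data frame.
#' @export
read_biodistribution <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("conjugate", "time_h", "organ", "animal_id", "pct_ia_per_g"),
                 "biodistribution table", path)
  if (!is.numeric(df$time_h) || !is.numeric(df$pct_ia_per_g))
    stop("'time_h' and 'pct_ia_per_g' must be numeric", call. = FALSE)
  if (any(df$pct_ia_per_g < 0)) stop("negative %IA/g value in ", path, call. = FALSE)
  df
}

#' @rdname read_biodistribution
#' @param data biodistribution data frame to write.
#' @export
write_biodistribution <- function(data, path) {
  .check_columns(data, c("conjugate", "time_h", "organ", "animal_id", "pct_ia_per_g"),
                 "biodistribution table", path)
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' Read a deconvoluted peak list
#'
#' Schema: `mass_da`, `intensity`.
#'
#' @param path CSV file path.
#' @inheritParams spectrum_peaks
#' @return a [spectrum_peaks()] object.
#' @export
read_peaklist <- function(path, base_mass = 108394, adduct_mass = 551) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("mass_da", "intensity"), "peak list", path)
  spectrum_peaks(df$mass_da, df$intensity, base_mass, adduct_mass)
}

#' Read a Lindmo assay table
#'
#' Schema: `cells`, `bound_fraction`, and optional `blocked_fraction`.
#'
#' @param path CSV file path.
#' @return a [lindmo_assay()] object.
#' @export
read_lindmo <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("cells", "bound_fraction"), "Lindmo table", path)
  lindmo_assay(df$cells, df$bound_fraction,
               if ("blocked_fraction" %in% names(df)) df$blocked_fraction else NULL)
}

#' Read a normalized time-activity curve table
#'
#' Schema: `organ`, `time_h`, `na` (normalized activity, fraction of
#' injected). The decay-correction convention is passed as an argument
#' because CSV carries no header metadata.
#'
#' @param path CSV file path.
#' @param decay_corrected whether the values are decay-corrected.
#' @return named list of [ntac()] objects, one per organ.
#' @export
read_ntac <- function(path, decay_corrected = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("organ", "time_h", "na"), "nTAC table", path)
  lapply(split(df, df$organ), function(d) {
    d <- d[order(d$time_h), ]
    ntac(d$organ[1], d$time_h, d$na, decay_corrected)
  })
}
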