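#' Spectrum CSV I/O
#'
#' Comma-separated, period decimal, UTF-8, mandatory header. Columns
#' `wavelength_nm`, `epsilon` and optionally `delta_epsilon`; a file
#' without the CD column yields a spectrum with an absent CD channel.
#' Round trips preserve values to full double precision.
#'
#' @param path File path.
#' @return [read_spectrum_csv()]: a [dye_spectrum()].
#' @export
read_spectrum_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("wavelength_nm", "epsilon")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  bad <- which(diff(df$wavelength_nm) <= 0)
  if (length(bad))
    stop(sprintf("%s: wavelength grid not strictly increasing at data row %d",
                 path, bad[1] + 1L), call. = FALSE)
  dye_spectrum(df$wavelength_nm, df$epsilon,
               if ("delta_epsilon" %in% names(df)) df$delta_epsilon)
}

#' @rdname read_spectrum_csv
#' @param spectrum A [dye_spectrum()].
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "dye_spectrum"))
  df <- data.frame(wavelength_nm = spectrum$wavelength_nm,
                   epsilon = spectrum$epsilon)
  if (has_cd_channel(spectrum)) df$delta_epsilon <- spectrum$delta_epsilon
  .write_csv_full(df, path)
  invisible(path)
}

# full-precision CSV writer shared by all emitters
.write_csv_full <- function(df, path, meta = character()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(meta)) writeLines(paste0("# ", meta), con)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
}

# "# key=value" metadata lines at the top of a CSV
.read_meta <- function(path) {
  lines <- readLines(path, n = 50L, warn = FALSE)
  lines <- lines[startsWith(lines, "#")]
  kv <- sub("^#\\s*", "", lines)
  kv <- kv[grepl("=", kv, fixed = TRUE)]
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  stats::setNames(as.list(trimws(vals)), trimws(keys))
}

#' Concentration-series CSV I/O
#'
#' Columns `c_total_M`, `epsilon_obs`, `delta_epsilon_obs`, preceded by
#' metadata comment lines recording the probe wavelengths
#' (`# lambda_A_nm=750`, `# lambda_C_nm=746`).
#'
#' @param path File path.
#' @return [read_series_csv()]: the series data frame with probe
#'   wavelengths as attributes.
#' @export
read_series_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  meta <- .read_meta(path)
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("c_total_M", "epsilon_obs", "delta_epsilon_obs")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (!is.null(meta$lambda_A_nm))
    attr(df, "lambda_A_nm") <- as.numeric(meta$lambda_A_nm)
  if (!is.null(meta$lambda_C_nm))
    attr(df, "lambda_C_nm") <- as.numeric(meta$lambda_C_nm)
  df
}

#' @rdname read_series_csv
#' @param series Series data frame (see [observable_series()]).
#' @export
write_series_csv <- function(series, path) {
  meta <- c(
    if (!is.null(attr(series, "lambda_A_nm")))
      sprintf("lambda_A_nm=%g", attr(series, "lambda_A_nm")),
    if (!is.null(attr(series, "lambda_C_nm")))
      sprintf("lambda_C_nm=%g", attr(series, "lambda_C_nm")))
  .write_csv_full(as.data.frame(series), path, meta = meta)
  invisible(path)
}

#' Kinetic-trace CSV I/O
#'
#' Columns `time_h`, `g`, preceded by metadata comment lines
#' (`# condition=30:70`, `# cT_M=1e-05`, `# T_K=293`).
#'
#' @param path File path.
#' @return [read_trace_csv()]: a [kinetic_trace()].
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  meta <- .read_meta(path)
  df <- utils::read.csv(path, comment.char = "#")
  miss <- setdiff(c("time_h", "g"), names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  kinetic_trace(df$time_h, df$g,
                condition = meta$condition %||% NA_character_,
                c_T = if (!is.null(meta$cT_M)) as.numeric(meta$cT_M)
                      else NA_real_,
                T_K = if (!is.null(meta$T_K)) as.numeric(meta$T_K)
                      else NA_real_)
}

#' @rdname read_trace_csv
#' @param trace A [kinetic_trace()].
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "kinetic_trace"))
  meta <- c(
    if (!is.na(trace$condition)) sprintf("condition=%s", trace$condition),
    if (!is.na(trace$c_T)) sprintf("cT_M=%.17g", trace$c_T),
    if (!is.na(trace$T_K)) sprintf("T_K=%g", trace$T_K))
  .write_csv_full(data.frame(time_h = trace$time_h, g = trace$g), path,
                  meta = meta)
  invisible(path)
}

#' Export an energy landscape as CSV
#'
#' @param landscape An [energy_landscape()] data frame.
#' @param path File path.
#' @export
write_landscape_csv <- function(landscape, path) {
  stopifnot(inherits(landscape, "energy_landscape"))
  .write_csv_full(as.data.frame(landscape)[, c("process", "K",
                                               "dG_kJ_per_mol")], path)
  invisible(path)
}

#' Export a rate table as CSV
#'
#' @param rates Data frame from [rate_table()].
#' @param path File path.
#' @export
write_rate_table_csv <- function(rates, path) {
  .write_csv_full(rates, path)
  invisible(path)
}
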