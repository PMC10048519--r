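#' Read and write spectrum and titration CSV files
#'
#' Plain-CSV dialects for the objects the analysis functions consume.
#' Emission spectra use columns `wavelength_nm`, `intensity` with metadata in
#' header comments (`# temperature_K=297`, `# quencher_M=2e-05`); titration
#' curves use `q_mol_per_L`, `intensity`; infrared spectra use
#' `wavenumber_cm1`, `absorbance`.
#'
#' @param path File path.
#' @param x Object to write.
#' @return The read object, or (invisibly) `path` for the writers.
#' @name spectrum_io
NULL

.read_header_meta <- function(path) {
  lines <- readLines(path, n = 50)
  lines <- lines[startsWith(lines, "#")]
  meta <- list()
  for (l in lines) {
    kv <- strsplit(sub("^#\\s*", "", l), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[trimws(kv[1])]] <- as.numeric(trimws(kv[2]))
  }
  meta
}

#' @rdname spectrum_io
#' @export
read_spectrum_csv <- function(path) {
  meta <- .read_header_meta(path)
  if (is.null(meta$temperature_K) || is.null(meta$quencher_M))
    stop("header comments must declare temperature_K and quencher_M")
  d <- utils::read.csv(path, comment.char = "#")
  emission_spectrum(d$wavelength_nm, d$intensity,
                    temperature = meta$temperature_K,
                    quencher_conc = meta$quencher_M)
}

#' @rdname spectrum_io
#' @export
write_spectrum_csv <- function(x, path) {
  stopifnot(inherits(x, "emission_spectrum"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# temperature_K=%.10g", x$temperature), con)
  writeLines(sprintf("# quencher_M=%.10g", x$quencher_conc), con)
  utils::write.csv(data.frame(wavelength_nm = x$wavelength, intensity = x$intensity),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname spectrum_io
#' @export
read_titration_csv <- function(path) {
  meta <- .read_header_meta(path)
  if (is.null(meta$temperature_K))
    stop("header comment must declare temperature_K")
  d <- utils::read.csv(path, comment.char = "#")
  titration_curve(d$q_mol_per_L, d$intensity, temperature = meta$temperature_K,
                  f0 = meta$f0)
}

#' @rdname spectrum_io
#' @export
write_titration_csv <- function(x, path) {
  stopifnot(inherits(x, "titration_curve"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# temperature_K=%.10g", x$temperature), con)
  if (!any(x$q == 0)) writeLines(sprintf("# f0=%.10g", x$f0), con)
  utils::write.csv(data.frame(q_mol_per_L = x$q, intensity = x$f),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname spectrum_io
#' @export
read_ir_csv <- function(path) {
  d <- utils::read.csv(path, comment.char = "#")
  ir_spectrum(d$wavenumber_cm1, d$absorbance)
}

#' @rdname spectrum_io
#' @export
write_ir_csv <- function(x, path) {
  stopifnot(inherits(x, "ir_spectrum"))
  utils::write.csv(data.frame(wavenumber_cm1 = x$wavenumber,
                              absorbance = x$absorbance),
                   path, row.names = FALSE)
  invisible(path)
}
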