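#' Construct an emission spectrum
#'
#' A single fluorescence emission scan recorded at one temperature and one
#' quencher concentration. Intensities are assumed background-subtracted
#' (see [subtract_blank()]); negative values are rejected.
#'
#' @param wavelength Numeric vector of emission wavelengths (nm), strictly
#'   increasing.
#' @param intensity Numeric vector of fluorescence intensities (arbitrary
#'   units), same length as `wavelength`, non-negative.
#' @param temperature Temperature of the scan (K).
#' @param quencher_conc Quencher concentration in the cuvette (mol/L).
#' @return An object of class `emission_spectrum`.
#' @export
emission_spectrum <- function(wavelength, intensity, temperature, quencher_conc) {
  stopifnot(is.numeric(wavelength), is.numeric(intensity),
            length(wavelength) == length(intensity), length(wavelength) >= 2)
  if (any(!is.finite(wavelength)) || any(!is.finite(intensity)))
    stop("wavelengths and intensities must be finite")
  if (any(diff(wavelength) <= 0))
    stop("wavelengths must be strictly increasing")
  if (any(intensity < 0))
    stop("negative intensities: apply background subtraction before constructing")
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be positive (kelvin)")
  if (!is.finite(quencher_conc) || quencher_conc < 0)
    stop("quencher_conc must be non-negative (mol/L)")
  structure(list(wavelength = wavelength, intensity = intensity,
                 temperature = temperature, quencher_conc = quencher_conc),
            class = "emission_spectrum")
}

#' @export
print.emission_spectrum <- function(x, ...) {
  cat(sprintf("<emission_spectrum> %g-%g nm (%d points), T = %g K, [Q] = %g mol/L\n",
              min(x$wavelength), max(x$wavelength), length(x$wavelength),
              x$temperature, x$quencher_conc))
  invisible(x)
}

#' Subtract a blank (background) spectrum
#'
#' Subtracts a blank scan point-wise from a sample scan sharing the same
#' wavelength grid. Intensities that would fall below zero are truncated at 0.
#'
#' @param spectrum,blank `emission_spectrum` objects on identical grids.
#' @return A background-subtracted `emission_spectrum`.
#' @export
subtract_blank <- function(spectrum, blank) {
  stopifnot(inherits(spectrum, "emission_spectrum"), inherits(blank, "emission_spectrum"))
  if (!isTRUE(all.equal(spectrum$wavelength, blank$wavelength)))
    stop("sample and blank must share the same wavelength grid")
  emission_spectrum(spectrum$wavelength,
                    pmax(spectrum$intensity - blank$intensity, 0),
                    spectrum$temperature, spectrum$quencher_conc)
}

#' Construct a titration curve
#'
#' Paired quencher concentrations and peak fluorescence intensities at one
#' temperature. The unquenched intensity F0 is either supplied explicitly or
#' taken from the point at zero quencher concentration.
#'
#' @param q Quencher concentrations (mol/L), non-negative, strictly increasing
#'   after sorting.
#' @param f Peak fluorescence intensities paired with `q`.
#' @param temperature Temperature (K).
#' @param f0 Unquenched intensity; defaults to `f` at `q == 0`, which must then
#'   be present.
#' @return An object of class `titration_curve`.
#' @export
titration_curve <- function(q, f, temperature, f0 = NULL) {
  stopifnot(is.numeric(q), is.numeric(f), length(q) == length(f))
  if (any(!is.finite(q)) || any(!is.finite(f))) stop("q and f must be finite")
  if (any(q < 0)) stop("quencher concentrations must be non-negative")
  ord <- order(q)
  q <- q[ord]; f <- f[ord]
  if (anyDuplicated(q)) stop("quencher concentrations must be distinct")
  if (is.null(f0)) {
    if (!any(q == 0)) stop("f0 must be supplied when q does not contain 0")
    f0 <- f[q == 0]
  }
  if (!is.finite(f0) || f0 <= 0) stop("f0 must be positive")
  if (!is.finite(temperature) || temperature <= 0) stop("temperature must be positive")
  structure(list(temperature = temperature, q = q, f = f, f0 = f0),
            class = "titration_curve")
}

#' @export
print.titration_curve <- function(x, ...) {
  cat(sprintf("<titration_curve> T = %g K, %d points, [Q] %g-%g mol/L, F0 = %g\n",
              x$temperature, length(x$q), min(x$q), max(x$q), x$f0))
  invisible(x)
}

#' Extract a titration curve from a series of emission spectra
#'
#' Reduces each spectrum of a titration series to its peak intensity F
#' (the maximum within the 300-500 nm window) and peak position lambda_max,
#' and labels the emission shift of each quenched spectrum relative to the
#' zero-quencher scan: `"blue"` (lambda_max decreased), `"red"` (increased)
#' or `"none"` (unchanged within one grid step). Argmax ties resolve to the
#' lowest wavelength.
#'
#' Taking F at the running maximum rather than at a fixed wavelength keeps the
#' quench readout from being confounded by the peak shift itself.
#'
#' @param spectra List of [emission_spectrum()] objects sharing temperature and
#'   wavelength grid; exactly one must have `quencher_conc == 0`.
#' @param window Wavelength window (nm) searched for the peak.
#' @return A list of class `titration_extract` with elements `curve`
#'   (a [titration_curve()]) and `peaks` (data frame: `q`, `f`, `lambda_max`,
#'   `shift`).
#' @export
extract_titration <- function(spectra, window = c(300, 500)) {
  stopifnot(is.list(spectra), length(spectra) >= 2)
  if (!all(vapply(spectra, inherits, logical(1), "emission_spectrum")))
    stop("spectra must be a list of emission_spectrum objects")
  temps <- vapply(spectra, `[[`, numeric(1), "temperature")
  if (length(unique(temps)) != 1L)
    stop("all spectra in a titration series must share one temperature")
  grid <- spectra[[1]]$wavelength
  shared <- vapply(spectra, function(s)
    length(s$wavelength) == length(grid) && isTRUE(all.equal(s$wavelength, grid)),
    logical(1))
  if (!all(shared)) stop("all spectra must share the same wavelength grid")
  qs <- vapply(spectra, `[[`, numeric(1), "quencher_conc")
  if (sum(qs == 0) != 1L)
    stop("exactly one spectrum must have quencher_conc == 0")

  sel <- grid >= window[1] & grid <= window[2]
  if (!any(sel)) stop("no wavelengths inside the peak window")
  peak <- function(s) {
    int <- s$intensity[sel]
    i <- which(int == max(int))[1]  # ties -> lowest wavelength
    c(f = int[i], lambda = grid[sel][i])
  }
  pk <- t(vapply(spectra, peak, numeric(2)))
  step <- min(diff(grid))
  lam0 <- pk[qs == 0, "lambda"]
  shift <- ifelse(qs == 0, "none",
           ifelse(abs(pk[, "lambda"] - lam0) <= step + 1e-12, "none",
           ifelse(pk[, "lambda"] < lam0, "blue", "red")))
  ord <- order(qs)
  peaks <- data.frame(q = qs, f = pk[, "f"], lambda_max = pk[, "lambda"],
                      shift = shift, row.names = NULL)[ord, ]
  rownames(peaks) <- NULL
  curve <- titration_curve(peaks$q, peaks$f, temperature = temps[1])
  structure(list(curve = curve, peaks = peaks), class = "titration_extract")
}

#' @export
print.titration_extract <- function(x, ...) {
  print(x$curve)
  print(x$peaks, digits = 4)
  invisible(x)
}
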