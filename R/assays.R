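#' Ligand binding rate from total and free amounts
#'
#' B(%) = 100 (A - A0) / A, where A is the total ligand amount and A0 the free
#' amount recovered in the supernatant. Units cancel, so any consistent
#' concentration or amount unit may be used. Small negative rates (free
#' exceeding total, expected from replicate HPLC noise) are clamped to 0 with
#' a warning rather than raising an error, so batch processing is not
#' interrupted.
#'
#' @param a_total Total ligand amount(s), positive.
#' @param a_free Free (supernatant) ligand amount(s), non-negative.
#' @return Binding rate(s) in percent.
#' @export
binding_rate <- function(a_total, a_free) {
  if (any(!is.finite(a_total)) || any(a_total <= 0))
    stop("a_total must be positive")
  if (any(!is.finite(a_free)) || any(a_free < 0))
    stop("a_free must be non-negative")
  b <- 100 * (a_total - a_free) / a_total
  if (any(b < 0)) {
    warning(sprintf("%d measurement(s) with a_free > a_total clamped to 0%%", sum(b < 0)))
    b <- pmax(b, 0)
  }
  b
}

#' Free sulfhydryl content by the Ellman assay
#'
#' SH (umol/g) = 73.53 * A412 * D / C, with A412 the absorbance at 412 nm, D
#' the dilution factor and C the sample concentration in g/L. The constant
#' 73.53 is 1e6 / 13600, i.e. the reciprocal molar absorptivity of the TNB
#' chromophore (13,600 M-1 cm-1) expressed so that a g/L concentration yields
#' umol per g of protein.
#'
#' @param a412 Absorbance at 412 nm, non-negative.
#' @param dilution Dilution factor, >= 1.
#' @param conc_g_per_l Sample concentration (g/L), positive.
#' @return Free sulfhydryl content in umol/g.
#' @export
sulfhydryl_content <- function(a412, dilution = 1, conc_g_per_l) {
  if (any(!is.finite(a412)) || any(a412 < 0)) stop("a412 must be non-negative")
  if (any(!is.finite(dilution)) || any(dilution < 1)) stop("dilution factor must be >= 1")
  if (any(!is.finite(conc_g_per_l)) || any(conc_g_per_l <= 0))
    stop("sample concentration must be positive (g/L)")
  73.53 * a412 * dilution / conc_g_per_l
}

#' Ligand release rate during simulated digestion
#'
#' R(%) = 100 A1 / A, with A1 the free ligand in the digestive-fluid
#' supernatant and A the total ligand in the same fluid. Rates above 100%
#' (free exceeding total) are returned as computed but flagged with a warning.
#'
#' @param a_free Free ligand amount(s), non-negative.
#' @param a_total Total ligand amount(s), positive.
#' @return Release rate(s) in percent.
#' @export
release_rate <- function(a_free, a_total) {
  if (any(!is.finite(a_total)) || any(a_total <= 0)) stop("a_total must be positive")
  if (any(!is.finite(a_free)) || any(a_free < 0)) stop("a_free must be non-negative")
  r <- 100 * a_free / a_total
  if (any(r > 100))
    warning(sprintf("%d measurement(s) with release > 100%%", sum(r > 100)))
  r
}

#' Aggregate per-replicate rates as mean and standard deviation
#'
#' Rates are computed per replicate first and aggregated afterwards (never
#' rates of group means), matching mean +/- SD reporting of triplicate assays.
#'
#' @param data Data frame of per-replicate values.
#' @param value Name of the numeric column to aggregate.
#' @param by Character vector of grouping column names.
#' @return Data frame with the grouping columns plus `mean`, `sd`, `n`.
#' @export
aggregate_replicates <- function(data, value, by) {
  stopifnot(is.data.frame(data), value %in% names(data), all(by %in% names(data)))
  groups <- interaction(data[by], drop = TRUE, sep = "\r")
  agg <- function(f) tapply(data[[value]], groups, f)
  keys <- do.call(rbind, strsplit(names(agg(length)), "\r", fixed = TRUE))
  out <- data.frame(keys, mean = as.numeric(agg(mean)),
                    sd = as.numeric(agg(stats::sd)),
                    n = as.integer(agg(length)), row.names = NULL)
  names(out)[seq_along(by)] <- by
  out
}
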