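#' Gibbs free energy of binding
#'
#' dG = -R T ln(KA), reported in kJ/mol. Vectorised over `ka` and `t`.
#'
#' @param ka Binding constant(s), L/mol, positive.
#' @param t Temperature(s), K, positive.
#' @return dG in kJ/mol.
#' @export
gibbs <- function(ka, t) {
  if (any(!is.finite(ka)) || any(ka <= 0)) stop("ka must be positive")
  if (any(!is.finite(t)) || any(t <= 0)) stop("temperature must be positive (kelvin)")
  -R_GAS * t * log(ka) / 1000
}

#' Van't Hoff enthalpy from temperature-resolved binding constants
#'
#' Least squares of ln(KA) on 1/T; the binding enthalpy is
#' dH = -R * slope / 1000 (kJ/mol), assumed constant over the temperature
#' range (single-slope model). Pairwise two-point enthalpies are returned as a
#' diagnostic of linearity.
#'
#' @param t Temperatures (K), at least two, distinct.
#' @param ka Binding constants (L/mol), positive, same length.
#' @return List of class `vant_hoff_fit`: `dh` (kJ/mol), `slope` (K),
#'   `intercept`, `r2`, and `pairwise` (data frame of two-point dH
#'   diagnostics).
#' @export
vant_hoff <- function(t, ka) {
  stopifnot(is.numeric(t), is.numeric(ka), length(t) == length(ka))
  if (length(t) < 2) stop("need at least 2 (temperature, KA) pairs")
  if (anyDuplicated(t)) stop("temperatures must be distinct")
  if (any(!is.finite(t)) || any(t <= 0)) stop("temperatures must be positive")
  if (any(!is.finite(ka)) || any(ka <= 0)) stop("binding constants must be positive")
  x <- 1 / t
  y <- log(ka)
  fit <- stats::lm(y ~ x, data = list(y = y, x = x))
  co <- unname(stats::coef(fit))
  pw <- utils::combn(seq_along(t), 2)
  pairwise <- data.frame(
    t1 = t[pw[1, ]], t2 = t[pw[2, ]],
    dh = -R_GAS * (y[pw[2, ]] - y[pw[1, ]]) / (x[pw[2, ]] - x[pw[1, ]]) / 1000)
  structure(list(dh = -R_GAS * co[2] / 1000, slope = co[2], intercept = co[1],
                 r2 = .r_squared(y, stats::fitted(fit)), pairwise = pairwise),
            class = "vant_hoff_fit")
}

#' @export
print.vant_hoff_fit <- function(x, ...) {
  cat(sprintf("van't Hoff fit: dH = %.2f kJ/mol (slope %.4g K, R2 = %.4f)\n",
              x$dh, x$slope, x$r2))
  invisible(x)
}

#' Binding entropy from dH, dG and temperature
#'
#' dS = (dH - dG) * 1000 / T, in J mol-1 K-1. Vectorised.
#'
#' @param dh Enthalpy (kJ/mol).
#' @param dg Gibbs energy (kJ/mol).
#' @param t Temperature (K), positive.
#' @return dS in J mol-1 K-1.
#' @export
entropy <- function(dh, dg, t) {
  if (any(!is.finite(t)) || any(t <= 0)) stop("temperature must be positive (kelvin)")
  (dh - dg) * 1000 / t
}

#' Classify the dominant interaction forces from thermodynamic signs
#'
#' Sign rules for protein--small-molecule binding: dH < 0 with dS < 0 points
#' to hydrogen bonding plus van der Waals contacts; dH > 0 with dS > 0 to
#' hydrophobic association; dH near zero (|dH| < `dh_zero_tol`) or negative
#' with dS > 0 to electrostatic interactions. A positive dH with negative dS
#' does not fit any rule and is labelled `"unclassified"` with a warning.
#'
#' @param dh Enthalpy (kJ/mol).
#' @param ds Entropy (J mol-1 K-1).
#' @param dh_zero_tol Magnitude below which dH counts as "approximately zero"
#'   for the electrostatic rule (kJ/mol).
#' @return One of `"hbond_vdw"`, `"hydrophobic"`, `"electrostatic"`,
#'   `"unclassified"`.
#' @export
classify_forces <- function(dh, ds, dh_zero_tol = 5) {
  if (!is.finite(dh) || !is.finite(ds)) stop("dh and ds must be finite")
  if (ds > 0) {
    if (dh >= dh_zero_tol) return("hydrophobic")
    return("electrostatic")  # dH negative or ~0 with dS > 0
  }
  if (dh <= 0) return("hbond_vdw")
  warning("dH > 0 with dS <= 0 matches no sign rule: unclassified")
  "unclassified"
}

#' Complete thermodynamic analysis of a binding-constant series
#'
#' Computes dG at each temperature, a single van't Hoff dH for the series, dS
#' at each temperature, spontaneity flags (dG < 0), and the interaction-force
#' class from the signs of dH and dS. The identity dG = dH - T dS / 1000 holds
#' exactly at every temperature by construction.
#'
#' @inheritParams vant_hoff
#' @inheritParams classify_forces
#' @return List of class `thermo_result`: `table` (data frame with `t`, `ka`,
#'   `dg`, `ds`, `spontaneous`), `dh`, `forces`, `vant_hoff` (the underlying
#'   fit).
#' @export
thermo_analysis <- function(t, ka, dh_zero_tol = 5) {
  vh <- vant_hoff(t, ka)
  dg <- gibbs(ka, t)
  ds <- entropy(vh$dh, dg, t)
  tab <- data.frame(t = t, ka = ka, dg = dg, ds = ds, spontaneous = dg < 0)
  structure(list(table = tab, dh = vh$dh,
                 forces = classify_forces(vh$dh, mean(ds), dh_zero_tol),
                 vant_hoff = vh),
            class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf("Thermodynamic analysis: dH = %.2f kJ/mol, forces = %s\n",
              x$dh, x$forces))
  print(transform(x$table, dg = round(dg, 2), ds = round(ds, 2)), row.names = FALSE)
  invisible(x)
}
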