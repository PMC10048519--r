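#' Fit the Stern-Volmer quenching model
#'
#' Linear least squares of F0/F on quencher concentration. The Stern-Volmer
#' model F0/F = 1 + Ksv[Q] forces an intercept of 1; the fit nevertheless
#' estimates a free intercept and warns when it strays more than
#' `intercept_tol` from 1, since a displaced intercept is the usual signature
#' of faulty background subtraction. The reported Ksv is the slope, and the
#' bimolecular quenching rate constant is Kq = Ksv / tau0.
#'
#' @param curve A [titration_curve()].
#' @param tau0 Unquenched fluorophore lifetime (s). The conventional value for
#'   intrinsic protein fluorescence, 1e-8 s, is the default.
#' @param intercept_tol Warn if the free intercept deviates from 1 by more
#'   than this.
#' @return List of class `sv_fit`: `ksv` (L/mol), `kq` (L mol-1 s-1), `tau0`,
#'   `intercept`, `r2`, `degenerate` (TRUE when the fitted slope is <= 0),
#'   `n_points`.
#' @export
fit_stern_volmer <- function(curve, tau0 = 1e-8, intercept_tol = 0.05) {
  stopifnot(inherits(curve, "titration_curve"))
  if (!is.finite(tau0) || tau0 <= 0) stop("tau0 must be positive (seconds)")
  if (any(curve$f <= 0)) stop("all intensities must be positive for F0/F")
  if (length(unique(curve$q)) < 3) stop("need at least 3 distinct [Q] points")
  y <- curve$f0 / curve$f
  fit <- stats::lm(y ~ q, data = list(y = y, q = curve$q))
  co <- unname(stats::coef(fit))
  ksv <- co[2]
  r2 <- .r_squared(y, stats::fitted(fit))
  if (abs(co[1] - 1) > intercept_tol)
    warning(sprintf("Stern-Volmer intercept %.4f deviates from 1: check background subtraction", co[1]))
  degenerate <- !is.finite(ksv) || ksv <= 0
  if (degenerate) warning("degenerate Stern-Volmer fit: Ksv <= 0 (no quenching trend)")
  structure(list(ksv = ksv, kq = ksv / tau0, tau0 = tau0, intercept = co[1],
                 r2 = r2, degenerate = degenerate, n_points = length(y)),
            class = "sv_fit")
}

#' @export
print.sv_fit <- function(x, ...) {
  cat(sprintf("Stern-Volmer fit (%d points)\n", x$n_points))
  cat(sprintf("  Ksv = %.4g L/mol   Kq = %.4g L mol-1 s-1 (tau0 = %g s)\n",
              x$ksv, x$kq, x$tau0))
  cat(sprintf("  intercept = %.4f   R2 = %.4f%s\n", x$intercept, x$r2,
              if (x$degenerate) "   [degenerate]" else ""))
  invisible(x)
}

#' Classify the quenching mechanism from Kq
#'
#' Quenching is classified as static (ground-state complex formation) when the
#' bimolecular quenching rate constant exceeds the diffusion-limited threshold,
#' strictly: `kq > threshold`. Values at or below the threshold are labelled
#' `"not_static"`.
#'
#' @param kq Bimolecular quenching rate constant (L mol-1 s-1), finite and
#'   non-negative.
#' @param threshold Diffusion-limited threshold (default 2e10 L mol-1 s-1).
#' @return `"static"` or `"not_static"`.
#' @export
classify_mechanism <- function(kq, threshold = 2e10) {
  if (length(kq) != 1 || !is.finite(kq)) stop("kq must be a single finite number")
  if (kq < 0) stop("kq must be non-negative")
  if (kq > threshold) "static" else "not_static"
}

#' Fit the double-logarithmic binding model
#'
#' Least squares of log10((F0 - F)/F) on log10([Q]) over the quenched points.
#' The intercept gives the apparent binding constant KA = 10^intercept and the
#' slope the number of binding sites n. Points with F >= F0 (no apparent
#' quench, attributable to noise) are dropped with a warning; the [Q] = 0
#' point is excluded by construction.
#'
#' @param curve A [titration_curve()].
#' @param base Logarithm base. The model is conventionally written in base 10;
#'   a natural-log fit changes the intercept scale and is supported for
#'   comparison (`base = exp(1)`), with KA then `base^intercept`.
#' @return List of class `dl_fit`: `ka` (L/mol), `n`, `r2`, `base`,
#'   `n_points`.
#' @export
fit_double_log <- function(curve, base = 10) {
  stopifnot(inherits(curve, "titration_curve"))
  if (!is.finite(base) || base <= 1) stop("log base must exceed 1")
  use <- curve$q > 0
  bad <- use & curve$f >= curve$f0
  if (any(bad)) {
    warning(sprintf("%d point(s) with F >= F0 at [Q] > 0 rejected", sum(bad)))
    use <- use & !bad
  }
  use <- use & curve$f > 0
  if (sum(use) < 3) stop("fewer than 3 usable points for the double-log fit")
  x <- log(curve$q[use], base)
  y <- log((curve$f0 - curve$f[use]) / curve$f[use], base)
  fit <- stats::lm(y ~ x, data = list(y = y, x = x))
  co <- unname(stats::coef(fit))
  structure(list(ka = base^co[1], n = co[2],
                 r2 = .r_squared(y, stats::fitted(fit)),
                 base = base, n_points = sum(use)),
            class = "dl_fit")
}

#' @export
print.dl_fit <- function(x, ...) {
  cat(sprintf("Double-logarithmic fit (%d points, base %g)\n", x$n_points, x$base))
  cat(sprintf("  KA = %.4g L/mol   n = %.3f   R2 = %.4f\n", x$ka, x$n, x$r2))
  invisible(x)
}

#' Full quenching analysis of one titration curve
#'
#' Runs the Stern-Volmer and double-logarithmic fits and classifies the
#' quenching mechanism from Kq. By construction `kq * tau0 == ksv` exactly.
#'
#' @inheritParams fit_stern_volmer
#' @inheritParams fit_double_log
#' @param kq_threshold Passed to [classify_mechanism()].
#' @return List of class `quench_analysis` with `temperature`, `ksv`, `kq`,
#'   `tau0`, `r2_sv`, `ka`, `n`, `r2_dl`, `mechanism`.
#' @export
quench_analysis <- function(curve, tau0 = 1e-8, base = 10, kq_threshold = 2e10) {
  sv <- fit_stern_volmer(curve, tau0 = tau0)
  dl <- fit_double_log(curve, base = base)
  mech <- if (sv$degenerate) NA_character_ else classify_mechanism(sv$kq, kq_threshold)
  structure(list(temperature = curve$temperature,
                 ksv = sv$ksv, kq = sv$kq, tau0 = tau0, r2_sv = sv$r2,
                 ka = dl$ka, n = dl$n, r2_dl = dl$r2,
                 mechanism = mech, sv = sv, dl = dl),
            class = "quench_analysis")
}

#' @export
print.quench_analysis <- function(x, ...) {
  cat(sprintf("Quenching analysis at %g K\n", x$temperature))
  cat(sprintf("  Ksv = %.4g L/mol  Kq = %.4g L mol-1 s-1  (R2 = %.4f)\n",
              x$ksv, x$kq, x$r2_sv))
  cat(sprintf("  KA  = %.4g L/mol  n = %.3f             (R2 = %.4f)\n",
              x$ka, x$n, x$r2_dl))
  cat(sprintf("  mechanism: %s\n", x$mechanism))
  invisible(x)
}

# Coefficient of determination against the mean model.
.r_squared <- function(y, yhat) {
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(if (ss_res == 0) 1 else 0)
  1 - ss_res / ss_tot
}
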