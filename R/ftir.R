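#' Construct an infrared spectrum
#'
#' Wavenumber/absorbance pairs, stored in ascending wavenumber order whatever
#' the input order. All values must be finite.
#'
#' @param wavenumber Wavenumbers (cm-1).
#' @param absorbance Absorbance values (AU), same length.
#' @return An object of class `ir_spectrum`.
#' @export
ir_spectrum <- function(wavenumber, absorbance) {
  stopifnot(is.numeric(wavenumber), is.numeric(absorbance),
            length(wavenumber) == length(absorbance), length(wavenumber) >= 3)
  if (any(!is.finite(wavenumber)) || any(!is.finite(absorbance)))
    stop("wavenumbers and absorbance must be finite")
  ord <- order(wavenumber)
  wavenumber <- wavenumber[ord]; absorbance <- absorbance[ord]
  if (any(diff(wavenumber) <= 0)) stop("wavenumbers must be distinct")
  structure(list(wavenumber = wavenumber, absorbance = absorbance),
            class = "ir_spectrum")
}

#' @export
print.ir_spectrum <- function(x, ...) {
  cat(sprintf("<ir_spectrum> %g-%g cm-1 (%d points)\n",
              min(x$wavenumber), max(x$wavenumber), length(x$wavenumber)))
  invisible(x)
}

#' Amide I and II peak positions
#'
#' Locates the absorbance maxima within the amide I (1700-1600 cm-1) and
#' amide II (1600-1500 cm-1) windows. Ties resolve to the lower wavenumber.
#' Invariant to wavenumber ordering and to uniform absorbance scaling. A flat
#' window (no peak above baseline) is an error.
#'
#' @param s An [ir_spectrum()] covering at least 1700-1500 cm-1.
#' @param amide_I,amide_II Window bounds (cm-1).
#' @return List with `amide_I` and `amide_II`, each `list(position, intensity)`.
#' @export
amide_peaks <- function(s, amide_I = c(1600, 1700), amide_II = c(1500, 1600)) {
  stopifnot(inherits(s, "ir_spectrum"))
  locate <- function(win, label) {
    sel <- s$wavenumber >= win[1] & s$wavenumber <= win[2]
    if (!any(sel) || min(s$wavenumber) > win[1] || max(s$wavenumber) < win[2])
      stop(sprintf("spectrum does not cover the %s window (%g-%g cm-1)",
                   label, win[1], win[2]))
    a <- s$absorbance[sel]; w <- s$wavenumber[sel]
    if (diff(range(a)) <= 1e-10 * max(abs(a), 1e-300))
      stop(sprintf("no peak above baseline in the %s window", label))
    i <- which(a == max(a))[1]
    list(position = w[i], intensity = a[i])
  }
  list(amide_I = locate(amide_I, "amide I"), amide_II = locate(amide_II, "amide II"))
}

#' Default amide I band-to-structure assignment windows
#'
#' Standard amide I assignment convention (cm-1): beta-sheet 1610-1640 and
#' 1682-1700, random coil 1640-1650, alpha-helix 1650-1660, beta-turn
#' 1660-1682.
#'
#' @return Data frame with columns `class`, `lo`, `hi`.
#' @export
amide_assignment_windows <- function() {
  data.frame(class = c("beta_sheet", "random_coil", "alpha_helix", "beta_turn",
                       "beta_sheet"),
             lo = c(1610, 1640, 1650, 1660, 1682),
             hi = c(1640, 1650, 1660, 1682, 1700))
}

.assign_band <- function(center, windows) {
  hit <- windows$lo <= center & center < windows$hi
  # make the very top of the last window inclusive
  hit <- hit | (center == max(windows$hi) & windows$hi == max(windows$hi))
  if (!any(hit)) NA_character_ else windows$class[which(hit)[1]]
}

.gaussian <- function(x, amp, center, fwhm) {
  amp * exp(-4 * log(2) * (x - center)^2 / fwhm^2)
}

#' Deconvolve the amide I band into Gaussian components
#'
#' Estimates secondary-structure percentages from the amide I region
#' (1600-1700 cm-1). The region is baseline-corrected with a straight line
#' through the window endpoints (averaged over `edge_points` samples at each
#' end), band positions are seeded at the minima of the Savitzky-Golay
#' smoothed second derivative (window `sg_n` points, order `sg_p`), minima
#' shallower than `seed_frac` of the deepest minimum or within `merge_dist`
#' cm-1 of a deeper one are discarded, and the surviving bands are fitted by
#' bounded least squares (Levenberg-Marquardt): centers within
#' `center_tol` cm-1 of their seeds, FWHM within `width_bounds`, non-negative
#' amplitudes. Structure percentages are the summed fitted band areas per
#' assignment window over the total assigned area.
#'
#' @param s An [ir_spectrum()] covering the amide I region.
#' @param n_bands Optional cap on the number of bands (the deepest seeds are
#'   kept).
#' @param windows Assignment windows, as from [amide_assignment_windows()].
#' @param region Amide I bounds (cm-1).
#' @param sg_n,sg_p Savitzky-Golay window length (odd) and polynomial order.
#' @param seed_frac Discard second-derivative minima shallower than this
#'   fraction of the deepest minimum.
#' @param merge_dist Minimum separation (cm-1) between seeds; closer minima
#'   merge into the deeper one.
#' @param center_tol Allowed center movement from seed (cm-1).
#' @param width_bounds FWHM bounds (cm-1).
#' @param edge_points Points averaged at each end for the baseline.
#' @return List of class `amide_deconvolution`: `bands` (data frame: center,
#'   fwhm, amplitude, area, assignment), `structure` (named percentages
#'   summing to 100), `seeds`, `converged`.
#' @export
deconvolve_amide_I <- function(s, n_bands = NULL,
                               windows = amide_assignment_windows(),
                               region = c(1600, 1700),
                               sg_n = 9, sg_p = 3,
                               seed_frac = 0.10, merge_dist = 6,
                               center_tol = 4, width_bounds = c(5, 30),
                               edge_points = 3) {
  stopifnot(inherits(s, "ir_spectrum"))
  keep <- s$wavenumber >= region[1] & s$wavenumber <= region[2]
  if (sum(keep) < sg_n + 2) stop("amide I region not covered densely enough")
  x <- s$wavenumber[keep]; a <- s$absorbance[keep]
  h <- diff(x)
  if (diff(range(h)) > 1e-6 * mean(h)) {
    # resample to a uniform grid for the derivative filter
    xg <- seq(min(x), max(x), by = stats::median(h))
    a <- stats::approx(x, a, xout = xg)$y
    x <- xg
  }
  np <- length(x)
  e <- min(edge_points, np %/% 2)
  x1 <- mean(x[1:e]); x2 <- mean(x[(np - e + 1):np])
  a1 <- mean(a[1:e]); a2 <- mean(a[(np - e + 1):np])
  y <- a - (a1 + (a2 - a1) * (x - x1) / (x2 - x1))

  d2 <- signal::sgolayfilt(y, p = sg_p, n = sg_n, m = 2, ts = x[2] - x[1])
  idx <- which(diff(sign(diff(d2))) == 2) + 1
  idx <- idx[d2[idx] < 0]
  if (length(idx)) idx <- idx[d2[idx] <= seed_frac * min(d2)]
  # non-max suppression: keep the deepest minimum within merge_dist
  ord <- idx[order(d2[idx])]
  sel <- integer(0)
  for (i in ord)
    if (!length(sel) || all(abs(x[i] - x[sel]) > merge_dist)) sel <- c(sel, i)
  if (!is.null(n_bands) && length(sel) > n_bands)
    sel <- sel[seq_len(n_bands)]  # ord is depth-sorted, so these are deepest
  idx <- sort(sel)
  seeds <- x[idx]
  if (length(seeds) < 2)
    stop(sprintf("fewer than 2 bands detected (seeds: %s)",
                 paste(round(seeds, 1), collapse = ", ")))

  k <- length(seeds)
  par0 <- c(pmax(y[idx], max(y) * 0.05), seeds, rep(mean(width_bounds), k))
  lower <- c(rep(0, k), seeds - center_tol, rep(width_bounds[1], k))
  upper <- c(rep(Inf, k), seeds + center_tol, rep(width_bounds[2], k))
  model <- function(p) {
    rowSums(vapply(seq_len(k), function(i)
      .gaussian(x, p[i], p[k + i], p[2 * k + i]), numeric(np)))
  }
  fit <- minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                            fn = function(p) y - model(p),
                            control = minpack.lm::nls.lm.control(maxiter = 400))
  if (!fit$info %in% 1:4)
    stop(sprintf("band fit did not converge (info %d; seeds: %s)",
                 fit$info, paste(round(seeds, 1), collapse = ", ")))
  p <- fit$par
  amp <- p[1:k]; ce <- p[(k + 1):(2 * k)]; fw <- p[(2 * k + 1):(3 * k)]
  area <- amp * fw * sqrt(pi / (4 * log(2)))
  assignment <- vapply(ce, .assign_band, character(1), windows = windows)
  bands <- data.frame(center = ce, fwhm = fw, amplitude = amp, area = area,
                      assignment = assignment)
  bands <- bands[order(bands$center), ]
  rownames(bands) <- NULL
  ok <- !is.na(bands$assignment) & bands$area > 0
  if (any(!ok & bands$area > 1e-9 * sum(bands$area)))
    warning("band(s) outside the assignment windows excluded from percentages")
  tot <- sum(bands$area[ok])
  if (tot <= 0) stop("no assignable band area")
  classes <- c("beta_sheet", "random_coil", "alpha_helix", "beta_turn")
  pct <- vapply(classes, function(cl)
    100 * sum(bands$area[ok][bands$assignment[ok] == cl]) / tot, numeric(1))
  structure(list(bands = bands, structure = pct, seeds = seeds,
                 converged = TRUE),
            class = "amide_deconvolution")
}

#' @export
print.amide_deconvolution <- function(x, ...) {
  cat(sprintf("Amide I deconvolution: %d bands\n", nrow(x$bands)))
  print(x$bands, row.names = FALSE, digits = 4)
  cat("structure (%):",
      paste(sprintf("%s %.2f", names(x$structure), x$structure), collapse = ", "), "\n")
  invisible(x)
}
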