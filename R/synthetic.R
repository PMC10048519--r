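#' Define a quenching titration scenario with known ground truth
#'
#' Parameters of a synthetic fluorescence titration experiment. Binding
#' constants at temperatures other than `t_ref` follow the exact van't Hoff
#' relation `K(T) = k_ref * exp(-dh*1000/R * (1/T - 1/t_ref))`, so a negative
#' `dh` gives constants that fall with temperature. Defaults mirror a typical
#' protein--acrylamide titration design: nine quencher levels from 0 to 200
#' umol/L read at 297, 304 and 311 K.
#'
#' @param ka_ref Binding constant at `t_ref` (L/mol).
#' @param ksv_ref Stern-Volmer constant at `t_ref` (L/mol).
#' @param t_ref Reference temperature (K).
#' @param dh Binding enthalpy (kJ/mol) linking the temperatures.
#' @param n_sites Number of binding sites (double-log slope).
#' @param f0 Unquenched peak intensity (arbitrary units).
#' @param temperatures Temperatures of the series (K).
#' @param q Quencher concentrations (mol/L), including 0.
#' @param noise_sigma Additive Gaussian noise sd as a fraction of `f0`.
#' @param tau0 Fluorophore lifetime (s), for downstream Kq.
#' @param seed Integer seed making every generated dataset reproducible;
#'   `NULL` uses the current RNG stream.
#' @return List of class `quench_scenario`.
#' @export
quench_scenario <- function(ka_ref = 4.13e4, ksv_ref = 1.20e4, t_ref = 297,
                            dh = -50.17, n_sites = 1.16, f0 = 1000,
                            temperatures = c(297, 304, 311),
                            q = c(0, 20, 40, 60, 80, 100, 120, 160, 200) * 1e-6,
                            noise_sigma = 0, tau0 = 1e-8, seed = NULL) {
  stopifnot(ka_ref > 0, ksv_ref > 0, t_ref > 0, n_sites > 0, f0 > 0,
            all(temperatures > 0), all(q >= 0), noise_sigma >= 0, tau0 > 0)
  if (!any(q == 0)) stop("q must include the zero-quencher point")
  structure(list(ka_ref = ka_ref, ksv_ref = ksv_ref, t_ref = t_ref, dh = dh,
                 n_sites = n_sites, f0 = f0, temperatures = temperatures,
                 q = sort(q), noise_sigma = noise_sigma, tau0 = tau0,
                 seed = seed),
            class = "quench_scenario")
}

# van't Hoff temperature scaling of an equilibrium constant
.k_at <- function(k_ref, t_ref, dh, t) {
  k_ref * exp(-dh * 1000 / R_GAS * (1 / t - 1 / t_ref))
}

#' Generate a synthetic titration curve
#'
#' Intensities follow the inverted binding model
#' `F = F0 / (1 + KA(T) [Q]^n)` (`model = "binding"`, the double-log model
#' solved for F) or the Stern-Volmer line `F = F0 / (1 + Ksv(T) [Q])`
#' (`model = "stern_volmer"`). Additive Gaussian noise of sd
#' `noise_sigma * f0` is applied to every point (including [Q] = 0) and
#' truncated at zero; truncation biases very noisy points upward, so keep
#' `noise_sigma` small. Reproducible for a fixed scenario seed: the stream is
#' seeded with `seed + round(t)` so each temperature gets its own draw.
#'
#' @param sc A [quench_scenario()].
#' @param t Temperature (K), typically one of `sc$temperatures`.
#' @param model Generative model, `"binding"` or `"stern_volmer"`.
#' @return A [titration_curve()] with attribute `truth`: the generating
#'   `ka`, `ksv`, `n_sites`, `f0`, `model` and `temperature`.
#' @export
gen_titration <- function(sc, t, model = c("binding", "stern_volmer")) {
  stopifnot(inherits(sc, "quench_scenario"))
  model <- match.arg(model)
  ka <- .k_at(sc$ka_ref, sc$t_ref, sc$dh, t)
  ksv <- .k_at(sc$ksv_ref, sc$t_ref, sc$dh, t)
  if (!is.finite(ka) || !is.finite(ksv) || ka <= 0 || ksv <= 0)
    stop("infeasible scenario parameters")
  f_true <- if (model == "binding") sc$f0 / (1 + ka * sc$q^sc$n_sites)
            else sc$f0 / (1 + ksv * sc$q)
  f <- with_seed(if (is.null(sc$seed)) NULL else sc$seed + round(t),
                 pmax(f_true + stats::rnorm(length(sc$q), 0, sc$noise_sigma * sc$f0), 0))
  curve <- titration_curve(sc$q, f, temperature = t)
  attr(curve, "truth") <- list(ka = ka, ksv = ksv, n_sites = sc$n_sites,
                               f0 = sc$f0, model = model, temperature = t)
  curve
}

#' Generate synthetic emission spectra for a titration
#'
#' One Gaussian emission peak per quencher level whose amplitude equals the
#' corresponding [gen_titration()] intensity (noise included there), centered
#' at `center0` nm and shifted linearly with [Q] up to `shift_at_max_q` nm at
#' the highest concentration (negative = blue shift).
#'
#' @inheritParams gen_titration
#' @param center0 Peak position at [Q] = 0 (nm).
#' @param fwhm_nm Peak full width at half maximum (nm).
#' @param shift_at_max_q Peak shift at the largest [Q] (nm).
#' @param wavelengths Emission wavelength grid (nm).
#' @return List of [emission_spectrum()] objects (ascending [Q]) with
#'   attribute `truth` (the titration truth plus the shift settings).
#' @export
gen_spectra <- function(sc, t, center0 = 340, fwhm_nm = 60, shift_at_max_q = -5,
                        wavelengths = seq(300, 500, by = 0.5),
                        model = "binding") {
  curve <- gen_titration(sc, t, model = model)
  qmax <- max(curve$q)
  centers <- center0 + if (qmax > 0) shift_at_max_q * curve$q / qmax else 0
  spectra <- lapply(seq_along(curve$q), function(i)
    emission_spectrum(wavelengths,
                      .gaussian(wavelengths, curve$f[i], centers[i], fwhm_nm),
                      temperature = t, quencher_conc = curve$q[i]))
  attr(spectra, "truth") <- c(attr(curve, "truth"),
                              list(center0 = center0,
                                   shift_at_max_q = shift_at_max_q,
                                   f = curve$f))
  spectra
}

#' Generate a synthetic amide I spectrum with known structure percentages
#'
#' Sums one Gaussian band per secondary-structure class, with areas
#' proportional to `truth_pct`, plus optional additive noise (sd =
#' `noise_sigma` times the maximum absorbance). Default band centers put one
#' band in each assignment window of [amide_assignment_windows()].
#'
#' @param truth_pct Percentages for beta-sheet, random coil, alpha-helix and
#'   beta-turn (summing to ~100; renormalised exactly).
#' @param centers,fwhm Band centers and widths (cm-1), one per class.
#' @param total_area Total band area (absorbance x cm-1).
#' @param noise_sigma Noise sd as a fraction of the maximum absorbance.
#' @param wavenumbers Sampling grid (cm-1).
#' @param seed Integer seed; `NULL` uses the current stream.
#' @return An [ir_spectrum()] with attribute `truth` (named percentages,
#'   centers, fwhm, areas).
#' @export
gen_ftir <- function(truth_pct = c(beta_sheet = 40.17, random_coil = 16.78,
                                   alpha_helix = 17.29, beta_turn = 25.77),
                     centers = c(1627, 1645, 1655, 1668),
                     fwhm = c(20, 9, 9, 15), total_area = 10,
                     noise_sigma = 0, wavenumbers = seq(1580, 1720, by = 1),
                     seed = NULL) {
  stopifnot(length(truth_pct) == 4, length(centers) == 4, length(fwhm) == 4,
            all(truth_pct >= 0), all(fwhm > 0), total_area > 0)
  if (abs(sum(truth_pct) - 100) > 0.5)
    stop("truth percentages must sum to 100 (within 0.5)")
  pct <- 100 * truth_pct / sum(truth_pct)
  areas <- pct / 100 * total_area
  amps <- areas / (fwhm * sqrt(pi / (4 * log(2))))
  a <- rowSums(vapply(1:4, function(i)
    .gaussian(wavenumbers, amps[i], centers[i], fwhm[i]),
    numeric(length(wavenumbers))))
  a <- with_seed(seed, a + stats::rnorm(length(a), 0, noise_sigma * max(a)))
  s <- ir_spectrum(wavenumbers, a)
  attr(s, "truth") <- list(pct = pct, centers = centers, fwhm = fwhm,
                           areas = areas)
  s
}

#' Default release-rate scenario means
#'
#' Group means (% release) for a treatments-by-phase design mirroring the
#' typical ordering of a protein--ligand digestion study: release is lower in
#' the intestinal than the gastric phase for every treatment, thermal and
#' ultrasound treatments release less than the untreated protein, and
#' high-pressure homogenisation releases more.
#'
#' @return Data frame with columns `treatment`, `phase`, `mean_release`.
#' @export
release_scenario_means <- function() {
  data.frame(
    treatment = rep(c("nontreated", "thermal", "hph", "ultrasound"), each = 2),
    phase = rep(c("gastric", "intestinal"), 4),
    mean_release = c(60, 45, 50, 35, 70, 55, 48, 32))
}

#' Generate a synthetic release-rate replicate table
#'
#' Per-replicate free and total ligand amounts whose release rates are normal
#' around the scenario means (truncated to [0, 100]).
#'
#' @param means Data frame with `treatment`, `phase`, `mean_release` columns
#'   (default [release_scenario_means()]).
#' @param sd Replicate standard deviation of the release rate (percentage
#'   points).
#' @param n_reps Replicates per cell (default 3, the usual triplicate).
#' @param a_total Total ligand amount per replicate.
#' @param seed Integer seed; `NULL` uses the current stream.
#' @return Data frame with `treatment`, `phase`, `replicate`, `a_total`,
#'   `a_free`, and attribute `truth` (the means table and sd).
#' @export
gen_release <- function(means = release_scenario_means(), sd = 2, n_reps = 3,
                        a_total = 100, seed = NULL) {
  stopifnot(is.data.frame(means),
            all(c("treatment", "phase", "mean_release") %in% names(means)),
            sd >= 0, n_reps >= 1, a_total > 0)
  idx <- rep(seq_len(nrow(means)), each = n_reps)
  rate <- with_seed(seed,
    pmin(pmax(stats::rnorm(length(idx), means$mean_release[idx], sd), 0), 100))
  out <- data.frame(treatment = means$treatment[idx], phase = means$phase[idx],
                    replicate = rep(seq_len(n_reps), nrow(means)),
                    a_total = a_total, a_free = rate / 100 * a_total)
  attr(out, "truth") <- list(means = means, sd = sd)
  out
}

#' Generate a synthetic binding-rate dataset over protein and ligand levels
#'
#' Emulates a protein-concentration by ligand-concentration binding grid with
#' triplicate HPLC-style measurements. The generating binding rate increases
#' and saturates with protein concentration and peaks at `aa_peak_mmol_per_l`
#' over the ligand axis:
#' `B = b_scale * spi/(spi + k_spi) * 2u/(1 + u^2)` with
#' `u = aa / aa_peak_mmol_per_l`.
#'
#' @param spi_pct Protein concentrations (% w/v).
#' @param aa_mmol_per_l Ligand concentrations (mmol/L).
#' @param aa_peak_mmol_per_l Ligand concentration at which the generating
#'   binding rate peaks.
#' @param b_scale,k_spi Saturation parameters of the protein axis.
#' @param sd Replicate noise on the free amount, as percent of total.
#' @param n_reps Replicates per cell.
#' @param a_total Total ligand amount per measurement.
#' @param seed Integer seed; `NULL` uses the current stream.
#' @return Data frame with `spi_pct`, `aa_mmol_per_l`, `replicate`,
#'   `a_total`, `a_free`, plus attribute `truth` (the generating rate per
#'   cell).
#' @export
gen_binding <- function(spi_pct = c(0.1, 0.25, 0.5, 1, 2),
                        aa_mmol_per_l = c(0.5, 1, 2.5, 5),
                        aa_peak_mmol_per_l = 2.5, b_scale = 60, k_spi = 0.5,
                        sd = 0.5, n_reps = 3, a_total = 100, seed = NULL) {
  grid <- expand.grid(spi_pct = spi_pct, aa_mmol_per_l = aa_mmol_per_l)
  u <- grid$aa_mmol_per_l / aa_peak_mmol_per_l
  b <- b_scale * grid$spi_pct / (grid$spi_pct + k_spi) * 2 * u / (1 + u^2)
  idx <- rep(seq_len(nrow(grid)), each = n_reps)
  free <- a_total * (1 - b[idx] / 100)
  free <- with_seed(seed,
    pmin(pmax(free + stats::rnorm(length(idx), 0, sd / 100 * a_total), 0), a_total))
  out <- data.frame(spi_pct = grid$spi_pct[idx],
                    aa_mmol_per_l = grid$aa_mmol_per_l[idx],
                    replicate = rep(seq_len(n_reps), nrow(grid)),
                    a_total = a_total, a_free = free)
  attr(out, "truth") <- cbind(grid, rate = b)
  out
}
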