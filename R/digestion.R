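#' Final concentration of one electrolyte stock after dilution
#'
#' A volume `volume_ml` of a `stock_conc` mol/L stock made up to
#' `final_volume_ml` with water gives
#' `stock_conc * volume_ml / final_volume_ml * 1000` mmol/L.
#'
#' @param stock_conc Stock concentration (mol/L), non-negative.
#' @param volume_ml Stock volume added (mL), non-negative.
#' @param final_volume_ml Made-up final volume (mL), positive (default 500).
#' @return Final concentration in mmol/L.
#' @export
component_final_conc <- function(stock_conc, volume_ml, final_volume_ml = 500) {
  if (any(!is.finite(final_volume_ml)) || any(final_volume_ml <= 0))
    stop("final volume must be positive")
  if (any(!is.finite(volume_ml)) || any(volume_ml < 0)) stop("volumes must be non-negative")
  if (any(!is.finite(stock_conc)) || any(stock_conc < 0)) stop("stock concentration must be non-negative")
  stock_conc * volume_ml / final_volume_ml * 1000
}

# Built-in electrolyte recipes for the three simulated digestion fluids
# (salivary SSF pH 7, gastric SGF pH 3, intestinal SIF pH 7), each made up to
# 500 mL with water. Declared concentrations are stored with the number of
# decimals at which they are declared, so validation can compare at declared
# precision. CaCl2 is deliberately absent: it is added at phase level.
.fluid_table <- function() {
  comp <- c("KCl", "KH2PO4", "NaHCO3", "NaCl", "MgCl2(H2O)6", "(NH4)2CO3", "HCl")
  stock <- c(0.5, 0.5, 1, 2, 0.15, 0.5, 6)
  list(
    SSF = data.frame(component = comp, stock_mol_per_l = stock,
                     volume_ml = c(15.1, 3.7, 6.8, NA, 0.5, 0.06, 0.09),
                     declared_mmol_per_l = c(15.1, 3.7, 13.6, NA, 0.15, 0.06, 1.1),
                     declared_digits = c(1, 1, 1, NA, 2, 2, 1)),
    SGF = data.frame(component = comp, stock_mol_per_l = stock,
                     volume_ml = c(6.9, 0.9, 12.5, 11.8, 0.4, 0.5, 1.3),
                     declared_mmol_per_l = c(6.9, 0.9, 25, 47.2, 0.1, 0.5, 15.6),
                     declared_digits = c(1, 1, 0, 1, 1, 1, 1)),
    SIF = data.frame(component = comp, stock_mol_per_l = stock,
                     volume_ml = c(6.8, 0.8, 42.5, 9.6, 1.1, NA, 0.7),
                     declared_mmol_per_l = c(6.8, 0.8, 85, 38.4, 0.33, NA, 8.4),
                     declared_digits = c(1, 1, 0, 1, 2, NA, 1)))
}

#' Built-in simulated digestion fluid recipe
#'
#' Electrolyte stock recipe for one of the simulated salivary (SSF, pH 7),
#' gastric (SGF, pH 3) or intestinal (SIF, pH 7) fluids, made up to 500 mL
#' with distilled water. CaCl2 is excluded from the electrolyte stocks and is
#' added separately at each digestion phase.
#'
#' @param fluid `"SSF"`, `"SGF"` or `"SIF"`.
#' @return List of class `fluid_recipe`: `fluid`, `ph`, `final_volume_ml`,
#'   `components` (data frame with stock concentration, volume and declared
#'   final concentration per electrolyte).
#' @export
fluid_recipe <- function(fluid = c("SSF", "SGF", "SIF")) {
  fluid <- match.arg(fluid)
  tab <- .fluid_table()[[fluid]]
  tab <- tab[!is.na(tab$volume_ml), ]
  rownames(tab) <- NULL
  structure(list(fluid = fluid,
                 ph = c(SSF = 7, SGF = 3, SIF = 7)[[fluid]],
                 final_volume_ml = 500, components = tab),
            class = "fluid_recipe")
}

#' @export
print.fluid_recipe <- function(x, ...) {
  cat(sprintf("<fluid_recipe> %s (pH %g, made up to %g mL)\n",
              x$fluid, x$ph, x$final_volume_ml))
  print(x$components, row.names = FALSE)
  invisible(x)
}

#' Validate a fluid recipe against its declared concentrations
#'
#' Recomputes every component's final concentration from the dilution algebra
#' and compares it with the declared value after rounding to the declared
#' precision (e.g. 6 mol/L x 0.09 mL / 500 mL = 1.08 mmol/L, declared 1.1).
#' Component volumes summing beyond the final made-up volume are an error.
#'
#' @param recipe A [fluid_recipe()] (or a compatible list).
#' @return Data frame of class `recipe_validation`: component, computed and
#'   declared concentrations, and a `pass` flag; attribute `all_pass`.
#' @export
validate_recipe <- function(recipe) {
  stopifnot(inherits(recipe, "fluid_recipe"))
  comp <- recipe$components
  if (sum(comp$volume_ml) > recipe$final_volume_ml)
    stop("component volumes exceed the final made-up volume")
  computed <- component_final_conc(comp$stock_mol_per_l, comp$volume_ml,
                                   recipe$final_volume_ml)
  rounded <- round(computed, comp$declared_digits)
  pass <- abs(rounded - comp$declared_mmol_per_l) < 1e-9
  out <- data.frame(component = comp$component, computed_mmol_per_l = computed,
                    declared_mmol_per_l = comp$declared_mmol_per_l, pass = pass)
  attr(out, "all_pass") <- all(pass)
  class(out) <- c("recipe_validation", "data.frame")
  out
}

#' @export
print.recipe_validation <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat(if (attr(x, "all_pass")) "all components pass\n" else "MISMATCHES present\n")
  invisible(x)
}

.incubation <- function(minutes) list(rpm = 55, temp_c = 37, minutes = minutes)

.phase_plan <- function(phase, input_volume_ml, additions, target_ph, minutes,
                        final_concs, notes = character()) {
  structure(list(phase = phase, input_volume_ml = input_volume_ml,
                 additions = additions, target_ph = target_ph,
                 incubation = .incubation(minutes),
                 resulting_volume_ml = input_volume_ml + sum(additions$volume_ml),
                 final_concs = final_concs, notes = notes),
            class = "phase_plan")
}

#' @export
print.phase_plan <- function(x, ...) {
  cat(sprintf("<phase_plan> %s: %g mL in -> %g mL out, pH %g, %g min at %g rpm / %g C\n",
              x$phase, x$input_volume_ml, x$resulting_volume_ml, x$target_ph,
              x$incubation$minutes, x$incubation$rpm, x$incubation$temp_c))
  print(x$additions, row.names = FALSE, digits = 4)
  if (length(x$final_concs))
    cat("final:", paste(sprintf("%s = %.4g %s", names(x$final_concs),
                                vapply(x$final_concs, `[[`, 0, "value"),
                                vapply(x$final_concs, `[[`, "", "unit")),
                        collapse = ", "), "\n")
  for (n in x$notes) cat("note:", n, "\n")
  invisible(x)
}

#' Plan the oral digestion phase
#'
#' For a 10 mL sample the oral mix is: alpha-amylase 1 mL of a 1500 U/mL
#' stock, SSF electrolyte 8 mL, CaCl2 50 uL of 0.3 mol/L, and water 1.95 mL
#' (21 mL total, 2 min at 55 rpm / 37 C). Other sample volumes scale every
#' addition proportionally, leaving the final concentrations unchanged
#' (amylase 1500/21 = 71.43 U/mL; CaCl2 0.714 mmol/L).
#'
#' @param sample_volume_ml Sample volume (mL), positive.
#' @param amylase_stock_u_per_ml Amylase stock activity (U/mL).
#' @return A `phase_plan`.
#' @export
plan_oral <- function(sample_volume_ml = 10, amylase_stock_u_per_ml = 1500) {
  if (!is.finite(sample_volume_ml) || sample_volume_ml <= 0)
    stop("sample volume must be positive")
  s <- sample_volume_ml / 10
  additions <- data.frame(
    substance = c("alpha-amylase stock", "SSF electrolyte", "CaCl2 0.3 mol/L", "water"),
    volume_ml = c(1, 8, 0.05, 1.95) * s)
  v_out <- sample_volume_ml + sum(additions$volume_ml)
  final <- list(
    amylase = list(value = amylase_stock_u_per_ml * 1 * s / v_out, unit = "U/mL"),
    cacl2 = list(value = 0.3 * 0.05 * s / v_out * 1000, unit = "mmol/L"))
  .phase_plan("oral", sample_volume_ml, additions, target_ph = 7, minutes = 2,
              final_concs = final)
}

# Shared gastric/intestinal mixing logic. Enzyme/bile volumes are solved so the
# stated final concentrations hold in the total resulting volume V:
#   v_i = (target_i / stock_i) * V,  V = V0 / (1 - sum_i target_i/stock_i)
.plan_mix <- function(phase, plan_in, fluid, ratio, targets, target_ph,
                      ph_reagent, ph_adjust_volume_ml, ph_molarity,
                      cacl2, minutes) {
  stopifnot(inherits(plan_in, "phase_plan"))
  if (!is.finite(ratio) || ratio < 0) stop("mixing ratio must be non-negative")
  v_in <- plan_in$resulting_volume_ml
  v_fluid <- v_in * ratio
  # CaCl2 scaled from the oral pattern (50 uL per 21 mL of resulting volume);
  # the protocol source does not state phase-level CaCl2 amounts.
  v_cacl2 <- if (cacl2) (0.05 / 21) * (v_in + v_fluid) else 0
  v0 <- v_in + v_fluid + v_cacl2 + ph_adjust_volume_ml
  frac <- sum(vapply(targets, function(tg) {
    if (tg$target >= tg$stock)
      stop(sprintf("%s stock (%g %s) cannot reach target %g %s",
                   tg$substance, tg$stock, tg$unit, tg$target, tg$unit))
    tg$target / tg$stock
  }, numeric(1)))
  if (frac >= 1) stop("combined targets unreachable from the given stocks")
  v_total <- v0 / (1 - frac)
  add <- data.frame(
    substance = c(paste(fluid, "electrolyte"),
                  if (cacl2) "CaCl2 0.3 mol/L",
                  vapply(targets, `[[`, "", "substance"),
                  sprintf("%s (%g mol/L, to pH %g)", ph_reagent, ph_molarity, target_ph)),
    volume_ml = c(v_fluid, if (cacl2) v_cacl2,
                  vapply(targets, function(tg) tg$target / tg$stock * v_total, 0),
                  ph_adjust_volume_ml))
  final <- lapply(targets, function(tg) list(value = tg$target, unit = tg$unit))
  names(final) <- vapply(targets, `[[`, "", "name")
  if (cacl2)
    final$cacl2 <- list(value = 0.3 * v_cacl2 / v_total * 1000, unit = "mmol/L")
  notes <- c(sprintf("digesta:%s mixing ratio 1:%g assumed (not stated by the protocol)",
                     fluid, ratio),
             if (cacl2) "phase-level CaCl2 scaled from the oral pattern (assumption)")
  .phase_plan(phase, v_in, add, target_ph, minutes, final, notes)
}

#' Plan the gastric digestion phase
#'
#' Mixes the oral digesta with SGF electrolyte at `ratio` (v/v), adds pepsin
#' to a 2000 U/mL final activity, and adjusts to pH 3.0 for 2 h at 55 rpm /
#' 37 C. The digesta:SGF proportion is not fixed by the protocol and defaults
#' to 1:1 (the standardised static-digestion convention); every plan carries a
#' note flagging the assumption.
#'
#' @param plan_in The preceding `phase_plan` (oral).
#' @param ratio SGF volume per digesta volume (v/v).
#' @param pepsin_target_u_per_ml,pepsin_stock_u_per_ml Final and stock pepsin
#'   activities (U/mL); the stock must exceed the target.
#' @param ph_adjust_volume_ml Volume of acid used for the pH change (mL),
#'   tracked as an addition; the protocol states the target pH, not a volume.
#' @param ph_molarity Acid molarity (mol/L).
#' @param cacl2 Add phase-level CaCl2 scaled from the oral pattern.
#' @return A `phase_plan`.
#' @export
plan_gastric <- function(plan_in, ratio = 1,
                         pepsin_target_u_per_ml = 2000,
                         pepsin_stock_u_per_ml = 25000,
                         ph_adjust_volume_ml = 0, ph_molarity = 1,
                         cacl2 = TRUE) {
  .plan_mix("gastric", plan_in, "SGF", ratio,
            targets = list(list(name = "pepsin", substance = "pepsin stock",
                                target = pepsin_target_u_per_ml,
                                stock = pepsin_stock_u_per_ml, unit = "U/mL")),
            target_ph = 3, ph_reagent = "HCl",
            ph_adjust_volume_ml = ph_adjust_volume_ml, ph_molarity = ph_molarity,
            cacl2 = cacl2, minutes = 120)
}

#' Plan the intestinal digestion phase
#'
#' Mixes the gastric digesta with SIF electrolyte at `ratio` (v/v), adds
#' pancreatin to 2000 U/mL and bile to 0.16 mol/L final (unit label kept as
#' stated by the protocol, although molarity is an odd unit for a bile
#' mixture), and adjusts to pH 7.0 for 2 h at 55 rpm / 37 C.
#'
#' @inheritParams plan_gastric
#' @param pancreatin_target_u_per_ml,pancreatin_stock_u_per_ml Final and stock
#'   pancreatin activities (U/mL).
#' @param bile_target_mol_per_l,bile_stock_mol_per_l Final and stock bile
#'   concentrations (mol/L).
#' @return A `phase_plan`.
#' @export
plan_intestinal <- function(plan_in, ratio = 1,
                            pancreatin_target_u_per_ml = 2000,
                            pancreatin_stock_u_per_ml = 25000,
                            bile_target_mol_per_l = 0.16,
                            bile_stock_mol_per_l = 1,
                            ph_adjust_volume_ml = 0, ph_molarity = 1,
                            cacl2 = TRUE) {
  .plan_mix("intestinal", plan_in, "SIF", ratio,
            targets = list(
              list(name = "pancreatin", substance = "pancreatin stock",
                   target = pancreatin_target_u_per_ml,
                   stock = pancreatin_stock_u_per_ml, unit = "U/mL"),
              list(name = "bile", substance = "bile stock",
                   target = bile_target_mol_per_l,
                   stock = bile_stock_mol_per_l, unit = "mol/L")),
            target_ph = 7, ph_reagent = "NaOH",
            ph_adjust_volume_ml = ph_adjust_volume_ml, ph_molarity = ph_molarity,
            cacl2 = cacl2, minutes = 120)
}

#' Plan a full oral-gastric-intestinal digestion
#'
#' Chains [plan_oral()], [plan_gastric()] and [plan_intestinal()] and reports
#' the cumulative dilution factor of the original sample after each phase.
#'
#' @inheritParams plan_oral
#' @param gastric_ratio,intestinal_ratio Digesta:fluid mixing ratios (v/v).
#' @param ... Passed on to [plan_gastric()] and [plan_intestinal()].
#' @return List of class `digestion_plan`: `oral`, `gastric`, `intestinal`
#'   phase plans plus `dilution` (named cumulative dilution factors).
#' @export
digestion_plan <- function(sample_volume_ml = 10, gastric_ratio = 1,
                           intestinal_ratio = 1, ...) {
  oral <- plan_oral(sample_volume_ml)
  gast <- plan_gastric(oral, ratio = gastric_ratio, ...)
  inte <- plan_intestinal(gast, ratio = intestinal_ratio, ...)
  dil <- c(oral = oral$resulting_volume_ml,
           gastric = gast$resulting_volume_ml,
           intestinal = inte$resulting_volume_ml) / sample_volume_ml
  structure(list(oral = oral, gastric = gast, intestinal = inte, dilution = dil),
            class = "digestion_plan")
}

#' @export
print.digestion_plan <- function(x, ...) {
  for (p in x[c("oral", "gastric", "intestinal")]) { print(p); cat("\n") }
  cat("cumulative dilution:",
      paste(sprintf("%s %.3f x", names(x$dilution), x$dilution), collapse = ", "), "\n")
  invisible(x)
}

#' Null-digestion conservation check for a non-interacting tracer
#'
#' Pushes a conserved, non-binding tracer through the full digestion plan,
#' updating its concentration at every single volume addition, and computes
#' the release rate from the final concentration times the final volume
#' against the known total amount. With consistent volume bookkeeping the
#' release is exactly 100% at both the gastric and intestinal stages; any
#' discrepancy exposes an accounting error in the plan.
#'
#' @inheritParams digestion_plan
#' @param tracer_amount Amount of tracer in the sample (arbitrary unit).
#' @return Named vector with the gastric and intestinal release rates (%).
#' @export
null_digestion_release <- function(sample_volume_ml = 10, tracer_amount = 1, ...) {
  plan <- digestion_plan(sample_volume_ml, ...)
  conc <- tracer_amount / sample_volume_ml
  vol <- sample_volume_ml
  release_at <- function(phase) {
    for (v in phase$additions$volume_ml) {
      conc <<- conc * vol / (vol + v)  # each addition dilutes the tracer
      vol <<- vol + v
    }
    stopifnot(isTRUE(all.equal(vol, phase$resulting_volume_ml)))
    release_rate(a_free = conc * vol, a_total = tracer_amount)
  }
  release_at(plan$oral)
  g <- release_at(plan$gastric)
  i <- release_at(plan$intestinal)
  c(gastric = g, intestinal = i)
}
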