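# quenchbind

Analysis of protein–ligand interactions measured by fluorescence quenching,
from raw emission spectra to binding thermodynamics — plus the surrounding
wet-lab bookkeeping: simulated-digestion planning, amide I secondary-structure
deconvolution, and the gated ANOVA statistics used to report triplicate
assays. The motivating system is a soy-protein isolate binding acrylamide,
but nothing in the package is specific to it.

## The science in one paragraph

When a small molecule quenches a protein's intrinsic fluorescence, the
Stern–Volmer slope K<sub>sv</sub> of F₀/F against [Q] measures the quenching
efficiency; dividing by the fluorophore lifetime τ₀ (~10⁻⁸ s) gives the
bimolecular rate constant K<sub>q</sub>, and a K<sub>q</sub> far above the
diffusion limit (2×10¹⁰ L mol⁻¹ s⁻¹) proves the quencher forms a ground-state
complex (static quenching) rather than merely colliding. The
double-logarithmic plot of log((F₀−F)/F) against log[Q] then yields the
binding constant K<sub>A</sub> (intercept) and binding-site count n (slope).
Repeating at several temperatures, the van't Hoff slope of ln K<sub>A</sub>
vs 1/T gives ΔH, ΔG = −RT ln K<sub>A</sub>, and ΔS by difference; the signs
of ΔH and ΔS identify the dominant forces (both negative → hydrogen bonds +
van der Waals). Downstream, the package validates simulated
salivary/gastric/intestinal fluid recipes by dilution algebra, plans the
three-phase digestion with closed-form enzyme volumes, deconvolves the FTIR
amide I band into secondary-structure percentages, and reports grouped
triplicates through a Levene/K-S-gated one-way ANOVA with compact letter
display.

## Worked example

Every generator returns its ground truth as an attribute, so the full
pipeline can be exercised end to end without laboratory data. Generate a
titration at 0.5 % noise, reduce the spectra to a curve, and fit:

```r
library(quenchbind)

sc <- quench_scenario(noise_sigma = 0.005, seed = 11)   # Ksv 1.2e4, KA 4.13e4, dH -50.17
spectra <- gen_spectra(sc, 297, model = "stern_volmer") # one spectrum per [Q]
ext <- extract_titration(spectra)
ext
#> <titration_curve> T = 297 K, 9 points, [Q] 0-0.0002 mol/L, F0 = 1000.83
#>         q      f lambda_max shift
#> 1 0.00000 1000.8      340.0  none
#> 2 0.00002  803.8      339.5  none
#> 3 0.00004  667.6      339.0  blue
#> 4 0.00006  587.8      338.5  blue
#> 5 0.00008  505.8      338.0  blue
#> 6 0.00010  449.2      337.5  blue
#> 7 0.00012  410.3      337.0  blue
#> 8 0.00016  334.8      336.0  blue
#> 9 0.00020  290.9      335.0  blue

sv <- fit_stern_volmer(ext$curve)
sv
#> Stern-Volmer fit (9 points)
#>   Ksv = 1.227e+04 L/mol   Kq = 1.227e+12 L mol-1 s-1 (tau0 = 1e-08 s)
#>   intercept = 0.9950   R2 = 0.9994
classify_mechanism(sv$kq)
#> [1] "static"
```

Three temperatures chain into the thermodynamics:

```r
kas <- vapply(sc$temperatures, function(t) {
  suppressWarnings(fit_double_log(gen_titration(sc, t))$ka)
}, numeric(1))
thermo_analysis(sc$temperatures, kas)
#> Thermodynamic analysis: dH = -67.54 kJ/mol, forces = hbond_vdw
#>    t       ka     dg      ds spontaneous
#>  297 40074.20 -26.17 -139.30        TRUE
#>  304 31033.75 -26.14 -136.19        TRUE
#>  311 11629.96 -24.21 -139.35        TRUE
```

Note the ΔH: the generating value is −50.17 kJ/mol, and this single 0.5 %-noise
dataset returns −67.5. That is not a bug — the double-log intercept
extrapolates about four decades beyond the data, and the van't Hoff slope
differences three such intercepts over 14 K, so chained single-study
enthalpies carry roughly ±50 % noise. The vignette quantifies this; treat
one-shot ΔH values from this route as order-of-magnitude statements.

Digestion bookkeeping and triplicate statistics:

```r
null_digestion_release(10)   # conserved tracer must come back at exactly 100%
#>    gastric intestinal
#>        100        100

d <- gen_release(seed = 4)                    # triplicate release-rate table
d$rate <- release_rate(d$a_free, d$a_total)
g <- d[d$phase == "gastric", ]
anova_cld(g$rate, g$treatment)
#> One-way ANOVA: F = 71.41, p = 4.072e-06 (alpha = 0.05, posthoc = tukey)
#> gates: Levene p = 0.122, K-S p = 0.586
#>       group  mean     sd n letters
#>         hph 70.25 0.4555 3       A
#>  nontreated 60.38 1.4345 3       B
#>     thermal 50.27 3.2342 3       C
#>  ultrasound 48.77 2.0091 3       C
```

## Package layout

| Area | Functions |
|---|---|
| Spectra → curves | `emission_spectrum`, `subtract_blank`, `titration_curve`, `extract_titration` |
| Quenching fits | `fit_stern_volmer`, `classify_mechanism`, `fit_double_log`, `quench_analysis` |
| Thermodynamics | `gibbs`, `vant_hoff`, `entropy`, `classify_forces`, `thermo_analysis` |
| Wet chemistry | `binding_rate`, `sulfhydryl_content`, `release_rate`, `aggregate_replicates` |
| Digestion | `component_final_conc`, `fluid_recipe`, `validate_recipe`, `plan_oral`, `plan_gastric`, `plan_intestinal`, `digestion_plan`, `null_digestion_release` |
| FTIR | `ir_spectrum`, `amide_peaks`, `amide_assignment_windows`, `deconvolve_amide_I` |
| Statistics | `levene_test`, `ks_normality`, `ks_null_d`, `anova_cld`, `cld_letters`, `type1_calibration` |
| Synthetic data | `quench_scenario`, `gen_titration`, `gen_spectra`, `gen_ftir`, `gen_release`, `gen_binding`, `release_scenario_means` |
| File I/O | `read_/write_spectrum_csv`, `read_/write_titration_csv`, `read_/write_ir_csv` |

The methods vignette (`vignettes/protein-ligand-binding.Rmd`) documents the
models, the default parameters and their rationale, and the known
identifiability limits of the chained enthalpy estimate and of coil-heavy
amide I mixtures.
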