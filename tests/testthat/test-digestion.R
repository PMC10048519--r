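test_that("component_final_conc obeys c1 v1 = c2 v2", {
  conc <- component_final_conc(0.5, 15.1, 500)   # mmol/L
  expect_equal(conc / 1000 * 500, 0.5 * 15.1)    # moles balance (per mL basis)
  expect_equal(conc, 15.1)
  expect_equal(component_final_conc(6, 0.09, 500), 1.08)
  expect_equal(component_final_conc(1, 42.5, 500), 85)
  expect_error(component_final_conc(0.5, -1), "non-negative")
  expect_error(component_final_conc(0.5, 1, 0), "positive")
})

test_that("every built-in fluid recipe validates at declared precision", {
  n_cells <- 0
  for (fl in c("SSF", "SGF", "SIF")) {
    val <- validate_recipe(fluid_recipe(fl))
    expect_true(attr(val, "all_pass"), label = paste(fl, "all_pass"))
    n_cells <- n_cells + nrow(val)
  }
  # the source table declares 19 filled electrolyte cells across the 3 fluids
  expect_equal(n_cells, 19)
  # rounding to declared precision matters: HCl/SSF computes to 1.08, declared 1.1
  ssf <- validate_recipe(fluid_recipe("SSF"))
  hcl <- ssf[ssf$component == "HCl", ]
  expect_equal(hcl$computed_mmol_per_l, 1.08)
  expect_equal(hcl$declared_mmol_per_l, 1.1)
  expect_true(hcl$pass)
})

test_that("validate_recipe catches a corrupted declaration", {
  r <- fluid_recipe("SGF")
  r$components$declared_mmol_per_l[1] <- 7.2  # truth is 6.9
  val <- validate_recipe(r)
  expect_false(attr(val, "all_pass"))
  expect_false(val$pass[1])
  r2 <- fluid_recipe("SSF")
  r2$components$volume_ml[1] <- 600  # exceeds the 500 mL made-up volume
  expect_error(validate_recipe(r2), "exceed")
})

test_that("plan_oral reproduces the reference 10 mL mix and scales proportionally", {
  p <- plan_oral(10)
  expect_equal(p$resulting_volume_ml, 21)
  expect_equal(sort(p$additions$volume_ml), sort(c(1, 8, 0.05, 1.95)))
  expect_equal(p$final_concs$amylase$value, 1500 / 21)
  expect_equal(p$final_concs$cacl2$value, 0.3 * 0.05 / 21 * 1000)
  # scaling the sample leaves every final concentration unchanged
  p2 <- plan_oral(25)
  expect_equal(p2$resulting_volume_ml, 21 * 2.5)
  expect_equal(p2$final_concs$amylase$value, p$final_concs$amylase$value)
  expect_equal(p2$final_concs$cacl2$value, p$final_concs$cacl2$value)
  expect_error(plan_oral(0), "positive")
})

test_that("gastric and intestinal plans hit their target concentrations exactly", {
  oral <- plan_oral(10)
  g <- plan_gastric(oral)
  vp <- g$additions$volume_ml[g$additions$substance == "pepsin stock"]
  expect_equal(25000 * vp / g$resulting_volume_ml, 2000, tolerance = 1e-12)
  expect_equal(g$final_concs$pepsin$value, 2000)
  expect_equal(g$target_ph, 3)
  # 1:1 fluid mixing by default
  expect_equal(g$additions$volume_ml[g$additions$substance == "SGF electrolyte"],
               oral$resulting_volume_ml)
  i <- plan_intestinal(g)
  vb <- i$additions$volume_ml[i$additions$substance == "bile stock"]
  vpa <- i$additions$volume_ml[i$additions$substance == "pancreatin stock"]
  expect_equal(1 * vb / i$resulting_volume_ml, 0.16, tolerance = 1e-12)
  expect_equal(25000 * vpa / i$resulting_volume_ml, 2000, tolerance = 1e-12)
  # volume bookkeeping: output = input + all additions
  expect_equal(i$resulting_volume_ml,
               i$input_volume_ml + sum(i$additions$volume_ml))
  # unreachable targets fail loudly
  expect_error(plan_gastric(oral, pepsin_stock_u_per_ml = 1500), "cannot reach")
})

test_that("digestion_plan chains phases with consistent cumulative dilution", {
  dp <- digestion_plan(10)
  expect_equal(unname(dp$dilution["oral"]), 2.1)
  expect_equal(dp$gastric$input_volume_ml, dp$oral$resulting_volume_ml)
  expect_equal(dp$intestinal$input_volume_ml, dp$gastric$resulting_volume_ml)
  expect_equal(unname(dp$dilution["intestinal"]),
               dp$intestinal$resulting_volume_ml / 10)
  expect_true(all(diff(dp$dilution) > 0))
  # assumption about the unstated mixing ratio is flagged on the plan
  expect_true(any(grepl("assumed", dp$gastric$notes)))
})

test_that("a conserved tracer is released at exactly 100%", {
  rel <- null_digestion_release(10)
  expect_equal(unname(rel["gastric"]), 100, tolerance = 1e-12)
  expect_equal(unname(rel["intestinal"]), 100, tolerance = 1e-12)
  # invariant to sample volume and mixing ratios
  rel2 <- null_digestion_release(3.7, gastric_ratio = 2, intestinal_ratio = 0.5)
  expect_equal(unname(rel2), c(100, 100), tolerance = 1e-12)
})
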