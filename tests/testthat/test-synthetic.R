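test_that("quench_scenario validates and sorts concentrations", {
  sc <- quench_scenario(q = c(2e-5, 0, 1e-5))
  expect_equal(sc$q, c(0, 1e-5, 2e-5))
  expect_error(quench_scenario(q = c(1e-5, 2e-5)), "zero-quencher")
  expect_error(quench_scenario(ka_ref = -1), "ka_ref")
})

test_that("generated constants follow the exact van't Hoff relation", {
  sc <- quench_scenario(dh = -50.17)
  kas <- vapply(sc$temperatures, function(t)
    attr(gen_titration(sc, t), "truth")$ka, numeric(1))
  vh <- vant_hoff(sc$temperatures, kas)
  expect_equal(vh$dh, -50.17, tolerance = 1e-9)
  expect_equal(vh$r2, 1, tolerance = 1e-12)
  # a negative dh makes both constants fall with temperature
  ksvs <- vapply(sc$temperatures, function(t)
    attr(gen_titration(sc, t), "truth")$ksv, numeric(1))
  expect_true(all(diff(kas) < 0))
  expect_true(all(diff(ksvs) < 0))
})

test_that("noiseless curves equal the generating model exactly", {
  sc <- quench_scenario()
  cv <- gen_titration(sc, 297)
  tr <- attr(cv, "truth")
  expect_equal(cv$f, sc$f0 / (1 + tr$ka * sc$q^sc$n_sites), tolerance = 1e-14)
  cvs <- gen_titration(sc, 297, model = "stern_volmer")
  expect_equal(cvs$f, sc$f0 / (1 + attr(cvs, "truth")$ksv * sc$q),
               tolerance = 1e-14)
})

test_that("generation is reproducible by seed and leaves the RNG stream alone", {
  sc <- quench_scenario(noise_sigma = 0.01, seed = 42)
  a <- gen_titration(sc, 297)
  b <- gen_titration(sc, 297)
  expect_identical(a$f, b$f)
  c <- gen_titration(sc, 304)
  expect_false(identical(a$f, c$f))  # each temperature draws its own noise
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(gen_titration(sc, 297)); after <- runif(1)
  expect_identical(before, after)
})

test_that("gen_spectra peaks reproduce the titration curve and its blue shift", {
  sc <- quench_scenario(seed = 3)
  spectra <- gen_spectra(sc, 297, shift_at_max_q = -5)
  ext <- extract_titration(spectra)
  tr <- attr(spectra, "truth")
  expect_equal(ext$peaks$f, tr$f, tolerance = 1e-6)
  expect_identical(ext$peaks$shift[which.max(ext$peaks$q)], "blue")
  expect_equal(ext$peaks$lambda_max[ext$peaks$q == 0], 340)
})

test_that("gen_ftir truth percentages are exact and the spectrum integrates to them", {
  s <- gen_ftir()
  tr <- attr(s, "truth")
  expect_equal(sum(tr$pct), 100, tolerance = 1e-12)
  expect_equal(unname(tr$areas / sum(tr$areas) * 100), unname(tr$pct),
               tolerance = 1e-12)
  # numeric integral over a wide grid matches the total area
  s2 <- gen_ftir(wavenumbers = seq(1500, 1800, by = 0.5), total_area = 10)
  integral <- sum(diff(s2$wavenumber) *
                  (head(s2$absorbance, -1) + tail(s2$absorbance, -1)) / 2)
  expect_equal(integral, 10, tolerance = 1e-3)
  expect_error(gen_ftir(truth_pct = c(50, 30, 30, 10)), "sum to 100")
})

test_that("gen_release reproduces its scenario ordering", {
  d <- gen_release(sd = 1, seed = 8)
  expect_equal(nrow(d), 8 * 3)
  expect_true(all(d$a_free >= 0 & d$a_free <= d$a_total))
  rates <- release_rate(d$a_free, d$a_total)
  agg <- aggregate_replicates(transform(d, rate = rates), "rate",
                              c("treatment", "phase"))
  m <- attr(d, "truth")$means
  for (i in seq_len(nrow(m))) {
    est <- agg$mean[agg$treatment == m$treatment[i] & agg$phase == m$phase[i]]
    expect_lt(abs(est - m$mean_release[i]), 3.5)
  }
  # gastric release exceeds intestinal for every treatment (scenario property)
  wide <- reshape(agg[c("treatment", "phase", "mean")], idvar = "treatment",
                  timevar = "phase", direction = "wide")
  expect_true(all(wide$mean.gastric > wide$mean.intestinal))
  expect_identical(gen_release(sd = 1, seed = 8)$a_free, d$a_free)
})

test_that("gen_binding saturates over protein and peaks over ligand", {
  d <- gen_binding(sd = 0, seed = 1)
  tr <- attr(d, "truth")
  # increasing protein at fixed ligand raises the generating rate
  for (aa in unique(tr$aa_mmol_per_l)) {
    sub <- tr[tr$aa_mmol_per_l == aa, ]
    expect_true(all(diff(sub$rate[order(sub$spi_pct)]) > 0))
  }
  # the generating rate is maximal at the stated peak ligand level
  for (spi in unique(tr$spi_pct)) {
    sub <- tr[tr$spi_pct == spi, ]
    expect_equal(sub$aa_mmol_per_l[which.max(sub$rate)], 2.5)
  }
  # with sd = 0 measured rates equal generating rates
  rates <- binding_rate(d$a_total, d$a_free)
  expect_equal(rates, tr$rate[rep(seq_len(nrow(tr)), each = 3)],
               tolerance = 1e-12)
})
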