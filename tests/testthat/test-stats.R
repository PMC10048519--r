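# Hand-rolled Levene statistic: one-way ANOVA F on |x - group center|.
.levene_oracle <- function(values, groups, center = mean) {
  g <- factor(groups)
  z <- abs(values - ave(values, g, FUN = center))
  anova(lm(z ~ g))[1, c("F value", "Pr(>F)")]
}

test_that("levene_test matches the hand formula", {
  set.seed(11)
  x <- c(rnorm(5, sd = 1), rnorm(5, sd = 1), rnorm(5, sd = 4))
  g <- rep(c("a", "b", "c"), each = 5)
  lt <- levene_test(x, g)
  orc <- .levene_oracle(x, g)
  expect_equal(lt$statistic, orc[[1]])
  expect_equal(lt$p_value, orc[[2]])
  expect_equal(lt$df, c(2, 12))
  # the Brown-Forsythe variant via center = median
  lt2 <- levene_test(x, g, center = median)
  orc2 <- .levene_oracle(x, g, center = median)
  expect_equal(lt2$statistic, orc2[[1]])
  # degenerate constant data -> statistic 0, p 1
  ident <- levene_test(rep(7, 8), rep(c("a", "b"), each = 4))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)
  expect_error(levene_test(1:4, c("a", "a", "a", "b")), "at least 2 values")
})

test_that("the K-S statistic matches a direct ECDF supremum", {
  set.seed(7)
  x <- rnorm(12)
  ks <- ks_normality(x, mc_reps = 200)
  # oracle: evaluate |ECDF - fitted normal CDF| on a fine grid around the jumps
  z <- (x - mean(x)) / sd(x)
  grid <- sort(c(z, z - 1e-9))
  d_oracle <- max(abs(ecdf(z)(grid) - pnorm(grid)))
  expect_equal(ks$statistic, d_oracle, tolerance = 1e-7)
  expect_true(ks$p_value > 0 && ks$p_value <= 1)
  expect_error(ks_normality(c(1, 2)), "at least 3")
  expect_error(ks_normality(rep(1, 5)), "constant")
})

test_that("the Monte-Carlo K-S p-value is calibrated for normal samples", {
  set.seed(21)
  nulltab <- ks_null_d(12, reps = 1000)
  pvals <- vapply(1:400, function(i) {
    ks_normality(rnorm(12), null_d = nulltab)$p_value
  }, numeric(1))
  # under the null the rejection rate at alpha = 0.1 should be near 0.1
  expect_lt(abs(mean(pvals <= 0.1) - 0.1), 0.06)
})

test_that("cld_letters satisfies the share-iff-nonsignificant property", {
  set.seed(33)
  for (rep in 1:40) {
    k <- sample(3:6, 1)
    p <- matrix(1, k, k)
    vals <- runif(k * (k - 1) / 2)  # mix of significant and not
    p[lower.tri(p)] <- vals
    p <- pmin(p, t(p))
    means <- setNames(sort(runif(k, 0, 10), decreasing = TRUE), paste0("g", 1:k))
    dimnames(p) <- list(names(means), names(means))
    lets <- cld_letters(means, p, alpha = 0.5)
    share <- function(i, j) {
      any(strsplit(lets[i], "")[[1]] %in% strsplit(lets[j], "")[[1]])
    }
    for (i in 1:(k - 1)) for (j in (i + 1):k)
      expect_identical(share(i, j), p[i, j] >= 0.5,
                       label = sprintf("rep %d pair %d-%d", rep, i, j))
    # every group carries at least one letter
    expect_true(all(nchar(lets) >= 1))
    # the largest mean carries "A"
    expect_true(grepl("A", lets[which.max(means)]))
  }
})

test_that("anova_cld reproduces a known grouping with Tukey letters", {
  set.seed(5)
  g <- rep(c("w", "x", "y", "z"), each = 5)
  x <- rnorm(20, mean = rep(c(30, 20, 10, 10.3), each = 5), sd = 0.8)
  res <- anova_cld(x, g)
  expect_lt(res$p, 0.05)
  tab <- res$letters
  expect_equal(tab$group, c("w", "x", "z", "y"))  # decreasing mean
  expect_equal(tab$letters, c("A", "B", "C", "C"))
  expect_true(isSymmetric(res$pairwise_p))
  # group labels with hyphens must not break contrast parsing
  g2 <- rep(c("heat-60", "heat-90", "ctrl-a", "ctrl-b"), each = 5)
  res2 <- anova_cld(x, g2)
  expect_equal(sort(res2$letters$group), sort(unique(g2)))
  expect_equal(res2$letters$letters, c("A", "B", "C", "C"))
})

test_that("anova_cld LSD post hoc matches pairwise.t.test", {
  set.seed(9)
  g <- rep(c("a", "b", "c"), each = 4)
  x <- rnorm(12, rep(c(0, 1, 3), each = 4))
  res <- anova_cld(x, g, posthoc = "lsd")
  pt <- pairwise.t.test(x, g, p.adjust.method = "none", pool.sd = TRUE)$p.value
  expect_equal(res$pairwise_p["b", "a"], pt["b", "a"])
  expect_equal(res$pairwise_p["c", "b"], pt["c", "b"])
})

test_that("the gates refuse pathological data unless overridden", {
  # grossly heteroscedastic: Levene gate must trip
  set.seed(13)
  x <- c(rnorm(6, sd = 0.01), rnorm(6, sd = 50), rnorm(6, sd = 0.01))
  g <- rep(c("a", "b", "c"), each = 6)
  expect_error(anova_cld(x, g), "homogeneity")
  res <- anova_cld(x, g, override = TRUE)
  expect_true(res$levene$p_value <= 0.05)
  expect_s3_class(res, "anova_cld")
  # gate = FALSE skips gating entirely
  res2 <- anova_cld(x, g, gate = FALSE)
  expect_null(res2$levene)
})

test_that("identical groups yield F = 0, p = 1 and a shared letter", {
  x <- rep(c(4, 5, 6), 4)
  g <- rep(c("a", "b", "c", "d"), each = 3)
  res <- anova_cld(x, g)
  expect_equal(res$f, 0)
  expect_equal(res$p, 1)
  expect_equal(res$letters$letters, rep("A", 4))
})

test_that("type1_calibration reports a plausible null rejection rate", {
  set.seed(101)
  cal <- type1_calibration(n_sims = 300, gate_reps = 400)
  expect_true(cal$n_passed > 200)
  expect_true(cal$rejection_rate >= 0 && cal$rejection_rate < 0.15)
})
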