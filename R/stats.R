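#' Levene's test for homogeneity of variance
#'
#' Levene's test with group deviations taken about the group mean
#' (`center = mean`), as classically defined; `center = median` gives the
#' Brown-Forsythe variant. Wraps [car::leveneTest()]. Constant data (zero
#' deviation in every group) returns statistic 0, p = 1 instead of NaN.
#'
#' @param values Numeric measurements.
#' @param groups Group labels, same length; at least 2 groups with at least 2
#'   values each.
#' @param center Centering function (default `mean`).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
levene_test <- function(values, groups, center = mean) {
  g <- .check_grouped(values, groups)
  lt <- car::leveneTest(values ~ g, center = center)
  stat <- lt[1, "F value"]; p <- lt[1, "Pr(>F)"]
  if (is.nan(stat)) { stat <- 0; p <- 1 }  # zero deviation everywhere
  list(statistic = stat, df = c(lt[1, "Df"], lt[2, "Df"]), p_value = p)
}

.check_grouped <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  if (any(!is.finite(values))) stop("values must be finite")
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("every group needs at least 2 values")
  g
}

# sup |ECDF - Phi((x - mean)/sd)| for a sample with estimated parameters
.ks_d <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  u <- stats::pnorm(z)
  max(max(seq_len(n) / n - u), max(u - (seq_len(n) - 1) / n))
}

#' Monte-Carlo null distribution of the normality K-S statistic
#'
#' Distribution of the Kolmogorov-Smirnov D statistic against a normal with
#' estimated mean and sd (Lilliefors situation), by simulation. When
#' `group_sizes` is given, each simulated sample is centered within groups of
#' those sizes first, matching the distribution of one-way residuals.
#'
#' @param n Sample size.
#' @param reps Number of simulated samples.
#' @param group_sizes Optional integer vector of group sizes summing to `n`.
#' @return Numeric vector of `reps` simulated D values.
#' @export
ks_null_d <- function(n, reps = 2000, group_sizes = NULL) {
  stopifnot(n >= 3, reps >= 100)
  if (!is.null(group_sizes)) {
    stopifnot(sum(group_sizes) == n)
    g <- rep(seq_along(group_sizes), group_sizes)
  }
  vapply(seq_len(reps), function(i) {
    x <- stats::rnorm(n)
    if (!is.null(group_sizes)) x <- x - stats::ave(x, g)
    .ks_d(x)
  }, numeric(1))
}

#' One-sample Kolmogorov-Smirnov normality check
#'
#' D = sup |ECDF(x) - Phi((x - mean)/sd)| with mean and sd estimated from the
#' sample. Because the parameters are estimated, the classical asymptotic
#' p-value is invalid (badly so at the n = 3..12 sizes of triplicate assays),
#' so the p-value is Monte-Carlo (Lilliefors-style): the rank of the observed
#' D within `mc_reps` simulated null statistics. Supply `null_d` (e.g. from
#' [ks_null_d()]) to reuse a precomputed null distribution; otherwise one is
#' drawn from the current RNG stream.
#'
#' @param values Numeric sample, n >= 3, non-constant.
#' @param mc_reps Monte-Carlo replicates when `null_d` is not supplied.
#' @param null_d Optional precomputed null D values for the same sample size.
#' @return List with `statistic`, `p_value`, `mc_reps`.
#' @export
ks_normality <- function(values, mc_reps = 2000, null_d = NULL) {
  if (length(values) < 3) stop("need at least 3 values")
  if (any(!is.finite(values))) stop("values must be finite")
  if (stats::sd(values) == 0) stop("degenerate constant sample")
  d <- .ks_d(values)
  if (is.null(null_d)) null_d <- ks_null_d(length(values), mc_reps)
  list(statistic = d,
       p_value = (1 + sum(null_d >= d)) / (length(null_d) + 1),
       mc_reps = length(null_d))
}

#' Gated one-way ANOVA with compact letter display
#'
#' The parametric analysis used for grouped triplicate assays: Levene's test
#' (variance homogeneity) and a Monte-Carlo K-S normality check on the
#' group-centered residuals gate the analysis; if either gate fails at
#' `alpha` the function refuses (naming the failed gate) unless
#' `override = TRUE`. One-way ANOVA is followed by pairwise comparisons
#' (Tukey HSD by default, or unadjusted pairwise t / Fisher LSD) and letters
#' are assigned by the insert-and-absorb algorithm from the largest mean
#' downward: groups share a letter exactly when their pairwise comparison is
#' non-significant at `alpha`.
#'
#' @param values Numeric measurements.
#' @param groups Group labels.
#' @param alpha Significance level for gates, ANOVA and letters.
#' @param gate Run the Levene/K-S gates.
#' @param override Proceed despite a failed gate (gates still reported).
#' @param posthoc `"tukey"` or `"lsd"`.
#' @param gate_reps Monte-Carlo replicates for the K-S gate.
#' @param null_d Optional precomputed null D values (see [ks_null_d()], with
#'   `group_sizes` matching the design) to make the K-S gate reproducible and
#'   cheap across many calls.
#' @return List of class `anova_cld`: `f`, `p`, `levene`, `ks`, `letters`
#'   (data frame: group, mean, sd, n, letters, ordered by decreasing mean),
#'   `pairwise_p` (matrix), `alpha`, `posthoc`.
#' @export
anova_cld <- function(values, groups, alpha = 0.05, gate = TRUE,
                      override = FALSE, posthoc = c("tukey", "lsd"),
                      gate_reps = 2000, null_d = NULL) {
  posthoc <- match.arg(posthoc)
  g <- .check_grouped(values, groups)
  lev <- ks <- NULL
  if (gate) {
    lev <- levene_test(values, g)
    res <- values - stats::ave(values, g)
    if (stats::sd(res) == 0) {
      ks <- list(statistic = 0, p_value = 1, mc_reps = 0)  # identical groups
    } else {
      if (is.null(null_d))
        null_d <- ks_null_d(length(values), gate_reps,
                            group_sizes = as.integer(table(g)))
      ks <- ks_normality(res, null_d = null_d)
    }
    if (lev$p_value <= alpha && !override)
      stop(sprintf("variance homogeneity gate failed (Levene p = %.4g)", lev$p_value))
    if (ks$p_value <= alpha && !override)
      stop(sprintf("normality gate failed (K-S p = %.4g)", ks$p_value))
  }
  lv <- levels(g)
  k <- length(lv)
  # fit on hyphen-free internal labels so Tukey contrast names parse safely
  gs <- factor(as.integer(g), levels = seq_len(k))
  fit <- stats::aov(values ~ gs, data = data.frame(values = values, gs = gs))
  at <- stats::anova(fit)
  fstat <- at[1, "F value"]; pval <- at[1, "Pr(>F)"]
  if (is.nan(fstat)) { fstat <- 0; pval <- 1 }

  pmat <- matrix(1, k, k, dimnames = list(lv, lv))
  if (posthoc == "tukey") {
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$gs
    for (r in rownames(tk)) {
      ij <- as.integer(strsplit(r, "-", fixed = TRUE)[[1]])
      pmat[ij[1], ij[2]] <- pmat[ij[2], ij[1]] <- tk[r, "p adj"]
    }
  } else {
    pt <- stats::pairwise.t.test(values, gs, p.adjust.method = "none",
                                 pool.sd = TRUE)$p.value
    for (i in rownames(pt)) for (j in colnames(pt))
      if (!is.na(pt[i, j])) {
        ii <- as.integer(i); jj <- as.integer(j)
        pmat[ii, jj] <- pmat[jj, ii] <- pt[i, j]
      }
  }
  pmat[is.nan(pmat)] <- 1  # identical groups: no evidence of difference

  means <- tapply(values, g, mean)
  sds <- tapply(values, g, stats::sd)
  ns <- as.integer(table(g))
  letters <- cld_letters(means, pmat, alpha)
  ordm <- order(-means)
  tab <- data.frame(group = lv, mean = as.numeric(means), sd = as.numeric(sds),
                    n = ns, letters = letters)[ordm, ]
  rownames(tab) <- NULL
  structure(list(f = fstat, p = pval, levene = lev, ks = ks, letters = tab,
                 pairwise_p = pmat, alpha = alpha, posthoc = posthoc),
            class = "anova_cld")
}

#' @export
print.anova_cld <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.4g, p = %.4g (alpha = %g, posthoc = %s)\n",
              x$f, x$p, x$alpha, x$posthoc))
  if (!is.null(x$levene))
    cat(sprintf("gates: Levene p = %.3g, K-S p = %.3g\n",
                x$levene$p_value, x$ks$p_value))
  print(x$letters, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Compact letter display by insert-and-absorb
#'
#' Assigns letters so that two groups share a letter if and only if their
#' pairwise comparison is non-significant at `alpha`. Starting from one
#' letter covering all groups, each significant pair splits every letter
#' containing both; letters that are subsets of others are absorbed. Letters
#' are ordered by the largest group mean they contain (ties broken by group
#' order), so the group with the highest mean carries "A".
#'
#' @param means Named numeric vector of group means.
#' @param p_matrix Symmetric matrix of pairwise p-values with matching
#'   dimnames.
#' @param alpha Significance level.
#' @return Character vector of letter sets, one per group, in `means` order.
#' @export
cld_letters <- function(means, p_matrix, alpha = 0.05) {
  k <- length(means)
  stopifnot(nrow(p_matrix) == k, ncol(p_matrix) == k)
  cols <- list(seq_len(k))
  absorb <- function(cols) {
    drop <- rep(FALSE, length(cols))
    for (i in seq_along(cols)) for (j in seq_along(cols))
      if (i != j && !drop[j] && all(cols[[i]] %in% cols[[j]])) drop[i] <- TRUE
    unique(cols[!drop])
  }
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    if (p_matrix[i, j] < alpha) {
      newcols <- list()
      for (col in cols) {
        if (all(c(i, j) %in% col)) {
          newcols <- c(newcols, list(setdiff(col, i)), list(setdiff(col, j)))
        } else newcols <- c(newcols, list(col))
      }
      cols <- absorb(newcols)
    }
  }
  # order letters by the largest mean they contain, ties by group order
  keym <- vapply(cols, function(col) max(means[col]), numeric(1))
  keyi <- vapply(cols, function(col) min(col[means[col] == max(means[col])]), numeric(1))
  cols <- cols[order(-keym, keyi)]
  vapply(seq_len(k), function(gi) {
    paste(LETTERS[which(vapply(cols, function(col) gi %in% col, logical(1)))],
          collapse = "")
  }, character(1))
}

#' Empirical type-I error of the gated pipeline under the null
#'
#' Simulates `n_sims` null datasets (all group means equal, unit-variance
#' normal noise), runs the Levene / K-S gates and, when both pass, the
#' one-way ANOVA, and reports the rejection rate among gate-passing
#' simulations. A well-calibrated pipeline rejects at about `alpha`.
#'
#' @param n_sims Number of simulated datasets.
#' @param n_groups,n_per_group Design.
#' @param alpha Significance level.
#' @param gate_reps Monte-Carlo replicates for the shared K-S null table.
#' @return List with `rejection_rate`, `n_passed`, `n_sims`, `alpha`,
#'   `ci95` (binomial 95% CI half-width for a rate of `alpha` at `n_passed`).
#' @export
type1_calibration <- function(n_sims = 5000, n_groups = 4, n_per_group = 3,
                              alpha = 0.05, gate_reps = 2000) {
  n <- n_groups * n_per_group
  g <- factor(rep(seq_len(n_groups), each = n_per_group))
  gi <- as.integer(g)
  nulltab <- ks_null_d(n, gate_reps, group_sizes = rep(n_per_group, n_groups))
  rejected <- passed <- 0L
  for (s in seq_len(n_sims)) {
    x <- stats::rnorm(n)
    lev <- levene_test(x, g)
    if (lev$p_value <= alpha) next
    res <- x - stats::ave(x, gi)
    ksp <- (1 + sum(nulltab >= .ks_d(res))) / (length(nulltab) + 1)
    if (ksp <= alpha) next
    passed <- passed + 1L
    p <- stats::anova(stats::lm(x ~ g))[1, "Pr(>F)"]
    if (p < alpha) rejected <- rejected + 1L
  }
  list(rejection_rate = rejected / passed, n_passed = passed, n_sims = n_sims,
       alpha = alpha, ci95 = 1.96 * sqrt(alpha * (1 - alpha) / passed))
}
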