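# LD score regression: heritability and intercept recovery, confounding
# ratio, difference tests and cross-trait genetic correlation.

test_that("null summary statistics give zero heritability and unit intercept", {
  s <- simulate_ldsc_summary(M = 20000, N = 10000, h2 = 0, a = 0, seed = 61)
  fit <- ldsc_fit(s$CHISQ, s$L2, 10000, M = 20000, chr = s$CHR, bp = s$BP)
  expect_lt(abs(fit$h2 / fit$h2_se), 2.5)
  expect_lt(abs(fit$intercept - 1), 3 * fit$intercept_se)
})

test_that("heritability and confounded intercept recover their truths", {
  s <- simulate_ldsc_summary(M = 30000, N = 20000, h2 = 0.4, a = 0, seed = 62)
  fit <- ldsc_fit(s$CHISQ, s$L2, 20000, M = 30000, chr = s$CHR, bp = s$BP)
  expect_lt(abs(fit$h2 - 0.4), 2.5 * fit$h2_se)
  # confounding: intercept ~ 1 + N a = 2
  c2 <- simulate_ldsc_summary(M = 30000, N = 10000, h2 = 0.2, a = 1e-4, seed = 63)
  fitc <- ldsc_fit(c2$CHISQ, c2$L2, 10000, M = 30000, chr = c2$CHR, bp = c2$BP)
  expect_lt(abs(fitc$intercept - 2), 3 * fitc$intercept_se)
})

test_that("confounding ratio matches its closed form and edge cases", {
  fit <- list(intercept = 1, mean_chi2 = 1.5)
  expect_equal(as.numeric(ldsc_ratio(fit)), 0)
  pure <- list(intercept = 1.5, mean_chi2 = 1.5)
  expect_equal(as.numeric(ldsc_ratio(pure)), 1)
  under <- list(intercept = 1.2, mean_chi2 = 0.99)
  expect_true(is.na(ldsc_ratio(under)))
  expect_equal(attr(ldsc_ratio(under), "flag"), "undefined")
  # mixed generative case: ratio ~ Na / (mean chi2 - 1)
  s <- simulate_ldsc_summary(M = 40000, N = 10000, h2 = 0.2, a = 1e-4, seed = 64)
  f <- ldsc_fit(s$CHISQ, s$L2, 10000, M = 40000, chr = s$CHR, bp = s$BP)
  expected <- 10000 * 1e-4 / (mean(s$CHISQ) - 1)
  expect_lt(abs(as.numeric(f$ratio) - expected), 0.12)
})

test_that("scaling chi-squares by (1-k)^2 scales the fitted h2 exactly", {
  s <- simulate_ldsc_summary(M = 10000, N = 10000, h2 = 0.3, a = 0, seed = 65)
  f1 <- ldsc_fit(s$CHISQ, s$L2, 10000, M = 10000, chr = s$CHR, bp = s$BP)
  k <- 0.47
  f2 <- ldsc_fit((1 - k)^2 * s$CHISQ, s$L2, 10000, M = 10000,
                 chr = s$CHR, bp = s$BP)
  expect_equal(f2$slope, (1 - k)^2 * f1$slope, tolerance = 1e-8)
  expect_equal(f2$h2, (1 - k)^2 * f1$h2, tolerance = 1e-8)
})

test_that("expected within-sibship h2 under uniform shrinkage is (1-k)^2 y", {
  expect_equal(effective_n_adjustment_check(0.3, k = 0), 0.3)
  expect_equal(effective_n_adjustment_check(0.3, k = 1), 0)
  expect_equal(effective_n_adjustment_check(0.13, k = 0.47), 0.0365,
               tolerance = 1e-3)
  expect_error(effective_n_adjustment_check(0.3, k = 1.2), "k")
})

test_that("h2 difference test reproduces a hand calculation", {
  pop <- structure(list(h2 = 0.3, h2_se = 0.05), class = "ldsc_fit")
  ws <- structure(list(h2 = 0.1, h2_se = 0.05), class = "ldsc_fit")
  out <- h2_difference_test(pop, ws, cross_intercept = 0.4)
  expect_equal(out$se, sqrt(0.0025 + 0.0025 - 2 * 0.4 * 0.0025),
               tolerance = 1e-12)
  expect_equal(out$z, 0.2 / out$se, tolerance = 1e-12)
  expect_lt(abs(out$z - 3.65), 0.01)
  # identical fits: zero difference, p = 1
  same <- h2_difference_test(pop, pop, cross_intercept = 0.4)
  expect_equal(same$diff, 0)
  expect_equal(same$p, 1)
  expect_error(h2_difference_test(pop, ws, cross_intercept = 1), "< 1")
})

test_that("h2 difference test is null-calibrated for overlapping samples", {
  # null regime: one trait, two designs on overlapping samples, so the true
  # per-variant effects are shared and only the noise (with correlation
  # equal to the cross-GWAS intercept) is resampled
  set.seed(66)
  reps <- 300L
  pvals <- vapply(seq_len(reps), function(r) {
    pair <- simulate_ldsc_pair(3000, 10000, 10000, 0.3, 0.3, rg = 1,
                               cross_intercept = 0.4, seed = 6000 + r,
                               shared_effects = TRUE)
    f1 <- ldsc_fit(pair$Z1^2, pair$L2, 10000, M = 3000, n_blocks = 50,
                   chr = pair$CHR, bp = pair$BP)
    f2 <- ldsc_fit(pair$Z2^2, pair$L2, 10000, M = 3000, n_blocks = 50,
                   chr = pair$CHR, bp = pair$BP)
    rgf <- cross_trait_rg(pair$Z1, pair$Z2, pair$L2, 10000, 10000,
                          M = 3000, n_blocks = 50)
    h2_difference_test(f1, f2, min(max(rgf$cross_intercept, -0.99), 0.99))$p
  }, numeric(1))
  expect_gt(mean(pvals < 0.05), 0.02)
  expect_lt(mean(pvals < 0.05), 0.10)
})

test_that("a trait's genetic correlation with itself is exactly 1", {
  s <- simulate_ldsc_summary(M = 5000, N = 10000, h2 = 0.3, a = 0, seed = 67)
  rg <- cross_trait_rg(s$Z, s$Z, s$L2, 10000, 10000, M = 5000,
                       chr = s$CHR, bp = s$BP)
  expect_equal(rg$rg, 1, tolerance = 1e-10)
  expect_lt(rg$se, 0.01)
})

test_that("cross-trait rg recovers planted correlations and the null", {
  pair <- simulate_ldsc_pair(20000, 20000, 20000, 0.3, 0.25, rg = 0.5, seed = 68)
  rg <- cross_trait_rg(pair$Z1, pair$Z2, pair$L2, 20000, 20000, M = 20000,
                       chr = pair$CHR, bp = pair$BP)
  expect_lt(abs(rg$rg - 0.5), 2.5 * rg$se)
  null <- simulate_ldsc_pair(20000, 20000, 20000, 0.3, 0.25, rg = 0, seed = 69)
  rg0 <- cross_trait_rg(null$Z1, null$Z2, null$L2, 20000, 20000, M = 20000,
                        chr = null$CHR, bp = null$BP)
  expect_lt(abs(rg0$rg), 3 * rg0$se)
  # symmetry in trait order
  rg_ba <- cross_trait_rg(pair$Z2, pair$Z1, pair$L2, 20000, 20000, M = 20000,
                          chr = pair$CHR, bp = pair$BP)
  expect_equal(rg$rg, rg_ba$rg, tolerance = 1e-10)
})

test_that("block jackknife converges to leave-one-out on small instances", {
  pair <- simulate_ldsc_pair(250, 10000, 10000, 0.3, 0.3, rg = 0.5, seed = 70)
  rg_blocks <- cross_trait_rg(pair$Z1, pair$Z2, pair$L2, 10000, 10000,
                              M = 250, n_blocks = 250,
                              chr = pair$CHR, bp = pair$BP)
  # manual delete-one jackknife of the same rg computation
  ord <- order(pair$CHR, pair$BP)
  z1 <- pair$Z1[ord]; z2 <- pair$Z2[ord]; l2 <- pair$L2[ord]
  rg_of <- function(idx) {
    x <- pmax(l2[idx], 1); w <- 1 / x
    sl <- function(y) {
      sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
      (sw * sum(w * x * y) - swx * swy) / (sw * sum(w * x^2) - swx^2)
    }
    sl(z1[idx] * z2[idx]) / sqrt(sl(z1[idx]^2) * sl(z2[idx]^2))
  }
  loo <- vapply(seq_len(250), function(i) rg_of(setdiff(1:250, i)), numeric(1))
  expect_equal(rg_blocks$se, jackknife_se(loo), tolerance = 1e-10)
})

test_that("rg difference test is exact on identical inputs and detects change", {
  pair <- simulate_ldsc_pair(4000, 20000, 20000, 0.3, 0.25, rg = -0.3, seed = 71)
  same <- rg_difference_jackknife(pair$Z1, pair$Z2, 20000, 20000,
                                  pair$Z1, pair$Z2, 20000, 20000,
                                  ldscore = pair$L2, M = 4000,
                                  chr = pair$CHR, bp = pair$BP)
  expect_equal(same$diff, 0)
  # identical inputs leave every leave-block difference at exactly 0, so the
  # jackknife spread is 0 and the test reports no evidence of a difference
  expect_equal(same$se, 0)
  expect_equal(same$p, 1)
  # planted attenuation: population rg inflated, within-sibship near zero
  ws <- simulate_ldsc_pair(4000, 20000, 20000, 0.3, 0.25, rg = -0.05,
                           seed = 72, ldscore = pair$L2)
  diff <- rg_difference_jackknife(pair$Z1, pair$Z2, 20000, 20000,
                                  ws$Z1, ws$Z2, 20000, 20000,
                                  ldscore = pair$L2, M = 4000,
                                  chr = pair$CHR, bp = pair$BP)
  expect_lt(diff$p, 0.05)
  expect_lt(diff$diff, 0)  # pop more negative than ws
  expect_error(rg_difference_jackknife(1:10, 1:10, 1, 1, 1:10, 1:10, 1, 1,
                                       ldscore = 1:10), ">= 200")
})
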