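# Instrument selection, weighted scores, shrinkage, jackknife SEs and
# heterogeneity statistics.

test_that("clumping keeps the best of a correlated pair and all independents", {
  tab <- data.table::data.table(
    SNP = c("s1", "s2"), CHR = 1L, BP = c(1e6, 2e6),
    BETA = c(0.2, 0.19), SE = 0.01, P = c(1e-10, 1e-9))
  ld <- matrix(c(1, 0.99, 0.99, 1), 2, 2, dimnames = list(tab$SNP, tab$SNP))
  out <- select_instruments(tab, 5e-8, ld = ld)
  expect_equal(out$SNP, "s1")
  # independent variants below threshold: all retained
  out2 <- select_instruments(tab, 5e-8)
  expect_setequal(out2$SNP, c("s1", "s2"))
  # nothing passes: empty set with a warning
  expect_warning(none <- select_instruments(tab, 1e-20), "empty")
  expect_equal(nrow(none), 0L)
})

test_that("clumping matches an exhaustive greedy oracle on a toy LD matrix", {
  set.seed(51)
  snp <- paste0("v", 1:6)
  tab <- data.table::data.table(SNP = snp, CHR = 1L, BP = (1:6) * 1e5,
                                BETA = rnorm(6), SE = 0.01,
                                P = c(1e-9, 1e-8, 1e-7, 1e-12, 1e-6, 1e-10))
  r2 <- matrix(0, 6, 6, dimnames = list(snp, snp))
  r2[1, 2] <- r2[2, 1] <- 0.5
  r2[4, 5] <- r2[5, 4] <- 0.9
  r2[3, 6] <- r2[6, 3] <- 0.2
  diag(r2) <- 1
  out <- select_instruments(tab, 1e-5, ld = r2)
  # brute-force greedy: ascending p, drop correlated survivors
  ordp <- order(tab$P)
  kept <- integer(0)
  for (i in ordp) {
    if (!length(kept) || all(r2[i, kept] < 0.001)) kept <- c(kept, i)
  }
  expect_setequal(out$SNP, snp[kept])
})

test_that("weighted score follows its algebra and the WLS-slope oracle", {
  # single variant: S = beta/w, sigma = se/|w|
  s1 <- weighted_score(0.4, 0.1, 2)
  expect_equal(s1$S, 0.2)
  expect_equal(s1$sigma_S, 0.05)
  # weights equal to betas: self-consistency S = 1
  set.seed(52)
  b <- rnorm(10, 0.2, 0.05)
  expect_equal(weighted_score(b, rep(0.03, 10), b)$S, 1, tolerance = 1e-12)
  # 20-variant random input vs an independent no-intercept WLS fit
  b2 <- rnorm(20, 0.1, 0.05); se2 <- runif(20, 0.01, 0.05); w2 <- rnorm(20, 0.1, 0.05)
  ws <- weighted_score(b2, se2, w2)
  fit <- lm(b2 ~ 0 + w2, weights = 1 / se2^2)
  expect_equal(ws$S, unname(coef(fit)), tolerance = 1e-10)
})

test_that("shrinkage point estimate and weight-rescaling invariance hold", {
  expect_equal(shrinkage_estimate(1, 1)$delta, 0)
  expect_equal(shrinkage_estimate(0.5, 1)$percent, 50)
  set.seed(53)
  b_w <- rnorm(15, 0.05, 0.01); b_p <- rnorm(15, 0.1, 0.01)
  se <- runif(15, 0.005, 0.02); w <- rnorm(15, 0.1, 0.03)
  d1 <- 1 - weighted_score(b_w, se, w)$S / weighted_score(b_p, se, w)$S
  d2 <- 1 - weighted_score(b_w, se, 7 * w)$S / weighted_score(b_p, se, 7 * w)$S
  expect_equal(d1, d2, tolerance = 1e-12)
  # unstable denominator is flagged
  weak <- weighted_score(rnorm(5, 0, 0.1), rep(1, 5), rnorm(5))
  strong <- weighted_score(rnorm(5, 1, 0.01), rep(0.01, 5), rep(1, 5))
  expect_warning(shrinkage_estimate(strong, weak), "unstable")
})

test_that("leave-one-out jackknife for shrinkage behaves at its limits", {
  # jackknife of identical contributions: zero SE
  M <- 8
  jk <- jackknife_se_shrinkage(rep(0.05, M), rep(0.01, M),
                               rep(0.10, M), rep(0.01, M), rep(0.1, M))
  expect_equal(jk$se, 0)
  expect_equal(jk$delta, 0.5)
  # supplying a positive covariance lowers the delta-method SE
  set.seed(54)
  b_w <- rnorm(20, 0.05, 0.01); b_p <- rnorm(20, 0.1, 0.01)
  se <- rep(0.01, 20); w <- rnorm(20, 0.1, 0.02)
  jk0 <- jackknife_se_shrinkage(b_w, se, b_p, se, w, cov_scores = 0)
  jk1 <- jackknife_se_shrinkage(b_w, se, b_p, se, w, cov_scores = 4e-6)
  expect_lt(jk1$se_delta_method, jk0$se_delta_method)
  expect_error(jackknife_se_shrinkage(0.1, 0.01, 0.2, 0.01, 1), "at least 2")
})

test_that("jackknife SE for shrinkage tracks the Monte-Carlo spread", {
  reps <- 300L
  M <- 40L
  set.seed(55)
  w_true <- runif(M, 0.08, 0.15)
  deltas <- jks <- numeric(reps)
  for (r in seq_len(reps)) {
    se_p <- runif(M, 0.008, 0.012); se_w <- runif(M, 0.012, 0.018)
    b_p <- w_true + rnorm(M, 0, se_p)
    b_w <- 0.6 * w_true + rnorm(M, 0, se_w)
    jk <- jackknife_se_shrinkage(b_w, se_w, b_p, se_p, w_true)
    deltas[r] <- jk$delta; jks[r] <- jk$se
  }
  ratio <- mean(jks) / sd(deltas)
  expect_gt(ratio, 0.85)
  expect_lt(ratio, 1.15)
  # and the estimate itself recovers the planted 40% shrinkage
  expect_lt(abs(mean(deltas) - 0.4), 3 * sd(deltas) / sqrt(reps))
})

test_that("variant-level heterogeneity Q is calibrated and detects planting", {
  # null calibration over homogeneous-shrinkage replicates
  set.seed(56)
  reps <- 400L; M <- 30L; S_true <- 1.8
  pvals <- replicate(reps, {
    bw_true <- runif(M, 0.08, 0.15) * sample(c(-1, 1), M, TRUE)
    se_w <- runif(M, 0.008, 0.012); se_p <- runif(M, 0.006, 0.009)
    bw <- bw_true + rnorm(M, 0, se_w)
    bp <- S_true * bw_true + rnorm(M, 0, se_p)
    suppressMessages(heterogeneity_Q(bp, se_p, bw, se_w, bw_true))$p
  })
  expect_gt(mean(pvals < 0.05), 0.025)
  expect_lt(mean(pvals < 0.05), 0.075)
  # two variants with opposite planted shrinkage at tiny SEs: large Q
  het <- suppressMessages(heterogeneity_Q(
    beta_p = c(0.10, 0.12), se_p = c(0.002, 0.002),
    beta_w = c(0.10, 0.04), se_w = c(0.002, 0.002),
    weights = c(0.1, 0.12)))
  expect_gt(het$Q, 10)
  expect_lt(het$p, 0.01)
  # single usable variant: Q = 0, df = 0, missing p
  one <- suppressMessages(heterogeneity_Q(0.1, 0.01, 0.1, 0.01, 0.1))
  expect_equal(one$Q, 0)
  expect_equal(one$df, 0L)
  expect_true(is.na(one$p))
})

test_that("study-level heterogeneity matches Cochran's closed form", {
  same <- study_level_heterogeneity(c(0.3, 0.3, 0.3), c(0.05, 0.05, 0.05))
  expect_equal(same$Q, 0)
  expect_equal(same$p, 1)
  # two studies 0 and 0.5 with se 0.05: Q = sum w (d - pooled)^2 = 50
  two <- study_level_heterogeneity(c(0, 0.5), c(0.05, 0.05))
  expect_equal(two$Q, 50, tolerance = 1e-10)
  expect_lt(two$p, 1e-6)
  expect_error(study_level_heterogeneity(0.5, 0.05), ">= 2")
  # homogeneous studies: p uniform
  set.seed(57)
  ps <- replicate(300, {
    d <- 0.3 + rnorm(4, 0, 0.05)
    study_level_heterogeneity(d, rep(0.05, 4))$p
  })
  expect_gt(mean(ps < 0.05), 0.02)
  expect_lt(mean(ps < 0.05), 0.09)
})

test_that("shrinkage analysis aligns tables and reports a coherent row", {
  set.seed(58)
  M <- 25L
  w <- runif(M, 0.08, 0.15)
  snp <- sprintf("1:%d:SNP", seq_len(M) * 1000L)
  inst <- data.table::data.table(SNP = snp, CHR = 1L, BP = seq_len(M) * 1000L,
                                 P = 1e-8, WEIGHT = w)
  pop <- data.table::data.table(SNP = snp, BETA = w + rnorm(M, 0, 0.01),
                                SE = rep(0.01, M))
  ws <- data.table::data.table(SNP = sample(snp), BETA = NA_real_, SE = NA_real_)
  ws[match(snp, SNP), `:=`(BETA = 0.5 * w + rnorm(M, 0, 0.015),
                           SE = rep(0.015, M))]
  res <- suppressMessages(shrinkage_analysis(pop, ws, inst))
  expect_equal(res$M, M)
  expect_lt(abs(res$delta - 0.5), 4 * res$se)
  expect_equal(res$ci_low, res$delta - 1.96 * res$se, tolerance = 1e-12)
  expect_equal(res$percent, 100 * res$delta)
})
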