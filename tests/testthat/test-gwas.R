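# Population and within-sibship association models: centering algebra,
# missingness and QC rules, bias separation and clustered standard errors.

test_that("family-mean centering reproduces the worked sibling-pair example", {
  co <- manual_cohort(matrix(c(2L, 1L), ncol = 1), fid = c("F1", "F1"))
  cg <- center_genotypes(co)
  expect_equal(unname(cg$gf[, 1L]), c(1.5, 1.5))
  expect_equal(unname(cg$gc[, 1L]), c(0.5, -0.5))
  # identical genotypes: zero deviations
  co2 <- manual_cohort(matrix(c(1L, 1L), ncol = 1), fid = c("F1", "F1"))
  cg2 <- center_genotypes(co2)
  expect_equal(unname(cg2$gc[, 1L]), c(0, 0))
  # sibship of three
  co3 <- manual_cohort(matrix(c(0L, 1L, 2L), ncol = 1), fid = rep("F1", 3))
  cg3 <- center_genotypes(co3)
  expect_equal(unname(cg3$gf[, 1L]), rep(1, 3))
  expect_equal(unname(cg3$gc[, 1L]), c(-1, 0, 1))
  # singleton sibship is an error
  co4 <- manual_cohort(matrix(c(1L, 1L, 2L), ncol = 1),
                       fid = c("F1", "F1", "F2"))
  expect_error(center_genotypes(co4), "singleton")
})

test_that("centered genotypes sum to zero exactly within every sibship", {
  cfg <- sim_config(n_sibships = 300L, sibs_per_family = c("2" = .6, "3" = .3, "4" = .1),
                    n_variants = 40L, seed = 31)
  cohort <- simulate_cohort(cfg, phenotypes = list())
  cg <- center_genotypes(cohort)
  sums <- rowsum(cg$gc, cg$sibship)
  expect_equal(max(abs(sums)), 0)
  expect_true(all(cg$gf >= 0 & cg$gf <= 2))
})

test_that("missingness rule blanks sibships with a single observed phenotype", {
  g <- matrix(1L, 5, 1)
  fid <- c("F1", "F1", "F2", "F2", "F2")
  y <- c(1.0, NA, 2.0, NA, 3.0)
  co <- manual_cohort(g, fid, pheno = list(tr = y))
  co <- apply_missingness_rule(co, "tr")
  # pair with one missing: both go missing
  expect_true(all(is.na(co$pheno$tr[1:2])))
  # trio with one missing: the two observed values survive
  expect_equal(co$pheno$tr[3:5], c(2.0, NA, 3.0))
  # complete data: identity
  co2 <- manual_cohort(g, fid, pheno = list(tr = c(1, 2, 3, 4, 5)))
  expect_equal(apply_missingness_rule(co2, "tr")$pheno$tr, c(1, 2, 3, 4, 5))
  expect_error(apply_missingness_rule(co2, "nope"), "unknown phenotype")
})

test_that("QC removes rare and poorly imputed variants, keeps clean tables", {
  tab <- data.table::data.table(
    SNP = c("a", "b", "c", "d"),
    EAF = c(0.005, 0.3, 0.3, 0.3),
    INFO = c(1, 0.2, 1, 0.31),
    BETA = 0, SE = 1)
  suppressMessages(out <- qc_filter_variants(tab))
  expect_setequal(out$SNP, c("c", "d"))
  clean <- data.table::data.table(SNP = letters[1:3], EAF = 0.3, INFO = 1)
  expect_equal(nrow(qc_filter_variants(clean)), 3L)
})

test_that("population model recovers an exact noiseless linear signal", {
  set.seed(32)
  cfg <- sim_config(n_sibships = 200L, n_variants = 3L, seed = 33)
  cohort <- simulate_cohort(cfg, phenotypes = list())
  age_effect <- 0.01
  y <- 2 * cohort$genotypes[, 2L] + age_effect * cohort$covar$AGE
  cohort$pheno$exact <- y
  fit <- fit_population_model(cohort, "exact", covariates = c("AGE", "SEX"))
  expect_equal(fit$BETA[2L], 2, tolerance = 1e-8)
  expect_lt(fit$SE[2L], 1e-8)  # residual variance ~ 0 at the causal variant
  expect_lt(fit$P[2L], 1e-20)
})

test_that("parental indirect effects bias the population but not the within model", {
  # analytic oracle: with beta = 0 and eta_parental = eta, random mating,
  # cov(G_child, G_m + G_f) = var(G_child), so the population slope tends to
  # eta while the centered-genotype slope tends to 0
  cfg <- sim_config(n_sibships = 8000L, n_variants = 4L,
                    maf_range = c(0.25, 0.35), beta_direct = 0,
                    eta_parental = 0.1, seed = 34)
  cohort <- simulate_cohort(cfg)
  pop <- fit_population_model(cohort, "trait", covariates = c("AGE", "SEX"))
  ws <- fit_within_sibship_model(cohort, "trait", covariates = c("AGE", "SEX"))
  mc_se <- mean(pop$SE) / sqrt(length(pop$SE))
  expect_lt(abs(mean(pop$BETA) - 0.1), 3 * mc_se)
  expect_lt(abs(mean(ws$BETA)), 3 * mean(ws$SE) / sqrt(length(ws$BETA)))
  # the sibship-mean coefficient absorbs the parental path
  expect_gt(mean(ws$FBETA), 0.05)
})

test_that("within-sibship slope equals the sibling-difference regression", {
  cfg <- sim_config(n_sibships = 500L, sibs_per_family = 2L,
                    n_variants = 5L, beta_direct = 0.1, seed = 35)
  cohort <- simulate_cohort(cfg)
  ws <- fit_within_sibship_model(cohort, "trait", covariates = character(0))
  fam <- cohort$fam_idx
  first <- which(!duplicated(fam))
  for (v in 1:5) {
    dg <- cohort$genotypes[first, v] - cohort$genotypes[first + 1L, v]
    dy <- cohort$pheno$trait[first] - cohort$pheno$trait[first + 1L]
    slope <- sum(dg * dy) / sum(dg^2)
    expect_equal(ws$BETA[v], slope, tolerance = 1e-10)
  }
})

test_that("a pure family-level phenotype gives a zero centered-genotype slope", {
  cfg <- sim_config(n_sibships = 400L, n_variants = 2L, seed = 36)
  cohort <- simulate_cohort(cfg, phenotypes = list())
  cg <- center_genotypes(cohort)
  cohort$pheno$fameff <- 3 * cg$gf[, 1L]
  ws <- fit_within_sibship_model(cohort, "fameff", covariates = character(0))
  expect_lt(abs(ws$BETA[1L]), 1e-8)
  expect_equal(ws$FBETA[1L], 3, tolerance = 1e-8)
})

test_that("monomorphic and family-concordant variants are flagged, not dropped", {
  g <- cbind(rep(1L, 6), c(0L, 0L, 1L, 1L, 2L, 2L))
  fid <- rep(c("F1", "F2", "F3"), each = 2)
  co <- manual_cohort(g, fid, pheno = list(tr = rnorm(6)))
  pop <- fit_population_model(co, "tr", covariates = character(0))
  expect_equal(pop$FLAG, c("zero_variance", "ok"))
  expect_true(is.na(pop$BETA[1L]))
  ws <- fit_within_sibship_model(co, "tr", covariates = character(0))
  # both variants concordant within every sibship
  expect_equal(ws$FLAG, c("zero_within_variance", "zero_within_variance"))
  expect_equal(nrow(ws), 2L)
})

test_that("sibship-clustered standard errors track the sampling distribution", {
  # shared-environment correlation between siblings: naive SEs understate,
  # clustered SEs match the Monte-Carlo spread of the estimator
  reps <- 300L
  betas <- ses_cl <- ses_naive <- numeric(reps)
  for (r in seq_len(reps)) {
    cfg <- sim_config(n_sibships = 150L, n_variants = 1L,
                      maf_range = c(0.28, 0.32), shared_env_var = 0.5,
                      seed = 4000L + r)
    cohort <- simulate_cohort(cfg)
    fit <- fit_population_model(cohort, "trait", covariates = character(0))
    fitn <- fit_population_model(cohort, "trait", covariates = character(0),
                                 cluster_se = FALSE)
    betas[r] <- fit$BETA; ses_cl[r] <- fit$SE; ses_naive[r] <- fitn$SE
  }
  emp <- sd(betas)
  expect_gt(mean(ses_cl) / emp, 0.9)
  expect_lt(mean(ses_cl) / emp, 1.1)
  expect_lt(mean(ses_naive), mean(ses_cl))
})

test_that("cryptic relatedness inflates population precision but not within", {
  # sibships linked in cousin pairs share genotype (r = 1/8) and an
  # environment component; the population-model clustered SE (clusters =
  # sibships) misses the cross-sibship dependence, while the within-sibship
  # estimator is driven by independent segregation and stays calibrated.
  # One cohort with many independent null variants gives a tight estimate of
  # the SE/sampling-SD ratio (MC error ~ 1/sqrt(2 * n_variants) ~ 0.016).
  cfg <- sim_config(n_sibships = 3000L, n_variants = 2000L,
                    maf_range = c(0.2, 0.4), cryptic_relatedness_frac = 1,
                    cryptic_env_var = 0.55, shared_env_var = 0.2, seed = 99)
  cohort <- simulate_cohort(cfg)
  fitp <- fit_population_model(cohort, "trait", covariates = character(0))
  fitw <- fit_within_sibship_model(cohort, "trait", covariates = character(0))
  ratio_pop <- mean(fitp$SE) / sd(fitp$BETA)
  ratio_ws <- mean(fitw$SE) / sd(fitw$BETA)
  expect_lt(ratio_pop, 0.97)          # anti-conservative
  expect_gt(ratio_ws, 0.94)           # calibrated
  expect_lt(ratio_ws, 1.06)
})
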