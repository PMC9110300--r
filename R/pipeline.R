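# End-to-end desk-scale scenario: simulate an independent discovery sample
# and several sibship "studies", fit both GWAS models per study, standardize
# and meta-analyze, then run the shrinkage, heritability, genetic
# correlation, Mendelian randomization and polygenic-adaptation stages.

#' Scenario configuration for the end-to-end pipeline
#'
#' Nested configuration with sensible defaults for an "education-like"
#' scenario (parental indirect effects and assortative mating present, so
#' positive shrinkage and attenuated within-sibship heritability and
#' genetic correlation are expected by construction). Any element can be
#' overridden; \code{yaml} files with the same structure are accepted by
#' \code{\link{run_scenario}}.
#'
#' @param name scenario label.
#' @param seed master seed; all stage seeds derive from it.
#' @param ... named overrides of the default elements (see the returned
#'   list's names: \code{cohort}, \code{trait}, \code{exposure},
#'   \code{outcome}, \code{studies}, \code{discovery_n}, \code{ldsc},
#'   \code{rg}, \code{adaptation}, \code{instrument_p}, \code{mr_p}).
#' @return a \code{scenario_config} list.
#' @export
scenario_config <- function(name = "education-like", seed = 1L, ...) {
  cfg <- list(
    name = name,
    seed = as.integer(seed),
    studies = c(1200L, 800L),
    discovery_n = 8000L,
    cohort = list(n_variants = 600L, maf_range = c(0.1, 0.5),
                  sibs_per_family = 2L, am_corr = 0.2,
                  strat_delta_p = 0, strat_pheno_offset = 0,
                  shared_env_var = 0.1, cryptic_relatedness_frac = 0),
    trait = list(n_causal = 80L, beta = 0.08, eta_parental = 0.04,
                 eta_sibling = 0),
    exposure = list(n_causal = 60L, beta = 0.15),
    outcome = list(causal_effect = 0.2),
    instrument_p = 1e-5,
    mr_p = 5e-8,
    ldsc = list(M = 20000L, N = 20000L, h2 = 0.3, a = 0,
                cross_intercept = 0.4, ld_mean = 50),
    rg = list(M = 20000L, rg_pop = -0.3, rg_ws = -0.05,
              h2_1 = 0.3, h2_2 = 0.2, N = 20000L),
    adaptation = list(selection_strength = 0.3)
  )
  over <- list(...)
  for (nm in names(over)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      utils::modifyList(cfg[[nm]], over[[nm]])
    } else over[[nm]]
  }
  class(cfg) <- "scenario_config"
  cfg
}

# Per-variant effect vectors from the scenario's causal-block layout:
# trait effects on variants [1, n_causal], exposure effects on the next
# block, so instruments for the two phenotypes do not overlap.
.scenario_effects <- function(cfg) {
  V <- cfg$cohort$n_variants
  tr <- numeric(V); tr[seq_len(min(cfg$trait$n_causal, V))] <- cfg$trait$beta
  eta <- numeric(V); eta[seq_len(min(cfg$trait$n_causal, V))] <- cfg$trait$eta_parental
  etas <- numeric(V); etas[seq_len(min(cfg$trait$n_causal, V))] <- cfg$trait$eta_sibling
  ex <- numeric(V)
  i0 <- min(cfg$trait$n_causal, V)
  ex[seq(i0 + 1L, min(i0 + cfg$exposure$n_causal, V))] <- cfg$exposure$beta
  list(trait_beta = tr, trait_eta_parental = eta, trait_eta_sibling = etas,
       exposure_beta = ex)
}

.simulate_study <- function(cfg, eff, map, n_sibships, seed) {
  base <- do.call(sim_config, c(cfg$cohort,
                                list(n_sibships = n_sibships,
                                     beta_direct = eff$trait_beta,
                                     seed = seed)))
  cohort <- simulate_cohort(base, phenotypes = list(), variants = map)
  cohort <- simulate_phenotype(cohort, "trait",
                               beta_direct = eff$trait_beta,
                               eta_parental = eff$trait_eta_parental,
                               eta_sibling = eff$trait_eta_sibling)
  cohort <- simulate_phenotype(cohort, "exposure",
                               beta_direct = eff$exposure_beta,
                               eta_parental = 0, eta_sibling = 0)
  simulate_phenotype(cohort, "outcome", beta_direct = 0,
                     eta_parental = 0, eta_sibling = 0,
                     extra = cfg$outcome$causal_effect *
                       cohort$pheno[["exposure"]])
}

.study_gwas <- function(cohort, phenotype) {
  cohort <- apply_missingness_rule(cohort, phenotype)
  list(population = fit_population_model(cohort, phenotype, n_pcs = 10L),
       within_sibship = fit_within_sibship_model(cohort, phenotype, n_pcs = 10L))
}

#' Run a full scenario
#'
#' Simulates the discovery sample and every study cohort, fits both GWAS
#' models per study and phenotype, standardizes to phenotype-SD units,
#' meta-analyzes, and runs the downstream stages: shrinkage (with
#' across-variant and across-study heterogeneity), LD score regression
#' heritability comparison (on summary statistics generated under the LDSC
#' model with the scenario's implied shrinkage coefficient), genetic
#' correlation difference, IVW Mendelian randomization comparison, and the
#' tSDS polygenic-adaptation test. Deterministic given the scenario seed.
#'
#' @param config a \code{\link{scenario_config}}, a plain list with the
#'   same structure, or the path of a \code{yaml} file holding one.
#' @param out_dir optional directory; when given, every intermediate table
#'   and the report are written there as TSV.
#' @return a \code{scenario_report} list of stage results.
#' @export
run_scenario <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading yaml scenario files requires the yaml package", call. = FALSE)
    }
    config <- do.call(scenario_config, yaml::read_yaml(config))
  }
  if (!inherits(config, "scenario_config")) {
    config <- do.call(scenario_config, config)
  }
  cfg <- config
  eff <- .scenario_effects(cfg)
  map <- variant_map(do.call(sim_config,
                             c(cfg$cohort,
                               list(beta_direct = eff$trait_beta,
                                    seed = cfg$seed))))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", what, conditionMessage(e)), call. = FALSE)
    })
  }

  # -- discovery GWAS (independent sample; population model only)
  disc <- stage("discovery", {
    dcfg <- do.call(sim_config, c(cfg$cohort,
                                  list(n_sibships = cfg$discovery_n,
                                       beta_direct = eff$trait_beta,
                                       seed = cfg$seed + 1000L)))
    d <- simulate_discovery(dcfg, phenotypes = list(), variants = map)
    d <- simulate_phenotype(d, "trait", beta_direct = eff$trait_beta,
                            eta_parental = 0, eta_sibling = 0)
    d <- simulate_phenotype(d, "exposure", beta_direct = eff$exposure_beta,
                            eta_parental = 0, eta_sibling = 0)
    list(trait = fit_population_model(d, "trait", n_pcs = 10L),
         exposure = fit_population_model(d, "exposure", n_pcs = 10L))
  })

  # -- per-study GWAS, both models, three phenotypes
  studies <- stage("study_gwas", {
    lapply(seq_along(cfg$studies), function(s) {
      cohort <- .simulate_study(cfg, eff, map, cfg$studies[s],
                                cfg$seed + 10L * s)
      res <- lapply(c(trait = "trait", exposure = "exposure",
                      outcome = "outcome"),
                    function(ph) .study_gwas(cohort, ph))
      res$label <- sprintf("study%d", s)
      res
    })
  })

  # -- meta-analysis per phenotype and model
  meta <- stage("meta", {
    out <- list()
    for (ph in c("trait", "exposure", "outcome")) {
      for (mod in c("population", "within_sibship")) {
        out[[ph]][[mod]] <- fixed_effects_meta(
          lapply(studies, function(s) s[[ph]][[mod]]))
      }
    }
    out
  })

  # -- shrinkage on the trait
  shrink <- stage("shrinkage", {
    inst <- select_instruments(disc$trait, cfg$instrument_p)
    tab <- shrinkage_analysis(meta$trait$population,
                              meta$trait$within_sibship, inst)
    per_study <- lapply(studies, function(s) {
      shrinkage_analysis(s$trait$population, s$trait$within_sibship, inst)
    })
    het <- study_level_heterogeneity(
      vapply(per_study, function(x) x$delta, numeric(1)),
      vapply(per_study, function(x) x$se, numeric(1)))
    list(meta = tab, per_study = per_study, study_heterogeneity = het,
         instruments = inst)
  })

  # -- LDSC heritability comparison under the implied shrinkage coefficient
  h2cmp <- stage("ldsc", {
    k <- shrink$meta$delta
    k <- min(max(k, 0), 1)
    pop_sum <- simulate_ldsc_summary(cfg$ldsc$M, cfg$ldsc$N, cfg$ldsc$h2,
                                     cfg$ldsc$a, cfg$ldsc$ld_mean,
                                     seed = cfg$seed + 2000L)
    ws_sum <- simulate_ldsc_summary(cfg$ldsc$M, cfg$ldsc$N,
                                    (1 - k)^2 * cfg$ldsc$h2, cfg$ldsc$a,
                                    cfg$ldsc$ld_mean, seed = cfg$seed + 2001L,
                                    ldscore = pop_sum$L2)
    fit_pop <- ldsc_fit(pop_sum$CHISQ, pop_sum$L2, cfg$ldsc$N, cfg$ldsc$M,
                        chr = pop_sum$CHR, bp = pop_sum$BP)
    fit_ws <- ldsc_fit(ws_sum$CHISQ, ws_sum$L2, cfg$ldsc$N, cfg$ldsc$M,
                       chr = ws_sum$CHR, bp = ws_sum$BP)
    list(pop = fit_pop, ws = fit_ws, k = k,
         expected_ws = effective_n_adjustment_check(fit_pop, k),
         difference = h2_difference_test(fit_pop, fit_ws,
                                         cfg$ldsc$cross_intercept))
  })

  # -- genetic correlation comparison
  rgcmp <- stage("rg", {
    pop <- simulate_ldsc_pair(cfg$rg$M, cfg$rg$N, cfg$rg$N, cfg$rg$h2_1,
                              cfg$rg$h2_2, cfg$rg$rg_pop,
                              ld_mean = cfg$ldsc$ld_mean,
                              seed = cfg$seed + 3000L)
    ws <- simulate_ldsc_pair(cfg$rg$M, cfg$rg$N, cfg$rg$N, cfg$rg$h2_1,
                             cfg$rg$h2_2, cfg$rg$rg_ws,
                             ld_mean = cfg$ldsc$ld_mean,
                             seed = cfg$seed + 3001L, ldscore = pop$L2)
    diff <- rg_difference_jackknife(pop$Z1, pop$Z2, cfg$rg$N, cfg$rg$N,
                                    ws$Z1, ws$Z2, cfg$rg$N, cfg$rg$N,
                                    ldscore = pop$L2, M = cfg$rg$M,
                                    chr = pop$CHR, bp = pop$BP)
    diff
  })

  # -- Mendelian randomization comparison on exposure -> outcome
  mrcmp <- stage("mr", {
    inst <- select_instruments(disc$exposure, cfg$mr_p)
    if (nrow(inst) < 2L) stop("fewer than 2 MR instruments", call. = FALSE)
    a <- function(tab) tab[match(inst$SNP, tab$SNP)]
    ep <- a(meta$exposure$population); op <- a(meta$outcome$population)
    ew <- a(meta$exposure$within_sibship); ow <- a(meta$outcome$within_sibship)
    res <- mr_difference_jackknife(ep$BETA, op$BETA, op$SE,
                                   ew$BETA, ow$BETA, ow$SE)
    res$n_instruments <- nrow(inst)
    res
  })

  # -- polygenic adaptation on the trait
  adapt <- stage("adaptation", {
    mt <- meta$trait$population
    vt <- data.table::data.table(SNP = mt$SNP, CHR = mt$CHR, BP = mt$BP,
                                 DAF = pmin(pmax(mt$EAF, 0.001), 0.999))
    sds <- simulate_sds(vt, cfg$adaptation$selection_strength,
                        effect = eff$trait_beta[match(mt$SNP, map$SNP)],
                        seed = cfg$seed + 4000L)
    sds <- exclude_selected_regions(sds)
    sds <- normalize_sds(sds)
    res <- lapply(c(population = "population", within_sibship = "within_sibship"),
                  function(mod) {
      gw <- filter_low_effective_n(meta$trait[[mod]])
      al <- align_tsds(sds, gw)
      tsds_correlation(al$TSDS, al$Z, n_blocks = 50L,
                       chr = al$CHR, bp = al$BP, model = mod)
    })
    res
  })

  report <- structure(list(name = cfg$name, seed = cfg$seed, config = cfg,
                           discovery = disc, meta = meta,
                           shrinkage = shrink, h2 = h2cmp, rg = rgcmp,
                           mr = mrcmp, adaptation = adapt),
                      class = "scenario_report")
  if (!is.null(out_dir)) .write_report(report, out_dir)
  report
}

.write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (ph in names(report$meta)) {
    for (mod in names(report$meta[[ph]])) {
      write_gwas(report$meta[[ph]][[mod]],
                 file.path(out_dir, sprintf("meta_%s_%s.tsv", ph, mod)))
    }
  }
  write_gwas(report$shrinkage$instruments,
             file.path(out_dir, "instruments_trait.tsv"))
  data.table::fwrite(report$shrinkage$meta,
                     file.path(out_dir, "shrinkage_trait.tsv"), sep = "\t")
  summary_dt <- .report_summary(report)
  data.table::fwrite(summary_dt, file.path(out_dir, "summary.tsv"), sep = "\t")
  invisible(out_dir)
}

.report_summary <- function(r) {
  data.table::data.table(
    stage = c("shrinkage_percent", "shrinkage_se_percent",
              "study_heterogeneity_p",
              "h2_pop", "h2_ws", "h2_ws_expected", "h2_diff_p",
              "rg_pop", "rg_ws", "rg_diff_p",
              "mr_pop", "mr_ws", "mr_diff_p",
              "tsds_rho_pop", "tsds_rho_ws"),
    value = c(r$shrinkage$meta$percent, 100 * r$shrinkage$meta$se,
              r$shrinkage$study_heterogeneity$p,
              r$h2$pop$h2, r$h2$ws$h2, r$h2$expected_ws, r$h2$difference$p,
              r$rg$rg_pop, r$rg$rg_ws, r$rg$p,
              r$mr$mr_pop$beta, r$mr$mr_ws$beta, r$mr$p,
              r$adaptation$population$rho, r$adaptation$within_sibship$rho),
    seed = r$seed
  )
}

#' Human-readable summary of a scenario report
#'
#' Renders the shrinkage, heritability, genetic-correlation, Mendelian
#' randomization and adaptation stages as aligned text tables, one section
#' per stage, each estimate with its standard error and the producing seed.
#'
#' @param report a \code{scenario_report} (or a list of them).
#' @return the summary \code{data.table}, invisibly; prints as a side
#'   effect.
#' @export
make_report <- function(report) {
  if (inherits(report, "scenario_report")) report <- list(report)
  if (!length(report)) {
    cat("(no scenarios)\n")
    return(invisible(data.table::data.table()))
  }
  out <- list()
  for (r in report) {
    cat(sprintf("== scenario: %s (seed %d) ==\n", r$name, r$seed))
    cat(sprintf("shrinkage: %.1f%% (se %.1f%%), 95%% CI [%.1f, %.1f], M = %d, variant-Q p = %.3g, study-het p = %.3g\n",
                r$shrinkage$meta$percent, 100 * r$shrinkage$meta$se,
                100 * r$shrinkage$meta$ci_low, 100 * r$shrinkage$meta$ci_high,
                r$shrinkage$meta$M, r$shrinkage$meta$Q_p,
                r$shrinkage$study_heterogeneity$p))
    cat(sprintf("h2: population %.3f (se %.3f), within-sibship %.3f (se %.3f), expected WS %.3f, diff p = %.3g\n",
                r$h2$pop$h2, r$h2$pop$h2_se, r$h2$ws$h2, r$h2$ws$h2_se,
                r$h2$expected_ws, r$h2$difference$p))
    cat(sprintf("rg: population %.3f, within-sibship %.3f, diff p = %.3g\n",
                r$rg$rg_pop, r$rg$rg_ws, r$rg$p))
    cat(sprintf("MR: population %.3f (se %.3f), within-sibship %.3f (se %.3f), diff p = %.3g\n",
                r$mr$mr_pop$beta, r$mr$mr_pop$se, r$mr$mr_ws$beta,
                r$mr$mr_ws$se, r$mr$p))
    cat(sprintf("adaptation: rho population %.4f (p %.3g), within-sibship %.4f (p %.3g)\n",
                r$adaptation$population$rho, r$adaptation$population$p,
                r$adaptation$within_sibship$rho, r$adaptation$within_sibship$p))
    out[[r$name]] <- .report_summary(r)
  }
  invisible(data.table::rbindlist(out))
}

#' @export
print.scenario_report <- function(x, ...) {
  make_report(x)
  invisible(x)
}
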