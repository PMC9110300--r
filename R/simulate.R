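# Family-cohort simulator. Generates two-subpopulation parent pools with
# phenotype-based assortative mating, Mendelian transmission into sibships,
# phenotypes with direct, parental-indirect, sibling-indirect, stratification
# and shared-environment components, and truth tables for recovery tests.
#
# Randomness: every operation takes its stream from the config seed plus a
# fixed per-operation offset (parents +1, transmission +2, phenotype +3, ...),
# so a single seed reproduces the whole cohort and individual stages can be
# re-run in isolation.

#' Simulation configuration for a sibship cohort
#'
#' Bundles and validates the generative knobs of the cohort simulator:
#' sibship structure, allele frequencies, direct and indirect genetic
#' effects, cross-mate phenotypic correlation (assortative mating),
#' two-subpopulation stratification, shared environment and cryptic
#' relatedness between sibships.
#'
#' @param n_sibships number of sibships (one mated couple each).
#' @param sibs_per_family either a single integer \eqn{\ge 2}, or a named
#'   probability vector over sibship sizes (e.g. \code{c("2" = .8, "3" = .2)}).
#' @param n_variants number of biallelic variants.
#' @param maf_range range the per-variant minor allele frequencies are drawn
#'   from, strictly inside (0, 1).
#' @param beta_direct per-variant direct effect of one effect allele on the
#'   phenotype (SD scale); recycled to \code{n_variants}.
#' @param eta_parental per-variant indirect effect of one parental allele
#'   (acts through the rearing environment); recycled.
#' @param eta_sibling per-variant indirect effect of one sibling allele;
#'   recycled.
#' @param am_corr target cross-mate phenotypic correlation in [0, 1).
#' @param strat_delta_p per-variant allele-frequency divergence between the
#'   two subpopulations (frequencies become p +/- delta with a random sign
#'   per variant).
#' @param strat_pheno_offset phenotype mean offset of subpopulation 2.
#' @param shared_env_var variance of the sibship-shared environment component.
#' @param cryptic_relatedness_frac fraction of sibships linked in pairs whose
#'   fathers are themselves siblings (cousin sibships).
#' @param cryptic_env_var variance of an environment component shared across
#'   a linked sibship pair.
#' @param pc_noise_sd noise SD of the simulated principal components around
#'   the standardized subpopulation indicator (controls how completely PCs
#'   absorb stratification); \code{Inf} gives pure-noise PCs.
#' @param n_pcs number of principal-component covariates to simulate.
#' @param seed integer seed from which all stage streams are derived.
#' @return an object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_sibships = 1000L,
                       sibs_per_family = 2L,
                       n_variants = 100L,
                       maf_range = c(0.05, 0.5),
                       beta_direct = 0,
                       eta_parental = 0,
                       eta_sibling = 0,
                       am_corr = 0,
                       strat_delta_p = 0,
                       strat_pheno_offset = 0,
                       shared_env_var = 0,
                       cryptic_relatedness_frac = 0,
                       cryptic_env_var = 0,
                       pc_noise_sd = 1,
                       n_pcs = 10L,
                       seed = 1L) {
  stopifnot(n_sibships >= 1, n_variants >= 1)
  .check_prob(maf_range, "maf_range")
  if (!is.numeric(am_corr) || length(am_corr) != 1L || am_corr < 0 || am_corr >= 1) {
    stop("`am_corr` must lie in [0, 1)", call. = FALSE)
  }
  .check_pos(shared_env_var, "shared_env_var", strict = FALSE)
  .check_pos(cryptic_env_var, "cryptic_env_var", strict = FALSE)
  if (cryptic_relatedness_frac < 0 || cryptic_relatedness_frac > 1) {
    stop("`cryptic_relatedness_frac` must lie in [0, 1]", call. = FALSE)
  }
  if (is.numeric(sibs_per_family) && is.null(names(sibs_per_family))) {
    if (length(sibs_per_family) != 1L || sibs_per_family < 1L) {
      stop("`sibs_per_family` must be a single size or a named distribution",
           call. = FALSE)
    }
  }
  cfg <- list(
    n_sibships = as.integer(n_sibships),
    sibs_per_family = sibs_per_family,
    n_variants = as.integer(n_variants),
    maf_range = maf_range,
    beta_direct = rep_len(beta_direct, n_variants),
    eta_parental = rep_len(eta_parental, n_variants),
    eta_sibling = rep_len(eta_sibling, n_variants),
    am_corr = am_corr,
    strat_delta_p = rep_len(strat_delta_p, n_variants),
    strat_pheno_offset = strat_pheno_offset,
    shared_env_var = shared_env_var,
    cryptic_relatedness_frac = cryptic_relatedness_frac,
    cryptic_env_var = cryptic_env_var,
    pc_noise_sd = pc_noise_sd,
    n_pcs = as.integer(n_pcs),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Build the variant map for a configuration
#'
#' Draws the variant panel (positions across 22 chromosomes, harmonized
#' chr:bp:SNP identifiers, per-variant allele frequencies including the
#' subpopulation divergence, and the per-variant true effects) from its own
#' seed stream. Passing the same map to several cohorts puts them on an
#' identical panel, which is what multi-study meta-analysis requires.
#'
#' @param config a \code{\link{sim_config}}.
#' @return a \code{data.table} variant map.
#' @export
variant_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 9L)
  .make_variant_map(config)
}

# Variant map with harmonized IDs (chr:bp:SNP), spread across 22 chromosomes.
.make_variant_map <- function(cfg) {
  V <- cfg$n_variants
  chr <- sort(rep_len(1:22, V))
  bp <- integer(V)
  for (c in unique(chr)) {
    k <- sum(chr == c)
    bp[chr == c] <- sort(sample.int(250e6, k))
  }
  maf <- runif(V, cfg$maf_range[1], cfg$maf_range[2])
  sgn <- sample(c(-1, 1), V, replace = TRUE)
  clamp <- function(p) pmin(pmax(p, 0.005), 0.995)
  data.table::data.table(
    SNP = sprintf("%d:%d:SNP", chr, bp), CHR = chr, BP = bp,
    EA = "A", OA = "G",
    MAF = maf,
    MAF_POP1 = clamp(maf + sgn * cfg$strat_delta_p),
    MAF_POP2 = clamp(maf - sgn * cfg$strat_delta_p),
    BETA_TRUE = cfg$beta_direct,
    ETA_PARENTAL = cfg$eta_parental,
    ETA_SIBLING = cfg$eta_sibling
  )
}

.draw_genotypes <- function(n, freqs_by_row) {
  # freqs_by_row: n x V matrix of effect-allele frequencies
  g <- matrix(rbinom(length(freqs_by_row), 2L, freqs_by_row),
              nrow = n)
  storage.mode(g) <- "integer"
  g
}

# Parent phenotype: direct effects + stratification offset, noise to var 1.
.parent_phenotype <- function(G, beta, subpop, offset) {
  sys <- as.numeric(G %*% beta) + offset * (subpop == 2L)
  v <- var(sys)
  if (v >= 1) stop("systematic phenotype variance exceeds 1; reduce effects",
                   call. = FALSE)
  sys + rnorm(nrow(G), 0, sqrt(1 - v))
}

#' Simulate a pool of mated parent couples
#'
#' Draws \code{2 * n_sibships} parents from two subpopulations (with the
#' configured allele-frequency divergence), gives each a phenotype driven by
#' the direct effects plus a subpopulation offset, and mates them within
#' subpopulation. Assortative mating is implemented by rank-matching mothers
#' to a noisy latent copy of the father's phenotype calibrated so the
#' realized cross-mate phenotypic correlation approaches \code{am_corr}.
#' A configured fraction of couples is linked in pairs whose fathers are
#' full siblings (cryptic relatedness between the resulting sibships).
#'
#' @param config a \code{\link{sim_config}}.
#' @param variants optional pre-built variant map from
#'   \code{\link{variant_map}}; use one shared map to put several cohorts
#'   on an identical variant panel.
#' @return a \code{parent_pool} list: father/mother genotype matrices and
#'   phenotypes (couples aligned by row), couple subpopulation labels,
#'   cryptic-pair ids (NA when unlinked) and the variant map.
#' @export
simulate_parent_pool <- function(config, variants = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- config$n_sibships
  map <- if (is.null(variants)) .make_variant_map(config) else
    data.table::as.data.table(variants)
  subpop <- sample(rep_len(1:2, n))
  freq_row <- function(sp) {
    rbind(map$MAF_POP1, map$MAF_POP2)[sp, , drop = FALSE]
  }
  geno_f <- .draw_genotypes(n, freq_row(subpop))
  geno_m <- .draw_genotypes(n, freq_row(subpop))

  # Cryptic relatedness: re-draw selected father pairs as full siblings.
  cryptic_pair <- rep(NA_integer_, n)
  n_pairs <- floor(config$cryptic_relatedness_frac * n / 2)
  if (n_pairs > 0) {
    idx <- sample.int(n, 2L * n_pairs)
    cryptic_pair[idx] <- rep(seq_len(n_pairs), each = 2L)
    for (p in seq_len(n_pairs)) {
      pair <- idx[c(2L * p - 1L, 2L * p)]
      sp <- subpop[pair[1L]]
      subpop[pair[2L]] <- sp  # siblings share subpopulation
      gp1 <- .draw_genotypes(1L, freq_row(sp))
      gp2 <- .draw_genotypes(1L, freq_row(sp))
      kids <- .transmit(gp1[rep(1L, 2L), , drop = FALSE],
                        gp2[rep(1L, 2L), , drop = FALSE])
      geno_f[pair, ] <- kids
    }
  }

  pheno_f <- .parent_phenotype(geno_f, map$BETA_TRUE, subpop,
                               config$strat_pheno_offset)
  pheno_m <- .parent_phenotype(geno_m, map$BETA_TRUE, subpop,
                               config$strat_pheno_offset)

  # Assortative mating by within-subpopulation rank matching.
  r <- config$am_corr
  if (r > 0) {
    for (sp in 1:2) {
      i <- which(subpop == sp)
      if (length(i) < 2L) next
      latent <- r * scale(pheno_f[i])[, 1L] +
        sqrt(1 - r^2) * rnorm(length(i))
      # mother with phenotype rank equal to the latent rank marries father i
      perm <- order(pheno_m[i])[rank(latent, ties.method = "first")]
      geno_m[i, ] <- geno_m[i[perm], , drop = FALSE]
      pheno_m[i] <- pheno_m[i[perm]]
    }
  }

  structure(list(geno_f = geno_f, geno_m = geno_m,
                 pheno_f = pheno_f, pheno_m = pheno_m,
                 subpop = subpop, cryptic_pair = cryptic_pair,
                 variants = map, config = config),
            class = "parent_pool")
}

# Mendelian transmission: one allele drawn uniformly from each parent.
.transmit <- function(Gm, Gf) {
  a1 <- matrix(rbinom(length(Gm), 1L, Gm / 2), nrow = nrow(Gm))
  a2 <- matrix(rbinom(length(Gf), 1L, Gf / 2), nrow = nrow(Gf))
  g <- a1 + a2
  storage.mode(g) <- "integer"
  g
}

#' Simulate sibships from a mated parent pool
#'
#' Each couple produces a sibship whose size is fixed or drawn from the
#' configured distribution; every child allele is drawn independently and
#' uniformly from the parent's two alleles (segregation at meiosis).
#' Covariates (age, sex and simulated principal components) are attached.
#'
#' @param parents a \code{parent_pool} from \code{\link{simulate_parent_pool}}.
#' @param config the same \code{\link{sim_config}}.
#' @return a \code{sib_cohort}: genotype matrix (individuals x variants),
#'   pedigree, covariates, variant map, latent parent data and an empty
#'   phenotype/truth slot filled by \code{\link{simulate_phenotype}}.
#' @export
simulate_sibships <- function(parents, config) {
  stopifnot(inherits(parents, "parent_pool"))
  set.seed(config$seed + 2L)
  n_fam <- config$n_sibships
  spf <- config$sibs_per_family
  sizes <- if (!is.null(names(spf))) {
    sample(as.integer(names(spf)), n_fam, replace = TRUE, prob = spf)
  } else {
    rep_len(as.integer(spf), n_fam)
  }
  fam_idx <- rep(seq_len(n_fam), sizes)
  N <- length(fam_idx)

  G <- .transmit(parents$geno_m[fam_idx, , drop = FALSE],
                 parents$geno_f[fam_idx, , drop = FALSE])

  ped <- data.table::data.table(
    IID = sprintf("I%06d", seq_len(N)),
    FID = sprintf("F%06d", fam_idx),
    FATHER = sprintf("P%06dF", fam_idx),
    MOTHER = sprintf("P%06dM", fam_idx),
    SUBPOP = parents$subpop[fam_idx]
  )

  covar <- data.table::data.table(
    IID = ped$IID,
    AGE = round(rnorm(N, 50, 10), 1),
    SEX = rbinom(N, 1L, 0.5)
  )
  pc_base <- scale(as.numeric(ped$SUBPOP == 2L))[, 1L]
  for (k in seq_len(config$n_pcs)) {
    covar[[paste0("PC", k)]] <- if (k == 1L && is.finite(config$pc_noise_sd)) {
      pc_base + rnorm(N, 0, config$pc_noise_sd)
    } else {
      rnorm(N)
    }
  }

  structure(list(genotypes = G, ped = ped, covar = covar,
                 variants = parents$variants,
                 fam_idx = fam_idx,
                 parents = parents,
                 pheno = list(), truth = list(),
                 config = config),
            class = "sib_cohort")
}

#' @export
print.sib_cohort <- function(x, ...) {
  cat(sprintf("<sib_cohort> %d individuals in %d sibships, %d variants\n",
              nrow(x$genotypes), length(unique(x$ped$FID)),
              ncol(x$genotypes)))
  if (length(x$pheno)) {
    cat("phenotypes:", paste(names(x$pheno), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Attach a simulated phenotype to a cohort
#'
#' Builds the phenotype as the sum of direct genetic effects, parental and
#' sibling indirect genetic effects, a subpopulation mean offset, a
#' sibship-shared environment term, an optional extra component (e.g. a
#' causal effect of another phenotype) and iid Gaussian noise scaled so the
#' total variance is approximately 1. The realized variance contribution of
#' every component is recorded in the cohort's truth table.
#'
#' @param cohort a \code{sib_cohort}.
#' @param name phenotype name.
#' @param beta_direct,eta_parental,eta_sibling per-variant effects; default
#'   to the values in the cohort's config.
#' @param subpop_offset,shared_env_var,cryptic_env_var scalars; default to
#'   the config values.
#' @param extra optional numeric vector (one value per individual) added to
#'   the systematic part before the noise is scaled.
#' @param noise_var noise variance; when \code{NULL} it is set to
#'   \code{1 - var(systematic part)} (error if that is negative).
#' @param missing_frac fraction of individuals whose phenotype is set
#'   missing at random.
#' @param seed stream seed; defaults to the config seed + an offset derived
#'   from the phenotype name so different phenotypes get distinct noise.
#' @return the cohort with \code{cohort$pheno[[name]]} and a truth entry.
#' @export
simulate_phenotype <- function(cohort, name,
                               beta_direct = NULL, eta_parental = NULL,
                               eta_sibling = NULL, subpop_offset = NULL,
                               shared_env_var = NULL, cryptic_env_var = NULL,
                               extra = NULL, noise_var = NULL,
                               missing_frac = 0, seed = NULL) {
  stopifnot(inherits(cohort, "sib_cohort"))
  cfg <- cohort$config
  V <- ncol(cohort$genotypes)
  beta <- rep_len(beta_direct %||% cfg$beta_direct, V)
  eta_p <- rep_len(eta_parental %||% cfg$eta_parental, V)
  eta_s <- rep_len(eta_sibling %||% cfg$eta_sibling, V)
  offset <- subpop_offset %||% cfg$strat_pheno_offset
  env_var <- shared_env_var %||% cfg$shared_env_var
  cr_var <- cryptic_env_var %||% cfg$cryptic_env_var
  if (any(eta_p != 0) && is.null(cohort$parents)) {
    stop("parental genotypes not retained but `eta_parental` is nonzero",
         call. = FALSE)
  }
  set.seed(seed %||% (cfg$seed + 3L + sum(utf8ToInt(name)) %% 1000L))

  fam <- cohort$fam_idx
  N <- nrow(cohort$genotypes)
  direct <- as.numeric(cohort$genotypes %*% beta)
  parental <- if (any(eta_p != 0)) {
    gp <- cohort$parents$geno_m + cohort$parents$geno_f
    as.numeric(gp[fam, , drop = FALSE] %*% eta_p)
  } else numeric(N)
  sibling <- if (any(eta_s != 0)) {
    famtot <- rowsum(cohort$genotypes, fam)
    as.numeric((famtot[fam, , drop = FALSE] - cohort$genotypes) %*% eta_s)
  } else numeric(N)
  strat <- offset * (cohort$ped$SUBPOP == 2L)
  n_fam <- max(fam)
  env_f <- rnorm(n_fam, 0, sqrt(env_var))
  if (cr_var > 0 && any(!is.na(cohort$parents$cryptic_pair))) {
    cp <- cohort$parents$cryptic_pair
    pair_env <- rnorm(max(cp, na.rm = TRUE), 0, sqrt(cr_var))
    env_f <- env_f + ifelse(is.na(cp), 0, pair_env[cp])
  }
  shared <- env_f[fam]
  extra <- extra %||% numeric(N)

  sys <- direct + parental + sibling + strat + shared + extra
  if (is.null(noise_var)) {
    noise_var <- 1 - var(sys)
    if (noise_var < 0) {
      stop("systematic phenotype variance exceeds 1; supply `noise_var`",
           call. = FALSE)
    }
  }
  y <- sys + rnorm(N, 0, sqrt(noise_var))
  if (missing_frac > 0) y[runif(N) < missing_frac] <- NA_real_

  cohort$pheno[[name]] <- y
  cohort$truth[[name]] <- list(
    beta_direct = beta, eta_parental = eta_p, eta_sibling = eta_s,
    components = c(direct = var(direct), parental = var(parental),
                   sibling = var(sibling), stratification = var(strat),
                   shared_env = var(shared), extra = var(extra),
                   noise = noise_var),
    var_systematic = var(sys), var_total = var(y)
  )
  cohort
}

#' Simulate a complete sibship cohort
#'
#' Convenience wrapper: parent pool, sibships, then one phenotype per entry
#' of \code{phenotypes} (each entry a list of arguments passed to
#' \code{\link{simulate_phenotype}}).
#'
#' @param config a \code{\link{sim_config}}.
#' @param phenotypes named list of per-phenotype argument lists; default one
#'   phenotype \code{"trait"} using the config's effects.
#' @param variants optional shared variant map (see \code{\link{variant_map}}).
#' @return a \code{sib_cohort} with phenotypes attached.
#' @export
simulate_cohort <- function(config, phenotypes = list(trait = list()),
                            variants = NULL) {
  parents <- simulate_parent_pool(config, variants)
  cohort <- simulate_sibships(parents, config)
  for (nm in names(phenotypes)) {
    cohort <- do.call(simulate_phenotype,
                      c(list(cohort = cohort, name = nm), phenotypes[[nm]]))
  }
  cohort
}

#' Simulate an independent unrelated-individuals discovery sample
#'
#' Generates a cohort of singleton "sibships" from the same variant panel and
#' generative model, for use as an independent discovery GWAS when selecting
#' instruments (avoids winner's curse in the shrinkage and MR analyses).
#' Only the population model can be fitted to it.
#'
#' @param config a \code{\link{sim_config}}; \code{n_sibships} is the number
#'   of unrelated individuals. Use a different seed from the target cohort.
#' @param phenotypes as in \code{\link{simulate_cohort}}.
#' @param variants optional shared variant map (see \code{\link{variant_map}}).
#' @return a \code{sib_cohort} of singletons, flagged as a discovery sample.
#' @export
simulate_discovery <- function(config, phenotypes = list(trait = list()),
                               variants = NULL) {
  config$sibs_per_family <- 1L
  cohort <- simulate_cohort(config, phenotypes, variants)
  cohort$discovery <- TRUE
  cohort
}
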