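# Population and within-sibship association models.
#
# Both models are fitted per variant by ordinary least squares after
# projecting out the shared covariates (Frisch-Waugh partialling), which
# makes the genome-wide scan a handful of matrix products. Standard errors
# are CR0 cluster-robust over sibships with a G/(G-1) small-sample factor.

#' Set phenotypes missing for effectively-singleton sibships
#'
#' If only one individual in a sibship has a nonmissing phenotype value, that
#' value is set missing too: the within-sibship estimator needs at least two
#' phenotyped siblings per family, and fitting both models to identical
#' samples requires the population model to drop the same rows.
#'
#' @param cohort a \code{sib_cohort}.
#' @param phenotype_name phenotype to apply the rule to.
#' @return the cohort with the phenotype updated; afterwards every sibship
#'   has either 0 or >= 2 nonmissing values.
#' @export
apply_missingness_rule <- function(cohort, phenotype_name) {
  y <- cohort$pheno[[phenotype_name]]
  if (is.null(y)) {
    stop(sprintf("unknown phenotype '%s'", phenotype_name), call. = FALSE)
  }
  n_obs <- rowsum(as.numeric(!is.na(y)), cohort$ped$FID)
  lone <- rownames(n_obs)[n_obs[, 1L] == 1]
  y[cohort$ped$FID %in% lone] <- NA_real_
  cohort$pheno[[phenotype_name]] <- y
  cohort
}

#' Quality-control filter on association or variant tables
#'
#' Retains common variants (MAF strictly above \code{maf_min}) with adequate
#' imputation quality (INFO at least \code{info_min}). The minor allele
#' frequency is the folded effect-allele frequency; an absent INFO column is
#' taken as 1 (directly genotyped / simulated data).
#'
#' @param table a \code{data.frame}/\code{data.table} with an EAF (or MAF)
#'   column and optionally INFO.
#' @param maf_min,info_min thresholds (defaults 0.01 and 0.3).
#' @return the filtered table; the number of removals is reported via
#'   \code{message()}.
#' @export
qc_filter_variants <- function(table, maf_min = 0.01, info_min = 0.3) {
  table <- data.table::as.data.table(table)
  eaf <- table$EAF %||% table$MAF
  if (is.null(eaf)) stop("table needs an EAF or MAF column", call. = FALSE)
  maf <- pmin(eaf, 1 - eaf)
  info <- table$INFO %||% rep(1, nrow(table))
  keep <- maf > maf_min & info >= info_min & !is.na(maf)
  if (any(!keep)) {
    message(sprintf("qc_filter_variants: removed %d of %d variants (MAF <= %g or INFO < %g)",
                    sum(!keep), length(keep), maf_min, info_min))
  }
  table[keep]
}

#' Family-mean-centered genotypes
#'
#' For sibling \eqn{j} in sibship \eqn{i}, computes the sibship mean genotype
#' \eqn{G^F_i = \sum_j G_{ij} / n_i} over the analyzed (study-present)
#' siblings and the centered genotype \eqn{G^C_{ij} = G_{ij} - G^F_i}.
#' Within every sibship the centered values sum to zero exactly.
#'
#' @param cohort a \code{sib_cohort}.
#' @param rows optional integer vector of analyzed individuals (defaults to
#'   everyone); every retained sibship must have >= 2 members.
#' @return a list of class \code{centered_genotypes} with matrices \code{gc}
#'   and \code{gf} (rows aligned with \code{rows}) and the sibship factor.
#' @export
center_genotypes <- function(cohort, rows = NULL) {
  rows <- rows %||% seq_len(nrow(cohort$genotypes))
  fid <- cohort$ped$FID[rows]
  sizes <- table(fid)
  if (any(sizes < 2L)) {
    stop("singleton sibship encountered; apply the missingness rule first",
         call. = FALSE)
  }
  G <- cohort$genotypes[rows, , drop = FALSE]
  f <- factor(fid)
  fam_sum <- rowsum(G, f)
  gf <- fam_sum[as.integer(f), , drop = FALSE] / as.numeric(sizes[levels(f)])[as.integer(f)]
  structure(list(gc = G - gf, gf = gf, sibship = f),
            class = "centered_genotypes")
}


.design_matrix <- function(cohort, rows, covariates) {
  X <- matrix(1, length(rows), 1L)
  if (length(covariates)) {
    X <- cbind(X, as.matrix(cohort$covar[rows, covariates, with = FALSE]))
  }
  X
}

# Complete-case analysis rows for a phenotype + covariate set.
.analysis_rows <- function(cohort, phenotype, covariates) {
  y <- cohort$pheno[[phenotype]]
  if (is.null(y)) stop(sprintf("unknown phenotype '%s'", phenotype), call. = FALSE)
  keep <- !is.na(y)
  if (length(covariates)) {
    X <- as.matrix(cohort$covar[, covariates, with = FALSE])
    keep <- keep & complete.cases(X)
  }
  which(keep)
}

.default_covariates <- function(cohort, n_pcs = 20L) {
  pcs <- grep("^PC", names(cohort$covar), value = TRUE)
  c("AGE", "SEX", head(pcs, n_pcs))
}

# Assemble the per-variant output table shared by both models.
.assoc_table <- function(cohort, rows, beta, se, flag, model, phenotype,
                         covariates, sd_resid, extra = NULL) {
  map <- cohort$variants
  G <- cohort$genotypes[rows, , drop = FALSE]
  eaf <- colMeans(G) / 2
  maf <- pmin(eaf, 1 - eaf)
  p <- 2 * pnorm(-abs(beta / se))
  eff_n <- ifelse(is.na(se) | maf <= 0 | maf >= 1, NA_real_,
                  (1 / se^2) * sd_resid^2 / (2 * maf * (1 - maf)))
  out <- data.table::data.table(
    SNP = map$SNP, CHR = map$CHR, BP = map$BP, EA = map$EA, OA = map$OA,
    EAF = eaf, BETA = beta, SE = se, P = p,
    N = length(rows), EFF_N = eff_n, MODEL = model, FLAG = flag
  )
  if (!is.null(extra)) out <- cbind(out, extra)
  data.table::setattr(out, "phenotype", phenotype)
  data.table::setattr(out, "covariates", covariates)
  data.table::setattr(out, "sd_resid", sd_resid)
  out
}

#' Population-model GWAS scan
#'
#' Per variant, ordinary least squares of the phenotype on the raw genotype
#' with age, sex and principal components as covariates; standard errors are
#' cluster-robust (CR0 sandwich) over sibships with a G/(G-1) factor, and
#' two-sided p-values use the normal approximation. Variants with zero
#' genotype variance are emitted as flagged missing records so tables stay
#' alignable across models.
#'
#' @param cohort a \code{sib_cohort}.
#' @param phenotype phenotype name.
#' @param covariates covariate column names in \code{cohort$covar}; default
#'   age, sex and up to \code{n_pcs} principal components.
#' @param n_pcs number of PCs in the default covariate set (20, or 10 for
#'   smaller studies).
#' @param cluster_se set \code{FALSE} for naive iid OLS standard errors
#'   (used to demonstrate the necessity of clustering; not recommended).
#' @return an association \code{data.table} with columns SNP, CHR, BP, EA,
#'   OA, EAF, BETA, SE, P, N, EFF_N, MODEL, FLAG.
#' @export
fit_population_model <- function(cohort, phenotype, covariates = NULL,
                                 n_pcs = 20L, cluster_se = TRUE) {
  covariates <- covariates %||% .default_covariates(cohort, n_pcs)
  rows <- .analysis_rows(cohort, phenotype, covariates)
  if (length(unique(cohort$ped$FID[rows])) < 2L) {
    stop("need phenotype data in at least 2 sibships", call. = FALSE)
  }
  y <- cohort$pheno[[phenotype]][rows]
  X <- .design_matrix(cohort, rows, covariates)
  qrX <- qr(X)
  ytil <- qr.resid(qrX, y)
  Gtil <- qr.resid(qrX, cohort$genotypes[rows, , drop = FALSE])
  fid <- factor(cohort$ped$FID[rows])
  nG <- nlevels(fid)

  denom <- colSums(Gtil^2)
  ok <- denom > 1e-8
  beta <- ifelse(ok, colSums(Gtil * ytil) / denom, NA_real_)

  if (cluster_se) {
    Sgy <- rowsum(Gtil * ytil, fid)
    Sg2 <- rowsum(Gtil * Gtil, fid)
    scores <- Sgy - sweep(Sg2, 2L, beta, `*`)
    meat <- colSums(scores^2)
    se <- sqrt(meat / denom^2 * nG / (nG - 1))
  } else {
    rss <- sum(ytil^2) - beta^2 * denom
    df <- length(rows) - ncol(X) - 1L
    se <- sqrt(rss / df / denom)
  }
  se[!ok] <- NA_real_
  flag <- ifelse(ok, "ok", "zero_variance")
  sd_resid <- sd(ytil)
  .assoc_table(cohort, rows, beta, se, flag, "population",
               phenotype, covariates, sd_resid)
}

#' Within-sibship GWAS scan
#'
#' Per variant, ordinary least squares of the phenotype on the
#' family-mean-centered genotype \eqn{G^C} with the sibship mean genotype
#' \eqn{G^F} and the usual covariates included; the reported BETA/SE is the
#' \eqn{G^C} coefficient (the direct-effect estimate) and the \eqn{G^F}
#' coefficient is retained as FBETA/FSE. Standard errors are CR0
#' cluster-robust over sibships. Variants that are genotype-concordant
#' within every sibship are emitted as flagged missing records.
#'
#' @inheritParams fit_population_model
#' @return an association \code{data.table} as in
#'   \code{\link{fit_population_model}} plus FBETA and FSE columns.
#' @export
fit_within_sibship_model <- function(cohort, phenotype, covariates = NULL,
                                     n_pcs = 20L, cluster_se = TRUE) {
  covariates <- covariates %||% .default_covariates(cohort, n_pcs)
  rows <- .analysis_rows(cohort, phenotype, covariates)
  cg <- center_genotypes(cohort, rows)
  y <- cohort$pheno[[phenotype]][rows]
  X <- .design_matrix(cohort, rows, covariates)
  qrX <- qr(X)
  ytil <- qr.resid(qrX, y)
  Gc <- qr.resid(qrX, cg$gc)
  Gf <- qr.resid(qrX, cg$gf)
  fid <- cg$sibship
  nG <- nlevels(fid)

  a11 <- colSums(Gc^2); a12 <- colSums(Gc * Gf); a22 <- colSums(Gf^2)
  b1 <- colSums(Gc * ytil); b2 <- colSums(Gf * ytil)
  det <- a11 * a22 - a12^2
  ok <- a11 > 1e-8 & det > 1e-12
  bc <- ifelse(ok, (a22 * b1 - a12 * b2) / det, NA_real_)
  bf <- ifelse(ok, (a11 * b2 - a12 * b1) / det, NA_real_)

  if (cluster_se) {
    Scy <- rowsum(Gc * ytil, fid); Sfy <- rowsum(Gf * ytil, fid)
    Scc <- rowsum(Gc * Gc, fid); Sff <- rowsum(Gf * Gf, fid)
    Scf <- rowsum(Gc * Gf, fid)
    Uc <- Scy - sweep(Scc, 2L, bc, `*`) - sweep(Scf, 2L, bf, `*`)
    Uf <- Sfy - sweep(Scf, 2L, bc, `*`) - sweep(Sff, 2L, bf, `*`)
    m11 <- colSums(Uc^2); m12 <- colSums(Uc * Uf); m22 <- colSums(Uf^2)
    fac <- nG / (nG - 1)
    var_c <- (a22^2 * m11 - 2 * a22 * a12 * m12 + a12^2 * m22) / det^2 * fac
    var_f <- (a12^2 * m11 - 2 * a11 * a12 * m12 + a11^2 * m22) / det^2 * fac
  } else {
    rss <- sum(ytil^2) - (bc * b1 + bf * b2)
    df <- length(rows) - ncol(X) - 2L
    sigma2 <- rss / df
    var_c <- sigma2 * a22 / det
    var_f <- sigma2 * a11 / det
  }
  se <- sqrt(var_c); se[!ok] <- NA_real_
  fse <- sqrt(var_f); fse[!ok] <- NA_real_
  flag <- ifelse(ok, "ok", "zero_within_variance")
  sd_resid <- sd(ytil)
  .assoc_table(cohort, rows, ifelse(ok, bc, NA_real_), se, flag,
               "within_sibship", phenotype, covariates, sd_resid,
               extra = data.table::data.table(
                 FBETA = ifelse(ok, bf, NA_real_), FSE = fse,
                 FP = 2 * pnorm(-abs(bf / fse))))
}
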