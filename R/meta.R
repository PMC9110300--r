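# Study harmonization and fixed-effects inverse-variance meta-analysis.

#' Standardize association estimates to phenotype-SD units
#'
#' Divides betas and standard errors (including the sibship-mean
#' coefficient, if present) by the study's phenotype standard deviation so
#' studies measured in different units can be meta-analyzed; Z scores are
#' unchanged.
#'
#' @param table an association table.
#' @param phenotype_sd positive scalar, the phenotype SD in the cohort.
#' @return the rescaled table.
#' @export
standardize_units <- function(table, phenotype_sd) {
  if (!is.numeric(phenotype_sd) || length(phenotype_sd) != 1L ||
      !is.finite(phenotype_sd) || phenotype_sd <= 0) {
    stop("`phenotype_sd` must be a positive number", call. = FALSE)
  }
  table <- data.table::copy(data.table::as.data.table(table))
  for (col in intersect(c("BETA", "SE", "FBETA", "FSE"), names(table))) {
    data.table::set(table, j = col, value = table[[col]] / phenotype_sd)
  }
  table
}

#' Effective sample size implied by a GWAS standard error
#'
#' \deqn{N_{eff} = \frac{1}{se^2} \cdot \frac{sd_{Resid}^2}{2 \, MAF \, (1 - MAF)}}
#'
#' the number of independent observations that would give the observed
#' standard error under iid OLS, given the variant's minor allele frequency
#' and the covariate-adjusted residual SD of the phenotype. Within-sibship
#' estimates have larger SEs than population estimates at the same raw N, so
#' their effective N is smaller; it is the N that downstream LD score
#' regression should be given.
#'
#' @param se positive standard error(s).
#' @param maf allele frequency in (0, 1); frequencies above 0.5 are folded.
#' @param sd_resid covariate-adjusted residual SD of the phenotype.
#' @return effective sample size(s), same length as \code{se}.
#' @export
effective_sample_size <- function(se, maf, sd_resid = 1) {
  .check_pos(se, "se")
  .check_pos(sd_resid, "sd_resid")
  if (any(!is.finite(maf) | maf <= 0 | maf >= 1)) {
    stop("`maf` must lie strictly inside (0, 1)", call. = FALSE)
  }
  maf <- pmin(maf, 1 - maf)
  (1 / se^2) * sd_resid^2 / (2 * maf * (1 - maf))
}

#' Study-level effective sample size summary
#'
#' Median of the per-variant effective N over variants with MAF in
#' [0.1, 0.4] (low-frequency variants are noisy in the per-variant formula).
#'
#' @param table an association table with EAF, SE and EFF_N (or the columns
#'   to recompute it).
#' @return a single number.
#' @export
study_effective_n <- function(table) {
  maf <- pmin(table$EAF, 1 - table$EAF)
  keep <- !is.na(maf) & maf >= 0.1 & maf <= 0.4 & !is.na(table$EFF_N)
  if (!any(keep)) return(NA_real_)
  median(table$EFF_N[keep])
}

# Align a study table to reference effect/other alleles: flip strand-free
# swaps, drop unresolvable variants.
.harmonize_to <- function(ref, tab) {
  m <- match(tab$SNP, ref$SNP)
  keep <- !is.na(m)
  tab <- tab[keep]; m <- m[keep]
  same <- tab$EA == ref$EA[m] & tab$OA == ref$OA[m]
  swap <- tab$EA == ref$OA[m] & tab$OA == ref$EA[m]
  drop <- !(same | swap)
  if (any(drop)) {
    message(sprintf("fixed_effects_meta: dropped %d variants with unresolvable alleles",
                    sum(drop)))
  }
  if (any(swap)) {
    for (col in intersect(c("BETA", "FBETA"), names(tab))) {
      data.table::set(tab, which(swap), col, -tab[[col]][swap])
    }
    data.table::set(tab, which(swap), "EAF", 1 - tab$EAF[swap])
    ea <- tab$EA; oa <- tab$OA
    data.table::set(tab, which(swap), "EA", oa[swap])
    data.table::set(tab, which(swap), "OA", ea[swap])
  }
  tab[!drop]
}

#' Fixed-effects inverse-variance meta-analysis of association tables
#'
#' Harmonizes every study to the first study's effect alleles (swapping
#' alleles and flipping beta signs where needed; unresolvable variants are
#' dropped with a message), then pools per variant:
#' \deqn{\beta = \frac{\sum_s \beta_s/\sigma_s^2}{\sum_s 1/\sigma_s^2},
#'       \quad se = \Big(\sum_s 1/\sigma_s^2\Big)^{-1/2}}
#' The per-variant effective N is the sum over the studies in which the
#' variant was present.
#'
#' @param tables list of association tables (same model, same phenotype).
#' @return a pooled association \code{data.table} with N_STUDIES.
#' @export
fixed_effects_meta <- function(tables) {
  stopifnot(length(tables) >= 1L)
  tables <- lapply(tables, function(t) {
    data.table::copy(data.table::as.data.table(t))
  })
  ref <- tables[[1L]]
  tables <- c(list(ref), lapply(tables[-1L], .harmonize_to, ref = ref))
  long <- data.table::rbindlist(tables, fill = TRUE)
  long <- long[!is.na(BETA) & !is.na(SE) & SE > 0]
  pooled <- long[, {
    w <- 1 / SE^2
    list(CHR = CHR[1L], BP = BP[1L], EA = EA[1L], OA = OA[1L],
         EAF = sum(w * EAF) / sum(w),
         BETA = sum(w * BETA) / sum(w),
         SE = sqrt(1 / sum(w)),
         N = sum(N), EFF_N = sum(EFF_N),
         N_STUDIES = .N,
         MODEL = MODEL[1L])
  }, by = "SNP"]
  pooled[, P := 2 * pnorm(-abs(BETA / SE))]
  data.table::setorder(pooled, CHR, BP)
  pooled[]
}
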