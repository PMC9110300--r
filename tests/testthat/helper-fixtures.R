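# Fixtures are built in code at test time; nothing is read from disk.

# Hand-built cohort for exact worked examples: `genotypes` is an
# individuals x variants matrix, `fid` the sibship labels.
manual_cohort <- function(genotypes, fid, pheno = NULL, covar = NULL) {
  n <- nrow(genotypes)
  V <- ncol(genotypes)
  storage.mode(genotypes) <- "integer"
  ped <- data.table::data.table(
    IID = sprintf("I%03d", seq_len(n)), FID = fid,
    FATHER = paste0(fid, "F"), MOTHER = paste0(fid, "M"),
    SUBPOP = 1L)
  if (is.null(covar)) {
    covar <- data.table::data.table(IID = ped$IID,
                                    AGE = rep(50, n), SEX = rep(0L, n))
  }
  variants <- data.table::data.table(
    SNP = sprintf("1:%d:SNP", seq_len(V) * 1000L),
    CHR = 1L, BP = seq_len(V) * 1000L, EA = "A", OA = "G",
    MAF = colMeans(genotypes) / 2)
  structure(list(genotypes = genotypes, ped = ped, covar = covar,
                 variants = variants,
                 fam_idx = as.integer(factor(fid, levels = unique(fid))),
                 parents = NULL,
                 pheno = if (is.null(pheno)) list() else pheno,
                 truth = list(), config = NULL),
            class = "sib_cohort")
}

# Hand-built parent pool (couples aligned by row) for transmission tests.
manual_parents <- function(geno_f, geno_m, config) {
  storage.mode(geno_f) <- "integer"
  storage.mode(geno_m) <- "integer"
  n <- nrow(geno_f)
  V <- ncol(geno_f)
  map <- data.table::data.table(
    SNP = sprintf("1:%d:SNP", seq_len(V) * 1000L),
    CHR = 1L, BP = seq_len(V) * 1000L, EA = "A", OA = "G",
    MAF = 0.5, MAF_POP1 = 0.5, MAF_POP2 = 0.5,
    BETA_TRUE = 0, ETA_PARENTAL = 0, ETA_SIBLING = 0)
  structure(list(geno_f = geno_f, geno_m = geno_m,
                 pheno_f = rnorm(n), pheno_m = rnorm(n),
                 subpop = rep(1L, n), cryptic_pair = rep(NA_integer_, n),
                 variants = map, config = config),
            class = "parent_pool")
}

# Sibling-pair genotype correlation at given variants (brute force).
sib_pair_cor <- function(cohort, variant = 1L) {
  fam <- cohort$fam_idx
  g <- cohort$genotypes[, variant]
  first <- !duplicated(fam)
  second <- duplicated(fam) & !duplicated(fam, fromLast = FALSE) |
    c(FALSE, head(fam, -1) == tail(fam, -1))
  g1 <- g[which(first)]
  g2 <- g[which(first) + 1L]
  cor(g1, g2)
}
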