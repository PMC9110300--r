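# Tab-separated on-disk interchange: pedigree, genotype matrix,
# phenotype/covariate table, variant map and truth tables, plus the GWAS
# summary TSV dialect used by every downstream stage.

#' Write a cohort as tab-separated files
#'
#' Writes \code{<prefix>.pedigree.tsv} (IID, FID, FATHER, MOTHER, SUBPOP),
#' \code{<prefix>.genotypes.tsv} (IID by variant allele counts),
#' \code{<prefix>.phenotypes.tsv} (IID, covariates, phenotypes),
#' \code{<prefix>.variants.tsv} (the map, including per-variant truth
#' effects) and \code{<prefix>.truth.tsv} (per-phenotype variance
#' components).
#'
#' @param cohort a \code{sib_cohort}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default "cohort").
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir, prefix = "cohort") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(part) file.path(dir, sprintf("%s.%s.tsv", prefix, part))
  data.table::fwrite(cohort$ped, path("pedigree"), sep = "\t")
  gt <- data.table::as.data.table(cohort$genotypes)
  data.table::setnames(gt, cohort$variants$SNP)
  data.table::fwrite(cbind(data.table::data.table(IID = cohort$ped$IID), gt),
                     path("genotypes"), sep = "\t")
  ph <- data.table::copy(cohort$covar)
  for (nm in names(cohort$pheno)) ph[[nm]] <- cohort$pheno[[nm]]
  data.table::fwrite(ph, path("phenotypes"), sep = "\t")
  data.table::fwrite(cohort$variants, path("variants"), sep = "\t")
  if (length(cohort$truth)) {
    comp <- data.table::rbindlist(lapply(names(cohort$truth), function(nm) {
      cc <- cohort$truth[[nm]]$components
      data.table::data.table(PHENOTYPE = nm, COMPONENT = names(cc),
                             VARIANCE = as.numeric(cc))
    }))
    data.table::fwrite(comp, path("truth"), sep = "\t")
  }
  invisible(vapply(c("pedigree", "genotypes", "phenotypes", "variants"),
                   path, character(1)))
}

#' Read a cohort written by \code{\link{write_cohort}}
#'
#' Reconstructs a \code{sib_cohort} from the tab-separated files. Latent
#' parent genotypes are not serialized, so phenotypes with parental indirect
#' effects cannot be re-simulated from the result, but both GWAS models can
#' be fitted.
#'
#' @param dir directory containing the files.
#' @param prefix file-name prefix used at write time.
#' @return a \code{sib_cohort}.
#' @export
read_cohort <- function(dir, prefix = "cohort") {
  path <- function(part) file.path(dir, sprintf("%s.%s.tsv", prefix, part))
  ped <- data.table::fread(path("pedigree"), sep = "\t")
  gt <- data.table::fread(path("genotypes"), sep = "\t")
  variants <- data.table::fread(path("variants"), sep = "\t")
  ph <- data.table::fread(path("phenotypes"), sep = "\t")
  G <- as.matrix(gt[, -1L])
  storage.mode(G) <- "integer"
  covar_cols <- c("IID", "AGE", "SEX", grep("^PC", names(ph), value = TRUE))
  pheno_cols <- setdiff(names(ph), covar_cols)
  pheno <- lapply(pheno_cols, function(nm) ph[[nm]])
  names(pheno) <- pheno_cols
  fam_idx <- as.integer(factor(ped$FID, levels = unique(ped$FID)))
  structure(list(genotypes = G, ped = ped,
                 covar = ph[, covar_cols, with = FALSE],
                 variants = variants, fam_idx = fam_idx,
                 parents = NULL, pheno = pheno, truth = list(),
                 config = NULL),
            class = "sib_cohort")
}

#' Write a GWAS summary table
#'
#' Tab-separated with the columns SNP, CHR, BP, EA, OA, EAF, BETA, SE, P,
#' N, EFF_N, MODEL (+ FBETA, FSE for within-sibship fits).
#'
#' @param table an association table.
#' @param file output path.
#' @export
write_gwas <- function(table, file) {
  data.table::fwrite(table, file, sep = "\t", na = "NA", quote = FALSE)
  invisible(file)
}

#' Read a GWAS summary table written by \code{\link{write_gwas}}
#' @param file path to the TSV.
#' @return a \code{data.table}.
#' @export
read_gwas <- function(file) {
  data.table::fread(file, sep = "\t", na.strings = "NA")
}
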