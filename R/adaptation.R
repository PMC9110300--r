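# Polygenic-adaptation testing: singleton density score (SDS) processing,
# alignment to the trait-increasing allele (tSDS), and Spearman rank
# correlation with absolute GWAS Z scores using block-jackknife standard
# errors.

# Regions under strong recent selection, excluded before SDS analysis
# (1-based inclusive coordinates): the MHC and the lactase locus.
.selected_regions <- data.frame(
  CHR = c(6L, 2L),
  START = c(25892529L, 134608646L),
  END = c(33436144L, 138608646L)
)

#' Remove variants in regions under strong recent selection
#'
#' Drops variants inside the MHC (chr6:25,892,529-33,436,144) or the lactase
#' region (chr2:134,608,646-138,608,646); intervals are 1-based inclusive.
#'
#' @param table a variant table with CHR and BP columns.
#' @return the table without variants in the excluded intervals.
#' @export
exclude_selected_regions <- function(table) {
  table <- data.table::as.data.table(table)
  drop <- rep(FALSE, nrow(table))
  for (i in seq_len(nrow(.selected_regions))) {
    r <- .selected_regions[i, ]
    drop <- drop | (table$CHR == r$CHR & table$BP >= r$START & table$BP <= r$END)
  }
  table[!drop]
}

#' Normalize SDS within 1\% allele-frequency bins
#'
#' Within each derived-allele-frequency bin [k/100, (k+1)/100) (the final
#' bin is closed), SDS are centered and scaled to mean 0, SD 1. Bins with
#' fewer than 2 variants are passed through unchanged and flagged.
#'
#' @param table an SDS table with DAF and SDS columns.
#' @return the table with SDS replaced by its within-bin standardization
#'   and a logical SDS_RAW_FLAG column marking degenerate bins.
#' @export
normalize_sds <- function(table) {
  table <- data.table::copy(data.table::as.data.table(table))
  .check_prob(table$DAF, "DAF")
  bin <- pmin(floor(table$DAF * 100), 99L)  # last bin closed at 1
  norm <- table$SDS
  flag <- rep(FALSE, nrow(table))
  for (b in unique(bin)) {
    i <- which(bin == b)
    if (length(i) < 2L) {
      flag[i] <- TRUE
    } else {
      norm[i] <- (table$SDS[i] - mean(table$SDS[i])) / sd(table$SDS[i])
    }
  }
  table[, `:=`(SDS = norm, SDS_RAW_FLAG = flag)]
  table[]
}

#' Drop variants with low effective sample size
#'
#' Removes variants whose effective N is strictly below
#' \code{threshold * max(effective N)}; a variant at exactly the threshold
#' is retained.
#'
#' @param table a table with an EFF_N column.
#' @param threshold fraction of the maximum (default 0.5).
#' @return the filtered table.
#' @export
filter_low_effective_n <- function(table, threshold = 0.5) {
  table <- data.table::as.data.table(table)
  if (is.null(table$EFF_N)) stop("table needs an EFF_N column", call. = FALSE)
  cut <- threshold * max(table$EFF_N, na.rm = TRUE)
  table[!is.na(EFF_N) & EFF_N >= cut]
}

#' Align SDS to the phenotype-increasing allele (tSDS)
#'
#' Joins the SDS table with a GWAS table on variant ID and allele identity,
#' then signs the SDS so it refers to the phenotype-increasing allele:
#' tSDS = SDS where the GWAS beta for the SDS reference allele is positive,
#' -SDS where negative. Variants with beta exactly 0 are left unflipped and
#' flagged; allele-mismatched variants are dropped with a message.
#'
#' @param sds_table SDS table with SNP, SDS and (optionally) EA/OA alleles.
#' @param gwas_table association table with SNP, EA, OA, BETA, SE.
#' @return the joined table with TSDS, Z and a TIE_FLAG column.
#' @export
align_tsds <- function(sds_table, gwas_table) {
  sds <- data.table::as.data.table(sds_table)
  gw <- data.table::as.data.table(gwas_table)
  m <- match(sds$SNP, gw$SNP)
  keep <- !is.na(m)
  sds <- sds[keep]; m <- m[keep]
  beta <- gw$BETA[m]
  # when the SDS table carries alleles, the SDS reference allele must match
  # one of the GWAS alleles; a swap flips the beta orientation
  if (!is.null(sds$EA)) {
    same <- sds$EA == gw$EA[m]
    swap <- sds$EA == gw$OA[m]
    bad <- !(same | swap)
    if (any(bad)) {
      message(sprintf("align_tsds: dropped %d allele-mismatched variants", sum(bad)))
      sds <- sds[!bad]; m <- m[!bad]
      beta <- gw$BETA[m]; same <- same[!bad]; swap <- swap[!bad]
    }
    beta[swap] <- -beta[swap]
  }
  out <- data.table::copy(sds)
  out[, `:=`(
    TSDS = ifelse(beta < 0, -SDS, SDS),
    TIE_FLAG = beta == 0,
    Z = gw$BETA[m] / gw$SE[m],
    EFF_N = if (!is.null(gw$EFF_N)) gw$EFF_N[m] else NA_real_
  )]
  out[]
}

#' Spearman correlation of tSDS with absolute GWAS Z scores
#'
#' Rank correlation (average ranks for ties) between the trait-aligned SDS
#' and |Z|; a positive correlation indicates recent selection favoring the
#' trait-increasing alleles. The standard error is a delete-one-block
#' jackknife over \code{n_blocks} contiguous blocks in (chromosome,
#' position) order, and the two-sided p-value comes from the jackknife Z.
#'
#' @param tsds trait-aligned SDS values.
#' @param z_scores GWAS Z scores (absolute value is taken internally).
#' @param n_blocks jackknife blocks (default 100).
#' @param chr,bp optional coordinates for block ordering.
#' @param model optional tag carried into the result.
#' @return an object of class \code{adaptation_result}: rho, se, z, p,
#'   n_variants, n_blocks, model.
#' @export
tsds_correlation <- function(tsds, z_scores, n_blocks = 100L,
                             chr = NULL, bp = NULL, model = NA_character_) {
  stopifnot(length(tsds) == length(z_scores))
  keep <- is.finite(tsds) & is.finite(z_scores)
  tsds <- tsds[keep]; z <- abs(z_scores[keep])
  if (!is.null(chr)) chr <- chr[keep]
  if (!is.null(bp)) bp <- bp[keep]
  n <- length(tsds)
  if (n < 4L) stop("too few variants", call. = FALSE)
  if (sd(tsds) == 0 || sd(z) == 0) {
    stop("constant input vector; rank correlation undefined", call. = FALSE)
  }
  ord <- .genome_order(chr, bp, n)
  tsds <- tsds[ord]; z <- z[ord]
  rho <- cor(rank(tsds), rank(z))
  blocks <- .block_index(n, n_blocks)
  loo <- vapply(seq_len(max(blocks)), function(b) {
    i <- blocks != b
    cor(rank(tsds[i]), rank(z[i]))
  }, numeric(1))
  se <- jackknife_se(loo)
  zp <- .z_p(rho, se)
  structure(list(rho = rho, se = se, z = zp$z, p = zp$p,
                 n_variants = n, n_blocks = max(blocks), model = model),
            class = "adaptation_result")
}

#' @export
print.adaptation_result <- function(x, ...) {
  cat(sprintf("<adaptation_result%s> rho = %.4f (se %.4f), p = %.3g over %d variants\n",
              if (is.na(x$model)) "" else paste0(": ", x$model),
              x$rho, x$se, x$p, x$n_variants))
  invisible(x)
}

#' Mean tSDS at top associated loci
#'
#' Secondary adaptation statistic: the mean trait-aligned SDS among the
#' most strongly associated variants (putative loci), with its standard
#' error; positive under directional selection, ~0 under the null.
#'
#' @param tsds trait-aligned SDS values.
#' @param p_values association p-values, same order.
#' @param p_max inclusion threshold for putative loci (default 1e-5).
#' @return a list: mean, se, p, n_loci.
#' @export
mean_tsds_top_loci <- function(tsds, p_values, p_max = 1e-5) {
  i <- which(is.finite(tsds) & is.finite(p_values) & p_values < p_max)
  if (length(i) < 2L) {
    return(list(mean = NA_real_, se = NA_real_, p = NA_real_,
                n_loci = length(i)))
  }
  m <- mean(tsds[i])
  se <- sd(tsds[i]) / sqrt(length(i))
  list(mean = m, se = se, p = 2 * pnorm(-abs(m / se)), n_loci = length(i))
}
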