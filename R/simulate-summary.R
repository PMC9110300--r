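# Summary-statistic generators: GWAS Z scores drawn directly under the LD
# score regression model (univariate and bivariate), and synthetic singleton
# density scores for the polygenic-adaptation machinery.

#' Simulate GWAS summary statistics under the LD score regression model
#'
#' Draws per-variant Z scores as \eqn{Z_j ~ N(0, s_j)} with
#' \eqn{s_j^2 = N h^2 l_j / M + N a + 1}, so the expected chi-square of each
#' variant matches the LD score regression model exactly: a polygenic signal
#' proportional to the variant's LD score \eqn{l_j} plus a uniform
#' confounding inflation \eqn{N a} plus 1.
#'
#' @param M number of variants.
#' @param N (effective) GWAS sample size.
#' @param h2 true SNP heritability in [0, 1].
#' @param a per-individual confounding inflation (nonnegative).
#' @param ld_mean mean of the LD score distribution; scores are drawn as
#'   \code{1 + rexp(M, 1/(ld_mean - 1))} (all \eqn{\ge 1}).
#' @param seed integer seed.
#' @param ldscore optional length-M vector of LD scores to reuse, so two
#'   GWAS can be simulated on an identical variant panel.
#' @return a \code{data.table} with columns SNP, CHR, BP, L2, Z, CHISQ,
#'   N_EFF and a HAPMAP quality flag (all TRUE for simulated panels).
#' @export
simulate_ldsc_summary <- function(M, N, h2, a = 0, ld_mean = 50, seed = 1L,
                                  ldscore = NULL) {
  if (h2 < 0 || h2 > 1) stop("`h2` must lie in [0, 1]", call. = FALSE)
  .check_pos(a, "a", strict = FALSE)
  set.seed(seed)
  chr <- sort(rep_len(1:22, M))
  bp <- unlist(lapply(unique(chr), function(c) sort(sample.int(250e6, sum(chr == c)))))
  l2 <- if (!is.null(ldscore)) {
    stopifnot(length(ldscore) == M)
    ldscore
  } else if (ld_mean > 1) 1 + rexp(M, 1 / (ld_mean - 1)) else rep(1, M)
  s2 <- N * h2 * l2 / M + N * a + 1
  z <- rnorm(M, 0, sqrt(s2))
  data.table::data.table(
    SNP = sprintf("%d:%d:SNP", chr, bp), CHR = chr, BP = bp,
    L2 = l2, Z = z, CHISQ = z^2, N_EFF = N, HAPMAP = TRUE
  )
}

#' Simulate a correlated pair of GWAS under the bivariate LDSC model
#'
#' Per variant, \code{(Z1, Z2)} are bivariate normal with variances
#' \eqn{N_t h_t^2 l_j / M + N_t a_t + 1} and covariance
#' \eqn{\sqrt{N_1 N_2} r_g \sqrt{h_1^2 h_2^2} l_j / M + c}, where \code{c}
#' is the cross-trait intercept induced by sample overlap.
#'
#' @param M,ld_mean,seed as in \code{\link{simulate_ldsc_summary}}.
#' @param N1,N2 sample sizes of the two GWAS.
#' @param h2_1,h2_2 true heritabilities of the two traits.
#' @param rg true genetic correlation in [-1, 1].
#' @param a1,a2 confounding inflations.
#' @param cross_intercept sample-overlap cross-trait intercept.
#' @param ldscore optional shared LD score vector (see
#'   \code{\link{simulate_ldsc_summary}}).
#' @param shared_effects when TRUE, the two GWAS share a single realization
#'   of the per-variant genetic means (the regime for one trait measured by
#'   two designs on overlapping samples: only the noise is resampled, with
#'   correlation \code{cross_intercept}); when FALSE (default), effects are
#'   drawn jointly with genetic correlation \code{rg} (two distinct traits).
#'   Both modes have the same second moments for the LD score regressions.
#' @return a \code{data.table} with SNP, CHR, BP, L2, Z1, Z2, N1, N2.
#' @export
simulate_ldsc_pair <- function(M, N1, N2, h2_1, h2_2, rg,
                               a1 = 0, a2 = 0, cross_intercept = 0,
                               ld_mean = 50, seed = 1L, ldscore = NULL,
                               shared_effects = FALSE) {
  if (abs(rg) > 1) stop("`rg` must lie in [-1, 1]", call. = FALSE)
  base <- simulate_ldsc_summary(M, N1, h2_1, a1, ld_mean, seed, ldscore)
  set.seed(seed + 1L)
  l2 <- base$L2
  if (shared_effects) {
    u <- rnorm(M)
    u2 <- rg * u + sqrt(1 - rg^2) * rnorm(M)
    mu1 <- sqrt(N1 * h2_1 * l2 / M) * u
    mu2 <- sqrt(N2 * h2_2 * l2 / M) * u2
    e1 <- rnorm(M, 0, sqrt(1 + N1 * a1))
    e2 <- cross_intercept * e1 +
      rnorm(M, 0, sqrt(pmax((1 + N2 * a2) - cross_intercept^2 * (1 + N1 * a1), 0)))
    z1 <- mu1 + e1
    z2 <- mu2 + e2
  } else {
    v1 <- N1 * h2_1 * l2 / M + N1 * a1 + 1
    v2 <- N2 * h2_2 * l2 / M + N2 * a2 + 1
    c12 <- sqrt(N1 * N2 * h2_1 * h2_2) * rg * l2 / M + cross_intercept
    c12 <- sign(c12) * pmin(abs(c12), 0.999 * sqrt(v1 * v2))
    z1 <- rnorm(M, 0, sqrt(v1))
    # conditional draw keeps the exact covariance structure
    z2 <- c12 / v1 * z1 + rnorm(M, 0, sqrt(pmax(v2 - c12^2 / v1, 0)))
  }
  data.table::data.table(SNP = base$SNP, CHR = base$CHR, BP = base$BP,
                         L2 = l2, Z1 = z1, Z2 = z2, N1 = N1, N2 = N2,
                         HAPMAP = TRUE)
}

#' Simulate singleton density scores for a variant panel
#'
#' Raw SDS are standard normal within allele-frequency strata; when
#' \code{selection_strength > 0} the score for each variant's reference
#' allele is shifted in proportion to the (standardized rank of the)
#' trait effect of that allele, emulating recent directional selection on
#' the trait-increasing allele.
#'
#' @param variants a \code{data.frame}/\code{data.table} with SNP, CHR, BP
#'   and a derived-allele-frequency column DAF (or MAF, used as DAF).
#' @param selection_strength nonnegative scalar; 0 gives pure noise.
#' @param effect optional per-variant effect of the SDS reference allele on
#'   the trait; required when \code{selection_strength > 0}.
#' @param seed integer seed.
#' @return a \code{data.table} with SNP, CHR, BP, DAF, SDS and a
#'   SELECTION_FLAG truth marker.
#' @export
simulate_sds <- function(variants, selection_strength = 0, effect = NULL,
                         seed = 1L) {
  variants <- data.table::as.data.table(variants)
  if (nrow(variants) == 0L) {
    return(data.table::data.table(SNP = character(), CHR = integer(),
                                  BP = integer(), DAF = numeric(),
                                  SDS = numeric(),
                                  SELECTION_FLAG = logical()))
  }
  daf <- variants$DAF %||% variants$MAF
  .check_prob(daf, "derived-allele frequency")
  set.seed(seed)
  n <- nrow(variants)
  sds <- rnorm(n)
  flag <- rep(FALSE, n)
  if (selection_strength > 0) {
    if (is.null(effect)) {
      stop("`effect` required when `selection_strength` > 0", call. = FALSE)
    }
    shift <- scale(rank(effect, ties.method = "average"))[, 1L]
    sds <- sds + selection_strength * shift
    flag <- effect != 0
  }
  data.table::data.table(SNP = variants$SNP, CHR = variants$CHR,
                         BP = variants$BP, DAF = daf, SDS = sds,
                         SELECTION_FLAG = flag)
}
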