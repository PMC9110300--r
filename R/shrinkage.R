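# Weighted variant scores, shrinkage of population relative to
# within-sibship estimates, jackknife standard errors and heterogeneity.

#' Select independent instruments from a discovery GWAS
#'
#' Greedy p-value clumping: variants are visited in ascending p-value order;
#' each retained variant removes all later variants with \eqn{r^2 \ge}
#' \code{r2_max} within \code{window_kb} on the same chromosome. The
#' discovery table must come from a sample independent of the target cohort
#' (winner's-curse guard). Simulated variant panels carry no LD, so an
#' absent \code{ld} matrix means all variants are treated as independent.
#'
#' @param discovery_table association table with SNP, CHR, BP, BETA, SE, P.
#' @param p_threshold selection threshold; 5e-8 (genome-wide) or the more
#'   liberal 1e-5 used as the primary reporting threshold.
#' @param ld optional square \eqn{r^2} matrix with dimnames = SNP ids.
#' @param r2_max,window_kb clumping parameters (defaults 0.001 and 10,000 kb).
#' @return a \code{data.table} of retained variants (instrument set) with
#'   the discovery betas as the WEIGHT column; zero rows (with a warning)
#'   when nothing passes the threshold.
#' @export
select_instruments <- function(discovery_table, p_threshold = 1e-5,
                               ld = NULL, r2_max = 0.001,
                               window_kb = 10000) {
  tab <- data.table::as.data.table(discovery_table)
  tab <- tab[!is.na(P) & P < p_threshold]
  if (nrow(tab) == 0L) {
    warning("no variant passes the p-value threshold; empty instrument set")
    return(tab[, WEIGHT := numeric(0)][])
  }
  data.table::setorder(tab, P)
  keep <- logical(nrow(tab))
  alive <- rep(TRUE, nrow(tab))
  for (i in seq_len(nrow(tab))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    later <- which(alive & seq_len(nrow(tab)) > i)
    if (!length(later)) next
    near <- tab$CHR[later] == tab$CHR[i] &
      abs(tab$BP[later] - tab$BP[i]) <= window_kb * 1000
    r2 <- if (is.null(ld)) 0 else ld[tab$SNP[later], tab$SNP[i]]
    alive[later[near & r2 >= r2_max]] <- FALSE
  }
  out <- tab[keep]
  out[, WEIGHT := BETA]
  data.table::setattr(out, "p_threshold", p_threshold)
  out[]
}

#' Summary-based weighted score of target estimates on discovery weights
#'
#' \deqn{S = \frac{\sum_k w_k \beta_k / \sigma_k^2}
#'                {\sum_k w_k^2 / \sigma_k^2}, \qquad
#'       \sigma_S = \sqrt{\frac{1}{\sum_k w_k^2/\sigma_k^2}}}
#'
#' the inverse-variance-weighted average association of the instrument set
#' with the phenotype in the target (population or within-sibship) GWAS,
#' using the independent discovery betas as weights. Equals the
#' no-intercept weighted-least-squares slope of \eqn{\beta} on \eqn{w} with
#' weights \eqn{1/\sigma^2}.
#'
#' @param betas,ses target-GWAS estimates for the instruments.
#' @param weights discovery betas.
#' @return a list of class \code{weighted_score}: S, sigma_S, M, z, p.
#' @export
weighted_score <- function(betas, ses, weights) {
  stopifnot(length(betas) == length(ses), length(betas) == length(weights))
  keep <- is.finite(betas) & is.finite(ses) & is.finite(weights) & ses > 0
  betas <- betas[keep]; ses <- ses[keep]; weights <- weights[keep]
  if (!length(betas)) stop("no usable instruments", call. = FALSE)
  denom <- sum(weights^2 / ses^2)
  S <- sum(weights * betas / ses^2) / denom
  sigma_S <- sqrt(1 / denom)
  zp <- .z_p(S, sigma_S)
  structure(list(S = S, sigma_S = sigma_S, M = length(betas),
                 z = zp$z, p = zp$p),
            class = "weighted_score")
}

#' @export
print.weighted_score <- function(x, ...) {
  cat(sprintf("<weighted_score> S = %.4g (se %.3g), M = %d, p = %.3g\n",
              x$S, x$sigma_S, x$M, x$p))
  invisible(x)
}

#' Shrinkage of the population estimate relative to the within-sibship one
#'
#' \deqn{\delta = 1 - S_W / S_P}
#'
#' the proportional decrease of the weighted score from the population to
#' the within-sibship model; reported as a percentage via \code{100 * delta}.
#'
#' @param s_within,s_population \code{weighted_score} objects (or numbers).
#' @return a list: delta, percent, and an unstable-denominator flag set
#'   when the population score has |Z| < 2.
#' @export
shrinkage_estimate <- function(s_within, s_population) {
  sw <- if (inherits(s_within, "weighted_score")) s_within$S else s_within
  sp <- if (inherits(s_population, "weighted_score")) s_population$S else s_population
  if (sp == 0) stop("population score is zero; shrinkage undefined", call. = FALSE)
  unstable <- FALSE
  if (inherits(s_population, "weighted_score") &&
      abs(s_population$z) < 2) {
    unstable <- TRUE
    warning("population score |Z| < 2: shrinkage denominator is unstable")
  }
  delta <- 1 - sw / sp
  list(delta = delta, percent = 100 * delta, unstable_denominator = unstable)
}

#' Leave-one-variant-out jackknife standard error for shrinkage
#'
#' Removes each instrument in turn, recomputes both weighted scores and the
#' shrinkage, and returns
#' \eqn{\sigma_\delta = \sqrt{(M-1)/M \sum_k (\delta_{(k)} - \bar\delta)^2}}.
#' When the covariance of the two scores is supplied, the delta-method
#' standard error
#' \eqn{(S_W/S_P)\sqrt{\sigma_{S_W}^2/S_W^2 + \sigma_{S_P}^2/S_P^2
#'      - 2 Cov/(S_W S_P)}}
#' is returned alongside.
#'
#' @param beta_w,se_w within-sibship estimates for the instruments.
#' @param beta_p,se_p population estimates for the same instruments.
#' @param weights discovery betas.
#' @param cov_scores optional Cov(S_W, S_P) for the delta-method SE.
#' @return a list: delta, se (jackknife), se_delta_method, ci (95\%),
#'   loo (leave-one-out estimates) and the two scores.
#' @export
jackknife_se_shrinkage <- function(beta_w, se_w, beta_p, se_p, weights,
                                   cov_scores = NULL) {
  M <- length(weights)
  if (M < 2L) stop("need at least 2 instruments for the jackknife", call. = FALSE)
  sw <- weighted_score(beta_w, se_w, weights)
  sp <- weighted_score(beta_p, se_p, weights)
  delta <- shrinkage_estimate(sw, sp)$delta
  loo <- vapply(seq_len(M), function(k) {
    1 - weighted_score(beta_w[-k], se_w[-k], weights[-k])$S /
      weighted_score(beta_p[-k], se_p[-k], weights[-k])$S
  }, numeric(1))
  se_jack <- jackknife_se(loo)
  se_dm <- NA_real_
  if (!is.null(cov_scores)) {
    inner <- sw$sigma_S^2 / sw$S^2 + sp$sigma_S^2 / sp$S^2 -
      2 * cov_scores / (sw$S * sp$S)
    se_dm <- abs(sw$S / sp$S) * sqrt(max(inner, 0))
  }
  list(delta = delta, se = se_jack, se_delta_method = se_dm,
       ci = delta + c(-1, 1) * 1.96 * se_jack,
       loo = loo, score_within = sw, score_population = sp)
}

#' Heterogeneity of shrinkage across variants
#'
#' Per-variant Wald ratios \eqn{s_k = \beta_{P,k} / \beta_{W,k}} are
#' compared with the combined ratio \eqn{S = S_P / S_W} via
#' \deqn{Q = \sum_k w_k^2 (s_k - S)^2, \qquad
#'       w_k = \frac{1}{\sqrt{\sigma_{s_k}^2 + \sigma_S^2}}}
#' where \eqn{\sigma_{s_k}} is the delta-method standard error of the
#' per-variant ratio,
#' \eqn{\sigma_{s_k}^2 = (\sigma_{P,k}^2 + S^2 \sigma_{W,k}^2)/\beta_{W,k}^2},
#' and \eqn{\sigma_S} the delta-method SE of the combined ratio: both SEs in
#' the weight are expressed on the ratio scale (they reduce to the raw
#' \eqn{\sigma_{W,k}} and \eqn{S \sigma_{S}} forms when the within-sibship
#' effects are standardized to unit size), so that Q is a calibrated
#' Cochran-type statistic. Variants with weak within-sibship estimates
#' (|Z| <= \code{z_min}) are filtered before forming ratios. Q is referred
#' to a chi-square with M - 1 degrees of freedom; with a single usable
#' variant Q = 0, df = 0 and p is NA.
#'
#' @param beta_p,se_p,beta_w,se_w per-variant estimates from both models.
#' @param weights discovery betas (for the combined scores).
#' @param z_min within-model |Z| filter for ratio stability (default 2).
#' @return a list: Q, df, p, M (variants used), n_filtered.
#' @export
heterogeneity_Q <- function(beta_p, se_p, beta_w, se_w, weights,
                            z_min = 2) {
  ok <- is.finite(beta_w) & is.finite(se_w) & se_w > 0 &
    abs(beta_w / se_w) > z_min & is.finite(beta_p)
  n_filtered <- sum(!ok)
  if (n_filtered > 0) {
    message(sprintf("heterogeneity_Q: filtered %d variants with within-model |Z| <= %g",
                    n_filtered, z_min))
  }
  if (!any(ok)) stop("all variants filtered; cannot compute Q", call. = FALSE)
  bp <- beta_p[ok]; sp_ <- se_p[ok]; bw <- beta_w[ok]; sw_ <- se_w[ok]
  w <- weights[ok]
  M <- length(bp)
  s_k <- bp / bw
  score_p <- weighted_score(bp, sp_, w)
  score_w <- weighted_score(bw, sw_, w)
  S <- score_p$S / score_w$S
  sigma_S <- abs(S) * sqrt(score_p$sigma_S^2 / score_p$S^2 +
                             score_w$sigma_S^2 / score_w$S^2)
  if (M == 1L) {
    return(list(Q = 0, df = 0L, p = NA_real_, M = 1L,
                n_filtered = n_filtered))
  }
  var_sk <- (sp_^2 + S^2 * sw_^2) / bw^2
  w_k <- 1 / sqrt(var_sk + sigma_S^2)
  Q <- sum(w_k^2 * (s_k - S)^2)
  list(Q = Q, df = M - 1L, p = pchisq(Q, M - 1L, lower.tail = FALSE),
       M = M, n_filtered = n_filtered)
}

#' Cochran heterogeneity of shrinkage estimates across studies
#'
#' Standard inverse-variance Cochran Q over per-study shrinkage estimates.
#'
#' @param study_deltas,study_ses per-study estimates and standard errors.
#' @return a list: Q, df, p, pooled (inverse-variance pooled delta).
#' @export
study_level_heterogeneity <- function(study_deltas, study_ses) {
  if (length(study_deltas) < 2L) stop("need >= 2 studies", call. = FALSE)
  .check_pos(study_ses, "study_ses")
  w <- 1 / study_ses^2
  pooled <- sum(w * study_deltas) / sum(w)
  Q <- sum(w * (study_deltas - pooled)^2)
  df <- length(study_deltas) - 1L
  list(Q = Q, df = df, p = pchisq(Q, df, lower.tail = FALSE), pooled = pooled)
}

#' Full shrinkage analysis for one phenotype
#'
#' Aligns the two target tables to an instrument set, computes both weighted
#' scores, the shrinkage with its leave-one-out jackknife SE, and the
#' across-variant heterogeneity Q.
#'
#' @param pop_table,ws_table association tables (population and
#'   within-sibship) indexed by SNP.
#' @param instruments output of \code{\link{select_instruments}}.
#' @return a one-row \code{data.table}: delta, percent, se, ci_low, ci_high,
#'   p, M, Q, Q_df, Q_p, plus the scores as attributes.
#' @export
shrinkage_analysis <- function(pop_table, ws_table, instruments) {
  if (nrow(instruments) < 2L) stop("need >= 2 instruments", call. = FALSE)
  mp <- match(instruments$SNP, pop_table$SNP)
  mw <- match(instruments$SNP, ws_table$SNP)
  keep <- !is.na(mp) & !is.na(mw)
  inst <- instruments[keep]; mp <- mp[keep]; mw <- mw[keep]
  jk <- jackknife_se_shrinkage(ws_table$BETA[mw], ws_table$SE[mw],
                               pop_table$BETA[mp], pop_table$SE[mp],
                               inst$WEIGHT)
  Q <- tryCatch(
    heterogeneity_Q(pop_table$BETA[mp], pop_table$SE[mp],
                    ws_table$BETA[mw], ws_table$SE[mw], inst$WEIGHT),
    error = function(e) list(Q = NA_real_, df = NA_integer_, p = NA_real_,
                             M = 0L, n_filtered = nrow(inst)))
  zp <- .z_p(jk$delta, jk$se)
  out <- data.table::data.table(
    delta = jk$delta, percent = 100 * jk$delta, se = jk$se,
    ci_low = jk$ci[1L], ci_high = jk$ci[2L], p = zp$p, M = nrow(inst),
    Q = Q$Q, Q_df = Q$df, Q_p = Q$p
  )
  data.table::setattr(out, "score_within", jk$score_within)
  data.table::setattr(out, "score_population", jk$score_population)
  out
}
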