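# Compact LD score regression: SNP heritability, intercept and confounding
# ratio, cross-trait genetic correlation, and block-jackknife difference
# tests between population and within-sibship summary statistics.
#
# Under the model chi2_j ~ N h2 l_j / M + N a + 1, the slope of a weighted
# regression of chi2 on the LD score l_j estimates N h2 / M and the
# intercept estimates 1 + N a. Weights are 1/max(l_j, 1) with one
# reweighting iteration on the fitted values; standard errors come from a
# delete-one-block jackknife over contiguous (chromosome, position) blocks.
# Weights are computed once on the full data and held fixed across
# jackknife resamples.

.ldsc_weights <- function(x, y) {
  w1 <- 1 / x
  fit1 <- .wls_solve(.wls_sums(x, y, w1))
  fitted <- pmax(fit1[["intercept"]] + fit1[["slope"]] * x, 1e-8)
  # relative fitted values: the weight profile is invariant to rescaling all
  # chi-squares, so uniform shrinkage scales the fitted slope exactly
  rel <- fitted / mean(fitted)
  1 / (x * rel^2)
}

# Leave-one-block-out estimates of c(intercept, slope) given block sums.
.jackknife_fits <- function(block_sums) {
  tot <- colSums(block_sums)
  t(vapply(seq_len(nrow(block_sums)), function(b) {
    .wls_solve(as.list(tot - block_sums[b, ]))
  }, numeric(2)))
}

#' LD score regression fit for one GWAS
#'
#' Weighted regression of per-variant chi-square statistics on LD scores;
#' the slope scaled by M/N gives the SNP heritability and the intercept
#' measures confounding inflation (1 + N a). Standard errors are estimated
#' by a delete-one-block jackknife over \code{n_blocks} contiguous blocks in
#' (chromosome, position) order.
#'
#' @param chi2 per-variant chi-square (squared Z) statistics.
#' @param ldscore per-variant LD scores (floored at 1).
#' @param effective_n GWAS (effective) sample size N; a vector is averaged.
#' @param M number of variants the heritability is spread over (defaults to
#'   the number supplied).
#' @param n_blocks jackknife blocks (default 100; reduced with a warning if
#'   fewer than 2 variants per block are available).
#' @param chr,bp optional coordinates used to order variants into blocks.
#' @return an object of class \code{ldsc_fit}: h2, h2_se, intercept,
#'   intercept_se, mean_chi2, ratio (see \code{\link{ldsc_ratio}}), slope,
#'   N, M, n_blocks.
#' @export
ldsc_fit <- function(chi2, ldscore, effective_n, M = length(chi2),
                     n_blocks = 100L, chr = NULL, bp = NULL) {
  stopifnot(length(chi2) == length(ldscore))
  .check_pos(effective_n, "effective_n")
  N <- mean(effective_n)
  n <- length(chi2)
  if (n < 2L * n_blocks) {
    n_blocks <- max(2L, n %/% 2L)
    warning(sprintf("fewer variants than 2 * n_blocks; using %d blocks", n_blocks))
  }
  ord <- .genome_order(chr, bp, n)
  x <- pmax(ldscore, 1)[ord]
  y <- chi2[ord]
  w <- .ldsc_weights(x, y)
  blocks <- .block_index(n, n_blocks)
  bs <- .wls_block_sums(x, y, w, blocks)
  full <- .wls_solve(as.list(colSums(bs)))
  jk <- .jackknife_fits(bs)
  h2 <- full[["slope"]] * M / N
  fit <- list(
    h2 = h2,
    h2_se = jackknife_se(jk[, 2L] * M / N),
    intercept = full[["intercept"]],
    intercept_se = jackknife_se(jk[, 1L]),
    slope = full[["slope"]],
    mean_chi2 = mean(y),
    N = N, M = M, n_blocks = max(blocks)
  )
  class(fit) <- "ldsc_fit"
  fit$ratio <- ldsc_ratio(fit)
  fit
}

#' @export
print.ldsc_fit <- function(x, ...) {
  cat(sprintf("<ldsc_fit> h2 = %.4f (se %.4f), intercept = %.4f (se %.4f), mean chi2 = %.3f\n",
              x$h2, x$h2_se, x$intercept, x$intercept_se, x$mean_chi2))
  if (!is.na(x$ratio)) cat(sprintf("  confounding ratio = %.3f\n", x$ratio))
  invisible(x)
}

#' Confounding ratio of an LD score regression fit
#'
#' \deqn{ratio = \frac{intercept - 1}{\overline{\chi^2} - 1}}
#'
#' the proportion of the mean association signal attributable to confounding
#' rather than polygenicity. Clipped to [0, 1] with an attribute flag when
#' sampling noise pushes it outside; undefined (NA, flagged) when the mean
#' chi-square does not exceed 1.
#'
#' @param fit an \code{ldsc_fit}.
#' @return a single number with attribute \code{"flag"} in
#'   \code{c("ok", "clipped", "undefined")}.
#' @export
ldsc_ratio <- function(fit) {
  if (fit$mean_chi2 <= 1) {
    return(structure(NA_real_, flag = "undefined"))
  }
  raw <- (fit$intercept - 1) / (fit$mean_chi2 - 1)
  flag <- if (raw < 0 || raw > 1) "clipped" else "ok"
  structure(min(max(raw, 0), 1), flag = flag)
}

#' Expected within-sibship heritability under uniform shrinkage
#'
#' Uniform shrinkage of effect estimates by a factor (1 - k) multiplies Z
#' scores by (1 - k) and chi-square statistics by (1 - k)^2; with effective
#' sample sizes absorbing the power difference, the expected within-sibship
#' SNP heritability is \eqn{(1 - k)^2 h^2_{Pop}}.
#'
#' @param pop_fit population-model \code{ldsc_fit} or an h2 value.
#' @param k shrinkage coefficient in [0, 1].
#' @param ws_fit optional within-sibship fit; when supplied the observed h2
#'   and its gap from the expectation are returned too.
#' @return expected within-sibship h2 (with comparison fields if
#'   \code{ws_fit} was given).
#' @export
effective_n_adjustment_check <- function(pop_fit, k, ws_fit = NULL) {
  if (k < 0 || k > 1) stop("`k` must lie in [0, 1]", call. = FALSE)
  h2_pop <- if (inherits(pop_fit, "ldsc_fit")) pop_fit$h2 else pop_fit
  expected <- (1 - k)^2 * h2_pop
  if (is.null(ws_fit)) return(expected)
  h2_ws <- if (inherits(ws_fit, "ldsc_fit")) ws_fit$h2 else ws_fit
  list(expected = expected, observed = h2_ws, gap = h2_ws - expected)
}

#' Difference test between population and within-sibship heritabilities
#'
#' \deqn{h^2_{Diff} = h^2_{Pop} - h^2_{WS}}
#' with
#' \deqn{se = \sqrt{se_{Pop}^2 + se_{WS}^2 - 2\,Cor \cdot se_{Pop} se_{WS}}}
#' where Cor, the sampling correlation of the two estimates, is estimated by
#' the cross-GWAS LD score regression intercept between the two sets of
#' summary statistics.
#'
#' @param pop_fit,ws_fit \code{ldsc_fit} objects.
#' @param cross_intercept estimated Cor(h2_Pop, h2_WS), |value| < 1.
#' @return a list: diff, se, z, p.
#' @export
h2_difference_test <- function(pop_fit, ws_fit, cross_intercept = 0) {
  if (abs(cross_intercept) >= 1) stop("|cross_intercept| must be < 1", call. = FALSE)
  diff <- pop_fit$h2 - ws_fit$h2
  v <- pop_fit$h2_se^2 + ws_fit$h2_se^2 -
    2 * cross_intercept * pop_fit$h2_se * ws_fit$h2_se
  if (v <= 0) stop("implied difference variance is not positive", call. = FALSE)
  se <- sqrt(v)
  zp <- .z_p(diff, se)
  list(diff = diff, se = se, z = zp$z, p = zp$p)
}

# Shared machinery for rg: block sums for the three regressions (chi2 of
# each trait and the z1*z2 cross product) under one fixed weight vector, and
# an rg evaluator on any subset of blocks. Using the same weights for all
# three regressions makes rg(trait, itself) exactly 1.
.rg_engine <- function(z1, z2, ldscore, n1, n2, M, n_blocks, chr, bp) {
  n <- length(z1)
  ord <- .genome_order(chr, bp, n)
  x <- pmax(ldscore, 1)[ord]
  z1 <- z1[ord]; z2 <- z2[ord]
  w <- 1 / x
  blocks <- .block_index(n, n_blocks)
  bs1 <- .wls_block_sums(x, z1^2, w, blocks)
  bs2 <- .wls_block_sums(x, z2^2, w, blocks)
  bsc <- .wls_block_sums(x, z1 * z2, w, blocks)
  eval_rg <- function(drop_block = NULL) {
    pick <- function(bs) {
      tot <- colSums(bs)
      if (!is.null(drop_block)) tot <- tot - bs[drop_block, ]
      .wls_solve(as.list(tot))
    }
    f1 <- pick(bs1); f2 <- pick(bs2); fc <- pick(bsc)
    h1 <- f1[["slope"]] * M / n1
    h2 <- f2[["slope"]] * M / n2
    gencov <- fc[["slope"]] * M / sqrt(n1 * n2)
    rg <- if (is.na(h1) || is.na(h2) || h1 <= 0 || h2 <= 0) NA_real_ else
      gencov / sqrt(h1 * h2)
    c(rg = rg, h1 = h1, h2 = h2, gencov = gencov,
      cross_intercept = fc[["intercept"]])
  }
  list(eval_rg = eval_rg, n_blocks = max(blocks))
}

#' Cross-trait genetic correlation by LD score regression
#'
#' Regresses the product of the two traits' Z scores on LD scores; the slope
#' scaled by \eqn{M/\sqrt{N_1 N_2}} estimates the genetic covariance and the
#' intercept the sample-overlap term. The genetic correlation is the genetic
#' covariance over the geometric mean of the two heritabilities (all three
#' regressions share one weight vector, so a trait's correlation with itself
#' is exactly 1). Standard errors are delete-one-block jackknife over the
#' full rg computation; |rg| beyond 1.25 is flagged.
#'
#' @param z1,z2 allele-aligned per-variant Z scores of the two traits.
#' @param ldscore,M,n_blocks,chr,bp as in \code{\link{ldsc_fit}}.
#' @param n1,n2 (effective) sample sizes of the two GWAS.
#' @return an object of class \code{rg_result}: rg, se, z, p, h2_1, h2_2,
#'   gencov, cross_intercept, flag.
#' @export
cross_trait_rg <- function(z1, z2, ldscore, n1, n2, M = length(z1),
                           n_blocks = 100L, chr = NULL, bp = NULL) {
  stopifnot(length(z1) == length(z2), length(z1) == length(ldscore))
  eng <- .rg_engine(z1, z2, ldscore, n1, n2, M, n_blocks, chr, bp)
  full <- eng$eval_rg()
  flag <- "ok"
  if (is.na(full[["rg"]])) {
    flag <- "undefined_h2"
    se <- NA_real_; zp <- list(z = NA_real_, p = NA_real_)
  } else {
    loo <- vapply(seq_len(eng$n_blocks),
                  function(b) eng$eval_rg(b)[["rg"]], numeric(1))
    se <- jackknife_se(loo)
    zp <- .z_p(full[["rg"]], se)
    if (abs(full[["rg"]]) > 1.25) flag <- "out_of_range"
  }
  structure(list(rg = full[["rg"]], se = se, z = zp$z, p = zp$p,
                 h2_1 = full[["h1"]], h2_2 = full[["h2"]],
                 gencov = full[["gencov"]],
                 cross_intercept = full[["cross_intercept"]],
                 n_blocks = eng$n_blocks, flag = flag),
            class = "rg_result")
}

#' @export
print.rg_result <- function(x, ...) {
  cat(sprintf("<rg_result> rg = %.3f (se %.3f), p = %.3g [h2: %.3f, %.3f]\n",
              x$rg, x$se, x$p, x$h2_1, x$h2_2))
  invisible(x)
}

#' Block-jackknife difference between population and within-sibship rg
#'
#' Computes the genetic correlation between two traits from the population
#' summary statistics and from the within-sibship summary statistics,
#' removes each of \code{n_blocks} contiguous variant blocks in turn,
#' recomputes the difference \eqn{r_{g,Diff} = r_{g,Pop} - r_{g,WS}}, and
#' returns \eqn{se = \sqrt{(B-1)/B \sum_b (r_{g,Diff,b} - \mu)^2}} with a
#' two-sided p-value from the difference Z score.
#'
#' @param z1_pop,z2_pop,n1_pop,n2_pop population-model inputs.
#' @param z1_ws,z2_ws,n1_ws,n2_ws within-sibship inputs (same variants).
#' @param ldscore,M,n_blocks,chr,bp shared variant panel information.
#' @return a list: diff, se, z, p, rg_pop, rg_ws.
#' @export
rg_difference_jackknife <- function(z1_pop, z2_pop, n1_pop, n2_pop,
                                    z1_ws, z2_ws, n1_ws, n2_ws,
                                    ldscore, M = length(z1_pop),
                                    n_blocks = 100L,
                                    chr = NULL, bp = NULL) {
  if (length(z1_pop) < 200L) stop("need >= 200 variants", call. = FALSE)
  ep <- .rg_engine(z1_pop, z2_pop, ldscore, n1_pop, n2_pop, M, n_blocks, chr, bp)
  ew <- .rg_engine(z1_ws, z2_ws, ldscore, n1_ws, n2_ws, M, n_blocks, chr, bp)
  B <- min(ep$n_blocks, ew$n_blocks)
  diff_full <- ep$eval_rg()[["rg"]] - ew$eval_rg()[["rg"]]
  loo <- vapply(seq_len(B), function(b) {
    ep$eval_rg(b)[["rg"]] - ew$eval_rg(b)[["rg"]]
  }, numeric(1))
  se <- jackknife_se(loo)
  zp <- .z_p_degenerate(diff_full, se)
  list(diff = diff_full, se = se, z = zp$z, p = zp$p,
       rg_pop = ep$eval_rg()[["rg"]], rg_ws = ew$eval_rg()[["rg"]])
}
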