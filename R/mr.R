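# Inverse-variance-weighted Mendelian randomization from summary statistics,
# with a leave-one-variant-out jackknife test for the difference between the
# population-model and within-sibship-model estimates.

#' Inverse-variance-weighted Mendelian randomization
#'
#' \deqn{\beta_{MR} = \frac{\sum_k \beta_{Exp,k} \beta_{Out,k} / \sigma_{Out,k}^2}
#'                         {\sum_k \beta_{Exp,k}^2 / \sigma_{Out,k}^2}, \qquad
#'       se = \sqrt{\frac{1}{\sum_k \beta_{Exp,k}^2/\sigma_{Out,k}^2}}}
#'
#' the fixed-effect IVW combination of per-variant Wald ratios, using
#' first-order weights (the exposure standard errors are ignored). With a
#' single instrument this reduces to the Wald ratio
#' \eqn{\beta_{Out}/\beta_{Exp}}. An over-dispersion note is attached when
#' Cochran's Q across the Wald ratios clearly exceeds its degrees of
#' freedom.
#'
#' @param beta_exp exposure association estimates for the instruments.
#' @param beta_out,se_out outcome association estimates and standard errors
#'   for the same variants, aligned to the same effect alleles.
#' @param model optional tag ("population" or "within_sibship").
#' @return an object of class \code{mr_result}: beta, se, z, p,
#'   n_instruments, model, overdispersed (logical note from Cochran's Q).
#' @export
mr_ivw <- function(beta_exp, beta_out, se_out, model = NA_character_) {
  stopifnot(length(beta_exp) == length(beta_out),
            length(beta_exp) == length(se_out))
  keep <- is.finite(beta_exp) & is.finite(beta_out) & is.finite(se_out) & se_out > 0
  beta_exp <- beta_exp[keep]; beta_out <- beta_out[keep]; se_out <- se_out[keep]
  if (!length(beta_exp)) stop("zero usable instruments", call. = FALSE)
  if (all(beta_exp == 0)) stop("all exposure betas are zero", call. = FALSE)
  denom <- sum(beta_exp^2 / se_out^2)
  beta <- sum(beta_exp * beta_out / se_out^2) / denom
  se <- sqrt(1 / denom)
  zp <- .z_p(beta, se)
  # over-dispersion check on the Wald ratios (flag only; SE stays fixed-effect)
  overdispersed <- FALSE
  if (length(beta_exp) >= 2L) {
    wald <- beta_out / beta_exp
    w <- beta_exp^2 / se_out^2
    Q <- sum(w * (wald - beta)^2)
    df <- length(beta_exp) - 1L
    overdispersed <- pchisq(Q, df, lower.tail = FALSE) < 0.05 && Q > 2 * df
  }
  structure(list(beta = beta, se = se, z = zp$z, p = zp$p,
                 n_instruments = length(beta_exp), model = model,
                 overdispersed = overdispersed),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("<mr_result%s> beta = %.4f (se %.4f), p = %.3g, %d instruments\n",
              if (is.na(x$model)) "" else paste0(": ", x$model),
              x$beta, x$se, x$p, x$n_instruments))
  if (isTRUE(x$overdispersed)) cat("  note: Wald ratios over-dispersed relative to fixed-effect model\n")
  invisible(x)
}

#' Jackknife difference between population and within-sibship MR estimates
#'
#' \eqn{\beta_{MR,Diff} = \beta_{MR,Pop} - \beta_{MR,WS}} over the common
#' instrument set; each instrument is removed in turn, both IVW estimates
#' and their difference recomputed, and
#' \eqn{se = \sqrt{(n-1)/n \sum_k (\beta_{MR,Diff,k} - \mu)^2}} with a
#' two-sided p-value from the difference Z score.
#'
#' @param beta_exp_pop,beta_out_pop,se_out_pop population-model instrument
#'   estimates.
#' @param beta_exp_ws,beta_out_ws,se_out_ws within-sibship estimates for the
#'   same instruments, same order.
#' @return a list: diff, se, z, p, mr_pop, mr_ws (the full-sample fits).
#' @export
mr_difference_jackknife <- function(beta_exp_pop, beta_out_pop, se_out_pop,
                                    beta_exp_ws, beta_out_ws, se_out_ws) {
  n <- length(beta_exp_pop)
  if (n < 2L) stop("need >= 2 common instruments", call. = FALSE)
  stopifnot(length(beta_exp_ws) == n)
  mr_pop <- mr_ivw(beta_exp_pop, beta_out_pop, se_out_pop, "population")
  mr_ws <- mr_ivw(beta_exp_ws, beta_out_ws, se_out_ws, "within_sibship")
  loo <- vapply(seq_len(n), function(k) {
    mr_ivw(beta_exp_pop[-k], beta_out_pop[-k], se_out_pop[-k])$beta -
      mr_ivw(beta_exp_ws[-k], beta_out_ws[-k], se_out_ws[-k])$beta
  }, numeric(1))
  diff <- mr_pop$beta - mr_ws$beta
  se <- jackknife_se(loo)
  zp <- .z_p_degenerate(diff, se)
  list(diff = diff, se = se, z = zp$z, p = zp$p,
       mr_pop = mr_pop, mr_ws = mr_ws)
}
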