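# Internal helpers shared across modules: jackknife machinery, block
# assignment, weighted-regression sums and small argument checks.

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0) || any(x >= 1)) {
    stop(sprintf("`%s` must lie strictly inside (0, 1)", name), call. = FALSE)
  }
  invisible(x)
}

.check_pos <- function(x, name, strict = TRUE) {
  bad <- if (strict) any(!is.finite(x) | x <= 0) else any(!is.finite(x) | x < 0)
  if (!is.numeric(x) || bad) {
    stop(sprintf("`%s` must be %s", name,
                 if (strict) "positive and finite" else "nonnegative and finite"),
         call. = FALSE)
  }
  invisible(x)
}

#' Jackknife standard error from a vector of leave-one-out estimates
#'
#' Computes \code{sqrt((m - 1)/m * sum((est_k - mean(est))^2))}, the
#' delete-one (or delete-one-block) jackknife standard error used throughout
#' the shrinkage, genetic-correlation, Mendelian randomization and adaptation
#' difference tests.
#'
#' @param estimates numeric vector of leave-one-out (or leave-one-block-out)
#'   estimates of the statistic.
#' @return the jackknife standard error (a single number).
#' @examples
#' jackknife_se(c(0.5, 0.5, 0.5))  # identical estimates -> 0
#' @export
jackknife_se <- function(estimates) {
  estimates <- estimates[is.finite(estimates)]
  m <- length(estimates)
  if (m < 2L) stop("need at least 2 leave-one-out estimates", call. = FALSE)
  mu <- mean(estimates)
  sqrt((m - 1) / m * sum((estimates - mu)^2))
}

# Assign n ordered items to n_blocks contiguous blocks of (near-)equal size;
# n_blocks = n gives delete-one blocks (the leave-one-out limit).
.block_index <- function(n, n_blocks) {
  n_blocks <- max(1L, min(as.integer(n_blocks), n))
  sort(rep_len(seq_len(n_blocks), n))
}

# Ordering by (chromosome, position); falls back to input order when absent.
.genome_order <- function(chr, bp, n) {
  if (is.null(chr) || is.null(bp)) return(seq_len(n))
  order(chr, bp)
}

# Weighted simple linear regression y ~ 1 + x via sufficient statistics.
# Returns c(intercept, slope). Used by the LD score regressions so that
# block-jackknife resamples reduce to subtracting block sums.
.wls_sums <- function(x, y, w) {
  c(sw = sum(w), swx = sum(w * x), swy = sum(w * y),
    swxx = sum(w * x * x), swxy = sum(w * x * y))
}

.wls_solve <- function(s) {
  det <- s[["sw"]] * s[["swxx"]] - s[["swx"]]^2
  if (det <= 0) return(c(intercept = NA_real_, slope = NA_real_))
  slope <- (s[["sw"]] * s[["swxy"]] - s[["swx"]] * s[["swy"]]) / det
  intercept <- (s[["swy"]] - slope * s[["swx"]]) / s[["sw"]]
  c(intercept = intercept, slope = slope)
}

# Per-block sufficient statistics for .wls_solve; rows = blocks.
.wls_block_sums <- function(x, y, w, blocks) {
  cbind(sw = rowsum(w, blocks)[, 1L],
        swx = rowsum(w * x, blocks)[, 1L],
        swy = rowsum(w * y, blocks)[, 1L],
        swxx = rowsum(w * x * x, blocks)[, 1L],
        swxy = rowsum(w * x * y, blocks)[, 1L])
}

# Two-sided normal p-value from an estimate and its SE.
.z_p <- function(est, se) {
  z <- est / se
  list(z = z, p = 2 * pnorm(-abs(z)))
}

# As .z_p but defined in the degenerate jackknife limit: identical inputs
# give a zero estimate with zero resampling spread (no evidence against the
# null, p = 1), while a nonzero estimate with zero spread is conclusive.
.z_p_degenerate <- function(est, se) {
  if (is.finite(se) && se == 0) {
    return(list(z = if (est == 0) 0 else sign(est) * Inf,
                p = if (est == 0) 1 else 0))
  }
  .z_p(est, se)
}
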