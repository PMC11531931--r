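# MCMC convergence diagnostics: split-Rhat and effective sample size,
# computed from a draws matrix with one column per chain.

# split each chain in half, stack as extra chains
split_chains <- function(mat) {
  n <- nrow(mat)
  half <- n %/% 2L
  cbind(mat[seq_len(half), , drop = FALSE],
        mat[(n - half + 1L):n, , drop = FALSE])
}

#' Split-Rhat for one parameter
#'
#' Potential scale reduction factor computed on split chains; values near 1
#' indicate between-chain agreement.
#'
#' @param mat numeric matrix, iterations x chains.
#' @return scalar Rhat (NA for constant draws).
#' @export
split_rhat <- function(mat) {
  m <- split_chains(mat)
  n <- nrow(m); k <- ncol(m)
  if (n < 2L) return(NA_real_)
  W <- mean(apply(m, 2L, stats::var))
  if (!is.finite(W) || W == 0) return(NA_real_)
  B <- n * stats::var(colMeans(m))
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}

#' Effective sample size for one parameter
#'
#' Bulk ESS from combined split-chain autocorrelations, truncated by Geyer's
#' initial monotone positive-pair sequence.
#'
#' @param mat numeric matrix, iterations x chains.
#' @return scalar ESS (NA for constant draws).
#' @export
ess_bulk <- function(mat) {
  m <- split_chains(mat)
  n <- nrow(m); k <- ncol(m)
  if (n < 4L) return(NA_real_)
  W <- mean(apply(m, 2L, stats::var))
  if (!is.finite(W) || W == 0) return(NA_real_)
  B <- n * stats::var(colMeans(m))
  var_plus <- (n - 1) / n * W + B / n
  max_lag <- n - 1L
  acov <- sapply(seq_len(k), function(c) {
    a <- stats::acf(m[, c], lag.max = max_lag, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a
  })
  mean_acov <- rowMeans(acov)  # lag 0..max_lag
  rho <- 1 - (W - mean_acov[-1L]) / var_plus
  # pair sums, truncate at first negative pair, enforce monotone decrease
  npair <- length(rho) %/% 2L
  if (npair == 0L) return(k * n)
  psum <- rho[2 * seq_len(npair) - 1L] + rho[2 * seq_len(npair)]
  s <- 0
  prev <- Inf
  for (i in seq_len(npair)) {
    if (psum[i] < 0) break
    p <- min(psum[i], prev)
    s <- s + p
    prev <- p
  }
  tau <- 1 + 2 * s  # tau = 1 + 2 * sum of retained autocorrelations
  tau <- max(tau, 1 / log10(k * n + 10))
  min(k * n / tau, k * n * log10(k * n))
}

#' Convergence gate check
#'
#' Passes when every monitored parameter has split-Rhat at or below
#' `rhat_max` and an ESS ratio (ESS over retained post-warmup draws) at or
#' above `ess_ratio_min`.
#'
#' @param result a fitted [fit_gamma_multilevel()] object.
#' @param rhat_max maximum acceptable Rhat (default 1.01).
#' @param ess_ratio_min minimum acceptable ESS ratio (default 0.1).
#' @return object of class `convergence_report`: `pass` flag plus a table of
#'   offending parameters.
#' @export
check_convergence <- function(result, rhat_max = 1.01, ess_ratio_min = 0.1) {
  stopifnot(inherits(result, "gamma_glmm"))
  sm <- result$summary
  bad <- sm[!is.na(sm$rhat) & (sm$rhat > rhat_max | sm$ess_ratio < ess_ratio_min), ,
            drop = FALSE]
  structure(list(pass = nrow(bad) == 0L, failures = bad,
                 rhat_max = rhat_max, ess_ratio_min = ess_ratio_min,
                 max_rhat = max(sm$rhat, na.rm = TRUE),
                 min_ess_ratio = min(sm$ess_ratio, na.rm = TRUE)),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("Convergence: %s (max Rhat %.4f <= %.3g: %s; min ESS ratio %.3f >= %.3g: %s)\n",
              if (x$pass) "PASS" else "FAIL",
              x$max_rhat, x$rhat_max, x$max_rhat <= x$rhat_max,
              x$min_ess_ratio, x$ess_ratio_min, x$min_ess_ratio >= x$ess_ratio_min))
  if (nrow(x$failures)) {
    cat("offending parameters:\n")
    print(x$failures[, c("param", "rhat", "ess_ratio")], row.names = FALSE)
  }
  invisible(x)
}
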