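#' Sampler configuration for the multilevel Gamma regression
#'
#' Defaults mirror the published analysis settings (4 chains, 10,000
#' iterations, thinning 4); tests and desk-scale runs pass a reduced
#' configuration — convergence gates still apply either way.
#'
#' @param chains number of chains.
#' @param iter total iterations per chain (including warmup).
#' @param warmup warmup (adaptation) iterations per chain; discarded.
#' @param thin keep every `thin`-th post-warmup draw.
#' @param seed integer seed; chain c uses `seed + c`.
#' @param prior list of prior hyperparameters: `intercept_scale` (Student-t3
#'   scale on the intercept), `slope_sd` (normal sd on slopes), `sd_scale`
#'   (half-Student-t3 scale on group SDs), `shape_rate`/`shape_shape`
#'   (Gamma prior on the Gamma shape).
#' @return list of class `fit_config`.
#' @export
fit_config <- function(chains = 4, iter = 10000, warmup = floor(iter / 2), thin = 4,
                       seed = 1,
                       prior = list(intercept_scale = 2.5, slope_sd = 5,
                                    sd_scale = 2.5, shape_shape = 0.01,
                                    shape_rate = 0.01)) {
  if (warmup >= iter) stop("`warmup` must be smaller than `iter`")
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), thin = as.integer(thin),
                 seed = as.integer(seed), prior = prior),
            class = "fit_config")
}

# generic univariate slice sampler (Neal 2003, stepping out + shrinkage)
slice1 <- function(x0, logf, w = 1, max_steps = 50L, lower = -Inf, upper = Inf) {
  f0 <- logf(x0)
  if (!is.finite(f0)) stop("slice sampler started at zero-density point")
  z <- f0 - stats::rexp(1)
  u <- stats::runif(1)
  L <- x0 - w * u
  R <- L + w
  k <- max_steps
  while (k > 0L && L > lower && logf(L) > z) { L <- L - w; k <- k - 1L }
  k <- max_steps
  while (k > 0L && R < upper && logf(R) > z) { R <- R + w; k <- k - 1L }
  L <- max(L, lower); R <- min(R, upper)
  repeat {
    x1 <- stats::runif(1, L, R)
    if (logf(x1) >= z) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
    if (R - L < 1e-12) return(x0)
  }
}

log_half_t3 <- function(s, scale) -2 * log1p((s / scale)^2 / 3)

# one MCMC chain for: y ~ Gamma(nu, nu/mu), log mu = alpha + X beta + u[j] + v[t]
run_gamma_chain <- function(y, X, j, t, cfg, chain_id) {
  n <- length(y); p <- ncol(X)
  J <- max(j); Tn <- max(t)
  pr <- cfg$prior
  set.seed(cfg$seed + chain_id)

  alpha <- log(mean(y)) + stats::rnorm(1, 0, 0.1)
  beta <- stats::rnorm(p, 0, 0.1)
  u <- rep(0, J); v <- rep(0, Tn)
  sigma_u <- 0.5; sigma_v <- 0.5
  nu <- 2
  nj <- tabulate(j, J); nt <- tabulate(t, Tn)
  sly <- sum(log(y))

  eta_fix <- as.vector(X %*% beta) + alpha
  eta <- eta_fix + u[j] + v[t]

  scale_u <- 0.5; scale_v <- 0.5
  adapt_n <- 0L

  n_keep <- (cfg$iter - cfg$warmup) %/% cfg$thin
  mon <- matrix(NA_real_, n_keep, p + 4L)
  u_draws <- matrix(NA_real_, n_keep, J)
  v_draws <- matrix(NA_real_, n_keep, Tn)
  keep_i <- 0L

  for (it in seq_len(cfg$iter)) {
    ## intercept: likelihood collapses to O(1) in alpha
    eta_rest <- eta - alpha
    S <- sum(y * exp(-eta_rest))
    alpha <- slice1(alpha, function(a)
      -nu * (n * a + exp(-a) * S) - 2 * log1p((a / pr$intercept_scale)^2 / 3),
      w = 0.5)
    eta <- eta_rest + alpha

    ## slopes, one coordinate at a time
    for (k in seq_len(p)) {
      xk <- X[, k]
      eta_k <- eta - xk * beta[k]
      yk <- y * exp(-eta_k)
      sxk <- sum(xk)
      beta[k] <- slice1(beta[k], function(b)
        -nu * (b * sxk + sum(yk * exp(-xk * b))) - b^2 / (2 * pr$slope_sd^2),
        w = 0.5)
      eta <- eta_k + xk * beta[k]
    }

    ## unit intercepts: vectorized Metropolis, conditionally independent
    eps <- stats::rnorm(J) * scale_u
    w_row <- y * exp(-eta)
    Wj <- rowsum(w_row, j)[, 1]
    dll <- -nu * (nj * eps + Wj * (exp(-eps) - 1))
    ustar <- u + eps
    dlp <- (u^2 - ustar^2) / (2 * sigma_u^2)
    acc <- log(stats::runif(J)) < dll + dlp
    if (any(acc)) {
      u[acc] <- ustar[acc]
      eta <- eta + (eps * acc)[j]
    }
    acc_rate_u <- mean(acc)

    ## year intercepts
    eps_t <- stats::rnorm(Tn) * scale_v
    w_row <- y * exp(-eta)
    Wt <- rowsum(w_row, t)[, 1]
    dll <- -nu * (nt * eps_t + Wt * (exp(-eps_t) - 1))
    vstar <- v + eps_t
    dlp <- (v^2 - vstar^2) / (2 * sigma_v^2)
    acc_t <- log(stats::runif(Tn)) < dll + dlp
    if (any(acc_t)) {
      v[acc_t] <- vstar[acc_t]
      eta <- eta + (eps_t * acc_t)[t]
    }
    acc_rate_v <- mean(acc_t)

    if (it <= cfg$warmup) {
      adapt_n <- adapt_n + 1L
      gain <- 1 / sqrt(adapt_n)
      scale_u <- scale_u * exp(gain * (acc_rate_u - 0.44))
      scale_v <- scale_v * exp(gain * (acc_rate_v - 0.44))
    }

    ## ridge moves: shift mass between the intercept and each random-effect
    ## block (alpha + d, effects - d). The likelihood is invariant (every
    ## eta unchanged), so only the effect prior and intercept prior enter —
    ## this decorrelates alpha from the block means, which Gibbs alone
    ## traverses very slowly.
    Sv <- sum(v)
    d <- slice1(0, function(d)
      -(Tn * d^2 - 2 * d * Sv) / (2 * sigma_v^2) -
        2 * log1p(((alpha + d) / pr$intercept_scale)^2 / 3), w = 0.5)
    alpha <- alpha + d; v <- v - d
    Su <- sum(u)
    d <- slice1(0, function(d)
      -(J * d^2 - 2 * d * Su) / (2 * sigma_u^2) -
        2 * log1p(((alpha + d) / pr$intercept_scale)^2 / 3), w = 0.5)
    alpha <- alpha + d; u <- u - d

    ## group SDs: slice on log sigma
    ssu <- sum(u^2)
    sigma_u <- exp(slice1(log(sigma_u), function(ls) {
      s <- exp(ls)
      -J * ls - ssu / (2 * s^2) + log_half_t3(s, pr$sd_scale) + ls
    }, w = 0.7))
    ssv <- sum(v^2)
    sigma_v <- exp(slice1(log(sigma_v), function(ls) {
      s <- exp(ls)
      -Tn * ls - ssv / (2 * s^2) + log_half_t3(s, pr$sd_scale) + ls
    }, w = 0.7))

    ## Gamma shape: slice on log nu (likelihood is O(1) given eta sums)
    sum_eta <- sum(eta)
    S2 <- sum(y * exp(-eta))
    nu <- exp(slice1(log(nu), function(lnu) {
      nn <- exp(lnu)
      n * (nn * lnu - lgamma(nn)) + (nn - 1) * sly - nn * (sum_eta + S2) +
        (pr$shape_shape - 1) * lnu - pr$shape_rate * nn + lnu
    }, w = 0.5))

    if (it > cfg$warmup && (it - cfg$warmup) %% cfg$thin == 0L) {
      keep_i <- keep_i + 1L
      mon[keep_i, ] <- c(alpha, beta, sigma_u, sigma_v, nu)
      u_draws[keep_i, ] <- u
      v_draws[keep_i, ] <- v
    }
  }
  list(mon = mon, u = u_draws, v = v_draws)
}

#' Fit the multilevel Bayesian Gamma log-link regression
#'
#' Fits `response ~ covariates + (1 | unit) + (1 | year)` with a Gamma
#' likelihood (shape `nu`, mean `mu`, `log mu` linear) by MCMC: univariate
#' slice sampling for the intercept, slopes, group SDs and shape, and
#' vectorized Metropolis-within-Gibbs for the unit and year random
#' intercepts. Unit and year enter as two unnested levels. Priors are
#' weakly informative (Student-t(3, 0, 2.5) intercept and group SDs, wide
#' normal slopes, Gamma(0.01, 0.01) shape) and configurable via
#' [fit_config()].
#'
#' Covariates are used as supplied: apply [standardize_covariates()] (2-SD
#' scaling, training moments) beforehand when fitting observational panels.
#'
#' @param train data.frame with the response, covariate, unit and year
#'   columns.
#' @param covariates covariate column names (fixed-effect design).
#' @param response response column (strictly positive).
#' @param unit_col,year_col grouping columns.
#' @param config a [fit_config()].
#' @return object of class `gamma_glmm` with elements `summary` (posterior
#'   mean/sd/2.5/50/97.5 quantiles, Rhat, ESS and ESS ratio per monitored
#'   parameter), `draws` (all chains stacked), `u_draws`, `v_draws`,
#'   `unit_levels`, `year_levels`, `covariates`, `config`.
#' @export
fit_gamma_multilevel <- function(train,
                                 covariates = c("lcu", "no_hunt", "public_hunt",
                                                "deer_density_prev"),
                                 response = "min_deer_density",
                                 unit_col = "unit_id", year_col = "year_label",
                                 config = fit_config()) {
  stopifnot(is.data.frame(train))
  miss <- setdiff(c(covariates, response, unit_col, year_col), names(train))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  y <- train[[response]]
  if (any(!is.finite(y)) || any(y <= 0))
    stop("response must be strictly positive and finite (Gamma support)")
  X <- as.matrix(train[covariates])
  if (any(!is.finite(X))) stop("covariates contain missing/non-finite values")
  if (qr(cbind(1, X))$rank < ncol(X) + 1L) stop("singular fixed-effect design")
  unit_levels <- sort(unique(as.character(train[[unit_col]])))
  year_levels <- sort(unique(train[[year_col]]))
  j <- match(as.character(train[[unit_col]]), unit_levels)
  t <- match(train[[year_col]], year_levels)

  chains <- lapply(seq_len(config$chains), function(c)
    run_gamma_chain(y, X, j, t, config, c))

  par_names <- c("(Intercept)", covariates, "sigma_unit", "sigma_year", "shape")
  n_par <- length(par_names)
  n_keep <- nrow(chains[[1]]$mon)
  draws <- do.call(rbind, lapply(chains, `[[`, "mon"))
  colnames(draws) <- par_names
  u_draws <- do.call(rbind, lapply(chains, `[[`, "u"))
  v_draws <- do.call(rbind, lapply(chains, `[[`, "v"))

  sm <- data.frame(param = par_names,
                   mean = colMeans(draws),
                   sd = apply(draws, 2L, stats::sd),
                   q2.5 = apply(draws, 2L, stats::quantile, 0.025),
                   q50 = apply(draws, 2L, stats::quantile, 0.5),
                   q97.5 = apply(draws, 2L, stats::quantile, 0.975),
                   stringsAsFactors = FALSE)
  per_chain <- lapply(seq_len(n_par), function(k)
    sapply(chains, function(ch) ch$mon[, k]))
  sm$rhat <- vapply(per_chain, split_rhat, numeric(1))
  sm$ess <- vapply(per_chain, ess_bulk, numeric(1))
  sm$ess_ratio <- sm$ess / nrow(draws)
  rownames(sm) <- NULL

  structure(list(summary = sm, draws = draws, u_draws = u_draws, v_draws = v_draws,
                 unit_levels = unit_levels, year_levels = year_levels,
                 covariates = covariates, response = response,
                 unit_col = unit_col, year_col = year_col,
                 data = list(y = y, X = X, j = j, t = t),
                 config = config),
            class = "gamma_glmm")
}

#' @export
print.gamma_glmm <- function(x, ...) {
  cat(sprintf("Multilevel Gamma regression (log link): %d rows, %d units, %d years\n",
              length(x$data$y), length(x$unit_levels), length(x$year_levels)))
  cat(sprintf("%d chains x %d kept draws (iter %d, warmup %d, thin %d)\n",
              x$config$chains, nrow(x$draws) / x$config$chains,
              x$config$iter, x$config$warmup, x$config$thin))
  print(format(x$summary, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Penalized-likelihood fallback fit
#'
#' Non-Bayesian Gamma GLMM via `lme4::glmer` for quick point estimates;
#' posterior quantities (credibility intervals, Rhat, Bayesian R^2) require
#' the MCMC path.
#'
#' @inheritParams fit_gamma_multilevel
#' @return the fitted `glmerMod` object.
#' @export
fit_gamma_glmm_ml <- function(train,
                              covariates = c("lcu", "no_hunt", "public_hunt",
                                             "deer_density_prev"),
                              response = "min_deer_density",
                              unit_col = "unit_id", year_col = "year_label") {
  if (!requireNamespace("lme4", quietly = TRUE))
    stop("the fallback fit needs the lme4 package")
  if (any(train[[response]] <= 0)) stop("response must be strictly positive")
  fml <- stats::as.formula(paste(response, "~",
                                 paste(covariates, collapse = " + "),
                                 sprintf("+ (1 | %s) + (1 | %s)", unit_col, year_col)))
  lme4::glmer(fml, data = train, family = stats::Gamma(link = "log"))
}

#' Bayesian R-squared
#'
#' Per posterior draw, the variance of the fitted means over the variance of
#' the fitted means plus the model-based residual variance (for a Gamma
#' model, `mean(mu^2) / shape`); summarized by the posterior median.
#'
#' @param result a fitted `gamma_glmm`.
#' @param data optional data.frame to evaluate on; defaults to the training
#'   rows stored in the fit.
#' @return posterior median R^2 (numeric scalar) with the per-draw values in
#'   attribute `"draws"`.
#' @export
bayesian_r2 <- function(result, data = NULL) {
  stopifnot(inherits(result, "gamma_glmm"))
  if (is.null(data)) {
    X <- result$data$X; j <- result$data$j; t <- result$data$t
  } else {
    X <- as.matrix(data[result$covariates])
    j <- match(as.character(data[[result$unit_col]]), result$unit_levels)
    t <- match(data[[result$year_col]], result$year_levels)
  }
  S <- nrow(result$draws)
  p <- length(result$covariates)
  r2 <- numeric(S)
  for (s in seq_len(S)) {
    d <- result$draws[s, ]
    eta <- d[1] + X %*% d[2:(p + 1)]
    eta <- eta + ifelse(is.na(j), 0, result$u_draws[s, ][j])
    eta <- eta + ifelse(is.na(t), 0, result$v_draws[s, ][t])
    mu <- exp(eta)
    vfit <- stats::var(as.vector(mu))
    vres <- mean(mu^2) / d[["shape"]]
    r2[s] <- vfit / (vfit + vres)
  }
  out <- stats::median(r2)
  attr(out, "draws") <- r2
  out
}

#' Coefficient to proportional change in the response
#'
#' On the log link, a coefficient `beta` for a 2-SD-scaled covariate implies
#' a proportional change of `exp(|beta|) - 1` in minimum deer density when
#' the covariate moves from low to high, in the direction of `sign(beta)`.
#'
#' @param beta numeric vector of coefficients.
#' @return data.frame with columns `beta`, `direction` ("Increase",
#'   "Decrease" or "None") and `change`.
#' @export
coefficient_change <- function(beta) {
  if (any(!is.finite(beta))) stop("`beta` must be finite")
  data.frame(beta = beta,
             direction = ifelse(beta > 0, "Increase",
                                ifelse(beta < 0, "Decrease", "None")),
             change = exp(abs(beta)) - 1,
             stringsAsFactors = FALSE)
}

#' Held-out prediction error summary
#'
#' Point predictions are posterior-mean `mu`; random intercepts of unit or
#' year levels unseen in training are set to zero (population level), seen
#' levels use their posterior draws. Reports summary statistics of the
#' absolute differences between observed and predicted densities.
#'
#' @param result a fitted `gamma_glmm`.
#' @param test data.frame of held-out rows (same columns as training;
#'   covariates already standardized with the training parameters).
#' @param params optional named per-covariate standardization parameters (as
#'   from [standardize_covariates()]) to apply to raw test covariates.
#' @return object of class `prediction_summary` with fields `min`, `median`,
#'   `mean`, `p75`, `p95`, `max`, `n` and the per-row `abs_diff`.
#' @export
predict_and_summarize <- function(result, test, params = NULL) {
  stopifnot(inherits(result, "gamma_glmm"))
  truth <- test[[result$response]]
  if (any(!is.finite(truth)) || any(truth <= 0))
    stop("test rows must have strictly positive observed densities")
  if (!is.null(params))
    test <- standardize_covariates(test, result$covariates, params)$data
  X <- as.matrix(test[result$covariates])
  j <- match(as.character(test[[result$unit_col]]), result$unit_levels)
  t <- match(test[[result$year_col]], result$year_levels)
  p <- length(result$covariates)
  B <- result$draws[, 2:(p + 1), drop = FALSE]
  lin <- X %*% t(B)                       # m x S
  lin <- sweep(lin, 2L, result$draws[, 1], `+`)
  # random-effect contributions row-wise (m x S)
  m <- nrow(X); S <- nrow(result$draws)
  re <- matrix(0, m, S)
  seen_u <- which(!is.na(j))
  if (length(seen_u)) re[seen_u, ] <- t(result$u_draws[, j[seen_u], drop = FALSE])
  seen_t <- which(!is.na(t))
  if (length(seen_t)) re[seen_t, ] <- re[seen_t, ] + t(result$v_draws[, t[seen_t], drop = FALSE])
  pred <- rowMeans(exp(lin + re))
  ad <- abs(truth - pred)
  structure(list(min = min(ad), median = stats::median(ad), mean = mean(ad),
                 p75 = unname(stats::quantile(ad, 0.75)),
                 p95 = unname(stats::quantile(ad, 0.95)),
                 max = max(ad), n = length(ad),
                 abs_diff = ad, predicted = pred),
            class = "prediction_summary")
}

#' @export
print.prediction_summary <- function(x, ...) {
  cat(sprintf(paste0("Held-out |truth - prediction| (deer/km^2), n = %d:\n",
                     "  min %.4g | median %.4g | mean %.4g | p75 %.4g | p95 %.4g | max %.4g\n"),
              x$n, x$min, x$median, x$mean, x$p75, x$p95, x$max))
  invisible(x)
}
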