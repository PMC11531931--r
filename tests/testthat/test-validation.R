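test_that("2-SD standardization matches its definition and a hand computation", {
  x <- c(1, 2, 3, 4, 5)
  st <- standardize_2sd(x)
  s <- sd(x)  # sample sd = sqrt(2.5)
  expect_equal(st$scaled, (x - 3) / (2 * s))
  expect_equal(st$params$mean, 3)
  expect_equal(st$params$sd, s)
  # x = mean -> 0; x = mean + 2 sd -> 1
  expect_equal(apply_standardization(st$params$mean, st$params), 0)
  expect_equal(apply_standardization(st$params$mean + 2 * st$params$sd, st$params), 1)
  expect_error(standardize_2sd(rep(4, 10)), "constant")
  expect_error(standardize_2sd(3), "at least 2")
})

test_that("train/test split is seeded, partition-exact and sized correctly", {
  df <- data.frame(id = 1:10, x = rnorm(10))
  sp <- split_train_test(df, 0.8, seed = 42)
  expect_equal(nrow(sp$train), 8)
  expect_equal(nrow(sp$test), 2)
  expect_setequal(c(sp$train$id, sp$test$id), df$id)
  sp2 <- split_train_test(df, 0.8, seed = 42)
  expect_identical(sp$train$id, sp2$train$id)
  sp3 <- split_train_test(data.frame(id = 1:200), 0.8, seed = 1)
  sp4 <- split_train_test(data.frame(id = 1:200), 0.8, seed = 2)
  expect_false(identical(sp3$train$id, sp4$train$id))
  expect_error(split_train_test(df, 1.2), "train_frac")
})

test_that("coefficient_change computes exp(|beta|) - 1 with the sign as direction", {
  cc <- coefficient_change(c(0.344, -0.599, 0))
  expect_equal(round(cc$change, 3), c(0.411, 0.820, 0))
  expect_equal(cc$direction, c("Increase", "Decrease", "None"))
  expect_error(coefficient_change(NaN), "finite")
})

small_fit <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      pan <- simulate_density_panel(panel_params(), n_units = 60, n_years = 5, seed = 3)
      memo <<- list(panel = pan,
                    fit = fit_gamma_multilevel(pan,
                      config = fit_config(chains = 2, iter = 3000, warmup = 1500,
                                          thin = 2, seed = 9)))
    }
    memo
  }
})

test_that("the sampler recovers generating parameters on a moderate panel", {
  sf <- small_fit()
  rep <- recovery_report(panel_params(), sf$fit)
  expect_equal(nrow(rep), 8)  # intercept + 4 betas + 2 SDs + shape
  expect_equal(rep$truth[rep$param == "lcu"], 0.344)
  expect_true(all(rep$covered))
  # credibility intervals contain their posterior means
  sm <- sf$fit$summary
  expect_true(all(sm$mean >= sm$q2.5 & sm$mean <= sm$q97.5))
})

test_that("fit rejects non-positive responses and singular designs", {
  pan <- simulate_density_panel(panel_params(), n_units = 20, n_years = 3, seed = 5)
  pan$min_deer_density[1] <- 0
  expect_error(fit_gamma_multilevel(pan, config = fit_config(chains = 1, iter = 20,
                                                             warmup = 10)),
               "positive")
  pan2 <- simulate_density_panel(panel_params(), n_units = 20, n_years = 3, seed = 5)
  pan2$no_hunt <- pan2$lcu  # collinear
  expect_error(fit_gamma_multilevel(pan2, config = fit_config(chains = 1, iter = 20,
                                                              warmup = 10)),
               "singular")
})

test_that("convergence gates flag deliberately short chains and pass good ones", {
  sf <- small_fit()
  expect_true(check_convergence(sf$fit)$pass)

  pan <- simulate_density_panel(panel_params(), n_units = 30, n_years = 3, seed = 7)
  bad <- fit_gamma_multilevel(pan, config = fit_config(chains = 2, iter = 16,
                                                       warmup = 8, thin = 1, seed = 1))
  rep_bad <- check_convergence(bad)
  expect_false(rep_bad$pass)
  expect_gt(nrow(rep_bad$failures), 0)
  # degenerate ESS threshold disables the ESS gate
  rep_ess0 <- check_convergence(bad, rhat_max = Inf, ess_ratio_min = 0)
  expect_true(rep_ess0$pass)
})

test_that("Bayesian R2 stays in [0,1], approaches 1 in the noiseless limit, and drops under permutation", {
  sf <- small_fit()
  r2 <- bayesian_r2(sf$fit)
  draws <- attr(r2, "draws")
  expect_true(all(draws >= 0 & draws <= 1))

  # near-noiseless response (huge shape) -> R2 ~ 1
  quiet <- simulate_density_panel(panel_params(shape = 1e6), n_units = 40, n_years = 4,
                                  seed = 11)
  fit_q <- fit_gamma_multilevel(quiet, config = fit_config(chains = 2, iter = 700,
                                                           warmup = 350, thin = 1,
                                                           seed = 2))
  expect_gt(as.numeric(bayesian_r2(fit_q)), 0.98)

  # shuffling covariates against the response collapses toward the
  # random-effects-only baseline
  perm <- sf$panel
  set.seed(99)
  shuffle <- sample(nrow(perm))
  for (v in c("lcu", "no_hunt", "public_hunt", "deer_density_prev"))
    perm[[v]] <- perm[[v]][shuffle]
  fit_p <- fit_gamma_multilevel(perm, config = fit_config(chains = 2, iter = 700,
                                                          warmup = 350, thin = 1,
                                                          seed = 3))
  expect_lt(as.numeric(bayesian_r2(fit_p)), as.numeric(r2) - 0.2)
})

test_that("held-out prediction summaries are ordered and beat shuffled baselines in-sample", {
  sf <- small_fit()
  pan <- sf$panel
  ps_train <- predict_and_summarize(sf$fit, pan)
  expect_true(ps_train$min <= ps_train$median)
  expect_true(ps_train$median <= ps_train$p75)
  expect_true(ps_train$p75 <= ps_train$p95)
  expect_true(ps_train$p95 <= ps_train$max)
  expect_equal(ps_train$n, nrow(pan))

  # unseen units fall back to the population level and still predict sanely
  new <- pan[1:20, ]
  new$unit_id <- paste0("NEW-", seq_len(nrow(new)))
  ps_new <- predict_and_summarize(sf$fit, new)
  expect_true(is.finite(ps_new$median))
  # in-sample error should not exceed leave-out error for the same rows
  expect_lte(ps_train$median, ps_new$median + 1e-9)

  bad <- pan[1:3, ]; bad$min_deer_density <- c(1, -1, 2)
  expect_error(predict_and_summarize(sf$fit, bad), "positive")
})

test_that("a zero coefficient is covered by its credibility interval across replicates", {
  hits <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    p <- panel_params(beta = c(lcu = 0.5, no_hunt = 0, public_hunt = 0.1,
                               deer_density_prev = 0.6))
    pan <- simulate_density_panel(p, n_units = 40, n_years = 4, seed = 500 + r)
    fit <- fit_gamma_multilevel(pan, config = fit_config(chains = 2, iter = 600,
                                                         warmup = 300, thin = 1,
                                                         seed = 700 + r))
    sm <- fit$summary
    ci <- sm[sm$param == "no_hunt", c("q2.5", "q97.5")]
    if (ci$q2.5 <= 0 && 0 <= ci$q97.5) hits <- hits + 1L
  }
  expect_gte(hits, 0.9 * n_rep)
})

test_that("the lme4 fallback agrees with the Bayesian point estimates", {
  skip_if_not_installed("lme4")
  sf <- small_fit()
  ml <- fit_gamma_glmm_ml(sf$panel)
  b_ml <- lme4::fixef(ml)
  sm <- sf$fit$summary
  for (v in c("lcu", "no_hunt", "public_hunt", "deer_density_prev"))
    expect_lt(abs(unname(b_ml[[v]]) - sm$mean[sm$param == v]), 0.03)
})
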