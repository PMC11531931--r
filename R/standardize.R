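#' Two-standard-deviation standardization
#'
#' Centers and scales a covariate by subtracting its mean and dividing by
#' twice its (sample) standard deviation, which puts binary and continuous
#' predictors on comparable coefficient scales. The returned parameters are
#' reused on test rows via [apply_standardization()].
#'
#' @param values numeric vector with at least 2 values and positive sd.
#' @return list with `scaled` and `params` (a list of `mean` and `sd`).
#' @export
standardize_2sd <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values to standardize")
  m <- mean(values); s <- stats::sd(values)
  if (!is.finite(s) || s == 0) stop("cannot standardize a constant vector (sd = 0)")
  list(scaled = (values - m) / (2 * s), params = list(mean = m, sd = s))
}

#' Apply stored standardization parameters
#'
#' @param values numeric vector.
#' @param params `params` element from [standardize_2sd()].
#' @return `(values - mean) / (2 * sd)`.
#' @export
apply_standardization <- function(values, params) {
  (values - params$mean) / (2 * params$sd)
}

#' Standardize a set of covariate columns
#'
#' Estimates 2-SD standardization per column on `data` (or applies
#' previously estimated `params`) and returns the transformed data plus the
#' per-column parameters for reuse on held-out rows.
#'
#' @param data data.frame.
#' @param covariates column names to standardize.
#' @param params optional named list of per-column params to apply instead of
#'   estimating.
#' @return list with `data` and `params`.
#' @export
standardize_covariates <- function(data, covariates, params = NULL) {
  if (is.null(params)) {
    params <- list()
    for (v in covariates) {
      st <- standardize_2sd(data[[v]])
      data[[v]] <- st$scaled
      params[[v]] <- st$params
    }
  } else {
    for (v in covariates) data[[v]] <- apply_standardization(data[[v]], params[[v]])
  }
  list(data = data, params = params)
}

#' Seeded train/test split
#'
#' Partitions the rows into a training set of `floor(train_frac * n)` rows
#' and a test set of the remainder, reproducibly under `seed`.
#'
#' @param data data.frame.
#' @param train_frac training fraction in (0, 1); default 0.8.
#' @param seed integer seed.
#' @return list with `train` and `test` data.frames.
#' @export
split_train_test <- function(data, train_frac = 0.8, seed = 1) {
  n <- nrow(data)
  if (train_frac <= 0 || train_frac >= 1) stop("`train_frac` must be in (0, 1)")
  if (n < 5L) stop("need at least 5 rows to split")
  n_train <- floor(train_frac * n)
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = data[sort(idx), , drop = FALSE],
       test = data[setdiff(seq_len(n), idx), , drop = FALSE])
}
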