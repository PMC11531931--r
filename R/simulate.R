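#' Parameters for synthetic landscape generation
#'
#' The generator emulates a Midwestern agricultural mosaic on an NLCD-like
#' 30 m lattice: cultivated crops dominate, forest and wetland occur in
#' clusters, and a small developed/water fraction is present. Clustering is
#' produced by thresholding Gaussian-smoothed white noise at the class
#' proportion quantiles, so the expected patch diameter grows with
#' `cluster_cells`.
#'
#' @param nrow,ncol grid dimensions.
#' @param cell_size_m cell size (default 30 m).
#' @param proportions named numeric vector (names = class codes) summing to
#'   1; the default is an Illinois-like mix (55% row crops, 17% forest, 4%
#'   wetland, 11% developed/water, the rest grassland/pasture/shrub).
#' @param cluster_cells expected patch diameter in cells (0 = independent
#'   per-cell draws).
#' @param seed integer seed.
#' @return list of class `landscape_params`.
#' @export
landscape_params <- function(nrow = 300, ncol = 300, cell_size_m = 30,
                             proportions = c("11" = 0.02, "21" = 0.05, "22" = 0.04,
                                             "23" = 0.02, "24" = 0.01, "82" = 0.54,
                                             "81" = 0.06, "71" = 0.04, "52" = 0.01,
                                             "41" = 0.14, "42" = 0.01, "43" = 0.01,
                                             "90" = 0.03, "95" = 0.01, "31" = 0.01),
                             cluster_cells = 8, seed = 1) {
  if (nrow < 1 || ncol < 1) stop("grid dimensions must be >= 1")
  if (abs(sum(proportions) - 1) > 1e-8) stop("class proportions must sum to 1")
  if (any(proportions < 0)) stop("class proportions must be nonnegative")
  if (is.null(names(proportions))) stop("proportions must be named by class code")
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 cell_size_m = cell_size_m, proportions = proportions,
                 cluster_cells = cluster_cells, seed = as.integer(seed)),
            class = "landscape_params")
}

gauss_row_kernel <- function(n, sigma) {
  K <- exp(-outer(seq_len(n), seq_len(n), `-`)^2 / (2 * sigma^2))
  K / rowSums(K)
}

#' Generate a clustered synthetic land-cover raster
#'
#' Seeded and reproducible; empirical class proportions track the targets
#' (quantile thresholding makes them near-exact) and same-class spatial
#' autocorrelation increases with `cluster_cells`.
#'
#' @param params a [landscape_params()].
#' @return a [class_grid()].
#' @export
generate_landscape <- function(params = landscape_params()) {
  stopifnot(inherits(params, "landscape_params"))
  codes <- as.integer(names(params$proportions))
  pr <- as.numeric(params$proportions)
  nr <- params$nrow; nc <- params$ncol
  vals <- with_seed(params$seed, {
    if (params$cluster_cells <= 0) {
      matrix(sample(codes, nr * nc, replace = TRUE, prob = pr), nr, nc)
    } else {
      sigma <- params$cluster_cells / 2
      Z <- gauss_row_kernel(nr, sigma) %*% matrix(stats::rnorm(nr * nc), nr, nc) %*%
        t(gauss_row_kernel(nc, sigma))
      qs <- stats::quantile(Z, cumsum(pr)[-length(pr)])
      matrix(codes[findInterval(Z, qs) + 1L], nr, nc)
    }
  })
  class_grid(vals, cell_size_m = params$cell_size_m)
}

#' Generate nested rectangular spatial units over a grid
#'
#' Tiles the raster into TRS-like square sections (default 54 x 54 cells of
#' 30 m, i.e. 2.62 km^2 — a PLSS section is one square mile), groups them
#' into townships of `township_trs` x `township_trs` sections (6 x 6, the
#' PLSS convention) and townships into county blocks. Edge tiles may be
#' partial; nesting is exact (every child's cells are a subset of its
#' parent's). Unit areas are the tiled cell count times the cell area.
#'
#' @param grid a grid object; must be at least one TRS tile in each
#'   dimension.
#' @param trs_cells TRS tile edge, in cells.
#' @param township_trs township edge, in TRS tiles.
#' @param county_townships county edge, in townships.
#' @return a [spatial_units()] with explicit cell membership, rectangle
#'   geometries and a TRS -> township -> county parent map.
#' @export
generate_units <- function(grid, trs_cells = 54, township_trs = 6, county_townships = 2) {
  vals <- grid_values(grid)
  nr <- nrow(vals); nc <- ncol(vals); cs <- grid$cell_size_m
  if (nr < trs_cells || nc < trs_cells)
    stop("grid is smaller than one TRS tile")
  rows <- rep(seq_len(nr), times = nc)
  cols <- rep(seq_len(nc), each = nr)
  cell_km2 <- (cs / 1000)^2

  tile_index <- function(block_i, block_j, n_i) (block_j - 1L) * n_i + block_i
  lv <- list()
  ti <- ceiling(rows / trs_cells); tj <- ceiling(cols / trs_cells)
  n_ti <- ceiling(nr / trs_cells); n_tj <- ceiling(nc / trs_cells)
  lv$TRS <- list(i = ti, j = tj, ni = n_ti, nj = n_tj, edge = trs_cells)
  wi <- ceiling(ti / township_trs); wj <- ceiling(tj / township_trs)
  n_wi <- ceiling(n_ti / township_trs); n_wj <- ceiling(n_tj / township_trs)
  lv$TOWNSHIP <- list(i = wi, j = wj, ni = n_wi, nj = n_wj,
                      edge = trs_cells * township_trs)
  ci <- ceiling(wi / county_townships); cj <- ceiling(wj / county_townships)
  lv$COUNTY <- list(i = ci, j = cj, ni = ceiling(n_wi / county_townships),
                    nj = ceiling(n_wj / county_townships),
                    edge = trs_cells * township_trs * county_townships)

  prefix <- c(TRS = "TRS", TOWNSHIP = "TWN", COUNTY = "CTY")
  id_of <- function(level, i, j) sprintf("%s-r%02d-c%02d", prefix[[level]], i, j)

  membership <- list(); tables <- list(); geoms <- list()
  for (level in names(lv)) {
    L <- lv[[level]]
    idx <- tile_index(L$i, L$j, L$ni)
    membership[[level]] <- idx
    counts <- tabulate(idx, L$ni * L$nj)
    keep <- which(counts > 0L)
    bi <- ((keep - 1L) %% L$ni) + 1L
    bj <- ((keep - 1L) %/% L$ni) + 1L
    ids <- id_of(level, bi, bj)
    parent <- switch(level,
      TRS = id_of("TOWNSHIP", ceiling(bi / township_trs), ceiling(bj / township_trs)),
      TOWNSHIP = id_of("COUNTY", ceiling(bi / county_townships), ceiling(bj / county_townships)),
      COUNTY = rep(NA_character_, length(keep)))
    tables[[level]] <- data.frame(unit_id = ids, level = level,
                                  area_km2 = counts[keep] * cell_km2,
                                  parent_id = parent, stringsAsFactors = FALSE)
    # rectangle geometry, clipped to the grid extent
    for (k in seq_along(keep)) {
      r0 <- (bi[k] - 1L) * L$edge; r1 <- min(bi[k] * L$edge, nr)
      c0 <- (bj[k] - 1L) * L$edge; c1 <- min(bj[k] * L$edge, nc)
      x0 <- grid$origin[1] + c0 * cs; x1 <- grid$origin[1] + c1 * cs
      y0 <- grid$origin[2] - r0 * cs; y1 <- grid$origin[2] - r1 * cs
      geoms[[ids[k]]] <- list(cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1)))
    }
    # compact membership to kept-unit row indices
    membership[[level]] <- match(idx, keep)
  }
  spatial_units(do.call(rbind, tables), geoms = geoms,
                membership = membership, grid_dim = c(nr, nc))
}

#' True parameters for a synthetic deer-density panel
#'
#' Defaults are the posterior means of the published TRS-level validation
#' model (intercept -0.084; prior-year density 0.724, LCU 0.344, no-hunt
#' area 0.21, public hunting sites 0.075) with unit/year random-intercept
#' SDs of 0.3 and Gamma shape 5, so parameter-recovery runs exercise the
#' regime the real analysis operated in.
#'
#' @param alpha true intercept (log scale).
#' @param beta named true coefficient vector (names become panel columns).
#' @param sigma_unit,sigma_year random-intercept SDs (>= 0).
#' @param shape Gamma shape (> 0); larger = less noise around the mean.
#' @return list of class `panel_params`.
#' @export
panel_params <- function(alpha = -0.084,
                         beta = c(lcu = 0.344, no_hunt = 0.21, public_hunt = 0.075,
                                  deer_density_prev = 0.724),
                         sigma_unit = 0.3, sigma_year = 0.3, shape = 5) {
  if (shape <= 0) stop("`shape` must be positive")
  if (sigma_unit < 0 || sigma_year < 0) stop("group SDs must be >= 0")
  if (is.null(names(beta))) stop("`beta` must be named")
  structure(list(alpha = alpha, beta = beta, sigma_unit = sigma_unit,
                 sigma_year = sigma_year, shape = shape),
            class = "panel_params")
}

#' Simulate a Gamma deer-density panel with known parameters
#'
#' Generative mirror of the validation model: per row,
#' `mu = exp(alpha + X beta + u[unit] + v[year])` with
#' `u ~ N(0, sigma_unit^2)`, `v ~ N(0, sigma_year^2)`, and the response
#' drawn as `Gamma(shape, shape / mu)` (strictly positive). Covariates are
#' standard normal on the post-2-SD-scaling scale by default, so the true
#' coefficients are directly comparable to published magnitudes; an
#' `lcu_table` may replace the LCU covariate with pipeline output
#' (standardized internally).
#'
#' @param params a [panel_params()].
#' @param n_units,n_years panel dimensions (ignored for units when `units`
#'   is given).
#' @param seed integer seed.
#' @param units optional [spatial_units()]; its `level` units become the
#'   panel units.
#' @param level level to take from `units` (default "TRS").
#' @param lcu optional `lcu_table` giving a real LCU covariate per unit
#'   (recycled across years, 2-SD standardized).
#' @return data.frame with columns `unit_id`, `year_label`,
#'   `min_deer_density` and one column per coefficient; the generating
#'   truth (including drawn `u`, `v`) is attached as attribute `"truth"`.
#' @export
simulate_density_panel <- function(params = panel_params(), n_units = 500, n_years = 9,
                                   seed = 1, units = NULL, level = "TRS", lcu = NULL) {
  stopifnot(inherits(params, "panel_params"))
  if (!is.null(units)) {
    ids <- units$units$unit_id[units$units$level == level]
    if (!length(ids)) stop("no units at level ", level)
  } else {
    ids <- sprintf("U%04d", seq_len(n_units))
  }
  J <- length(ids); Tn <- n_years
  years <- 2000L + seq_len(Tn)
  with_seed(seed, {
    u <- stats::rnorm(J, 0, params$sigma_unit)
    v <- stats::rnorm(Tn, 0, params$sigma_year)
    df <- expand.grid(unit_id = ids, year_label = years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    n <- nrow(df)
    X <- matrix(stats::rnorm(n * length(params$beta)), n, length(params$beta),
                dimnames = list(NULL, names(params$beta)))
    if (!is.null(lcu) && "lcu" %in% colnames(X)) {
      raw <- lcu$lcu[match(df$unit_id, lcu$unit_id)]
      if (any(is.na(raw))) stop("lcu table does not cover every panel unit")
      X[, "lcu"] <- standardize_2sd(raw)$scaled
    }
    j <- match(df$unit_id, ids)
    t <- match(df$year_label, years)
    mu <- exp(params$alpha + as.vector(X %*% params$beta) + u[j] + v[t])
    df$min_deer_density <- stats::rgamma(n, shape = params$shape,
                                         rate = params$shape / mu)
    df <- cbind(df, as.data.frame(X))
    attr(df, "truth") <- c(unclass(params), list(u = u, v = v, seed = seed))
    df
  })
}

#' Parameter-recovery report
#'
#' One row per generating parameter (intercept, each coefficient, the two
#' group SDs and the Gamma shape) comparing the truth with the fitted
#' posterior mean and 95% credibility interval.
#'
#' @param true_params the [panel_params()] the panel was generated from.
#' @param fitted a [fit_gamma_multilevel()] result on that panel.
#' @return data.frame with columns `param`, `truth`, `posterior_mean`,
#'   `lower`, `upper`, `covered`.
#' @export
recovery_report <- function(true_params, fitted) {
  stopifnot(inherits(true_params, "panel_params"), inherits(fitted, "gamma_glmm"))
  if (!all(names(true_params$beta) %in% fitted$covariates))
    stop("fitted covariates do not match the generating coefficient names")
  truth <- c("(Intercept)" = true_params$alpha, true_params$beta,
             sigma_unit = true_params$sigma_unit,
             sigma_year = true_params$sigma_year,
             shape = true_params$shape)
  sm <- fitted$summary
  idx <- match(names(truth), sm$param)
  if (any(is.na(idx))) stop("parameter-name mismatch with the fitted summary")
  data.frame(param = names(truth), truth = unname(truth),
             posterior_mean = sm$mean[idx],
             lower = sm$q2.5[idx], upper = sm$q97.5[idx],
             covered = truth >= sm$q2.5[idx] & truth <= sm$q97.5[idx],
             row.names = NULL, stringsAsFactors = FALSE)
}
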