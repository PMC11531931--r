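#' Published Illinois validation coefficients
#'
#' Posterior summaries (mean, 95% credibility interval, direction and
#' printed proportional-change column) of the statewide Illinois LCU
#' validation regressions at the TRS, township and county levels, shipped
#' as reference inputs for the coefficient-change transform and for
#' parameter-recovery simulations that exercise the published regime.
#'
#' @param level optional filter: "TRS", "TOWNSHIP" or "COUNTY".
#' @return data.frame with columns `level`, `covariate`, `estimate`,
#'   `lower`, `upper`, `direction`, `change`.
#' @export
reference_coefficients <- function(level = NULL) {
  path <- system.file("extdata", "il_deer_regression_coefficients.csv",
                      package = "deerlcu", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(level)) {
    level <- match.arg(toupper(level), c("TRS", "TOWNSHIP", "COUNTY"))
    tab <- tab[tab$level == level, , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}
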