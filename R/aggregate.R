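#' Aggregate cell scores into per-unit LCU values
#'
#' The land cover utility (LCU) score of a unit is the sum of its member
#' cells' habitat quality scores divided by the unit's declared total area
#' (km^2) — a unitless "score per km^2". Cells belong to the unit containing
#' their center; units with no scored habitat get LCU 0. Years are kept as
#' separate rows, never averaged.
#'
#' @param scores a [score_grid()].
#' @param units a [spatial_units()].
#' @param membership optional membership list from [assign_cells_to_units()];
#'   computed from the grid geometry (or taken from the units object) when
#'   absent.
#' @param year_label year for the output rows; defaults to the score grid's.
#' @return data.frame of class `lcu_table` with columns `unit_id`, `level`,
#'   `year`, `lcu`, `score_sum`, `n_cells`, ordered by (level, unit_id, year).
#' @export
compute_lcu <- function(scores, units, membership = NULL, year_label = NULL) {
  stopifnot(inherits(scores, "score_grid"), inherits(units, "spatial_units"))
  if (any(units$units$area_km2 <= 0)) stop("unit with area_km2 <= 0")
  if (is.null(membership)) membership <- unit_membership(scores, units)
  if (is.null(year_label)) year_label <- scores$year_label
  s <- as.vector(scores$scores)
  out <- lapply(names(membership), function(level) {
    sel <- which(units$units$level == level)
    m <- membership[[level]]
    assigned <- !is.na(m)
    sums <- rep(0, length(sel))
    ncell <- rep(0L, length(sel))
    if (any(assigned)) {
      agg <- rowsum(s[assigned], m[assigned])
      idx <- as.integer(rownames(agg))
      sums[idx] <- agg[, 1]
      cnt <- table(m[assigned])
      ncell[as.integer(names(cnt))] <- as.integer(cnt)
    }
    data.frame(unit_id = units$units$unit_id[sel], level = level,
               year = rep(as.integer(year_label), length(sel)),
               lcu = sums / units$units$area_km2[sel],
               score_sum = sums, n_cells = ncell, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, out)
  tab <- tab[order(tab$level, tab$unit_id, tab$year), ]
  rownames(tab) <- NULL
  class(tab) <- c("lcu_table", "data.frame")
  tab
}

#' Write an LCU table to CSV
#'
#' Header `unit_id,level,year,lcu,score_sum,n_cells`, rows ordered by
#' (level, unit_id, year), values at full double precision.
#'
#' @param table an `lcu_table` (or compatible data.frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lcu_table <- function(table, path) {
  cols <- c("unit_id", "level", "year", "lcu", "score_sum", "n_cells")
  stopifnot(all(cols %in% names(table)))
  tab <- table[order(table$level, table$unit_id, table$year), cols]
  # %.17g guarantees an exact double round-trip through the text file
  tab$lcu <- sprintf("%.17g", tab$lcu)
  tab$score_sum <- sprintf("%.17g", tab$score_sum)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an LCU table written by [write_lcu_table()]
#'
#' @param path CSV path.
#' @return an `lcu_table` data.frame.
#' @export
read_lcu_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(unit_id = "character", level = "character",
                                        year = "integer", lcu = "numeric",
                                        score_sum = "numeric", n_cells = "integer"))
  class(tab) <- c("lcu_table", "data.frame")
  tab
}

#' Run the full raster-to-LCU pipeline
#'
#' Remaps a class grid to habitat groups, builds qualifying masks for both
#' groups (min-area filter + proximal inclusion), scores cells by the
#' distance bands, and aggregates to the supplied units.
#'
#' @param grid a [class_grid()].
#' @param units a [spatial_units()].
#' @param mapping a [class_mapping()].
#' @param min_area_km2 minimum qualifying patch area (km^2).
#' @param radius_m proximal-inclusion radius (m).
#' @return list with `habitat`, `masks`, `scores`, `lcu` (an `lcu_table`).
#' @export
lcu_pipeline <- function(grid, units, mapping = default_nlcd_mapping(),
                         min_area_km2 = 0.02, radius_m = 500) {
  habitat <- remap_to_habitat_groups(grid, mapping)
  m_sf <- qualifying_mask(habitat, HAB_SHELTER_FOOD, min_area_km2, radius_m)
  m_fo <- qualifying_mask(habitat, HAB_FOOD, min_area_km2, radius_m)
  sc <- score_grid(habitat, m_sf, m_fo)
  list(habitat = habitat, masks = list(shelter_food = m_sf, food = m_fo),
       scores = sc, lcu = compute_lcu(sc, units))
}
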