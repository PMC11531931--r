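#' Spatial unit set
#'
#' Holds the analysis units (section/TRS-, township- and county-level
#' polygons or cell masks) that raster scores are aggregated into. Each unit
#' has an id, a level, a positive area in km^2 and optionally a parent id
#' (TRS -> township -> county nesting). Geometry may be supplied as polygon
#' rings in the raster CRS, or as an explicit cell-membership map produced
#' by [generate_units()] / [assign_cells_to_units()].
#'
#' @param units data.frame with columns `unit_id`, `level` (one of "TRS",
#'   "TOWNSHIP", "COUNTY"), `area_km2`, and optionally `parent_id`.
#' @param geoms optional named list (by `unit_id`) of lists of rings; each
#'   ring is a two-column (x, y) matrix.
#' @param membership optional named list (by level) of integer vectors of
#'   length `prod(grid_dim)` mapping each cell (column-major) to the row
#'   index of its unit within that level (NA = unassigned).
#' @param grid_dim the (nrow, ncol) the membership vectors refer to.
#' @return object of class `spatial_units`.
#' @export
spatial_units <- function(units, geoms = NULL, membership = NULL, grid_dim = NULL) {
  stopifnot(is.data.frame(units), all(c("unit_id", "level", "area_km2") %in% names(units)))
  if (any(units$area_km2 <= 0)) stop("every unit must have area_km2 > 0")
  if (anyDuplicated(units[c("unit_id", "level")]))
    stop("duplicate (unit_id, level) pairs")
  if (!"parent_id" %in% names(units))
    units$parent_id <- rep(NA_character_, nrow(units))
  structure(list(units = units, geoms = geoms, membership = membership,
                 grid_dim = grid_dim),
            class = "spatial_units")
}

#' @export
print.spatial_units <- function(x, ...) {
  tab <- table(x$units$level)
  cat("<spatial_units>", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

grid_values <- function(grid) {
  if (inherits(grid, "class_grid")) grid$values
  else if (inherits(grid, "habitat_grid")) grid$groups
  else if (inherits(grid, "score_grid")) grid$scores
  else stop("not a grid object")
}

#' Even-odd point-in-polygon test
#'
#' Ray-casting with the even-odd rule over all rings (holes handled
#' naturally). Vectorized over points.
#'
#' @param px,py point coordinates.
#' @param rings list of two-column (x, y) ring matrices.
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, rings) {
  inside <- logical(length(px))
  for (ring in rings) {
    x <- ring[, 1]; y <- ring[, 2]
    nv <- length(x)
    if (x[1] == x[nv] && y[1] == y[nv]) nv <- nv - 1L  # drop closing vertex
    j <- nv
    for (i in seq_len(nv)) {
      crosses <- ((y[i] > py) != (y[j] > py)) &
        (px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i])
      inside <- xor(inside, crosses)
      j <- i
    }
  }
  inside
}

shoelace_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1L }
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' Assign raster cells to spatial units
#'
#' A cell belongs to the unit whose polygon contains its center. Centers
#' exactly on a shared edge are broken deterministically by testing the
#' point nudged a millionth of a cell down-left ("lower-left wins").
#' Cells falling in no unit are unassigned (NA). Errors if two units of one
#' level claim the same cell.
#'
#' @param grid a grid object (`class_grid`, `habitat_grid` or `score_grid`).
#' @param units a [spatial_units()] with polygon geometries.
#' @return named list (by level) of integer membership vectors, as stored in
#'   [spatial_units()].
#' @export
assign_cells_to_units <- function(grid, units) {
  stopifnot(inherits(units, "spatial_units"))
  vals <- grid_values(grid)
  nr <- nrow(vals); nc <- ncol(vals); cs <- grid$cell_size_m
  rows <- rep(seq_len(nr), times = nc)
  cols <- rep(seq_len(nc), each = nr)
  eps <- cs * 1e-6
  px <- grid$origin[1] + (cols - 0.5) * cs - eps
  py <- grid$origin[2] - (rows - 0.5) * cs - eps
  out <- list()
  for (level in unique(units$units$level)) {
    sel <- which(units$units$level == level)
    m <- rep(NA_integer_, nr * nc)
    for (k in seq_along(sel)) {
      uid <- units$units$unit_id[sel[k]]
      rings <- units$geoms[[uid]]
      if (is.null(rings)) stop("unit ", uid, " has no geometry")
      bb <- do.call(rbind, rings)
      cand <- which(px >= min(bb[, 1]) - eps & px <= max(bb[, 1]) &
                    py >= min(bb[, 2]) - eps & py <= max(bb[, 2]))
      if (!length(cand)) next
      hit <- cand[point_in_polygon(px[cand], py[cand], rings)]
      clash <- hit[!is.na(m[hit])]
      if (length(clash))
        stop("overlapping units at level ", level, ": cell claimed twice")
      m[hit] <- k
    }
    out[[level]] <- m
  }
  out
}

# membership lookup: use stored membership when it matches the grid, else PIP
unit_membership <- function(grid, units) {
  vals <- grid_values(grid)
  if (!is.null(units$membership) &&
      !is.null(units$grid_dim) && all(units$grid_dim == dim(vals))) {
    return(units$membership)
  }
  assign_cells_to_units(grid, units)
}

#' Read spatial units from GeoJSON
#'
#' Parses a FeatureCollection of Polygon/MultiPolygon features with
#' properties `unit_id`, `level` and optionally `area_km2` (computed from
#' the geometry — shoelace, outer ring minus holes, m^2 to km^2 — when
#' absent) and `parent_id`. Coordinates must be in the raster's projected
#' meter CRS.
#'
#' @param path path to a GeoJSON file.
#' @return a [spatial_units()].
#' @export
read_units_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection")
  rows <- list(); geoms <- list()
  for (f in gj$features) {
    p <- f$properties
    if (is.null(p$unit_id) || is.null(p$level))
      stop("every feature needs unit_id and level properties")
    geom <- f$geometry
    polys <- switch(geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      stop("unsupported geometry type: ", geom$type))
    rings <- list()
    area_m2 <- 0
    for (poly in polys) {
      for (j in seq_along(poly)) {
        ring <- do.call(rbind, lapply(poly[[j]], function(xy) c(xy[[1]], xy[[2]])))
        rings[[length(rings) + 1L]] <- ring
        a <- shoelace_area(ring)
        area_m2 <- area_m2 + if (j == 1L) a else -a
      }
    }
    area <- if (!is.null(p$area_km2)) as.numeric(p$area_km2) else area_m2 / 1e6
    rows[[length(rows) + 1L]] <- data.frame(
      unit_id = as.character(p$unit_id), level = as.character(p$level),
      area_km2 = area,
      parent_id = if (!is.null(p$parent_id)) as.character(p$parent_id) else NA_character_,
      stringsAsFactors = FALSE)
    geoms[[as.character(p$unit_id)]] <- rings
  }
  spatial_units(do.call(rbind, rows), geoms = geoms)
}

#' Write spatial units to GeoJSON
#'
#' @param units a [spatial_units()] with polygon geometries.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_units_geojson <- function(units, path) {
  feats <- lapply(seq_len(nrow(units$units)), function(i) {
    u <- units$units[i, ]
    rings <- units$geoms[[u$unit_id]]
    if (is.null(rings)) stop("unit ", u$unit_id, " has no geometry to write")
    coords <- lapply(rings, function(r) {
      r <- rbind(r, r[1, ])  # close ring
      lapply(seq_len(nrow(r)), function(k) c(r[k, 1], r[k, 2]))
    })
    list(type = "Feature",
         properties = list(unit_id = u$unit_id, level = u$level,
                           area_km2 = u$area_km2, parent_id = u$parent_id),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats), path,
                       auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}
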