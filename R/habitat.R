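#' Habitat-group codes
#'
#' Integer codes used in a [habitat_grid]: cells provide neither food nor
#' shelter (`HAB_NONE`), both shelter and food (`HAB_SHELTER_FOOD`: forests
#' and wetlands), or food only (`HAB_FOOD`: crops, pasture, grassland, shrub).
#'
#' @format Integer scalars.
#' @name habitat-codes
NULL

#' @rdname habitat-codes
#' @export
HAB_NONE <- 0L
#' @rdname habitat-codes
#' @export
HAB_SHELTER_FOOD <- 1L
#' @rdname habitat-codes
#' @export
HAB_FOOD <- 2L

#' Class-to-habitat-group mapping
#'
#' Declares which land-cover class codes provide shelter and food, food only,
#' and which classes (human development, open water) prohibit hunting. The
#' three habitat-relevant sets must be disjoint.
#'
#' @param shelter_food_classes integer codes mapped to `HAB_SHELTER_FOOD`.
#' @param food_classes integer codes mapped to `HAB_FOOD`.
#' @param no_hunt_classes integer codes counted as no-hunt land (need not be
#'   habitat; must not overlap either habitat set).
#' @return object of class `class_mapping`.
#' @export
class_mapping <- function(shelter_food_classes, food_classes, no_hunt_classes = integer()) {
  sf <- as.integer(shelter_food_classes); fo <- as.integer(food_classes)
  nh <- as.integer(no_hunt_classes)
  if (length(intersect(sf, fo)))
    stop("a class code appears in both the shelter/food and food sets: ",
         paste(intersect(sf, fo), collapse = ", "))
  if (length(intersect(nh, c(sf, fo))))
    stop("no-hunt classes must be disjoint from habitat classes")
  structure(list(shelter_food_classes = sf, food_classes = fo, no_hunt_classes = nh),
            class = "class_mapping")
}

#' Default NLCD habitat-group mapping
#'
#' The standard assignment of NLCD class codes: deciduous (41), evergreen
#' (42) and mixed (43) forest plus woody (90) and herbaceous (95) wetlands
#' provide shelter and food; shrub/scrub (52), grassland/herbaceous (71),
#' pasture/hay (81) and cultivated crops (82) provide food only. Developed
#' land (21-24) and open water (11) form the no-hunt set. Unlisted classes
#' (e.g. barren land, 31) are not deer habitat.
#'
#' @return a [class_mapping()].
#' @export
default_nlcd_mapping <- function() {
  class_mapping(shelter_food_classes = c(41L, 42L, 43L, 90L, 95L),
                food_classes = c(52L, 71L, 81L, 82L),
                no_hunt_classes = c(21L, 22L, 23L, 24L, 11L))
}

#' Remap land-cover classes to habitat groups
#'
#' Every cell whose class is in the mapping's shelter/food set becomes
#' `HAB_SHELTER_FOOD`, food set becomes `HAB_FOOD`; everything else —
#' including nodata and classes outside the mapping — becomes `HAB_NONE`.
#' Shape and georeference are preserved.
#'
#' @param grid a [class_grid()].
#' @param mapping a [class_mapping()]; defaults to [default_nlcd_mapping()].
#' @return object of class `habitat_grid` with fields `groups`,
#'   `cell_size_m`, `origin`, `year_label`.
#' @export
remap_to_habitat_groups <- function(grid, mapping = default_nlcd_mapping()) {
  stopifnot(inherits(grid, "class_grid"), inherits(mapping, "class_mapping"))
  groups <- matrix(HAB_NONE, nrow(grid$values), ncol(grid$values))
  groups[grid$values %in% mapping$shelter_food_classes] <- HAB_SHELTER_FOOD
  groups[grid$values %in% mapping$food_classes] <- HAB_FOOD
  storage.mode(groups) <- "integer"
  structure(list(groups = groups, cell_size_m = grid$cell_size_m,
                 origin = grid$origin, year_label = grid$year_label),
            class = "habitat_grid")
}

#' Construct a habitat grid directly from group codes
#'
#' Convenience constructor for tests and synthetic fixtures.
#'
#' @param groups integer matrix over `{HAB_NONE, HAB_SHELTER_FOOD, HAB_FOOD}`.
#' @inheritParams class_grid
#' @return a `habitat_grid`.
#' @export
habitat_grid <- function(groups, cell_size_m = 30,
                         origin = c(0, nrow(groups) * cell_size_m),
                         year_label = NA_integer_) {
  if (!is.matrix(groups)) stop("`groups` must be a matrix")
  if (!all(groups %in% c(HAB_NONE, HAB_SHELTER_FOOD, HAB_FOOD)))
    stop("`groups` may only contain the three habitat codes 0/1/2")
  storage.mode(groups) <- "integer"
  structure(list(groups = groups, cell_size_m = as.numeric(cell_size_m),
                 origin = as.numeric(origin), year_label = as.integer(year_label)),
            class = "habitat_grid")
}

#' @export
print.habitat_grid <- function(x, ...) {
  n <- length(x$groups)
  cat(sprintf("<habitat_grid> %d x %d, %g m cells | shelter/food %d, food %d, none %d\n",
              nrow(x$groups), ncol(x$groups), x$cell_size_m,
              sum(x$groups == HAB_SHELTER_FOOD), sum(x$groups == HAB_FOOD),
              sum(x$groups == HAB_NONE)))
  invisible(x)
}

#' No-hunt land area per spatial unit
#'
#' Total area (km^2) of cells whose class is in the mapping's no-hunt set
#' (human development or open water), per spatial unit: the count of no-hunt
#' cells whose centers fall in the unit times the cell area.
#'
#' @param grid a [class_grid()].
#' @param mapping a [class_mapping()] with a non-empty `no_hunt_classes` set.
#' @param units a [spatial_units()] object.
#' @return data.frame with columns `unit_id`, `level`, `no_hunt_km2`.
#' @export
no_hunt_area <- function(grid, mapping, units) {
  stopifnot(inherits(grid, "class_grid"), inherits(mapping, "class_mapping"))
  if (!inherits(units, "spatial_units") || nrow(units$units) == 0L)
    stop("`units` must be a non-empty spatial_units object")
  member <- unit_membership(grid, units)
  nh <- grid$values %in% mapping$no_hunt_classes
  cell_km2 <- (grid$cell_size_m / 1000)^2
  out <- lapply(names(member), function(level) {
    m <- member[[level]]
    counts <- tabulate_by_unit(which(nh), m, nlevels = sum(units$units$level == level))
    ids <- units$units$unit_id[units$units$level == level]
    data.frame(unit_id = ids, level = level, no_hunt_km2 = counts * cell_km2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# sum of 1 per cell in `cells` grouped by the unit slot of membership vector m
tabulate_by_unit <- function(cells, m, nlevels) {
  slot <- m[cells]
  slot <- slot[!is.na(slot)]
  tabulate(slot, nbins = nlevels)
}
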