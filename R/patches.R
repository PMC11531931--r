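#' Label contiguous habitat patches
#'
#' Finds the maximal 8-connected components ("patches") of cells belonging to
#' one habitat group. Contiguity means sharing a side or a corner. Labels are
#' 1..K in order of first (column-major) cell encountered; cells of other
#' groups get 0.
#'
#' @param grid a [habitat_grid()].
#' @param group `HAB_SHELTER_FOOD` or `HAB_FOOD`.
#' @return object of class `patch_labeling`: `labels` (integer matrix),
#'   `group`, `patch_cells` (per-label cell count), `patch_area_m2`,
#'   `cell_size_m`.
#' @export
label_patches <- function(grid, group) {
  stopifnot(inherits(grid, "habitat_grid"))
  if (!group %in% c(HAB_SHELTER_FOOD, HAB_FOOD))
    stop("`group` must be HAB_SHELTER_FOOD or HAB_FOOD")
  g <- grid$groups
  nr <- nrow(g); nc <- ncol(g)
  cells <- which(g == group)          # column-major linear indices
  labels <- matrix(0L, nr, nc)
  if (!length(cells)) {
    return(structure(list(labels = labels, group = group,
                          patch_cells = integer(), patch_area_m2 = numeric(),
                          cell_size_m = grid$cell_size_m),
                     class = "patch_labeling"))
  }
  vid <- integer(nr * nc)
  vid[cells] <- seq_along(cells)
  in_group <- vid > 0L
  row_of <- ((cells - 1L) %% nr) + 1L
  col_of <- ((cells - 1L) %/% nr) + 1L
  edges <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    rr <- row_of + off[1]; cc <- col_of + off[2]
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    if (!any(ok)) next
    nb <- (cc[ok] - 1L) * nr + rr[ok]
    hit <- in_group[nb]
    if (!any(hit)) next
    edges <- c(edges, rbind(vid[cells[ok]][hit], vid[nb][hit]))
  }
  gr <- igraph::make_graph(edges = edges, n = length(cells), directed = FALSE)
  memb <- igraph::components(gr)$membership
  # relabel in order of first appearance so labels are scan-order deterministic
  relab <- match(memb, unique(memb))
  labels[cells] <- relab
  counts <- tabulate(relab)
  structure(list(labels = labels, group = group, patch_cells = counts,
                 patch_area_m2 = counts * grid$cell_size_m^2,
                 cell_size_m = grid$cell_size_m),
            class = "patch_labeling")
}

#' @export
print.patch_labeling <- function(x, ...) {
  cat(sprintf("<patch_labeling> group %d: %d patches, %d cells\n",
              x$group, length(x$patch_cells), sum(x$patch_cells)))
  invisible(x)
}

#' Filter patches by minimum area
#'
#' Returns the labels of patches whose area meets the minimum-area rule
#' (closed inequality, area >= `min_area_km2`). With 900 m^2 cells and the
#' default 0.02 km^2 threshold the smallest qualifying patch is 23 cells.
#'
#' @param labeling a [label_patches()] result.
#' @param min_area_km2 minimum qualifying patch area in km^2 (default 0.02).
#' @return integer vector of qualifying patch labels.
#' @export
filter_min_area <- function(labeling, min_area_km2 = 0.02) {
  stopifnot(inherits(labeling, "patch_labeling"))
  if (!is.numeric(min_area_km2) || length(min_area_km2) != 1L || min_area_km2 < 0)
    stop("`min_area_km2` must be a nonnegative scalar")
  which(labeling$patch_area_m2 >= min_area_km2 * 1e6)
}

#' Qualifying habitat mask with proximal inclusion
#'
#' Cells of qualifying (>= min-area) patches are retained, together with
#' cells of the same habitat group — possibly in sub-threshold patches —
#' whose centers lie within `radius_m` (closed, Euclidean, center-to-center)
#' of any cell of a qualifying patch of that group. The default 500 m radius
#' is the radius of a circle with the average Illinois female home-range
#' area (0.99 km^2).
#'
#' @param grid a [habitat_grid()].
#' @param labeling a [label_patches()] result for one group.
#' @param qualifying_labels labels from [filter_min_area()].
#' @param radius_m proximal-inclusion radius in meters (default 500).
#' @return object of class `qualifying_mask`: logical matrices `qualifying`
#'   and `qualifying_patch_mask`, plus `group`, `cell_size_m`.
#' @export
include_proximal <- function(grid, labeling, qualifying_labels, radius_m = 500) {
  stopifnot(inherits(grid, "habitat_grid"), inherits(labeling, "patch_labeling"))
  if (radius_m < 0) stop("`radius_m` must be >= 0")
  qpm <- matrix(labeling$labels %in% qualifying_labels,
                nrow(labeling$labels), ncol(labeling$labels))
  in_group <- grid$groups == labeling$group
  if (any(qpm) && radius_m > 0) {
    d <- distance_transform(qpm, grid$cell_size_m)
    qualifying <- qpm | (in_group & d <= radius_m)
  } else {
    qualifying <- qpm
  }
  structure(list(qualifying = qualifying, qualifying_patch_mask = qpm,
                 group = labeling$group, cell_size_m = grid$cell_size_m,
                 radius_m = radius_m),
            class = "qualifying_mask")
}

#' One-call qualifying mask for a habitat group
#'
#' Chains [label_patches()], [filter_min_area()] and [include_proximal()].
#'
#' @inheritParams include_proximal
#' @param group habitat group code.
#' @param min_area_km2 minimum patch area (km^2).
#' @return a `qualifying_mask`.
#' @export
qualifying_mask <- function(grid, group, min_area_km2 = 0.02, radius_m = 500) {
  lab <- label_patches(grid, group)
  include_proximal(grid, lab, filter_min_area(lab, min_area_km2), radius_m)
}
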