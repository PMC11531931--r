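#' Quality score for shelter/food cells
#'
#' Band function over the distance (m) from a shelter/food cell to the
#' nearest qualifying food patch: up to 500 m scores 1, 500-700 m scores
#' 0.8, and beyond 700 m (including no food patch anywhere) scores 0.6, so
#' every shelter/food cell of a qualifying patch is retained — forest cores
#' are habitat even when far from forage.
#'
#' @param dist_m nonnegative distances (may be `Inf`); vectorized.
#' @return scores in `{1, 0.8, 0.6}`.
#' @export
score_shelter_food <- function(dist_m) {
  if (any(dist_m < 0, na.rm = TRUE)) stop("distances must be nonnegative")
  ifelse(dist_m <= 500, 1, ifelse(dist_m <= 700, 0.8, 0.6))
}

#' Quality score for food cells
#'
#' Band function over the distance (m) from a food cell to the nearest
#' qualifying shelter/food patch. Food value decays with distance from
#' cover and is 0 beyond 500 m: the cores of expansive fields are out of
#' reach of sheltering deer.
#'
#' @param dist_m nonnegative distances (may be `Inf`); vectorized.
#' @return scores in `{1, 0.8, 0.6, 0.4, 0.2, 0}`.
#' @export
score_food <- function(dist_m) {
  if (any(dist_m < 0, na.rm = TRUE)) stop("distances must be nonnegative")
  ifelse(dist_m < 200, 1,
  ifelse(dist_m <= 275, 0.8,
  ifelse(dist_m <= 350, 0.6,
  ifelse(dist_m <= 425, 0.4,
  ifelse(dist_m <= 500, 0.2, 0)))))
}

#' Distance from one group's habitat to the other group's qualifying patches
#'
#' Center-to-center Euclidean distances (m) from every cell to the nearest
#' cell of the target mask — by convention the `qualifying_patch_mask` of
#' the opposite habitat group (proximally-included stragglers are not
#' targets). All-`Inf` when the target mask is empty.
#'
#' @param qualifying a [qualifying_mask] for the group being scored (used
#'   for shape/cell-size checks).
#' @param targets logical matrix: qualifying-patch cells of the opposite group.
#' @return list of class `distance_grid`: `dist_m` matrix, `target_group`.
#' @export
distance_to_opposite <- function(qualifying, targets) {
  stopifnot(inherits(qualifying, "qualifying_mask"), is.matrix(targets))
  if (!all(dim(qualifying$qualifying) == dim(targets)))
    stop("mask and target grids have different shapes")
  d <- distance_transform(targets, qualifying$cell_size_m)
  structure(list(dist_m = d,
                 target_group = if (qualifying$group == HAB_FOOD) HAB_SHELTER_FOOD else HAB_FOOD),
            class = "distance_grid")
}

#' Score a habitat grid
#'
#' Scores every qualifying shelter/food cell by [score_shelter_food()] on
#' its distance to the nearest qualifying food patch, and every qualifying
#' food cell by [score_food()] on its distance to the nearest qualifying
#' shelter/food patch. Non-qualifying and non-habitat cells score 0 (the
#' grid keeps its shape).
#'
#' @param habitat a [habitat_grid()].
#' @param mask_shelter_food [qualifying_mask] for `HAB_SHELTER_FOOD`.
#' @param mask_food [qualifying_mask] for `HAB_FOOD`.
#' @return object of class `score_grid`: `scores` matrix, `cell_size_m`,
#'   `origin`, `year_label`.
#' @export
score_grid <- function(habitat,
                       mask_shelter_food = qualifying_mask(habitat, HAB_SHELTER_FOOD),
                       mask_food = qualifying_mask(habitat, HAB_FOOD)) {
  stopifnot(inherits(habitat, "habitat_grid"))
  scores <- matrix(0, nrow(habitat$groups), ncol(habitat$groups))
  sf_cells <- mask_shelter_food$qualifying
  if (any(sf_cells)) {
    d <- distance_transform(mask_food$qualifying_patch_mask, habitat$cell_size_m)
    scores[sf_cells] <- score_shelter_food(d[sf_cells])
  }
  fo_cells <- mask_food$qualifying
  if (any(fo_cells)) {
    d <- distance_transform(mask_shelter_food$qualifying_patch_mask, habitat$cell_size_m)
    scores[fo_cells] <- score_food(d[fo_cells])
  }
  structure(list(scores = scores, cell_size_m = habitat$cell_size_m,
                 origin = habitat$origin, year_label = habitat$year_label),
            class = "score_grid")
}

#' @export
print.score_grid <- function(x, ...) {
  cat(sprintf("<score_grid> %d x %d, score sum %.1f, %d scored cells\n",
              nrow(x$scores), ncol(x$scores), sum(x$scores), sum(x$scores > 0)))
  invisible(x)
}
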