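# Independent oracles, deliberately implemented with different algorithms
# than the package code paths they check.

# 8-connected component oracle: iterative min-label propagation to a
# fixpoint (vs the package's graph-component route). Returns an integer
# matrix of component ids (0 off-group), arbitrary labels.
oracle_label_8conn <- function(groups, code) {
  nr <- nrow(groups); nc <- ncol(groups)
  lab <- matrix(0L, nr, nc)
  in_g <- groups == code
  lab[in_g] <- which(in_g)
  pad <- function(m) rbind(0L, cbind(0L, m, 0L), 0L)
  repeat {
    p <- pad(lab)
    cand <- lab
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      nb <- p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc), drop = FALSE]
      take <- in_g & nb > 0L & (cand == 0L | nb < cand)
      cand[take] <- nb[take]
    }
    cand[!in_g] <- 0L
    if (identical(cand, lab)) break
    lab <- cand
  }
  lab
}

# partition of labeled cells as a canonical set-of-sets signature
partition_signature <- function(lab) {
  cells <- which(lab > 0L)
  if (!length(cells)) return(character())
  sets <- split(cells, lab[cells])
  sort(unname(vapply(sets, function(s) paste(sort(s), collapse = ","), character(1))))
}

# all-pairs minimum Euclidean center distance oracle (meters)
oracle_distance <- function(targets, cell_size_m = 30) {
  nr <- nrow(targets); nc <- ncol(targets)
  out <- matrix(Inf, nr, nc)
  tg <- which(targets)
  if (!length(tg)) return(out)
  tr <- ((tg - 1L) %% nr) + 1L
  tc <- ((tg - 1L) %/% nr) + 1L
  rows <- rep(seq_len(nr), times = nc)
  cols <- rep(seq_len(nc), each = nr)
  d2 <- outer(rows, tr, function(a, b) (a - b)^2) + outer(cols, tc, function(a, b) (a - b)^2)
  matrix(sqrt(apply(d2, 1L, min)) * cell_size_m, nr, nc)
}

# random three-code habitat grid
random_habitat <- function(nr, nc, p_sf = 0.3, p_food = 0.3, seed = 1, cell_size_m = 30) {
  set.seed(seed)
  g <- matrix(sample(c(0L, 1L, 2L), nr * nc, replace = TRUE,
                     prob = c(1 - p_sf - p_food, p_sf, p_food)), nr, nc)
  habitat_grid(g, cell_size_m = cell_size_m)
}

# square spatial unit covering cell rows/cols [r0,r1] x [c0,c1] of a grid
rect_unit <- function(grid, unit_id, level, r0, r1, c0, c1) {
  cs <- grid$cell_size_m
  x0 <- grid$origin[1] + (c0 - 1) * cs; x1 <- grid$origin[1] + c1 * cs
  y0 <- grid$origin[2] - (r0 - 1) * cs; y1 <- grid$origin[2] - r1 * cs
  list(unit_id = unit_id, level = level,
       area_km2 = (r1 - r0 + 1) * (c1 - c0 + 1) * (cs / 1000)^2,
       ring = cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1)))
}

units_from_rects <- function(rects) {
  tab <- do.call(rbind, lapply(rects, function(r)
    data.frame(unit_id = r$unit_id, level = r$level, area_km2 = r$area_km2,
               stringsAsFactors = FALSE)))
  geoms <- stats::setNames(lapply(rects, function(r) list(r$ring)),
                           vapply(rects, `[[`, "", "unit_id"))
  spatial_units(tab, geoms = geoms)
}
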