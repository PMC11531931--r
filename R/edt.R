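#' Exact Euclidean distance transform
#'
#' Distance (in meters) from every cell center to the nearest `TRUE` cell
#' center in `targets`, computed with the separable lower-envelope algorithm
#' (exact squared distances, two passes). Cells are `Inf` when the target
#' mask is empty. The transform is clipped to the grid extent: no padding or
#' wraparound.
#'
#' @param targets logical matrix of target cells.
#' @param cell_size_m cell edge length in meters.
#' @return numeric matrix of distances in meters (0 on targets).
#' @export
distance_transform <- function(targets, cell_size_m = 30) {
  stopifnot(is.matrix(targets), is.logical(targets))
  if (!any(targets)) {
    out <- matrix(Inf, nrow(targets), ncol(targets))
    return(out)
  }
  sqrt(edt_squared_cells(targets)) * cell_size_m
}

# squared distances in cell units
edt_squared_cells <- function(targets) {
  nr <- nrow(targets); nc <- ncol(targets)
  # pass 1: per column, distance in rows to nearest target in that column
  d <- matrix(Inf, nr, nc)
  d[targets] <- 0
  if (nr > 1L) {
    for (r in 2:nr) d[r, ] <- pmin(d[r, ], d[r - 1L, ] + 1)
    for (r in (nr - 1L):1L) d[r, ] <- pmin(d[r, ], d[r + 1L, ] + 1)
  }
  g <- d * d
  # pass 2: per row, 1D lower envelope over columns
  out <- matrix(Inf, nr, nc)
  for (r in 1:nr) out[r, ] <- dt1d(g[r, ])
  out
}

# 1D squared-distance transform of sampled function f (Inf allowed)
dt1d <- function(f) {
  n <- length(f)
  finite <- which(is.finite(f))
  if (!length(finite)) return(f)
  v <- integer(n)          # parabola locations
  z <- numeric(n + 1L)     # envelope breakpoints
  k <- 0L
  for (q in finite) {
    s <- 0
    repeat {
      if (k == 0L) break
      p <- v[k]
      s <- ((f[q] + q * q) - (f[p] + p * p)) / (2 * (q - p))
      if (s <= z[k]) k <- k - 1L else break
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- if (k == 1L) -Inf else s
    z[k + 1L] <- Inf
  }
  d <- numeric(n)
  j <- 1L
  for (q in 1:n) {
    while (z[j + 1L] < q) j <- j + 1L
    p <- v[j]
    d[q] <- (q - p)^2 + f[p]
  }
  d
}
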