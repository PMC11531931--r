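#' Categorical land-cover grid
#'
#' Light container for a single-band categorical raster on a regular square
#' lattice in a projected, meter-unit coordinate system. `values` is an
#' integer matrix in raster scan order (row 1 = northernmost row); `origin`
#' is the (x, y) of the grid's top-left corner.
#'
#' @param values integer matrix of land-cover class codes.
#' @param cell_size_m cell edge length in meters (default 30, the NLCD cell).
#' @param origin numeric length-2, (x, y) of the top-left corner.
#' @param nodata_code integer code treated as missing (default -9999L).
#' @param year_label integer year the raster represents.
#' @return An object of class `class_grid`.
#' @export
class_grid <- function(values, cell_size_m = 30, origin = c(0, nrow(values) * cell_size_m),
                       nodata_code = -9999L, year_label = NA_integer_) {
  if (!is.matrix(values) || nrow(values) < 1L || ncol(values) < 1L)
    stop("`values` must be a matrix with at least one cell")
  if (any(!is.finite(values)))
    stop("`values` must be finite")
  if (any(values != round(values)))
    stop("`values` must be integer-coded (found non-integer cell values)")
  if (!is.numeric(cell_size_m) || length(cell_size_m) != 1L || cell_size_m <= 0)
    stop("`cell_size_m` must be a positive scalar")
  storage.mode(values) <- "integer"
  structure(
    list(values = values, cell_size_m = as.numeric(cell_size_m),
         origin = as.numeric(origin), nodata_code = as.integer(nodata_code),
         year_label = as.integer(year_label)),
    class = "class_grid")
}

#' @export
print.class_grid <- function(x, ...) {
  cat(sprintf("<class_grid> %d x %d cells, %g m cells, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cell_size_m, x$origin[1], x$origin[2]))
  tab <- table(x$values)
  cat("  classes:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Read an ESRI ASCII grid
#'
#' Parses the plain-text grid dialect (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, optional `NODATA_value` header, then rows from
#' north to south). Values may be integer or floating point; use
#' [read_landcover_raster()] when an integer land-cover band is required.
#'
#' @param path path to an ASCII grid file.
#' @return list with `values` (numeric matrix), `cell_size_m`, `origin`
#'   (top-left corner), `nodata_code`.
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^[[:space:]]*[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(parts) != 2L) stop("malformed header line: ", lines[i])
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("ASCII grid header must declare ncols, nrows and cellsize")
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  if (!is.finite(hdr$cellsize) || hdr$cellsize <= 0) stop("degenerate cellsize")
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               what = numeric(), quiet = TRUE)
  if (length(vals) != nr * nc)
    stop(sprintf("expected %d values, found %d", nr * nc, length(vals)))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else 0
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else 0
  list(values = m, cell_size_m = hdr$cellsize,
       origin = c(xll, yll + nr * hdr$cellsize),
       nodata_code = if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999)
}

#' Write a matrix as an ESRI ASCII grid
#'
#' @param values numeric or integer matrix (row 1 = north).
#' @param path output path.
#' @param cell_size_m cell size in meters.
#' @param origin top-left corner (x, y).
#' @param nodata_code NODATA_value header entry.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(values, path, cell_size_m = 30,
                             origin = c(0, nrow(values) * cell_size_m),
                             nodata_code = -9999) {
  nr <- nrow(values); nc <- ncol(values)
  hdr <- c(sprintf("ncols %d", nc),
           sprintf("nrows %d", nr),
           sprintf("xllcorner %.10g", origin[1]),
           sprintf("yllcorner %.10g", origin[2] - nr * cell_size_m),
           sprintf("cellsize %.10g", cell_size_m),
           sprintf("NODATA_value %.10g", nodata_code))
  body <- apply(values, 1L, function(r) paste(format(r, trim = TRUE, scientific = FALSE),
                                              collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a categorical land-cover raster
#'
#' Reads an ASCII-grid land-cover file into a [class_grid()]. Errors if the
#' band contains non-integer values (land-cover codes are categorical).
#'
#' @param path path to an ASCII grid.
#' @param year_label optional year to attach.
#' @return a `class_grid`.
#' @export
read_landcover_raster <- function(path, year_label = NA_integer_) {
  g <- read_ascii_grid(path)
  if (any(g$values != round(g$values)))
    stop("land-cover raster must be integer-coded; found a floating-point band")
  class_grid(g$values, cell_size_m = g$cell_size_m, origin = g$origin,
             nodata_code = as.integer(g$nodata_code), year_label = year_label)
}

#' Write a class or habitat grid to an ASCII raster
#'
#' @param grid a `class_grid` or `habitat_grid`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landcover_raster <- function(grid, path) {
  vals <- if (inherits(grid, "habitat_grid")) grid$groups else grid$values
  write_ascii_grid(vals, path, cell_size_m = grid$cell_size_m, origin = grid$origin,
                   nodata_code = if (is.null(grid$nodata_code)) -9999 else grid$nodata_code)
}
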