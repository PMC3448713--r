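#' Gridded coastal raster
#'
#' All spatial layers in an analysis live on one uniform grid: a numeric
#' matrix whose first row is the northern edge, a cell size in km, the (x, y)
#' position of the top-left *outer corner* in km, and a logical validity mask.
#' Values at invalid cells are stored as `NA` and excluded from every
#' statistic. Cell coordinates are 1-based `(row, col)` with row 1 at the top;
#' values are attributed to cell centres.
#'
#' @param values numeric matrix (row 1 = top/north).
#' @param cell_size edge length of a cell in km (> 0).
#' @param origin numeric length-2, (x, y) of the top-left outer corner in km.
#' @param valid logical matrix of the same dimension; defaults to
#'   `!is.na(values)`.
#' @return an object of class `sea_raster`.
#' @export
sea_raster <- function(values, cell_size = 1, origin = c(0, 0), valid = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number")
  if (is.null(valid)) valid <- !is.na(values)
  valid <- as.matrix(valid)
  if (!identical(dim(valid), dim(values)))
    stop("valid mask dimensions do not match values")
  values[!valid] <- NA_real_
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin)[1:2], valid = valid),
    class = "sea_raster")
}

#' @export
dim.sea_raster <- function(x) dim(x$values)

#' @export
print.sea_raster <- function(x, ...) {
  v <- x$values[x$valid]
  cat(sprintf("<sea_raster> %d x %d cells, %.3g km cell size, %d valid\n",
              nrow(x$values), ncol(x$values), x$cell_size, sum(x$valid)))
  if (length(v))
    cat(sprintf("  values: [%.4g, %.4g], mean %.4g\n",
                min(v), max(v), mean(v)))
  invisible(x)
}

#' Test that two rasters share one grid geometry
#'
#' Layers of one analysis must agree in extent, cell size, origin and
#' validity mask.
#'
#' @param a,b `sea_raster` objects.
#' @param check_mask also require identical validity masks (default TRUE).
#' @export
same_geometry <- function(a, b, check_mask = TRUE) {
  ok <- identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$origin, b$origin))
  if (ok && check_mask) ok <- identical(a$valid, b$valid)
  ok
}

stopifnot_same_geometry <- function(a, b, what = "rasters") {
  if (!same_geometry(a, b)) stop(sprintf("geometry mismatch between %s", what))
  invisible(TRUE)
}

#' Cell-centre coordinates
#'
#' @param r a `sea_raster`.
#' @param rows,cols integer vectors (recycled pairwise).
#' @return data.frame with columns `x`, `y` in km.
#' @export
cell_centers <- function(r, rows, cols) {
  data.frame(
    x = r$origin[1] + (cols - 0.5) * r$cell_size,
    y = r$origin[2] - (rows - 0.5) * r$cell_size)
}

#' Construct a raster sharing geometry with a template
#'
#' @param template a `sea_raster` supplying geometry and mask.
#' @param values matrix of new values (same dimension).
#' @export
raster_like <- function(template, values) {
  sea_raster(values, template$cell_size, template$origin, template$valid)
}

#' Read and write ESRI ASCII grids
#'
#' Plain-text raster interchange: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows of
#' values from north to south. Invalid cells are written as the NODATA value.
#' GeoTIFF output is not provided (no raster/GDAL binding in the supported
#' dependency set); the ASCII grid carries the identical information.
#'
#' @param r a `sea_raster`.
#' @param path file path.
#' @param nodata sentinel for invalid cells (default -9999).
#' @return `write_ascii_grid` returns `path` invisibly; `read_ascii_grid`
#'   returns a `sea_raster`.
#' @export
write_ascii_grid <- function(r, path, nodata = -9999) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", r$origin[1]),
    sprintf("yllcorner %.10g", r$origin[2] - nr * r$cell_size),
    sprintf("cellsize %.10g", r$cell_size),
    sprintf("NODATA_value %.10g", nodata))
  vals <- r$values
  vals[!r$valid] <- nodata
  body <- apply(vals, 1L, function(row) paste(format(row, trim = TRUE, digits = 10),
                                              collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[`, "", 1L))
  vals <- as.numeric(vapply(hdr, `[`, "", 2L))
  h <- stats::setNames(vals, keys)
  nc <- as.integer(h[["ncols"]]); nr <- as.integer(h[["nrows"]])
  body <- lines[-(1:6)]
  body <- body[nzchar(trimws(body))]
  m <- do.call(rbind, lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  if (!identical(dim(m), c(nr, nc))) stop("grid body does not match header dimensions")
  nodata <- h[["nodata_value"]]
  valid <- m != nodata
  m[!valid] <- NA_real_
  origin <- c(h[["xllcorner"]], h[["yllcorner"]] + nr * h[["cellsize"]])
  sea_raster(m, h[["cellsize"]], origin, valid)
}

#' Summary statistics over valid cells
#'
#' @param r a `sea_raster`.
#' @export
valid_values <- function(r) r$values[r$valid]
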