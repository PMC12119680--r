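#' Georeferenced raster grid
#'
#' A minimal planar raster container: a numeric, integer, logical or
#' character matrix plus a pixel size and the planar coordinates of the
#' lower-left corner. Row 1 of the matrix is the *top* row of the grid
#' (map orientation), matching the row order of ASCII grid files.
#'
#' @param values matrix of cell values; row 1 is the northernmost row.
#' @param pixel_size cell edge length in metres (> 0).
#' @param origin numeric length-2, planar (x, y) of the lower-left corner
#'   of the grid in metres.
#' @param nodata value standing for missing cells when written to disk.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, pixel_size, origin = c(0, 0), nodata = -9999) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number")
  if (length(origin) != 2L) stop("`origin` must have length 2")
  structure(
    list(values = values, pixel_size = as.numeric(pixel_size),
         origin = as.numeric(origin), nodata = nodata),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("raster_grid: %d rows x %d cols, pixel %g m, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$pixel_size,
              x$origin[1], x$origin[2]))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' Planar coordinates of pixel centres
#'
#' @param grid a [raster_grid()].
#' @return A two-column matrix (x, y) in matrix element order
#'   (column-major over `grid$values`).
#' @export
pixel_centres <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values); px <- grid$pixel_size
  col <- rep(seq_len(nc), each = nr)
  row <- rep(seq_len(nr), times = nc)
  cbind(x = grid$origin[1] + (col - 0.5) * px,
        y = grid$origin[2] + (nr - row + 0.5) * px)
}

rasters_aligned <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$pixel_size, b$pixel_size)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

#' Write a raster as an Esri ASCII grid
#'
#' Plain-text interchange format readable by standard GIS tools.
#' Character-valued grids are written through an integer code table
#' stored in a side-car `<file>.levels` file.
#'
#' @param grid a [raster_grid()].
#' @param file output path (conventionally `.asc`).
#' @export
write_ascii_grid <- function(grid, file) {
  v <- grid$values
  levels_file <- NULL
  if (is.character(v)) {
    lev <- sort(unique(as.vector(v[!is.na(v)])))
    codes <- matrix(match(v, lev), nrow(v))
    levels_file <- paste0(file, ".levels")
    writeLines(lev, levels_file)
    v <- codes
  }
  v[is.na(v)] <- grid$nodata
  if (is.logical(v)) storage.mode(v) <- "integer"
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", grid$origin[1]),
    sprintf("yllcorner %.10g", grid$origin[2]),
    sprintf("cellsize %.10g", grid$pixel_size),
    sprintf("NODATA_value %.10g", as.numeric(grid$nodata))
  )
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read an Esri ASCII grid
#'
#' @param file path written by [write_ascii_grid()] or any conforming tool.
#' @return A [raster_grid()]. If a `<file>.levels` side-car exists the
#'   integer codes are mapped back to character labels.
#' @export
read_ascii_grid <- function(file) {
  hdr <- readLines(file, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  key <- tolower(kv[, 1]); val <- as.numeric(kv[, 2])
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% key)) stop("malformed ASCII grid header in ", file)
  g <- function(k) val[match(k, key)]
  v <- as.matrix(utils::read.table(file, skip = 6L))
  dimnames(v) <- NULL
  stopifnot(nrow(v) == g("nrows"), ncol(v) == g("ncols"))
  v[v == g("nodata_value")] <- NA
  levels_file <- paste0(file, ".levels")
  if (file.exists(levels_file)) {
    lev <- readLines(levels_file)
    v <- matrix(lev[v], nrow(v))
  }
  raster_grid(v, pixel_size = g("cellsize"),
              origin = c(g("xllcorner"), g("yllcorner")),
              nodata = g("nodata_value"))
}
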