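# Minimal single-band georeferenced grid, serialized as ESRI ASCII grid
# (.asc), a plain-text interchange format every GIS reads.  Values are stored
# as a matrix with row 1 = northernmost row, matching the file layout.
# Categorical grids carry a `levels` character vector: cell values are
# 1-based indices into it (0 = background / first level, see generators).

#' Construct a grid raster
#'
#' @param values Numeric matrix; row 1 is the top (northern) row.
#' @param xll,yll Coordinates of the lower-left corner of the grid (metres).
#' @param cellsize Cell edge length in metres; cells are square.
#' @param levels Optional character vector naming categorical classes; cell
#'   values are then 1-based indices into it.
#' @param nodata Value written for missing cells (default -9999).
#' @return An object of class `grid_raster`.
#' @export
grid_raster <- function(values, xll, yll, cellsize, levels = NULL,
                        nodata = -9999) {
  stopifnot(is.matrix(values))
  if (cellsize <= 0) stop("cellsize must be > 0", call. = FALSE)
  structure(
    list(values = values, xll = xll, yll = yll, cellsize = cellsize,
         levels = levels, nodata = nodata),
    class = "grid_raster"
  )
}

#' @export
print.grid_raster <- function(x, ...) {
  cat("<grid_raster> ", nrow(x$values), " x ", ncol(x$values),
      " cells of ", x$cellsize, " m; origin (", x$xll, ", ", x$yll, ")",
      if (!is.null(x$levels)) paste0("; classes: ",
                                     paste(x$levels, collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}

#' Extent of a raster
#'
#' @param r A [grid_raster()].
#' @return Named numeric vector `c(xmin, xmax, ymin, ymax)`.
#' @export
raster_extent <- function(r) {
  c(xmin = r$xll, xmax = r$xll + ncol(r$values) * r$cellsize,
    ymin = r$yll, ymax = r$yll + nrow(r$values) * r$cellsize)
}

#' Sample raster values at points (nearest cell)
#'
#' Cell membership follows the half-open convention `[x0, x0 + w)` in both
#' axes, so a point exactly on a boundary belongs to the cell to its
#' east/north side's lower edge — results are bit-stable.
#'
#' @param r A [grid_raster()].
#' @param x,y Point coordinates (metres, same frame as the raster).
#' @return Numeric vector of cell values; `NA` for points outside the raster.
#' @export
raster_extract <- function(r, x, y) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  col <- floor((x - r$xll) / r$cellsize) + 1
  row_from_bottom <- floor((y - r$yll) / r$cellsize) + 1
  row <- nr - row_from_bottom + 1
  ok <- !is.na(col) & !is.na(row) & col >= 1 & col <= nc & row >= 1 & row <= nr
  out <- rep(NA_real_, length(x))
  out[ok] <- r$values[cbind(row[ok], col[ok])]
  out
}

#' Write a raster as ESRI ASCII grid
#'
#' Categorical levels, if any, are recorded in a sidecar `<path>.levels.json`
#' so the class labels survive the round trip.
#'
#' @param r A [grid_raster()].
#' @param path Output file path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @export
write_asc <- function(r, path) {
  v <- r$values
  v[is.na(v)] <- r$nodata
  hdr <- c(
    paste("ncols", ncol(v)), paste("nrows", nrow(v)),
    paste("xllcorner", format(r$xll, scientific = FALSE)),
    paste("yllcorner", format(r$yll, scientific = FALSE)),
    paste("cellsize", format(r$cellsize, scientific = FALSE)),
    paste("NODATA_value", r$nodata)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  if (!is.null(r$levels))
    jsonlite::write_json(r$levels, paste0(path, ".levels.json"))
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path Path to a `.asc` file written by [write_asc()] or any GIS.
#' @return A [grid_raster()].
#' @export
read_asc <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  key <- tolower(kv[, 1]); val <- as.numeric(kv[, 2])
  names(val) <- key
  for (k in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (!k %in% key) stop("missing ASCII grid header field: ", k, call. = FALSE)
  nodata <- if ("nodata_value" %in% key) val[["nodata_value"]] else -9999
  v <- matrix(scan(path, skip = 6, quiet = TRUE),
              nrow = val[["nrows"]], ncol = val[["ncols"]], byrow = TRUE)
  v[v == nodata] <- NA
  lev_path <- paste0(path, ".levels.json")
  levels <- if (file.exists(lev_path))
    as.character(jsonlite::read_json(lev_path, simplifyVector = TRUE))
  grid_raster(v, val[["xllcorner"]], val[["yllcorner"]], val[["cellsize"]],
              levels = levels, nodata = nodata)
}
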