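# Minimal regular lon/lat grid container + ESRI ASCII round-trip.
# Values are stored as a matrix with row 1 the northernmost row (the ESRI
# ASCII row order) and columns running west to east.

#' Construct a regular lon/lat grid layer
#'
#' @param values numeric matrix, row 1 = northernmost row, columns west-east.
#' @param xll,yll lower-left corner (degrees, cell edge not center).
#' @param cellsize cell size in degrees.
#' @param nodata value written for missing cells.
#' @return an object of class `sdm_grid`.
#' @export
sdm_grid <- function(values, xll, yll, cellsize, nodata = -9999) {
  stopifnot(is.matrix(values), cellsize > 0)
  structure(list(values = values, xll = xll, yll = yll,
                 cellsize = cellsize, nodata = nodata,
                 ncol = ncol(values), nrow = nrow(values)),
            class = "sdm_grid")
}

#' @exportS3Method base::print
print.sdm_grid <- function(x, ...) {
  cat(sprintf("<sdm_grid> %d x %d cells, cellsize %g deg, origin (%g, %g)\n",
              x$nrow, x$ncol, x$cellsize, x$xll, x$yll))
  invisible(x)
}

#' Cell-center coordinates of a grid
#'
#' @param grid an `sdm_grid`.
#' @return list with `lon` (west to east) and `lat` (north to south, matching
#'   row order of the value matrix).
#' @export
grid_centers <- function(grid) {
  lon <- grid$xll + (seq_len(grid$ncol) - 0.5) * grid$cellsize
  lat_s2n <- grid$yll + (seq_len(grid$nrow) - 0.5) * grid$cellsize
  list(lon = lon, lat = rev(lat_s2n))
}

#' Bilinear sample of a grid at point locations
#'
#' Values outside the grid extent raise an error; points in the outer half-cell
#' ring are clamped to the edge cell centers.
#'
#' @param grid an `sdm_grid`.
#' @param lon,lat numeric vectors of equal length.
#' @export
grid_sample <- function(grid, lon, lat) {
  cc <- grid_centers(grid)
  xmax <- grid$xll + grid$ncol * grid$cellsize
  ymax <- grid$yll + grid$nrow * grid$cellsize
  if (any(lon < grid$xll | lon > xmax | lat < grid$yll | lat > ymax))
    stop_sdm("grid_sample: location outside grid extent", class = "sdm_data_error")
  # work in south-to-north row index space then map to matrix rows
  fx <- (lon - cc$lon[1]) / grid$cellsize
  fy <- (lat - (grid$yll + 0.5 * grid$cellsize)) / grid$cellsize
  fx <- pmin(pmax(fx, 0), grid$ncol - 1)
  fy <- pmin(pmax(fy, 0), grid$nrow - 1)
  i0 <- pmin(floor(fx), grid$ncol - 2); j0 <- pmin(floor(fy), grid$nrow - 2)
  if (grid$ncol == 1) i0 <- rep(0, length(fx))
  if (grid$nrow == 1) j0 <- rep(0, length(fy))
  tx <- fx - i0; ty <- fy - j0
  v <- function(jj, ii) {
    # jj is 0-based south-to-north row, convert to matrix row (north first)
    grid$values[cbind(grid$nrow - jj, ii + 1)]
  }
  if (grid$ncol == 1 && grid$nrow == 1) return(rep(grid$values[1, 1], length(lon)))
  if (grid$ncol == 1) return(v(j0, i0) * (1 - ty) + v(j0 + 1, i0) * ty)
  if (grid$nrow == 1) return(v(j0, i0) * (1 - tx) + v(j0, i0 + 1) * tx)
  v(j0, i0) * (1 - tx) * (1 - ty) + v(j0, i0 + 1) * tx * (1 - ty) +
    v(j0 + 1, i0) * (1 - tx) * ty + v(j0 + 1, i0 + 1) * tx * ty
}

#' Write a grid layer as an ESRI ASCII raster
#'
#' Standard 6-line header (ncols, nrows, xllcorner, yllcorner, cellsize,
#' NODATA_value) followed by rows north to south. Round-trips bit-exactly
#' through [read_raster()].
#'
#' @param grid an `sdm_grid` (finite values or NA; NA written as NODATA).
#' @param path output path.
#' @param format only `"asc"` is supported.
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path, format = c("asc")) {
  format <- match.arg(format)
  stopifnot(inherits(grid, "sdm_grid"))
  vals <- grid$values
  if (any(!is.finite(vals) & !is.na(vals)))
    stop_sdm("write_raster: non-finite values present", class = "sdm_data_error")
  vals[is.na(vals)] <- grid$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", grid$ncol),
               sprintf("nrows %d", grid$nrow),
               sprintf("xllcorner %.10g", grid$xll),
               sprintf("yllcorner %.10g", grid$yll),
               sprintf("cellsize %.10g", grid$cellsize),
               sprintf("NODATA_value %.10g", grid$nodata)), con)
  writeLines(apply(vals, 1, function(r) paste(format(r, digits = 17), collapse = " ")), con)
  invisible(path)
}

#' Read an ESRI ASCII raster
#'
#' @param path file path.
#' @return an `sdm_grid`; NODATA cells become NA.
#' @export
read_raster <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  vals <- matrix(scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE),
                 nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  vals[vals == hdr$nodata_value] <- NA
  sdm_grid(vals, hdr$xllcorner, hdr$yllcorner, hdr$cellsize, hdr$nodata_value)
}
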