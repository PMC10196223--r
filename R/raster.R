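#' Create a lightweight lon/lat raster grid
#'
#' A minimal in-memory raster: a numeric matrix whose first row is the
#' northernmost row of cells, georeferenced by the lower-left corner of the
#' extent and a square cell size in decimal degrees (WGS84 lon/lat
#' convention throughout). Missing cells are `NA`; the NODATA sentinel only
#' exists on disk.
#'
#' @param values numeric matrix, row 1 = northernmost row, column 1 = west.
#' @param xll,yll longitude/latitude of the lower-left corner of the extent.
#' @param cellsize cell edge length in decimal degrees.
#' @return object of class `raster_grid`.
#' @export
raster_grid <- function(values, xll, yll, cellsize) {
  stopifnot(is.matrix(values), is.numeric(cellsize), cellsize > 0)
  structure(
    list(values = values, xll = as.numeric(xll), yll = as.numeric(yll),
         cellsize = as.numeric(cellsize)),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf(
    "<raster_grid> %d rows x %d cols, cell %g deg\n  extent: lon [%g, %g], lat [%g, %g]\n  values: [%g, %g], %d NA\n",
    nrow(x$values), ncol(x$values), x$cellsize,
    x$xll, x$xll + ncol(x$values) * x$cellsize,
    x$yll, x$yll + nrow(x$values) * x$cellsize,
    suppressWarnings(min(x$values, na.rm = TRUE)),
    suppressWarnings(max(x$values, na.rm = TRUE)),
    sum(is.na(x$values))))
  invisible(x)
}

#' Cell-center longitudes (by column) and latitudes (by row)
#' @param r a `raster_grid`
#' @return numeric vector of cell-center coordinates
#' @export
grid_lon <- function(r) r$xll + (seq_len(ncol(r$values)) - 0.5) * r$cellsize

#' @rdname grid_lon
#' @export
grid_lat <- function(r) {
  ny <- nrow(r$values)
  r$yll + (ny - seq_len(ny) + 0.5) * r$cellsize  # row 1 is northernmost
}

#' @exportS3Method tibble::as_tibble
as_tibble.raster_grid <- function(x, ...) {
  tibble::tibble(
    lon = rep(grid_lon(x), each = nrow(x$values)),
    lat = rep(grid_lat(x), times = ncol(x$values)),
    value = as.vector(x$values)
  )
}

#' Test two grids for co-registration (same extent, resolution, shape)
#' @param a,b raster grids
#' @export
grids_aligned <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(c(a$xll, a$yll, a$cellsize), c(b$xll, b$yll, b$cellsize),
                     tolerance = 1e-9))
}

stop_if_misaligned <- function(...) {
  gs <- list(...)
  for (i in seq_along(gs)[-1]) {
    if (!grids_aligned(gs[[1]], gs[[i]]))
      stop("raster grids are not co-registered", call. = FALSE)
  }
  invisible(TRUE)
}

#' Per-cell area in square kilometres
#'
#' Equirectangular approximation with cosine-latitude correction:
#' one degree of longitude spans 111.32 * cos(lat) km, one degree of
#' latitude 110.57 km.
#'
#' @param r a `raster_grid`
#' @return matrix of cell areas (km^2), same shape as `r$values`
#' @export
cell_area_km2 <- function(r) {
  lat <- grid_lat(r)
  w <- 111.32 * cos(lat * pi / 180) * r$cellsize
  h <- 110.57 * r$cellsize
  matrix(w * h, nrow = nrow(r$values), ncol = ncol(r$values))
}

#' Point-sample a raster at lon/lat locations
#'
#' @param r a `raster_grid`
#' @param lon,lat coordinate vectors (equal length)
#' @return numeric vector of cell values (NA outside the extent)
#' @export
extract_at <- function(r, lon, lat) {
  nyr <- nrow(r$values); nxr <- ncol(r$values)
  col <- floor((lon - r$xll) / r$cellsize) + 1
  row_from_s <- floor((lat - r$yll) / r$cellsize) + 1
  row <- nyr - row_from_s + 1
  ok <- col >= 1 & col <= nxr & row >= 1 & row <= nyr &
    !is.na(lon) & !is.na(lat)
  out <- rep(NA_real_, length(lon))
  out[ok] <- r$values[cbind(row[ok], col[ok])]
  out
}

#' Read an ESRI ASCII grid
#'
#' Supports the standard 6-line header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `nodata_value`); NODATA cells become `NA`.
#'
#' @param path file path
#' @return a `raster_grid`
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- list(); i <- 1
  while (grepl("^[a-zA-Z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  nodata <- hdr[["nodata_value"]]
  if (!is.null(nodata)) m[m == nodata] <- NA
  raster_grid(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize)
}

#' Write an ESRI ASCII grid
#' @param r a `raster_grid`
#' @param path output file
#' @param nodata NODATA sentinel written for `NA` cells
#' @return `path`, invisibly
#' @export
write_esri_ascii <- function(r, path, nodata = -9999) {
  m <- r$values
  m[is.na(m)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", r$xll),
    sprintf("yllcorner %.10g", r$yll),
    sprintf("cellsize %.10g", r$cellsize),
    sprintf("NODATA_value %.10g", nodata))
  body <- apply(m, 1, function(row) paste(format(row, trim = TRUE,
                                                 digits = 15),
                                          collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Terrain ruggedness index
#'
#' Per cell, the mean absolute elevation difference to the (up to) eight
#' neighbouring cells; edge and corner cells use the neighbours that exist.
#' Cells with `NA` elevation give `NA`; `NA` neighbours are excluded from
#' the mean.
#'
#' @param dem a `raster_grid` of elevations (m)
#' @return a `raster_grid` of TRI values (m)
#' @export
compute_tri <- function(dem) {
  z <- dem$values
  if (nrow(z) < 3 || ncol(z) < 3) stop("DEM must be at least 3x3 cells")
  nr <- nrow(z); nc <- ncol(z)
  acc <- matrix(0, nr, nc)   # sum of |differences|
  cnt <- matrix(0L, nr, nc)  # number of non-NA neighbours
  shifts <- expand.grid(dr = -1:1, dc = -1:1)
  shifts <- shifts[!(shifts$dr == 0 & shifts$dc == 0), ]
  for (k in seq_len(nrow(shifts))) {
    dr <- shifts$dr[k]; dc <- shifts$dc[k]
    rs <- max(1, 1 + dr):min(nr, nr + dr)   # rows of the neighbour image
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    r0 <- rs - dr; c0 <- cs - dc            # rows/cols of the focal image
    d <- abs(z[r0, c0, drop = FALSE] - z[rs, cs, drop = FALSE])
    ok <- !is.na(d)
    d[!ok] <- 0
    acc[r0, c0] <- acc[r0, c0] + d
    cnt[r0, c0] <- cnt[r0, c0] + ok
  }
  tri <- acc / pmax(cnt, 1L)
  tri[is.na(z) | cnt == 0L] <- NA
  raster_grid(tri, dem$xll, dem$yll, dem$cellsize)
}

#' @exportS3Method ggplot2::autoplot
autoplot.raster_grid <- function(object, ...) {
  df <- as_tibble.raster_grid(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_fixed(1 / cos(mean(grid_lat(object)) * pi / 180)) +
    ggplot2::labs(x = "Longitude", y = "Latitude")
}
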