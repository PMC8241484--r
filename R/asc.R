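#' Read an ESRI ASCII grid
#'
#' Parses a plain-text `.asc` raster (header of `ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, optional `NODATA_value`, followed by
#' `nrows` rows of values, northernmost row first).  Coordinates are planar
#' kilometres throughout the package; no projection handling is performed.
#'
#' @param path path to the `.asc` file.
#' @return an object of class `asc_raster`: a list with `x0`, `y0` (lower-left
#'   corner), `cellsize`, `nrow`, `ncol` and `values` (a matrix whose first row
#'   is the northernmost raster row; `NA` marks NODATA cells).
#' @seealso [write_asc()], [build_habitat_grid()]
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  repeat {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (!key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
                    "nodata_value")) break
    hdr[[key]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ASCII grid body of ", path, " has ", length(vals),
         " values, expected ", hdr$ncols * hdr$nrows)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  structure(list(x0 = hdr$xllcorner, y0 = hdr$yllcorner,
                 cellsize = hdr$cellsize, nrow = hdr$nrows,
                 ncol = hdr$ncols, values = m),
            class = "asc_raster")
}

#' Write an ESRI ASCII grid
#'
#' @param raster an `asc_raster` (see [read_asc()]) or a plain matrix together
#'   with `x0`, `y0` and `cellsize`.
#' @param path output path.
#' @param x0,y0,cellsize lower-left corner and cell size, used when `raster`
#'   is a plain matrix.
#' @param nodata value written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_asc <- function(raster, path, x0 = NULL, y0 = NULL, cellsize = NULL,
                      nodata = -9999) {
  if (!inherits(raster, "asc_raster")) {
    raster <- structure(list(x0 = x0, y0 = y0, cellsize = cellsize,
                             nrow = nrow(raster), ncol = ncol(raster),
                             values = raster),
                        class = "asc_raster")
  }
  m <- raster$values
  m[is.na(m)] <- nodata
  hdr <- c(paste("ncols", raster$ncol), paste("nrows", raster$nrow),
           paste("xllcorner", format(raster$x0, digits = 15)),
           paste("yllcorner", format(raster$y0, digits = 15)),
           paste("cellsize", format(raster$cellsize, digits = 15)),
           paste("NODATA_value", nodata))
  body <- apply(m, 1, function(r) paste(format(r, digits = 15, trim = TRUE),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# value of an asc_raster as a function of lattice indices; row 1 = north
.asc_cell_value <- function(raster, rowi, coli) {
  raster$values[raster$nrow - rowi + 1L, coli]
}
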