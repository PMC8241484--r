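#' Build the discrete habitat grid
#'
#' Lays a regular axis-aligned lattice of square habitat cells over a core
#' extent expanded by a buffer, and resamples a spatial density covariate to
#' the cell resolution by area-weighted averaging.  The buffer allows latent
#' activity centres to sit outside the detector-covered region, so that
#' emigration and mortality are distinguishable.  All coordinates are planar
#' kilometres in an equal-area projection; cells are indexed row-major from
#' the lower-left corner (0-based ids in serialized output).
#'
#' @param extent numeric `c(xmin, xmax, ymin, ymax)` of the core (detector)
#'   extent, km.
#' @param cell_size habitat cell side length, km (default 20).
#' @param covariate the density covariate `X`: a single number (constant
#'   surface), a function `f(x, y)` evaluated at cell centres, or an
#'   `asc_raster` (see [read_asc()]) resampled by area-weighted mean.  Raster
#'   NODATA regions produce dropped (absent) cells, never `NA` placeholders.
#' @param buffer_width buffer added on every side, km (default 60).
#' @param regions `NULL` (single region), a function `f(x, y)` returning an
#'   integer region id per cell centre, or an integer vector over cells.
#' @param sigma_max optional upper prior bound on the detection scale
#'   `sigma`; a warning is issued when `buffer_width < 6 * sigma_max`.
#' @return an object of class `habitat_grid`: list with `cells` (data.frame
#'   `cell` 0-based id, `x`, `y`, `X`, `region`), `cell_size`, `buffer_width`,
#'   `extent_core`, `extent` (buffered), and lattice metadata.
#' @export
build_habitat_grid <- function(extent, cell_size = 20, covariate = 0,
                               buffer_width = 60, regions = NULL,
                               sigma_max = NULL) {
  stopifnot(length(extent) == 4, extent[2] > extent[1], extent[4] > extent[3],
            cell_size > 0, buffer_width >= 0)
  if (!is.null(sigma_max) && buffer_width < 6 * sigma_max)
    warning("buffer_width = ", buffer_width, " km is below 6 * sigma_max = ",
            6 * sigma_max, " km; activity centres near the edge may be truncated")
  x0 <- extent[1] - buffer_width
  y0 <- extent[3] - buffer_width
  nx <- ceiling(((extent[2] + buffer_width) - x0) / cell_size - 1e-9)
  ny <- ceiling(((extent[4] + buffer_width) - y0) / cell_size - 1e-9)
  cx <- x0 + (seq_len(nx) - 0.5) * cell_size
  cy <- y0 + (seq_len(ny) - 0.5) * cell_size
  cells <- expand.grid(x = cx, y = cy, KEEP.OUT.ATTRS = FALSE) # row-major from lower-left
  X <- .habitat_covariate(cells$x, cells$y, cell_size, covariate)
  keep <- !is.na(X)
  if (!any(keep)) stop("no habitat cells remain after covariate masking")
  cells <- cells[keep, , drop = FALSE]
  X <- X[keep]
  if (is.null(regions)) {
    region <- rep(1L, nrow(cells))
  } else if (is.function(regions)) {
    region <- as.integer(regions(cells$x, cells$y))
  } else {
    region <- as.integer(regions)[keep]
  }
  if (anyNA(region) || anyNA(X) || any(!is.finite(X)))
    stop("habitat covariate or region ids contain non-finite values")
  grid <- list(
    cells = data.frame(cell = seq_len(nrow(cells)) - 1L, x = cells$x,
                       y = cells$y, X = X, region = region),
    cell_size = cell_size, buffer_width = buffer_width,
    extent_core = extent,
    extent = c(x0, x0 + nx * cell_size, y0, y0 + ny * cell_size),
    x0 = x0, y0 = y0, nx = nx, ny = ny,
    index = {
      idx <- matrix(NA_integer_, nrow = ny, ncol = nx)
      col <- as.integer(round((cells$x - x0 - cell_size / 2) / cell_size)) + 1L
      row <- as.integer(round((cells$y - y0 - cell_size / 2) / cell_size)) + 1L
      idx[cbind(row, col)] <- seq_len(nrow(cells))
      idx
    })
  class(grid) <- "habitat_grid"
  grid
}

# resolve the covariate argument to one value per candidate cell centre
.habitat_covariate <- function(cx, cy, cell_size, covariate) {
  if (is.numeric(covariate) && length(covariate) == 1) {
    rep(as.numeric(covariate), length(cx))
  } else if (is.function(covariate)) {
    as.numeric(covariate(cx, cy))
  } else if (inherits(covariate, "asc_raster")) {
    xmin <- min(cx) - cell_size / 2; xmax <- max(cx) + cell_size / 2
    ymin <- min(cy) - cell_size / 2; ymax <- max(cy) + cell_size / 2
    rx1 <- covariate$x0 + covariate$ncol * covariate$cellsize
    ry1 <- covariate$y0 + covariate$nrow * covariate$cellsize
    if (xmin < covariate$x0 - 1e-9 || ymin < covariate$y0 - 1e-9 ||
        xmax > rx1 + 1e-9 || ymax > ry1 + 1e-9)
      stop("covariate raster does not cover the buffered habitat extent (",
           "raster [", covariate$x0, ", ", rx1, "] x [", covariate$y0, ", ",
           ry1, "], needed [", xmin, ", ", xmax, "] x [", ymin, ", ", ymax, "])")
    vapply(seq_along(cx), function(k) {
      .area_weighted_mean(covariate, cx[k] - cell_size / 2,
                          cx[k] + cell_size / 2, cy[k] - cell_size / 2,
                          cy[k] + cell_size / 2)
    }, numeric(1))
  } else {
    stop("`covariate` must be a constant, a function(x, y), or an asc_raster")
  }
}

# area-weighted mean of raster values over an axis-aligned rectangle;
# NA raster cells carry no weight, an all-NA rectangle yields NA (cell dropped)
.area_weighted_mean <- function(raster, xa, xb, ya, yb) {
  cs <- raster$cellsize
  ci0 <- max(1L, floor((xa - raster$x0) / cs) + 1L)
  ci1 <- min(raster$ncol, ceiling((xb - raster$x0) / cs - 1e-12))
  ri0 <- max(1L, floor((ya - raster$y0) / cs) + 1L)
  ri1 <- min(raster$nrow, ceiling((yb - raster$y0) / cs - 1e-12))
  wsum <- 0; vsum <- 0
  for (ri in ri0:ri1) {
    oy <- min(yb, raster$y0 + ri * cs) - max(ya, raster$y0 + (ri - 1) * cs)
    if (oy <= 0) next
    for (ci in ci0:ci1) {
      ox <- min(xb, raster$x0 + ci * cs) - max(xa, raster$x0 + (ci - 1) * cs)
      if (ox <= 0) next
      v <- .asc_cell_value(raster, ri, ci)
      if (is.na(v)) next
      wsum <- wsum + ox * oy
      vsum <- vsum + ox * oy * v
    }
  }
  if (wsum <= 0) NA_real_ else vsum / wsum
}

#' Locate the habitat cell containing a point
#'
#' @param habitat a `habitat_grid`.
#' @param x,y coordinates, km (vectorized).
#' @return integer row index into `habitat$cells` (1-based), `NA` when the
#'   point falls outside the habitat.
#' @export
habitat_cell_at <- function(habitat, x, y) {
  col <- floor((x - habitat$x0) / habitat$cell_size) + 1
  row <- floor((y - habitat$y0) / habitat$cell_size) + 1
  out <- rep(NA_integer_, length(x))
  ok <- col >= 1 & col <= habitat$nx & row >= 1 & row <= habitat$ny &
    !is.na(col) & !is.na(row)
  out[ok] <- habitat$index[cbind(as.integer(row[ok]), as.integer(col[ok]))]
  out
}

#' Build the detector grid with habitat-overlap subdetector counts
#'
#' Detectors are the centres of a coarse lattice over the core extent; each is
#' subdivided into `(detector_size / subdetector_size)^2` subdetectors.  The
#' binomial sample size `K_j` counts the detector's subdetector centres that
#' fall inside a habitat cell; detectors with `K_j = 0` are dropped.
#'
#' @param extent numeric `c(xmin, xmax, ymin, ymax)` of the detector extent, km.
#' @param detector_size detector cell side, km (default 10).
#' @param subdetector_size subdetector side, km (default 2); must divide
#'   `detector_size`.
#' @param habitat a `habitat_grid`.
#' @param county `NULL` (single county), a function `f(x, y)` giving an
#'   integer county id per detector centre, or an integer vector.
#' @return an object of class `detector_grid`: list with `detectors`
#'   (data.frame `detector` 0-based id, `x`, `y`, `K`, `county`),
#'   `detector_size`, `subdetector_size`, `sub_centres` (per-detector matrix
#'   of the habitat-overlapping subdetector centres), and empty covariate slot.
#' @export
build_detector_grid <- function(extent, detector_size = 10,
                                subdetector_size = 2, habitat,
                                county = NULL) {
  stopifnot(length(extent) == 4, inherits(habitat, "habitat_grid"))
  m <- detector_size / subdetector_size
  if (abs(m - round(m)) > 1e-9)
    stop("detector_size (", detector_size, ") must be an integer multiple of ",
         "subdetector_size (", subdetector_size, ")")
  m <- as.integer(round(m))
  nx <- ceiling((extent[2] - extent[1]) / detector_size - 1e-9)
  ny <- ceiling((extent[4] - extent[3]) / detector_size - 1e-9)
  dx <- extent[1] + (seq_len(nx) - 0.5) * detector_size
  dy <- extent[3] + (seq_len(ny) - 0.5) * detector_size
  centres <- expand.grid(x = dx, y = dy, KEEP.OUT.ATTRS = FALSE)
  suboff <- (seq_len(m) - (m + 1) / 2) * subdetector_size
  sub_centres <- vector("list", nrow(centres))
  K <- integer(nrow(centres))
  for (j in seq_len(nrow(centres))) {
    sx <- rep(centres$x[j] + suboff, times = m)
    sy <- rep(centres$y[j] + suboff, each = m)
    inside <- !is.na(habitat_cell_at(habitat, sx, sy))
    K[j] <- sum(inside)
    sub_centres[[j]] <- cbind(x = sx[inside], y = sy[inside])
  }
  keep <- K > 0L
  centres <- centres[keep, , drop = FALSE]
  K <- K[keep]
  sub_centres <- sub_centres[keep]
  if (is.null(county)) {
    cid <- rep(1L, nrow(centres))
  } else if (is.function(county)) {
    cid <- as.integer(county(centres$x, centres$y))
  } else {
    cid <- as.integer(county)[keep]
  }
  det <- list(
    detectors = data.frame(detector = seq_len(nrow(centres)) - 1L,
                           x = centres$x, y = centres$y, K = K, county = cid),
    detector_size = detector_size, subdetector_size = subdetector_size,
    sub_centres = sub_centres, extent_core = extent,
    covariates = NULL, cov_centers = NULL, cov_scales = NULL)
  class(det) <- "detector_grid"
  det
}

#' Attach standardized per-detector, per-season covariates
#'
#' Covariates (search-track length, road distance, snow cover, ...) are
#' z-scored over all detector x season values; the standardization constants
#' are stored with the grid so linear predictors are reproducible.
#'
#' @param detectors a `detector_grid`.
#' @param covariates named list of `J x T` numeric matrices on their natural
#'   scales.
#' @return the `detector_grid` with a `J x T x P` `covariates` array and
#'   stored centers/scales.
#' @export
set_detector_covariates <- function(detectors, covariates) {
  stopifnot(inherits(detectors, "detector_grid"), is.list(covariates),
            length(names(covariates)) == length(covariates))
  J <- nrow(detectors$detectors)
  Tn <- unique(vapply(covariates, ncol, integer(1)))
  if (length(Tn) != 1) stop("covariate matrices disagree on season count")
  arr <- array(NA_real_, dim = c(J, Tn, length(covariates)),
               dimnames = list(NULL, NULL, names(covariates)))
  ctr <- scl <- setNames(numeric(length(covariates)), names(covariates))
  for (p in seq_along(covariates)) {
    v <- covariates[[p]]
    if (nrow(v) != J) stop("covariate '", names(covariates)[p],
                           "' has ", nrow(v), " rows, expected ", J)
    if (anyNA(v) || any(!is.finite(v)))
      stop("covariate '", names(covariates)[p], "' contains non-finite values")
    ctr[p] <- mean(v)
    scl[p] <- sd(as.numeric(v))
    if (!is.finite(scl[p]) || scl[p] <= 0)
      stop("covariate '", names(covariates)[p],
           "' is degenerate (zero variance) after pooling")
    arr[, , p] <- (v - ctr[p]) / scl[p]
  }
  detectors$covariates <- arr
  detectors$cov_centers <- ctr
  detectors$cov_scales <- scl
  detectors
}

#' Aggregate detection records to subdetector counts
#'
#' Each record is assigned to the nearest detector centre, then to the nearest
#' of that detector's subdetector centres (distance ties broken by lowest
#' index).  `y[i, j, t]` is the number of distinct subdetectors of detector
#' `j` holding at least one detection of individual `i` in season `t`.
#' Records farther from every detector centre than half the detector-cell
#' diagonal are excluded; their count is attached as attribute `excluded`.
#'
#' @param records data.frame with columns `individual_id`, `season`, `x`, `y`.
#' @param detectors a `detector_grid`.
#' @return data.frame (`individual_id`, `detector` 0-based, `season`, `y`)
#'   with one row per positive count, attribute `excluded` giving the number
#'   of out-of-grid records dropped.
#' @export
assign_detections <- function(records, detectors) {
  stopifnot(all(c("individual_id", "season", "x", "y") %in% names(records)),
            inherits(detectors, "detector_grid"))
  if (nrow(records) == 0) {
    out <- data.frame(individual_id = character(), detector = integer(),
                      season = integer(), y = integer())
    attr(out, "excluded") <- 0L
    return(out)
  }
  if (anyNA(records$x) || anyNA(records$y) || any(!is.finite(records$x)))
    stop("detection records contain non-finite coordinates")
  dd <- detectors$detectors
  maxd2 <- (detectors$detector_size^2 / 2) + 1e-6 # half-diagonal squared
  n <- nrow(records)
  det_idx <- integer(n)
  sub_idx <- integer(n)
  ok <- logical(n)
  for (r in seq_len(n)) {
    d2 <- (dd$x - records$x[r])^2 + (dd$y - records$y[r])^2
    j <- which.min(d2) # ties: lowest index
    if (d2[j] > maxd2) next
    sc <- detectors$sub_centres[[j]]
    s2 <- (sc[, 1] - records$x[r])^2 + (sc[, 2] - records$y[r])^2
    det_idx[r] <- j
    sub_idx[r] <- which.min(s2)
    ok[r] <- TRUE
  }
  excluded <- sum(!ok)
  if (excluded > 0)
    message(excluded, " detection record(s) outside the detector grid were excluded")
  kept <- records[ok, , drop = FALSE]
  key <- paste(kept$individual_id, kept$season, det_idx[ok], sub_idx[ok],
               sep = "\r")
  uk <- !duplicated(key)
  agg <- data.frame(individual_id = kept$individual_id[uk],
                    season = kept$season[uk], detector = det_idx[ok][uk])
  tab <- aggregate(rep(1L, nrow(agg)),
                   by = list(individual_id = agg$individual_id,
                             season = agg$season, detector = agg$detector),
                   FUN = sum)
  out <- data.frame(individual_id = as.character(tab$individual_id),
                    detector = dd$detector[tab$detector],
                    season = as.integer(tab$season), y = as.integer(tab$x))
  out <- out[order(out$individual_id, out$season, out$detector), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Retention filter around reference points
#'
#' Keeps the records whose minimum Euclidean distance to any reference point
#' is at most `radius`; used to restrict non-invasive samples to the
#' neighbourhood of collared-individual sample locations so collared and
#' non-collared individuals share the sampled landscape.
#'
#' @param records data.frame with `x`, `y` columns.
#' @param reference_points matrix or data.frame of reference `x`, `y`.
#' @param radius retention radius, km (default 70).
#' @return the retained subset of `records`.
#' @export
retain_within_radius <- function(records, reference_points, radius = 70) {
  stopifnot(radius > 0)
  rp <- as.matrix(reference_points)[, 1:2, drop = FALSE]
  if (nrow(rp) == 0) stop("empty reference set: retention filter undefined")
  if (nrow(records) == 0) return(records)
  keep <- vapply(seq_len(nrow(records)), function(r) {
    min((rp[, 1] - records$x[r])^2 + (rp[, 2] - records$y[r])^2) <= radius^2
  }, logical(1))
  records[keep, , drop = FALSE]
}
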