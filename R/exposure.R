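# Daily exposure assignment. Gridded PM2.5 goes grid centroid -> block
# (mean of encompassed centroids, nearest-centroid fallback) -> block group
# (population-weighted). Gridded meteorology goes grid cell -> block group by
# areal weighting of square cell footprints. The assembled panel is held in a
# SummarizedExperiment subclass: rows are block groups, columns are days.

#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData colData
NULL

#' ExposurePanel: block group x day exposure matrices
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass. Rows are Census
#' block groups, columns are calendar days (on the 365-day gridded-meteorology
#' calendar). Assays: `pm25` (ug/m^3), `tmin`, `tmax`, `tmean` (degrees C),
#' `vp` (vapor pressure, kPa) and `pm25_ma2` .. `pm25_ma5` (k-day moving
#' averages of PM2.5 over lags 0..k-1). `tmean` is always (tmin + tmax)/2.
#'
#' @aliases ExposurePanel
#' @export
setClass("ExposurePanel", contains = "SummarizedExperiment")

setValidity("ExposurePanel", function(object) {
  need <- c("pm25", "tmin", "tmax", "tmean", "vp", paste0("pm25_ma", 2:5))
  miss <- setdiff(need, assayNames(object))
  if (length(miss)) return(paste("missing assays:", paste(miss, collapse = ", ")))
  if (!"date" %in% colnames(colData(object))) return("colData needs a 'date' column")
  if (!"geoid12" %in% colnames(rowData(object))) return("rowData needs 'geoid12'")
  tm <- (assay(object, "tmin") + assay(object, "tmax")) / 2
  if (max(abs(tm - assay(object, "tmean")), na.rm = TRUE) > 1e-8)
    return("tmean must equal (tmin + tmax)/2")
  if (any(assay(object, "pm25") < 0, na.rm = TRUE)) return("pm25 must be >= 0")
  if (any(assay(object, "vp") < 0, na.rm = TRUE)) return("vp must be >= 0")
  TRUE
})

#' Construct an ExposurePanel
#'
#' @param pm25,tmin,tmax,vp Numeric matrices, block groups x days, in panel
#'   units (ug/m^3, degrees C, degrees C, kPa).
#' @param geoids Character vector of 12-character block-group GEOIDs (rows).
#' @param dates `Date` vector (columns), sorted.
#' @param population Optional block-group populations (row metadata).
#' @param redlined Optional logical row metadata (HOLC grade D residence).
#' @return An [ExposurePanel-class] object with `tmean` and the PM2.5 moving
#'   averages computed.
#' @export
ExposurePanel <- function(pm25, tmin, tmax, vp, geoids, dates,
                          population = NULL, redlined = NULL) {
  dates <- as.Date(dates)
  stopifnot(!is.unsorted(dates), nrow(pm25) == length(geoids),
            ncol(pm25) == length(dates))
  tmean <- (tmin + tmax) / 2
  mas <- lapply(2:5, function(k) movingAverage(pm25, dates, k))
  names(mas) <- paste0("pm25_ma", 2:5)
  assays <- c(list(pm25 = pm25, tmin = tmin, tmax = tmax,
                   tmean = tmean, vp = vp), mas)
  assays <- lapply(assays, function(m) {
    dimnames(m) <- list(geoids, as.character(dates)); m
  })
  rd <- DataFrame(geoid12 = geoids)
  if (!is.null(population)) rd$population <- population
  if (!is.null(redlined)) rd$redlined <- redlined
  se <- SummarizedExperiment(assays = assays, rowData = rd,
                             colData = DataFrame(date = dates))
  rownames(se) <- geoids
  colnames(se) <- as.character(dates)
  new("ExposurePanel", se)
}

#' @describeIn ExposurePanel-class PM2.5 assay matrix (`k = 1` the daily
#'   values, `k` in 2..5 the k-day moving average).
#' @param x,object An `ExposurePanel`.
#' @param k Moving-average window (1 = same day).
#' @export
pm25 <- function(x, k = 1) {
  stopifnot(is(x, "ExposurePanel"), k %in% 1:5)
  assay(x, if (k == 1) "pm25" else paste0("pm25_ma", k))
}

#' @describeIn ExposurePanel-class daily minimum temperature matrix.
#' @export
tminTemperature <- function(x) assay(x, "tmin")

#' @describeIn ExposurePanel-class daily mean temperature matrix.
#' @export
tmeanTemperature <- function(x) assay(x, "tmean")

#' @describeIn ExposurePanel-class daily vapor-pressure matrix.
#' @export
vaporPressure <- function(x) assay(x, "vp")

#' @describeIn ExposurePanel-class panel dates.
#' @export
panelDates <- function(x) as.Date(colData(x)$date)

#' @describeIn ExposurePanel-class block-group GEOIDs.
#' @export
geoids <- function(x) as.character(rowData(x)$geoid12)

setMethod("show", "ExposurePanel", function(object) {
  cat("ExposurePanel:", nrow(object), "block groups x",
      ncol(object), "days (",
      as.character(min(panelDates(object))), "..",
      as.character(max(panelDates(object))), ")\n")
  cat("assays:", paste(assayNames(object), collapse = ", "), "\n")
})

#' Assign grid-centroid values to Census blocks
#'
#' Each block gets the mean of values at grid centroids encompassed by its
#' polygon (boundary counts as contained). Blocks containing no grid centroid
#' fall back to the value of the Euclidean-nearest grid centroid to the block
#' centroid.
#'
#' @param cellXY `data.frame` with columns `x`, `y`: grid-cell centroids.
#' @param cellValues Numeric matrix, cells x days, rows ordered as `cellXY`.
#' @param blockPolys Named list (by `geoid15`) of block polygons.
#' @param blockXY `data.frame` with `geoid15`, `x`, `y` block centroids.
#' @return Matrix blocks x days with `geoid15` rownames.
#' @export
assignGridToBlocks <- function(cellXY, cellValues, blockPolys, blockXY) {
  if (nrow(cellXY) == 0L) stop("empty grid")
  stopifnot(nrow(cellValues) == nrow(cellXY))
  ids <- blockXY$geoid15
  out <- matrix(NA_real_, length(ids), ncol(cellValues),
                dimnames = list(ids, colnames(cellValues)))
  nearest <- .nearestIndex(blockXY$x, blockXY$y, cellXY$x, cellXY$y)
  for (i in seq_along(ids)) {
    inb <- pointInPolygon(cellXY$x, cellXY$y, blockPolys[[ids[i]]])
    out[i, ] <- if (any(inb)) {
      colMeans(cellValues[inb, , drop = FALSE])
    } else {
      cellValues[nearest[i], ]
    }
  }
  out
}

#' Population-weighted aggregation of block values to block groups
#'
#' @param blockValues Matrix blocks x days (rownames `geoid15`) or vector.
#' @param population Non-negative block populations, same order.
#' @param geoid12 Parent block-group GEOIDs, same order (defaults to the
#'   truncation of the rownames).
#' @return Matrix block groups x days.
#' @export
blocksToGroups <- function(blockValues, population,
                           geoid12 = truncateBlockGeoid(rownames(blockValues))) {
  if (is.null(dim(blockValues))) blockValues <- cbind(value = blockValues)
  stopifnot(length(population) == nrow(blockValues), all(population >= 0))
  wsum <- rowsum(blockValues * population, geoid12)
  wtot <- rowsum(population, geoid12)
  if (any(wtot == 0))
    stop("block group(s) with zero total population: ",
         paste(utils::head(rownames(wtot)[wtot == 0], 3L), collapse = ", "))
  wsum / as.vector(wtot)
}

#' Areal-weighted aggregation of grid cells to block groups
#'
#' Grid cells are modelled as square footprints of side `pitch` centred on
#' their centroids; each block group's value is the intersection-area-weighted
#' mean over cells.
#'
#' @inheritParams assignGridToBlocks
#' @param pitch Grid pitch (cell side) in coordinate units.
#' @param bgPolys Named list (by `geoid12`) of block-group polygons.
#' @return Matrix block groups x days.
#' @export
gridToGroupsAreal <- function(cellXY, pitch, cellValues, bgPolys) {
  if (nrow(cellXY) == 0L) stop("empty grid")
  ids <- names(bgPolys)
  out <- matrix(NA_real_, length(ids), ncol(cellValues),
                dimnames = list(ids, colnames(cellValues)))
  h <- pitch / 2
  for (i in seq_along(ids)) {
    poly <- bgPolys[[ids[i]]]
    if (is.matrix(poly)) poly <- list(poly)
    bb <- apply(.closeRing(poly[[1L]]), 2L, range)
    cand <- which(cellXY$x + h > bb[1L, 1L] & cellXY$x - h < bb[2L, 1L] &
                  cellXY$y + h > bb[1L, 2L] & cellXY$y - h < bb[2L, 2L])
    w <- vapply(cand, function(j)
      polygonRectIntersectionArea(poly, cellXY$x[j] - h, cellXY$y[j] - h,
                                  cellXY$x[j] + h, cellXY$y[j] + h),
      numeric(1L))
    keep <- w > 0
    if (!any(keep))
      stop("block group ", ids[i], " intersects no grid cell footprint")
    w <- w[keep]
    out[i, ] <- crossprod(cellValues[cand[keep], , drop = FALSE], w) / sum(w)
  }
  out
}

#' Assemble the block-group daily exposure panel from gridded inputs
#'
#' PM2.5 follows the centroid rule ([assignGridToBlocks()]) then
#' population weighting ([blocksToGroups()]); minimum/maximum temperature and
#' vapor pressure follow areal weighting ([gridToGroupsAreal()]).
#'
#' @inheritParams assignGridToBlocks
#' @inheritParams gridToGroupsAreal
#' @param values Named list of cells x days matrices: `pm25`, `tmin`, `tmax`,
#'   `vp`.
#' @param dates `Date` vector labelling columns.
#' @param blocks `data.frame` with `geoid15`, `x`, `y`, `population`.
#' @param crosswalk Optional crosswalk from [buildCrosswalk()]; when given,
#'   the panel rows carry the `redlined` flag.
#' @return An [ExposurePanel-class].
#' @export
buildExposurePanel <- function(cellXY, pitch, values, dates, blocks,
                               blockPolys, bgPolys, crosswalk = NULL) {
  pmBlock <- assignGridToBlocks(cellXY, values$pm25, blockPolys,
                                blocks[, c("geoid15", "x", "y")])
  pmBG <- blocksToGroups(pmBlock, blocks$population)
  met <- lapply(values[c("tmin", "tmax", "vp")], function(v)
    gridToGroupsAreal(cellXY, pitch, v, bgPolys))
  ids <- rownames(pmBG)
  met <- lapply(met, function(m) m[ids, , drop = FALSE])
  pop <- as.vector(rowsum(blocks$population,
                          truncateBlockGeoid(blocks$geoid15))[ids, ])
  red <- NULL
  if (!is.null(crosswalk)) {
    red <- crosswalk$redlined[match(ids, crosswalk$geoid12)]
    red[is.na(red)] <- FALSE
  }
  ExposurePanel(pm25 = pmBG, tmin = met$tmin, tmax = met$tmax, vp = met$vp,
                geoids = ids, dates = dates, population = pop, redlined = red)
}
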