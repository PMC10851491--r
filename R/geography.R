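# HOLC grade apportionment: standardize Census identifiers and assign block
# groups to HOLC security-map grades by the population-threshold algorithm
# (bin block populations into the grade of the HOLC polygon containing the
# block centroid, then label the block group by the bin exceeding a share
# threshold of its total population).

.HOLC_GRADES <- c("A", "B", "C", "D", "E")
.BIN_LEVELS <- c(.HOLC_GRADES, "Unclassified")

#' Truncate block GEOIDs to block-group GEOIDs
#'
#' Census block identifiers are 15 digits; the first 12 identify the parent
#' block group.
#'
#' @param geoid15 Character vector of 15-digit block GEOIDs.
#' @return Character vector of 12-character block-group GEOIDs.
#' @examples
#' truncateBlockGeoid("250250101011001")
#' @export
truncateBlockGeoid <- function(geoid15) {
  geoid15 <- as.character(geoid15)
  bad <- nchar(geoid15) != 15L | !grepl("^[0-9]{15}$", geoid15)
  if (any(bad))
    stop("malformed block GEOID (need 15 digits): ",
         paste(utils::head(geoid15[bad], 3L), collapse = ", "))
  substr(geoid15, 1L, 12L)
}

#' Bin block populations into HOLC grades by centroid containment
#'
#' Performs the point-in-polygon spatial join of block centroids against HOLC
#' polygons and sums block populations into per-block-group grade bins. Blocks
#' whose centroid falls in no HOLC polygon are binned as `Unclassified`. A
#' centroid on a polygon boundary counts as contained; if several polygons
#' contain one centroid the worst grade (latest in A < B < C < D < E) wins and
#' the event is recorded in the `"overlaps"` attribute.
#'
#' @param blocks `data.frame` with columns `geoid15`, `x`, `y`, `population`
#'   (planar centroid coordinates, non-negative decennial counts).
#' @param holc List of HOLC features, each a list with elements `grade` (one of
#'   A--E) and `geometry` (a list of polygons; see [pointInPolygon()]).
#' @return `data.frame` with one row per block group: `geoid12`, one column per
#'   bin (`A`,`B`,`C`,`D`,`E`,`Unclassified`) and `total_population`.
#' @export
binPopulation <- function(blocks, holc) {
  stopifnot(all(c("geoid15", "x", "y", "population") %in% names(blocks)))
  if (any(blocks$population < 0)) stop("negative block population")
  geoid12 <- truncateBlockGeoid(blocks$geoid15)

  grade <- rep(NA_character_, nrow(blocks))
  overlaps <- 0L
  for (feat in holc) {
    if (!feat$grade %in% .HOLC_GRADES)
      stop("unknown HOLC grade: ", feat$grade)
    hit <- .pipGeometry(blocks$x, blocks$y, feat$geometry)
    already <- hit & !is.na(grade) & grade != feat$grade
    if (any(already)) {
      overlaps <- overlaps + sum(already)
      # worse grade (later in A..E) wins
      worse <- match(feat$grade, .HOLC_GRADES) > match(grade, .HOLC_GRADES)
      grade[already & worse] <- feat$grade
      hit <- hit & is.na(grade)
    }
    grade[hit & is.na(grade)] <- feat$grade
  }
  bin <- factor(ifelse(is.na(grade), "Unclassified", grade),
                levels = .BIN_LEVELS)

  tab <- tapply(blocks$population, list(geoid12, bin), sum, default = 0)
  out <- data.frame(geoid12 = rownames(tab), as.data.frame(unclass(tab)),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$total_population <- rowSums(out[, .BIN_LEVELS])
  if (overlaps > 0L)
    message(overlaps, " block centroid(s) in overlapping HOLC polygons; ",
            "worst grade assigned")
  attr(out, "overlaps") <- overlaps
  out
}

#' Assign block groups a HOLC grade by population-share threshold
#'
#' Labels each block group with the bin holding strictly more than
#' `threshold` of its total population, `Ambiguous` when no bin qualifies.
#' With `threshold > 0.5` at most one bin can qualify. `redlined` is `TRUE`
#' exactly for grade D.
#'
#' @param bins Output of [binPopulation()].
#' @param threshold Population-share threshold in (0, 1]; the main analysis of
#'   the underlying design uses 0.9, with 0.5 and 0.99 as sensitivity values.
#' @return `data.frame`: `geoid12`, `label` (A--E, `Unclassified`,
#'   `Ambiguous`), `redlined`, per-bin shares (`share_A`, ...), and
#'   `total_population`, `threshold`.
#' @export
assignGrade <- function(bins, threshold = 0.9) {
  stopifnot(length(threshold) == 1L, threshold > 0, threshold <= 1)
  if (any(bins$total_population == 0))
    stop("block group(s) with zero total population: ",
         paste(utils::head(bins$geoid12[bins$total_population == 0], 3L),
               collapse = ", "))
  shares <- as.matrix(bins[, .BIN_LEVELS]) / bins$total_population
  exceeds <- shares > threshold              # strict comparison
  label <- rep("Ambiguous", nrow(bins))
  hit <- which(rowSums(exceeds) > 0L)
  label[hit] <- .BIN_LEVELS[max.col(exceeds[hit, , drop = FALSE],
                                    ties.method = "first")]
  out <- data.frame(geoid12 = bins$geoid12, label = label,
                    redlined = label == "D", stringsAsFactors = FALSE)
  colnames(shares) <- paste0("share_", .BIN_LEVELS)
  cbind(out, shares,
        data.frame(total_population = bins$total_population,
                   threshold = threshold))
}

#' Build the block-group to HOLC-grade crosswalk
#'
#' Convenience wrapper: [binPopulation()] then [assignGrade()]. Block groups
#' with zero total population are dropped from grading but retained in the
#' result with `label = NA` so callers can still look up their population.
#'
#' @inheritParams binPopulation
#' @inheritParams assignGrade
#' @return `data.frame` as from [assignGrade()] plus `NA`-labelled
#'   zero-population rows.
#' @export
buildCrosswalk <- function(blocks, holc, threshold = 0.9) {
  bins <- binPopulation(blocks, holc)
  zero <- bins$total_population == 0
  graded <- assignGrade(bins[!zero, , drop = FALSE], threshold)
  if (any(zero)) {
    z <- bins[zero, , drop = FALSE]
    shares <- matrix(NA_real_, nrow(z), length(.BIN_LEVELS),
                     dimnames = list(NULL, paste0("share_", .BIN_LEVELS)))
    zr <- cbind(data.frame(geoid12 = z$geoid12, label = NA_character_,
                           redlined = NA, stringsAsFactors = FALSE),
                shares,
                data.frame(total_population = 0, threshold = threshold))
    graded <- rbind(graded, zr)
  }
  graded[order(graded$geoid12), , drop = FALSE]
}

#' Read HOLC polygons from GeoJSON
#'
#' Parses a GeoJSON FeatureCollection whose features carry a `grade` property
#' (A--E) and Polygon or MultiPolygon geometry in planar coordinates.
#'
#' @param path Path to a GeoJSON file.
#' @return List of features as consumed by [binPopulation()].
#' @export
readHOLCGeoJSON <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection")
  lapply(gj$features, function(f) {
    geom <- f$geometry
    ringify <- function(r)
      do.call(rbind, lapply(r, function(pt) c(pt[[1L]], pt[[2L]])))
    polys <- switch(geom$type,
      Polygon = list(lapply(geom$coordinates, ringify)),
      MultiPolygon = lapply(geom$coordinates,
                            function(p) lapply(p, ringify)),
      stop("unsupported geometry type: ", geom$type))
    list(grade = f$properties$grade, geometry = polys)
  })
}

#' Write HOLC polygons to GeoJSON
#'
#' Inverse of [readHOLCGeoJSON()]; the synthetic-data generator uses this so
#' the pipeline consumes the same file format as real HOLC map exports.
#'
#' @param holc List of features (`grade` + `geometry`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeHOLCGeoJSON <- function(holc, path) {
  features <- lapply(holc, function(f) {
    coords <- lapply(f$geometry, function(poly)
      lapply(poly, function(ring) {
        ring <- .closeRing(ring)
        lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1L], ring[i, 2L]))
      }))
    list(type = "Feature",
         properties = list(grade = f$grade),
         geometry = list(type = "MultiPolygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
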