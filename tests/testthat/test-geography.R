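# HOLC grade apportionment: GEOID handling, population binning by centroid
# containment, and threshold-based grade assignment.

test_that("block GEOIDs truncate to block-group GEOIDs and malformed input errors", {
  expect_identical(truncateBlockGeoid("250250101011001"), "250250101011")
  expect_identical(truncateBlockGeoid("060371234561999"), "060371234561")
  expect_identical(truncateBlockGeoid(c("250250101011001", "060371234561999")),
                   c("250250101011", "060371234561"))
  expect_error(truncateBlockGeoid("12345"), "malformed")
  expect_error(truncateBlockGeoid("25025010101100X"), "malformed")
})

test_that("population bins follow centroid containment, with Unclassified fallback", {
  blocks <- data.frame(
    geoid15 = paste0("250250101011", c("001", "002", "003")),
    x = c(1, 2, 9), y = c(1, 2, 9),
    population = c(10, 20, 70))
  dSquare <- list(grade = "D",
                  geometry = list(list(cbind(c(0, 4, 4, 0), c(0, 0, 4, 4)))))
  bins <- binPopulation(blocks, list(dSquare))
  expect_equal(bins$D, 30)
  expect_equal(bins$Unclassified, 70)
  expect_equal(bins$total_population, 100)

  empty <- binPopulation(blocks, list())
  expect_equal(empty$Unclassified, 100)
  expect_equal(empty$total_population, 100)
})

test_that("a centroid on a polygon boundary counts as contained", {
  blocks <- data.frame(geoid15 = "250250101011001", x = 4, y = 2,
                       population = 50)
  dSquare <- list(grade = "D",
                  geometry = list(list(cbind(c(0, 4, 4, 0), c(0, 0, 4, 4)))))
  bins <- binPopulation(blocks, list(dSquare))
  expect_equal(bins$D, 50)
})

test_that("overlapping HOLC polygons resolve to the worse grade and are logged", {
  blocks <- data.frame(geoid15 = "250250101011001", x = 1, y = 1,
                       population = 10)
  sq <- list(cbind(c(0, 2, 2, 0), c(0, 0, 2, 2)))
  holc <- list(list(grade = "B", geometry = list(sq)),
               list(grade = "D", geometry = list(sq)))
  expect_message(bins <- binPopulation(blocks, holc), "overlapping")
  expect_equal(bins$D, 10)
  expect_equal(bins$B, 0)
  expect_gte(attr(bins, "overlaps"), 1L)
  # order of features must not matter
  expect_message(bins2 <- binPopulation(blocks, rev(holc)), "overlapping")
  expect_equal(bins2$D, 10)
})

test_that("random block/polygon fixtures match the all-pairs containment oracle", {
  set.seed(101)
  for (rep in 1:20) {
    nBlocks <- 50L
    nPolys <- sample(3:10, 1)
    # axis-aligned rectangles so the oracle is plain coordinate comparison
    rects <- data.frame(xmin = runif(nPolys, 0, 8), ymin = runif(nPolys, 0, 8))
    rects$xmax <- rects$xmin + runif(nPolys, 0.5, 3)
    rects$ymax <- rects$ymin + runif(nPolys, 0.5, 3)
    grades <- sample(c("A", "B", "C", "D", "E"), nPolys, replace = TRUE)
    holc <- lapply(seq_len(nPolys), function(i)
      list(grade = grades[i],
           geometry = list(list(cbind(
             c(rects$xmin[i], rects$xmax[i], rects$xmax[i], rects$xmin[i]),
             c(rects$ymin[i], rects$ymin[i], rects$ymax[i], rects$ymax[i]))))))
    blocks <- data.frame(
      geoid15 = sprintf("25025%06d1%03d", sample(1:4, nBlocks, TRUE),
                        seq_len(nBlocks)),
      x = runif(nBlocks, 0, 10), y = runif(nBlocks, 0, 10),
      population = sample(0:500, nBlocks, TRUE))

    # oracle: test every (block, polygon) pair, worst containing grade wins
    oracleBin <- vapply(seq_len(nBlocks), function(b) {
      inPoly <- rects$xmin <= blocks$x[b] & blocks$x[b] <= rects$xmax &
        rects$ymin <= blocks$y[b] & blocks$y[b] <= rects$ymax
      if (!any(inPoly)) return("Unclassified")
      sort(grades[inPoly], decreasing = TRUE)[1]
    }, character(1))
    oracleTab <- tapply(blocks$population,
                        list(truncateBlockGeoid(blocks$geoid15),
                             factor(oracleBin, levels = c("A", "B", "C", "D",
                                                          "E", "Unclassified"))),
                        sum, default = 0)

    bins <- suppressMessages(binPopulation(blocks, holc))
    got <- as.matrix(bins[, c("A", "B", "C", "D", "E", "Unclassified")])
    rownames(got) <- bins$geoid12
    expect_equal(got[rownames(oracleTab), ], unclass(oracleTab)[, ],
                 ignore_attr = TRUE)
    # population conservation per block group
    expect_equal(unname(rowSums(got)),
                 as.vector(rowsum(blocks$population,
                                  truncateBlockGeoid(blocks$geoid15))))
  }
})

test_that("grade assignment uses a strict share threshold", {
  bins <- data.frame(geoid12 = c("250250101011", "250250101012"),
                     A = c(0, 0), B = c(0, 0), C = c(5, 40), D = c(95, 60),
                     E = c(0, 0), Unclassified = c(0, 0),
                     total_population = c(100, 100))
  a <- assignGrade(bins, 0.9)
  expect_equal(a$label, c("D", "Ambiguous"))
  expect_equal(a$redlined, c(TRUE, FALSE))
  # exactly at the threshold -> Ambiguous (strict comparison)
  atT <- data.frame(geoid12 = "x", A = 0, B = 0, C = 10, D = 90, E = 0,
                    Unclassified = 0, total_population = 100)
  expect_equal(assignGrade(atT, 0.9)$label, "Ambiguous")
  expect_error(assignGrade(data.frame(geoid12 = "z", A = 0, B = 0, C = 0,
                                      D = 0, E = 0, Unclassified = 0,
                                      total_population = 0), 0.9),
               "zero")
})

test_that("threshold sweep matches brute-force share enumeration", {
  set.seed(202)
  lv <- c("A", "B", "C", "D", "E", "Unclassified")
  for (rep in 1:20) {
    n <- 30L
    pops <- matrix(rpois(n * 6, lambda = sample(c(2, 20, 100), 1)), n, 6,
                   dimnames = list(NULL, lv))
    keep <- rowSums(pops) > 0
    bins <- data.frame(geoid12 = sprintf("25025%06d%d", 1:n, 1), pops,
                       total_population = rowSums(pops))[keep, ]
    for (th in c(0.5, 0.9, 0.99)) {
      got <- assignGrade(bins, th)
      want <- apply(as.matrix(bins[, lv]) / bins$total_population, 1,
                    function(s) {
                      hit <- which(s > th)
                      if (length(hit)) lv[hit[1]] else "Ambiguous"
                    })
      expect_equal(got$label, unname(want))
    }
  }
})

test_that("labels are monotone in the threshold", {
  set.seed(303)
  lv <- c("A", "B", "C", "D", "E", "Unclassified")
  n <- 200L
  pops <- matrix(rpois(n * 6, 15), n, 6, dimnames = list(NULL, lv))
  pops[sample(n, 50), 4] <- pops[sample(n, 50), 4] + 200  # concentrated bins
  bins <- data.frame(geoid12 = sprintf("25025%06d%d", 1:n, 1), pops,
                     total_population = rowSums(pops))
  bins <- bins[bins$total_population > 0, ]
  ths <- c(0.55, 0.75, 0.9, 0.99)
  labels <- sapply(ths, function(t) assignGrade(bins, t)$label)
  for (j in seq_along(ths)[-1]) {
    hi <- labels[, j]; lo <- labels[, j - 1]
    # a concrete grade at the higher threshold persists at every lower one
    conc <- hi != "Ambiguous"
    expect_true(all(lo[conc] == hi[conc]))
    # raising the threshold never converts Ambiguous to a concrete grade
    expect_true(all(hi[lo == "Ambiguous"] == "Ambiguous"))
  }
})

test_that("the crosswalk round-trips HOLC polygons through GeoJSON", {
  study <- smallStudy()
  path <- tempfile(fileext = ".geojson")
  writeHOLCGeoJSON(study$geography$holc, path)
  back <- readHOLCGeoJSON(path)
  expect_equal(vapply(back, `[[`, "", "grade"),
               vapply(study$geography$holc, `[[`, "", "grade"))
  cw1 <- buildCrosswalk(study$geography$blocks, study$geography$holc, 0.9)
  cw2 <- buildCrosswalk(study$geography$blocks, back, 0.9)
  expect_equal(cw1, cw2)
})
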