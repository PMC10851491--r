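# Grid-to-block-group exposure assignment and moving averages.

test_that("blocks take the mean of encompassed grid centroids, else the nearest cell", {
  cellXY <- data.frame(x = c(1, 3, 10), y = c(1, 1, 10))
  vals <- matrix(c(8, 12, 7.5), 3, 1)
  blockPolys <- list(
    b1 = list(cbind(c(0, 4, 4, 0), c(0, 0, 2, 2))),   # contains cells 1, 2
    b2 = list(cbind(c(5, 6, 6, 5), c(8, 8, 9, 9))))   # contains none
  blockXY <- data.frame(geoid15 = c("b1", "b2"), x = c(2, 5.5), y = c(1, 8.5))
  out <- assignGridToBlocks(cellXY, vals, blockPolys, blockXY)
  expect_equal(unname(out["b1", 1]), 10)
  expect_equal(unname(out["b2", 1]), 7.5)  # nearest is cell 3
  expect_error(assignGridToBlocks(cellXY[0, ], vals[0, , drop = FALSE],
                                  blockPolys, blockXY), "empty grid")
})

test_that("random grids match the brute-force containment + nearest-neighbour oracle", {
  set.seed(404)
  for (rep in 1:5) {
    g <- expand.grid(x = seq(0.5, 19.5, 1), y = seq(0.5, 19.5, 1))
    vals <- matrix(rnorm(nrow(g) * 3, 10, 2), nrow(g), 3)
    nB <- 30L
    bx <- runif(nB, 1, 18); by <- runif(nB, 1, 18)
    w <- runif(nB, 0.3, 3); h <- runif(nB, 0.3, 3)
    blockPolys <- lapply(seq_len(nB), function(i)
      list(cbind(c(bx[i] - w[i] / 2, bx[i] + w[i] / 2, bx[i] + w[i] / 2,
                   bx[i] - w[i] / 2),
                 c(by[i] - h[i] / 2, by[i] - h[i] / 2, by[i] + h[i] / 2,
                   by[i] + h[i] / 2))))
    names(blockPolys) <- sprintf("b%02d", seq_len(nB))
    blockXY <- data.frame(geoid15 = names(blockPolys), x = bx, y = by)
    out <- assignGridToBlocks(g, vals, blockPolys, blockXY)
    for (i in seq_len(nB)) {
      inb <- g$x >= bx[i] - w[i] / 2 & g$x <= bx[i] + w[i] / 2 &
        g$y >= by[i] - h[i] / 2 & g$y <= by[i] + h[i] / 2
      want <- if (any(inb)) colMeans(vals[inb, , drop = FALSE])
      else vals[which.min((g$x - bx[i])^2 + (g$y - by[i])^2), ]
      expect_equal(unname(out[i, ]), unname(want))
    }
  }
})

test_that("population weighting is exact, convex and scale-invariant", {
  v <- cbind(c(10, 20))
  expect_equal(unname(blocksToGroups(v, c(100, 100), c("g", "g"))[1, 1]), 15)
  expect_equal(unname(blocksToGroups(v, c(300, 100), c("g", "g"))[1, 1]), 12.5)
  # constant values map to the constant under any weights
  expect_equal(unname(blocksToGroups(cbind(c(7, 7, 7)), c(1, 50, 3),
                                     rep("g", 3))[1, 1]), 7)
  # scaling all weights leaves the output unchanged
  set.seed(1)
  vals <- cbind(rnorm(6), rnorm(6))
  pops <- sample(1:100, 6)
  gid <- rep(c("a", "b"), each = 3)
  expect_equal(blocksToGroups(vals, pops, gid),
               blocksToGroups(vals, pops * 13, gid))
  # convexity: each group value lies within the member range, per column
  out <- blocksToGroups(vals, pops, gid)
  for (j in 1:2) {
    lo <- tapply(vals[, j], gid, min)
    hi <- tapply(vals[, j], gid, max)
    expect_true(all(out[names(lo), j] >= lo - 1e-12 &
                      out[names(hi), j] <= hi + 1e-12))
  }
  expect_error(blocksToGroups(vals, rep(0, 6), gid), "zero")
})

test_that("areal weighting reproduces hand-computable intersections", {
  # block group entirely inside one cell of value 9
  cellXY <- data.frame(x = c(5, 15), y = c(5, 5))
  vals <- matrix(c(9, 4), 2, 1)
  inner <- list(g1 = list(cbind(c(2, 4, 4, 2), c(2, 2, 4, 4))))
  expect_equal(unname(gridToGroupsAreal(cellXY, 10, vals, inner)[1, 1]), 9)
  # 25% in a cell valued 0, 75% in a cell valued 4 -> 3
  vals2 <- matrix(c(0, 4), 2, 1)
  split <- list(g1 = list(cbind(c(7.5, 17.5, 17.5, 7.5), c(2, 2, 4, 4))))
  expect_equal(unname(gridToGroupsAreal(cellXY, 10, vals2, split)[1, 1]), 3)
  # no intersecting footprint -> error
  far <- list(g1 = list(cbind(c(50, 51, 51, 50), c(50, 50, 51, 51))))
  expect_error(gridToGroupsAreal(cellXY, 10, vals, far), "no grid cell")
})

test_that("areal weights over a random polygon match a Monte-Carlo oracle", {
  set.seed(505)
  cellXY <- expand.grid(x = seq(1, 19, 2), y = seq(1, 19, 2))
  vals <- matrix(runif(nrow(cellXY), 5, 15), nrow(cellXY), 1)
  for (rep in 1:3) {
    poly <- randomStarPolygon(9, runif(1, 6, 14), runif(1, 6, 14), 2, 5)
    got <- gridToGroupsAreal(cellXY, 2, vals, list(g = list(poly)))[1, 1]
    # sample uniformly in the polygon, average the containing cell's value
    bb <- apply(poly, 2, range)
    px <- runif(2e5, bb[1, 1], bb[2, 1])
    py <- runif(2e5, bb[1, 2], bb[2, 2])
    keep <- oracleInRingVec(px, py, poly)
    cellOf <- pmin(pmax(ceiling(px[keep] / 2), 1), 10) +
      10 * (pmin(pmax(ceiling(py[keep] / 2), 1), 10) - 1)
    mc <- mean(vals[cellOf, 1])
    expect_lt(abs(got - mc) / mc, 0.01)
  }
})

test_that("moving averages honour the lag window and calendar gaps", {
  d <- as.Date("2005-03-01") + 0:9
  x <- c(1, 2, 3, 8, 10, 12, 5, 5, 5, 5)
  ma3 <- movingAverage(x, d, 3)
  expect_equal(ma3[6], 10)           # mean of 8, 10, 12
  expect_true(all(is.na(ma3[1:2])))  # window precedes the series
  expect_equal(movingAverage(x, d, 1), x)

  # leap-year Dec 31 is absent from the 365-day calendar: windows crossing it
  # are missing
  dates <- daymetDates(2004:2005)
  x2 <- rep(1, length(dates))
  ma5 <- movingAverage(x2, dates, 5)
  jan <- which(format(dates, "%Y-%m-%d") %in%
                 paste0("2005-01-0", 1:4))
  expect_true(all(is.na(ma5[jan])))
  expect_false(is.na(ma5[which(format(dates, "%Y-%m-%d") == "2005-01-05")]))

  # conservation: k-day averages of a constant series equal the constant
  expect_true(all(ma5[!is.na(ma5)] == 1))
  full <- movingAverage(rep(3, 100), as.Date("2010-01-01") + 0:99, 4)
  expect_equal(sum(full[4:100]), 3 * 97)
})

test_that("the exposure panel enforces its invariants and exposes accessors", {
  study <- smallStudy()
  p <- study$panel
  expect_s4_class(p, "ExposurePanel")
  expect_equal(tmeanTemperature(p),
               (tminTemperature(p) + SummarizedExperiment::assay(p, "tmax")) / 2)
  expect_true(all(pm25(p) >= 0))
  expect_true(all(vaporPressure(p) >= 0))
  expect_identical(rownames(pm25(p, k = 5)), geoids(p))
  # aggregation outputs are convex: panel values lie within the grid's range
  expos <- study$exposures
  expect_true(all(pm25(p) >= min(expos$values$pm25) - 1e-9 &
                    pm25(p) <= max(expos$values$pm25) + 1e-9))
  # validity catches a broken tmean identity
  broken <- p
  SummarizedExperiment::assay(broken, "tmean")[1, 1] <-
    SummarizedExperiment::assay(broken, "tmean")[1, 1] + 5
  expect_error(methods::validObject(broken), "tmean")
})
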