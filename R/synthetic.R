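# Seeded synthetic study generator. Emits a rectangular city (an inner
# HOLC-graded core of grade bands inside a larger ungraded region, deliberately
# misaligned with the block-group lattice), gridded daily exposures (seasonal
# temperature and vapor-pressure cycles with AR(1) noise; log-normal AR(1)
# PM2.5 elevated inside redlined polygons), and mortality cases whose death
# day is drawn within its month / day-of-week referent stratum with
# probability proportional to exp(eta) under known true coefficients - the
# exact generative counterpart of the conditional logistic likelihood, so
# parameter recovery is a correctly-specified test of the fitter.

#' SimConfig: parameters of the synthetic study
#'
#' @slot seed Integer; fully determines every generated output.
#' @slot nBGx,nBGy Block-group lattice dimensions.
#' @slot bgSize Block-group square side (m).
#' @slot blocksPerSide Blocks per block-group side (so blocks per group is its
#'   square).
#' @slot gridPitch Exposure grid pitch (m).
#' @slot years Calendar years simulated.
#' @slot nCases Mortality cases drawn.
#' @slot betaTrue Named true log-odds coefficients: `pm25` (per 10 ug/m^3),
#'   `pm25_redlined` (interaction, per 10 ug/m^3), `heat`, `heat_redlined`.
#' @slot pm25RedlinedOffset Additive PM2.5 elevation (ug/m^3) inside redlined
#'   polygons, calibrated to the observed redlined vs. overall contrast
#'   (about 10.95 vs 9.61 ug/m^3).
#' @slot tempRedlinedOffset Urban-heat-island temperature elevation (deg C)
#'   inside redlined polygons.
#' @slot threshold Population-share threshold for the grade crosswalk.
#' @slot heatPercentile Extreme-heat percentile.
#' @slot caseSampling `"stratum"` (within-referent-stratum softmax, the
#'   default) or `"hazard"` (death day drawn across the whole calendar,
#'   emulating a per-day hazard and its small post-death sampling bias).
#' @slot stateFips Two-digit state FIPS prefix of all GEOIDs.
#' @export
setClass("SimConfig", representation(
  seed = "integer", nBGx = "integer", nBGy = "integer", bgSize = "numeric",
  blocksPerSide = "integer", gridPitch = "numeric", years = "integer",
  nCases = "integer", betaTrue = "numeric", pm25RedlinedOffset = "numeric",
  tempRedlinedOffset = "numeric", threshold = "numeric",
  heatPercentile = "numeric", caseSampling = "character",
  stateFips = "character"))

setValidity("SimConfig", function(object) {
  need <- c("pm25", "pm25_redlined", "heat", "heat_redlined")
  if (!all(need %in% names(object@betaTrue)))
    return(paste("betaTrue needs names:", paste(need, collapse = ", ")))
  if (!all(is.finite(object@betaTrue))) return("betaTrue must be finite")
  if (!object@caseSampling %in% c("stratum", "hazard"))
    return("caseSampling must be 'stratum' or 'hazard'")
  TRUE
})

#' Construct a SimConfig
#'
#' Defaults define the reference synthetic study: an 8 x 8 lattice of 1-km
#' block groups (4 blocks each), a 600-m exposure grid, four years including
#' one leap year, true interaction log-ORs log(1.01) per 10 ug/m^3 (PM2.5) and
#' log(1.02) (extreme heat), and a +1.34 ug/m^3 redlined PM2.5 offset.
#'
#' @param seed Integer seed.
#' @param ... Any [SimConfig-class] slot by name.
#' @return A [SimConfig-class].
#' @examples
#' cfg <- simConfig(seed = 1, nCases = 500L)
#' @export
simConfig <- function(seed = 1L, ...) {
  args <- list(...)
  defaults <- list(
    seed = as.integer(seed), nBGx = 8L, nBGy = 8L, bgSize = 1000,
    blocksPerSide = 2L, gridPitch = 600, years = 2001:2004,
    nCases = 2000L,
    betaTrue = c(pm25 = log(1.01), pm25_redlined = log(1.01),
                 heat = log(1.03), heat_redlined = log(1.02)),
    pm25RedlinedOffset = 1.34, tempRedlinedOffset = 0.5,
    threshold = 0.9, heatPercentile = 95,
    caseSampling = "stratum", stateFips = "25")
  defaults[names(args)] <- args
  defaults$seed <- as.integer(defaults$seed)
  defaults$years <- as.integer(defaults$years)
  defaults$nCases <- as.integer(defaults$nCases)
  defaults$nBGx <- as.integer(defaults$nBGx)
  defaults$nBGy <- as.integer(defaults$nBGy)
  defaults$blocksPerSide <- as.integer(defaults$blocksPerSide)
  do.call(new, c(list("SimConfig"), defaults))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: seed", object@seed, "-", object@nBGx, "x", object@nBGy,
      "block groups,", length(object@years), "years,",
      object@nCases, "cases\n")
})

.rectPoly <- function(xmin, ymin, xmax, ymax) {
  list(.rectRing(xmin, ymin, xmax, ymax))
}

#' Generate the synthetic city geography
#'
#' A rectangular lattice of square block groups, each split into square
#' blocks with log-normal populations. An inner core carries HOLC grade bands
#' A--D (plus one small grade-E patch), drawn as polygons shifted off the
#' block-group lattice so grades and block groups are spatially misaligned, as
#' on real security maps; the outer ring is ungraded.
#'
#' @param config A [SimConfig-class].
#' @return List: `blocks` (`data.frame` geoid15, x, y, population),
#'   `blockPolys`, `bgPolys` (named polygon lists), `holc` (feature list),
#'   `bgMeta` (`data.frame` geoid12, state, black_share, white_share).
#' @export
genGeography <- function(config) {
  set.seed(config@seed)
  s <- config@bgSize
  bps <- config@blocksPerSide
  bs <- s / bps
  nx <- config@nBGx; ny <- config@nBGy

  bgIdx <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  geoid12 <- sprintf("%s025%06d1", config@stateFips, seq_len(nrow(bgIdx)))
  bgPolys <- lapply(seq_len(nrow(bgIdx)), function(i)
    .rectPoly((bgIdx$ix[i] - 1) * s, (bgIdx$iy[i] - 1) * s,
              bgIdx$ix[i] * s, bgIdx$iy[i] * s))
  names(bgPolys) <- geoid12

  blocks <- do.call(rbind, lapply(seq_len(nrow(bgIdx)), function(i) {
    sub <- expand.grid(jx = seq_len(bps), jy = seq_len(bps))
    data.frame(
      geoid15 = sprintf("%s%03d", geoid12[i], seq_len(nrow(sub))),
      x = (bgIdx$ix[i] - 1) * s + (sub$jx - 0.5) * bs,
      y = (bgIdx$iy[i] - 1) * s + (sub$jy - 0.5) * bs,
      stringsAsFactors = FALSE)
  }))
  blocks$population <- round(stats::rlnorm(nrow(blocks), log(250), 0.5))
  blockPolys <- lapply(seq_len(nrow(blocks)), function(i)
    .rectPoly(blocks$x[i] - bs / 2, blocks$y[i] - bs / 2,
              blocks$x[i] + bs / 2, blocks$y[i] + bs / 2))
  names(blockPolys) <- blocks$geoid15

  # HOLC core: inner (nx-2) x (ny-2) block-group region, split into vertical
  # bands A | B | C | C | D | D, then shifted so polygon and lattice edges
  # disagree (the source of Ambiguous assignments).
  shiftX <- 0.15 * s  # keeps band edges off block centroids (clean columns)
  shiftY <- 0.35 * s  # splits the top/bottom core rows 50/50 (Ambiguous)
  x0 <- s; x1 <- (nx - 1) * s
  y0 <- s + shiftY; y1 <- (ny - 1) * s + shiftY
  coreW <- x1 - x0
  bandGrades <- c("A", "B", "C", "C", "D", "D")
  nb <- length(bandGrades)
  edges <- x0 + coreW * (0:nb) / nb + shiftX
  holc <- lapply(seq_len(nb), function(b)
    list(grade = bandGrades[b],
         geometry = list(.rectPoly(edges[b], y0, edges[b + 1], y1))))
  holc <- c(holc, list(list(
    grade = "E",
    geometry = list(.rectPoly(0.1 * s, (ny - 0.9) * s,
                              0.9 * s, (ny - 0.1) * s)))))

  # higher Black population share inside the redlined bands
  dBand <- edges[c(nb - 1, nb + 1)]
  bgCx <- (bgIdx$ix - 0.5) * s
  inD <- bgCx > dBand[1] & bgCx < dBand[2]
  blackShare <- stats::plogis(stats::qlogis(0.15) + 1.8 * inD +
                              stats::rnorm(nrow(bgIdx), 0, 0.5))
  bgMeta <- data.frame(geoid12 = geoid12, state = config@stateFips,
                       black_share = blackShare,
                       white_share = 1 - blackShare,
                       stringsAsFactors = FALSE)
  list(blocks = blocks, blockPolys = blockPolys, bgPolys = bgPolys,
       holc = holc, bgMeta = bgMeta)
}

#' Generate gridded daily exposures
#'
#' Minimum temperature is an annual sinusoid plus a city-wide AR(1) and
#' cell-level noise; maximum temperature sits above it; vapor pressure tracks
#' mean temperature; PM2.5 is log-normal with a city-wide AR(1) day component,
#' elevated additively inside redlined (grade D) polygons. Cells inside
#' redlined polygons are also warmed by the configured urban-heat-island
#' offset. The calendar is 365-day (no December 31 in leap years).
#'
#' @param config A [SimConfig-class].
#' @param geography Output of [genGeography()].
#' @return List: `cellXY`, `pitch`, `values` (named matrices cells x days),
#'   `dates`.
#' @export
genExposures <- function(config, geography) {
  set.seed(config@seed + 1L)
  s <- config@bgSize
  W <- config@nBGx * s; H <- config@nBGy * s
  pitch <- config@gridPitch
  gx <- seq(pitch / 2, W, by = pitch)
  gy <- seq(pitch / 2, H, by = pitch)
  cellXY <- expand.grid(x = gx, y = gy)
  nC <- nrow(cellXY)

  dGeom <- Filter(function(f) f$grade == "D", geography$holc)
  redCell <- rep(FALSE, nC)
  for (f in dGeom) redCell <- redCell | .pipGeometry(cellXY$x, cellXY$y, f$geometry)

  dates <- daymetDates(config@years)
  nD <- length(dates)
  doy <- as.POSIXlt(dates)$yday + 1

  ar1 <- function(n, phi, sd) {
    z <- numeric(n)
    z[1L] <- stats::rnorm(1L, 0, sd / sqrt(1 - phi^2))
    eps <- stats::rnorm(n - 1L, 0, sd)
    for (i in 2:n) z[i] <- phi * z[i - 1L] + eps[i - 1L]
    z
  }
  seasonal <- 10 + 12 * sin(2 * pi * (doy - 105) / 365.25)
  cityT <- ar1(nD, 0.7, 1.8)
  cellT <- stats::rnorm(nC, 0, 0.7) + redCell * config@tempRedlinedOffset
  tmin <- outer(cellT, seasonal + cityT, "+") +
    matrix(stats::rnorm(nC * nD, 0, 1.2), nC, nD)
  tmax <- tmin + 8 + matrix(stats::rnorm(nC * nD, 0, 1.5), nC, nD)
  tmeanC <- (tmin + tmax) / 2
  vp <- pmax(0.55 + 0.045 * tmeanC +
               matrix(stats::rnorm(nC * nD, 0, 0.12), nC, nD), 0.05)
  cityP <- ar1(nD, 0.6, 0.35)
  logpm <- log(8.2) + matrix(cityP, nC, nD, byrow = TRUE) +
    matrix(stats::rnorm(nC * nD, 0, 0.25), nC, nD)
  pm25 <- exp(logpm) + redCell * config@pm25RedlinedOffset

  dn <- list(NULL, as.character(dates))
  values <- lapply(list(pm25 = pm25, tmin = tmin, tmax = tmax, vp = vp),
                   `dimnames<-`, dn)
  list(cellXY = cellXY, pitch = pitch, values = values, dates = dates)
}

# Table-1-style categorical margins (overall vs redlined columns).
.demoMargins <- list(
  sex = list(levels = c("Male", "Female"),
             all = c(0.4865, 0.5135), red = c(0.4944, 0.5056)),
  race = list(levels = c("White", "Black", "Other", "Unknown"),
              all = c(0.8572, 0.1032, 0.0359, 0.0037),
              red = c(0.5372, 0.3878, 0.0717, 0.0033)),
  education = list(levels = c("LessThanHS", "HS", "MoreThanHS", "Unknown"),
                   all = c(0.2212, 0.4115, 0.3251, 0.0422),
                   red = c(0.3349, 0.4025, 0.2090, 0.0536)))

.INTERNAL_CAUSES <- c("I21.9", "I25.1", "C34.9", "J44.9", "G30.9",
                      "E11.9", "I64", "N18.9", "A41.9", "R99")

#' Generate mortality cases with known ground truth
#'
#' Each case draws a home block group (population-weighted), a calendar month
#' and a weekday; the death day is then drawn among that month's same-weekday
#' days with probability proportional to `exp(eta)`, where `eta` combines the
#' true PM2.5 (per 10 ug/m^3) and extreme-heat effects and their redlined
#' interactions from `betaTrue`. Days absent from the 365-day calendar cannot
#' be drawn. Demographics echo observed case margins; redlined block groups
#' use the redlined-subpopulation margins.
#'
#' @param config A [SimConfig-class].
#' @param panel An [ExposurePanel-class].
#' @param heat A [HeatCalendar-class].
#' @param crosswalk Crosswalk from [buildCrosswalk()].
#' @param n Number of cases (default `config@nCases`).
#' @param seed Seed for the case draw (default `config@seed + 2`), separate
#'   from the geography/exposure seeds so replicate case draws can reuse one
#'   simulated city.
#' @return `data.frame` of mortality records.
#' @export
genCases <- function(config, panel, heat, crosswalk, n = config@nCases,
                     seed = config@seed + 2L) {
  set.seed(seed)
  beta <- config@betaTrue
  cw <- crosswalk[!is.na(crosswalk$label) & crosswalk$total_population > 0, ]
  cw <- cw[cw$geoid12 %in% rownames(panel), ]
  bgDraw <- sample(nrow(cw), n, replace = TRUE, prob = cw$total_population)
  bgRow <- match(cw$geoid12[bgDraw], rownames(panel))
  red <- as.numeric(cw$redlined[bgDraw])

  dates <- panelDates(panel)
  ymAll <- format(dates, "%Y-%m")
  months <- sort(unique(ymAll))
  ym <- sample(months, n, replace = TRUE)
  wd <- sample(1:7, n, replace = TRUE)

  pmM <- pm25(panel)
  extM <- extremeHeat(heat) * 1

  deathDate <- rep(as.Date(NA), n)
  grp <- split(seq_len(n), paste(ym, wd))
  for (g in grp) {
    m <- ym[g[1L]]; w <- wd[g[1L]]
    first <- as.Date(paste0(m, "-01"))
    allDays <- seq(first, by = "day", length.out = 31)
    allDays <- allDays[format(allDays, "%Y-%m") == m &
                         as.POSIXlt(allDays)$wday ==
                           (w %% 7L)]
    cols <- match(as.character(allDays), colnames(panel))
    keep <- !is.na(cols)
    allDays <- allDays[keep]; cols <- cols[keep]
    if (length(cols) == 0L) { next }
    P <- pmM[bgRow[g], cols, drop = FALSE] / 10
    E <- extM[bgRow[g], cols, drop = FALSE]
    eta <- beta["pm25"] * P + beta["pm25_redlined"] * red[g] * P +
      beta["heat"] * E + beta["heat_redlined"] * red[g] * E
    eta <- eta - apply(eta, 1L, max)
    pr <- exp(eta)
    pr <- pr / rowSums(pr)
    u <- stats::runif(length(g))
    if (ncol(pr) == 1L) {
      pickIdx <- rep(1L, length(g))
    } else {
      cum <- t(apply(pr, 1L, cumsum))
      pickIdx <- rowSums(cum < u) + 1L
    }
    deathDate[g] <- allDays[pickIdx]
  }

  if (config@caseSampling == "hazard") {
    # per-day hazard mode: the death day competes across the whole calendar
    for (i in seq_len(n)) {
      eta <- beta["pm25"] * pmM[bgRow[i], ] / 10 +
        beta["pm25_redlined"] * red[i] * pmM[bgRow[i], ] / 10 +
        beta["heat"] * extM[bgRow[i], ] +
        beta["heat_redlined"] * red[i] * extM[bgRow[i], ]
      pr <- exp(eta - max(eta))
      deathDate[i] <- dates[sample.int(length(dates), 1L, prob = pr)]
    }
  }

  drawDemo <- function(margin, isRed) {
    lv <- margin$levels
    out <- character(n)
    out[!isRed] <- sample(lv, sum(!isRed), replace = TRUE, prob = margin$all)
    if (any(isRed))
      out[isRed] <- sample(lv, sum(isRed), replace = TRUE, prob = margin$red)
    out
  }
  isRed <- red == 1
  ageMean <- ifelse(isRed, 72.55, 75.96)
  ageSD <- ifelse(isRed, 15.69, 14.68)
  age <- pmax(18, round(stats::rnorm(n, ageMean, ageSD)))

  ok <- !is.na(deathDate)
  data.frame(
    record_id = sprintf("R%06d", seq_len(n)),
    death_date = deathDate,
    geoid12 = cw$geoid12[bgDraw],
    age = age,
    sex = drawDemo(.demoMargins$sex, isRed),
    race = drawDemo(.demoMargins$race, isRed),
    education = drawDemo(.demoMargins$education, isRed),
    state = config@stateFips,
    cause_code = sample(.INTERNAL_CAUSES, n, replace = TRUE),
    stringsAsFactors = FALSE)[ok, , drop = FALSE]
}

#' Run the full synthetic study end to end
#'
#' Geography, exposures, crosswalk, exposure panel, heat calendar, cases,
#' exclusion cascade and strata, all determined by `config@seed`.
#'
#' @param config A [SimConfig-class].
#' @return List with components `geography`, `exposures`, `crosswalk`,
#'   `panel`, `heat`, `records`, `ledger`, `recordsKept`, `strata`.
#' @export
simulateStudy <- function(config = simConfig()) {
  geo <- genGeography(config)
  expo <- genExposures(config, geo)
  crosswalk <- buildCrosswalk(geo$blocks, geo$holc, config@threshold)
  panel <- buildExposurePanel(expo$cellXY, expo$pitch, expo$values,
                              expo$dates, geo$blocks, geo$blockPolys,
                              geo$bgPolys, crosswalk)
  heat <- buildHeatCalendar(panel, config@heatPercentile)
  records <- genCases(config, panel, heat, crosswalk)
  window <- c(as.Date(paste0(min(config@years), "-01-05")),
              as.Date(paste0(max(config@years), "-12-31")))
  excl <- applyExclusions(records, crosswalk, window = window)
  strata <- buildStrata(excl$records, panel, heat, crosswalk)
  list(geography = geo, exposures = expo, crosswalk = crosswalk,
       panel = panel, heat = heat, records = records,
       ledger = excl$ledger, recordsKept = excl$records, strata = strata)
}

#' Permute the exposure within each stratum
#'
#' Randomly reorders the exposure-bearing columns within every stratum,
#' breaking any exposure-outcome association while preserving the stratum
#' structure and the time-invariant redlined flag - the null-calibration
#' device for the interaction estimator.
#'
#' @param strata Long strata table from [buildStrata()].
#' @param columns Columns to permute jointly (default: all day-varying
#'   exposure columns).
#' @return The permuted strata table.
#' @export
permuteExposureWithinStrata <- function(strata,
                                        columns = c("pm25",
                                                    paste0("pm25_ma", 2:5),
                                                    "extreme", "wave_day",
                                                    "singleton")) {
  ord <- order(match(strata$record_id, unique(strata$record_id)),
               stats::runif(nrow(strata)))
  strata[columns] <- strata[ord, columns]
  strata
}
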