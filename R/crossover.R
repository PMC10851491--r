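# Time-stratified bidirectional case-crossover construction. Each death is
# compared with itself on referent days: every other day in the same calendar
# month falling on the same day of the week, before and after the case. The
# record-exclusion cascade mirrors the subject-restriction flow of the design:
# external causes, minors, missing/coarse geocodes, out-of-state residences,
# deaths outside the study window, zero-population block groups, and deaths
# whose 0-4 day lag window touches the missing December 31 of a leap year.

#' Referent (control) days for a case day
#'
#' All other dates in the case's calendar month sharing its day of the week,
#' sorted; depending on month length and alignment there are always 3 or 4.
#'
#' @param date A single `Date` (or coercible).
#' @return Sorted `Date` vector of 3 or 4 referent days.
#' @examples
#' referentDates(as.Date("2010-07-14"))
#' @export
referentDates <- function(date) {
  date <- as.Date(date)
  stopifnot(length(date) == 1L, !is.na(date))
  cand <- date + seq(-28L, 28L, by = 7L)
  cand <- cand[format(cand, "%Y-%m") == format(date, "%Y-%m")]
  sort(cand[cand != date])
}

.DEFAULT_WINDOW <- c("2001-01-05", "2016-12-31")

#' Apply the record-exclusion cascade
#'
#' Filters mortality records sequentially and returns the survivors plus a
#' ledger of per-step exclusion counts. Steps, in order: non-internal cause
#' (outside ICD-10 A00--R99); age under 18; missing or coarse geocode (not a
#' 12-digit block-group GEOID); home state differing from the reporting state;
#' death outside the study window; home block group with zero decennial
#' population; lag days 0--4 including December 31 of a leap year (absent from
#' the 365-day meteorology calendar).
#'
#' @param records `data.frame` with columns `record_id`, `death_date`,
#'   `geoid12`, `age`, `state` (2-digit FIPS of the reporting state) and
#'   `cause_code` (ICD-10).
#' @param crosswalk Crosswalk from [buildCrosswalk()]; its `total_population`
#'   backs the zero-population step (block groups absent from the crosswalk
#'   are treated as zero-population).
#' @param window Length-2 study window (dates, inclusive). The default start
#'   of January 5 exists so that lag 4 still falls inside the exposure record.
#' @return List with `records` (survivors) and `ledger` (`data.frame` of
#'   `step`, `description`, `excluded`, `remaining`).
#' @export
applyExclusions <- function(records, crosswalk,
                            window = as.Date(.DEFAULT_WINDOW)) {
  window <- as.Date(window)
  ledger <- data.frame(step = integer(0), description = character(0),
                       excluded = integer(0), remaining = integer(0))
  note <- function(desc, keep) {
    ledger <<- rbind(ledger, data.frame(
      step = nrow(ledger) + 1L, description = desc,
      excluded = sum(!keep), remaining = sum(keep)))
    records <<- records[keep, , drop = FALSE]
  }

  note("external (non-internal) cause of death",
       grepl("^[A-R][0-9]{2}", records$cause_code))
  note("age under 18 years", !is.na(records$age) & records$age >= 18)
  note("geocode missing or coarser than block group",
       !is.na(records$geoid12) & grepl("^[0-9]{12}$", records$geoid12))
  note("home location outside reporting state",
       substr(records$geoid12, 1L, 2L) == records$state)
  note("death outside study window",
       records$death_date >= window[1L] & records$death_date <= window[2L])
  pop <- crosswalk$total_population[match(records$geoid12, crosswalk$geoid12)]
  note("home block group with zero population",
       !is.na(pop) & pop > 0)
  lagHitsGap <- Reduce(`|`, lapply(0:4, function(k)
    .isLeapDec31(records$death_date - k)))
  note("lag window includes December 31 of a leap year", !lagHitsGap)

  list(records = records, ledger = ledger)
}

#' Materialize case-crossover strata with exposure rows
#'
#' One stratum per record: the case day plus its referent days, each row
#' carrying the exposures used by the models (PM2.5 and its 2--5 day moving
#' averages, mean temperature, vapor pressure, the extreme-heat indicator,
#' heat-wave day number, singleton flag) and the time-invariant redlined flag
#' of the record's block group. Strata with any missing exposure row (e.g. a
#' referent day absent from the 365-day calendar) are dropped whole and
#' counted in the `"dropped"` attribute, as are records whose block group is
#' not in the panel.
#'
#' @param records Filtered records from [applyExclusions()].
#' @param panel An [ExposurePanel-class].
#' @param heat A [HeatCalendar-class] on the same dimensions.
#' @param crosswalk Crosswalk from [buildCrosswalk()].
#' @return Long `data.frame`: `record_id`, `date`, `is_case`, exposures,
#'   `redlined`; attribute `dropped` gives counts of dropped strata.
#' @export
buildStrata <- function(records, panel, heat, crosswalk) {
  stopifnot(is(panel, "ExposurePanel"), is(heat, "HeatCalendar"))
  n <- nrow(records)
  if (n == 0L) {
    out <- data.frame(record_id = character(0), date = as.Date(character(0)),
                      is_case = logical(0))
    attr(out, "dropped") <- c(missing_geoid = 0L, missing_exposure = 0L)
    return(out)
  }

  uniq <- unique(records$death_date)
  refList <- lapply(uniq, referentDates)
  ridx <- match(records$death_date, uniq)
  nref <- lengths(refList)[ridx]

  blockLen <- nref + 1L
  recRow <- rep(seq_len(n), times = blockLen)
  starts <- cumsum(blockLen) - blockLen + 1L
  dateNum <- numeric(sum(blockLen))
  dateNum[starts] <- as.numeric(records$death_date)
  refNum <- lapply(refList, as.numeric)
  dateNum[-starts] <- unlist(refNum[ridx], use.names = FALSE)
  dates <- as.Date(dateNum, origin = "1970-01-01")
  isCase <- logical(sum(blockLen))
  isCase[starts] <- TRUE

  row <- match(records$geoid12[recRow], rownames(panel))
  col <- match(as.character(dates), colnames(panel))
  pick <- function(m) {
    v <- rep(NA_real_, length(row))
    ok <- !is.na(row) & !is.na(col)
    v[ok] <- m[cbind(row[ok], col[ok])]
    v
  }
  out <- data.frame(
    record_id = records$record_id[recRow],
    date = dates,
    is_case = isCase,
    pm25 = pick(assay(panel, "pm25")),
    pm25_ma2 = pick(assay(panel, "pm25_ma2")),
    pm25_ma3 = pick(assay(panel, "pm25_ma3")),
    pm25_ma4 = pick(assay(panel, "pm25_ma4")),
    pm25_ma5 = pick(assay(panel, "pm25_ma5")),
    tmean = pick(assay(panel, "tmean")),
    vp = pick(assay(panel, "vp")),
    extreme = pick(extremeHeat(heat) * 1),
    wave_day = pick(waveDay(heat) * 1),
    singleton = pick(singletonHeat(heat) * 1),
    stringsAsFactors = FALSE)
  # off-wave days have no wave-day number; encode as 0 when the day is present
  present <- !is.na(out$extreme)
  out$wave_day[present & is.na(out$wave_day)] <- 0
  red <- crosswalk$redlined[match(records$geoid12[recRow], crosswalk$geoid12)]
  out$redlined <- as.numeric(red)

  exposureCols <- c("pm25", paste0("pm25_ma", 2:5), "tmean", "vp",
                    "extreme", "wave_day", "singleton", "redlined")
  badRow <- rowSums(is.na(out[, exposureCols])) > 0
  missGeo <- is.na(row)
  dropGeo <- unique(out$record_id[missGeo])
  dropExp <- setdiff(unique(out$record_id[badRow]), dropGeo)
  keep <- !(out$record_id %in% c(dropGeo, dropExp))
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- c(missing_geoid = length(dropGeo),
                            missing_exposure = length(dropExp))
  out
}
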