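# End-to-end orchestration: the primary exposure grid and the sensitivity /
# subgroup axes, run over one simulated (or supplied) study, with results,
# exclusion ledger and a manifest written as plain text. One config object
# drives everything, so the manifest fully determines the outputs.

.PRIMARY_EXPOSURES <- c(.PM_EXPOSURES, .HEAT_EXPOSURES)

#' Lay out the analysis grid
#'
#' One row per model fit: every exposure crossed with the requested
#' population-threshold and heat-percentile sensitivity values (heat
#' percentiles apply only to heat exposures), plus optional subgroup cells
#' (individual race, neighbourhood racial majority, state, year).
#'
#' @param exposures Exposure names (see [ModelSpec-class]).
#' @param thresholds Population-share thresholds for the grade crosswalk.
#' @param percentiles Extreme-heat percentiles.
#' @param subgroups Character; any of `"race_Black"`, `"race_White"`,
#'   `"nbhd_Black"`, `"nbhd_White"`, `"state"`, `"year"`.
#' @return `data.frame` with columns `exposure`, `threshold`, `percentile`,
#'   `subgroup`.
#' @export
analysisPlan <- function(exposures = .PRIMARY_EXPOSURES,
                         thresholds = 0.9, percentiles = 95,
                         subgroups = character(0)) {
  base <- expand.grid(exposure = exposures, threshold = thresholds,
                      percentile = percentiles, subgroup = "all",
                      stringsAsFactors = FALSE)
  # heat percentile is inert for PM2.5 exposures: keep only the first
  isPM <- base$exposure %in% .PM_EXPOSURES
  base <- base[!isPM | base$percentile == percentiles[1L], , drop = FALSE]
  if (length(subgroups)) {
    sub <- expand.grid(exposure = exposures, threshold = thresholds[1L],
                       percentile = percentiles[1L], subgroup = subgroups,
                       stringsAsFactors = FALSE)
    base <- rbind(base, sub)
  }
  rownames(base) <- NULL
  base
}

.subgroupRecordIds <- function(tag, records, bgMeta) {
  if (tag == "all") return(records$record_id)
  if (tag %in% c("race_Black", "race_White"))
    return(records$record_id[records$race == sub("race_", "", tag)])
  if (tag %in% c("nbhd_Black", "nbhd_White")) {
    share <- if (tag == "nbhd_Black") bgMeta$black_share else bgMeta$white_share
    bg <- bgMeta$geoid12[share >= 0.5]
    return(records$record_id[records$geoid12 %in% bg])
  }
  stop("unknown subgroup: ", tag)
}

#' Run the full analysis grid on a synthetic study
#'
#' Simulates one study from `config`, then for every cell of `plan` rebuilds
#' the crosswalk/heat calendar as needed, filters strata to the subgroup, fits
#' the conditional logistic interaction model and collects the interaction
#' estimate. Cells that cannot be fit (no strata, non-convergence) are
#' recorded with a status, never silently skipped. When `dir` is given,
#' writes `results.csv`, `exclusion_ledger.csv`, `crosswalk.csv` and
#' `manifest.json` there.
#'
#' @param config A [SimConfig-class].
#' @param plan Grid from [analysisPlan()].
#' @param dir Optional output directory.
#' @return `data.frame`: the plan plus `n_strata`, `status`, the interaction
#'   coefficient/OR/CI and percent-excess columns; attribute `"fits"` holds
#'   the [FitResult-class] objects, `"study"` the simulated study.
#' @export
runAnalysis <- function(config = simConfig(), plan = analysisPlan(),
                        dir = NULL) {
  study <- simulateStudy(config)
  geo <- study$geography
  panel <- study$panel

  crossCache <- list()
  getCross <- function(th) {
    key <- as.character(th)
    if (is.null(crossCache[[key]]))
      crossCache[[key]] <<- buildCrosswalk(geo$blocks, geo$holc, th)
    crossCache[[key]]
  }
  crossCache[[as.character(config@threshold)]] <- study$crosswalk
  heatCache <- list()
  getHeat <- function(p) {
    key <- as.character(p)
    if (is.null(heatCache[[key]]))
      heatCache[[key]] <<- buildHeatCalendar(panel, p)
    heatCache[[key]]
  }
  heatCache[[as.character(config@heatPercentile)]] <- study$heat
  strataCache <- list()
  getStrata <- function(th, p) {
    key <- paste(th, p)
    if (is.null(strataCache[[key]]))
      strataCache[[key]] <<- buildStrata(study$recordsKept, panel,
                                         getHeat(p), getCross(th))
    strataCache[[key]]
  }
  strataCache[[paste(config@threshold, config@heatPercentile)]] <- study$strata

  fits <- vector("list", nrow(plan))
  rows <- list()
  recYear <- as.integer(format(study$recordsKept$death_date, "%Y"))
  for (i in seq_len(nrow(plan))) {
    cell <- plan[i, ]
    strata <- getStrata(cell$threshold, cell$percentile)
    ids <- if (cell$subgroup == "year") {
      NULL  # expanded below
    } else if (cell$subgroup == "state") {
      NULL
    } else {
      .subgroupRecordIds(cell$subgroup, study$recordsKept, geo$bgMeta)
    }
    splitTags <- switch(cell$subgroup,
      year = split(study$recordsKept$record_id, recYear),
      state = split(study$recordsKept$record_id, study$recordsKept$state),
      stats::setNames(list(ids), cell$subgroup))
    for (tag in names(splitTags)) {
      sel <- strata[strata$record_id %in% splitTags[[tag]], , drop = FALSE]
      label <- if (cell$subgroup %in% c("year", "state"))
        paste0(cell$subgroup, "_", tag) else cell$subgroup
      row <- data.frame(exposure = cell$exposure, threshold = cell$threshold,
                        percentile = cell$percentile, subgroup = label,
                        n_strata = length(unique(sel$record_id)),
                        status = "ok", beta_interaction = NA_real_,
                        se = NA_real_, or = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, pct_excess = NA_real_,
                        stringsAsFactors = FALSE)
      if (nrow(sel) == 0L) {
        row$status <- "no data"
      } else {
        fit <- tryCatch(
          withCallingHandlers(
            fitClogit(sel, modelSpec(cell$exposure)),
            warning = function(w) invokeRestart("muffleWarning")),
          error = function(e) e)
        if (inherits(fit, "error")) {
          row$status <- paste("error:", conditionMessage(fit))
        } else {
          if (!fit@converged) row$status <- "not converged"
          ir <- interactionResult(fit)
          row$beta_interaction <- ir$beta
          row$se <- ir$se
          row$or <- ir$or
          row$ci_low <- ir$ci_low
          row$ci_high <- ir$ci_high
          row$pct_excess <- ir$pct_excess
          fits[[i]] <- fit
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  res <- do.call(rbind, rows)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res, file.path(dir, "results.csv"), row.names = FALSE)
    utils::write.csv(study$ledger, file.path(dir, "exclusion_ledger.csv"),
                     row.names = FALSE)
    utils::write.csv(study$crosswalk, file.path(dir, "crosswalk.csv"),
                     row.names = FALSE)
    manifest <- list(
      package = "holcmod",
      version = as.character(utils::packageVersion("holcmod")),
      seed = config@seed,
      n_cases = config@nCases,
      years = config@years,
      threshold = config@threshold,
      heat_percentile = config@heatPercentile,
      beta_true = as.list(config@betaTrue),
      tolerances = list(loglik_rel = 1e-9, gradient_max = 1e-6, wald_z = .Z95),
      plan = plan)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  attr(res, "fits") <- fits
  attr(res, "study") <- study
  res
}
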