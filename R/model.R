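# Conditional logistic regression with interaction terms.
#
# The conditional likelihood of each stratum (one case day plus its referent
# days) is the softmax probability of the case day's linear predictor among
# the stratum's rows; stratum-constant covariates (in particular the redlined
# main effect) cancel. Two model families are supported, matching the study
# design:
#   PM2.5:  eta = b1 * PM/10 + ns(TMEAN,4) %*% b2..5 + ns(VP,4) %*% b6..9
#                 + b10 * redlined * PM/10
#   heat:   eta = b1 * extreme + ns(VP,4) %*% b2..5 + b6 * redlined * extreme
# The interaction coefficient is the estimand of interest in both.

.PM_EXPOSURES <- c("pm25", paste0("pm25_ma", 2:5))
.HEAT_EXPOSURES <- c("heat_any", paste0("heat_wave", 1:4), "heat_singleton")

#' Natural cubic spline basis
#'
#' Four-column natural (restricted) cubic spline basis: interior knots at the
#' 25th, 50th and 75th percentiles of `x`, boundary knots at its range,
#' linear beyond the boundary knots. A thin wrapper over [splines::ns()] with
#' the knot convention pinned.
#'
#' @param x Numeric covariate values.
#' @param df Degrees of freedom (basis columns); 4 in the study models.
#' @param knots,boundary Optional explicit interior/boundary knots.
#' @return Matrix with `df` columns and attributes `knots`, `boundary`.
#' @export
nsBasis <- function(x, df = 4, knots = NULL, boundary = NULL) {
  if (length(unique(x)) < df + 1)
    stop("degenerate covariate: fewer than df + 1 distinct values")
  if (is.null(boundary)) boundary <- range(x)
  if (is.null(knots)) {
    probs <- seq_len(df - 1) / df
    knots <- stats::quantile(x, probs, type = 7, names = FALSE)
  }
  b <- splines::ns(x, knots = knots, Boundary.knots = boundary)
  b <- unclass(b)[, , drop = FALSE]
  attr(b, "knots") <- knots
  attr(b, "boundary") <- boundary
  b
}

#' ModelSpec: which exposure, adjusters and interaction to fit
#'
#' @slot exposure One of `"pm25"`, `"pm25_ma2"`..`"pm25_ma5"` (PM2.5 family,
#'   scaled per 10 ug/m^3, adjusted for TMEAN and VP splines) or
#'   `"heat_any"`, `"heat_wave1"`..`"heat_wave4"`, `"heat_singleton"` (heat
#'   family, adjusted for the VP spline).
#' @slot family `"pm25"` or `"heat"`.
#' @slot scale Divisor applied to the raw exposure (10 for PM2.5, 1 for heat).
#' @export
setClass("ModelSpec", representation(exposure = "character",
                                     family = "character",
                                     scale = "numeric"))

setValidity("ModelSpec", function(object) {
  if (!object@exposure %in% c(.PM_EXPOSURES, .HEAT_EXPOSURES))
    return(paste("unknown exposure:", object@exposure))
  TRUE
})

#' Construct a ModelSpec
#'
#' @param exposure Exposure name; see [ModelSpec-class].
#' @return A [ModelSpec-class].
#' @examples
#' modelSpec("pm25")
#' modelSpec("heat_any")
#' @export
modelSpec <- function(exposure = "pm25") {
  fam <- if (exposure %in% .PM_EXPOSURES) "pm25" else "heat"
  new("ModelSpec", exposure = exposure, family = fam,
      scale = if (fam == "pm25") 10 else 1)
}

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec:", object@exposure, "(", object@family, "family ) x redlined",
      if (object@scale != 1) sprintf(", per %g units", object@scale), "\n")
})

# Extract the raw exposure column named by a spec from a strata table.
.exposureColumn <- function(strata, spec) {
  switch(spec@exposure,
    pm25 = strata$pm25,
    pm25_ma2 = strata$pm25_ma2,
    pm25_ma3 = strata$pm25_ma3,
    pm25_ma4 = strata$pm25_ma4,
    pm25_ma5 = strata$pm25_ma5,
    heat_any = as.numeric(strata$extreme),
    heat_wave1 = as.numeric(strata$wave_day == 1),
    heat_wave2 = as.numeric(strata$wave_day == 2),
    heat_wave3 = as.numeric(strata$wave_day == 3),
    heat_wave4 = as.numeric(strata$wave_day == 4),
    heat_singleton = as.numeric(strata$singleton))
}

# Design matrix for a strata table under a spec. Spline knots come from the
# pooled case + referent covariate distribution of the fitted data.
.buildDesign <- function(strata, spec) {
  expo <- .exposureColumn(strata, spec) / spec@scale
  X <- cbind(exposure = expo)
  if (spec@family == "pm25") {
    tm <- nsBasis(strata$tmean, 4)
    colnames(tm) <- paste0("ns_tmean", 1:4)
    X <- cbind(X, tm)
  }
  vp <- nsBasis(strata$vp, 4)
  colnames(vp) <- paste0("ns_vp", 1:4)
  X <- cbind(X, vp, interaction = strata$redlined * expo)
  X
}

# Padded index representation of strata: matrix S x maxRows of row indices
# into the long table (NA-padded), plus the case row of each stratum.
.strataIndex <- function(sid, isCase) {
  f <- factor(sid, levels = unique(sid))
  sizes <- tabulate(f)
  S <- nlevels(f)
  R <- max(sizes)
  idx <- matrix(NA_integer_, S, R)
  ord <- order(as.integer(f))
  pos <- sequence(sizes)
  idx[cbind(as.integer(f)[ord], pos)] <- ord
  caseRow <- which(isCase)
  if (length(caseRow) != S) stop("each stratum needs exactly one case row")
  if (!all(tapply(isCase, f, sum) == 1L))
    stop("each stratum needs exactly one case row")
  list(idx = idx, caseRow = caseRow[order(as.integer(f)[caseRow])], f = f)
}

#' Conditional logistic log-likelihood, gradient and Hessian
#'
#' For strata of one case plus referents, the contribution of stratum s is
#' `eta_case - log(sum_i exp(eta_i))` with `eta = X beta`; the linear
#' predictor is max-subtracted within stratum before exponentiation so the
#' value is overflow-safe. Analytic gradient and Hessian are returned.
#'
#' @param X Numeric design matrix (rows = person-days).
#' @param isCase Logical; exactly one `TRUE` per stratum.
#' @param sid Stratum identifier per row.
#' @param beta Coefficient vector, `ncol(X)` long.
#' @return List with `value`, `gradient`, `hessian`.
#' @export
conditionalLoglik <- function(X, isCase, sid, beta) {
  st <- .strataIndex(sid, isCase)
  .condLoglikCore(X, st, beta)
}

.condLoglikCore <- function(X, st, beta) {
  idx <- st$idx
  eta <- drop(X %*% beta)
  E <- matrix(eta[idx], nrow(idx), ncol(idx))
  m <- do.call(pmax, c(lapply(seq_len(ncol(E)), function(j) E[, j]),
                       list(na.rm = TRUE)))
  es <- exp(E - m)
  S <- rowSums(es, na.rm = TRUE)
  value <- sum(eta[st$caseRow]) - sum(log(S) + m)

  p <- numeric(length(eta))
  ok <- !is.na(idx)
  p[idx[ok]] <- (es / S)[ok]
  y <- as.numeric(seq_along(eta) %in% st$caseRow)
  gradient <- drop(crossprod(X, y - p))
  pX <- X * p
  A <- crossprod(X, pX)
  Xbar <- rowsum(pX, as.integer(st$f))
  hessian <- crossprod(Xbar) - A
  list(value = value, gradient = gradient, hessian = hessian)
}

#' FitResult: a fitted conditional logistic model
#'
#' @slot beta Named coefficient vector.
#' @slot vcov Covariance (inverse observed information).
#' @slot loglik Maximized conditional log-likelihood.
#' @slot converged Logical; `FALSE` flags non-convergence or separation.
#' @slot niter Newton iterations used.
#' @slot nStrata Number of strata fitted.
#' @slot table Per-term summary (beta, SE, OR, Wald 95% CI, percent excess).
#' @slot spec The [ModelSpec-class] fitted (may be a placeholder for raw fits).
#' @export
setClass("FitResult", representation(beta = "numeric", vcov = "matrix",
                                     loglik = "numeric", converged = "logical",
                                     niter = "integer", nStrata = "integer",
                                     table = "data.frame", spec = "ModelSpec"))

.Z95 <- 1.959964

.fitTable <- function(beta, vcov) {
  se <- sqrt(pmax(diag(vcov), 0))
  or <- exp(beta)
  lo <- exp(beta - .Z95 * se)
  hi <- exp(beta + .Z95 * se)
  data.frame(term = names(beta), beta = beta, se = se, or = or,
             ci_low = lo, ci_high = hi,
             pct_excess = (or - 1) * 100,
             pct_low = (lo - 1) * 100, pct_high = (hi - 1) * 100,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Maximize the conditional logistic likelihood
#'
#' Newton--Raphson with step-halving on the analytic gradient and Hessian.
#' Convergence requires a relative log-likelihood change below `tolLL` and a
#' maximum absolute score below `tolG`. Diverging coefficients (separation)
#' yield `converged = FALSE` with a warning rather than silent output.
#'
#' @param X Design matrix (or use [fitClogit()] on a strata table).
#' @inheritParams conditionalLoglik
#' @param maxit,tolLL,tolG Iteration cap and convergence tolerances.
#' @param spec Optional [ModelSpec-class] recorded in the result.
#' @return A [FitResult-class].
#' @export
fitClogitRaw <- function(X, isCase, sid, maxit = 30L, tolLL = 1e-9,
                         tolG = 1e-6, spec = modelSpec("pm25")) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  st <- .strataIndex(sid, isCase)
  beta <- numeric(ncol(X))
  names(beta) <- colnames(X)
  cl <- .condLoglikCore(X, st, beta)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(maxit)) {
    step <- tryCatch(solve(-cl$hessian, cl$gradient),
                     error = function(e) NULL)
    if (is.null(step)) break
    newBeta <- beta + step
    newCl <- .condLoglikCore(X, st, newBeta)
    halvings <- 0L
    while ((!is.finite(newCl$value) || newCl$value < cl$value) &&
           halvings < 20L) {
      step <- step / 2
      newBeta <- beta + step
      newCl <- .condLoglikCore(X, st, newBeta)
      halvings <- halvings + 1L
    }
    relChange <- abs(newCl$value - cl$value) / (abs(cl$value) + 1e-12)
    beta <- newBeta
    cl <- newCl
    if (relChange < tolLL && max(abs(cl$gradient)) < tolG) {
      converged <- TRUE
      break
    }
    if (max(abs(beta)) > 25) break  # separation guard
  }
  vcov <- tryCatch(solve(-cl$hessian), error = function(e)
    matrix(NA_real_, ncol(X), ncol(X)))
  dimnames(vcov) <- list(colnames(X), colnames(X))
  if (!converged)
    warning("conditional logistic fit did not converge (possible separation); ",
            "max |beta| = ", signif(max(abs(beta)), 3))
  new("FitResult", beta = beta, vcov = vcov, loglik = cl$value,
      converged = converged, niter = iter, nStrata = nrow(st$idx),
      table = .fitTable(beta, vcov), spec = spec)
}

#' Fit a study model on a strata table
#'
#' Builds the design for `spec` (exposure, spline adjusters on pooled
#' case + referent quantiles, redlined x exposure interaction) from a long
#' strata table ([buildStrata()]) and maximizes the conditional likelihood.
#' The redlined main effect is absorbed by the stratification and is not a
#' model term.
#'
#' @param strata Long strata table from [buildStrata()].
#' @param spec A [ModelSpec-class] (or exposure name).
#' @param ... Passed to [fitClogitRaw()].
#' @return A [FitResult-class]; PM2.5 ORs are per 10 ug/m^3.
#' @export
fitClogit <- function(strata, spec = modelSpec("pm25"), ...) {
  if (is.character(spec)) spec <- modelSpec(spec)
  X <- .buildDesign(strata, spec)
  fitClogitRaw(X, strata$is_case, strata$record_id, spec = spec, ...)
}

#' Convert an odds ratio to percent excess daily risk
#'
#' @param or Positive odds ratio(s).
#' @return `(or - 1) * 100`, the percent increase in daily risk.
#' @examples
#' orToPercent(1.0093)  # 0.93
#' @export
orToPercent <- function(or) {
  if (any(or <= 0, na.rm = TRUE)) stop("odds ratio must be positive")
  (or - 1) * 100
}

#' @describeIn FitResult-class named coefficient vector.
#' @param object A `FitResult`.
#' @param ... Unused.
#' @export
setMethod("coef", "FitResult", function(object, ...) object@beta)

#' @describeIn FitResult-class covariance matrix of the coefficients.
#' @export
setMethod("vcov", "FitResult", function(object, ...) object@vcov)

#' @describeIn FitResult-class per-term summary table.
#' @param x A `FitResult`.
#' @export
resultTable <- function(x) x@table

#' @describeIn FitResult-class the interaction row of the summary table.
#' @export
interactionResult <- function(x) {
  x@table[x@table$term == "interaction", , drop = FALSE]
}

setMethod("show", "FitResult", function(object) {
  cat("FitResult (", object@spec@exposure, " x redlined ), ",
      object@nStrata, " strata, ",
      if (object@converged) "converged" else "NOT CONVERGED",
      " in ", object@niter, " iterations\n", sep = "")
  tab <- object@table
  num <- vapply(tab, is.numeric, logical(1L))
  tab[num] <- lapply(tab[num], signif, 5)
  print(tab[, c("term", "beta", "se", "or", "ci_low", "ci_high")],
        row.names = FALSE)
})
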