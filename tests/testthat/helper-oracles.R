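# Independent brute-force oracles. These deliberately use different
# algorithms from the package implementations (winding angle instead of ray
# casting, explicit order-statistic interpolation instead of quantile(),
# rle() instead of the streaming run scanner, loop-based softmax instead of
# the padded-matrix likelihood).

# Winding-number containment via summed signed angles; points assumed off the
# boundary (random fixtures are, almost surely).
oracleInRing <- function(px, py, ring) {
  if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  vapply(seq_along(px), function(i) {
    dx <- ring[, 1] - px[i]
    dy <- ring[, 2] - py[i]
    n <- nrow(ring)
    ang <- 0
    for (e in seq_len(n - 1)) {
      cross <- dx[e] * dy[e + 1] - dx[e + 1] * dy[e]
      dot <- dx[e] * dx[e + 1] + dy[e] * dy[e + 1]
      ang <- ang + atan2(cross, dot)
    }
    abs(ang) > pi
  }, logical(1))
}

# Vectorized winding oracle for large point sets (used by the Monte-Carlo
# areal oracle).
oracleInRingVec <- function(px, py, ring) {
  if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  n <- nrow(ring)
  ang <- 0
  for (e in seq_len(n - 1)) {
    dx1 <- ring[e, 1] - px; dy1 <- ring[e, 2] - py
    dx2 <- ring[e + 1, 1] - px; dy2 <- ring[e + 1, 2] - py
    ang <- ang + atan2(dx1 * dy2 - dx2 * dy1, dx1 * dx2 + dy1 * dy2)
  }
  abs(ang) > pi
}

# Explicit type-7 order-statistic interpolation.
oracleQuantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- min(lo + 1, n)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Run-length-encoding wave numbering.
oracleWaves <- function(ext) {
  r <- rle(as.logical(ext))
  wave <- rep(NA_integer_, length(ext))
  single <- rep(FALSE, length(ext))
  start <- cumsum(c(1L, r$lengths))
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    idx <- start[i]:(start[i] + r$lengths[i] - 1L)
    if (r$lengths[i] >= 2L) wave[idx] <- seq_len(r$lengths[i])
    else single[idx] <- TRUE
  }
  data.frame(wave_day = wave, singleton = single)
}

# Loop-based conditional log-likelihood (softmax enumeration).
oracleCondLoglik <- function(X, isCase, sid, beta) {
  ll <- 0
  for (s in unique(sid)) {
    rows <- which(sid == s)
    eta <- as.vector(X[rows, , drop = FALSE] %*% beta)
    ll <- ll + eta[isCase[rows]] - log(sum(exp(eta)))
  }
  ll
}

# Central finite-difference gradient of the conditional log-likelihood.
fdGradient <- function(X, isCase, sid, beta, h = 1e-5) {
  vapply(seq_along(beta), function(j) {
    bp <- beta; bm <- beta
    bp[j] <- bp[j] + h; bm[j] <- bm[j] - h
    (oracleCondLoglik(X, isCase, sid, bp) -
       oracleCondLoglik(X, isCase, sid, bm)) / (2 * h)
  }, numeric(1))
}

# Star-shaped simple polygon around a centre (never self-intersecting).
randomStarPolygon <- function(nVert, cx, cy, rmin, rmax) {
  th <- sort(runif(nVert, 0, 2 * pi))
  r <- runif(nVert, rmin, rmax)
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# Random small strata for likelihood/fitter tests: m rows per stratum, the
# case drawn by softmax under betaTrue (exact model).
randomStrata <- function(S, k, betaTrue = rep(0, k), mRange = 4:5) {
  m <- sample(mRange, S, replace = TRUE)
  n <- sum(m)
  X <- matrix(rnorm(n * k), n, k)
  sid <- rep(seq_len(S), m)
  isCase <- logical(n)
  pos <- 0L
  for (s in seq_len(S)) {
    rows <- pos + seq_len(m[s])
    eta <- as.vector(X[rows, , drop = FALSE] %*% betaTrue)
    p <- exp(eta - max(eta)); p <- p / sum(p)
    isCase[rows[sample.int(m[s], 1L, prob = p)]] <- TRUE
    pos <- pos + m[s]
  }
  list(X = X, isCase = isCase, sid = sid)
}
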