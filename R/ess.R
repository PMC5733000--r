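#' Sample autocorrelation at lags 1..maxLag
#'
#' Plain sample autocorrelation of a single series (lag 0 is implicitly 1).
#' For a constant series the autocorrelation is undefined; a vector of NA is
#' returned and is treated as perfect dependence by downstream ESS code.
#'
#' @param series numeric vector, length N >= 3.
#' @param maxLag largest lag, maxLag < N.
#' @return numeric vector of length maxLag with values in [-1, 1] (or NA for
#'   a constant series).
#' @examples
#' sampleAutocorrelation(rep(c(1, -1), 50), maxLag = 3)
#' @export
sampleAutocorrelation <- function(series, maxLag) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 3L) stop("series must have at least 3 points", call. = FALSE)
  maxLag <- assertCount(maxLag, "maxLag")
  if (maxLag >= n) stop("'maxLag' must be smaller than the series length", call. = FALSE)
  if (stats::var(series) <= 0) return(rep(NA_real_, maxLag))
  ac <- stats::acf(series, lag.max = maxLag, plot = FALSE, demean = TRUE)$acf
  as.numeric(ac[-1L])
}

# Geyer-style initial positive sequence truncation of 1 + 2 * sum(acf):
# consecutive lag pairs (rho_1 + rho_2), (rho_3 + rho_4), ... are summed
# while positive; the first non-positive pair sum stops the accumulation.
geyerTau <- function(ac) {
  if (anyNA(ac)) return(Inf)
  npair <- floor(length(ac) / 2)
  tau <- 1
  for (k in seq_len(npair)) {
    pair <- ac[2L * k - 1L] + ac[2L * k]
    if (pair <= 0) return(tau)
    tau <- tau + 2 * pair
  }
  # odd tail lag: include if positive, same monotonicity convention
  if (length(ac) %% 2L == 1L) {
    last <- ac[length(ac)]
    if (last > 0) tau <- tau + 2 * last
  }
  tau
}

#' @rdname effectiveSampleSize
#' @param maxLag largest autocorrelation lag examined; default
#'   `min(N - 1, 1000)`.  The Geyer initial-positive-sequence rule usually
#'   stops far earlier, so the cap only guards against O(N^2) autocovariance
#'   work on very long series.
#' @details
#' Per component j, `ESS_j = N / (1 + 2 * sum_t acf_j(t))` with the sum
#' truncated by the initial-positive-sequence rule (consecutive lag-pair
#' sums accumulated while positive).  The overall count is the conservative
#' minimum over components, floored and clamped to `[1, N]`.  A constant
#' component is treated as perfectly dependent and forces `nEffective = 1`.
#' Values above N (from negative autocorrelation) are clamped to N since
#' thinning cannot exceed the available time points.
setMethod("effectiveSampleSize", "ParcelTimeseries", function(object, maxLag = NULL) {
  essCore(tsValues(centerColumns(object)), maxLag)
})

#' @rdname effectiveSampleSize
setMethod("effectiveSampleSize", "matrix", function(object, maxLag = NULL) {
  essCore(centerColumns(object), maxLag)
})

#' @rdname effectiveSampleSize
setMethod("effectiveSampleSize", "numeric", function(object, maxLag = NULL) {
  essCore(matrix(object, ncol = 1L), maxLag)
})

essCore <- function(y, maxLag = NULL) {
  n <- nrow(y)
  if (n < 10L) stop("ESS estimation needs at least 10 time points", call. = FALSE)
  maxLag <- as.integer(maxLag %||% min(n - 1L, 1000L))
  if (maxLag >= n) maxLag <- n - 1L
  per <- apply(y, 2L, function(col) {
    if (stats::var(col) <= 0) return(1)           # constant: perfect dependence
    tau <- geyerTau(sampleAutocorrelation(col, maxLag))
    min(max(n / tau, 1), n)
  })
  overall <- as.integer(min(max(floor(min(per)), 1), n))
  new("EssResult", nEffective = overall, perComponentEss = as.numeric(per),
      maxLagUsed = maxLag)
}

#' @rdname accessors
setMethod("nEffective", "EssResult", function(object) object@nEffective)

#' @rdname accessors
setMethod("perComponentEss", "EssResult", function(object) object@perComponentEss)

setMethod("show", "EssResult", function(object) {
  cat(sprintf("EssResult: n_effective = %d over %d component(s) (max lag %d)\n",
              object@nEffective, length(object@perComponentEss),
              object@maxLagUsed))
})

#' Study-wide effective sample size across subjects
#'
#' Applies [effectiveSampleSize()] to every subject and returns the minimum
#' overall count: the conservative thinning target shared by all subjects.
#'
#' @param tsList list of [ParcelTimeseries-class].
#' @param maxLag passed through to [effectiveSampleSize()].
#' @return integer study-wide ESS.
#' @export
studyEss <- function(tsList, maxLag = NULL) {
  stopifnot(length(tsList) >= 1L)
  min(vapply(tsList, function(ts) nEffective(effectiveSampleSize(ts, maxLag = maxLag)),
             integer(1)))
}

#' @rdname thinSeries
#' @details Rows are taken at `1 + floor((0:(n-1)) * N / n)` (1-based), i.e.
#'   evenly spaced starting at the first time point, preserving order; for
#'   N = 10, n = 5 this keeps rows 1, 3, 5, 7, 9.
setMethod("thinSeries", "ParcelTimeseries", function(object, n) {
  v <- thinSeries(tsValues(object), n)
  initialize(object, values = v)
})

#' @rdname thinSeries
setMethod("thinSeries", "matrix", function(object, n) {
  N <- nrow(object)
  n <- assertCount(n, "n")
  if (n > N) stop("cannot thin to more rows than available (n > N)", call. = FALSE)
  idx <- 1L + floor((seq_len(n) - 1L) * N / n)
  object[idx, , drop = FALSE]
})
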