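#' @include AllClasses.R
NULL

#' Match imputed to ground-truth spikes by optimal assignment
#'
#' Minimum-total-|offset| one-to-one assignment between imputed and
#' ground-truth spike times, with matches restricted to |offset| <=
#' \code{maxDt} and a cost of unassignment of \code{maxDt / 2} per
#' unmatched spike (which exactly enforces the matching window: a pair
#' costing more than \code{maxDt} is never preferred to leaving both spikes
#' unmatched). Because both trains are sorted and the cost is the absolute
#' time difference, an optimal non-crossing assignment exists and is found
#' by dynamic programming in O(nm).
#'
#' @param imputed a \linkS4class{SpikeTrain}
#' @param truth a \linkS4class{SpikeTrain}
#' @param maxDt matching window (s), default 10 ms
#' @return a \linkS4class{MatchResult}; offsets are imputed minus truth
#'   (positive = imputed later)
#' @export
matchSpikes <- function(imputed, truth, maxDt = 0.010) {
  a <- spikeTimes(imputed); b <- spikeTimes(truth)
  n <- length(a); m <- length(b)
  u <- maxDt / 2
  D <- matrix(0, n + 1, m + 1)
  D[, 1] <- (0:n) * u
  D[1, ] <- (0:m) * u
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      best <- min(D[i, j + 1] + u, D[i + 1, j] + u)
      d <- abs(a[i] - b[j])
      if (d <= maxDt) best <- min(best, D[i, j] + d)
      D[i + 1, j + 1] <- best
    }
  }
  ## backtrack
  pi <- integer(0); pj <- integer(0)
  i <- n; j <- m
  while (i > 0 && j > 0) {
    d <- abs(a[i] - b[j])
    if (d <= maxDt && abs(D[i + 1, j + 1] - (D[i, j] + d)) < 1e-12) {
      pi <- c(i, pi); pj <- c(j, pj); i <- i - 1; j <- j - 1
    } else if (abs(D[i + 1, j + 1] - (D[i, j + 1] + u)) < 1e-12) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  pairs <- data.frame(imputed = a[pi], truth = b[pj],
                      offset = a[pi] - b[pj])
  new("MatchResult", pairs = pairs, nTp = length(pi),
      nFp = as.integer(n - length(pi)), nFn = as.integer(m - length(pj)),
      maxDt = maxDt)
}

#' Classification metrics from a spike match
#'
#' Precision (TP over all imputed), recall (TP over all truth), their
#' harmonic mean (F-score), and accuracy defined Jaccard-style as
#' TP / (TP + FP + FN). When a denominator is zero the metric is reported
#' as \code{NA} (undefined) so that aggregation can exclude it.
#'
#' @param match a \linkS4class{MatchResult}
#' @return list with precision, recall, fScore, accuracy
#' @export
classificationMetrics <- function(match) {
  tp <- match@nTp; fp <- match@nFp; fn <- match@nFn
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  fScore <- if (!is.na(precision) && !is.na(recall)) {
    if (precision + recall > 0) 2 * precision * recall / (precision + recall)
    else 0
  } else NA_real_
  accuracy <- if (tp + fp + fn > 0) tp / (tp + fp + fn) else NA_real_
  list(precision = precision, recall = recall, fScore = fScore,
       accuracy = accuracy)
}

#' Timing bias and uncertainty of imputed spikes
#'
#' Signed offset of each imputed spike to a ground-truth spike within
#' \code{window}: either the nearest truth spike (\code{mode = "nearest"})
#' or its assignment-matched partner (\code{mode = "matched"}). Positive
#' offsets mean the imputed spike is later than truth. Bias is the median
#' signed offset, uncertainty the median absolute offset.
#'
#' @param imputed,truth \linkS4class{SpikeTrain}s
#' @param window maximum |offset| retained (s), default 100 ms
#' @param mode "matched" or "nearest"
#' @return list with biasMs, uncertaintyMs, offsets (s)
#' @export
timingStats <- function(imputed, truth, window = 0.100,
                        mode = c("matched", "nearest")) {
  mode <- match.arg(mode)
  a <- spikeTimes(imputed); b <- spikeTimes(truth)
  if (!length(a) || !length(b))
    return(list(biasMs = NA_real_, uncertaintyMs = NA_real_,
                offsets = numeric(0)))
  offsets <- if (mode == "nearest") {
    vapply(a, function(t) {
      d <- t - b
      d[which.min(abs(d))]
    }, numeric(1))
  } else {
    matchSpikes(imputed, truth, maxDt = window)@pairs$offset
  }
  offsets <- offsets[abs(offsets) <= window]
  if (!length(offsets))
    return(list(biasMs = NA_real_, uncertaintyMs = NA_real_,
                offsets = numeric(0)))
  list(biasMs = 1000 * median(offsets),
       uncertaintyMs = 1000 * median(abs(offsets)),
       offsets = offsets)
}

#' Bin spike times onto a uniform grid
#'
#' Half-open bins [t, t + dt) starting at 0.
#'
#' @param spikes a \linkS4class{SpikeTrain}
#' @param nBins number of bins
#' @param rate bin rate (Hz)
#' @return integer vector of per-bin spike counts
#' @export
binSpikes <- function(spikes, nBins, rate) {
  idx <- floor(spikeTimes(spikes) * rate) + 1
  idx <- idx[idx >= 1 & idx <= nBins]
  tabulate(idx, nbins = nBins)
}

## Gaussian smoothing with SD in bins; kernel truncated at 5 SD,
## renormalized, edge-replicated padding (a constant signal stays constant).
.gaussSmooth <- function(x, sdBins) {
  if (sdBins <= 0) return(as.numeric(x))
  r <- max(1L, ceiling(5 * sdBins))
  k <- dnorm(seq(-r, r), sd = sdBins)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(x[1], r), x, rep(x[n], r))
  y <- stats::filter(xp, k, sides = 2)
  as.numeric(y[(r + 1):(r + n)])
}

#' Correlation between filtered spike probability and ground truth
#'
#' Convolves both the continuous per-bin spike probability (or density) and
#' the binned ground-truth train with Gaussian kernels of the given SDs and
#' reports the Pearson correlation at each width. Constant signals give
#' \code{NA}.
#'
#' @param prob numeric per-bin spike probability/density
#' @param truth a \linkS4class{SpikeTrain}
#' @param widths Gaussian SDs (s)
#' @param rate bin rate of \code{prob} (Hz)
#' @return named numeric vector of Pearson r per width
#' @export
filteredCorrelation <- function(prob, truth, widths, rate) {
  counts <- binSpikes(truth, length(prob), rate)
  vapply(widths, function(w) {
    ps <- .gaussSmooth(prob, w * rate)
    ts <- .gaussSmooth(counts, w * rate)
    if (sd(ps) == 0 || sd(ts) == 0) NA_real_ else cor(ps, ts)
  }, numeric(1)) |> setNames(paste0(widths * 1000, "ms"))
}

#' Robust summary statistics
#'
#' Median, interquartile range, and the robust standard deviation defined
#' as the median absolute deviation divided by 0.6745.
#'
#' @param values nonempty numeric vector
#' @return list with median, iqr, robustSd
#' @export
robustSummary <- function(values) {
  if (!length(values)) stop("robustSummary requires a nonempty vector")
  list(median = median(values),
       iqr = unname(diff(quantile(values, c(0.25, 0.75)))),
       robustSd = mad(values, constant = 1) / 0.6745)
}
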