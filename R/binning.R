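## Binning of spike trains into binary state series and assembly of lagged
## joint observations (I_F, I_P, J_P, ...).

## Canonical names for source past-state variables, in order.
sourceVarNames <- function(n)
  c("J_P", "K_P", "L_P", "M_P", "N_P", "O_P")[seq_len(n)]

#' Discretize a spike train into a binary bin series
#'
#' Bin b (0-based, half-open `[tStart + b*w, tStart + (b+1)*w)`) is 1 iff at
#' least one spike falls in it; the series has `floor((tEnd - tStart)/w)`
#' bins.
#'
#' @param times numeric spike times (seconds).
#' @param binWidthMs bin width in milliseconds.
#' @param tStart,tEnd interval bounds in seconds.
#' @return integer 0/1 vector.
#' @examples
#' binSpikes(c(0.001), 1.6, 0, 0.008)  # 1 0 0 0 0
#' @export
binSpikes <- function(times, binWidthMs, tStart, tEnd) {
  nb <- nBinsFor(tStart, tEnd, binWidthMs)
  if (nb < 1L) stop("empty binning interval", call. = FALSE)
  out <- integer(nb)
  occ <- occupiedBins(times, binWidthMs, tStart, nb)
  out[occ] <- 1L
  out
}

## Number of bins, robust to floating-point representation of the width.
nBinsFor <- function(tStart, tEnd, binWidthMs) {
  w <- binWidthMs / 1000
  as.integer(floor((tEnd - tStart) / w + 1e-9))
}

## 1-based indices of bins containing >= 1 spike (sorted, unique).
occupiedBins <- function(times, binWidthMs, tStart, nBins) {
  w <- binWidthMs / 1000
  b <- as.integer(floor((times - tStart) / w + 1e-9)) + 1L
  b <- b[b >= 1L & b <= nBins]
  sort(unique(b))
}

#' Assemble lagged binary observations for one receiver and its sources
#'
#' For each future index t with all required lags inside the series, the row
#' is `(i_F, i_P, j_P, ...)` with `i_F = receiver[t]`,
#' `i_P = receiver[t - receiverSelfLag]`, and source j at its own delay
#' `j_P = source_j[t - delay_j]`. The receiver self-past lag defaults to the
#' bin immediately preceding the future bin.
#'
#' @param receiver integer 0/1 series.
#' @param sources a single 0/1 vector or list of them.
#' @param delaysBins integer delay (bins) per source, recycled if length 1.
#' @param receiverSelfLag self-past lag in bins (default 1).
#' @return integer matrix with named columns `I_F`, `I_P`, `J_P`, `K_P`, ...
#' @examples
#' laggedObservations(c(0, 1, 0, 1), c(1, 0, 1, 0), 1)
#' @export
laggedObservations <- function(receiver, sources, delaysBins,
                               receiverSelfLag = 1L) {
  if (!is.list(sources)) sources <- list(sources)
  ns <- length(sources)
  delaysBins <- as.integer(rep(delaysBins, length.out = ns))
  if (any(delaysBins < 1L)) stop("delays must be >= 1 bin", call. = FALSE)
  len <- length(receiver)
  if (any(vapply(sources, length, 0L) != len))
    stop("all series must have the same length", call. = FALSE)
  stopIfNot01(receiver, "receiver")
  maxLag <- max(delaysBins, receiverSelfLag)
  if (len < maxLag + 1L)
    stop("series shorter than max delay + 1", call. = FALSE)
  t <- seq.int(maxLag + 1L, len)
  cols <- c(list(I_F = receiver[t], I_P = receiver[t - receiverSelfLag]),
            setNames(lapply(seq_len(ns), function(j) {
              stopIfNot01(sources[[j]], "source")
              sources[[j]][t - delaysBins[j]]
            }), sourceVarNames(ns)))
  do.call(cbind, cols)
}

## Joint state counts over binary lagged variables computed from sparse
## occupied-bin sets, avoiding materializing hour-scale dense series.
## `binsList`: list of sorted occupied-bin index vectors, one per variable,
## in the order (I_F, I_P, J_P, ...). `lags`: integer lag per variable
## (0 for I_F, selfLag for I_P, delay_j for each source). Returns counts of
## the 2^k cells in array order (first variable fastest).
jointStateCountsSparse <- function(binsList, lags, nBins) {
  k <- length(binsList)
  lo <- max(lags) + 1L
  if (nBins < lo) stop("series shorter than max delay + 1", call. = FALSE)
  nRows <- nBins - lo + 1L
  shifted <- lapply(seq_len(k), function(v) {
    b <- binsList[[v]] + lags[v]
    b[b >= lo & b <= nBins]
  })
  if (sum(lengths(shifted)) * 3L > nRows) {
    ## dense path: high-occupancy series are cheaper as aligned 0/1 vectors
    code <- integer(nRows)
    for (v in seq_len(k)) {
      d <- integer(nRows)
      d[shifted[[v]] - lo + 1L] <- as.integer(2^(v - 1))
      code <- code + d
    }
    return(tabulate(code + 1L, nbins = 2L^k))
  }
  u <- sort(unique(unlist(shifted, use.names = FALSE)))
  code <- integer(length(u))
  for (v in seq_len(k))
    code <- code + as.integer(u %in% shifted[[v]]) * as.integer(2^(v - 1))
  counts <- tabulate(code + 1L, nbins = 2L^k)
  counts[1L] <- counts[1L] + (nRows - length(u))
  counts
}

## Estimated joint distribution of the lagged states of a receiver and its
## sources directly from a SpikeTrainSet, at one bin width with per-source
## delays (in bins). Used by the TE/PID pipeline.
laggedJointDistribution <- function(spikes, receiver, sources, binWidthMs,
                                     delaysBins, receiverSelfLag = 1L) {
  nb <- nBinsFor(spikes@tStart, spikes@tEnd, binWidthMs)
  recBins <- occupiedBins(spikeTimes(spikes, receiver), binWidthMs,
                          spikes@tStart, nb)
  srcBins <- lapply(sources, function(s)
    occupiedBins(spikeTimes(spikes, s), binWidthMs, spikes@tStart, nb))
  binsList <- c(list(recBins, recBins), srcBins)
  lags <- c(0L, as.integer(receiverSelfLag), as.integer(delaysBins))
  counts <- jointStateCountsSparse(binsList, lags, nb)
  vn <- c("I_F", "I_P", sourceVarNames(length(sources)))
  jointDistribution(counts / sum(counts), vn)
}
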