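## Effective-network inference: pairwise TE with max-over-delay selection,
## spike-jitter surrogate significance, sub-network sampling, degree
## statistics, and the log-normal connection-weight fit.

## TE of one directed pair at every delay of a timescale, from sparse
## occupied-bin sets. Returns teBits per delay plus H(I_F) and row count.
.pairTEAllDelays <- function(srcBins, rcvBins, nBins, delaysBins,
                             selfLag = 1L) {
  vapply(delaysBins, function(d) {
    counts <- jointStateCountsSparse(list(rcvBins, rcvBins, srcBins),
                                     c(0L, selfLag, d), nBins)
    dist <- jointDistribution(counts / sum(counts), c("I_F", "I_P", "J_P"))
    conditionalMutualInformation(dist, "I_F", "J_P", "I_P")
  }, 0)
}

#' Pairwise transfer entropy for all directed pairs at one timescale
#'
#' For every ordered pair the TE is computed at each delay of the timescale
#' and the maximum over delays is retained together with the argmax delay
#' (reused downstream for triad distributions).
#'
#' @param spikes a [SpikeTrainSet-class].
#' @param ts a [Timescale-class].
#' @return data.frame with columns source, target, delayBins, teBits,
#'   teNormalized, nObs.
#' @export
pairwiseTE <- function(spikes, ts) {
  ids <- neuronIds(spikes)
  nb <- nBinsFor(spikes@tStart, spikes@tEnd, ts@binWidthMs)
  bins <- lapply(ids, function(i)
    occupiedBins(spikeTimes(spikes, i), ts@binWidthMs, spikes@tStart, nb))
  names(bins) <- ids
  hF <- vapply(ids, function(i) {
    p1 <- length(bins[[i]]) / nb
    -sum(c(p1, 1 - p1) * log2safe(c(p1, 1 - p1)))
  }, 0)
  pairs <- expand.grid(source = ids, target = ids,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  res <- lapply(seq_len(nrow(pairs)), function(r) {
    s <- pairs$source[r]; t <- pairs$target[r]
    tes <- .pairTEAllDelays(bins[[s]], bins[[t]], nb, ts@delaysBins)
    best <- which.max(tes)
    c(delay = ts@delaysBins[best], te = tes[best])
  })
  res <- do.call(rbind, res)
  data.frame(source = pairs$source, target = pairs$target,
             delayBins = as.integer(res[, "delay"]),
             teBits = res[, "te"],
             teNormalized = ifelse(hF[pairs$target] > 0,
                                   pmin(res[, "te"] / hF[pairs$target], 1), 0),
             nObs = nb - max(ts@delaysBins),
             row.names = NULL)
}

#' Spike-jitter surrogate trains
#'
#' Each surrogate displaces every spike independently by a uniform offset in
#' `[-window, +window]`, clamped to the recording interval; the spike count
#' is preserved. Jittering destroys millisecond-scale delay structure while
#' preserving slow rate fluctuations, making it a suitable null for
#' synaptic-timescale TE.
#'
#' @param times numeric spike times (seconds).
#' @param nSurrogates number of surrogate trains.
#' @param jitterWindowMs half-width of the uniform jitter window (ms).
#' @param tStart,tEnd recording interval (seconds) for clamping.
#' @param seed RNG seed.
#' @return list of `nSurrogates` sorted numeric vectors.
#' @export
jitterSurrogates <- function(times, nSurrogates, jitterWindowMs = 20,
                             tStart = 0, tEnd = Inf, seed = NULL) {
  stopifnot(nSurrogates >= 1, jitterWindowMs > 0)
  w <- jitterWindowMs / 1000
  withSeed(seed, lapply(seq_len(nSurrogates), function(i) {
    if (!length(times)) return(times)
    jit <- times + runif(length(times), -w, w)
    sort(pmin(pmax(jit, tStart), tEnd))
  }))
}

#' Surrogate-based significance of one connection
#'
#' `p = #(surrogate TE > real TE) / n_surrogates`; the connection is deemed
#' significant when `p < alpha` (with 5000 surrogates and alpha 0.001 this
#' is the "fewer than 5 surrogates larger" rule; a count of exactly 5 gives
#' p = 0.001 and is not significant).
#'
#' @param teReal observed TE (bits).
#' @param surrogateTEs numeric vector of surrogate TEs.
#' @param alpha significance level (default 0.001).
#' @return list with `pValue` and `isSignificant`.
#' @export
connectionSignificance <- function(teReal, surrogateTEs, alpha = 0.001) {
  stopifnot(length(surrogateTEs) >= 1)
  p <- sum(surrogateTEs > teReal) / length(surrogateTEs)
  list(pValue = p, isSignificant = p < alpha)
}

## Surrogate TE values for one pair: jitter the source train, rebin, and
## take the same max-over-delays statistic as the real pair.
.surrogateTEs <- function(spikes, source, target, ts, nSurrogates,
                          jitterWindowMs, seed = NULL) {
  nb <- nBinsFor(spikes@tStart, spikes@tEnd, ts@binWidthMs)
  rcvBins <- occupiedBins(spikeTimes(spikes, target), ts@binWidthMs,
                          spikes@tStart, nb)
  surr <- jitterSurrogates(spikeTimes(spikes, source), nSurrogates,
                           jitterWindowMs, spikes@tStart, spikes@tEnd, seed)
  vapply(surr, function(st) {
    sb <- occupiedBins(st, ts@binWidthMs, spikes@tStart, nb)
    max(.pairTEAllDelays(sb, rcvBins, nb, ts@delaysBins))
  }, 0)
}

#' Test one directed connection against jitter surrogates
#'
#' @param spikes a [SpikeTrainSet-class].
#' @param source,target neuron ids.
#' @param ts a [Timescale-class].
#' @param nSurrogates number of surrogates (paper-scale default 5000).
#' @param jitterWindowMs jitter half-width (ms).
#' @param alpha significance level.
#' @param seed RNG seed.
#' @return list with `teBits`, `delayBins`, `pValue`, `isSignificant`.
#' @export
testConnection <- function(spikes, source, target, ts, nSurrogates = 5000,
                           jitterWindowMs = 20, alpha = 0.001, seed = NULL) {
  nb <- nBinsFor(spikes@tStart, spikes@tEnd, ts@binWidthMs)
  sb <- occupiedBins(spikeTimes(spikes, source), ts@binWidthMs,
                     spikes@tStart, nb)
  rb <- occupiedBins(spikeTimes(spikes, target), ts@binWidthMs,
                     spikes@tStart, nb)
  tes <- .pairTEAllDelays(sb, rb, nb, ts@delaysBins)
  best <- which.max(tes)
  surr <- .surrogateTEs(spikes, source, target, ts, nSurrogates,
                        jitterWindowMs, seed)
  sig <- connectionSignificance(tes[best], surr, alpha)
  list(teBits = tes[best], delayBins = ts@delaysBins[best],
       pValue = sig$pValue, isSignificant = sig$isSignificant)
}

#' Build an effective network by surrogate-testing every directed pair
#'
#' Computes max-over-delay TE for all ordered pairs, tests each against
#' spike-jitter surrogates of its source train, and keeps significant edges
#' with their argmax delays.
#'
#' @param spikes a [SpikeTrainSet-class].
#' @param ts a [Timescale-class].
#' @param nSurrogates surrogates per pair (paper scale 5000).
#' @param jitterWindowMs jitter half-width (ms).
#' @param alpha significance level (default 0.001).
#' @param seed RNG seed.
#' @return An [EffectiveNetwork-class].
#' @export
buildNetwork <- function(spikes, ts, nSurrogates = 5000, jitterWindowMs = 20,
                         alpha = 0.001, seed = NULL) {
  te <- pairwiseTE(spikes, ts)
  if (!nrow(te))
    return(effectiveNetwork(te[, c("source", "target")],
                            nodes = neuronIds(spikes),
                            timescaleLabel = ts@label))
  pv <- vapply(seq_len(nrow(te)), function(r) {
    surr <- .surrogateTEs(spikes, te$source[r], te$target[r], ts,
                          nSurrogates, jitterWindowMs,
                          seed = if (is.null(seed)) NULL else seed + r)
    sum(surr > te$teBits[r]) / length(surr)
  }, 0)
  te$pValue <- pv
  keep <- te[pv < alpha, , drop = FALSE]
  effectiveNetwork(keep, nodes = neuronIds(spikes), timescaleLabel = ts@label)
}

#' Per-node degree summary of an effective network
#'
#' @param network an [EffectiveNetwork-class].
#' @return data.frame with node, inDegree, outDegree, totalDegree.
#' @export
degreeSummary <- function(network) {
  ed <- edgeTable(network)
  nodes <- neuronIds(network)
  inD <- table(factor(ed$target, levels = nodes))
  outD <- table(factor(ed$source, levels = nodes))
  data.frame(node = nodes, inDegree = as.integer(inD),
             outDegree = as.integer(outD),
             totalDegree = as.integer(inD) + as.integer(outD),
             row.names = NULL)
}

#' Sample sub-networks with a target average total degree
#'
#' Repeatedly samples node subsets uniformly and keeps the induced
#' sub-network when its average total degree (2 x edges / nodes) is within
#' `tolerance` of the target; sampling bias from network size and density is
#' thereby equalized across recordings.
#'
#' @param network an [EffectiveNetwork-class] with at least `size` nodes.
#' @param nSub number of sub-networks (paper scale 500).
#' @param size nodes per sub-network (paper scale 50).
#' @param targetAvgTotalDegree target average total degree (paper scale 3).
#' @param tolerance acceptance half-width (default 0.2).
#' @param maxRetries global rejection budget (default 1e5).
#' @param seed RNG seed.
#' @return list of [EffectiveNetwork-class] objects of length `nSub`.
#' @export
sampleSubnetworks <- function(network, nSub = 500, size = 50,
                              targetAvgTotalDegree = 3, tolerance = 0.2,
                              maxRetries = 1e5, seed = NULL) {
  nodes <- neuronIds(network)
  if (length(nodes) < size)
    stop("network has fewer nodes than the requested sub-network size",
         call. = FALSE)
  ed <- edgeTable(network)
  withSeed(seed, {
    out <- vector("list", nSub)
    found <- 0L
    tries <- 0L
    while (found < nSub && tries < maxRetries) {
      tries <- tries + 1L
      sub <- sample(nodes, size)
      keep <- ed$source %in% sub & ed$target %in% sub
      avg <- 2 * sum(keep) / size
      if (abs(avg - targetAvgTotalDegree) <= tolerance) {
        found <- found + 1L
        out[[found]] <- effectiveNetwork(ed[keep, , drop = FALSE],
                                         nodes = sub,
                                         timescaleLabel =
                                           network@timescaleLabel)
      }
    }
    if (found < nSub)
      stop(sprintf(paste("only %d of %d sub-networks found within the",
                         "degree tolerance after %d retries"),
                   found, nSub, tries), call. = FALSE)
    out
  })
}

#' Compare real degree distributions to matched random networks
#'
#' Generates `nRandom` uniform random directed networks with the same node
#' and edge counts as `network` (via [randomNetwork()]) and returns degree
#' summaries for both; a heavy-tailed real network shows maximum total
#' degrees far beyond the random ensemble.
#'
#' @param network an [EffectiveNetwork-class].
#' @param nRandom number of matched random networks (default 100).
#' @param seed RNG seed.
#' @return list with `real` (degree summary data.frame) and `random` (list
#'   of degree summaries).
#' @export
degreeDistributionComparison <- function(network, nRandom = 100,
                                         seed = NULL) {
  nNodes <- length(neuronIds(network))
  nEdges <- nrow(edgeTable(network))
  rand <- withSeed(seed, lapply(seq_len(nRandom), function(i) {
    el <- randomNetwork(nNodes, nEdges)
    degreeSummary(effectiveNetwork(el, nodes = as.character(0:(nNodes - 1))))
  }))
  list(real = degreeSummary(network), random = rand)
}

#' Fit a log10-normal mass function to positive connection weights
#'
#' Bins the values into 100 logarithmically spaced bins and fits
#' `p(x) = alpha/(sigma*sqrt(2*pi)) * exp(-(log10(x)-mu)^2 / (2*sigma^2))`
#' to the per-bin mass by nonlinear least squares; the normalization factor
#' alpha absorbs the binning.
#'
#' @param teValues positive numeric weights (at least 100 values).
#' @param nBins number of log-spaced bins (default 100).
#' @return list with `alphaNorm`, `mu`, `sigma`, `fitResidual`, `nBins`.
#' @export
fitLogNormal <- function(teValues, nBins = 100) {
  if (any(teValues <= 0)) stop("values must be positive", call. = FALSE)
  if (length(teValues) < 100)
    stop("need at least 100 values", call. = FALSE)
  lx <- log10(teValues)
  if (diff(range(lx)) < 1e-12)
    stop("degenerate (all-equal) values: sigma -> 0", call. = FALSE)
  edges <- seq(min(lx), max(lx), length.out = nBins + 1L)
  bin <- findInterval(lx, edges, rightmost.closed = TRUE, all.inside = TRUE)
  mass <- tabulate(bin, nbins = nBins) / length(lx)
  mids <- (edges[-1] + edges[-(nBins + 1L)]) / 2
  df <- data.frame(lx = mids, mass = mass)
  start <- list(alphaNorm = diff(edges[1:2]), mu = mean(lx), sigma = sd(lx))
  fit <- minpack.lm::nlsLM(
    mass ~ alphaNorm / (sigma * sqrt(2 * pi)) *
      exp(-(lx - mu)^2 / (2 * sigma^2)),
    data = df, start = start,
    lower = c(1e-12, -Inf, 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(fit)
  list(alphaNorm = unname(cf["alphaNorm"]), mu = unname(cf["mu"]),
       sigma = unname(cf["sigma"]),
       fitResidual = sum(residuals(fit)^2), nBins = as.integer(nBins))
}

#' @importFrom stats residuals
NULL
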