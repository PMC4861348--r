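## Synthetic spike data: the eight worked-example joint distributions, motif
## state samplers, recording generation with plantable triads and directed
## couplings, and matched random networks.

## The eight example joint probability columns over (I_F, I_P, J_P, K_P),
## rows in lexicographic order of (i_F, i_P, j_P, k_P) with k_P varying
## fastest, as printed. The synergistic_redundant column sums to 1.0002
## (printed values are rounded to 4 decimals) and is renormalized on use.
.motifTable <- local({
  rows <- expand.grid(K_P = 0:1, J_P = 0:1, I_P = 0:1, I_F = 0:1)[, 4:1]
  cols <- list(
    no_interaction = rep(1 / 16, 16),
    self = c(rep(1 / 8, 4), rep(0, 8), rep(1 / 8, 4)),
    hidden_self = c(1/4, 1/4, 0, 0,  0, 0, 0, 0,
                    0, 0, 0, 0,  0, 0, 1/4, 1/4),
    single = c(1/8, 1/8, 0, 0,  1/8, 1/8, 0, 0,
               0, 0, 1/8, 1/8,  0, 0, 1/8, 1/8),
    redundant = c(1/4, 0, 0, 0,  1/4, 0, 0, 0,
                  0, 0, 0, 1/4,  0, 0, 0, 1/4),
    single_redundant = c(0.1964, 0.0536, 0, 0,  0.1964, 0.0536, 0, 0,
                         0, 0, 0.0536, 0.1964,  0, 0, 0.0536, 0.1964),
    synergistic = c(1/8, 0, 0, 1/8,  1/8, 0, 0, 1/8,
                    0, 1/8, 1/8, 0,  0, 1/8, 1/8, 0),
    synergistic_redundant = c(0.0548, 0.0548, 0.0548, 0,
                              0.0548, 0.0548, 0.0548, 0,
                              0, 0, 0, 0.3357,
                              0, 0, 0, 0.3357))
  list(states = as.matrix(rows), columns = cols)
})

#' Names of the eight example interaction motifs
#' @return character vector of motif names.
#' @export
motifNames <- function() names(.motifTable$columns)

#' Joint distribution of one example interaction motif
#'
#' Returns the printed 16-entry joint probability mass over
#' `(I_F, I_P, J_P, K_P)` for one of the eight example interaction types,
#' renormalized to sum to exactly 1 (the printed synergistic-and-redundant
#' column sums to 1.0002 because its entries are rounded to four decimals).
#'
#' @param motifName one of [motifNames()].
#' @return A [JointDistribution-class] over `I_F`, `I_P`, `J_P`, `K_P`.
#' @examples
#' motifDistribution("no_interaction")
#' @export
motifDistribution <- function(motifName) {
  p <- .motifTable$columns[[motifName]]
  if (is.null(p)) stop("unknown motif name: ", motifName, call. = FALSE)
  p <- p / sum(p)
  st <- .motifTable$states
  ## map printed row order to array order (I_F fastest)
  code <- st[, "I_F"] + 2L * st[, "I_P"] + 4L * st[, "J_P"] + 8L * st[, "K_P"]
  arr <- numeric(16)
  arr[code + 1L] <- p
  jointDistribution(arr, c("I_F", "I_P", "J_P", "K_P"))
}

#' Printed (unnormalized) motif probability column
#'
#' The raw column as printed, in lexicographic row order of
#' `(I_F, I_P, J_P, K_P)`; useful for checking cell values before
#' renormalization.
#'
#' @param motifName one of [motifNames()].
#' @return data.frame with state columns and `p`.
#' @export
motifColumn <- function(motifName) {
  p <- .motifTable$columns[[motifName]]
  if (is.null(p)) stop("unknown motif name: ", motifName, call. = FALSE)
  cbind(as.data.frame(.motifTable$states), p = p)
}

#' Sample lagged-state tuples from a motif distribution
#'
#' @param dist a [JointDistribution-class] (e.g. from
#'   [motifDistribution()]).
#' @param nSamples number of i.i.d. draws.
#' @param seed RNG seed.
#' @return integer matrix `nSamples x k` with the distribution's variable
#'   names as columns.
#' @export
sampleMotifStates <- function(dist, nSamples, seed = NULL) {
  stopifnot(nSamples >= 1)
  p <- as.numeric(dist@probs)
  k <- length(dist@varNames)
  idx <- withSeed(seed,
                  sample.int(length(p), nSamples, replace = TRUE, prob = p))
  idx0 <- idx - 1L
  out <- vapply(seq_len(k),
                function(v) (idx0 %/% as.integer(2^(v - 1))) %% 2L,
                integer(nSamples))
  if (nSamples == 1L) out <- matrix(out, nrow = 1L)
  colnames(out) <- dist@varNames
  out
}

#' Specification of a planted three-neuron motif
#'
#' @param motifName one of [motifNames()].
#' @param neurons length-3 vector `(J, K, I)` of 0-based neuron indices.
#' @param delayMs source-to-receiver delay in ms (in (0, 20]).
#' @param binMs bin width in ms at which the motif operates.
#' @param baseRateHz optional extra independent Poisson background added to
#'   the motif neurons (default 0: motif drive only).
#' @return list of class `motifSpec`.
#' @export
motifSpec <- function(motifName, neurons, delayMs = 4.8, binMs = 1.6,
                      baseRateHz = 0) {
  if (!motifName %in% motifNames())
    stop("unknown motif name: ", motifName, call. = FALSE)
  stopifnot(length(neurons) == 3, delayMs > 0, delayMs <= 20, binMs > 0,
            baseRateHz >= 0)
  structure(list(motifName = motifName, neurons = as.integer(neurons),
                 delayMs = delayMs, binMs = binMs, baseRateHz = baseRateHz),
            class = "motifSpec")
}

#' Specification of a planted directed pairwise coupling
#'
#' The target receives, in addition to its own background, a copy of each
#' source spike at `delayMs` later with probability `copyProb`, producing
#' excess delayed coincidences.
#'
#' @param source,target 0-based neuron indices.
#' @param delayMs coupling delay in ms.
#' @param copyProb per-spike copy probability (default 0.5).
#' @return list of class `edgeSpec`.
#' @export
edgeSpec <- function(source, target, delayMs = 4.8, copyProb = 0.5) {
  stopifnot(source != target, delayMs > 0, copyProb >= 0, copyProb <= 1)
  structure(list(source = as.integer(source), target = as.integer(target),
                 delayMs = delayMs, copyProb = copyProb),
            class = "edgeSpec")
}

## Motif-neuron binary state generation. Six of the eight columns have an
## independent fair receiver past, so (J,K) can be drawn i.i.d. per bin from
## their joint marginal and I sampled from p(i_F | j_P, k_P) at the delay;
## the self/hidden_self columns require I_F = I_P and are realized with
## block-constant fair drive (block length `blockBins`), exact up to
## O(1/blockBins) boundary error.
.motifStates <- function(motifName, nBins, delayBins, blockBins = 250L,
                         jSt = NULL, kSt = NULL) {
  d <- delayBins
  blockSeries <- function() {
    nBlk <- ceiling(nBins / blockBins)
    rep(sample(0:1, nBlk, replace = TRUE), each = blockBins)[1:nBins]
  }
  if (motifName == "self") {
    iSt <- blockSeries()
    if (is.null(jSt)) jSt <- sample(0:1, nBins, replace = TRUE)
    if (is.null(kSt)) kSt <- sample(0:1, nBins, replace = TRUE)
  } else if (motifName == "hidden_self") {
    if (is.null(jSt)) jSt <- blockSeries()
    iSt <- c(rep(0L, d), jSt[seq_len(nBins - d)])
    if (is.null(kSt)) kSt <- sample(0:1, nBins, replace = TRUE)
  } else {
    dist <- motifDistribution(motifName)
    if (is.null(jSt) && is.null(kSt)) {
      pJK <- marginalDistribution(dist, c("J_P", "K_P"))@probs
      jk <- sample.int(4L, nBins, replace = TRUE, prob = as.numeric(pJK))
      jSt <- (jk - 1L) %% 2L
      kSt <- (jk - 1L) %/% 2L
    } else {
      ## valid only for motifs whose (J, K) marginal is two independent
      ## fair bits (enforced by the caller)
      if (is.null(jSt)) jSt <- sample(0:1, nBins, replace = TRUE)
      if (is.null(kSt)) kSt <- sample(0:1, nBins, replace = TRUE)
    }
    joint <- marginalDistribution(dist, c("I_F", "J_P", "K_P"))@probs
    ## p(I_F = 1 | j, k), indexed by code j + 2k
    p1 <- as.numeric(joint[2, , ]) / as.numeric(joint[1, , ] + joint[2, , ])
    p1[!is.finite(p1)] <- 0
    iSt <- integer(nBins)
    src <- seq_len(nBins - d)
    iSt[src + d] <- as.integer(runif(length(src)) <
                                 p1[jSt[src] + 2L * kSt[src] + 1L])
  }
  list(I = iSt, J = jSt, K = kSt)
}

## which motif sources exert actual directed drive on the receiver
.motifDrivingSources <- function(motifName) {
  switch(motifName,
         no_interaction = , self = , hidden_self = integer(0),
         single = 1L,
         1:2)
}

## spike times at bin centers for state-1 bins
.statesToSpikes <- function(states, binMs, tStart) {
  w <- binMs / 1000
  tStart + (which(states == 1L) - 0.5) * w
}

#' Generate a synthetic recording with planted motifs and couplings
#'
#' Background neurons are independent homogeneous Poisson processes. Each
#' motif triad is driven so that the lagged-state distribution of
#' `(I_F, I_P, J_P, K_P)` at the motif's bin width and delay converges to
#' the corresponding example column as the duration grows (motif neurons
#' spike at bin centers of their state-1 bins). Each planted edge copies
#' source spikes into the target at the stated delay with probability
#' `copyProb`, producing excess delayed coincidences. Source neurons of a
#' motif may be shared between motifs only when the motif's source marginal
#' factorizes into independent fair bits; assigning two motifs to the same
#' receiver is an error.
#'
#' @param nNeurons number of neurons (ids "0" .. "nNeurons-1").
#' @param durationS recording duration in seconds.
#' @param motifSpecs list of [motifSpec()] objects.
#' @param edgeSpecs list of [edgeSpec()] objects.
#' @param backgroundRateHz Poisson rate of non-motif neurons (motif neurons
#'   receive their own `baseRateHz`).
#' @param seed RNG seed; the generated recording is reproducible given the
#'   seed.
#' @return A [SyntheticRecording-class].
#' @examples
#' rec <- generateRecording(3, 60, list(motifSpec("synergistic", c(0, 1, 2))),
#'                          list(), 0, seed = 1)
#' rec@spikes
#' @export
generateRecording <- function(nNeurons, durationS, motifSpecs = list(),
                              edgeSpecs = list(), backgroundRateHz = 1,
                              seed = NULL) {
  stopifnot(durationS > 0, nNeurons >= 1)
  idx <- function(i) as.character(i) # 0-based ids
  recv <- vapply(motifSpecs, function(m) m$neurons[3], 0L)
  if (anyDuplicated(recv))
    stop("conflicting motif assignments to the same target neuron",
         call. = FALSE)
  allIdx <- unlist(lapply(motifSpecs, `[[`, "neurons"))
  if (length(allIdx) && max(allIdx) >= nNeurons)
    stop("motif neuron index out of range", call. = FALSE)
  for (e in edgeSpecs)
    if (max(e$source, e$target) >= nNeurons)
      stop("edge neuron index out of range", call. = FALSE)
  fairSources <- c("no_interaction", "single", "synergistic")
  srcSeen <- integer(0)

  allSrc <- unlist(lapply(motifSpecs, function(m) m$neurons[1:2]))
  if (length(intersect(recv, allSrc)))
    stop("a motif receiver cannot also be a motif source", call. = FALSE)

  withSeed(seed, {
    trains <- setNames(vector("list", nNeurons), idx(0:(nNeurons - 1)))
    motifNeuron <- rep(FALSE, nNeurons)
    states <- vector("list", nNeurons) # motif state series, for sharing
    for (m in motifSpecs) {
      jId <- m$neurons[1]; kId <- m$neurons[2]; iId <- m$neurons[3]
      shared <- intersect(c(jId, kId), srcSeen)
      if (length(shared) && !(m$motifName %in% fairSources))
        stop("source neuron(s) ", paste(shared, collapse = ","),
             " cannot be shared: motif '", m$motifName,
             "' has dependent sources", call. = FALSE)
      nb <- nBinsFor(0, durationS, m$binMs)
      dBins <- max(1L, as.integer(round(m$delayMs / m$binMs)))
      st <- .motifStates(m$motifName, nb, dBins,
                         jSt = states[[jId + 1L]], kSt = states[[kId + 1L]])
      for (pair in list(c(jId, 1), c(kId, 2), c(iId, 3))) {
        nid <- pair[1]
        sts <- st[[c("J", "K", "I")[pair[2]]]]
        if (!motifNeuron[nid + 1L]) {
          states[[nid + 1L]] <- sts
          trains[[idx(nid)]] <- .statesToSpikes(sts, m$binMs, 0)
          motifNeuron[nid + 1L] <- TRUE
        }
      }
      srcSeen <- union(srcSeen, c(jId, kId))
      if (m$baseRateHz > 0) {
        for (nid in m$neurons) {
          extra <- runif(rpois(1, m$baseRateHz * durationS)) * durationS
          trains[[idx(nid)]] <- sort(c(trains[[idx(nid)]], extra))
        }
      }
    }
    for (i in 0:(nNeurons - 1)) {
      if (!motifNeuron[i + 1L]) {
        n <- rpois(1, backgroundRateHz * durationS)
        trains[[idx(i)]] <- sort(runif(n) * durationS)
      }
    }
    for (e in edgeSpecs) {
      src <- trains[[idx(e$source)]]
      keep <- runif(length(src)) < e$copyProb
      copies <- src[keep] + e$delayMs / 1000
      copies <- copies[copies <= durationS]
      trains[[idx(e$target)]] <- sort(c(trains[[idx(e$target)]], copies))
    }
    gtEdges <- do.call(rbind, c(
      lapply(motifSpecs, function(m) {
        drv <- .motifDrivingSources(m$motifName)
        if (!length(drv)) return(NULL)
        data.frame(source = idx(m$neurons[drv]), target = idx(m$neurons[3]),
                   delayMs = m$delayMs)
      }),
      lapply(edgeSpecs, function(e)
        data.frame(source = idx(e$source), target = idx(e$target),
                   delayMs = e$delayMs))))
    if (is.null(gtEdges))
      gtEdges <- data.frame(source = character(), target = character(),
                            delayMs = numeric())
    gtMotifs <- do.call(rbind, lapply(motifSpecs, function(m)
      data.frame(motif = m$motifName, J = idx(m$neurons[1]),
                 K = idx(m$neurons[2]), I = idx(m$neurons[3]),
                 delayMs = m$delayMs, binMs = m$binMs)))
    if (is.null(gtMotifs))
      gtMotifs <- data.frame(motif = character(), J = character(),
                             K = character(), I = character(),
                             delayMs = numeric(), binMs = numeric())
    new("SyntheticRecording",
        spikes = spikeTrainSet(trains, 0, durationS),
        groundTruthEdges = gtEdges, groundTruthMotifs = gtMotifs,
        seed = as.integer(if (is.null(seed)) NA else seed))
  })
}

#' Uniform random directed network with a fixed number of edges
#'
#' Draws exactly `nEdges` directed non-self edges uniformly without
#' replacement (an Erdos-Renyi G(n, m) directed graph), used as the matched
#' null ensemble for degree-distribution comparisons.
#'
#' @param nNodes number of nodes (ids "0" .. "nNodes-1").
#' @param nEdges number of directed edges, at most `nNodes*(nNodes-1)`.
#' @param seed RNG seed.
#' @return data.frame with columns `source`, `target`.
#' @export
randomNetwork <- function(nNodes, nEdges, seed = NULL) {
  if (nEdges > nNodes * (nNodes - 1))
    stop("too many edges requested", call. = FALSE)
  withSeed(seed, {
    g <- igraph::sample_gnm(nNodes, nEdges, directed = TRUE)
    el <- igraph::as_edgelist(g, names = FALSE)
    data.frame(source = as.character(el[, 1] - 1L),
               target = as.character(el[, 2] - 1L))
  })
}
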