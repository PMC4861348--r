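#' Spike trains for a set of simultaneously recorded neurons
#'
#' Container for per-neuron spike-time vectors over a common recording
#' interval. Spike times are in seconds; each train is sorted ascending and
#' lies within `[tStart, tEnd]`.
#'
#' @slot trains named list of numeric vectors of spike times (seconds).
#' @slot tStart,tEnd recording interval bounds in seconds.
#'
#' @export
setClass("SpikeTrainSet",
  representation(trains = "list", tStart = "numeric", tEnd = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@tStart) != 1L || length(object@tEnd) != 1L ||
        object@tEnd <= object@tStart)
      msg <- c(msg, "tStart/tEnd must define a nonempty interval")
    if (is.null(names(object@trains)) && length(object@trains) > 0L)
      msg <- c(msg, "trains must be named by neuron id")
    for (tr in object@trains) {
      if (!is.numeric(tr)) { msg <- c(msg, "trains must be numeric"); break }
      if (is.unsorted(tr)) { msg <- c(msg, "spike times must be sorted"); break }
      if (length(tr) && (tr[1] < object@tStart - 1e-12 ||
                         tr[length(tr)] > object@tEnd + 1e-12)) {
        msg <- c(msg, "spike times outside [tStart, tEnd]"); break
      }
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a SpikeTrainSet
#'
#' @param trains named list of numeric spike-time vectors (seconds).
#' @param tStart,tEnd recording interval in seconds.
#' @return A [SpikeTrainSet-class] object.
#' @examples
#' sts <- spikeTrainSet(list(a = c(0.1, 0.5), b = 0.3), 0, 1)
#' nNeurons(sts)
#' @export
spikeTrainSet <- function(trains, tStart = 0, tEnd) {
  if (is.null(names(trains)))
    names(trains) <- as.character(seq_along(trains) - 1L)
  trains <- lapply(trains, function(x) sort(as.numeric(x)))
  new("SpikeTrainSet", trains = trains, tStart = as.numeric(tStart),
      tEnd = as.numeric(tEnd))
}

#' Joint probability distribution over binary lagged states
#'
#' Probability mass over tuples of binary variables such as the receiver
#' future state `I_F`, receiver past `I_P`, and source pasts `J_P`, `K_P`,
#' ... Stored as a k-dimensional `2 x 2 x ...` array whose dimnames encode
#' the state labels "0"/"1" and whose dimension names are the variables.
#'
#' @slot varNames ordered character vector of variable names.
#' @slot probs numeric array of dimension `rep(2, k)`, nonnegative, summing
#'   to 1 within 1e-9.
#' @export
setClass("JointDistribution",
  representation(varNames = "character", probs = "array"),
  validity = function(object) {
    k <- length(object@varNames)
    if (!isTRUE(all.equal(dim(object@probs), rep(2L, k),
                          check.attributes = FALSE)))
      return("probs must be a 2^k array matching varNames")
    if (any(object@probs < 0)) return("probabilities must be nonnegative")
    if (abs(sum(object@probs) - 1) > 1e-9)
      return("probabilities must sum to 1 within 1e-9")
    TRUE
  })

#' Construct a JointDistribution
#'
#' @param probs numeric vector of length `2^k` (state order: first variable
#'   fastest, i.e. `array()` order) or a `rep(2, k)` array.
#' @param varNames character vector of the k variable names.
#' @return A [JointDistribution-class].
#' @examples
#' d <- jointDistribution(rep(1/8, 8), c("I_F", "I_P", "J_P"))
#' entropyBits(d, "I_F")
#' @export
jointDistribution <- function(probs, varNames) {
  k <- length(varNames)
  a <- array(as.numeric(probs), dim = rep(2L, k),
             dimnames = setNames(rep(list(c("0", "1")), k), varNames))
  new("JointDistribution", varNames = varNames, probs = a)
}

#' Analysis timescale: bin width plus a set of candidate delays
#'
#' A timescale couples one bin width with the list of delays (in bins) over
#' which directed interactions are scanned; per pair the delay maximizing
#' transfer entropy is retained. The two canonical short timescales cover
#' interaction ranges of 1.6-6.4 ms and 3.5-14 ms, matching reported
#' monosynaptic delays of 1-20 ms.
#'
#' @slot binWidthMs bin width in milliseconds.
#' @slot delaysBins positive integer delays, in bins.
#' @slot label text label.
#' @export
setClass("Timescale",
  representation(binWidthMs = "numeric", delaysBins = "integer",
                 label = "character"),
  validity = function(object) {
    if (object@binWidthMs <= 0) return("binWidthMs must be positive")
    if (!length(object@delaysBins) || any(object@delaysBins < 1L))
      return("delaysBins must be positive integers")
    TRUE
  })

#' @rdname Timescale-class
#' @param binWidthMs bin width (ms).
#' @param delaysBins integer delays in bins (default 1:4).
#' @param label optional label.
#' @return A [Timescale-class].
#' @export
timescale <- function(binWidthMs, delaysBins = 1:4, label = NULL) {
  if (is.null(label))
    label <- sprintf("%g-%g ms", binWidthMs * min(delaysBins),
                     binWidthMs * max(delaysBins))
  new("Timescale", binWidthMs = as.numeric(binWidthMs),
      delaysBins = as.integer(delaysBins), label = label)
}

#' The two canonical short timescales
#'
#' @return list of two [Timescale-class] objects: 1.6 ms bins with delays
#'   1-4 (1.6-6.4 ms) and 3.5 ms bins with delays 1-4 (3.5-14 ms).
#' @export
canonicalTimescales <- function() {
  list(timescale(1.6, 1:4, "1.6-6.4 ms"), timescale(3.5, 1:4, "3.5-14 ms"))
}

#' Directed effective-connectivity network
#'
#' Nodes are neuron ids; edges are directed significant transfer-entropy
#' connections, each carrying the TE weight (raw and entropy-normalized),
#' the argmax delay in bins, and the surrogate p-value.
#'
#' @slot nodes character vector of neuron ids.
#' @slot edges data.frame with columns source, target, teBits, teNormalized,
#'   delayBins, pValue.
#' @slot timescaleLabel label of the timescale the network was built at.
#' @export
setClass("EffectiveNetwork",
  representation(nodes = "character", edges = "data.frame",
                 timescaleLabel = "character"),
  validity = function(object) {
    req <- c("source", "target", "teBits", "teNormalized", "delayBins",
             "pValue")
    if (!all(req %in% names(object@edges)))
      return(paste("edges must have columns:", paste(req, collapse = ", ")))
    if (nrow(object@edges)) {
      if (any(object@edges$source == object@edges$target))
        return("self-edges are not allowed")
      if (!all(c(object@edges$source, object@edges$target) %in% object@nodes))
        return("edge endpoints must be listed nodes")
    }
    TRUE
  })

#' Construct an EffectiveNetwork from an edge table
#'
#' @param edges data.frame with at least source and target columns; missing
#'   numeric columns are filled (teBits 0, pValue 0, ...).
#' @param nodes node ids (defaults to ids appearing in edges).
#' @param timescaleLabel label.
#' @return An [EffectiveNetwork-class].
#' @export
effectiveNetwork <- function(edges, nodes = NULL, timescaleLabel = "") {
  edges <- as.data.frame(edges)
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  for (col in c("teBits", "teNormalized", "delayBins", "pValue")) {
    if (is.null(edges[[col]]))
      edges[[col]] <- if (col == "delayBins") 1L else 0
  }
  if (is.null(nodes)) nodes <- unique(c(edges$source, edges$target))
  new("EffectiveNetwork", nodes = as.character(nodes),
      edges = edges[, c("source", "target", "teBits", "teNormalized",
                        "delayBins", "pValue")],
      timescaleLabel = timescaleLabel)
}

#' Synthetic recording with ground truth
#'
#' @slot spikes the generated [SpikeTrainSet-class].
#' @slot groundTruthEdges data.frame (source, target, delayMs).
#' @slot groundTruthMotifs data.frame (motif, J, K, I, delayMs, binMs).
#' @slot seed integer seed used.
#' @export
setClass("SyntheticRecording",
  representation(spikes = "SpikeTrainSet", groundTruthEdges = "data.frame",
                 groundTruthMotifs = "data.frame", seed = "integer"))

#' Two-layer probabilistic feedforward model state
#'
#' Input and output layers of `nNeurons` binary neurons; binary connections
#' (density 0.2) from input to output; all neurons driven by a network-wide
#' binary signal b with neuron-specific coupling currents; firing
#' probability given total current I is the sigmoid 1/(1+exp(-alpha*I+beta)).
#'
#' @slot nNeurons neurons per layer.
#' @slot iCon current delivered per active connection.
#' @slot alphaGain,betaOffset sigmoid constants.
#' @slot connectivity binary input x output matrix.
#' @slot inputCurrents,outputCurrents nNeurons x 2 matrices of signal
#'   currents for b = 0 and b = 1.
#' @slot scoreParams rewiring score coefficients (a1, a2, a3, a4).
#' @slot rule rewiring rule name.
#' @export
setClass("ModelState",
  representation(nNeurons = "integer", iCon = "numeric",
                 alphaGain = "numeric", betaOffset = "numeric",
                 connectivity = "matrix", inputCurrents = "matrix",
                 outputCurrents = "matrix", scoreParams = "numeric",
                 rule = "character"),
  validity = function(object) {
    n <- object@nNeurons
    if (!all(dim(object@connectivity) == c(n, n)))
      return("connectivity must be nNeurons x nNeurons")
    if (!all(object@connectivity %in% c(0, 1)))
      return("connectivity must be binary")
    if (length(object@scoreParams) != 4L)
      return("scoreParams must have length 4")
    TRUE
  })
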