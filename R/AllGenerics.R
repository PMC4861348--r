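#' Number of neurons
#' @param x a SpikeTrainSet or EffectiveNetwork.
#' @return integer count.
#' @export
setGeneric("nNeurons", function(x) standardGeneric("nNeurons"))

#' @rdname nNeurons
#' @export
setMethod("nNeurons", "SpikeTrainSet", function(x) length(x@trains))

#' @rdname nNeurons
#' @export
setMethod("nNeurons", "EffectiveNetwork", function(x) length(x@nodes))

#' Spike times of one neuron
#' @param x a SpikeTrainSet.
#' @param id neuron id (name) or index.
#' @return numeric vector of spike times (seconds).
#' @export
spikeTimes <- function(x, id) {
  stopifnot(is(x, "SpikeTrainSet"))
  tr <- if (is.character(id)) x@trains[[id]] else x@trains[[id]]
  if (is.null(tr)) stop("unknown neuron id: ", id, call. = FALSE)
  tr
}

#' Neuron ids
#' @param x a SpikeTrainSet or EffectiveNetwork.
#' @return character vector.
#' @export
setGeneric("neuronIds", function(x) standardGeneric("neuronIds"))

#' @rdname neuronIds
#' @export
setMethod("neuronIds", "SpikeTrainSet", function(x) names(x@trains))

#' @rdname neuronIds
#' @export
setMethod("neuronIds", "EffectiveNetwork", function(x) x@nodes)

#' Recording duration in seconds
#' @param x a SpikeTrainSet.
#' @return numeric duration.
#' @export
recordingDuration <- function(x) x@tEnd - x@tStart

#' Per-neuron firing rates (Hz)
#' @param x a SpikeTrainSet.
#' @return named numeric vector.
#' @export
firingRates <- function(x)
  vapply(x@trains, length, 0L) / recordingDuration(x)

#' Edge table of an effective network
#' @param x an EffectiveNetwork.
#' @return data.frame of edges.
#' @export
edgeTable <- function(x) x@edges

#' Variable names of a joint distribution
#' @param x a JointDistribution.
#' @return character vector.
#' @export
variableNames <- function(x) x@varNames

#' Probability masses of a joint distribution
#' @param x a JointDistribution.
#' @return numeric array.
#' @export
probMass <- function(x) x@probs

setMethod("show", "SpikeTrainSet", function(object) {
  cat("SpikeTrainSet:", length(object@trains), "neurons over [",
      object@tStart, ",", object@tEnd, "] s;",
      sprintf("mean rate %.3g Hz\n", mean(firingRates(object))))
})

setMethod("show", "JointDistribution", function(object) {
  cat("JointDistribution over (", paste(object@varNames, collapse = ", "),
      "); ", length(object@probs), " states\n", sep = "")
})

setMethod("show", "EffectiveNetwork", function(object) {
  cat("EffectiveNetwork [", object@timescaleLabel, "]: ",
      length(object@nodes), " nodes, ", nrow(object@edges),
      " significant edges\n", sep = "")
})

setMethod("show", "ModelState", function(object) {
  cat("ModelState: 2 x", object@nNeurons, "neurons,",
      sum(object@connectivity), "connections, rule =", object@rule, "\n")
})
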