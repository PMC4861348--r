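## Plain-text interchange formats: two-column spike files, ground-truth and
## edge-list CSVs.

#' Write spike trains as two-column delimited text
#'
#' Format: a header comment line `# t_start=<s> t_end=<s> seed=<int>`, then
#' one `neuron_id<TAB>time_seconds` row per spike, sorted by time.
#'
#' @param spikes a [SpikeTrainSet-class].
#' @param path output file path.
#' @param seed optional seed to record in the header.
#' @return `path`, invisibly.
#' @export
writeSpikeTrains <- function(spikes, path, seed = NA) {
  ids <- rep(neuronIds(spikes), vapply(spikes@trains, length, 0L))
  tt <- unlist(spikes@trains, use.names = FALSE)
  o <- order(tt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# t_start=%.9g t_end=%.9g seed=%s",
                     spikes@tStart, spikes@tEnd, seed), con)
  if (length(tt))
    writeLines(sprintf("%s\t%.9f", ids[o], tt[o]), con)
  invisible(path)
}

#' Read spike trains written by [writeSpikeTrains()]
#'
#' @param path input file path.
#' @return A [SpikeTrainSet-class].
#' @export
readSpikeTrains <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "#"))
    stop("missing spike-file header line", call. = FALSE)
  kv <- regmatches(hdr, gregexpr("[a-z_]+=[-0-9.eNA]+", hdr))[[1]]
  vals <- setNames(sub(".*=", "", kv), sub("=.*", "", kv))
  tab <- read.table(path, sep = "\t", skip = 1L,
                    col.names = c("id", "time"),
                    colClasses = c("character", "numeric"))
  ids <- unique(tab$id)
  trains <- lapply(ids, function(i) sort(tab$time[tab$id == i]))
  names(trains) <- ids
  spikeTrainSet(trains, as.numeric(vals[["t_start"]]),
                as.numeric(vals[["t_end"]]))
}

#' Write the ground truth of a synthetic recording
#'
#' Two CSVs: `<prefix>_edges.csv` (source, target, delayMs) and
#' `<prefix>_motifs.csv` (motif, J, K, I, delayMs, binMs).
#'
#' @param recording a [SyntheticRecording-class].
#' @param prefix output path prefix.
#' @return character vector of the two paths, invisibly.
#' @export
writeGroundTruth <- function(recording, prefix) {
  pe <- paste0(prefix, "_edges.csv")
  pm <- paste0(prefix, "_motifs.csv")
  write.csv(recording@groundTruthEdges, pe, row.names = FALSE)
  write.csv(recording@groundTruthMotifs, pm, row.names = FALSE)
  invisible(c(pe, pm))
}

#' Write an effective network as an edge-list CSV
#'
#' @param network an [EffectiveNetwork-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(network, path) {
  write.csv(edgeTable(network), path, row.names = FALSE)
  invisible(path)
}

#' @importFrom utils read.csv write.csv
NULL
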