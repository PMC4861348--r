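## Partial information decomposition (Imin redundancy) of multivariate
## transfer entropy, interaction information, and the information-gain bound
## on higher-order synergy.

#' Specific information a source set carries about one receiver outcome
#'
#' For the receiver future outcome `I_F = iF`, returns
#' `sum_{r, iP} p(r, iP | iF) log2[ p(r, iP, iF) / (p(r, iP) p(iF)) ]`,
#' the Kullback-Leibler divergence between the conditional and marginal
#' distributions of `(R, I_P)`. With `rVars = character(0)` this is the
#' specific information carried by the receiver past alone.
#'
#' @param dist a [JointDistribution-class] containing `I_F`, `I_P`, and
#'   source variables.
#' @param iFValue 0 or 1; must have positive marginal mass.
#' @param rVars character names of the source variables in the set R (the
#'   receiver past `I_P` is always included alongside R).
#' @return specific information in bits.
#' @export
specificInformation <- function(dist, iFValue, rVars = character(0)) {
  aVars <- c(rVars, "I_P")
  joint <- marginalDistribution(dist, c("I_F", aVars))@probs
  pF <- apply(joint, 1L, sum)[iFValue + 1L]
  if (pF <= 0) stop("I_F value has zero marginal mass", call. = FALSE)
  k <- length(aVars)
  slice <- do.call(`[`, c(list(joint, iFValue + 1L), rep(list(TRUE), k)))
  pA <- apply(joint, seq_len(k) + 1L, sum)
  condA <- as.numeric(slice) / pF
  pos <- condA > 0
  sum(condA[pos] * (log2(condA[pos]) - log2safe(as.numeric(pA)[pos])))
}

#' Imin redundancy of two sources about the receiver future
#'
#' `sum_iF p(iF) min_{R in {J_P, K_P}} [Ispec(iF; R, I_P) - Ispec(iF; I_P)]`:
#' the expectation over receiver outcomes of the smaller source-specific
#' information, conditioned on the receiver past. Nonnegative and bounded by
#' `min(TE(J->I), TE(K->I))`.
#'
#' @param dist a [JointDistribution-class] over `I_F`, `I_P`, `J_P`, `K_P`.
#' @return redundancy in bits.
#' @export
iminRedundancy <- function(dist) {
  pF <- as.numeric(marginalDistribution(dist, "I_F")@probs)
  total <- 0
  for (iF in 0:1) {
    if (pF[iF + 1L] <= 0) next
    base <- specificInformation(dist, iF, character(0))
    contrib <- min(specificInformation(dist, iF, "J_P") - base,
                   specificInformation(dist, iF, "K_P") - base)
    total <- total + pF[iF + 1L] * contrib
  }
  max(total, 0)
}

#' Partial information decomposition of two-source transfer entropy
#'
#' Decomposes `TE({J,K} -> I)` into synergy + unique_J + unique_K +
#' redundancy, with redundancy given by [iminRedundancy()], the unique terms
#' by subtracting redundancy from the bivariate TEs, and synergy by
#' subtracting all three from the joint TE. Each term is also normalized by
#' the entropy of the receiver future state `H(I_F)` (0 when `H(I_F) = 0`).
#' The synergy term quantifies information available only from simultaneous
#' knowledge of both sources and is interpreted as computation performed by
#' the receiver.
#'
#' @param dist a [JointDistribution-class] over `I_F`, `I_P`, `J_P`, `K_P`.
#' @return list with elements `teJoint`, `teJ`, `teK`, `redundancy`,
#'   `uniqueJ`, `uniqueK`, `synergy`, the same seven entropy-normalized under
#'   `normalized`, and `hIF`.
#' @examples
#' pidDecompose(motifDistribution("synergistic"))$synergy  # 1 bit
#' @export
pidDecompose <- function(dist) {
  teJ <- conditionalMutualInformation(dist, "I_F", "J_P", "I_P")
  teK <- conditionalMutualInformation(dist, "I_F", "K_P", "I_P")
  teJoint <- conditionalMutualInformation(dist, "I_F", c("J_P", "K_P"), "I_P")
  red <- iminRedundancy(dist)
  uniqueJ <- clampDust(teJ - red)
  uniqueK <- clampDust(teK - red)
  synergy <- clampDust(teJoint - red - uniqueJ - uniqueK)
  raw <- list(teJoint = teJoint, teJ = teJ, teK = teK, redundancy = red,
              uniqueJ = uniqueJ, uniqueK = uniqueK, synergy = synergy)
  hF <- entropyBits(dist, "I_F")
  norm <- lapply(raw, function(v)
    if (hF > 0) min(max(v / hF, 0), 1) else 0)
  c(raw, list(normalized = norm, hIF = hF))
}

#' Interaction information of two sources and the receiver future
#'
#' `II(J_P; K_P; I_F) = MI(J_P; K_P | I_F) - MI(J_P; K_P)`. Positive values
#' indicate synergy-dominated interactions, negative values
#' redundancy-dominated ones; unlike the partial information decomposition
#' the two cannot be separated, so simultaneous synergy and redundancy
#' cancel.
#'
#' @param dist a [JointDistribution-class] containing `I_F`, `J_P`, `K_P`.
#' @return interaction information in bits (may be negative).
#' @export
interactionInformation <- function(dist) {
  conditionalMutualInformation(dist, "J_P", "K_P", "I_F") -
    mutualInformation(dist, "J_P", "K_P")
}

#' Information gained by the n-th input: a bound on highest-order synergy
#'
#' For each sampled set of `n` source variables, the gain is the joint TE of
#' all `n` sources minus the mean over the `n` leave-one-out joint TEs (the
#' `n` ways of excluding one input); by monotonicity of conditional mutual
#' information each gain is nonnegative and upper-bounds the order-n synergy.
#' Gains are averaged over at most `maxCombinations` sampled input sets.
#'
#' @param observations 0/1 matrix with columns `I_F`, `I_P` and at least `n`
#'   source columns.
#' @param n number of inputs (2 to 6).
#' @param maxCombinations cap on sampled input sets (default 100).
#' @param seed RNG seed for combination sampling.
#' @return list with `meanGainBits`, `nInputs`, `nCombinationsSampled`.
#' @export
informationGain <- function(observations, n, maxCombinations = 100,
                            seed = NULL) {
  observations <- as.matrix(observations)
  srcVars <- setdiff(colnames(observations), c("I_F", "I_P"))
  if (n < 2 || n > 6) stop("n must be in [2, 6]", call. = FALSE)
  if (length(srcVars) < n)
    stop("fewer than n source columns", call. = FALSE)
  combs <- combn(srcVars, n, simplify = FALSE)
  if (length(combs) > maxCombinations)
    combs <- withSeed(seed, sample(combs, maxCombinations))
  gains <- vapply(combs, function(vars) {
    d <- estimateDistribution(observations[, c("I_F", "I_P", vars),
                                           drop = FALSE])
    full <- jointTransferEntropy(d, vars)
    loo <- vapply(seq_along(vars), function(i)
      jointTransferEntropy(d, vars[-i]), 0)
    full - mean(loo)
  }, 0)
  list(meanGainBits = clampDust(mean(gains)), nInputs = as.integer(n),
       nCombinationsSampled = length(combs))
}

#' Information-gain profile of one receiver in an effective network
#'
#' Convenience pipeline: for a receiver with at least `n` significant inputs
#' in `network`, builds the lagged joint observations of up to
#' `maxCombinations` sampled size-n input sets (each source at its own
#' stored edge delay) and returns the mean information gain.
#'
#' @param spikes a [SpikeTrainSet-class].
#' @param network an [EffectiveNetwork-class] whose edges carry delays.
#' @param receiver receiver neuron id.
#' @param n number of inputs (2 to 6).
#' @param binWidthMs bin width of the analysis timescale.
#' @param maxCombinations,seed see [informationGain()].
#' @return list as for [informationGain()].
#' @export
receiverInformationGain <- function(spikes, network, receiver, n,
                                    binWidthMs, maxCombinations = 100,
                                    seed = NULL) {
  ed <- edgeTable(network)
  inc <- ed[ed$target == as.character(receiver), , drop = FALSE]
  if (nrow(inc) < n) stop("receiver has fewer than n inputs", call. = FALSE)
  sets <- combn(seq_len(nrow(inc)), n, simplify = FALSE)
  if (length(sets) > maxCombinations)
    sets <- withSeed(seed, sample(sets, maxCombinations))
  gains <- vapply(sets, function(idx) {
    d <- laggedJointDistribution(spikes, receiver, inc$source[idx],
                                 binWidthMs, inc$delayBins[idx])
    vars <- sourceVarNames(n)
    full <- jointTransferEntropy(d, vars)
    loo <- vapply(seq_len(n), function(i)
      jointTransferEntropy(d, vars[-i]), 0)
    full - mean(loo)
  }, 0)
  list(meanGainBits = clampDust(mean(gains)), nInputs = as.integer(n),
       nCombinationsSampled = length(sets))
}
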