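## Two-layer probabilistic binary feedforward model with score-based
## rewiring (random, Hebbian, degree-modified, firing-rate-modified),
## network-wide binary drive, and MI / PID analyses of the rewired models.

#' Solve the sigmoid constants from the two firing-probability conditions
#'
#' The firing probability given total current I is
#' `p(I) = 1 / (1 + exp(-alpha*I + beta))`. The constants are fixed by
#' `p(0) = pZero` (neurons with no current rarely fire) and
#' `p(iCon * nNeurons) = pFull` (a maximally connected output neuron with
#' all inputs active sits at the sigmoid midpoint). Closed form:
#' `beta = log((1-pZero)/pZero)`,
#' `alpha = (beta + log(pFull/(1-pFull))) / (iCon*nNeurons)`.
#'
#' @param nNeurons neurons per layer (default 20).
#' @param iCon current per active connection (default 10).
#' @param pZero firing probability at zero current (default 0.01).
#' @param pFull firing probability at full current (default 0.5).
#' @return list with `alphaGain`, `betaOffset`, `nNeurons`, `iCon`.
#' @examples
#' solveSigmoidConstants(20, 10)  # alpha ~ 0.023, beta ~ 4.6
#' @export
solveSigmoidConstants <- function(nNeurons = 20, iCon = 10, pZero = 0.01,
                                  pFull = 0.5) {
  if (!(pZero > 0 && pZero < pFull && pFull < 1))
    stop("need 0 < pZero < pFull < 1", call. = FALSE)
  beta <- log((1 - pZero) / pZero)
  alpha <- (beta + log(pFull / (1 - pFull))) / (iCon * nNeurons)
  list(alphaGain = alpha, betaOffset = beta, nNeurons = as.integer(nNeurons),
       iCon = iCon)
}

#' Sigmoid firing probability
#' @param current total input current.
#' @param alphaGain,betaOffset sigmoid constants.
#' @return firing probability in (0, 1).
#' @export
sigmoidProb <- function(current, alphaGain, betaOffset)
  1 / (1 + exp(-alphaGain * current + betaOffset))

## invert the sigmoid: current that produces firing probability p
.currentForProb <- function(p, alphaGain, betaOffset)
  (betaOffset + log(p / (1 - p))) / alphaGain

#' Binary-signal coupling currents of one neuron
#'
#' In the absence of connectivity, the i-th input-layer neuron fires with
#' probability `0.5 -/+ 0.4*(i-1)/(N-1)` for signal b = 0 / b = 1, and the
#' o-th output-layer neuron with `0.5 -/+ 0.2*(o-1)/(N-1)`; low-index
#' neurons are uncorrelated with the signal, high-index neurons strongly
#' correlated (the output-layer coupling is weaker to leave room for
#' connectivity). The returned currents realize these probabilities through
#' the sigmoid.
#'
#' @param layer "input" or "output".
#' @param neuronIndex 1-based neuron index.
#' @param nNeurons neurons per layer.
#' @param sigmoid list from [solveSigmoidConstants()].
#' @return numeric `c(b0 = , b1 = )` currents.
#' @export
signalCurrents <- function(layer = c("input", "output"), neuronIndex,
                           nNeurons, sigmoid) {
  layer <- match.arg(layer)
  stopifnot(neuronIndex >= 1, neuronIndex <= nNeurons)
  span <- if (layer == "input") 0.4 else 0.2
  frac <- (neuronIndex - 1) / (nNeurons - 1)
  p0 <- 0.5 - span * frac
  p1 <- 0.5 + span * frac
  c(b0 = .currentForProb(p0, sigmoid$alphaGain, sigmoid$betaOffset),
    b1 = .currentForProb(p1, sigmoid$alphaGain, sigmoid$betaOffset))
}

#' Initialize a feedforward model with random connectivity
#'
#' Inserts `round(connectionDensity * nNeurons^2)` binary connections
#' uniformly at random from input to output layer (at most one per pair).
#'
#' @param nNeurons neurons per layer (default 20).
#' @param iCon current per connection (default 10).
#' @param connectionDensity fraction of possible connections (default 0.2,
#'   i.e. 80 connections at 20 neurons).
#' @param rule rewiring rule label to store ("random", "hebbian", "degree",
#'   "firing_rate").
#' @param scoreParams optional (a1, a2, a3, a4); defaults to
#'   [fittedScoreParams()] for the rule.
#' @param seed RNG seed.
#' @return A [ModelState-class].
#' @export
newModelState <- function(nNeurons = 20, iCon = 10, connectionDensity = 0.2,
                          rule = "random", scoreParams = NULL, seed = NULL) {
  sig <- solveSigmoidConstants(nNeurons, iCon)
  nConn <- round(connectionDensity * nNeurons^2)
  conn <- matrix(0, nNeurons, nNeurons)
  picks <- withSeed(seed, sample.int(nNeurons^2, nConn))
  conn[picks] <- 1
  ic <- t(vapply(seq_len(nNeurons), function(i)
    signalCurrents("input", i, nNeurons, sig), c(b0 = 0, b1 = 0)))
  oc <- t(vapply(seq_len(nNeurons), function(o)
    signalCurrents("output", o, nNeurons, sig), c(b0 = 0, b1 = 0)))
  if (is.null(scoreParams)) scoreParams <- fittedScoreParams(rule, nNeurons)
  new("ModelState", nNeurons = as.integer(nNeurons), iCon = iCon,
      alphaGain = sig$alphaGain, betaOffset = sig$betaOffset,
      connectivity = conn, inputCurrents = ic, outputCurrents = oc,
      scoreParams = as.numeric(scoreParams), rule = rule)
}

#' Fitted rewiring-score coefficients
#'
#' The (a1, a2, a3, a4) coefficients of the rewiring score
#' `S(i,o) = A(i,o) + a1*DegIn(o) + a2*DegOut(i) + a3*FR(o) + a4*FR(i)`
#' obtained by lattice-search fitting: degree-modified rule
#' `(0.05, -1.75, 0, 0)` at 20 neurons per layer and `(0.16, -0.3, 0, 0)`
#' at 40; firing-rate rule `(0, 0, 0.35, 3.1)` at both sizes; the pure
#' Hebbian rule is all zeros (score = agreement only).
#'
#' @param rule "random", "hebbian", "degree", or "firing_rate".
#' @param nNeurons neurons per layer (20 or 40 select the fitted values;
#'   other sizes fall back to the 20-neuron values).
#' @return numeric length-4 vector.
#' @export
fittedScoreParams <- function(rule = c("random", "hebbian", "degree",
                                       "firing_rate"), nNeurons = 20) {
  rule <- match.arg(rule)
  switch(rule,
         random = , hebbian = c(0, 0, 0, 0),
         degree = if (nNeurons == 40) c(0.16, -0.3, 0, 0)
                  else c(0.05, -1.75, 0, 0),
         firing_rate = c(0, 0, 0.35, 3.1))
}

#' Run the feedforward network
#'
#' Each run is independent: a fair binary signal value b is drawn; input
#' neurons fire Bernoulli with the sigmoid of their signal current; each
#' output neuron receives `iCon` units of current per active incoming
#' connection plus its own signal current and fires Bernoulli with the
#' sigmoid of the total.
#'
#' @param state a [ModelState-class].
#' @param nRuns number of independent runs.
#' @param seed RNG seed.
#' @return list with `b` (length nRuns), `inputStates`, `outputStates`
#'   (nNeurons x nRuns binary matrices).
#' @export
runNetwork <- function(state, nRuns, seed = NULL) {
  n <- state@nNeurons
  withSeed(seed, {
    b <- sample(0:1, nRuns, replace = TRUE)
    inCur <- state@inputCurrents[, b + 1L, drop = FALSE] # n x nRuns
    pIn <- sigmoidProb(inCur, state@alphaGain, state@betaOffset)
    x <- matrix((runif(n * nRuns) < pIn) + 0L, n, nRuns)
    outCur <- state@iCon * crossprod(state@connectivity, x) +
      state@outputCurrents[, b + 1L, drop = FALSE]
    pOut <- sigmoidProb(outCur, state@alphaGain, state@betaOffset)
    y <- matrix((runif(n * nRuns) < pOut) + 0L, n, nRuns)
    list(b = b, inputStates = x, outputStates = y)
  })
}

#' Agreement matrix between input and output neurons
#'
#' `A(i, o)` is the proportion of runs in which input neuron i and output
#' neuron o were in identical binary states; the Hebbian term of the
#' rewiring score.
#'
#' @param runLog output of [runNetwork()].
#' @return nNeurons x nNeurons numeric matrix in `[0, 1]`.
#' @export
agreementMatrix <- function(runLog) {
  x <- runLog$inputStates
  y <- runLog$outputStates
  r <- ncol(x)
  (x %*% t(y) + (1 - x) %*% t(1 - y)) / r
}

#' Rewiring score matrix
#'
#' `S(i,o) = A(i,o) + a1*DegIn(o) + a2*DegOut(i) + a3*FR(o) + a4*FR(i)`,
#' with degrees taken from the current connectivity and firing rates from
#' the current statistics pass.
#'
#' @param state a [ModelState-class].
#' @param agreement agreement matrix from [agreementMatrix()].
#' @param runLog the statistics-pass run log (for firing rates).
#' @return nNeurons x nNeurons score matrix.
#' @export
rewiringScore <- function(state, agreement, runLog) {
  a <- state@scoreParams
  degIn <- colSums(state@connectivity)
  degOut <- rowSums(state@connectivity)
  frIn <- rowMeans(runLog$inputStates)
  frOut <- rowMeans(runLog$outputStates)
  agreement +
    matrix(a[1] * degIn, state@nNeurons, state@nNeurons, byrow = TRUE) +
    a[2] * degOut +
    matrix(a[3] * frOut, state@nNeurons, state@nNeurons, byrow = TRUE) +
    a[4] * frIn
}

#' Rewire the model with its score rule
#'
#' Performs `nSteps` rewiring iterations (default: one per connection, 80
#' at 20 neurons). Each iteration runs the network `nStatsRuns` times to
#' gather statistics, computes the score for every input/output pair,
#' disconnects the connected pair with the lowest score, and connects the
#' unconnected pair with the highest score (score ties broken uniformly at
#' random). The connection count is invariant. With rule "random" no
#' rewiring is performed.
#'
#' @param state a [ModelState-class].
#' @param nStatsRuns runs per statistics pass (paper scale 500).
#' @param nSteps rewiring iterations (default: number of connections).
#' @param seed RNG seed.
#' @return list with `state` (rewired [ModelState-class]) and
#'   `connectionCounts` (count after every step).
#' @export
rewireModel <- function(state, nStatsRuns = 500, nSteps = NULL,
                        seed = NULL) {
  nConn <- sum(state@connectivity)
  if (is.null(nSteps)) nSteps <- nConn
  if (state@rule == "random")
    return(list(state = state, connectionCounts = rep(nConn, nSteps)))
  withSeed(seed, {
    counts <- integer(nSteps)
    for (s in seq_len(nSteps)) {
      rl <- runNetwork(state, nStatsRuns)
      sc <- rewiringScore(state, agreementMatrix(rl), rl)
      conn <- which(state@connectivity == 1)
      unconn <- which(state@connectivity == 0)
      worst <- conn[.whichExtreme(sc[conn], min)]
      best <- unconn[.whichExtreme(sc[unconn], max)]
      state@connectivity[worst] <- 0
      state@connectivity[best] <- 1
      counts[s] <- sum(state@connectivity)
    }
    list(state = state, connectionCounts = counts)
  })
}

## index of the extreme value, ties broken uniformly at random
.whichExtreme <- function(x, fn) {
  idx <- which(x == fn(x))
  if (length(idx) == 1L) idx else idx[sample.int(length(idx), 1L)]
}

#' Average mutual information between connected pairs of a model
#'
#' Runs the network and returns the average over connected (input, output)
#' pairs of the empirical mutual information between their binary states,
#' both unconditioned and conditioned on the binary signal b. Unconditioned
#' MI largely reflects the network-wide signal; the conditioned MI measures
#' neuron-to-neuron communication once the common drive is removed.
#'
#' @param state a (possibly rewired) [ModelState-class].
#' @param nRuns evaluation runs (default 2000).
#' @param seed RNG seed.
#' @return list with `mi` and `cmi` (bits, averaged over connections).
#' @export
connectionMI <- function(state, nRuns = 2000, seed = NULL) {
  rl <- runNetwork(state, nRuns, seed)
  conn <- state@connectivity == 1
  mi <- .pairwiseBinaryMI(rl$inputStates, rl$outputStates)
  cmi <- matrix(0, state@nNeurons, state@nNeurons)
  for (bv in 0:1) {
    sel <- rl$b == bv
    w <- mean(sel)
    if (w > 0)
      cmi <- cmi + w * .pairwiseBinaryMI(rl$inputStates[, sel, drop = FALSE],
                                         rl$outputStates[, sel,
                                                         drop = FALSE])
  }
  list(mi = mean(mi[conn]), cmi = mean(cmi[conn]))
}

## MI(X_i; Y_o) for all (i, o) pairs of two binary state matrices (rows =
## neurons, columns = runs), in bits.
.pairwiseBinaryMI <- function(x, y) {
  r <- ncol(x)
  p11 <- (x %*% t(y)) / r
  pX <- rowMeans(x)
  pY <- rowMeans(y)
  p10 <- pX - p11
  p01 <- matrix(pY, nrow(x), nrow(y), byrow = TRUE) - p11
  p00 <- 1 - p11 - p10 - p01
  term <- function(pab, pa, pb) {
    out <- pab * (log2safe(pab) - log2safe(pa * pb))
    out[pab <= 0] <- 0
    out
  }
  mX1 <- matrix(pX, nrow(x), nrow(y))
  mY1 <- matrix(pY, nrow(x), nrow(y), byrow = TRUE)
  pmax(term(p11, mX1, mY1) + term(p10, mX1, 1 - mY1) +
         term(p01, 1 - mX1, mY1) + term(p00, 1 - mX1, 1 - mY1), 0)
}

#' Degree-versus-synergy correlations inside a model
#'
#' Enumerates structural triads (two inputs connected to the same output),
#' estimates each triad's PID from run samples — the receiver past state is
#' the output's state on the previous run, which is independent across runs
#' by construction — and correlates normalized synergy with output
#' in-degree ("in" mode) and input out-degree ("out" mode, two points per
#' triad), exactly as in the recording analysis.
#'
#' @param state a (rewired) [ModelState-class].
#' @param nRuns evaluation runs (default 2000).
#' @param method correlation coefficient.
#' @param seed RNG seed.
#' @return list with `inCorrelation`, `outCorrelation`, `triads`
#'   (data.frame compatible with [degreeSynergyCorrelation()]).
#' @export
modelSynergyDegreeAnalysis <- function(state, nRuns = 2000,
                                       method = "pearson", seed = NULL) {
  rl <- runNetwork(state, nRuns, seed)
  degIn <- colSums(state@connectivity)
  degOut <- rowSums(state@connectivity)
  triads <- NULL
  rows <- list()
  for (o in which(degIn >= 2)) {
    ins <- which(state@connectivity[, o] == 1)
    pr <- combn(ins, 2)
    for (c0 in seq_len(ncol(pr))) {
      j <- pr[1, c0]; k <- pr[2, c0]
      obs <- cbind(I_F = rl$outputStates[o, -1],
                   I_P = rl$outputStates[o, -nRuns],
                   J_P = rl$inputStates[j, -1],
                   K_P = rl$inputStates[k, -1])
      p <- pidDecompose(estimateDistribution(obs))
      rows[[length(rows) + 1L]] <-
        data.frame(receiver = o, J = j, K = k,
                   synergyNormalized = p$normalized$synergy,
                   receiverInDegree = degIn[o],
                   JOutDegree = degOut[j], KOutDegree = degOut[k])
    }
  }
  if (length(rows) < 3) stop("fewer than 3 triads in model", call. = FALSE)
  triads <- do.call(rbind, rows)
  inC <- degreeSynergyCorrelation(triads, "in", method)
  outC <- degreeSynergyCorrelation(triads, "out", method)
  list(inCorrelation = inC$correlation, outCorrelation = outC$correlation,
       triads = triads)
}

#' Build and analyze an ensemble of rewired models for one rule
#'
#' Produces `nInstances` independently seeded models, rewires each with the
#' rule, and evaluates connected-pair MI (raw and signal-conditioned) and
#' the degree-versus-synergy correlations.
#'
#' @param rule "random", "hebbian", "degree", or "firing_rate".
#' @param nInstances models per rule (paper scale 100).
#' @param nNeurons neurons per layer.
#' @param nStatsRuns runs per rewiring statistics pass (paper scale 500).
#' @param nEvalRuns evaluation runs for MI/PID (default 2000).
#' @param scoreParams optional override of [fittedScoreParams()].
#' @param seed base RNG seed; instance k uses `seed + k`.
#' @return data.frame with one row per instance: mi, cmi, inCorrelation,
#'   outCorrelation.
#' @export
modelEnsemble <- function(rule, nInstances = 100, nNeurons = 20,
                          nStatsRuns = 500, nEvalRuns = 2000,
                          scoreParams = NULL, seed = 0) {
  res <- lapply(seq_len(nInstances), function(k) {
    s <- seed + k
    st <- newModelState(nNeurons = nNeurons, rule = rule,
                        scoreParams = scoreParams, seed = s)
    rw <- rewireModel(st, nStatsRuns = nStatsRuns, seed = s + 10000L)
    mi <- connectionMI(rw$state, nEvalRuns, seed = s + 20000L)
    sd <- modelSynergyDegreeAnalysis(rw$state, nEvalRuns,
                                     seed = s + 30000L)
    data.frame(instance = k, mi = mi$mi, cmi = mi$cmi,
               inCorrelation = sd$inCorrelation,
               outCorrelation = sd$outCorrelation)
  })
  do.call(rbind, res)
}

#' Compare connected-pair MI distributions across model ensembles
#'
#' Pairwise Mann-Whitney rank-sum tests between rules on a per-instance
#' statistic, with Benjamini-Hochberg false-discovery-rate adjustment.
#'
#' @param values named list: rule -> numeric vector of per-instance values
#'   (e.g. the `mi` or `cmi` column of [modelEnsemble()] results).
#' @return data.frame with ruleA, ruleB, pValue, pAdjusted.
#' @export
connectionMIAnalysis <- function(values) {
  rules <- names(values)
  prs <- combn(rules, 2, simplify = FALSE)
  p <- vapply(prs, function(pr)
    wilcox.test(values[[pr[1]]], values[[pr[2]]], exact = FALSE)$p.value, 0)
  data.frame(ruleA = vapply(prs, `[`, "", 1),
             ruleB = vapply(prs, `[`, "", 2),
             pValue = p, pAdjusted = p.adjust(p, "BH"))
}
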