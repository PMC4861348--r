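## Degree-versus-computation analysis: triad enumeration, PID synergy per
## triad, correlations with receiver in-degree and transmitter out-degree,
## shuffle nulls, skew tests, degree profiles, and the information-gain
## decay fit.

#' Enumerate all two-input triads of an effective network
#'
#' For every receiver with in-degree d >= 2, all `choose(d, 2)` unordered
#' pairs of its sources, annotated with the receiver in-degree and both
#' source out-degrees.
#'
#' @param network an [EffectiveNetwork-class].
#' @return data.frame with receiver, J, K, delayJ, delayK,
#'   receiverInDegree, JOutDegree, KOutDegree.
#' @export
enumerateTriads <- function(network) {
  ed <- edgeTable(network)
  deg <- degreeSummary(network)
  outD <- setNames(deg$outDegree, deg$node)
  inD <- setNames(deg$inDegree, deg$node)
  res <- lapply(split(ed, ed$target), function(sub) {
    if (nrow(sub) < 2L) return(NULL)
    pr <- combn(seq_len(nrow(sub)), 2)
    data.frame(receiver = sub$target[1],
               J = sub$source[pr[1, ]], K = sub$source[pr[2, ]],
               delayJ = sub$delayBins[pr[1, ]],
               delayK = sub$delayBins[pr[2, ]])
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    res <- data.frame(receiver = character(), J = character(),
                      K = character(), delayJ = integer(),
                      delayK = integer())
  res$receiverInDegree <- as.integer(inD[res$receiver])
  res$JOutDegree <- as.integer(outD[res$J])
  res$KOutDegree <- as.integer(outD[res$K])
  rownames(res) <- NULL
  res
}

#' PID synergy (computation) for every triad of a network
#'
#' For each triad the joint lagged distribution of
#' `(I_F, I_P, J_P, K_P)` is estimated with each source at its own stored
#' edge delay (the delays and binning are identical to the bivariate TE
#' stage), then decomposed with [pidDecompose()].
#'
#' @param spikes a [SpikeTrainSet-class].
#' @param network an [EffectiveNetwork-class] whose edges carry delays.
#' @param binWidthMs analysis bin width in ms.
#' @param triads optional precomputed [enumerateTriads()] table.
#' @return the triad table with columns `synergy`, `synergyNormalized`,
#'   `redundancy`, `uniqueJ`, `uniqueK` (raw bits; synergy also normalized).
#' @export
triadSynergies <- function(spikes, network, binWidthMs, triads = NULL) {
  if (is.null(triads)) triads <- enumerateTriads(network)
  if (!nrow(triads)) {
    triads$synergy <- numeric(0)
    triads$synergyNormalized <- numeric(0)
    triads$redundancy <- numeric(0)
    triads$uniqueJ <- numeric(0)
    triads$uniqueK <- numeric(0)
    return(triads)
  }
  res <- lapply(seq_len(nrow(triads)), function(r) {
    d <- laggedJointDistribution(spikes, triads$receiver[r],
                                 c(triads$J[r], triads$K[r]), binWidthMs,
                                 c(triads$delayJ[r], triads$delayK[r]))
    p <- pidDecompose(d)
    c(synergy = p$synergy, synergyNormalized = p$normalized$synergy,
      redundancy = p$redundancy, uniqueJ = p$uniqueJ, uniqueK = p$uniqueK)
  })
  cbind(triads, do.call(rbind, res))
}

#' Correlation between triad synergy and neuron degree
#'
#' Mode "in": one point per triad, (synergy, receiver in-degree). Mode
#' "out": two points per triad, (synergy, J out-degree) and (synergy, K
#' out-degree) — each transmitter is a distinct data point.
#'
#' @param triads triad table with a `synergyNormalized` column (e.g. from
#'   [triadSynergies()]).
#' @param mode "in" or "out".
#' @param method correlation coefficient: "pearson" (default) or
#'   "spearman".
#' @return list with `correlation` (NA with `degenerate = TRUE` when either
#'   coordinate has zero variance), `nPoints`, `degenerate`.
#' @export
degreeSynergyCorrelation <- function(triads, mode = c("in", "out"),
                                     method = c("pearson", "spearman")) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  pts <- .degreeSynergyPoints(triads, mode)
  if (nrow(pts) < 3) stop("need at least 3 data points", call. = FALSE)
  if (sd(pts$synergy) == 0 || sd(pts$degree) == 0)
    return(list(correlation = NA_real_, nPoints = nrow(pts),
                degenerate = TRUE))
  list(correlation = cor(pts$synergy, pts$degree, method = method),
       nPoints = nrow(pts), degenerate = FALSE)
}

.degreeSynergyPoints <- function(triads, mode) {
  if (mode == "in") {
    data.frame(synergy = triads$synergyNormalized,
               degree = triads$receiverInDegree)
  } else {
    data.frame(synergy = rep(triads$synergyNormalized, 2),
               degree = c(triads$JOutDegree, triads$KOutDegree))
  }
}

#' Shuffle null distribution for the degree-synergy correlation
#'
#' Permutes the synergy column against the degree column `nShuffles` times;
#' both marginals are preserved and the null correlations are centered at
#' zero.
#'
#' @param triads triad table.
#' @param mode "in" or "out".
#' @param nShuffles number of shuffles (default 400).
#' @param method correlation coefficient.
#' @param seed RNG seed.
#' @return numeric vector of null correlations.
#' @export
shuffledNull <- function(triads, mode = c("in", "out"), nShuffles = 400,
                         method = c("pearson", "spearman"), seed = NULL) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  pts <- .degreeSynergyPoints(triads, mode)
  withSeed(seed, vapply(seq_len(nShuffles), function(i)
    cor(sample(pts$synergy), pts$degree, method = method), 0))
}

#' Binomial skew test on a set of correlation values
#'
#' Under the null that positive and negative correlations are equally
#' likely, returns the one-sided binomial tail probability of observing at
#' least `max(nPos, nNeg)` same-sign values among the nonzero ones.
#' Zero/degenerate values are excluded from the counts.
#'
#' @param correlationValues numeric correlations (NAs dropped).
#' @return list with `nPos`, `nNeg`, `binomialP` (NA when no nonzero
#'   values).
#' @export
correlationSkewTest <- function(correlationValues) {
  v <- correlationValues[!is.na(correlationValues)]
  nPos <- sum(v > 0)
  nNeg <- sum(v < 0)
  n <- nPos + nNeg
  if (n == 0)
    return(list(nPos = 0L, nNeg = 0L, binomialP = NA_real_))
  k <- max(nPos, nNeg)
  p <- pbinom(k - 1L, n, 0.5, lower.tail = FALSE)
  list(nPos = as.integer(nPos), nNeg = as.integer(nNeg), binomialP = p)
}

#' Median and quartile synergy profile by degree
#'
#' Groups triad points by degree (mode "in": receiver in-degree; mode
#' "out": transmitter out-degree with two points per triad) and reports the
#' per-degree median and quartiles; degrees with fewer than `minGroup`
#' points are omitted.
#'
#' @param triads triad table.
#' @param mode "in" or "out".
#' @param minGroup minimum points per degree (default 20).
#' @return data.frame with degree, n, q1, median, q3.
#' @export
synergyVsDegreeProfile <- function(triads, mode = c("in", "out"),
                                   minGroup = 20) {
  mode <- match.arg(mode)
  pts <- .degreeSynergyPoints(triads, mode)
  grp <- split(pts$synergy, pts$degree)
  grp <- grp[vapply(grp, length, 0L) >= minGroup]
  out <- data.frame(degree = as.integer(names(grp)),
                    n = vapply(grp, length, 0L),
                    q1 = vapply(grp, function(x) unname(quantile(x, .25)), 0),
                    median = vapply(grp, median, 0),
                    q3 = vapply(grp, function(x) unname(quantile(x, .75)), 0),
                    row.names = NULL)
  out[order(out$degree), , drop = FALSE]
}

#' Exponential-decay fit of median information gain versus input count
#'
#' Fits `gain = a * exp(b * n)` to the per-n median information gains by
#' nonlinear least squares and reports the 95% confidence interval on the
#' exponent b; negative exponents indicate information gains that shrink as
#' inputs are added (higher-order computation does not dominate).
#'
#' @param infoGainResults data.frame with columns `n` (input count) and
#'   `gain` (bits), one row per receiver/input-set result.
#' @return list with `amplitude`, `exponent`, `exponentCI` (length 2),
#'   `medians` (the fitted points).
#' @export
infoGainDecayFit <- function(infoGainResults) {
  med <- vapply(split(infoGainResults$gain, infoGainResults$n), median, 0)
  df <- data.frame(n = as.numeric(names(med)), m = as.numeric(med))
  if (nrow(df) < 3) stop("need medians at >= 3 input counts", call. = FALSE)
  b0 <- if (all(df$m > 0))
    unname(coef(lm(log(m) ~ n, df))[2]) else 0
  a0 <- max(df$m[1], 1e-12)
  doFit <- function(b) minpack.lm::nlsLM(
    m ~ a * exp(b * n), data = df, start = list(a = a0, b = b),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  # a start that already fits exactly can present a numerically singular
  # gradient; retry from a mildly perturbed exponent
  fit <- tryCatch(doFit(b0), error = function(e) doFit(b0 - 0.05))
  cf <- coef(fit)
  se <- summary(fit)$coefficients["b", "Std. Error"]
  list(amplitude = unname(cf["a"]), exponent = unname(cf["b"]),
       exponentCI = unname(cf["b"]) + c(-1, 1) * 1.96 * se,
       medians = df)
}

#' @importFrom stats lm
NULL
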