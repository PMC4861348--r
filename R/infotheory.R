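## Discrete information measures over binary lagged-state distributions.
## All logarithms are base 2 (units: bits); 0*log(0) := 0 throughout.

#' Plug-in estimate of a joint distribution from observations
#'
#' Maximum-likelihood (frequency-counting) estimate; unobserved states get
#' mass 0.
#'
#' @param observations integer 0/1 matrix with named columns, e.g. from
#'   [laggedObservations()].
#' @return A [JointDistribution-class] over the observation columns.
#' @examples
#' obs <- rbind(matrix(0, 3, 3), matrix(1, 1, 3))
#' colnames(obs) <- c("I_F", "I_P", "J_P")
#' probMass(estimateDistribution(obs))[1]  # 0.75
#' @export
estimateDistribution <- function(observations) {
  observations <- as.matrix(observations)
  if (nrow(observations) < 1L) stop("empty observations", call. = FALSE)
  if (is.null(colnames(observations)))
    stop("observations must have named columns", call. = FALSE)
  stopIfNot01(observations, "observations")
  k <- ncol(observations)
  code <- as.integer(observations %*% 2L^(seq_len(k) - 1L))
  counts <- tabulate(code + 1L, nbins = 2L^k)
  jointDistribution(counts / sum(counts), colnames(observations))
}

#' Marginalize a joint distribution onto a subset of variables
#'
#' @param dist a [JointDistribution-class].
#' @param variables character subset of `variableNames(dist)`.
#' @return A [JointDistribution-class] over `variables` (in that order).
#' @export
marginalDistribution <- function(dist, variables) {
  idx <- match(variables, dist@varNames)
  if (anyNA(idx)) stop("unknown variable(s)", call. = FALSE)
  if (!length(idx)) stop("empty variable set", call. = FALSE)
  m <- apply(dist@probs, idx, sum)
  jointDistribution(as.numeric(m), variables)
}

#' Shannon entropy of a marginal, in bits
#'
#' @param dist a [JointDistribution-class].
#' @param variables variables whose marginal entropy is computed (default:
#'   all).
#' @return entropy in bits.
#' @examples
#' d <- jointDistribution(c(0.75, 0.25), "I_F")
#' entropyBits(d)  # 0.8113
#' @export
entropyBits <- function(dist, variables = variableNames(dist)) {
  p <- as.numeric(marginalDistribution(dist, variables)@probs)
  -sum(p * log2safe(p))
}

#' Mutual information between two variable sets, in bits
#'
#' `MI(X; Y) = H(X) + H(Y) - H(X, Y)`, nonnegative and symmetric.
#'
#' @param dist a [JointDistribution-class].
#' @param xVars,yVars disjoint variable subsets.
#' @return MI in bits.
#' @export
mutualInformation <- function(dist, xVars, yVars) {
  if (length(intersect(xVars, yVars)))
    stop("variable sets must be disjoint", call. = FALSE)
  mi <- entropyBits(dist, xVars) + entropyBits(dist, yVars) -
    entropyBits(dist, c(xVars, yVars))
  max(mi, 0)
}

#' Conditional mutual information, in bits
#'
#' `MI(X; Y | Z) = H(X,Z) + H(Y,Z) - H(Z) - H(X,Y,Z)`; conditioning states
#' with zero mass contribute 0.
#'
#' @param dist a [JointDistribution-class].
#' @param xVars,yVars,zVars pairwise disjoint variable subsets.
#' @return CMI in bits.
#' @export
conditionalMutualInformation <- function(dist, xVars, yVars, zVars) {
  vs <- list(xVars, yVars, zVars)
  for (i in 1:2) for (j in (i + 1):3)
    if (length(intersect(vs[[i]], vs[[j]])))
      stop("variable sets must be pairwise disjoint", call. = FALSE)
  if (!length(zVars)) return(mutualInformation(dist, xVars, yVars))
  cmi <- entropyBits(dist, c(xVars, zVars)) +
    entropyBits(dist, c(yVars, zVars)) -
    entropyBits(dist, zVars) -
    entropyBits(dist, c(xVars, yVars, zVars))
  max(cmi, 0)
}

#' Transfer entropy from lagged observations or a joint distribution
#'
#' `TE(J -> I) = MI(I_F; J_P | I_P)`; the entropy-normalized value divides
#' by `H(I_F)` (defined as 0 when `H(I_F) = 0`) and is clipped to `[0, 1]`.
#'
#' @param x a 0/1 observation matrix with columns `I_F`, `I_P`, `J_P` (e.g.
#'   from [laggedObservations()]) or a [JointDistribution-class] over those
#'   variables.
#' @return list with `teBits`, `teNormalized`, `nObservations` (NA when a
#'   distribution is supplied).
#' @export
transferEntropy <- function(x) {
  nObs <- NA_integer_
  if (is(x, "JointDistribution")) {
    dist <- x
  } else {
    x <- as.matrix(x)
    if (!all(c("I_F", "I_P", "J_P") %in% colnames(x)))
      stop("observations must have columns I_F, I_P, J_P", call. = FALSE)
    nObs <- nrow(x)
    dist <- estimateDistribution(x[, c("I_F", "I_P", "J_P"), drop = FALSE])
  }
  te <- conditionalMutualInformation(dist, "I_F", "J_P", "I_P")
  hF <- entropyBits(dist, "I_F")
  teNorm <- if (hF > 0) min(max(te / hF, 0), 1) else 0
  list(teBits = te, teNormalized = teNorm, nObservations = nObs)
}

#' Joint (multivariate) transfer entropy from a set of sources
#'
#' `TE({J1..Jn} -> I) = MI(I_F; {J1_P..Jn_P} | I_P)`.
#'
#' @param dist a [JointDistribution-class] containing `I_F`, `I_P`, and the
#'   source variables.
#' @param sourceVars character names of the source past variables (default:
#'   all variables except `I_F`, `I_P`).
#' @return TE in bits.
#' @export
jointTransferEntropy <- function(dist,
                                 sourceVars = setdiff(variableNames(dist),
                                                      c("I_F", "I_P"))) {
  conditionalMutualInformation(dist, "I_F", sourceVars, "I_P")
}
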