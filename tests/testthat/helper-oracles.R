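# Independent brute-force oracles: every information measure is recomputed
# here by direct summation over the explicit state table, never through the
# package's entropy-combination code paths.

# JointDistribution -> data.frame of states (one column per variable) + p
distDF <- function(dist) {
  vars <- variableNames(dist)
  grid <- do.call(expand.grid, setNames(rep(list(0:1), length(vars)), vars))
  grid$p <- as.numeric(probMass(dist))
  grid
}

bfMarg <- function(df, vars) {
  agg <- aggregate(df$p, by = df[vars], FUN = sum)
  names(agg)[ncol(agg)] <- "p"
  agg
}

# look up marginal probabilities for each row of `df`
bfLookup <- function(df, vars) {
  marg <- bfMarg(df, vars)
  key <- do.call(paste, c(df[vars], sep = "|"))
  mkey <- do.call(paste, c(marg[vars], sep = "|"))
  marg$p[match(key, mkey)]
}

# direct summation of MI(X; Y)
bfMI <- function(df, X, Y) {
  pxy <- bfLookup(df, c(X, Y))
  px <- bfLookup(df, X)
  py <- bfLookup(df, Y)
  sel <- df$p > 0
  # each (x, y) cell is visited once per full state; weight by p(state)
  sum(df$p[sel] * log2(pxy[sel] / (px[sel] * py[sel])))
}

# direct summation of MI(X; Y | Z)
bfCMI <- function(df, X, Y, Z) {
  pxyz <- bfLookup(df, c(X, Y, Z))
  pz <- bfLookup(df, Z)
  pxz <- bfLookup(df, c(X, Z))
  pyz <- bfLookup(df, c(Y, Z))
  sel <- df$p > 0
  sum(df$p[sel] * log2(pxyz[sel] * pz[sel] / (pxz[sel] * pyz[sel])))
}

# specific information of the source set R (plus the receiver past) about
# the outcome I_F = iFv, by direct summation over the (R, I_P) states
bfIspec <- function(df, iFv, R) {
  A <- c(R, "I_P")
  m <- bfMarg(df, c("I_F", A))
  pF <- sum(m$p[m$I_F == iFv])
  sub <- m[m$I_F == iFv & m$p > 0, , drop = FALSE]
  pA <- bfMarg(df, A)
  key <- do.call(paste, c(sub[A], sep = "|"))
  akey <- do.call(paste, c(pA[A], sep = "|"))
  pa <- pA$p[match(key, akey)]
  sum((sub$p / pF) * log2(sub$p / (pa * pF)))
}

bfImin <- function(df) {
  pF <- bfMarg(df, "I_F")
  total <- 0
  for (iFv in 0:1) {
    w <- pF$p[pF$I_F == iFv]
    if (w <= 0) next
    base <- bfIspec(df, iFv, character(0))
    total <- total + w * min(bfIspec(df, iFv, "J_P") - base,
                             bfIspec(df, iFv, "K_P") - base)
  }
  total
}

bfPID <- function(df) {
  teJ <- bfCMI(df, "I_F", "J_P", "I_P")
  teK <- bfCMI(df, "I_F", "K_P", "I_P")
  teJoint <- bfCMI(df, "I_F", c("J_P", "K_P"), "I_P")
  red <- bfImin(df)
  uJ <- teJ - red
  uK <- teK - red
  list(teJoint = teJoint, teJ = teJ, teK = teK, redundancy = red,
       uniqueJ = uJ, uniqueK = uK, synergy = teJoint - red - uJ - uK)
}

bfII <- function(df) bfCMI(df, "J_P", "K_P", "I_F") - bfMI(df, "J_P", "K_P")

# random strictly-positive distribution over the 16 binary states
randomDist16 <- function() {
  p <- rexp(16)
  jointDistribution(p / sum(p), c("I_F", "I_P", "J_P", "K_P"))
}

# observation matrix that exactly realizes a distribution with rational
# masses (counts = p * denom must be integers)
exactObservations <- function(dist, denom = 16) {
  df <- distDF(dist)
  counts <- round(df$p * denom)
  stopifnot(max(abs(counts - df$p * denom)) < 1e-9)
  idx <- rep(seq_len(nrow(df)), counts)
  as.matrix(df[idx, variableNames(dist), drop = FALSE])
}
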