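# build a triad table directly (bypassing spike estimation) for the
# correlation/profile operations
makeTriads <- function(synergy, inDeg, outJ, outK) {
  data.frame(receiver = as.character(seq_along(synergy)),
             J = "j", K = "k",
             synergyNormalized = synergy, receiverInDegree = inDeg,
             JOutDegree = outJ, KOutDegree = outK)
}

test_that("triad enumeration counts C(in-degree, 2) per receiver", {
  ed2 <- data.frame(source = c("a", "b"), target = "r")
  expect_equal(nrow(enumerateTriads(effectiveNetwork(ed2))), 1L)
  ed5 <- data.frame(source = letters[1:5], target = "r")
  tri5 <- enumerateTriads(effectiveNetwork(ed5))
  expect_equal(nrow(tri5), 10L)
  expect_equal(tri5$receiverInDegree, rep(5L, 10))
  # star: hub receives from k spokes
  k <- 7
  star <- effectiveNetwork(data.frame(source = as.character(1:k),
                                      target = "hub"))
  expect_equal(nrow(enumerateTriads(star)), choose(k, 2))
  expect_false(any(enumerateTriads(star)$J == enumerateTriads(star)$K))
})

test_that("degree-synergy correlation handles both modes and degeneracy", {
  tri <- makeTriads(c(1, 2, 3, 4), c(2, 2, 3, 3), c(1, 2, 3, 4),
                    c(1, 2, 3, 4))
  out <- degreeSynergyCorrelation(tri, "out")
  expect_equal(out$correlation, 1)
  expect_equal(out$nPoints, 8L) # two points per triad
  flat <- makeTriads(rep(1, 4), c(2, 2, 3, 3), 1:4, 1:4)
  expect_true(degreeSynergyCorrelation(flat, "out")$degenerate)
  expect_error(degreeSynergyCorrelation(tri[1:2, ], "in"), "3 data points")
  sp <- degreeSynergyCorrelation(tri, "in", method = "spearman")
  expect_false(is.na(sp$correlation))
})

test_that("shuffle nulls are centered at zero and are beaten by a perfect
           trend", {
  set.seed(81)
  tri <- makeTriads(1:40 + rnorm(40, 0, 1e-6), rep(2, 40), 1:40, 1:40)
  null <- shuffledNull(tri, "out", nShuffles = 400, seed = 82)
  expect_length(null, 400)
  se <- sd(null) / sqrt(400)
  expect_lt(abs(mean(null)), 3 * se + 0.02)
  obs <- degreeSynergyCorrelation(tri, "out")$correlation
  expect_true(all(null < obs))
})

test_that("the binomial skew test matches closed forms", {
  s <- correlationSkewTest(rep(0.5, 10))
  expect_equal(s$nPos, 10L)
  expect_equal(s$binomialP, 2^-10)
  even <- correlationSkewTest(c(rep(0.3, 5), rep(-0.3, 5)))
  expect_equal(even$binomialP, pbinom(4, 10, 0.5, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(round(even$binomialP, 3), 0.623)
  none <- correlationSkewTest(numeric(0))
  expect_true(is.na(none$binomialP))
  # NA and zero values are excluded from the counts
  mixed <- correlationSkewTest(c(0.2, -0.1, NA, 0))
  expect_equal(mixed$nPos + mixed$nNeg, 2L)
})

test_that("degree profiles group, filter, and order correctly", {
  tri <- makeTriads(c(rnorm(20, 1), rnorm(19, 2)),
                    c(rep(2, 20), rep(3, 19)), 1, 1)
  prof <- synergyVsDegreeProfile(tri, "in", minGroup = 20)
  expect_equal(prof$degree, 2L) # the 19-point group is omitted
  flat <- makeTriads(rep(0.4, 60), rep(c(2, 3, 4), each = 20), 1, 1)
  pf <- synergyVsDegreeProfile(flat, "in")
  expect_equal(pf$median, rep(0.4, 3))
  set.seed(83)
  trend <- makeTriads(rep(c(1, 2, 3), each = 25) + rnorm(75, 0, 0.1),
                      2, rep(c(1, 2, 3), each = 25),
                      rep(c(1, 2, 3), each = 25))
  pt <- synergyVsDegreeProfile(trend, "out", minGroup = 20)
  expect_true(all(diff(pt$median) > 0))
})

test_that("exponential-decay fits recover exact and noisy exponents", {
  gains <- data.frame(n = rep(2:6, each = 21),
                      gain = rep(2 * exp(-0.5 * (2:6)), each = 21))
  fit <- infoGainDecayFit(gains)
  expect_equal(fit$exponent, -0.5, tolerance = 1e-6)
  expect_equal(fit$amplitude, 2, tolerance = 1e-6)
  flat <- data.frame(n = rep(2:6, each = 21), gain = rep(0.3, 105))
  ff <- infoGainDecayFit(flat)
  expect_lt(abs(ff$exponent), 1e-6)
  # CI overlaps zero up to numerical dust on an exactly flat profile
  expect_true(ff$exponentCI[1] <= 1e-8 && ff$exponentCI[2] >= -1e-8)
})

test_that("decay-fit confidence intervals cover a known exponent", {
  set.seed(84)
  covered <- 0L
  for (rep in 1:20) {
    med <- vapply(2:6, function(n)
      median(0.8 * exp(-0.4 * n) + rnorm(31, 0, 0.01)), 0)
    fit <- infoGainDecayFit(data.frame(n = 2:6, gain = med))
    if (fit$exponentCI[1] <= -0.4 && -0.4 <= fit$exponentCI[2])
      covered <- covered + 1L
  }
  expect_gte(covered, 17L)
})

test_that("hub-broadcaster ensembles show the out-degree/computation link
           and no in-degree link", {
  outPos <- 0L
  inVals <- numeric(0)
  for (seed in 1:4) {
    # two hub transmitters each drive three XOR triads; six low-out-degree
    # redundant triads; extra copy edges vary receiver in-degree
    motifs <- list()
    nid <- 2L # hubs are 0 and 1
    for (h in 0:1) for (r in 1:3) {
      motifs <- c(motifs, list(motifSpec("synergistic",
                                         c(h, nid, nid + 1L))))
      nid <- nid + 2L
    }
    for (r in 1:6) {
      motifs <- c(motifs, list(motifSpec("redundant",
                                         c(nid, nid + 1L, nid + 2L))))
      nid <- nid + 3L
    }
    receivers <- vapply(motifs, function(m) m$neurons[3], 0L)
    extraSrc <- nid:(nid + 8L)
    extras <- list(edgeSpec(extraSrc[1], receivers[1]),
                   edgeSpec(extraSrc[2], receivers[2]),
                   edgeSpec(extraSrc[3], receivers[7]),
                   edgeSpec(extraSrc[4], receivers[8]),
                   edgeSpec(extraSrc[5], receivers[3]),
                   edgeSpec(extraSrc[6], receivers[3]),
                   edgeSpec(extraSrc[7], receivers[9]),
                   edgeSpec(extraSrc[8], receivers[9]))
    n <- max(extraSrc) + 1L
    rec <- generateRecording(n, 420, motifs, extras, 2, seed = 1000 + seed)
    net <- effectiveNetwork(
      data.frame(source = rec@groundTruthEdges$source,
                 target = rec@groundTruthEdges$target,
                 delayBins = 3L),
      nodes = neuronIds(rec@spikes))
    tri <- triadSynergies(rec@spikes, net, 1.6)
    outC <- degreeSynergyCorrelation(tri, "out")$correlation
    inC <- degreeSynergyCorrelation(tri, "in")$correlation
    if (outC > 0) outPos <- outPos + 1L
    inVals <- c(inVals, inC)
    expect_gt(outC, inC) # transmitter degree, not receiver degree, links
  }
  expect_gte(outPos, 4L * 0.8)
  # receiver in-degree carries no positive link to computation (triads that
  # mix a motif input with a weak extra input dilute synergy at high
  # in-degree, so the constructed ensemble sits slightly negative)
  expect_lt(mean(inVals), 0.1)
})
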