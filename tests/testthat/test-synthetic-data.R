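test_that("every printed example cell is reproduced after renormalization", {
  for (m in motifNames()) {
    col <- motifColumn(m)
    d <- motifDistribution(m)
    norm <- col$p / sum(col$p)
    got <- vapply(seq_len(nrow(col)), function(r)
      probMass(d)[col$I_F[r] + 1, col$I_P[r] + 1, col$J_P[r] + 1,
                  col$K_P[r] + 1], 0)
    expect_true(all(abs(got - norm) < 5e-4), info = m)
    expect_equal(sum(probMass(d)), 1, tolerance = 1e-12)
  }
  # the printed synergistic-and-redundant column sums to 1.0002
  sr <- motifColumn("synergistic_redundant")
  expect_equal(sum(sr$p), 1.0002, tolerance = 1e-9)
  expect_equal(sr$p[sr$I_F == 1 & sr$I_P == 0 & sr$J_P == 1 & sr$K_P == 1],
               0.3357)
  expect_equal(as.numeric(probMass(motifDistribution("no_interaction"))),
               rep(1 / 16, 16))
  expect_error(motifDistribution("nope"), "unknown motif")
})

test_that("motif state samples respect the support of their columns", {
  syn <- sampleMotifStates(motifDistribution("synergistic"), 1e5, seed = 3)
  expect_true(all(syn[, "I_F"] == (syn[, "J_P"] != syn[, "K_P"])))
  red <- sampleMotifStates(motifDistribution("redundant"), 1e5, seed = 4)
  expect_true(all(red[, "I_F"] == red[, "J_P"] &
                    red[, "I_F"] == red[, "K_P"]))
  # reproducible
  expect_identical(sampleMotifStates(motifDistribution("single"), 100,
                                     seed = 7),
                   sampleMotifStates(motifDistribution("single"), 100,
                                     seed = 7))
})

test_that("re-estimated motif distributions converge in total variation", {
  tv <- function(n, seed) {
    obs <- sampleMotifStates(motifDistribution("single_redundant"), n,
                             seed = seed)
    0.5 * sum(abs(as.numeric(probMass(estimateDistribution(obs))) -
                    as.numeric(probMass(motifDistribution(
                      "single_redundant")))))
  }
  small <- mean(vapply(1:5, function(s) tv(1000, s), 0))
  large <- mean(vapply(1:5, function(s) tv(16000, s), 0))
  expect_lt(large, small / 2)  # O(1/sqrt(n)) shrinkage, n ratio 16
})

test_that("background neurons are homogeneous Poisson at the stated rate", {
  rec <- generateRecording(10, 600, list(), list(), 2, seed = 8)
  counts <- vapply(neuronIds(rec@spikes),
                   function(i) length(spikeTimes(rec@spikes, i)), 0L)
  expect_true(all(counts >= qpois(0.005, 1200) &
                    counts <= qpois(0.995, 1200)))
  expect_true(all(unlist(rec@spikes@trains) >= 0 &
                    unlist(rec@spikes@trains) <= 600))
})

test_that("a planted motif reproduces its lagged joint distribution", {
  rec <- generateRecording(3, 600,
                           list(motifSpec("synergistic", c(0, 1, 2),
                                          delayMs = 4.8, binMs = 1.6)),
                           list(), 0, seed = 9)
  d <- spikePID:::laggedJointDistribution(rec@spikes, "2", c("0", "1"),
                                          1.6, c(3, 3))
  ref <- motifDistribution("synergistic")
  tv <- 0.5 * sum(abs(as.numeric(probMass(d)) - as.numeric(probMass(ref))))
  expect_lt(tv, 0.02)
  expect_equal(rec@groundTruthEdges$source, c("0", "1"))
})

test_that("recordings are bit-reproducible for a fixed seed", {
  args <- list(4, 60, list(motifSpec("redundant", c(0, 1, 2))),
               list(edgeSpec(0, 3)), 1)
  r1 <- do.call(generateRecording, c(args, seed = 123))
  r2 <- do.call(generateRecording, c(args, seed = 123))
  expect_identical(r1@spikes@trains, r2@spikes@trains)
})

test_that("conflicting motif assignments are rejected", {
  expect_error(generateRecording(4, 10,
                                 list(motifSpec("single", c(0, 1, 2)),
                                      motifSpec("redundant", c(0, 3, 2))),
                                 list(), 0, seed = 1),
               "conflicting")
  expect_error(generateRecording(5, 10,
                                 list(motifSpec("redundant", c(0, 1, 2)),
                                      motifSpec("redundant", c(0, 3, 4))),
                                 list(), 0, seed = 1),
               "shared")
  expect_error(generateRecording(2, 10,
                                 list(motifSpec("single", c(0, 1, 2))),
                                 list(), 0, seed = 1),
               "out of range")
})

test_that("a shared hub source keeps the XOR structure of both triads", {
  rec <- generateRecording(5, 300,
                           list(motifSpec("synergistic", c(0, 1, 2)),
                                motifSpec("synergistic", c(0, 3, 4))),
                           list(), 0, seed = 10)
  for (tri in list(c("0", "1", "2"), c("0", "3", "4"))) {
    d <- spikePID:::laggedJointDistribution(rec@spikes, tri[3], tri[1:2],
                                            1.6, c(3, 3))
    expect_gt(pidDecompose(d)$normalized$synergy, 0.9)
  }
})

test_that("random networks have exact edge counts sampled uniformly", {
  expect_equal(nrow(randomNetwork(50, 0, seed = 1)), 0L)
  g <- randomNetwork(50, 75, seed = 2)
  expect_equal(nrow(g), 75L)
  expect_false(any(g$source == g$target))
  expect_false(anyDuplicated(paste(g$source, g$target)) > 0)
  # average total degree = 2 m / n
  net <- effectiveNetwork(g, nodes = as.character(0:49))
  expect_equal(mean(degreeSummary(net)$totalDegree), 3)
  # saturation
  full <- randomNetwork(3, 6, seed = 3)
  expect_equal(nrow(full), 6L)
  expect_error(randomNetwork(3, 7), "too many")
})

test_that("spike files round-trip through the text format", {
  rec <- generateRecording(4, 30, list(), list(), 3, seed = 11)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeSpikeTrains(rec@spikes, path, seed = 11)
  back <- readSpikeTrains(path)
  expect_equal(back@tEnd, 30)
  for (i in neuronIds(rec@spikes))
    expect_equal(spikeTimes(back, i), spikeTimes(rec@spikes, i),
                 tolerance = 1e-8)
})
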