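---
title: "Quantifying computation in effective networks of spiking neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying computation in effective networks of spiking neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikePID)
```

# The scientific problem

Cortical neurons both transmit information and combine ("compute")
information from several inputs. spikePID implements a pipeline for asking
how computation relates to a neuron's position in its surrounding functional
network: spike trains are discretized into binary state series, directed
effective connectivity is inferred with transfer entropy (TE) against a
spike-jitter surrogate null, the information that two significant inputs
carry about a receiver is decomposed into synergistic, redundant, and unique
parts with the partial information decomposition (PID), and the synergy —
the part obtainable only from simultaneous knowledge of both inputs, a
natural operationalization of computation — is correlated with receiver
in-degree and transmitter out-degree. A two-layer probabilistic feedforward
model with score-based rewiring rules provides a mechanistic counterpart.

# The measures

All quantities are plug-in (frequency-counting) estimates over binary lagged
states, in bits. For a receiver series I and source series J, with `I_F` the
receiver's state in a future bin, `I_P` its state one bin earlier, and `J_P`
the source's state a delay `d` earlier,

* `TE(J -> I) = MI(I_F; J_P | I_P)`, the information the source past adds
  about the receiver future beyond the receiver's own past. We also report
  the entropy-normalized value `TE / H(I_F)` in [0, 1].
* For two sources, `TE({J,K} -> I)` splits as synergy + unique(J) +
  unique(K) + redundancy. Redundancy is the minimum-information measure:
  the expectation over receiver outcomes of the smaller source-specific
  information, each conditioned on the receiver past. Unique terms follow by
  subtracting redundancy from the bivariate TEs, synergy by subtracting all
  three from the joint TE. With this redundancy all four terms are
  nonnegative.
* Interaction information `II = MI(J_P; K_P | I_F) - MI(J_P; K_P)` is
  computed as a contrast: it conflates synergy (positive) with redundancy
  (negative), which is exactly what the PID avoids.
* For more than two inputs the highest-order synergy is bounded by the
  information gain `TE({J_1..J_n} -> I) - TE({J_1..J_{n-1}} -> I)`, averaged
  over the n choices of the excluded input and over at most 100 sampled
  input sets. We read the "n possible permutations" of the averaging as the
  n leave-one-out exclusions, since TE is invariant to the order of the
  retained inputs.

The eight worked-example joint distributions (no interaction, self, hidden
self, single, redundant, single+redundant, synergistic,
synergistic+redundant) ship as `motifDistribution()`, renormalized to sum
to one (the printed synergistic+redundant column sums to 1.0002 because its
entries are rounded to four decimals). They double as ground truth for the
oracle tests: every measure is checked against an independent brute-force
summation over all sixteen states.

```{r}
pidDecompose(motifDistribution("synergistic_redundant"))[
  c("synergy", "redundancy")]
```

# Binning and timescales

Spikes are binned half-open with an OR rule (a bin is 1 if it contains at
least one spike). A timescale couples one bin width with a list of candidate
delays; per directed pair, TE is computed at each delay and the maximum is
retained along with its argmax delay, which is reused for triad
distributions so that the bivariate TEs embedded in the decomposition equal
the pairwise stage's values. The two canonical timescales — 1.6 ms bins and
3.5 ms bins, each with delays 1-4 bins (interaction ranges 1.6-6.4 ms and
3.5-14 ms) — bracket reported monosynaptic latencies of 1-20 ms. The
receiver self-past is the bin immediately preceding the future bin
(`receiverSelfLag = 1`), a documented default exposed as a parameter, since
upstream work does not pin the convention.

# Significance testing

Connections are accepted when fewer than a fraction `alpha = 0.001` of
surrogate TEs exceed the observed TE; with the reference setting of 5000
surrogates this is the "fewer than 5 of 5000" rule, and a count of exactly 5
(p = 0.001) is not significant. Surrogates jitter every source spike
independently and uniformly within ±20 ms (configurable; wide enough to
destroy 1-20 ms delay structure while preserving slow rate fluctuations) and
are scored with the same max-over-delays statistic as the real pair, so the
null matches the selection procedure. Calibration on independent Poisson
pairs yields approximately uniform p-values (checked by a KS test in the
suite). Sub-network sampling (by default 500 sub-networks of 50 neurons with
average total degree 3 ± 0.2, by rejection) equalizes density and size
across recordings before degree-distribution comparisons; matched uniform
random networks with identical node and edge counts provide the null for
heavy-tail assessment, and TE weight distributions are fit with a
log10-normal mass function over 100 log-spaced bins with a free
normalization for the binning.

# The synthetic-data generator

No recordings are distributed, so the generator is a first-class module.
Background neurons are homogeneous Poisson (defaults emulate sparse cortical
culture activity, ~2 Hz over an hour). Directed couplings copy source
spikes into the target at a fixed delay with probability 0.5 by default —
excess delayed coincidences, the signature TE detects. Motif triads
reproduce the example joint distributions at a configured (bin, delay): six
of the eight columns have an independent fair receiver past, so sources are
drawn i.i.d. per bin from their joint marginal and the receiver samples
`p(i_F | j_P, k_P)` at the delay; the self and hidden-self columns require
`I_F = I_P` and are realized with block-constant fair drive (250-bin
blocks), exact up to an O(delay/block) boundary term of roughly 0.01-0.02
bits in the estimated TE. One caveat is intrinsic: the
synergistic+redundant column assigns the receiver future a 0.67/0.33
marginal but the receiver past a fair one, which no stationary series with a
one-bin self-lag can satisfy; the realized process matches the column in
every respect except the `I_P` marginal. Because `I_P` is independent of all
other variables in that column, every TE/PID term and `H(I_F)` — hence the
normalized PID profile — is unaffected. Motif neurons fire at fair-bit
rates (hundreds of Hz at millisecond bins) by construction; the generator
reproduces the information structure of the worked examples, not the
biophysics of real spike trains, and passing tests certify the pipeline's
estimators, not culture realism. Bursting, refractoriness, and
non-stationarity are deliberately out of scope.

# Degree-versus-computation analysis

For every receiver with in-degree d ≥ 2, all C(d, 2) source pairs form
triads; each triad's normalized synergy is one data point against the
receiver's in-degree (in-mode) and two points against the transmitters'
out-degrees (out-mode). Pearson correlation is the default with Spearman as
an option — the choice was genuinely open, and Pearson is the commoner
default for such scatter summaries; correlations are computed on the full
inferred network by default with per-sub-network aggregation available.
Shuffle nulls permute synergy against degree, preserving both marginals. The
sign skew of per-recording correlations is tested with a one-sided binomial
tail at p = 0.5, excluding degenerate (zero-variance) recordings. Degree
profiles report per-degree medians and quartiles, omitting degrees with
fewer than 20 triads. Median information gains versus input count n (2-6)
are fit with `a * exp(b * n)`; a negative exponent with a 95% CI excluding
zero indicates shrinking higher-order gains.

# The feedforward model

Two layers of `nNeurons = 20` binary neurons (also run at 40); firing
probability is a sigmoid of total current with constants solved from
`p(0) = 0.01` and `p(iCon * nNeurons) = 0.5` (alpha ≈ 0.023, beta ≈ 4.6 at
20 neurons, iCon = 10). A fair network-wide binary signal injects currents
producing no-connectivity firing probabilities `0.5 ± 0.4 (i-1)/(N-1)`
(inputs) and `0.5 ± 0.2 (o-1)/(N-1)` (outputs): low-index neurons ignore
the signal, high-index neurons follow it. 20% of input-output pairs are
connected (80 connections at n = 20), each delivering 10 current units when
its input fires. Rewiring repeats `nConnections` times: 500 statistics runs,
then the score `S(i,o) = A(i,o) + a1 DegIn(o) + a2 DegOut(i) + a3 FR(o) +
a4 FR(i)` (A = state-agreement proportion); the lowest-scoring connected
pair is cut and the highest-scoring unconnected pair added, ties broken at
random (the source leaves tie handling open). The pure Hebbian rule is all
zeros; the fitted degree rule is (0.05, -1.75, 0, 0) at n = 20 and
(0.16, -0.3, 0, 0) at n = 40; the firing-rate rule is (0, 0, 0.35, 3.1).
Fitting uses a three-stage lattice search (7 points per axis per stage,
re-gridding around the incumbent at one third span; the printed bounds
|a1|,|a2| ≤ 3 and |a3|,|a4| ≤ 4) against target (in, out) correlation
values; `latticeSearch()` accepts any objective, and
`modelCorrelationObjective()` builds the ensemble-matching one. Model PID
uses the output's previous-run state as the receiver past — runs are
i.i.d., so this equals the unconditioned decomposition; the convention is
stated because the source never specifies it.

# Numerical choices

Logarithms are base 2; `0 log 0 = 0`; conditional terms with zero
conditioning mass contribute 0. CMI is computed by entropy combination (the
test suite checks it against direct-summation oracles to 1e-12). Normalized
quantities are defined as 0 when `H(I_F) = 0` and clipped to [0, 1];
negative floating-point dust above -1e-9 in PID terms is clamped to 0.
Joint state counts are accumulated sparsely from occupied-bin sets, so
hour-long recordings at millisecond bins need no dense state matrices.
Surrogate p-values use the strictly-greater count without a +1 correction,
matching the stated rule. All randomness flows through explicit seeds.

# Problem sizes used in the checks

The test suite runs the full pipeline at reduced but honest scales chosen to
keep the suite fast while leaving effect sizes far above estimator noise:
hour-long single-motif recordings for PID profile recovery (each normalized
term within 0.05); ten planted couplings at 2 Hz background with 200
surrogates for edge sensitivity; model ensembles of 20 instances per rule
with 500-run statistics passes and 2000 evaluation runs; 1000 random
16-state distributions for the PID identities; 1e5 draws for the log-normal
fit recovery.

# Known limitations

* The minimum-information redundancy is one of several proposed PID
  redundancies; alternatives (and lattices beyond two sources) are out of
  scope, with the information-gain bound standing in for higher orders.
* Plug-in estimators are biased upward on small samples; the pipeline
  relies on surrogate testing, not debiasing, mirroring its design.
* One model-level claim did not reproduce under the printed equations and
  coefficients: with the fitted degree-modified rule, the positive in-degree
  term concentrates connections onto a few saturated outputs, and the
  signal-conditioned connected-pair MI of that ensemble falls below the
  random network's rather than above all rules. The corresponding
  acceptance check is left failing rather than weakened; the Hebbian rule's
  unconditioned-MI maximum and the degree rule's (in ≈ 0, out > 0)
  correlation pattern both reproduce.
* A pure XOR triad carries zero bivariate TE from either source, so it can
  never enter the triad enumeration of a TE-inferred network — an intrinsic
  property of TE-gated PID analysis, not of this implementation. Planted
  synergistic motifs are therefore evaluated at their known (bin, delay) or
  on ground-truth networks in the checks; detectable triads in data need
  some unique or redundant component, as in the synergistic+redundant
  example.
* Excitatory/inhibitory labeling, spike sorting, bursting dynamics, and
  multi-timescale multiplex constructions are out of scope.
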