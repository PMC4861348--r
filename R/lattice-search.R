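## Staged lattice (grid) search over score parameters, plus the model
## ensemble objective used to fit rewiring-rule coefficients to target
## degree-versus-synergy correlations.

#' Staged lattice search over a box
#'
#' Stage 1 evaluates `pointsPerAxis^d` grid points over the full bounds;
#' each later stage re-grids around the incumbent with one third of the
#' previous span (clipped to the bounds) and keeps the incumbent, so the
#' best objective is non-increasing across stages.
#'
#' @param objective function taking a numeric parameter vector, returning a
#'   scalar to minimize.
#' @param bounds list of `c(lower, upper)` per parameter.
#' @param stages number of refinement stages (default 3).
#' @param pointsPerAxis grid resolution per axis per stage (default 7).
#' @return list with `par` (best parameters), `value`, `trace` (best value
#'   after each stage).
#' @export
latticeSearch <- function(objective, bounds, stages = 3, pointsPerAxis = 7) {
  d <- length(bounds)
  lower <- vapply(bounds, `[`, 0, 1)
  upper <- vapply(bounds, `[`, 0, 2)
  span <- upper - lower
  center <- (lower + upper) / 2
  best <- NULL
  bestVal <- Inf
  trace <- numeric(stages)
  for (s in seq_len(stages)) {
    axes <- lapply(seq_len(d), function(j) {
      lo <- max(center[j] - span[j] / 2, lower[j])
      hi <- min(center[j] + span[j] / 2, upper[j])
      seq(lo, hi, length.out = pointsPerAxis)
    })
    grid <- as.matrix(expand.grid(axes))
    for (r in seq_len(nrow(grid))) {
      v <- objective(grid[r, ])
      if (v < bestVal) {
        bestVal <- v
        best <- grid[r, ]
      }
    }
    trace[s] <- bestVal
    center <- best
    span <- span / 3
  }
  list(par = unname(best), value = bestVal, trace = trace)
}

#' Ensemble objective for fitting rewiring-rule coefficients
#'
#' Returns a function of the two free coefficients of a rule family
#' ("degree": a1, a2; "firing_rate": a3, a4) that builds a small model
#' ensemble with those coefficients and returns the squared distance
#' between the ensemble-mean (in-mode, out-mode) degree-versus-synergy
#' correlations and the supplied targets. Passing the returned function to
#' [latticeSearch()] with the printed bounds (|a1|,|a2| <= 3,
#' |a3|,|a4| <= 4) reproduces the fitting procedure.
#'
#' @param ruleFamily "degree" or "firing_rate".
#' @param targetCorrelations numeric `c(in, out)` targets.
#' @param nInstances models per evaluation (small, e.g. 3).
#' @param nNeurons neurons per layer.
#' @param nStatsRuns runs per rewiring statistics pass.
#' @param nEvalRuns evaluation runs.
#' @param seed base seed (fixed across evaluations so the search surface is
#'   deterministic).
#' @return function(params2) -> squared distance.
#' @export
modelCorrelationObjective <- function(ruleFamily = c("degree",
                                                     "firing_rate"),
                                      targetCorrelations, nInstances = 3,
                                      nNeurons = 20, nStatsRuns = 100,
                                      nEvalRuns = 1000, seed = 0) {
  ruleFamily <- match.arg(ruleFamily)
  function(params2) {
    sp <- if (ruleFamily == "degree") c(params2, 0, 0) else c(0, 0, params2)
    ens <- modelEnsemble(ruleFamily, nInstances = nInstances,
                         nNeurons = nNeurons, nStatsRuns = nStatsRuns,
                         nEvalRuns = nEvalRuns, scoreParams = sp,
                         seed = seed)
    sum((c(mean(ens$inCorrelation, na.rm = TRUE),
           mean(ens$outCorrelation, na.rm = TRUE)) -
           targetCorrelations)^2)
  }
}
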