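#' @import methods
#' @importFrom stats runif rnorm rpois rbinom cor median quantile sd
#'   pbinom wilcox.test p.adjust setNames coef ks.test
#' @importFrom utils combn read.table write.table head
NULL

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Clamp floating-point dust: values in (-tol, 0) are set to 0.
clampDust <- function(x, tol = 1e-9) {
  bad <- x < 0 & x > -tol
  x[bad] <- 0
  x
}

stopIfNot01 <- function(x, what) {
  if (!all(x %in% c(0L, 1L)))
    stop(what, " must contain only binary states 0/1", call. = FALSE)
}

## base-2 log with the 0*log(0) := 0 convention applied by callers
log2safe <- function(x) {
  out <- rep(0, length(x))
  pos <- x > 0
  out[pos] <- log2(x[pos])
  out
}
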