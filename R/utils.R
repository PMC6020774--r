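#' @useDynLib vdrdti, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif plogis qnorm pnorm pt sd cor var complete.cases
#' @importFrom utils read.delim write.table
NULL

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive independent child seeds from one master seed
#'
#' All stochastic stages of the pipeline draw their own seed from a single
#' master seed so that stages are reproducible individually and jointly.
#'
#' @param seed Integer master seed.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
child_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

maybe_set_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
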