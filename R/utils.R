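#' @import methods
#' @importFrom stats rnorm runif sd median mad approx coef convolve cor cor.test
#'   dgamma ecdf lm anova aov na.omit p.adjust pgamma pnorm predict pt qt
#'   quantile t.test var wilcox.test setNames optim
#' @importFrom utils head tail read.csv write.csv
NULL

# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Seeded RNG scope
#'
#' Runs an expression under a local RNG state seeded with `seed`, restoring
#' the caller's state afterwards. All stochastic generator code funnels
#' through this so that per-session substreams are reproducible.
#' @noRd
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a bounded integer sub-seed from a base seed and stream labels.
# Strings are folded character by character (order-sensitive) so that
# distinct labels never share a stream.
subSeed <- function(seed, ...) {
  parts <- c(seed, unlist(lapply(list(...), function(x) {
    if (is.character(x)) utf8ToInt(x) else as.numeric(x)
  })))
  s <- 0
  for (p in parts) s <- (s * 1000003 + round(p)) %% 2147483587
  as.integer(s + 1)
}

# Mean-of-squares signal power.
meanPower <- function(x) mean(x^2)

# Sample indices of the half-open time window [t0, t1) at sampling rate fs,
# relative to a 0-based recording start (sample i covers time i/fs).
windowIndex <- function(t0, t1, fs, offset = 0) {
  i0 <- ceiling((t0 - offset) * fs - 1e-9)
  i1 <- ceiling((t1 - offset) * fs - 1e-9) - 1
  if (i1 < i0) return(integer(0))
  seq.int(i0, i1) + 1L
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
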