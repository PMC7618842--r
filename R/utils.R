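## Small shared helpers.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Derive a named sub-seed from a master seed
#'
#' All stochastic stages draw their seed from one master seed plus a stage
#' name, so a single `--seed` reproduces a full pipeline run while stages
#' remain independently re-runnable. The result is kept below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param name character stage name.
#' @return an integer seed.
#' @export
derive_seed <- function(master, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(master) * 48271 + h * 1299721) %% 2147483647L)
}

## Effective sample size via initial-positive-sequence autocorrelation sum.
ess <- function(x) {
  n <- length(x)
  if (n < 10 || sd(x) == 0) return(n)
  x <- x - mean(x)
  maxlag <- min(n - 2L, 2000L)
  ac <- stats::acf(x, lag.max = maxlag, plot = FALSE, demean = FALSE)$acf[-1]
  s <- 0
  for (k in seq_along(ac)) {
    if (ac[k] <= 0) break
    s <- s + ac[k]
  }
  n / (1 + 2 * s)
}

## Matrix exponential for rate matrices (Pade scaling-and-squaring via the
## Matrix package) -- deliberately a different algorithm from the spectral
## decomposition inside the C++ pruning core, so the two can cross-check.
expm_mat <- function(M) {
  unname(as.matrix(Matrix::expm(Matrix::Matrix(M))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(sprintf(...), call. = FALSE)
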