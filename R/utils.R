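#' Numerically stable log-sum-exp
#'
#' @param x numeric vector (may contain `-Inf`).
#' @return `log(sum(exp(x)))` computed without overflow.
#' @keywords internal
logsumexp <- function(x) {
  if (!length(x)) return(-Inf)
  mx <- max(x)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(x - mx)))
}

#' Derive a reproducible child seed from a master seed and tags
#'
#' Hierarchical seeding: every source of randomness in the package draws its
#' seed from a master integer plus a list of string tags (stream name,
#' scenario name, ensemble index, chain index, ...), so that scenarios are
#' comparable under a common master seed and the four error fields use
#' independent random-number streams. The hash is a simple 31-multiplier
#' polynomial modulo the Mersenne prime 2^31 - 1, exact in double precision.
#'
#' @param master integer master seed.
#' @param ... tags (coerced to character) identifying the stream.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "eps")
#' derive_seed(1, "scenario", 12)
derive_seed <- function(master, ...) {
  p <- 2147483647
  h <- as.numeric(master) %% p
  for (tag in list(...)) {
    for (v in utf8ToInt(paste0(as.character(tag), "|"))) {
      h <- (h * 31 + v) %% p
    }
  }
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state so that exported stochastic
# functions never disturb the caller's random-number stream.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Weighted sample quantiles
#'
#' Quantiles of a weighted sample, defined as the smallest observed value
#' whose cumulative normalized weight reaches the requested probability
#' (a weighted analogue of type-1 quantiles). Used to form the
#' centile-based intervals of the frequentist model averaging combiner.
#'
#' @param x numeric sample.
#' @param w non-negative weights, same length as `x`.
#' @param probs probabilities in `[0, 1]`.
#' @return numeric vector of quantiles, one per element of `probs`.
#' @export
weighted_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), all(w >= 0), all(probs >= 0 & probs <= 1))
  keep <- is.finite(x) & w > 0
  x <- x[keep]; w <- w[keep]
  if (!length(x)) stop("no finite observations with positive weight")
  o <- order(x)
  x <- x[o]
  cw <- cumsum(w[o]) / sum(w)
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1]], numeric(1))
}
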