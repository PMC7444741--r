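#' Stable softmax normalization
#'
#' Exponentiates and normalizes a real vector, shifting by the maximum first
#' so the computation is stable for large potentials. This is the map from
#' depolarization-like potentials `v` to firing-rate-like expectations `s`.
#'
#' @param v Numeric vector of finite values.
#' @return Probability vector of the same length, summing to 1.
#' @export
#' @examples
#' softmax_normalize(c(0, 0))       # (0.5, 0.5)
#' softmax_normalize(c(log(3), 0))  # (0.75, 0.25)
softmax_normalize <- function(v) {
  if (!is.numeric(v) || !all(is.finite(v))) {
    stop("softmax_normalize: input must be a finite numeric vector")
  }
  e <- exp(v - max(v))
  e / sum(e)
}

#' Floored logarithm of probabilities
#'
#' Returns `log(p + lambda)`. The additive floor `lambda` (default
#' `exp(-16)`) bounds log-probabilities below at about -16 nats, so
#' impossible outcomes contribute a large-but-finite penalty instead of
#' `-Inf`.
#'
#' @param p Numeric vector with non-negative entries.
#' @param lambda Positive log-floor; default `exp(-16)`.
#' @return `log(p + lambda)`.
#' @export
safe_log <- function(p, lambda = exp(-16)) {
  if (any(p < 0)) stop("safe_log: negative entries are outside the domain")
  log(p + lambda)
}

## Contract chosen dimensions of an array against weight vectors.
## `dims` are dimension indices of `arr`; `vecs` is a list aligned with
## `dims`. Contractions run from the highest dimension down so remaining
## indices keep their positions.
contract_dims <- function(arr, vecs, dims) {
  ord <- order(dims, decreasing = TRUE)
  for (k in ord) {
    d <- dims[k]
    w <- vecs[[k]]
    dm <- dim(arr)
    if (is.null(dm)) {
      if (d != 1L) stop("contract_dims: dimension bookkeeping error")
      arr <- sum(arr * w)
      next
    }
    perm <- c(setdiff(seq_along(dm), d), d)
    m <- matrix(aperm(arr, perm), ncol = dm[d])
    res <- as.vector(m %*% w)
    nd <- dm[-d]
    arr <- if (length(nd) > 1L) array(res, dim = nd) else res
  }
  arr
}

## Shannon entropy (nats) with 0*log(0) := 0.
shannon_entropy <- function(p) {
  -sum(ifelse(p > 0, p * log(p), 0))
}

#' Derive a sub-stream seed from a master seed
#'
#' Deterministically maps a master seed and an offset to a new integer seed
#' below 2^31, so that conditions, distractor draws and synthetic-data noise
#' each get an independent, reproducible stream.
#'
#' @param master Master integer seed.
#' @param offset Integer label of the sub-stream.
#' @return An integer seed.
#' @export
derive_seed <- function(master, offset) {
  as.integer((abs(as.double(master)) %% 94906249) * 1103 %% 2147483647 +
               (as.double(offset) * 7919 + 104729) %% 1048573) %% 2147483647L
}

## Evaluate an expression with a locally seeded RNG, restoring global state.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

is_one_hot <- function(x) {
  all(x %in% c(0, 1)) && sum(x) == 1
}

one_hot <- function(i, n) {
  v <- numeric(n)
  v[i] <- 1
  v
}
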