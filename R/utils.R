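#' @keywords internal
"_PACKAGE"

#' @import data.table
#' @importFrom stats kmeans hclust cutree dist rnorm runif rbinom rpois
#'   qnorm pnorm dnorm sd median cor chisq.test t.test setNames aggregate
#' @importFrom utils head tail
NULL

# Evaluate `code` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. All stochastic operations in the package go
# through this so that seeds are explicit arguments, never ambient state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Deterministically derive `n` child seeds (< 2^31) from one parent seed.
derive_seeds <- function(seed, n, labels = NULL) {
  s <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  if (!is.null(labels)) names(s) <- labels
  s
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

#' Cosine similarity and distance
#'
#' Cosine distance is defined throughout the package as 1 - cosine
#' similarity, so distances lie in \[0, 2\].
#'
#' @param a,b Numeric vectors of equal length, or matrices with vectors in
#'   rows (then similarity is computed row-wise against `b`'s rows).
#' @return Numeric scalar (vector inputs) or matrix of pairwise similarities.
#' @export
cosine_similarity <- function(a, b) {
  if (is.matrix(a) || is.matrix(b)) {
    a <- rbind(a); b <- rbind(b)
    na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
    s <- (a %*% t(b)) / outer(pmax(na, .Machine$double.eps),
                              pmax(nb, .Machine$double.eps))
    return(s)
  }
  denom <- sqrt(sum(a^2)) * sqrt(sum(b^2))
  if (denom == 0) return(NA_real_)
  sum(a * b) / denom
}

#' @rdname cosine_similarity
#' @export
cosine_distance <- function(a, b) 1 - cosine_similarity(a, b)

# Rows scaled to unit Euclidean norm (zero rows left untouched).
l2_normalize <- function(x) {
  n <- sqrt(rowSums(x^2))
  n[n == 0] <- 1
  x / n
}

`%||%` <- function(a, b) if (is.null(a)) b else a
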