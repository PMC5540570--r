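#' @importFrom stats rnorm runif sd cor median phyper pbinom p.adjust setNames ave cov2cor
#' @importFrom utils combn head
NULL

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
# All generator functions route their randomness through this so they are
# pure functions of (arguments, seed).
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Stable 31-bit seed derived from a base seed and a stream label, so each
# pipeline stage / iteration gets an independent stream and adding a stage
# never perturbs another stage's randomness.
derive_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(as.character(label))) h <- (h * 131 + ch) %% 2147483647
  as.integer((as.double(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

#' Area under the ROC curve by mid-rank statistic
#'
#' Computes P(score of a random positive > score of a random negative), with
#' ties counted 1/2, via the rank-sum identity. Equivalent to exhaustive
#' pairwise comparison.
#'
#' @param scores numeric vector.
#' @param labels logical vector, `TRUE` for positives; same length as `scores`.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), is.logical(labels))
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop("auroc needs at least one positive and one negative")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# canonical unordered pair orientation: gene_a < gene_b lexicographically
canonical_pairs <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  list(gene_a = a, gene_b = b)
}
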