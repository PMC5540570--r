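#' Shrinkage partial correlations for a gene subset
#'
#' Estimates the partial-correlation matrix of `k` genes from `n` samples by
#' Schafer-Strimmer shrinkage of the empirical correlation matrix toward the
#' identity target:
#' \deqn{R^* = \lambda^* I + (1 - \lambda^*) R,\qquad
#'       \lambda^* = \mathrm{clamp}\Big(
#'         \sum_{i<j} \widehat{Var}(r_{ij}) / \sum_{i<j} r_{ij}^2, [0,1]\Big)}
#' with \eqn{\widehat{Var}(r_{ij})} the standard unbiased estimate from the
#' products of standardized observations. Partial correlations come from the
#' inverse \eqn{\Omega = (R^*)^{-1}} as
#' \eqn{-\Omega_{ij} / \sqrt{\Omega_{ii}\Omega_{jj}}}; the diagonal is set
#' to 1. The shrunk matrix is positive definite whenever \eqn{\lambda^* > 0},
#' which is what makes the estimator usable with more genes than samples.
#'
#' Constant genes cannot be standardized; their rows/columns get all-zero
#' partial correlations with a warning rather than an error.
#'
#' @param x numeric matrix, k genes (rows) x n samples (columns) of
#'   log-scale expression; k >= 2, n >= 3, all finite.
#' @param lambda optional shrinkage intensity in \[0, 1\] to use instead of
#'   the estimated lambda* (mainly for closed-form checks).
#' @return A `ShrinkageEstimate`: list with `genes`, symmetric `pcor` matrix
#'   (unit diagonal, entries in \[-1, 1\]), and `lambda`.
#' @export
shrinkage_partial_correlation <- function(x, lambda = NULL) {
  if (!is.matrix(x) || !is.numeric(x)) stop("x must be a numeric matrix")
  if (any(!is.finite(x))) stop("non-finite values in expression submatrix")
  k <- nrow(x); n <- ncol(x)
  if (k < 2L) stop("need at least 2 genes")
  if (n < 3L) stop("need at least 3 samples")
  genes <- rownames(x)
  if (is.null(genes)) genes <- paste0("g", seq_len(k))

  sds <- apply(x, 1L, sd)
  const <- sds == 0
  if (any(const))
    warning(sum(const), " constant gene(s) in subset; their partial ",
            "correlations are reported as 0")
  live <- which(!const)
  pcor <- diag(1, k)
  dimnames(pcor) <- list(genes, genes)

  if (length(live) >= 2L) {
    xs <- x[live, , drop = FALSE]
    xs <- (xs - rowMeans(xs)) / sds[live]   # standardized rows
    m <- length(live)
    R <- tcrossprod(xs) / (n - 1)
    # lambda* from the variance of empirical correlations:
    # w_kij = z_ik z_jk, r_ij = n/(n-1) * mean(w), Var(r_ij) = n/(n-1)^3 * sum((w - wbar)^2)
    if (is.null(lambda)) {
      wbar <- R * (n - 1) / n
      S2 <- tcrossprod(xs^2)                # sum_k z_ik^2 z_jk^2
      varr <- n / (n - 1)^3 * (S2 - n * wbar^2)
      off <- upper.tri(R)
      denom <- sum(R[off]^2)
      lam <- if (denom > 0) sum(varr[off]) / denom else 1
      lam <- min(1, max(0, lam))
    } else {
      stopifnot(lambda >= 0, lambda <= 1)
      lam <- lambda
    }
    Rstar <- (1 - lam) * R
    diag(Rstar) <- 1
    Om <- tryCatch(solve(Rstar), error = function(e) {
      stop("shrunk correlation matrix is singular (k = ", m, " > n = ", n,
           " with lambda = 0?); use positive shrinkage", call. = FALSE)
    })
    d <- sqrt(diag(Om))
    P <- -Om / tcrossprod(d)
    P <- (P + t(P)) / 2
    diag(P) <- 1
    P[P > 1] <- 1; P[P < -1] <- -1
    pcor[live, live] <- P
  } else {
    lam <- if (is.null(lambda)) 1 else lambda
  }

  structure(list(genes = genes, pcor = pcor, lambda = lam),
            class = "ShrinkageEstimate")
}

#' @export
print.ShrinkageEstimate <- function(x, ...) {
  cat(sprintf("ShrinkageEstimate: %d genes, lambda = %.4g\n",
              length(x$genes), x$lambda))
  invisible(x)
}
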