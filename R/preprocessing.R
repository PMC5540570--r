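#' Filter lowly expressed genes
#'
#' Removes genes whose maximum FPKM across all samples falls below
#' `min_max_fpkm` (strictly; a gene whose maximum equals the threshold is
#' retained). Defined on the FPKM scale only. Gene order is preserved.
#'
#' @param m an `ExpressionMatrix` on the `fpkm` scale.
#' @param min_max_fpkm retention threshold on the per-gene maximum
#'   (default 20 FPKM).
#' @return The filtered `ExpressionMatrix`.
#' @export
filter_low_expression <- function(m, min_max_fpkm = 20) {
  if (expr_scale(m) != "fpkm")
    stop("filter_low_expression is defined on the fpkm scale, got ", expr_scale(m))
  keep <- apply(expr_values(m), 1L, max) >= min_max_fpkm
  if (!any(keep)) warning("no gene passed the expression filter")
  out <- m
  out$values <- expr_values(m)[keep, , drop = FALSE]
  out
}

#' Log-transform an FPKM matrix
#'
#' Replaces each value x by log2(x + 1), reducing the mean-variance
#' dependency typical of FPKM data before correlation analysis. Applying it
#' twice is an error (the scale tag guards it).
#'
#' @param m an `ExpressionMatrix` on the `fpkm` scale.
#' @return An `ExpressionMatrix` on the `log2p1` scale.
#' @export
log_transform <- function(m) {
  if (expr_scale(m) != "fpkm")
    stop("log_transform expects the fpkm scale, got ", expr_scale(m))
  expression_matrix(log2(expr_values(m) + 1), scale = "log2p1")
}

#' Per-gene mean-variance profile
#'
#' Ranks genes by mean expression (ascending; ties broken by gene id) and
#' reports each gene's mean, sample standard deviation, and a running-median
#' trend of the SD over a centered rank window (clipped at the boundaries).
#' Plotting SD against rank on the raw and log scales visualizes how the log
#' transform flattens the mean-variance dependency.
#'
#' @param m an `ExpressionMatrix` (either scale) with >= 2 samples.
#' @param window odd width of the centered running-median window (default 301).
#' @return data.frame with columns gene, rank, mean, sd, trend, ordered by rank.
#' @export
mean_variance_profile <- function(m, window = 301L) {
  v <- expr_values(m)
  if (ncol(v) < 2L) stop("mean_variance_profile needs >= 2 samples")
  mu <- rowMeans(v)
  s <- apply(v, 1L, sd)
  ord <- order(mu, rownames(v))          # ties broken by gene id
  n <- length(mu)
  half <- (window - 1L) %/% 2L
  s_ord <- s[ord]
  trend <- vapply(seq_len(n), function(i) {
    median(s_ord[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
  data.frame(gene = rownames(v)[ord], rank = seq_len(n),
             mean = mu[ord], sd = s_ord, trend = trend,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a mean-variance profile as TSV
#' @param profile output of [mean_variance_profile()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mean_variance_profile <- function(profile, path) {
  data.table::fwrite(profile, path, sep = "\t")
  invisible(path)
}
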