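#' Random-subset sampling plan for partial-correlation estimation
#'
#' The study-scale plan is 25,000 iterations of 2,000-gene subsets; reduced
#' plans are used for testing and small data.
#'
#' @param n_iterations number of random subsets to draw (>= 1).
#' @param subset_size genes per subset.
#' @param seed integer seed; each iteration derives its own independent
#'   stream from it, so results do not depend on execution order.
#' @return A `SamplingPlan` list.
#' @export
sampling_plan <- function(n_iterations = 25000L, subset_size = 2000L, seed = 1L) {
  stopifnot(n_iterations >= 1L, subset_size >= 2L)
  structure(list(n_iterations = as.integer(n_iterations),
                 subset_size = as.integer(subset_size),
                 seed = as.integer(seed)),
            class = "SamplingPlan")
}

# min-|.|-with-sign aggregation of a new pcor observation onto the current
# one; NA means "never co-sampled yet". Strict < keeps the earliest
# observation on ties (including opposite-sign ties), so aggregation is
# deterministic in iteration order.
update_min_abs <- function(current, new) {
  repl <- is.na(current) | (abs(new) < abs(current))
  current[repl] <- new[repl]
  current
}

#' Aggregated partial correlations over random gene subsets
#'
#' The estimator at the heart of the network construction. Each iteration
#' draws `subset_size` genes uniformly without replacement (from an
#' iteration-indexed seeded stream), computes the shrinkage partial
#' correlations of the subset, and records them for every co-sampled pair.
#' After all iterations a pair's aggregated Pcor is the recorded value of
#' minimum absolute value with its sign kept — a conservative choice that
#' suppresses partial correlations that are only high in some conditioning
#' subsets. Pairs never co-sampled get Pcor 0 and count 0.
#'
#' @param m an `ExpressionMatrix` on the `log2p1` scale.
#' @param plan a [sampling_plan()]; `subset_size` must not exceed the gene
#'   count.
#' @param min_expected_cosampling warn if the expected number of times a
#'   pair is co-sampled, `n_iterations * (s/g) * ((s-1)/(g-1))`, falls below
#'   this floor.
#' @return A `PairAssociation`: list with `genes`, symmetric `pcor` and
#'   integer `times_cosampled` matrices (zero diagonal), scalar `coverage`
#'   (fraction of pairs co-sampled at least once), and the `plan`.
#' @export
sampled_pcor_estimation <- function(m, plan, min_expected_cosampling = 1) {
  if (expr_scale(m) != "log2p1")
    stop("sampled_pcor_estimation expects the log2p1 scale, got ", expr_scale(m))
  x <- expr_values(m)
  g <- nrow(x)
  s <- plan$subset_size
  if (s > g) stop("subset_size (", s, ") exceeds number of genes (", g, ")")
  expected <- plan$n_iterations * (s / g) * ((s - 1) / (g - 1))
  if (expected < min_expected_cosampling)
    warning(sprintf(
      "expected co-sampling count per pair is %.3g (< %g); increase iterations or subset size",
      expected, min_expected_cosampling))

  agg <- matrix(NA_real_, g, g)
  times <- matrix(0L, g, g)
  for (it in seq_len(plan$n_iterations)) {
    idx <- sort(with_seed(derive_seed(plan$seed, paste0("iter", it)),
                          sample.int(g, s)))
    est <- shrinkage_partial_correlation(x[idx, , drop = FALSE])
    agg[idx, idx] <- update_min_abs(agg[idx, idx], est$pcor)
    times[idx, idx] <- times[idx, idx] + 1L
  }
  diag(times) <- 0L
  off <- upper.tri(agg)
  coverage <- mean(times[off] >= 1L)
  agg[is.na(agg)] <- 0
  diag(agg) <- 1
  dimnames(agg) <- dimnames(times) <- list(rownames(x), rownames(x))
  structure(list(genes = rownames(x), pcor = agg, times_cosampled = times,
                 coverage = coverage, plan = plan),
            class = "PairAssociation")
}

#' @export
print.PairAssociation <- function(x, ...) {
  cat(sprintf(
    "PairAssociation: %d genes, %d iterations x %d-gene subsets, coverage %.1f%%\n",
    length(x$genes), x$plan$n_iterations, x$plan$subset_size,
    100 * x$coverage))
  invisible(x)
}

#' Pearson correlations between genes
#'
#' Standard Pearson r between rows of the (log-scale) expression matrix.
#' Constant genes have undefined correlations; these are reported as 0 with
#' a warning.
#'
#' @param m an `ExpressionMatrix` with >= 3 samples.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_correlation <- function(m) {
  v <- expr_values(m)
  if (ncol(v) < 3L) stop("pearson_correlation needs >= 3 samples")
  const <- apply(v, 1L, sd) == 0
  r <- suppressWarnings(cor(t(v)))
  if (any(const)) {
    warning(sum(const), " constant gene(s); their correlations are reported as 0")
    r[const, ] <- 0
    r[, const] <- 0
  }
  diag(r) <- 1
  r
}

#' Select signed network edges from Pcor and PCC
#'
#' A gene pair becomes an edge iff its aggregated partial correlation and
#' Pearson correlation agree in sign and both clear their thresholds:
#' positive edge when `pcor >= pcor_threshold & pcc >= pcc_threshold`,
#' negative edge when `pcor <= -pcor_threshold & pcc <= -pcc_threshold`.
#' The edge sign is the sign of the Pcor.
#'
#' @param assoc a `PairAssociation` from [sampled_pcor_estimation()].
#' @param pcc Pearson correlation matrix over the same genes
#'   (from [pearson_correlation()]).
#' @param pcor_threshold Pcor magnitude threshold (default 0.035).
#' @param pcc_threshold PCC magnitude threshold (default 0.35).
#' @return A `SignedNetwork` (see [build_network()]) whose
#'   `attr(, "n_positive")` / `attr(, "n_negative")` report the selected
#'   counts by sign.
#' @export
select_edges <- function(assoc, pcc, pcor_threshold = 0.035,
                         pcc_threshold = 0.35) {
  stopifnot(inherits(assoc, "PairAssociation"),
            pcor_threshold > 0, pcor_threshold < 1,
            pcc_threshold > 0, pcc_threshold < 1)
  if (!identical(assoc$genes, rownames(pcc)))
    pcc <- pcc[assoc$genes, assoc$genes]
  P <- assoc$pcor
  off <- upper.tri(P)
  pos <- off & P >= pcor_threshold & pcc >= pcc_threshold
  neg <- off & P <= -pcor_threshold & pcc <= -pcc_threshold
  sel <- which(pos | neg, arr.ind = TRUE)
  edges <- data.frame(
    gene_a = assoc$genes[sel[, 1L]],
    gene_b = assoc$genes[sel[, 2L]],
    sign = ifelse(P[sel] > 0, 1L, -1L),
    pcor = P[sel],
    pcc = pcc[sel],
    stringsAsFactors = FALSE)
  net <- build_network(edges)
  attr(net, "n_positive") <- sum(pos)
  attr(net, "n_negative") <- sum(neg)
  net
}

#' Pair-association table
#'
#' Long-format view of a `PairAssociation`: one row per unordered gene pair
#' that was co-sampled at least once, with `gene_a < gene_b`
#' lexicographically.
#'
#' @param assoc a `PairAssociation`.
#' @param pcc optional Pearson correlation matrix to add a `pcc` column.
#' @return data.frame(gene_a, gene_b, pcor, \[pcc,\] times_cosampled).
#' @export
pair_association_table <- function(assoc, pcc = NULL) {
  idx <- which(upper.tri(assoc$times_cosampled) & assoc$times_cosampled >= 1L,
               arr.ind = TRUE)
  cp <- canonical_pairs(assoc$genes[idx[, 1L]], assoc$genes[idx[, 2L]])
  out <- data.frame(gene_a = cp$gene_a, gene_b = cp$gene_b,
                    pcor = assoc$pcor[idx],
                    times_cosampled = assoc$times_cosampled[idx],
                    stringsAsFactors = FALSE)
  if (!is.null(pcc)) {
    pcc <- pcc[assoc$genes, assoc$genes]
    out$pcc <- pcc[idx]
    out <- out[, c("gene_a", "gene_b", "pcor", "pcc", "times_cosampled")]
  }
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}
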