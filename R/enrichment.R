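#' GO-term over-representation in a gene module
#'
#' One-sided hypergeometric test per annotation term: with a universe of N
#' genes of which K carry the term, and a module of n genes of which k carry
#' it, the p-value is P(X >= k) for X ~ Hypergeometric(N, K, n). Terms with
#' no hit in the module are omitted. P-values are Benjamini-Hochberg
#' adjusted across the terms tested within the module and results are sorted
#' by ascending p. Annotations are taken as given; if GO-graph ancestor
#' propagation is wanted it must be applied to the table beforehand.
#'
#' @param module_genes character vector, a subset of `universe`.
#' @param universe character vector of background genes (non-empty).
#' @param annotations data.frame with columns `gene`, `term`.
#' @return data.frame(term, k, n, K, N, p_value, p_adjusted), sorted by
#'   `p_value`.
#' @export
go_enrichment <- function(module_genes, universe, annotations) {
  if (length(universe) == 0L) stop("empty universe")
  stopifnot(is.data.frame(annotations),
            all(c("gene", "term") %in% names(annotations)))
  if (!all(module_genes %in% universe))
    stop("module_genes must be a subset of the universe")
  ann <- annotations[annotations$gene %in% universe, , drop = FALSE]
  ann <- unique(ann[, c("gene", "term")])
  N <- length(unique(universe))
  n <- length(unique(module_genes))
  K_all <- table(ann$term)
  in_mod <- ann[ann$gene %in% module_genes, , drop = FALSE]
  if (nrow(in_mod) == 0L)
    return(data.frame(term = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p_value = numeric(),
                      p_adjusted = numeric(), stringsAsFactors = FALSE))
  k_tab <- table(in_mod$term)
  terms <- names(k_tab)
  k <- as.integer(k_tab)
  K <- as.integer(K_all[terms])
  p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term = terms, k = k, n = n, K = K, N = N,
                    p_value = p, p_adjusted = p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

IUPAC_CLASSES <- c(A = "A", C = "C", G = "G", T = "T",
                   R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
                   K = "[GT]", M = "[AC]",
                   B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]",
                   N = "[ACGT]")

iupac_to_regex <- function(motif) {
  chars <- strsplit(toupper(motif), "")[[1L]]
  if (length(chars) == 0L) stop("empty motif")
  bad <- setdiff(chars, names(IUPAC_CLASSES))
  if (length(bad)) stop("invalid IUPAC letter in motif: ", bad[[1L]])
  paste0(IUPAC_CLASSES[chars], collapse = "")
}

reverse_complement <- function(seqs) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}

count_overlapping <- function(seqs, regex) {
  hits <- gregexpr(paste0("(?=", regex, ")"), seqs, perl = TRUE)
  vapply(hits, function(h) if (h[[1L]] == -1L) 0L else length(h), integer(1))
}

#' Count IUPAC motif occurrences in promoter sequences
#'
#' Scans each promoter on both strands: occurrences of the degenerate motif
#' in the sequence plus occurrences in its reverse complement. Overlapping
#' matches are counted. Ambiguity codes expand only in the motif; an `N` in
#' the promoter sequence never matches.
#'
#' @param promoters named character vector or `Biostrings::DNAStringSet` of
#'   promoter sequences (alphabet ACGTN), keyed by gene id.
#' @param motif IUPAC pattern string (letters ACGTRYSWKMBDHVN).
#' @return Named integer vector of hit counts per gene.
#' @export
scan_promoters <- function(promoters, motif) {
  if (inherits(promoters, "DNAStringSet"))
    promoters <- setNames(as.character(promoters), names(promoters))
  stopifnot(is.character(promoters))
  regex <- iupac_to_regex(motif)
  seqs <- toupper(promoters)
  fwd <- count_overlapping(seqs, regex)
  nonempty <- nchar(seqs) > 0L
  rev_counts <- integer(length(seqs))
  if (any(nonempty))
    rev_counts[nonempty] <- count_overlapping(reverse_complement(seqs[nonempty]), regex)
  setNames(fwd + rev_counts, names(promoters))
}

#' Promoter-motif enrichment in a module by binomial test
#'
#' A gene "has the motif" iff its promoter hit count is >= 1. With p0 the
#' fraction of universe genes having the motif and k of the n module genes
#' having it, the p-value is the binomial upper tail P(X >= k),
#' X ~ Binomial(n, p0).
#'
#' @param module_genes character vector, subset of `universe`.
#' @param hits named integer vector of per-gene motif hit counts (from
#'   [scan_promoters()]), defined on the universe.
#' @param universe character vector of background genes.
#' @return list(k, n, p0, p_value).
#' @export
motif_enrichment <- function(module_genes, hits, universe) {
  if (!all(module_genes %in% universe))
    stop("module_genes must be a subset of the universe")
  if (!all(universe %in% names(hits)))
    stop("hits must be defined for every universe gene")
  has <- hits[universe] >= 1L
  p0 <- mean(has)
  n <- length(module_genes)
  k <- sum(has[module_genes])
  if (p0 == 0 && k > 0) {
    warning("motif absent from the universe but present in the module; ",
            "inconsistent universe, reporting the smallest representable p")
    return(list(k = k, n = n, p0 = p0, p_value = .Machine$double.xmin))
  }
  list(k = k, n = n, p0 = p0,
       p_value = pbinom(k - 1L, n, p0, lower.tail = FALSE))
}
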