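# Independent oracles used across tests. These deliberately share no code
# with the package implementations they check.

# Naive dense-matrix MCL: textbook alternation of expansion and inflation
# with no pruning, clusters read from attractor rows.
ref_mcl <- function(adj, inflation = 1.5, tol = 1e-12, maxit = 1000) {
  diag(adj) <- 1
  M <- sweep(adj, 2, colSums(adj), "/")
  for (i in seq_len(maxit)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2 <- sweep(M2, 2, colSums(M2), "/")
    if (max(abs(M2 - M)) < tol) { M <- M2; break }
    M <- M2
  }
  attractors <- which(diag(M) > 1e-8)
  sets <- lapply(attractors, function(a) which(M[a, ] > 1e-8))
  # merge overlapping attractor systems
  changed <- TRUE
  while (changed && length(sets) > 1) {
    changed <- FALSE
    for (i in seq_along(sets)) {
      for (j in seq_along(sets)) {
        if (i < j && length(intersect(sets[[i]], sets[[j]]))) {
          sets[[i]] <- union(sets[[i]], sets[[j]])
          sets[[j]] <- integer(0)
          changed <- TRUE
        }
      }
    }
    sets <- sets[lengths(sets) > 0]
  }
  lab <- rep(NA_integer_, nrow(adj))
  for (i in seq_along(sets)) lab[sets[[i]]] <- i
  lab
}

# AUROC by exhaustive pairwise comparison (ties count 1/2)
brute_auroc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Hypergeometric upper tail by enumerating every size-n draw from the
# universe (feasible for N <= 25 with small n)
brute_hyper_tail <- function(N, K, n, k) {
  draws <- combn(N, n)
  special <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% special))
  mean(hits >= k)
}

# Binomial upper tail by enumerating all 2^n outcomes
brute_binom_tail <- function(n, p0, k) {
  tot <- 0
  for (code in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(code))[1:n]
    s <- sum(bits)
    if (s >= k) tot <- tot + p0^s * (1 - p0)^(n - s)
  }
  tot
}

# label vector over all genes: unassigned genes become singletons so ARI
# penalizes both lost genes and merged modules
full_labels <- function(modules, genes) {
  lab <- stats::setNames(rep(NA_integer_, length(genes)), genes)
  common <- intersect(genes, names(modules$membership))
  lab[common] <- modules$membership[common]
  un <- which(is.na(lab))
  if (length(un)) lab[un] <- max(c(0L, lab), na.rm = TRUE) + seq_along(un)
  lab
}

truth_labels <- function(model, genes) {
  tru <- model$true_modules[genes]
  bg <- which(tru == 0)
  if (length(bg)) tru[bg] <- max(tru) + seq_along(bg)
  tru
}

# data whose sample correlation matrix is EXACTLY R: orthonormal mean-zero
# scores mixed through chol(R)
exact_corr_data <- function(R, n, seed = 1) {
  k <- nrow(R)
  set.seed(seed)
  A <- matrix(rnorm(n * k), n, k)
  A <- sweep(A, 2, colMeans(A))
  Q <- qr.Q(qr(A))
  X <- Q %*% chol(R)
  t(X)   # genes x samples
}

clique_edges <- function(genes) {
  p <- t(combn(genes, 2))
  data.frame(gene_a = p[, 1], gene_b = p[, 2], stringsAsFactors = FALSE)
}
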