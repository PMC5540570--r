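#' MCL parameter set
#'
#' Parameters of the Markov cluster algorithm as used for gene module
#' detection. Inflation 1.5 is the coarse-granularity setting used for
#' co-expression networks; the pruning bounds keep the iteration matrix
#' sparse at large scale without changing desk-scale fixed points.
#'
#' @param inflation elementwise power applied each iteration (> 1).
#' @param expansion matrix power applied each iteration (integer >= 2).
#' @param prune_threshold per-column entries below this are dropped.
#' @param max_per_column keep at most this many largest entries per column.
#' @param convergence_tol stop when the max absolute change of the
#'   iteration matrix falls below this.
#' @param max_iterations iteration cap; non-convergence at the cap returns
#'   the current clustering with a warning.
#' @param min_module_size modules below this size are set aside as
#'   `small_module_genes` rather than numbered.
#' @return An `MCLParams` list.
#' @export
mcl_params <- function(inflation = 1.5, expansion = 2L,
                       prune_threshold = 1e-6, max_per_column = 1500L,
                       convergence_tol = 1e-8, max_iterations = 200L,
                       min_module_size = 5L) {
  stopifnot(inflation > 1, expansion >= 2L, prune_threshold > 0,
            max_per_column >= 1L, convergence_tol > 0, max_iterations >= 1L,
            min_module_size >= 1L)
  structure(list(inflation = inflation, expansion = as.integer(expansion),
                 prune_threshold = prune_threshold,
                 max_per_column = as.integer(max_per_column),
                 convergence_tol = convergence_tol,
                 max_iterations = as.integer(max_iterations),
                 min_module_size = as.integer(min_module_size)),
            class = "MCLParams")
}

col_normalize <- function(M) {
  cs <- Matrix::colSums(M)
  cs[cs == 0] <- 1
  M %*% Matrix::Diagonal(x = 1 / cs)
}

# drop entries < thr per column, keep at most maxk largest, renormalize
prune_columns <- function(M, thr, maxk) {
  tr <- Matrix::summary(M)
  keep <- tr$x >= thr
  tr <- tr[keep, , drop = FALSE]
  if (maxk < nrow(M)) {
    ord <- order(tr$j, -tr$x)
    tr <- tr[ord, , drop = FALSE]
    within_rank <- stats::ave(tr$x, tr$j, FUN = seq_along)
    tr <- tr[within_rank <= maxk, , drop = FALSE]
  }
  out <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                              dims = dim(M), dimnames = dimnames(M))
  col_normalize(out)
}

#' Markov clustering of a gene network
#'
#' Runs MCL on the unweighted, sign-blind adjacency matrix with unit
#' self-loops: column-normalize, then alternate expansion (matrix power)
#' and inflation (elementwise power with column renormalization), with
#' per-column pruning, until the iteration matrix stops changing. Clusters
#' are read off the limit matrix's attractors (rows with positive diagonal):
#' each gene joins the cluster of the attractor(s) its column flows to, with
#' overlapping attractor systems merged; a gene reachable from several
#' clusters goes to the larger one (tie: smaller module id). Modules below
#' `min_module_size` are set aside, and surviving modules are renumbered
#' 1, 2, ... by descending size (ties by smallest member gene id).
#'
#' @param net a non-empty `SignedNetwork`.
#' @param params an [mcl_params()] object.
#' @return A `ModuleAssignment`: list with `membership` (named integer
#'   vector over retained genes), `small_module_genes` (character),
#'   `module_sizes` (named integer, by module id), `converged`,
#'   `n_iterations`, and `max_colsum_dev` (worst deviation of any column sum
#'   from 1 observed after an iteration's renormalization).
#' @export
mcl_cluster <- function(net, params = mcl_params()) {
  stopifnot(inherits(net, "SignedNetwork"))
  n <- length(net$nodes)
  if (n == 0L) stop("empty network")
  ia <- match(net$edges$gene_a, net$nodes)
  ib <- match(net$edges$gene_b, net$nodes)
  A <- Matrix::sparseMatrix(i = c(ia, ib, seq_len(n)),
                            j = c(ib, ia, seq_len(n)),
                            x = 1, dims = c(n, n),
                            dimnames = list(net$nodes, net$nodes))
  M <- col_normalize(A)
  converged <- FALSE
  dev <- 0
  it <- 0L
  while (it < params$max_iterations) {
    it <- it + 1L
    Mexp <- M
    for (e in seq_len(params$expansion - 1L)) Mexp <- Mexp %*% M
    Minf <- Mexp
    Minf@x <- Minf@x^params$inflation
    Minf <- col_normalize(Minf)
    dev <- max(dev, max(abs(Matrix::colSums(Minf) - 1)))
    Mnew <- prune_columns(Minf, params$prune_threshold, params$max_per_column)
    delta <- max(abs(Mnew - M))
    M <- Mnew
    if (delta < params$convergence_tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge in ", params$max_iterations,
            " iterations; returning current clustering")

  eps <- params$prune_threshold
  dg <- Matrix::diag(M)
  attractors <- which(dg > eps)
  tr <- Matrix::summary(M)
  tr <- tr[tr$x > eps & tr$i %in% attractors, , drop = FALSE]

  # merge attractors that co-occur in any column's support (union-find)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  supports <- split(tr$i, tr$j)
  for (sup in supports) {
    if (length(sup) > 1L) {
      r <- find(sup[[1L]])
      for (k in sup[-1L]) { rk <- find(k); if (rk != r) parent[rk] <- r }
    }
  }
  att_cluster <- vapply(attractors, find, integer(1))
  cluster_ids <- sort(unique(att_cluster))
  cl_index <- match(att_cluster, cluster_ids)      # attractor -> provisional cluster
  names(cl_index) <- as.character(attractors)

  # candidate clusters per node; node in several clusters -> larger
  # (tie -> smaller provisional id)
  node_cl <- rep(NA_integer_, n)
  cand <- lapply(split(cl_index[as.character(tr$i)], tr$j), unique)
  # provisional sizes counting each node once toward each candidate cluster
  prov_sizes <- tabulate(unlist(cand, use.names = FALSE), nbins = length(cluster_ids))
  for (jc in names(cand)) {
    cl <- cand[[jc]]
    if (length(cl) > 1L) {
      sz <- prov_sizes[cl]
      cl <- cl[order(-sz, cl)][1L]
    }
    node_cl[as.integer(jc)] <- cl
  }
  # nodes whose column support held no attractor (can happen before
  # convergence): leave unassigned -> small_module_genes
  assigned <- which(!is.na(node_cl))

  members <- split(net$nodes[assigned], node_cl[assigned])
  sizes <- vapply(members, length, integer(1))
  keep <- sizes >= params$min_module_size
  small <- c(net$nodes[is.na(node_cl)],
             unlist(members[!keep], use.names = FALSE))
  members <- members[keep]
  if (length(members)) {
    first_gene <- vapply(members, function(g) min(g), character(1))
    ord <- order(-vapply(members, length, integer(1)), first_gene)
    members <- members[ord]
  }
  membership <- setNames(rep(seq_along(members), lengths(members)),
                         unlist(members, use.names = FALSE))
  module_sizes <- setNames(lengths(members), seq_along(members))
  structure(list(membership = membership,
                 small_module_genes = sort(small),
                 module_sizes = module_sizes,
                 converged = converged, n_iterations = it,
                 max_colsum_dev = dev),
            class = "ModuleAssignment")
}

#' @export
print.ModuleAssignment <- function(x, ...) {
  cat(sprintf("ModuleAssignment: %d modules (>= min size), %d genes retained, %d in small modules\n",
              length(x$module_sizes), length(x$membership),
              length(x$small_module_genes)))
  invisible(x)
}

#' Write a module table as TSV
#'
#' Two columns (gene, module_id); genes from sub-minimum-size modules are
#' written with module_id 0.
#'
#' @param modules a `ModuleAssignment`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_modules <- function(modules, path) {
  dt <- data.frame(
    gene = c(names(modules$membership), modules$small_module_genes),
    module_id = c(unname(modules$membership),
                  rep(0L, length(modules$small_module_genes))),
    stringsAsFactors = FALSE)
  dt <- dt[order(dt$module_id, dt$gene), , drop = FALSE]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
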