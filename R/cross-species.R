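#' Conserved-interaction flags across two networks
#'
#' A gene g of `net1` has a conserved interaction if, taking A = its
#' neighbors in `net1` and B = the union of the neighbors (in `net2`) of all
#' of g's homologs present in `net2`, some gene of A has a homolog in B.
#' Genes without a homolog node in `net2`, or with empty A or B, are not
#' conserved. Many-to-many homolog pairs are all honored.
#'
#' @param net1,net2 `SignedNetwork` objects.
#' @param homolog_map data.frame with columns `gene_a` (net1 species) and
#'   `gene_b` (net2 species); duplicates ignored.
#' @return data.frame(gene, has_homolog, conserved) over `net1`'s nodes.
#' @export
conserved_interactions <- function(net1, net2, homolog_map) {
  stopifnot(is.data.frame(homolog_map),
            all(c("gene_a", "gene_b") %in% names(homolog_map)))
  map <- unique(data.frame(gene_a = as.character(homolog_map$gene_a),
                           gene_b = as.character(homolog_map$gene_b),
                           stringsAsFactors = FALSE))
  homs_of <- split(map$gene_b, map$gene_a)   # net1 gene -> net2 homologs
  nb1 <- neighbor_list(net1)
  nb2 <- neighbor_list(net2)
  genes <- net1$nodes
  has_homolog <- logical(length(genes))
  conserved <- logical(length(genes))
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    homs <- intersect(homs_of[[g]], net2$nodes)
    if (length(homs) == 0L) next
    has_homolog[[i]] <- TRUE
    A <- nb1[[g]]
    if (length(A) == 0L) next
    B <- unique(unlist(nb2[homs], use.names = FALSE))
    if (length(B) == 0L) next
    for (a in A) {
      if (length(intersect(homs_of[[a]], B))) { conserved[[i]] <- TRUE; break }
    }
  }
  data.frame(gene = genes, has_homolog = has_homolog, conserved = conserved,
             stringsAsFactors = FALSE)
}

#' Per-module conservation percentages
#'
#' For each module, the percentage of its genes flagged as having conserved
#' interactions, plus the network-wide percentage. By default every module
#' gene counts in the denominator, including genes without a homolog; set
#' `homologs_only = TRUE` to restrict denominators to genes with a homolog.
#'
#' @param flags data.frame from [conserved_interactions()] covering all
#'   module genes.
#' @param modules a `ModuleAssignment` (from [mcl_cluster()]).
#' @param homologs_only denominator switch (default `FALSE`).
#' @return A `ConservationReport`: list with `per_module`
#'   (data.frame module_id, n_genes, n_conserved, percent_conserved) and
#'   `network_wide_percent` (over all flagged genes).
#' @export
module_conservation <- function(flags, modules, homologs_only = FALSE) {
  stopifnot(inherits(modules, "ModuleAssignment"))
  genes <- names(modules$membership)
  miss <- setdiff(genes, flags$gene)
  if (length(miss))
    stop("flags missing for module gene(s), e.g. ", miss[[1L]])
  cons <- setNames(flags$conserved, flags$gene)
  hom <- setNames(flags$has_homolog, flags$gene)
  denom_ok <- if (homologs_only) hom else setNames(rep(TRUE, nrow(flags)), flags$gene)
  per <- lapply(split(genes, modules$membership[genes]), function(gs) {
    d <- sum(denom_ok[gs])
    k <- sum(cons[gs])
    c(n_genes = length(gs), n_denominator = d, n_conserved = k,
      percent_conserved = if (d > 0) 100 * k / d else 0)
  })
  per_module <- data.frame(module_id = as.integer(names(per)),
                           do.call(rbind, per), row.names = NULL)
  per_module <- per_module[order(per_module$module_id), , drop = FALSE]
  d_all <- sum(if (homologs_only) flags$has_homolog else rep(TRUE, nrow(flags)))
  structure(list(per_module = per_module,
                 network_wide_percent =
                   if (d_all > 0) 100 * sum(flags$conserved) / d_all else 0),
            class = "ConservationReport")
}

#' @export
print.ConservationReport <- function(x, ...) {
  cat(sprintf("ConservationReport: %d modules, network-wide %.1f%% conserved\n",
              nrow(x$per_module), x$network_wide_percent))
  invisible(x)
}

#' Read / write a two-column homolog map TSV
#' @param path file path.
#' @param homolog_map data.frame(gene_a, gene_b).
#' @return `read_homolog_map`: data.frame(gene_a, gene_b);
#'   `write_homolog_map`: `path`, invisibly.
#' @export
read_homolog_map <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          colClasses = "character")
  names(dt)[1:2] <- c("gene_a", "gene_b")
  dt
}

#' @rdname read_homolog_map
#' @export
write_homolog_map <- function(homolog_map, path) {
  data.table::fwrite(homolog_map[, c("gene_a", "gene_b")], path, sep = "\t")
  invisible(path)
}
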