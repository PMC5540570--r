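#' Module mean-expression profiles over ordered sample groups
#'
#' For each retained module and each sample group, the mean of the (log
#' scale by default) expression values over the module's genes and the
#' group's samples; plus relative values obtained by dividing each module
#' row by its maximum (an all-zero row stays all zero). Group order is
#' taken from the `groups` table, e.g. successive leaf segments.
#'
#' @param m an `ExpressionMatrix` (log2p1 scale expected by default; pass
#'   `require_log = FALSE` to profile raw FPKM).
#' @param modules a `ModuleAssignment`.
#' @param groups data.frame(sample_id, group_label, group_order); sample ids
#'   must exist in the matrix.
#' @param require_log guard that the matrix is on the log2p1 scale.
#' @return A `ModuleProfile`: list with `means` and `relative` matrices
#'   (modules x groups, group columns in `group_order`).
#' @export
module_mean_expression <- function(m, modules, groups, require_log = TRUE) {
  stopifnot(inherits(modules, "ModuleAssignment"),
            all(c("sample_id", "group_label", "group_order") %in% names(groups)))
  if (require_log && expr_scale(m) != "log2p1")
    stop("expected log2p1 scale; pass require_log = FALSE to profile raw FPKM")
  if (!all(groups$sample_id %in% sample_ids(m)))
    stop("groups reference sample ids missing from the matrix")
  v <- expr_values(m)
  glabs <- unique(groups[order(groups$group_order), "group_label"])
  mod_ids <- as.integer(names(modules$module_sizes))
  means <- matrix(NA_real_, length(mod_ids), length(glabs),
                  dimnames = list(mod_ids, glabs))
  drop_rows <- logical(length(mod_ids))
  for (i in seq_along(mod_ids)) {
    gs <- names(modules$membership)[modules$membership == mod_ids[[i]]]
    present <- intersect(gs, rownames(v))
    if (length(present) < length(gs))
      warning("module ", mod_ids[[i]], ": ", length(gs) - length(present),
              " gene(s) missing from the matrix, dropped")
    if (length(present) == 0L) {
      warning("module ", mod_ids[[i]], " has no gene in the matrix; row omitted")
      drop_rows[[i]] <- TRUE
      next
    }
    for (gl in glabs) {
      smp <- groups$sample_id[groups$group_label == gl]
      means[i, gl] <- mean(v[present, smp, drop = FALSE])
    }
  }
  means <- means[!drop_rows, , drop = FALSE]
  rmax <- apply(means, 1L, max)
  relative <- means / ifelse(rmax > 0, rmax, 1)
  structure(list(means = means, relative = relative), class = "ModuleProfile")
}

#' Write a module profile as wide TSV
#' @param profile a `ModuleProfile`.
#' @param path file path.
#' @param what `"relative"` (default) or `"means"`.
#' @return `path`, invisibly.
#' @export
write_module_profile <- function(profile, path, what = c("relative", "means")) {
  what <- match.arg(what)
  mat <- profile[[what]]
  dt <- data.table::data.table(module_id = rownames(mat))
  for (cn in colnames(mat)) dt[[cn]] <- mat[, cn]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Neighbor-voting evaluation of a network against gene sets
#'
#' Guilt-by-association check of network quality: for each gene set S, every
#' network gene of degree >= 1 is scored by the fraction of its neighbors
#' belonging to S (itself excluded), and the AUROC measures whether members
#' of S outscore non-members (mid-rank tie handling; leave-one-out, no fold
#' partition). Sets with fewer than 2 members among scored genes, or with no
#' negatives, are skipped with a warning.
#'
#' @param net a `SignedNetwork`.
#' @param gene_sets named list of character vectors.
#' @return data.frame(set, auroc, n_positives, n_scored), one row per
#'   evaluable set.
#' @export
neighbor_voting_auroc <- function(net, gene_sets) {
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  nb <- neighbor_list(net)
  scored <- net$nodes[vapply(nb[net$nodes], length, integer(1)) >= 1L]
  res <- lapply(names(gene_sets), function(nm) {
    S <- unique(gene_sets[[nm]])
    pos <- scored %in% S
    if (sum(pos) < 2L) {
      warning("gene set '", nm, "' has < 2 members among scored genes; skipped")
      return(NULL)
    }
    if (all(pos)) {
      warning("gene set '", nm, "' covers all scored genes (no negatives); skipped")
      return(NULL)
    }
    scores <- vapply(scored, function(g) {
      ngb <- nb[[g]]
      sum(ngb %in% setdiff(S, g)) / length(ngb)
    }, numeric(1))
    data.frame(set = nm, auroc = auroc(scores, pos),
               n_positives = sum(pos), n_scored = length(scored),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(set = character(), auroc = numeric(),
                      n_positives = integer(), n_scored = integer(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
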