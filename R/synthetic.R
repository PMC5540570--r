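#' Module assignment from a label vector
#'
#' Packs a named gene -> module-label vector into the `ModuleAssignment`
#' structure used across the package (modules renumbered 1, 2, ... by
#' descending size, ties by smallest member gene id; labels 0 or NA mean
#' unassigned). Used to treat planted ground-truth modules the same way as
#' MCL output.
#'
#' @param labels named vector of module labels per gene.
#' @param min_module_size modules below this size go to
#'   `small_module_genes` (default 1, i.e. keep all).
#' @return A `ModuleAssignment`.
#' @export
module_assignment <- function(labels, min_module_size = 1L) {
  stopifnot(!is.null(names(labels)))
  assigned <- !is.na(labels) & labels != 0
  members <- split(names(labels)[assigned], labels[assigned])
  keep <- lengths(members) >= min_module_size
  small <- c(names(labels)[!assigned], unlist(members[!keep], use.names = FALSE))
  members <- members[keep]
  if (length(members)) {
    first_gene <- vapply(members, min, character(1))
    members <- members[order(-lengths(members), first_gene)]
  }
  membership <- setNames(rep(seq_along(members), lengths(members)),
                         unlist(members, use.names = FALSE))
  structure(list(membership = membership,
                 small_module_genes = sort(small),
                 module_sizes = setNames(lengths(members), seq_along(members)),
                 converged = NA, n_iterations = NA_integer_,
                 max_colsum_dev = NA_real_),
            class = "ModuleAssignment")
}

#' Planted-module Gaussian graphical model
#'
#' Constructs a block-structured precision matrix: genes are grouped into
#' `n_modules` modules of `module_size` genes; within each module the
#' conditional-dependence pattern is a ring plus random chords (sparse, as a
#' GGM's edge set should be — a full-clique precision block would be near
#' singular at realistic magnitudes), with off-diagonal precision entries
#' set so the standardized partial correlation of every planted edge is
#' approximately `within_pcor`. Between-module entries are exactly zero, and
#' genes beyond the modules are independent. Positive definiteness is
#' repaired, when needed, by adding `delta * I` with
#' `delta = max(0, 1e-3 - lambda_min)` (a message reports it); the repair
#' shrinks planted partial correlations by the factor `1/(1 + delta)`.
#'
#' @param n_genes total gene count; `n_modules * module_size <= n_genes`.
#' @param n_modules number of planted modules.
#' @param module_size genes per module (>= 2).
#' @param within_pcor target partial-correlation magnitude of planted edges
#'   (0 gives an identity precision and no edges).
#' @param seed integer seed (chord placement).
#' @param n_chords random chords added to each module's ring (default
#'   `round(module_size / 2)`, giving mean within-module degree about 3).
#' @return A `PlantedModel`: list with `n_genes`, `module_sizes`,
#'   `within_pcor`, `precision` (named matrix), `true_edges`
#'   (data.frame gene_a, gene_b), `true_modules` (named integer, 0 for
#'   background genes), `seed`.
#' @export
generate_planted_model <- function(n_genes, n_modules, module_size,
                                   within_pcor, seed = 1L,
                                   n_chords = round(module_size / 2)) {
  stopifnot(n_modules >= 0, module_size >= 2, abs(within_pcor) < 1)
  if (n_modules * module_size > n_genes)
    stop("n_modules * module_size exceeds n_genes")
  genes <- sprintf("g%0*d", nchar(n_genes), seq_len(n_genes))
  Om <- diag(1, n_genes)
  dimnames(Om) <- list(genes, genes)
  modules <- setNames(rep(0L, n_genes), genes)
  ea <- integer(0); eb <- integer(0)
  with_seed(derive_seed(seed, "chords"), {
    for (m in seq_len(n_modules)) {
      idx <- ((m - 1L) * module_size + 1L):(m * module_size)
      modules[idx] <- m
      if (module_size == 2L) {
        pairs <- cbind(idx[1L], idx[2L])
      } else {
        ring <- cbind(idx, idx[c(2:module_size, 1L)])
        npair <- module_size * (module_size - 1L) / 2
        nch <- min(n_chords, npair - nrow(ring))
        chords <- NULL
        if (nch > 0) {
          all_pairs <- t(combn(idx, 2L))
          key <- paste(pmin(all_pairs[, 1], all_pairs[, 2]),
                       pmax(all_pairs[, 1], all_pairs[, 2]))
          ring_key <- paste(pmin(ring[, 1], ring[, 2]),
                            pmax(ring[, 1], ring[, 2]))
          free <- all_pairs[!(key %in% ring_key), , drop = FALSE]
          chords <- free[sample.int(nrow(free), nch), , drop = FALSE]
        }
        pairs <- rbind(ring, chords)
      }
      ea <- c(ea, pairs[, 1L]); eb <- c(eb, pairs[, 2L])
    }
  })
  if (within_pcor != 0 && length(ea)) {
    for (k in seq_along(ea)) {
      Om[ea[[k]], eb[[k]]] <- -within_pcor
      Om[eb[[k]], ea[[k]]] <- -within_pcor
    }
  }
  lmin <- min(eigen(Om, symmetric = TRUE, only.values = TRUE)$values)
  delta <- max(0, 1e-3 - lmin)
  if (delta > 0) {
    message(sprintf("precision repaired: + %.4g * I (lambda_min was %.4g)",
                    delta, lmin))
    Om <- Om + delta * diag(n_genes)
    lmin <- min(eigen(Om, symmetric = TRUE, only.values = TRUE)$values)
  }
  if (lmin <= 0)
    stop(sprintf("precision not positive definite after repair (lambda_min = %.4g)",
                 lmin))
  # true edges = non-zero off-diagonal precision entries
  if (within_pcor != 0 && length(ea)) {
    cp <- canonical_pairs(genes[ea], genes[eb])
    true_edges <- unique(data.frame(gene_a = cp$gene_a, gene_b = cp$gene_b,
                                    stringsAsFactors = FALSE))
    true_edges <- true_edges[order(true_edges$gene_a, true_edges$gene_b), ]
    rownames(true_edges) <- NULL
  } else {
    true_edges <- data.frame(gene_a = character(), gene_b = character(),
                             stringsAsFactors = FALSE)
  }
  structure(list(n_genes = n_genes,
                 module_sizes = rep(module_size, n_modules),
                 within_pcor = within_pcor, precision = Om,
                 true_edges = true_edges, true_modules = modules,
                 seed = seed),
            class = "PlantedModel")
}

#' Simulate FPKM-like expression from a planted model
#'
#' Draws samples from the multivariate normal whose precision is the
#' model's (standardized to unit variances), gives each gene a base mean and
#' scale on the latent log2 scale, and maps to the FPKM scale via
#' `FPKM = 2^z - 1` (clipped at 0) — the exact inverse of the
#' log2(FPKM + 1) preprocessing transform, so the latent Gaussian is
#' recovered by it. The exponential mapping reproduces the mean-variance
#' dependency of real FPKM data: per-gene SD rises with per-gene mean on the
#' raw scale.
#'
#' Default base means span log2 FPKM 3-8, the range typical of genes that
#' survive a max-FPKM filter in a bulk RNA-seq compendium.
#'
#' @param model a `PlantedModel`.
#' @param n_samples number of samples (>= 2).
#' @param base_log_mean_range per-gene base means are drawn uniformly from
#'   this interval on the log2 scale.
#' @param latent_sd_range per-gene latent scales, drawn uniformly.
#' @param seed integer seed.
#' @return An `ExpressionMatrix` on the `fpkm` scale.
#' @export
simulate_expression <- function(model, n_samples,
                                base_log_mean_range = c(3, 8),
                                latent_sd_range = c(0.6, 1.2),
                                seed = 1L) {
  stopifnot(inherits(model, "PlantedModel"))
  if (n_samples < 2L) stop("n_samples must be >= 2 (no variance estimable)")
  g <- model$n_genes
  Sigma <- solve(model$precision)
  Sigma <- stats::cov2cor(Sigma)
  L <- chol(Sigma)
  vals <- with_seed(derive_seed(seed, "expression"), {
    X <- matrix(rnorm(n_samples * g), n_samples, g) %*% L   # rows ~ MVN(0, R)
    mu <- runif(g, base_log_mean_range[[1L]], base_log_mean_range[[2L]])
    sdv <- runif(g, latent_sd_range[[1L]], latent_sd_range[[2L]])
    z <- t(X) * sdv + mu
    pmax(2^z - 1, 0)
  })
  dimnames(vals) <- list(rownames(model$precision),
                         sprintf("s%0*d", nchar(n_samples), seq_len(n_samples)))
  expression_matrix(vals, scale = "fpkm")
}

#' Rewired partner network and homolog map for conservation tests
#'
#' Produces a second-species stand-in: a relabeled copy of `network` (gene
#' ids prefixed) in which a fraction of edges is removed and replaced by
#' random non-edges, plus a homolog map linking a fraction of genes to their
#' relabeled copies. With `homolog_fraction = 1, edge_rewire_fraction = 0`
#' every gene of degree >= 1 is conserved by construction; full rewiring
#' drives conservation to chance level.
#'
#' @param network a `SignedNetwork`.
#' @param homolog_fraction fraction of genes with a homolog, in \[0, 1\].
#' @param edge_rewire_fraction fraction of edges rewired, in \[0, 1\].
#' @param seed integer seed.
#' @param prefix id prefix for the partner species (default `"sp2_"`).
#' @return list(partner_network = `SignedNetwork`,
#'   homolog_map = data.frame(gene_a, gene_b)).
#' @export
generate_conservation_scenario <- function(network, homolog_fraction,
                                           edge_rewire_fraction, seed = 1L,
                                           prefix = "sp2_") {
  stopifnot(homolog_fraction >= 0, homolog_fraction <= 1,
            edge_rewire_fraction >= 0, edge_rewire_fraction <= 1)
  nodes2 <- paste0(prefix, network$nodes)
  ed <- data.frame(gene_a = paste0(prefix, network$edges$gene_a),
                   gene_b = paste0(prefix, network$edges$gene_b),
                   stringsAsFactors = FALSE)
  E <- nrow(ed)
  out <- with_seed(derive_seed(seed, "conservation"), {
    n_rewire <- round(edge_rewire_fraction * E)
    if (n_rewire > 0) {
      drop_idx <- sample.int(E, n_rewire)
      kept <- ed[-drop_idx, , drop = FALSE]
      existing <- paste(pmin(ed$gene_a, ed$gene_b),
                        pmax(ed$gene_a, ed$gene_b))
      new_edges <- list()
      n_new <- 0L
      while (n_new < n_rewire) {
        a <- sample(nodes2, n_rewire - n_new, replace = TRUE)
        b <- sample(nodes2, n_rewire - n_new, replace = TRUE)
        ok <- a != b
        key <- paste(pmin(a, b), pmax(a, b))
        ok <- ok & !(key %in% existing) & !duplicated(key)
        if (any(ok)) {
          new_edges[[length(new_edges) + 1L]] <-
            data.frame(gene_a = a[ok], gene_b = b[ok], stringsAsFactors = FALSE)
          existing <- c(existing, key[ok])
          n_new <- n_new + sum(ok)
        }
      }
      ed <- rbind(kept, do.call(rbind, new_edges))
    }
    n_hom <- round(homolog_fraction * length(network$nodes))
    hom_genes <- if (n_hom > 0) sort(sample(network$nodes, n_hom)) else character()
    map <- if (length(hom_genes))
      data.frame(gene_a = hom_genes, gene_b = paste0(prefix, hom_genes),
                 stringsAsFactors = FALSE)
    else
      data.frame(gene_a = character(), gene_b = character(),
                 stringsAsFactors = FALSE)
    list(edges = ed, map = map)
  })
  list(partner_network = build_network(out$edges), homolog_map = out$map)
}

#' Module-enriched synthetic annotations
#'
#' For each retained module, emits `terms_per_module` marker terms that
#' annotate `signal_fraction` of the module's genes plus
#' `background_fraction` of all other genes (module and small-module genes
#' alike), giving enrichment tests a planted positive signal over a noise
#' floor.
#'
#' @param modules a `ModuleAssignment`.
#' @param terms_per_module marker terms per module (default 1).
#' @param signal_fraction fraction of the module's genes annotated.
#' @param background_fraction fraction of non-module genes annotated.
#' @param seed integer seed.
#' @return data.frame(gene, term); empty when there are no modules.
#' @export
generate_annotations <- function(modules, terms_per_module = 1L,
                                 signal_fraction = 0.8,
                                 background_fraction = 0.05, seed = 1L) {
  stopifnot(inherits(modules, "ModuleAssignment"),
            signal_fraction >= 0, signal_fraction <= 1,
            background_fraction >= 0, background_fraction <= 1)
  all_genes <- c(names(modules$membership), modules$small_module_genes)
  ids <- as.integer(names(modules$module_sizes))
  if (length(ids) == 0L)
    return(data.frame(gene = character(), term = character(),
                      stringsAsFactors = FALSE))
  with_seed(derive_seed(seed, "annotations"), {
    rows <- list()
    for (m in ids) {
      mod_genes <- names(modules$membership)[modules$membership == m]
      other <- setdiff(all_genes, mod_genes)
      for (t in seq_len(terms_per_module)) {
        term <- sprintf("TERM_M%d_%d", m, t)
        sig <- sample(mod_genes, round(signal_fraction * length(mod_genes)))
        bg <- if (length(other))
          sample(other, round(background_fraction * length(other)))
        else character()
        genes <- c(sig, bg)
        if (length(genes))
          rows[[length(rows) + 1L]] <-
            data.frame(gene = genes, term = term, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    if (is.null(out)) out <- data.frame(gene = character(), term = character(),
                                        stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}

# one concrete random expansion of an IUPAC pattern
expand_iupac <- function(motif) {
  chars <- strsplit(toupper(motif), "")[[1L]]
  paste(vapply(chars, function(ch) {
    cls <- IUPAC_CLASSES[[ch]]
    bases <- strsplit(gsub("\\[|\\]", "", cls), "")[[1L]]
    if (length(bases) == 1L) bases else sample(bases, 1L)
  }, character(1)), collapse = "")
}

#' Random promoters with an implanted motif
#'
#' Uniform-random ACGT sequences of the given length; for each gene in
#' `implant_genes` one concrete expansion of the IUPAC motif is written at a
#' random position (overwriting the background sequence there), so every
#' implant gene carries at least one hit by construction.
#'
#' @param genes character vector of gene ids.
#' @param length promoter length in bp (>= motif length).
#' @param motif IUPAC pattern to implant.
#' @param implant_genes subset of `genes` receiving an implant.
#' @param seed integer seed.
#' @return Named character vector of sequences.
#' @export
generate_promoters <- function(genes, length = 1000L, motif = "CGTAC",
                               implant_genes = character(), seed = 1L) {
  stopifnot(all(implant_genes %in% genes))
  mlen <- nchar(motif)
  if (mlen > length) stop("motif longer than promoter length")
  iupac_to_regex(motif)   # validates the alphabet
  with_seed(derive_seed(seed, "promoters"), {
    seqs <- vapply(genes, function(g)
      paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
            collapse = ""), character(1))
    for (g in implant_genes) {
      inst <- expand_iupac(motif)
      pos <- sample.int(length - mlen + 1L, 1L)
      substr(seqs[[g]], pos, pos + mlen - 1L) <- inst
    }
    seqs
  })
}

#' Write promoters as FASTA
#' @param promoters named character vector of sequences.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_promoters_fasta <- function(promoters, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(promoters), path)
  invisible(path)
}

#' Read promoters from FASTA
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_promoters_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Full synthetic study scenario
#'
#' Bundles all inputs of the analysis with the statistical structure it
#' assumes: a planted-module GGM, FPKM-like expression simulated from it,
#' module-enriched annotations, a rewired partner network with a homolog
#' map (built from the planted true-edge network), and promoters with a
#' motif implanted in the first module's genes. Every component is a pure
#' function of the arguments and `seed`.
#'
#' @param n_genes,n_modules,module_size,within_pcor planted-model geometry
#'   (see [generate_planted_model()]).
#' @param n_samples samples to simulate.
#' @param seed integer seed fanned out to the component generators.
#' @param homolog_fraction,edge_rewire_fraction conservation-scenario knobs.
#' @param motif IUPAC motif implanted in module 1's promoters.
#' @param promoter_length promoter length in bp.
#' @return A `SyntheticScenario` list: `model`, `expression`,
#'   `true_assignment`, `true_network`, `annotations`, `partner_network`,
#'   `homolog_map`, `promoters`, `seed`.
#' @export
generate_scenario <- function(n_genes = 200L, n_modules = 8L,
                              module_size = 20L, within_pcor = 0.3,
                              n_samples = 400L, seed = 1L,
                              homolog_fraction = 1, edge_rewire_fraction = 0,
                              motif = "CGTAC", promoter_length = 500L) {
  model <- generate_planted_model(n_genes, n_modules, module_size,
                                  within_pcor, seed = seed)
  expression <- simulate_expression(model, n_samples, seed = seed)
  true_assignment <- module_assignment(model$true_modules)
  true_network <- if (nrow(model$true_edges))
    build_network(model$true_edges) else NULL
  annotations <- generate_annotations(true_assignment, seed = seed)
  cons <- if (!is.null(true_network))
    generate_conservation_scenario(true_network, homolog_fraction,
                                   edge_rewire_fraction, seed = seed)
  else list(partner_network = NULL, homolog_map = NULL)
  genes <- rownames(model$precision)
  implant <- names(model$true_modules)[model$true_modules == 1L]
  promoters <- generate_promoters(genes, length = promoter_length,
                                  motif = motif, implant_genes = implant,
                                  seed = seed)
  structure(list(model = model, expression = expression,
                 true_assignment = true_assignment,
                 true_network = true_network, annotations = annotations,
                 partner_network = cons$partner_network,
                 homolog_map = cons$homolog_map, promoters = promoters,
                 seed = seed),
            class = "SyntheticScenario")
}
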