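log_matrix <- function(vals) expression_matrix(vals, "log2p1")

test_that("module means and relative-to-max values follow the worked cases", {
  vals <- matrix(c(2, 2, 4, 4,
                   4, 8, 8, 16,
                   0, 0, 0, 0), 3, 4, byrow = TRUE,
                 dimnames = list(c("g1", "g2", "g3"),
                                 c("s1", "s2", "s3", "s4")))
  groups <- data.frame(sample_id = c("s1", "s2", "s3", "s4"),
                       group_label = c("G1", "G1", "G2", "G2"),
                       group_order = c(1, 1, 2, 2))
  modules <- module_assignment(setNames(c(1L, 1L, 2L), c("g1", "g2", "g3")))
  # module_assignment renumbers by size: {g1,g2} -> 1, {g3} -> 2
  prof <- module_mean_expression(log_matrix(vals), modules, groups)
  expect_equal(prof$means["1", ], c(G1 = 4, G2 = 8))        # means 3+5 / 6+10 over genes
  expect_equal(prof$relative["1", ], c(G1 = 0.5, G2 = 1.0))
  # all-zero module row: relatives all 0, no division by zero
  expect_equal(prof$relative["2", ], c(G1 = 0, G2 = 0))
  # relative values invariant to uniform positive rescaling of a module row
  vals2 <- vals; vals2[c("g1", "g2"), ] <- vals[c("g1", "g2"), ] * 7
  prof2 <- module_mean_expression(log_matrix(vals2), modules, groups)
  expect_equal(prof2$relative["1", ], prof$relative["1", ])

  expect_error(module_mean_expression(expression_matrix(vals, "fpkm"),
                                      modules, groups), "log2p1")
  expect_error(module_mean_expression(
    log_matrix(vals), modules,
    data.frame(sample_id = "nope", group_label = "G", group_order = 1)),
    "missing from the matrix")
})

test_that("single-group module of two genes averages to the plain mean", {
  vals <- matrix(c(2, 4), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  groups <- data.frame(sample_id = "s1", group_label = "G", group_order = 1)
  modules <- module_assignment(setNames(c(1L, 1L), c("g1", "g2")))
  prof <- module_mean_expression(log_matrix(vals), modules, groups)
  expect_equal(unname(prof$means["1", "G"]), 3)
  expect_equal(unname(prof$relative["1", "G"]), 1.0)
})

test_that("neighbor-voting AUROC equals brute-force pairwise probability", {
  set.seed(21)
  for (rep in 1:5) {
    g <- igraph::sample_gnp(40, 0.12)
    el <- igraph::as_edgelist(g)
    if (nrow(el) == 0) next
    net <- build_network(data.frame(gene_a = paste0("g", el[, 1]),
                                    gene_b = paste0("g", el[, 2])))
    S <- sample(net$nodes, 12)
    res <- suppressWarnings(neighbor_voting_auroc(net, list(S = S)))
    # recompute scores independently and compare to brute-force AUROC
    nb <- igraph::as_adj_list(igraph::graph_from_data_frame(
      net$edges[, 1:2], directed = FALSE, vertices = net$nodes))
    deg <- lengths(nb)
    scored <- net$nodes[deg[net$nodes] >= 1]
    scores <- sapply(scored, function(v) {
      nbrs <- names(nb[[v]])
      sum(nbrs %in% setdiff(S, v)) / length(nbrs)
    })
    expect_equal(res$auroc, brute_auroc(scores, scored %in% S),
                 tolerance = 1e-12)
  }
})

test_that("perfect modules score AUROC 1 and degenerate sets are skipped", {
  ed <- rbind(clique_edges(paste0("a", 1:6)), clique_edges(paste0("b", 1:6)))
  net <- build_network(ed)
  res <- neighbor_voting_auroc(net, list(cliqueA = paste0("a", 1:6)))
  expect_equal(res$auroc, 1.0)
  expect_equal(res$n_positives, 6)
  expect_warning(neighbor_voting_auroc(net, list(tiny = "a1")), "< 2 members")
  expect_warning(neighbor_voting_auroc(net, list(all = net$nodes)),
                 "no negatives")
})

test_that("random half-sets of an ER graph score near chance", {
  set.seed(22)
  aucs <- replicate(20, {
    g <- igraph::sample_gnp(500, 0.02)
    el <- igraph::as_edgelist(g)
    net <- build_network(data.frame(gene_a = paste0("g", el[, 1]),
                                    gene_b = paste0("g", el[, 2])))
    S <- sample(net$nodes, floor(length(net$nodes) / 2))
    neighbor_voting_auroc(net, list(S = S))$auroc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("true modules outscore size-matched random sets on a recovered network", {
  scen <- generate_scenario(n_genes = 120, n_modules = 5, module_size = 15,
                            n_samples = 150, seed = 23)
  lg <- log_transform(scen$expression)
  assoc <- sampled_pcor_estimation(lg, sampling_plan(60, 60, seed = 23))
  net <- select_edges(assoc, pearson_correlation(lg), 0.05, 0.2)
  true_sets <- split(names(scen$model$true_modules),
                     scen$model$true_modules)[as.character(1:5)]
  names(true_sets) <- paste0("M", 1:5)
  res_true <- neighbor_voting_auroc(net, true_sets)
  set.seed(23)
  rand_sets <- lapply(true_sets, function(s) sample(net$nodes, length(s)))
  res_rand <- suppressWarnings(neighbor_voting_auroc(net, rand_sets))
  expect_gt(mean(res_true$auroc), mean(res_rand$auroc))
  expect_gt(mean(res_true$auroc), 0.9)
})
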