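test_that("planted precision is block-structured, positive definite, and hits the target pcor", {
  pm <- generate_planted_model(10, 2, 5, 0.3, seed = 1)
  Om <- pm$precision
  expect_equal(dim(Om), c(10, 10))
  expect_equal(max(abs(Om[1:5, 6:10])), 0)          # cross-block zeros
  ev <- eigen(Om, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_identical(unname(pm$true_modules[1:5]), rep(1L, 5))

  # standardized -omega_ij / sqrt(omega_ii omega_jj) of every planted edge
  # is within 10% of the target
  for (seed in 1:3) {
    pm2 <- generate_planted_model(40, 2, 20, 0.3, seed = seed)
    Om2 <- pm2$precision
    d <- sqrt(diag(Om2))
    PC <- -Om2 / tcrossprod(d)
    idx <- cbind(match(pm2$true_edges$gene_a, rownames(Om2)),
                 match(pm2$true_edges$gene_b, rownames(Om2)))
    expect_true(all(abs(PC[idx] - 0.3) <= 0.1 * 0.3))
  }
  # true edges are exactly the non-zero off-diagonal entries
  off <- upper.tri(Om)
  expect_equal(sum(Om[off] != 0), nrow(pm$true_edges))

  expect_error(generate_planted_model(9, 2, 5, 0.3), "exceeds n_genes")
})

test_that("zero within-module pcor yields the identity precision and no true edges", {
  pm <- generate_planted_model(4, 1, 4, 0.0, seed = 1)
  expect_equal(unname(pm$precision), diag(4))
  expect_equal(nrow(pm$true_edges), 0)
})

test_that("simulated expression honors the precision and shows the FPKM mean-variance trend", {
  pm <- generate_planted_model(8, 0, 2, 0, seed = 1)   # identity precision
  em <- simulate_expression(pm, 1000, seed = 2)
  z <- log2(expr_values(em) + 1)
  r <- cor(t(z))
  expect_lt(max(abs(r[upper.tri(r)])), 0.15)

  pm2 <- generate_planted_model(100, 5, 15, 0.3, seed = 3)
  em2 <- simulate_expression(pm2, 200, seed = 3)
  mu <- rowMeans(expr_values(em2))
  sdv <- apply(expr_values(em2), 1, sd)
  expect_gt(cor(mu, sdv, method = "spearman"), 0.5)
  expect_true(all(expr_values(em2) >= 0))

  em2b <- simulate_expression(pm2, 200, seed = 3)
  expect_identical(expr_values(em2), expr_values(em2b))   # pure in seed
  expect_error(simulate_expression(pm2, 1), "n_samples")
})

test_that("conservation scenarios span identity, empty, and chance-level regimes", {
  pm <- generate_planted_model(60, 3, 15, 0.3, seed = 5)
  net <- build_network(pm$true_edges)
  id <- generate_conservation_scenario(net, 1.0, 0.0, seed = 6)
  fl <- conserved_interactions(net, id$partner_network, id$homolog_map)
  expect_true(all(fl$conserved))    # every node has degree >= 1 here

  none <- generate_conservation_scenario(net, 0.0, 0.0, seed = 6)
  fl0 <- conserved_interactions(net, none$partner_network, none$homolog_map)
  expect_false(any(fl0$conserved))
  modules <- module_assignment(pm$true_modules)
  rep0 <- module_conservation(fl0, modules)
  expect_true(all(rep0$per_module$percent_conserved == 0))

  full <- generate_conservation_scenario(net, 1.0, 1.0, seed = 6)
  flf <- conserved_interactions(net, full$partner_network, full$homolog_map)
  expect_lt(mean(flf$conserved), mean(fl$conserved))
  # edge count preserved under rewiring
  expect_equal(nrow(full$partner_network$edges), nrow(net$edges))
})

test_that("annotation generator plants detectable signal and respects edge cases", {
  labels <- setNames(rep(1:3, each = 20), sprintf("g%02d", 1:60))
  modules <- module_assignment(labels)
  ann <- generate_annotations(modules, signal_fraction = 0.8,
                              background_fraction = 0.05, seed = 7)
  res <- go_enrichment(names(labels)[labels == 1], names(labels), ann)
  marker <- res[res$term == "TERM_M1_1", ]
  expect_lt(marker$p_value, 1e-3)

  empty <- module_assignment(setNames(integer(), character()))
  expect_equal(nrow(generate_annotations(empty, seed = 1)), 0)

  # equal signal and background: no planted excess, p-values not extreme
  labels50 <- setNames(rep(1:50, each = 15), sprintf("g%03d", 1:750))
  mods50 <- module_assignment(labels50)
  ann_null <- generate_annotations(mods50, signal_fraction = 0.2,
                                   background_fraction = 0.2, seed = 8)
  pmin_ <- min(sapply(as.integer(names(mods50$module_sizes)), function(m) {
    mg <- names(mods50$membership)[mods50$membership == m]
    r <- go_enrichment(mg, names(labels50), ann_null)
    r$p_value[r$term == sprintf("TERM_M%d_1", m)]
  }))
  expect_gt(pmin_, 1e-4)
})

test_that("promoter generator validates preconditions and writes FASTA round-trips", {
  expect_error(generate_promoters("g1", length = 3, motif = "CGTAC"),
               "longer than promoter")
  expect_error(generate_promoters("g1", implant_genes = "g9"), "implant_genes")
  prom <- generate_promoters(c("g1", "g2"), length = 50, motif = "GNATATNC",
                             implant_genes = "g1", seed = 9)
  expect_true(scan_promoters(prom, "GNATATNC")[["g1"]] >= 1)
  path <- withr::local_tempfile(fileext = ".fa")
  write_promoters_fasta(prom, path)
  expect_identical(read_promoters_fasta(path), prom)
})

test_that("edge recovery improves with sample size (paired replicates)", {
  deltas <- sapply(1:8, function(s) {
    pm <- generate_planted_model(60, 3, 15, 0.3, seed = 100 + s)
    truth <- matrix(FALSE, 60, 60,
                    dimnames = list(rownames(pm$precision), rownames(pm$precision)))
    truth[cbind(pm$true_edges$gene_a, pm$true_edges$gene_b)] <- TRUE
    truth <- truth | t(truth)
    off <- upper.tri(truth)
    au <- sapply(c(100, 400), function(n) {
      em <- simulate_expression(pm, n, seed = 100 + s)
      assoc <- sampled_pcor_estimation(log_transform(em),
                                       sampling_plan(40, 30, seed = 100 + s))
      auroc(abs(assoc$pcor[off]), truth[off])
    })
    au[[2]] - au[[1]]
  })
  expect_gt(mean(deltas), 0)
  expect_gt(mean(deltas > 0), 0.7)
})
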