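test_that("hypergeometric enrichment reproduces the exact tail and its contract", {
  universe <- paste0("g", 1:20)
  ann <- data.frame(gene = paste0("g", 1:5), term = "T1")
  res <- go_enrichment(paste0("g", c(1:4, 6)), universe, ann)
  expect_equal(res$p_value, 76 / 15504, tolerance = 1e-12)
  expect_equal(res$k, 4); expect_equal(res$K, 5); expect_equal(res$N, 20)

  # a term with no hit in the module is omitted
  ann2 <- rbind(ann, data.frame(gene = paste0("g", 15:18), term = "T2"))
  res2 <- go_enrichment(paste0("g", 1:4), universe, ann2)
  expect_identical(res2$term, "T1")

  # module = universe: every term certain, p = 1
  res3 <- go_enrichment(universe, universe, ann2)
  expect_equal(res3$p_value, rep(1, 2))

  expect_error(go_enrichment("g1", character(), ann), "empty universe")
  expect_error(go_enrichment("zz", universe, ann), "subset")
})

test_that("hypergeometric tail agrees with exhaustive draw enumeration for small universes", {
  cases <- list(c(N = 12, K = 4, n = 5, k = 2), c(N = 15, K = 6, n = 4, k = 3),
                c(N = 20, K = 5, n = 5, k = 4), c(N = 10, K = 7, n = 6, k = 5))
  for (cs in cases) {
    universe <- paste0("u", seq_len(cs["N"]))
    ann <- data.frame(gene = universe[seq_len(cs["K"])], term = "T")
    module <- c(universe[seq_len(cs["k"])],
                universe[(cs["K"] + 1):(cs["K"] + cs["n"] - cs["k"])])
    res <- go_enrichment(module, universe, ann)
    expect_equal(res$p_value,
                 brute_hyper_tail(cs["N"], cs["K"], cs["n"], cs["k"]),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("BH adjustment preserves the p-value ordering", {
  set.seed(20)
  universe <- paste0("g", 1:60)
  ann <- do.call(rbind, lapply(1:8, function(i)
    data.frame(gene = sample(universe, 12), term = paste0("T", i))))
  res <- go_enrichment(sample(universe, 15), universe, ann)
  expect_identical(order(res$p_value), order(res$p_adjusted))
  expect_true(all(res$p_adjusted >= res$p_value))
})

test_that("IUPAC scanning counts overlapping matches on both strands and rejects bad motifs", {
  # hand-verified: forward CGTAC at position 3; the reverse complement
  # GGTACGTT contains no CGTAC, so one hit in total
  expect_equal(unname(scan_promoters(c(x = "AACGTACC"), "CGTAC")), 1L)
  # NNNNN matches every position on each strand
  expect_equal(unname(scan_promoters(c(x = "ACGTG"), "NNNNN")), 2L)
  expect_equal(unname(scan_promoters(c(x = ""), "CGTAC")), 0L)
  # overlap: AAA contains AA twice, and its reverse complement TTT none
  expect_equal(unname(scan_promoters(c(x = "AAA"), "AA")), 2L)
  # N in the sequence never matches
  expect_equal(unname(scan_promoters(c(x = "CGNAC"), "CGTAC")), 0L)
  # degenerate letters: GGATATTC matches GNATATNC forward, and its reverse
  # complement GAATATCC matches it too
  expect_equal(unname(scan_promoters(c(x = "GGATATTC"), "GNATATNC")), 2L)
  expect_equal(unname(scan_promoters(c(x = "GGATATTG"), "GNATATNC")), 0L)
  expect_error(scan_promoters(c(x = "ACGT"), "CGXAC"), "invalid IUPAC")
})

test_that("binomial motif enrichment matches exact and brute-force tails", {
  universe <- paste0("g", 1:100)
  hits <- setNames(c(rep(1L, 10), rep(0L, 90)), universe)
  module <- c(paste0("g", 1:5), paste0("g", 11:15))   # k = 5 of n = 10, p0 = 0.1
  res <- motif_enrichment(module, hits, universe)
  expect_equal(res$k, 5); expect_equal(res$n, 10); expect_equal(res$p0, 0.1)
  expect_equal(res$p_value, 0.0016349374, tolerance = 1e-7)
  expect_equal(res$p_value, brute_binom_tail(10, 0.1, 5), tolerance = 1e-12)

  # k = 0: P(X >= 0) = 1
  res0 <- motif_enrichment(paste0("g", 20:24), hits, universe)
  expect_equal(res0$p_value, 1)
  # p0 = 1: certain event
  res1 <- motif_enrichment(module, setNames(rep(1L, 100), universe), universe)
  expect_equal(res1$p_value, 1)
  # hits must cover the whole universe
  expect_error(motif_enrichment("g1", hits[1:50], universe), "every universe gene")
})

test_that("implanted motifs are always found and the background rate matches the two-strand model", {
  genes <- paste0("g", 1:250)
  implant <- paste0("g", 1:30)
  prom <- generate_promoters(genes, length = 1000, motif = "CGTAC",
                             implant_genes = implant, seed = 31)
  hits <- scan_promoters(prom, "CGTAC")
  expect_true(all(hits[implant] >= 1))
  # per-position two-strand model: 1 - (1 - 4^-5)^(2 * (1000 - 5 + 1))
  bg <- mean(hits[setdiff(genes, implant)] >= 1)
  expect_lt(abs(bg - 0.857), 0.08)
  # determinism
  prom2 <- generate_promoters(genes, length = 1000, motif = "CGTAC",
                              implant_genes = implant, seed = 31)
  expect_identical(prom, prom2)
})

test_that("planted marker terms rank first for their module in almost every replicate", {
  labels <- setNames(rep(1:5, each = 20), sprintf("g%03d", 1:100))
  modules <- module_assignment(labels)
  universe <- names(labels)
  first <- logical(0)
  for (s in 1:100) {
    ann <- generate_annotations(modules, signal_fraction = 0.8,
                                background_fraction = 0.05, seed = s)
    for (m in as.integer(names(modules$module_sizes))) {
      mg <- names(modules$membership)[modules$membership == m]
      res <- go_enrichment(mg, universe, ann)
      first <- c(first, res$term[[1L]] == sprintf("TERM_M%d_1", m))
    }
  }
  expect_gte(mean(first), 0.95)
})
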