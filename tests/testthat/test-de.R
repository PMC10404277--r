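de_fixture <- function(n_genes = 200, rna_effects = numeric(0),
                       dispersion = 0.05, depth = 500, seed = 3) {
  genes <- sprintf("g%04d", seq_len(n_genes))
  des <- simulation_design(fractions = "total", mean_depth = depth,
                           dispersion = dispersion,
                           rna_effects = rna_effects, seed = seed)
  generate_fraction_counts(genes, des)
}

balanced_effects <- function(n_up, n_down, lfc = 2) {
  c(setNames(rep(lfc, n_up), sprintf("g%04d", seq_len(n_up))),
    setNames(rep(-lfc, n_down), sprintf("g%04d", n_up + seq_len(n_down))))
}

test_that("identical groups give zero fold-change and ns calls", {
  counts <- tibble::tibble(
    feature_id = c("g1", "g2"), is_spikein = FALSE,
    control_total_rep1 = c(100L, 50L), control_total_rep2 = c(120L, 40L),
    mutant_total_rep1 = c(100L, 50L), mutant_total_rep2 = c(120L, 40L))
  design <- tibble::tibble(
    library_id = names(counts)[-(1:2)],
    genotype = rep(c("control", "mutant"), each = 2),
    fraction = "total", replicate = rep(1:2, 2))
  de <- differential_expression(counts, design)
  expect_equal(de$log2fc, c(0, 0))
  expect_equal(de$de_class, c("ns", "ns"))
  expect_equal(de$p_value, c(1, 1), tolerance = 1e-9)
})

test_that("FDR adjustment is Benjamini-Hochberg step-up", {
  # monotone step-up computed by hand for p = .01,.02,.03,.04 (m = 4):
  # all adjusted values collapse to 0.04
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  fx <- de_fixture(n_genes = 100, rna_effects = balanced_effects(1, 1),
                   seed = 11)
  de <- differential_expression(fx$counts, fx$design)
  expect_equal(de$fdr, p.adjust(de$p_value, "BH"))
  # adjustment preserves p-value ordering
  expect_equal(order(de$fdr, de$p_value), order(de$p_value))
  expect_true(all(de$fdr >= de$p_value))
})

test_that("planted 4-fold changes are detected at depth 500 with 2v2", {
  eff <- balanced_effects(10, 10)
  fx <- de_fixture(n_genes = 400, rna_effects = eff,
                   dispersion = 0.05, seed = 21)
  de <- differential_expression(fx$counts, fx$design)
  want <- ifelse(eff > 0, "up", "down")
  hit <- de$de_class[match(names(eff), de$gene_id)] == want
  expect_gte(mean(hit), 0.8)
  null_called <- de$de_class[!de$gene_id %in% names(eff)] != "ns"
  expect_lt(mean(null_called), 0.05)
})

test_that("single-replicate designs are rejected", {
  genes <- sprintf("g%03d", 1:10)
  des <- simulation_design(fractions = "total", replicates = 1L,
                           dispersion = 0)
  fc <- generate_fraction_counts(genes, des)
  expect_error(differential_expression(fc$counts, fc$design),
               ">= 2 replicates")
  expect_error(estimate_common_dispersion(matrix(1:4, 2), c("a", "b")),
               "inestimable")
})

test_that("the exact test is two-sided and symmetric in its groups", {
  expect_equal(nb_exact_test(10, 10, 2, 2, 0.05), 1)
  expect_equal(nb_exact_test(30, 10, 2, 2, 0.05),
               nb_exact_test(10, 30, 2, 2, 0.05))
  expect_equal(nb_exact_test(0, 0, 2, 2, 0.05), 1)
  # alpha -> 0 limit agrees with the binomial exact test
  p_nb <- nb_exact_test(30, 12, 2, 2, 0)
  f <- dbinom(0:42, 42, 0.5)
  expect_equal(p_nb, sum(f[f <= f[31] * (1 + 1e-7)]))
})

test_that("results track an established exact-test implementation", {
  skip_if_not_installed("edgeR")
  fx <- de_fixture(n_genes = 150, rna_effects = balanced_effects(5, 5),
                   seed = 31)
  de <- differential_expression(fx$counts, fx$design)
  mat <- as.matrix(fx$counts[, fx$design$library_id])
  rownames(mat) <- fx$counts$feature_id
  y <- edgeR::DGEList(mat, group = fx$design$genotype)
  y <- edgeR::calcNormFactors(y, method = "none")
  y <- edgeR::estimateCommonDisp(y)
  et <- edgeR::exactTest(y, pair = c("control", "mutant"))
  ref_p <- et$table[de$gene_id, "PValue"]
  ref_fdr <- p.adjust(ref_p, "BH")
  # same test idea, different dispersion machinery: evidence strength and
  # fold-changes should track closely and the calls should coincide
  expect_gt(cor(log10(de$p_value + 1e-300), log10(ref_p + 1e-300)), 0.9)
  expect_gt(cor(de$log2fc, et$table[de$gene_id, "logFC"]), 0.99)
  ours_sig <- de$gene_id[de$fdr < 0.05]
  ref_sig <- de$gene_id[ref_fdr < 0.05]
  jaccard <- length(intersect(ours_sig, ref_sig)) /
    length(union(ours_sig, ref_sig))
  expect_gte(jaccard, 0.8)
})
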