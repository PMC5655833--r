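test_that("signed fold changes convert to log2 and round-trip", {
  expect_equal(signed_fold_to_log2(2), 1)
  expect_equal(signed_fold_to_log2(-2), -1)
  expect_equal(signed_fold_to_log2(-10.6), -log2(10.6))
  expect_equal(round(signed_fold_to_log2(-10.6), 3), -3.406)
  expect_error(signed_fold_to_log2(0.5), "fc")

  fcs <- c(1, 1.5, -1.5, 4, -10.6)
  expect_equal(log2_to_signed_fold(signed_fold_to_log2(fcs)), fcs)
})

test_that("gene-protein matching is per form, case-insensitive and exhaustive", {
  genes <- data.frame(gene = c("Rnpep", "Dgkg", "Lonely"),
                      log2_fc = c(-0.78, 1.42, 0.5),
                      p_value = c(0.001, 0.001, 0.5),
                      q_value = c(0.01, 0.01, 0.9))
  prots <- data.frame(accession = c("Q8VCT3", "Q8VCT3", "Q91WG7", "Z9999"),
                      form = c("none", "acetyl", "none", "none"),
                      fold_change = c(-3.47, -2.02, 1.51, 2),
                      p_value = c(0.01, 0.02, 0.03, 0.04))
  map <- data.frame(accession = c("Q8VCT3", "Q91WG7", "Z9999"),
                    gene = c("RNPEP", "dgkg", "Orphan"))
  ms <- match_gene_protein(genes, prots, map)
  # the two PTM forms of one protein match the same gene separately
  expect_equal(sum(ms$matches$gene == "Rnpep"), 2L)
  expect_equal(nrow(ms$matches), 3L)
  expect_equal(ms$unmatched_genes$gene, "Lonely")
  expect_equal(ms$unmatched_proteins$accession, "Z9999")
  # protein log2 fold change round-trips through the signed convention
  expect_equal(log2_to_signed_fold(ms$matches$protein_log2_fc),
               ms$matches$protein_fc)

  badmap <- rbind(map, data.frame(accession = "Q8VCT3", gene = "Other"))
  expect_error(match_gene_protein(genes, prots, badmap), "ambiguous")
})

test_that("constructed overlaps are recovered exactly", {
  k <- 7
  genes <- data.frame(gene = sprintf("G%02d", 1:20), log2_fc = rnorm(20),
                      p_value = 0.01, q_value = 0.01)
  prots <- data.frame(accession = sprintf("A%02d", 1:k), form = "none",
                      fold_change = 2, p_value = 0.01)
  map <- data.frame(accession = prots$accession, gene = genes$gene[1:k])
  ms <- match_gene_protein(genes, prots, map)
  expect_equal(nrow(ms$matches), k)
})

test_that("joint significance uses strict dual thresholds with a relaxed mode", {
  genes <- data.frame(gene = c("a", "b", "c"), log2_fc = 1,
                      p_value = c(0.01, 0.03, 0.2),
                      q_value = c(0.01, 0.05, 0.2))
  prots <- data.frame(accession = c("A", "B", "C"), form = "none",
                      fold_change = 2, p_value = c(0.05, 0.09, 0.01))
  map <- data.frame(accession = c("A", "B", "C"), gene = c("a", "b", "c"))
  ms <- match_gene_protein(genes, prots, map)
  # gene q exactly 0.05 is excluded under the strict threshold
  expect_equal(significant_matches(ms)$gene, "a")
  expect_setequal(significant_matches(ms, relaxed = TRUE)$gene, c("a", "b"))
})

test_that("correlation follows the textbook formula and its invariances", {
  m <- data.frame(gene_log2_fc = c(1, 2, 3), protein_fc = c(2, 4, 8),
                  protein_log2_fc = c(1, 2, 3))
  expect_equal(gene_protein_correlation(m, protein_scale = "log2")$r, 1)

  set.seed(12)
  x <- rnorm(50); yfc <- log2_to_signed_fold(rnorm(50))
  m2 <- data.frame(gene_log2_fc = x, protein_fc = yfc,
                   protein_log2_fc = signed_fold_to_log2(yfc))
  r <- gene_protein_correlation(m2)$r
  oracle <- sum((x - mean(x)) * (yfc - mean(yfc))) /
    sqrt(sum((x - mean(x))^2) * sum((yfc - mean(yfc))^2))
  expect_equal(r, oracle, tolerance = 1e-12)

  # symmetric in the axes and invariant to affine rescaling of either one
  m3 <- data.frame(gene_log2_fc = yfc, protein_fc = x, protein_log2_fc = NA)
  expect_equal(gene_protein_correlation(m3)$r, r)
  m4 <- m2; m4$gene_log2_fc <- 3 * m4$gene_log2_fc + 7
  expect_equal(gene_protein_correlation(m4)$r, r)

  expect_error(gene_protein_correlation(m2[1:2, ]), "at least 3")
  m5 <- data.frame(gene_log2_fc = c(1, 1, 1), protein_fc = c(1, 2, 3))
  expect_error(gene_protein_correlation(m5), "variance")
})

test_that("annotation splits known hits from novel ones", {
  m <- data.frame(gene = c("Mecp2", "Tfrc", "Qdpr"))
  cites <- data.frame(gene = c("MECP2", "Qdpr"), labels = c("1,2", "2"))
  ann <- annotate_rtt_hits(m, cites)
  expect_equal(ann$n_known, 2L)
  expect_equal(ann$n_novel, 1L)
  expect_equal(ann$matches$rtt_hit, c("1,2", "novel", "2"))

  all_novel <- annotate_rtt_hits(m, data.frame(gene = character(),
                                               labels = character()))
  expect_equal(all_novel$n_novel, 3L)
})

test_that("strict significant matches nest inside relaxed ones on BH tables", {
  # on q-values derived by BH, q >= p holds, so strict implies relaxed
  tbl <- simulate_de_table(de_sim_config(n_genes = 300, frac_de = 0.3, seed = 21))
  prots <- data.frame(accession = paste0("A", seq_len(300)), form = "none",
                      fold_change = 2, p_value = 0.01)
  map <- data.frame(accession = prots$accession, gene = tbl$gene)
  ms <- match_gene_protein(tbl, prots, map)
  strict <- significant_matches(ms)
  relaxed <- significant_matches(ms, relaxed = TRUE)
  expect_true(all(strict$gene %in% relaxed$gene))
})
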