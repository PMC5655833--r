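test_that("DIA simulator honors its configuration exactly", {
  sim <- simulate_dia_experiment(dia_sim_config(n_proteins = 100,
                                                frac_changed = 0.2, seed = 7))
  led <- sim$ledger
  expect_length(led$changed_proteins, 20L)
  expect_equal(sum(led$proteins$changed), 20L)
  # unchanged proteins carry a true log2 FC of exactly 0
  expect_true(all(led$proteins$true_log2_fc[!led$proteins$changed] == 0))
  expect_true(all(led$proteins$true_log2_fc[led$proteins$changed] != 0))
  # every protein appears exactly once in the ledger
  expect_equal(sort(led$proteins$protein_acc), sort(unique(led$proteins$protein_acc)))

  # zero missingness: every peptide detected in every run
  sim0 <- simulate_dia_experiment(dia_sim_config(n_proteins = 10,
                                                 missing_rate = 0, seed = 2))
  expect_true(all(sim0$detected))
  # every emitted peptide carries at least one fragment trace
  expect_true(all(table(sim0$traces$peptide_id) >= 1))
})

test_that("DIA simulator is bit-identical for a fixed seed", {
  cf <- dia_sim_config(n_proteins = 12, seed = 123)
  expect_identical(simulate_dia_experiment(cf), simulate_dia_experiment(cf))
})

test_that("trace tables satisfy their structural invariants", {
  sim <- small_sim()
  tr <- sim$traces
  expect_true(all(tr$intensity >= 0))
  # scan indices strictly increase within each fragment trace per run
  key <- paste(tr$run_id, tr$fragment_id)
  ok <- vapply(split(tr$scan_index, key), function(s) all(diff(s) > 0), logical(1))
  expect_true(all(ok))
})

test_that("a written simulation round-trips through the trace TSV", {
  sim <- simulate_dia_experiment(dia_sim_config(n_proteins = 5, seed = 3))
  dir <- write_simulation(sim, tempfile("simout"))
  back <- read.delim(file.path(dir, "traces.tsv"), stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(sim$traces))
  expect_equal(back$intensity, sim$traces$intensity, tolerance = 1e-12)
  expect_true(file.exists(file.path(dir, "ledger.json")))
  res <- quantify_dia(back, sim$groups, sim$detected)
  expect_gt(nrow(res$proteins), 0)
})

test_that("simulator rejects invalid configurations naming the field", {
  expect_error(dia_sim_config(frac_changed = 1.5), "frac_changed")
  expect_error(dia_sim_config(n_runs_per_group = 1), "n_runs_per_group")
  expect_error(dia_sim_config(peptides_per_protein = c(0, 2)),
               "peptides_per_protein")
  expect_error(dia_sim_config(missing_rate = -0.1), "missing_rate")
})

test_that("DE table simulator plants exactly the configured truth", {
  tbl <- simulate_de_table(de_sim_config(n_genes = 1000, frac_de = 0.1, seed = 3))
  expect_equal(nrow(tbl), 1000L)
  expect_equal(sum(tbl$true_de), 100L)
  expect_true(all(tbl$end >= tbl$start))
  expect_equal(tbl$length_kb, (tbl$end - tbl$start) / 1000)
  expect_true(any(tbl$biotype != "protein_coding"))
  # q-values are Benjamini-Hochberg over the simulated p-values
  expect_equal(tbl$q_value, p.adjust(tbl$p_value, method = "BH"))
  # determinism
  expect_identical(tbl, simulate_de_table(de_sim_config(n_genes = 1000,
                                                        frac_de = 0.1, seed = 3)))
})

test_that("a null DE table yields BH-significant counts within binomial bounds", {
  tbl <- simulate_de_table(de_sim_config(n_genes = 1000, frac_de = 0, seed = 17))
  n_sig <- nrow(significant_genes(tbl))
  expect_lte(n_sig, qbinom(0.99, 1000, 0.05))
})

test_that("a two-point length sampler drives the classifier split exactly", {
  cf <- de_sim_config(n_genes = 200, seed = 5,
                      length_sampler = function(n)
                        sample(c(50000, 150000), n, replace = TRUE))
  tbl <- simulate_de_table(cf)
  cls <- gene_length_class(tbl$length_kb)
  expect_equal(sum(cls == "long"), sum(tbl$length_kb == 150))
  expect_setequal(unique(tbl$length_kb), c(50, 150))
})

test_that("DE config rejects oversized cell-type blocks", {
  expect_error(de_sim_config(n_genes = 50,
                             block_sizes = c(neuron = 40, astrocyte = 20)),
               "block_sizes")
  expect_error(de_sim_config(block_sizes = c(dendrite = 5)), "unknown")
})

test_that("cell-type reference generator plants recoverable enrichment", {
  assign <- setNames(rep(CELL_TYPES_MERGED, each = 4),
                     sprintf("gene%05d", 1:20))
  ref <- simulate_celltype_reference(100, assign, enrichment_factor = 3, seed = 4)
  merged <- merge_oligo_subtypes(ref)
  calls <- classify_cell_type(names(assign), merged)
  expect_equal(calls$call, unname(assign))
  expect_true(all(abs(calls$ratio - 3) < 1e-12))

  # below the 3-fold boundary nothing is enriched
  ref29 <- simulate_celltype_reference(100, assign, enrichment_factor = 2.9,
                                       seed = 4)
  calls29 <- classify_cell_type(names(assign), merge_oligo_subtypes(ref29))
  expect_true(all(calls29$call == "not_enriched"))

  # background genes can never reach 3-fold enrichment
  bg <- setdiff(ref$gene, names(assign))
  expect_true(all(classify_cell_type(bg, merged)$call == "not_enriched"))

  # degenerate and invalid inputs
  expect_equal(nrow(simulate_celltype_reference(0)), 0L)
  expect_error(simulate_celltype_reference(10, c(gene00001 = "dendrite")),
               "unknown cell-type")
})
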