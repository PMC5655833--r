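make_trace <- function(mz, scans, rts, ints, ion = "y", charge = 1L) {
  data.frame(mz = mz, scan_index = scans, rt_minutes = rts, intensity = ints,
             ion_type = ion, charge = charge,
             fragment_id = paste0("f", mz), stringsAsFactors = FALSE)
}

test_that("deconvolution keeps apex-consistent fragments and merges by m/z", {
  # fragment at its maximum at the apex scan is retained
  tr <- make_trace(500.0, 1:3, c(1, 2, 3), c(10, 100, 95))
  dec <- deconvolve_fragments(tr)
  expect_equal(nrow(dec$fragments), 1L)
  expect_equal(dec$apex_scan, 2L)

  # fragment at 60% of its own maximum at the peptide apex is dropped
  dom <- make_trace(600.0, 1:3, c(1, 2, 3), c(10, 1000, 10))   # sets the apex
  weak <- make_trace(700.0, 1:3, c(1, 2, 3), c(100, 60, 20))   # max 100, apex 60
  dec <- deconvolve_fragments(rbind(dom, weak))
  expect_equal(dec$apex_scan, 2L)
  expect_true(600.0 %in% round(dec$fragments$mz, 3))
  expect_false(any(abs(dec$fragments$mz - 700.0) < 0.01))

  # records within the m/z tolerance merge into one fragment group
  a <- make_trace(500.003, 1:3, c(1, 2, 3), c(5, 50, 5))
  b <- make_trace(500.010, 1:3, c(1, 2, 3), c(5, 50, 5))
  dec <- deconvolve_fragments(rbind(a, b))
  expect_equal(nrow(dec$fragments), 1L)
  expect_equal(dec$fragments$max_intensity, 100)

  # all-zero trace yields an empty set, not an error
  z <- deconvolve_fragments(make_trace(500, 1:3, 1:3, c(0, 0, 0)))
  expect_equal(nrow(z$fragments), 0L)
})

test_that("quant fragment selection enforces ion type, charge, floor and bounds", {
  frags <- data.frame(
    ion_type = c(rep("y", 6), rep("b", 6)),
    charge = rep(c(1L, 2L), 6),
    apex_intensity = seq(120, 10, length.out = 12),
    stringsAsFactors = FALSE)
  sel <- select_quant_fragments(frags)
  expect_equal(nrow(sel), 9L)  # 12 eligible, capped at the 9 most intense
  expect_equal(sel$apex_intensity, sort(frags$apex_intensity, decreasing = TRUE)[1:9])

  # below the minimum of 5 eligible fragments: unquantifiable
  expect_null(select_quant_fragments(frags[1:4, ]))

  # a fragment at 9% of the strongest is ineligible
  frags2 <- data.frame(ion_type = "y", charge = 1L,
                       apex_intensity = c(100, 9, 50, 40, 30, 20))
  sel2 <- select_quant_fragments(frags2, min_n = 5)
  expect_equal(nrow(sel2), 5L)
  expect_false(9 %in% sel2$apex_intensity)

  # non-b/y ions and charge 3 never qualify
  frags3 <- data.frame(ion_type = c("a", "y"), charge = c(1L, 3L),
                       apex_intensity = c(100, 100))
  expect_null(select_quant_fragments(frags3, min_n = 1))
})

test_that("MS2 AUC is the summed per-fragment trapezoid over retention time", {
  # constant intensity 10 over 2 minutes: rectangle of area 20
  tr <- data.frame(group = 1, rt_minutes = c(0, 1, 2), intensity = c(10, 10, 10))
  expect_equal(integrate_ms2_auc(tr), 20)

  # triangular trace (0, 10, 0) at minutes (0, 1, 2): area 10
  tri <- data.frame(group = 1, rt_minutes = c(0, 1, 2), intensity = c(0, 10, 0))
  expect_equal(integrate_ms2_auc(tri), 10)

  # additivity across fragments
  two <- rbind(data.frame(group = 1, rt_minutes = c(0, 2), intensity = c(10, 10)),
               data.frame(group = 2, rt_minutes = c(0, 1), intensity = c(5, 5)))
  expect_equal(integrate_ms2_auc(two), 25)

  # a single-point trace contributes 0; an empty window warns and returns 0
  one <- data.frame(group = 1, rt_minutes = 1, intensity = 100)
  expect_equal(integrate_ms2_auc(one), 0)
  expect_warning(val <- integrate_ms2_auc(tri, rt_window = c(10, 11)), "window")
  expect_equal(val, 0)
})

test_that("retention-time maps recover affine shifts and match least squares", {
  rts <- setNames(seq(10, 60, length.out = 12), paste0("p", 1:12))

  ident <- fit_rt_map(rts, rts)
  expect_equal(ident$slope, 1)
  expect_equal(ident$intercept, 0)
  expect_equal(ident$sigma, 0)

  shifted <- fit_rt_map(rts, rts + 2)
  expect_equal(shifted$slope, 1)
  expect_equal(shifted$intercept, 2)

  # noisy affine shift: closed-form fit must equal lm() on the same pairs
  set.seed(99)
  tgt <- 1.03 * rts - 1.5 + rnorm(12, 0, 0.2)
  map <- fit_rt_map(rts, tgt)
  ref <- lm(tgt ~ rts)
  expect_equal(map$slope, unname(coef(ref)[2]), tolerance = 1e-10)
  expect_equal(map$intercept, unname(coef(ref)[1]), tolerance = 1e-10)

  expect_error(fit_rt_map(rts[1:3], rts[1:3]), "identity")
  expect_equal(predict_rt(identity_rt_map(), 42), 42)
})

test_that("rescaling places the matrix on a relative scale with minimum 1", {
  expect_equal(rescale_relative(matrix(c(2, 8, 4, 16), 2)),
               matrix(c(1, 4, 2, 8), 2))
  # idempotence
  m <- matrix(c(1, 3, 7, 2), 2)
  expect_equal(rescale_relative(m), m)
  # property: min exactly 1 and all pairwise ratios preserved
  set.seed(5)
  r <- matrix(rlnorm(60, 3, 2), 10)
  out <- rescale_relative(r)
  expect_identical(min(out), 1)
  expect_equal(out[2, ] / out[1, ], r[2, ] / r[1, ])
  expect_error(rescale_relative(matrix(c(-1, 2), 1)), "positive")
})

test_that("shared peptides resolve to the most frequent accession", {
  a <- data.frame(peptide_id = rep("pep1", 6),
                  protein_acc = c(rep("P1", 4), rep("P2", 2)))
  expect_equal(unname(resolve_shared_peptides(a)["pep1"]), "P1")

  b <- data.frame(peptide_id = "pep2", protein_acc = "P9")
  expect_equal(unname(resolve_shared_peptides(b)["pep2"]), "P9")

  # tie: lexicographically smaller accession wins
  tie <- data.frame(peptide_id = rep("pep3", 6),
                    protein_acc = c(rep("P2", 3), rep("P1", 3)))
  expect_equal(unname(resolve_shared_peptides(tie)["pep3"]), "P1")
})

test_that("protein roll-up follows the median/signed-fold convention and t-test", {
  runs <- c("c1", "c2", "m1", "m2")
  groups <- setNames(c("control", "control", "mutant", "mutant"), runs)
  mk_pm <- function(A, prot = "P1") {
    dimnames(A) <- list(sprintf("pep%d", seq_len(nrow(A))), runs)
    peptide_matrix(A, matrix("measured", nrow(A), 4, dimnames = dimnames(A)),
                   matrix(30, nrow(A), 4, dimnames = dimnames(A)),
                   data.frame(peptide_id = rownames(A), protein_acc = prot,
                              modification = "none", stringsAsFactors = FALSE))
  }

  # peptide ratios {2, 2, 4} -> median 2 -> signed FC +2
  A <- rbind(c(1, 1, 2, 2), c(3, 3, 6, 6), c(1, 1, 4, 4))
  q <- rollup_protein(mk_pm(A), groups)
  expect_equal(q$fold_change, 2)
  expect_equal(q$mode, "complete-peptides")
  expect_equal(q$n_peptides, 3L)

  # a single halved peptide: ratio 0.5 -> signed FC -2
  q2 <- rollup_protein(mk_pm(rbind(c(2, 2, 1, 1))), groups)
  expect_equal(q2$fold_change, -2)

  # |signed FC| >= 1 always
  set.seed(3)
  A3 <- matrix(rlnorm(20, 5, 1), 5)
  q3 <- rollup_protein(mk_pm(A3), groups)
  expect_true(abs(q3$fold_change) >= 1)

  # p-value equals the textbook pooled t-test on the log2 relative abundances
  A4 <- rbind(c(10, 12, 25, 21), c(100, 95, 180, 210))
  pm4 <- mk_pm(A4)
  rel <- log2(A4 / rowMeans(A4))
  expect_equal(rollup_protein(pm4, groups)$p_value,
               pooled_t_p(as.vector(rel[, 1:2]), as.vector(rel[, 3:4])))

  # per-peptide-ratio variant: one-sample t-test on log2 ratios
  A5 <- rbind(c(1, 1, 2.2, 2.0), c(5, 5, 9.5, 10.4), c(2, 2, 4.4, 3.8))
  ratios <- rowMeans(A5[, 3:4]) / rowMeans(A5[, 1:2])
  expect_equal(rollup_protein(mk_pm(A5), groups, test_input = "peptide_ratio")$p_value,
               t.test(log2(ratios), mu = 0)$p.value)

  # modified and unmodified peptides quantify as separate protein forms
  pm6 <- mk_pm(rbind(c(1, 1, 2, 2), c(1, 1, 8, 8)))
  pm6$peptides$modification <- c("none", "acetyl")
  q6 <- rollup_protein(pm6, groups)
  expect_equal(nrow(q6), 2L)
  expect_setequal(q6$form, c("none", "acetyl"))
  expect_equal(sort(q6$fold_change), c(2, 8))
})

test_that("significance selection on proteins uses a strict threshold", {
  q <- data.frame(accession = c("A", "B", "C"), p_value = c(0.099, 0.1, NA))
  sig <- significant_proteins(q, alpha = 0.1)
  expect_equal(sig$accession, "A")
})
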