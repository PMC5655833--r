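# Synthetic-data generators: DIA fragment traces with ground truth,
# Cuffdiff-style differential-expression tables, and a CNS cell-type
# reference expression matrix. Every downstream stage is testable against the
# recorded truth without raw data.

#' Configuration for the DIA experiment simulator
#'
#' Defaults emulate the study design the quantification engine targets: 4
#' biological replicates per genotype, multiplicative retention-time-dependent
#' matrix effects, log-normal peptide abundances and Dirichlet-partitioned
#' fragment intensities.
#'
#' @param n_proteins Number of simulated proteins.
#' @param peptides_per_protein Integer range `c(lo, hi)` of peptides per
#'   protein.
#' @param n_runs_per_group Runs per genotype group (default 4 vs 4; minimum 2).
#' @param frac_changed Fraction of proteins with a true genotype effect.
#' @param effect_log2 Bounds `c(lo, hi)` for the magnitude of true log2 fold
#'   changes (sign drawn at random).
#' @param rt_range Retention-time range in minutes peptide apexes are drawn
#'   from.
#' @param drift_coef_sd Scale of the per-run cubic retention-time drift
#'   coefficients (multiplicative bias `exp(c1 u + c2 u^2 + c3 u^3)` with `u`
#'   the rt scaled to [-1, 1]); 0 disables drift.
#' @param rt_shift_sd Scale (minutes) of the per-run affine retention-time
#'   shift the alignment step must undo.
#' @param fragment_count_range Integer range of fragments per peptide.
#' @param missing_rate Probability that a peptide is not identified in a run
#'   (its chromatographic signal is still present, so cross-run extraction can
#'   recover it).
#' @param noise_cv Coefficient of variation of multiplicative measurement
#'   noise.
#' @param seed Integer seed; every generator operation derives its own PRNG
#'   stream from it.
#' @return A list of class `dia_sim_config`.
#' @export
dia_sim_config <- function(n_proteins = 200,
                           peptides_per_protein = c(2, 4),
                           n_runs_per_group = 4,
                           frac_changed = 0.2,
                           effect_log2 = c(0.5, 2),
                           rt_range = c(10, 100),
                           drift_coef_sd = 0.2,
                           rt_shift_sd = 1,
                           fragment_count_range = c(6, 9),
                           missing_rate = 0.1,
                           noise_cv = 0.1,
                           seed = 1) {
  check_count(n_proteins, "n_proteins", min = 0L)
  check_range(peptides_per_protein, "peptides_per_protein", min = 1)
  check_count(n_runs_per_group, "n_runs_per_group", min = 2L)
  check_fraction(frac_changed, "frac_changed")
  check_range(effect_log2, "effect_log2", min = 0)
  check_range(rt_range, "rt_range", min = 0)
  if (!is.numeric(drift_coef_sd) || drift_coef_sd < 0)
    stop_config("drift_coef_sd", "must be >= 0")
  if (!is.numeric(rt_shift_sd) || rt_shift_sd < 0)
    stop_config("rt_shift_sd", "must be >= 0")
  check_range(fragment_count_range, "fragment_count_range", min = 1)
  check_fraction(missing_rate, "missing_rate")
  check_fraction(noise_cv, "noise_cv")
  check_count(seed, "seed")
  structure(as.list(environment()), class = "dia_sim_config")
}

#' Simulate a DIA proteomics experiment with recorded ground truth
#'
#' Emits a long-format fragment trace table per run plus a ground-truth
#' ledger. Peptide base abundances are log-normal; fragment intensities are
#' Dirichlet-partitioned from the peptide abundance; each run applies an
#' affine retention-time shift and a smooth multiplicative cubic drift in
#' retention time; measurement noise is multiplicative log-normal.
#' "Missingness" is an identification failure recorded in the `detected`
#' matrix - the chromatographic signal remains in the trace table so the
#' cross-run extraction path is exercised.
#'
#' @param config A [dia_sim_config()].
#' @return List with `traces` (trace table), `detected` (peptide x run logical
#'   matrix), `groups` (run id -> `"control"`/`"mutant"`), and `ledger`: a
#'   ground-truth record with `proteins` (`protein_acc`, `true_log2_fc`,
#'   `changed`), `peptide_truth` (true abundance per run before drift/noise),
#'   `noisy_abundance` (after noise, before drift - the measurement-path-free
#'   oracle input), `drift_coef`, `rt_shift`, and `changed_proteins`.
#' @examples
#' sim <- simulate_dia_experiment(dia_sim_config(n_proteins = 5, seed = 1))
#' head(sim$traces)
#' @export
simulate_dia_experiment <- function(config) {
  stopifnot(inherits(config, "dia_sim_config"))
  cf <- config
  n_runs <- 2L * cf$n_runs_per_group
  runs <- c(sprintf("WT_%d", seq_len(cf$n_runs_per_group)),
            sprintf("KO_%d", seq_len(cf$n_runs_per_group)))
  groups <- setNames(rep(c("control", "mutant"), each = cf$n_runs_per_group),
                     runs)

  # --- protein-level truth -------------------------------------------------
  prot <- sprintf("P%05d", seq_len(cf$n_proteins))
  n_changed <- round(cf$frac_changed * cf$n_proteins)
  truth <- with_op_seed(cf$seed, "protein_truth", {
    changed <- sort(sample(cf$n_proteins, n_changed))
    lfc <- numeric(cf$n_proteins)
    if (n_changed > 0L) {
      mag <- runif(n_changed, cf$effect_log2[1], cf$effect_log2[2])
      lfc[changed] <- mag * sample(c(-1, 1), n_changed, replace = TRUE)
    }
    list(changed = changed, lfc = lfc)
  })
  proteins <- data.frame(protein_acc = prot, true_log2_fc = truth$lfc,
                         changed = seq_len(cf$n_proteins) %in% truth$changed,
                         stringsAsFactors = FALSE)

  if (cf$n_proteins == 0L) {
    empty_traces <- data.frame(run_id = character(), peptide_id = character(),
                               protein_acc = character(), modification = character(),
                               fragment_id = character(), ion_type = character(),
                               charge = integer(), mz = numeric(),
                               rt_minutes = numeric(), scan_index = integer(),
                               intensity = numeric(), stringsAsFactors = FALSE)
    return(list(traces = empty_traces,
                detected = matrix(FALSE, 0, n_runs, dimnames = list(NULL, runs)),
                groups = groups,
                ledger = list(proteins = proteins,
                              peptide_truth = matrix(0, 0, n_runs),
                              noisy_abundance = matrix(0, 0, n_runs),
                              drift_coef = NULL, rt_shift = NULL,
                              changed_proteins = character())))
  }

  # --- peptide-level structure --------------------------------------------
  pep <- with_op_seed(cf$seed, "peptides", {
    npp <- sample(seq(cf$peptides_per_protein[1], cf$peptides_per_protein[2]),
                  cf$n_proteins, replace = TRUE)
    pep_prot <- rep(seq_len(cf$n_proteins), npp)
    n_pep <- length(pep_prot)
    data.frame(
      peptide_id = sprintf("pep%06d", seq_len(n_pep)),
      protein_acc = prot[pep_prot],
      protein_idx = pep_prot,
      modification = "none",
      base = rlnorm(n_pep, meanlog = log(1e5), sdlog = 1),
      apex_rt = runif(n_pep, cf$rt_range[1], cf$rt_range[2]),
      n_frag = sample(seq(cf$fragment_count_range[1], cf$fragment_count_range[2]),
                      n_pep, replace = TRUE),
      stringsAsFactors = FALSE)
  })
  n_pep <- nrow(pep)

  # --- per-run acquisition parameters -------------------------------------
  run_par <- with_op_seed(cf$seed, "runs", {
    list(shift_a = rnorm(n_runs, 0, cf$rt_shift_sd),
         shift_b = 1 + rnorm(n_runs, 0, 0.01),
         drift = matrix(rnorm(3L * n_runs, 0, cf$drift_coef_sd), nrow = 3L))
  })

  # true abundance per run before drift/noise
  is_mut <- groups[runs] == "mutant"
  peptide_truth <- outer(pep$base, rep(1, n_runs))
  lfc_pep <- proteins$true_log2_fc[pep$protein_idx]
  peptide_truth[, is_mut] <- peptide_truth[, is_mut] * 2^lfc_pep
  dimnames(peptide_truth) <- list(pep$peptide_id, runs)

  noise <- with_op_seed(cf$seed, "noise", {
    sdlog <- sqrt(log(1 + cf$noise_cv^2))
    matrix(rlnorm(n_pep * n_runs, -sdlog^2 / 2, sdlog), n_pep, n_runs)
  })
  noisy_abundance <- peptide_truth * noise
  dimnames(noisy_abundance) <- dimnames(peptide_truth)

  detected <- with_op_seed(cf$seed, "missingness", {
    matrix(runif(n_pep * n_runs) >= cf$missing_rate, n_pep, n_runs,
           dimnames = list(pep$peptide_id, runs))
  })

  # --- fragment structure ---------------------------------------------------
  frag <- with_op_seed(cf$seed, "fragments", {
    fp <- rep(seq_len(n_pep), pep$n_frag)
    n_fr <- length(fp)
    share <- rgamma(n_fr, shape = 1)
    share <- share / ave(share, fp, FUN = sum)
    data.frame(
      pep_idx = fp,
      fragment_id = sprintf("frag%07d", seq_len(n_fr)),
      ion_type = sample(c("b", "y"), n_fr, replace = TRUE),
      charge = sample(c(1L, 2L), n_fr, replace = TRUE),
      mz = runif(n_fr, 140, 1400),
      share = share,
      stringsAsFactors = FALSE)
  })
  n_fr <- nrow(frag)

  # --- assemble scan-level traces ------------------------------------------
  scan_off <- seq(-0.4, 0.4, by = 0.1)      # minutes around the apex
  peak_sd <- 0.15                           # chromatographic peak width
  k <- length(scan_off)
  shape <- dnorm(scan_off, 0, peak_sd)      # unit-area elution profile

  # rows ordered: run (outer), fragment (middle), scan (inner)
  run_i <- rep(seq_len(n_runs), each = n_fr * k)
  frag_i <- rep(rep(seq_len(n_fr), each = k), n_runs)
  pep_i <- frag$pep_idx[frag_i]
  off <- rep.int(scan_off, n_fr * n_runs)

  apex_run <- run_par$shift_a[run_i] + run_par$shift_b[run_i] * pep$apex_rt[pep_i]
  rt <- apex_run + off

  # smooth multiplicative drift as a cubic in scaled retention time
  u <- 2 * (apex_run - cf$rt_range[1]) / (cf$rt_range[2] - cf$rt_range[1]) - 1
  drift <- exp(run_par$drift[1, run_i] * u +
               run_par$drift[2, run_i] * u^2 +
               run_par$drift[3, run_i] * u^3)

  signal <- noisy_abundance[cbind(pep_i, run_i)] * drift * frag$share[frag_i]
  intensity <- signal * rep.int(shape, n_fr * n_runs)

  traces <- data.frame(
    run_id = runs[run_i],
    peptide_id = pep$peptide_id[pep_i],
    protein_acc = pep$protein_acc[pep_i],
    modification = pep$modification[pep_i],
    fragment_id = frag$fragment_id[frag_i],
    ion_type = frag$ion_type[frag_i],
    charge = frag$charge[frag_i],
    mz = frag$mz[frag_i],
    rt_minutes = rt,
    scan_index = as.integer(round(rt * 1000)),
    intensity = intensity,
    stringsAsFactors = FALSE)

  list(traces = traces, detected = detected, groups = groups,
       ledger = list(proteins = proteins,
                     peptide_truth = peptide_truth,
                     noisy_abundance = noisy_abundance,
                     drift_coef = run_par$drift,
                     rt_shift = data.frame(run_id = runs,
                                           intercept = run_par$shift_a,
                                           slope = run_par$shift_b),
                     changed_proteins = prot[truth$changed]))
}

#' Write a simulated DIA experiment to disk
#'
#' Serializes the trace table and detection matrix as TSV and the
#' ground-truth ledger as JSON (drift/shift parameters, protein truth) plus a
#' TSV of the per-run true peptide abundances.
#'
#' @param sim Output of [simulate_dia_experiment()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.table(sim$traces, file.path(dir, "traces.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  det <- data.frame(peptide_id = rownames(sim$detected), sim$detected,
                    check.names = FALSE)
  write.table(det, file.path(dir, "detected.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- data.frame(peptide_id = rownames(sim$ledger$peptide_truth),
                      sim$ledger$peptide_truth, check.names = FALSE)
  write.table(truth, file.path(dir, "peptide_truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(groups = as.list(sim$groups),
         proteins = sim$ledger$proteins,
         changed_proteins = sim$ledger$changed_proteins,
         rt_shift = sim$ledger$rt_shift,
         drift_coef = sim$ledger$drift_coef),
    file.path(dir, "ledger.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Configuration for the differential-expression table simulator
#'
#' @param n_genes Number of genes.
#' @param block_sizes Named integer vector of cell-type-enriched block sizes
#'   (names from neuron, astrocyte, microglia, oligodendrocyte, endothelial);
#'   must sum to at most `n_genes`; remaining genes are not enriched. The
#'   default assigns roughly a third of genes to cell types in the proportions
#'   observed for differentially expressed genes in MeCP2-deficient cortex
#'   (neuron 8%, astrocyte 12%, microglia 2.5%, oligodendrocyte 6.5%,
#'   endothelial 3.5%).
#' @param frac_de Fraction of genes truly differential.
#' @param effect_log2 Bounds for true |log2 fold change| of differential genes.
#' @param n_replicates Replicates per group used for the simulated test.
#' @param dispersion Standard deviation of replicate-level log2 FPKM noise.
#' @param frac_noncoding Fraction of genes given a non-coding biotype.
#' @param length_sampler Function(n) returning gene lengths in bp; the default
#'   is log-normal around 30 kb so a realistic minority of genes crosses the
#'   100-kb boundary.
#' @param dir_bias Function(cell_type, length_class) giving the probability a
#'   truly differential gene is increased; the default biases long genes
#'   toward increased and short genes toward decreased expression.
#' @param seed Integer seed.
#' @return A list of class `de_sim_config`.
#' @export
de_sim_config <- function(n_genes = 1000,
                          block_sizes = NULL,
                          frac_de = 0.1,
                          effect_log2 = c(0.5, 1.5),
                          n_replicates = 4,
                          dispersion = 0.25,
                          frac_noncoding = 0.1,
                          length_sampler = NULL,
                          dir_bias = NULL,
                          seed = 1) {
  check_count(n_genes, "n_genes", min = 0L)
  if (is.null(block_sizes))
    block_sizes <- round(n_genes * c(neuron = 0.08, astrocyte = 0.12,
                                     microglia = 0.025, oligodendrocyte = 0.065,
                                     endothelial = 0.035))
  if (length(block_sizes) > 0) {
    bad <- setdiff(names(block_sizes), CELL_TYPES_MERGED)
    if (length(bad) > 0)
      stop_config("block_sizes", paste("unknown cell type(s):",
                                       paste(bad, collapse = ", ")))
    if (sum(block_sizes) > n_genes)
      stop_config("block_sizes", "block sizes must sum to at most n_genes")
  }
  check_fraction(frac_de, "frac_de")
  check_range(effect_log2, "effect_log2", min = 0)
  check_count(n_replicates, "n_replicates", min = 2L)
  if (!is.numeric(dispersion) || dispersion < 0)
    stop_config("dispersion", "must be >= 0")
  check_fraction(frac_noncoding, "frac_noncoding")
  check_count(seed, "seed")
  if (is.null(length_sampler))
    length_sampler <- function(n) round(rlnorm(n, log(3e4), 1.1)) + 200
  if (is.null(dir_bias))
    dir_bias <- function(cell_type, length_class)
      ifelse(length_class == "long", 0.7, 0.25)
  structure(list(n_genes = n_genes, block_sizes = block_sizes,
                 frac_de = frac_de, effect_log2 = effect_log2,
                 n_replicates = n_replicates, dispersion = dispersion,
                 frac_noncoding = frac_noncoding,
                 length_sampler = length_sampler, dir_bias = dir_bias,
                 seed = seed),
            class = "de_sim_config")
}

#' Simulate a Cuffdiff-style differential-expression gene table
#'
#' Produces a gene table mirroring Cuffdiff's gene_exp output (FPKM per group,
#' log2 fold change, p, Benjamini-Hochberg q) plus biotype, coordinates
#' consistent with the assigned gene lengths, and per-gene truth labels.
#'
#' @param config A [de_sim_config()].
#' @return Data frame with columns `gene`, `chrom`, `start`, `end`, `locus`,
#'   `biotype`, `length_kb`, `value_1` (control FPKM), `value_2` (mutant
#'   FPKM), `log2_fc`, `p_value`, `q_value` and truth columns `true_de`,
#'   `true_log2_fc`, `cell_type`.
#' @export
simulate_de_table <- function(config) {
  stopifnot(inherits(config, "de_sim_config"))
  cf <- config
  n <- cf$n_genes
  gene <- sprintf("gene%05d", seq_len(n))
  if (n == 0L) {
    return(data.frame(gene = character(), chrom = character(),
                      start = integer(), end = integer(), locus = character(),
                      biotype = character(), length_kb = numeric(),
                      value_1 = numeric(), value_2 = numeric(),
                      log2_fc = numeric(), p_value = numeric(),
                      q_value = numeric(), true_de = logical(),
                      true_log2_fc = numeric(), cell_type = character(),
                      stringsAsFactors = FALSE))
  }

  cell_type <- rep("not_enriched", n)
  if (length(cf$block_sizes) > 0) {
    lab <- rep(names(cf$block_sizes), cf$block_sizes)
    cell_type[seq_along(lab)] <- lab
  }

  lengths_bp <- with_op_seed(cf$seed, "lengths", cf$length_sampler(n))
  if (any(lengths_bp <= 0)) stop_config("length_sampler", "lengths must be > 0")
  length_kb <- lengths_bp / 1000
  len_class <- ifelse(length_kb >= 100, "long", "short")

  coords <- with_op_seed(cf$seed, "coords", {
    chrom <- paste0("chr", sample(c(1:19, "X"), n, replace = TRUE))
    start <- sample.int(1e8, n, replace = TRUE)
    list(chrom = chrom, start = start, end = start + lengths_bp)
  })

  truth <- with_op_seed(cf$seed, "de_truth", {
    n_de <- round(cf$frac_de * n)
    de_idx <- sort(sample(n, n_de))
    lfc <- numeric(n)
    if (n_de > 0L) {
      mag <- runif(n_de, cf$effect_log2[1], cf$effect_log2[2])
      p_up <- vapply(de_idx, function(i) cf$dir_bias(cell_type[i], len_class[i]),
                     numeric(1))
      sign <- ifelse(runif(n_de) < p_up, 1, -1)
      lfc[de_idx] <- mag * sign
    }
    list(de = seq_len(n) %in% de_idx, lfc = lfc)
  })

  expr <- with_op_seed(cf$seed, "expression", {
    base <- rlnorm(n, log(20), 1)
    m <- cf$n_replicates
    l2b <- log2(base)
    x1 <- matrix(rnorm(n * m, l2b, cf$dispersion), n, m)
    x2 <- matrix(rnorm(n * m, l2b + truth$lfc, cf$dispersion), n, m)
    p <- vapply(seq_len(n), function(i) t.test(x2[i, ], x1[i, ])$p.value,
                numeric(1))
    v1 <- rowMeans(2^x1); v2 <- rowMeans(2^x2)
    list(v1 = v1, v2 = v2, lfc_obs = log2(v2 / v1), p = p)
  })

  biotype <- with_op_seed(cf$seed, "biotype", {
    nc <- runif(n) < cf$frac_noncoding
    ifelse(nc, sample(c("lincRNA", "antisense", "processed_transcript"),
                      n, replace = TRUE), "protein_coding")
  })

  data.frame(gene = gene, chrom = coords$chrom, start = coords$start,
             end = coords$end,
             locus = sprintf("%s:%d-%d", coords$chrom, coords$start, coords$end),
             biotype = biotype, length_kb = length_kb,
             value_1 = expr$v1, value_2 = expr$v2,
             log2_fc = expr$lfc_obs, p_value = expr$p,
             q_value = p.adjust(expr$p, method = "BH"),
             true_de = truth$de, true_log2_fc = truth$lfc,
             cell_type = cell_type, stringsAsFactors = FALSE)
}

#' Simulate a CNS cell-type reference expression matrix
#'
#' Builds a gene x cell-type matrix with the seven reference columns (neuron,
#' astrocyte, microglia, the three oligodendrocyte lineage stages, and
#' endothelial). Genes designated enriched get expression in the target cell
#' type equal to `enrichment_factor` times the maximum over all other cell
#' types (for oligodendrocyte assignments the enriched value is placed in one
#' lineage-stage sub-column, so sub-column merging is exercised). Background
#' expression of non-designated genes is drawn from a range that cannot reach
#' 3-fold enrichment by chance.
#'
#' @param n_genes Number of genes (named `gene00001`, ...).
#' @param enriched_assignments Named character vector: gene name -> merged
#'   cell-type label (one of neuron, astrocyte, microglia, oligodendrocyte,
#'   endothelial).
#' @param enrichment_factor Ratio of the enriched cell type's expression to
#'   the maximum of all others; must be > 0.
#' @param seed Integer seed.
#' @return Data frame with columns `gene` and the seven reference cell types.
#' @export
simulate_celltype_reference <- function(n_genes, enriched_assignments = character(),
                                        enrichment_factor = 3, seed = 1) {
  check_count(n_genes, "n_genes", min = 0L)
  if (!is.numeric(enrichment_factor) || enrichment_factor <= 0)
    stop_config("enrichment_factor", "must be > 0")
  check_count(seed, "seed")
  genes <- sprintf("gene%05d", seq_len(n_genes))
  if (length(enriched_assignments) > 0) {
    bad <- setdiff(unique(enriched_assignments), CELL_TYPES_MERGED)
    if (length(bad) > 0)
      stop("unknown cell-type label(s): ", paste(bad, collapse = ", "))
    missing <- setdiff(names(enriched_assignments), genes)
    if (length(missing) > 0)
      stop("enriched_assignments name genes outside the reference: ",
           paste(head(missing, 5), collapse = ", "))
  }
  cols <- CELL_TYPES_REFERENCE
  mat <- with_op_seed(seed, "celltype_reference", {
    # background in [5, 10]: max/min <= 2, so no accidental 3-fold enrichment
    m <- matrix(runif(n_genes * length(cols), 5, 10), n_genes, length(cols),
                dimnames = list(genes, cols))
    for (g in names(enriched_assignments)) {
      target <- enriched_assignments[[g]]
      if (target == "oligodendrocyte") {
        # place the enriched value in one lineage-stage sub-column; the ratio
        # is taken against the non-oligodendrocyte columns so that, after the
        # max-merge, the enrichment ratio equals the factor exactly
        sub <- sample(OLIGO_SUBTYPES, 1L)
        others <- setdiff(cols, OLIGO_SUBTYPES)
        m[g, sub] <- enrichment_factor * max(m[g, others])
      } else {
        others <- setdiff(cols, target)
        m[g, target] <- enrichment_factor * max(m[g, others])
      }
    }
    m
  })
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (cc in cols) out[[cc]] <- if (n_genes > 0) mat[, cc] else numeric()
  out
}
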