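# End-to-end DIA quantification: traces -> protein quantification table.

#' Quantify a DIA experiment from fragment traces
#'
#' Runs the full label-free quantification chain: per-run fragment
#' deconvolution ([deconvolve_fragments()]), quantification-fragment selection
#' ([select_quant_fragments()]), MS2 AUC integration ([integrate_ms2_auc()]),
#' retention-time mapping between runs ([fit_rt_map()]), cross-run extraction
#' of undetected peptides ([extract_missing_peptides()]), retention-time-aware
#' normalization ([normalize_matrix()]), rescaling to a relative scale with
#' minimum 1 ([rescale_relative()]), shared-peptide resolution
#' ([resolve_shared_peptides()]) and median peptide-to-protein roll-up with an
#' unpaired t-test ([rollup_protein()]).
#'
#' @param traces Long-format trace table with columns `run_id`, `peptide_id`,
#'   `protein_acc`, `modification`, `fragment_id`, `ion_type`, `charge`, `mz`,
#'   `rt_minutes`, `scan_index`, `intensity`.
#' @param groups Named character vector, run id -> group label.
#' @param detected Optional logical matrix (peptide x run): which cells were
#'   identified. Cells present in `traces` but not flagged detected are left
#'   to cross-run extraction. `NULL` treats every traced cell as detected.
#' @param control,mutant Group labels compared by the roll-up.
#' @param tolerance,retain_fraction Deconvolution parameters.
#' @param min_fragments,max_fragments,min_rel_intensity Fragment-selection
#'   parameters.
#' @param max_normalizers Normalization parameter.
#' @param extraction_k,extraction_min_halfwidth Extraction window parameters
#'   (residual-scale multiple; minimum half-width in minutes).
#' @param test,test_input Passed to [rollup_protein()].
#' @return List with `proteins` (the protein quantification table), `matrix`
#'   (the final [peptide_matrix]), `reference_run` and `rt_maps`.
#' @export
quantify_dia <- function(traces, groups, detected = NULL,
                         control = "control", mutant = "mutant",
                         tolerance = 0.01, retain_fraction = 0.70,
                         min_fragments = 5, max_fragments = 9,
                         min_rel_intensity = 0.10,
                         max_normalizers = 25,
                         extraction_k = 3, extraction_min_halfwidth = 0.5,
                         test = "pooled", test_input = "pooled_obs") {
  need <- c("run_id", "peptide_id", "protein_acc", "modification",
            "fragment_id", "ion_type", "charge", "mz", "rt_minutes",
            "scan_index", "intensity")
  miss <- setdiff(need, names(traces))
  if (length(miss) > 0L)
    stop("trace table is missing column(s): ", paste(miss, collapse = ", "))

  runs <- sort(unique(traces$run_id))
  peps <- unique(traces[, c("peptide_id", "protein_acc", "modification")])
  peps <- peps[order(peps$peptide_id), , drop = FALSE]
  rownames(peps) <- NULL
  pid <- peps$peptide_id

  if (is.null(detected)) {
    detected <- matrix(FALSE, nrow = length(pid), ncol = length(runs),
                       dimnames = list(pid, runs))
    seen <- unique(traces[, c("peptide_id", "run_id")])
    detected[cbind(match(seen$peptide_id, pid), match(seen$run_id, runs))] <- TRUE
  } else {
    detected <- detected[pid, runs, drop = FALSE]
  }

  A <- matrix(NA_real_, length(pid), length(runs), dimnames = list(pid, runs))
  S <- matrix("absent", length(pid), length(runs), dimnames = list(pid, runs))
  RT <- matrix(NA_real_, length(pid), length(runs), dimnames = list(pid, runs))
  frag_mz <- vector("list", length(pid)); names(frag_mz) <- pid

  cell_key <- paste(traces$peptide_id, traces$run_id, sep = "\r")
  idx <- split(seq_len(nrow(traces)), cell_key)

  for (p in pid) {
    for (r in runs) {
      if (!detected[p, r]) next
      rows <- idx[[paste(p, r, sep = "\r")]]
      if (is.null(rows)) next
      sub <- traces[rows, c("mz", "scan_index", "rt_minutes", "intensity",
                            "ion_type", "charge", "fragment_id")]
      dec <- deconvolve_fragments(sub, tolerance = tolerance,
                                  retain_fraction = retain_fraction)
      sel <- select_quant_fragments(dec$fragments, min_n = min_fragments,
                                    max_n = max_fragments,
                                    min_rel_intensity = min_rel_intensity)
      if (is.null(sel)) next  # unquantifiable in this run
      tr <- dec$traces[dec$traces$group %in% sel$group, , drop = FALSE]
      auc <- integrate_ms2_auc(tr)
      if (!is.finite(auc) || auc <= 0) next
      A[p, r] <- auc
      S[p, r] <- "measured"
      RT[p, r] <- dec$apex_rt
      if (is.null(frag_mz[[p]])) frag_mz[[p]] <- sel$mz
    }
  }

  keep <- rowSums(S == "measured") > 0
  pm <- peptide_matrix(A[keep, , drop = FALSE], S[keep, , drop = FALSE],
                       RT[keep, , drop = FALSE],
                       peps[keep, , drop = FALSE], frag_mz[keep])

  n_measured <- colSums(pm$status == "measured")
  reference_run <- runs[which.max(n_measured)]
  ref_rt <- pm$apex_rt[, reference_run]
  names(ref_rt) <- rownames(pm$abundance)
  ref_rt <- ref_rt[pm$status[, reference_run] == "measured"]

  rt_maps <- lapply(runs, function(r) {
    if (r == reference_run) return(identity_rt_map())
    tgt <- pm$apex_rt[, r]
    names(tgt) <- rownames(pm$abundance)
    tgt <- tgt[pm$status[, r] == "measured"]
    tryCatch(fit_rt_map(ref_rt, tgt), error = function(e) {
      warning(sprintf("run '%s': %s; falling back to the identity map",
                      r, conditionMessage(e)))
      identity_rt_map()
    })
  })
  names(rt_maps) <- runs

  pm <- extract_missing_peptides(pm, traces, rt_maps, reference_run,
                                 k_sigma = extraction_k,
                                 min_halfwidth = extraction_min_halfwidth,
                                 tolerance = tolerance)
  # extracted cells with no recoverable signal carry no abundance information:
  # demote to absent so downstream positivity requirements hold
  zero <- pm$status == "extracted" & (!is.finite(pm$abundance) | pm$abundance <= 0)
  pm$abundance[zero] <- NA_real_
  pm$status[zero] <- "absent"

  pm <- normalize_matrix(pm, max_normalizers = max_normalizers)
  pm <- rescale_relative(pm)

  assign_tab <- unique(traces[, c("peptide_id", "run_id", "protein_acc")])
  pep_map <- resolve_shared_peptides(assign_tab)

  proteins <- rollup_protein(pm, groups, control = control, mutant = mutant,
                             peptide_map = pep_map,
                             test = test, test_input = test_input)
  list(proteins = proteins, matrix = pm,
       reference_run = reference_run, rt_maps = rt_maps)
}

#' Write a protein quantification table to TSV
#'
#' Floats are serialized with 6 significant digits.
#' @param quants Protein quantification table from [rollup_protein()].
#' @param path Output file path.
#' @export
write_protein_quants <- function(quants, path) {
  out <- quants
  for (col in c("fold_change", "p_value"))
    out[[col]] <- signif(out[[col]], 6)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a peptide abundance matrix to TSV (long format)
#' @param pm A [peptide_matrix].
#' @param path Output file path.
#' @export
write_peptide_matrix <- function(pm, path) {
  long <- data.frame(
    peptide_id = rep(rownames(pm$abundance), ncol(pm$abundance)),
    run_id = rep(colnames(pm$abundance), each = nrow(pm$abundance)),
    abundance = signif(as.vector(pm$abundance), 6),
    status = as.vector(pm$status),
    apex_rt = signif(as.vector(pm$apex_rt), 6),
    stringsAsFactors = FALSE)
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
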