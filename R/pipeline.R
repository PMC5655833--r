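# Pipeline orchestration: configuration, validation, staged execution,
# summary reporting.

#' Build a pipeline configuration
#'
#' Inputs may be in-memory objects or file paths (TSV). Any stage whose inputs
#' are absent is skipped; the report stage runs whenever the bundled (or user)
#' summary tables are supplied.
#'
#' @param traces,detected,groups DIA quantification inputs (see
#'   [quantify_dia()]); `traces` may be a path to a trace TSV.
#' @param de_table Gene table (data frame or TSV path, see [load_de_table()]).
#' @param celltype_reference Reference expression matrix (data frame or TSV
#'   path with the seven reference columns).
#' @param symbol_map Accession -> gene symbol map for gene-protein matching.
#' @param citations Citation table for [annotate_rtt_hits()]; defaults to the
#'   bundled one when the report tables are used.
#' @param gene_hits_table,gene_protein_table Report-only inputs; `TRUE` loads
#'   the bundled tables.
#' @param gene_q,gene_relaxed_p,protein_p Significance thresholds.
#' @param enrichment_fold Cell-type enrichment threshold.
#' @param length_boundary_kb Short/long gene boundary.
#' @param t_test,t_test_input,oligo_merge,compare_rule Mode flags (see
#'   [rollup_protein()], [merge_oligo_subtypes()], [classify_cell_type()]).
#' @param seed Integer seed recorded in the summary.
#' @param output_dir Directory for stage outputs and `summary.json`; `NULL`
#'   returns results without writing.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(traces = NULL, detected = NULL, groups = NULL,
                            de_table = NULL, celltype_reference = NULL,
                            symbol_map = NULL, citations = NULL,
                            gene_hits_table = NULL, gene_protein_table = NULL,
                            gene_q = 0.05, gene_relaxed_p = 0.05,
                            protein_p = 0.1, enrichment_fold = 3,
                            length_boundary_kb = 100,
                            t_test = "pooled", t_test_input = "pooled_obs",
                            oligo_merge = "max", compare_rule = "max",
                            seed = 1, output_dir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' All violations are reported at once.
#'
#' @param config A [pipeline_config()].
#' @return Character vector of error messages; empty when the configuration
#'   is valid.
#' @export
validate_config <- function(config) {
  errs <- character()
  chk_prob <- function(value, field) {
    if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
        value <= 0 || value >= 1)
      errs[[length(errs) + 1L]] <<- sprintf("%s must be in (0, 1)", field)
  }
  chk_prob(config$gene_q, "gene_q")
  chk_prob(config$gene_relaxed_p, "gene_relaxed_p")
  chk_prob(config$protein_p, "protein_p")
  if (!is.numeric(config$enrichment_fold) || config$enrichment_fold <= 0)
    errs <- c(errs, "enrichment_fold must be > 0")
  if (!is.numeric(config$length_boundary_kb) || config$length_boundary_kb <= 0)
    errs <- c(errs, "length_boundary_kb must be > 0")
  if (!config$t_test %in% c("pooled", "welch"))
    errs <- c(errs, "t_test must be 'pooled' or 'welch'")
  if (!config$t_test_input %in% c("pooled_obs", "peptide_ratio"))
    errs <- c(errs, "t_test_input must be 'pooled_obs' or 'peptide_ratio'")
  if (!config$oligo_merge %in% c("max", "mean"))
    errs <- c(errs, "oligo_merge must be 'max' or 'mean'")
  if (!config$compare_rule %in% c("max", "mean"))
    errs <- c(errs, "compare_rule must be 'max' or 'mean'")
  if (!is.numeric(config$seed) || length(config$seed) != 1L || is.na(config$seed))
    errs <- c(errs, "seed must be a single number")
  errs
}

read_if_path <- function(x, loader) {
  if (is.character(x) && length(x) == 1L) loader(x) else x
}

#' Run the analysis pipeline end to end
#'
#' Executes, for whichever inputs the configuration supplies: DIA
#' quantification, differential-expression filtering, cell-type enrichment
#' classification, length/direction cross-tabulation, gene-protein
#' integration, and the report stage over the bundled summary tables. Stage
#' outputs are written as TSV under `output_dir` together with a single
#' `summary.json`; reruns on identical inputs and seed are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return The summary list (invisibly when written to disk).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  errs <- validate_config(config)
  if (length(errs) > 0)
    stop("invalid pipeline configuration:\n  - ", paste(errs, collapse = "\n  - "))

  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit <- function(obj, file) {
    if (!is.null(out_dir))
      write.table(obj, file.path(out_dir, file), sep = "\t", quote = FALSE,
                  row.names = FALSE)
  }
  stage <- function(name, expr) {
    message(sprintf("[rettomics] stage=%s seed=%s", name, config$seed))
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  summary <- list(seed = config$seed,
                  thresholds = list(gene_q = config$gene_q,
                                    gene_relaxed_p = config$gene_relaxed_p,
                                    protein_p = config$protein_p,
                                    enrichment_fold = config$enrichment_fold,
                                    length_boundary_kb = config$length_boundary_kb))
  proteins <- NULL
  sig_genes <- NULL

  if (!is.null(config$traces)) {
    quant <- stage("quant", {
      traces <- read_if_path(config$traces,
                             function(p) read.delim(p, stringsAsFactors = FALSE))
      quantify_dia(traces, groups = config$groups, detected = config$detected,
                   test = config$t_test, test_input = config$t_test_input)
    })
    proteins <- quant$proteins
    emit(proteins, "protein_quants.tsv")
    sig_prot <- significant_proteins(proteins, alpha = config$protein_p)
    summary$quant <- list(n_proteins = nrow(proteins),
                          n_significant = nrow(sig_prot))
  }

  de_tbl <- NULL
  if (!is.null(config$de_table)) {
    de_res <- stage("de_filter", {
      tbl <- read_if_path(config$de_table, load_de_table)
      if (!"length_kb" %in% names(tbl))
        tbl$length_kb <- (tbl$end - tbl$start) / 1000
      kept <- filter_noncoding(tbl, q_threshold = config$gene_q)
      sig <- significant_genes(kept, q_threshold = config$gene_q)
      list(kept = kept, sig = sig)
    })
    de_tbl <- de_res$kept
    sig_genes <- de_res$sig
    emit(sig_genes, "significant_genes.tsv")
    dirs <- direction_summary(sig_genes)
    summary$de <- c(list(n_loaded = nrow(de_tbl),
                         n_significant = nrow(sig_genes)), dirs)
  }

  calls <- NULL
  if (!is.null(config$celltype_reference) && !is.null(sig_genes)) {
    ct <- stage("celltype", {
      ref <- read_if_path(config$celltype_reference, load_celltype_reference)
      merged <- merge_oligo_subtypes(ref, method = config$oligo_merge)
      calls <- classify_cell_type(sig_genes$gene, merged,
                                  threshold = config$enrichment_fold,
                                  compare = config$compare_rule)
      list(calls = calls, summary = distribution_summary(calls))
    })
    calls <- ct$calls
    emit(calls, "celltype_calls.tsv")
    summary$celltype <- list(counts = as.list(ct$summary$counts))
  }

  if (!is.null(calls) && !is.null(sig_genes)) {
    lb <- stage("lengthbias",
                crosstab_length_direction(sig_genes, calls,
                                          boundary_kb = config$length_boundary_kb))
    emit(lb, "length_direction.tsv")
    overall <- lb[lb$stratum == "overall", ]
    summary$length_bias <- list(
      short_increased = overall$short_increased,
      short_decreased = overall$short_decreased,
      long_increased = overall$long_increased,
      long_decreased = overall$long_decreased)
  }

  if (!is.null(proteins) && !is.null(sig_genes) && !is.null(config$symbol_map)) {
    integ <- stage("integrate", {
      ms <- match_gene_protein(de_tbl, proteins, config$symbol_map,
                               gene_q = config$gene_q,
                               gene_p = config$gene_relaxed_p,
                               protein_p = config$protein_p)
      sig <- significant_matches(ms)
      r <- if (nrow(sig) >= 3) gene_protein_correlation(sig) else NULL
      list(matches = ms, sig = sig, r = r)
    })
    emit(integ$sig, "significant_matches.tsv")
    summary$integration <- list(
      n_matches = nrow(integ$matches$matches),
      n_significant = nrow(integ$sig),
      pearson_r = if (!is.null(integ$r)) integ$r$r else NA)
  }

  # report stage over the bundled summary tables
  hits <- config$gene_hits_table
  if (isTRUE(hits)) hits <- load_rtt_gene_hits()
  if (!is.null(hits) && !isFALSE(hits)) {
    rep1 <- stage("report_gene_hits", direction_summary(read_if_path(
      hits, function(p) read.delim(p, stringsAsFactors = FALSE))))
    summary$rtt_gene_hits <- rep1
  }
  gpt <- config$gene_protein_table
  if (isTRUE(gpt)) gpt <- load_gene_protein_table()
  if (!is.null(gpt) && !isFALSE(gpt)) {
    rep2 <- stage("report_gene_protein", {
      tab <- if (is.character(gpt)) load_gene_protein_table(gpt) else gpt
      sig <- significant_matches(tab)
      cites <- config$citations %||% rtt_citation_table(tab)
      ann <- annotate_rtt_hits(sig, cites)
      r <- gene_protein_correlation(sig)
      list(n_significant = nrow(sig), n_known = ann$n_known,
           n_novel = ann$n_novel, pearson_r = r$r, n_correlated = r$n)
    })
    summary$gene_protein <- rep2
  }

  if (!is.null(out_dir)) {
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(summary))
  }
  summary
}
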