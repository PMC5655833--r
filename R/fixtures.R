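# Bundled reference tables: the 35 differentially expressed genes previously
# reported as Rett-syndrome expression hits, and the 35 jointly significant
# gene-protein matches from the same cortex study design (gene q < 0.05,
# protein p < 0.1), including PTM forms.

#' Load the bundled table of previously reported Rett-syndrome gene hits
#'
#' 35 significant differentially expressed genes with their log2 fold change
#' and the citation references under which each was previously reported.
#'
#' @param path Path to the TSV; defaults to the bundled copy.
#' @return Data frame with columns `gene`, `log2_fc`, `reported_direction`,
#'   `references`.
#' @export
load_rtt_gene_hits <- function(path = system.file("extdata", "rtt_gene_hits.tsv",
                                                  package = "rettomics")) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Load the bundled gene-protein match table
#'
#' 35 jointly significant gene-protein matches (every row satisfies gene
#' q < 0.05 and protein p < 0.1 by construction of the source table, so the
#' significance flags are set; the underlying p/q values are not published and
#' are `NA`). PTM forms ("acetyl", "phospho") of one protein appear as
#' distinct matches.
#'
#' @param path Path to the TSV; defaults to the bundled copy.
#' @return A `gene_protein_matches`-style match table (data frame) with
#'   columns `gene`, `accession`, `form`, `gene_log2_fc`, `gene_p`, `gene_q`,
#'   `protein_fc`, `protein_log2_fc`, `protein_p`, `gene_sig_q`, `gene_sig_p`,
#'   `protein_sig`, plus `protein` (display name) and `rtt_hit_refs`.
#' @export
load_gene_protein_table <- function(path = system.file("extdata",
                                                       "gene_protein_matches.tsv",
                                                       package = "rettomics")) {
  raw <- read.delim(path, stringsAsFactors = FALSE, na.strings = NULL)
  data.frame(
    gene = raw$gene,
    protein = raw$protein,
    accession = raw$accession,
    form = raw$ptm,
    gene_log2_fc = raw$gene_log2_fc,
    gene_p = NA_real_,
    gene_q = NA_real_,
    protein_fc = raw$protein_fc,
    protein_log2_fc = signed_fold_to_log2(raw$protein_fc),
    protein_p = NA_real_,
    gene_sig_q = TRUE,
    gene_sig_p = TRUE,
    protein_sig = TRUE,
    rtt_hit_refs = ifelse(is.na(raw$rtt_hit_refs), "", raw$rtt_hit_refs),
    stringsAsFactors = FALSE)
}

#' Citation table of previously reported Rett-syndrome hits
#'
#' Derives a gene -> citation-labels table from the bundled match table,
#' suitable for [annotate_rtt_hits()].
#'
#' @param match_table Output of [load_gene_protein_table()].
#' @return Data frame with columns `gene`, `labels` (genes with at least one
#'   citation only).
#' @export
rtt_citation_table <- function(match_table = load_gene_protein_table()) {
  known <- match_table[match_table$rtt_hit_refs != "", c("gene", "rtt_hit_refs")]
  known <- known[!duplicated(tolower(known$gene)), ]
  data.frame(gene = known$gene, labels = known$rtt_hit_refs,
             stringsAsFactors = FALSE)
}
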