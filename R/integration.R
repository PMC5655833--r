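# Gene-protein integration: matching, dual significance thresholds,
# correlation, and annotation of previously reported Rett-syndrome hits.

#' Convert a signed fold change to a log2 value
#'
#' Under the signed convention a value >= 1 is the plain ratio and a value -k
#' denotes a 1/k ratio, so fc >= 1 maps to log2(fc) and fc <= -1 maps to
#' -log2(-fc). Values with |fc| < 1 violate the convention and raise an error.
#'
#' @param fc Numeric vector of signed fold changes.
#' @return Numeric vector of log2 fold changes.
#' @examples
#' signed_fold_to_log2(c(2, -2))  # 1, -1
#' @export
signed_fold_to_log2 <- function(fc) {
  if (any(abs(fc) < 1 - 1e-12, na.rm = TRUE))
    stop("signed fold changes must satisfy |fc| >= 1")
  sign(fc) * log2(abs(fc))
}

#' Invert [signed_fold_to_log2()]
#' @param l2 Numeric vector of log2 fold changes.
#' @return Signed fold changes (values in (-1, 1) never occur).
#' @export
log2_to_signed_fold <- function(l2) {
  ifelse(l2 >= 0, 2^l2, -(2^(-l2)))
}

#' Match gene records to protein quantifications
#'
#' Joins a gene table and a protein quantification table through an accession
#' to gene-symbol map; matching on symbols is case-insensitive. Every
#' (gene, protein form) pair yields one match, so PTM forms of one protein
#' (e.g. an acetylated and an unmodified form) give distinct matches. Genes
#' without a detected protein and proteins without a detected gene are
#' reported separately, never silently dropped.
#'
#' @param genes Gene table with `gene`, `log2_fc`, `p_value`, `q_value`.
#' @param proteins Protein table with `accession`, `form`, `fold_change`,
#'   `p_value`.
#' @param symbol_map Data frame with columns `accession`, `gene`. An accession
#'   mapping to more than one symbol is an error listing the conflicts.
#' @param gene_q,gene_p,protein_p Thresholds used to precompute the
#'   significance flags (strict inequalities).
#' @return List of class `gene_protein_matches`: `matches` (one row per pair
#'   with fold changes, p/q values and logical flags `gene_sig_q`,
#'   `gene_sig_p`, `protein_sig`), `unmatched_genes`, `unmatched_proteins`.
#' @export
match_gene_protein <- function(genes, proteins, symbol_map,
                               gene_q = 0.05, gene_p = 0.05, protein_p = 0.1) {
  stopifnot(all(c("accession", "gene") %in% names(symbol_map)))
  conflicts <- tapply(symbol_map$gene, symbol_map$accession,
                      function(g) length(unique(tolower(g))))
  bad <- names(conflicts)[conflicts > 1]
  if (length(bad) > 0)
    stop("ambiguous accession-to-symbol mapping for: ",
         paste(bad, collapse = ", "))

  map <- symbol_map[!duplicated(symbol_map$accession), ]
  psym <- tolower(map$gene[match(proteins$accession, map$accession)])
  gsym <- tolower(genes$gene)

  rows <- list()
  for (i in seq_len(nrow(proteins))) {
    if (is.na(psym[i])) next
    gi <- which(gsym == psym[i])
    for (g in gi) {
      plog2 <- signed_fold_to_log2(proteins$fold_change[i])
      rows[[length(rows) + 1L]] <- data.frame(
        gene = genes$gene[g],
        accession = proteins$accession[i],
        form = proteins$form[i] %||% "none",
        gene_log2_fc = genes$log2_fc[g],
        gene_p = genes$p_value[g],
        gene_q = genes$q_value[g],
        protein_fc = proteins$fold_change[i],
        protein_log2_fc = plog2,
        protein_p = proteins$p_value[i],
        stringsAsFactors = FALSE)
    }
  }
  matches <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(gene = character(), accession = character(), form = character(),
               gene_log2_fc = numeric(), gene_p = numeric(), gene_q = numeric(),
               protein_fc = numeric(), protein_log2_fc = numeric(),
               protein_p = numeric(), stringsAsFactors = FALSE)
  matches$gene_sig_q <- !is.na(matches$gene_q) & matches$gene_q < gene_q
  matches$gene_sig_p <- !is.na(matches$gene_p) & matches$gene_p < gene_p
  matches$protein_sig <- !is.na(matches$protein_p) & matches$protein_p < protein_p

  matched_genes <- unique(tolower(matches$gene))
  matched_prots <- !is.na(psym) & psym %in% matched_genes
  structure(list(
    matches = matches,
    unmatched_genes = genes[!(gsym %in% matched_genes), , drop = FALSE],
    unmatched_proteins = proteins[!matched_prots, , drop = FALSE]),
    class = "gene_protein_matches")
}

as_match_table <- function(matches) {
  if (inherits(matches, "gene_protein_matches")) matches$matches else matches
}

#' Select jointly significant gene-protein matches
#'
#' Strict mode requires gene q < `gene_q` and protein p < `protein_p`;
#' relaxed mode substitutes gene p < `gene_p` for the gene criterion.
#'
#' @param matches A `gene_protein_matches` object or its `matches` data frame
#'   (flags `gene_sig_q`, `gene_sig_p`, `protein_sig` must be present).
#' @param relaxed Use the relaxed gene criterion.
#' @return The significant subset of the match table.
#' @export
significant_matches <- function(matches, relaxed = FALSE) {
  m <- as_match_table(matches)
  gene_ok <- if (relaxed) m$gene_sig_p else m$gene_sig_q
  m[gene_ok & m$protein_sig, , drop = FALSE]
}

#' Pearson correlation of gene and protein fold changes
#'
#' Correlates the gene log2 fold change against the protein fold change.
#' `protein_scale = "fold"` (default) uses the signed fold change as
#' tabulated; `"log2"` transforms it through [signed_fold_to_log2()] first.
#'
#' @param matches A `gene_protein_matches` object or match table.
#' @param protein_scale `"fold"` or `"log2"`.
#' @return List with `r` (Pearson product-moment correlation) and `n`.
#' @export
gene_protein_correlation <- function(matches, protein_scale = c("fold", "log2")) {
  protein_scale <- match.arg(protein_scale)
  m <- as_match_table(matches)
  x <- m$gene_log2_fc
  y <- if (protein_scale == "log2") m$protein_log2_fc else m$protein_fc
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 matches to correlate")
  if (var(x) == 0 || var(y) == 0)
    stop("zero variance in one of the axes; correlation undefined")
  list(r = cor(x, y), n = length(x))
}

#' Annotate matches with previously reported Rett-syndrome hits
#'
#' Tags each match with the citation labels under which its gene was
#' previously reported as a Rett-syndrome expression hit, or `"novel"` when
#' absent from the citation table (case-insensitive on gene symbol).
#'
#' @param matches A `gene_protein_matches` object or match table.
#' @param citations Data frame with columns `gene` and `labels` (citation
#'   reference string).
#' @return List with `matches` (the table plus an `rtt_hit` column),
#'   `n_known`, `n_novel`.
#' @export
annotate_rtt_hits <- function(matches, citations) {
  m <- as_match_table(matches)
  if (nrow(citations) > 0) {
    lab <- citations$labels[match(tolower(m$gene), tolower(citations$gene))]
  } else lab <- rep(NA_character_, nrow(m))
  m$rtt_hit <- ifelse(is.na(lab) | lab == "", "novel", lab)
  list(matches = m,
       n_known = sum(m$rtt_hit != "novel"),
       n_novel = sum(m$rtt_hit == "novel"))
}
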