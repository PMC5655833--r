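# Cuffdiff-style differential-expression table handling: loading, the
# non-coding filter, significance selection, gene length classification and
# direction summaries.

#' Load a differential-expression gene table from TSV
#'
#' Expects the column layout of a Cuffdiff gene_exp table plus biotype:
#' `gene`, a `locus` string (`chr:start-end`) or explicit `chrom`/`start`/`end`
#' columns, FPKM columns `value_1` (control) and `value_2` (mutant),
#' `log2_fc` (also accepted under Cuffdiff's `log2.fold_change.` header),
#' `p_value`, `q_value` and `biotype`. Gene length in kb is derived from the
#' coordinates as (end - start) / 1000. Rows with unparsable coordinates or
#' `end < start` are rejected with their line numbers.
#'
#' @param path Path to a TSV file with a header row.
#' @return A gene-record data frame with a derived `length_kb` column.
#' @export
load_de_table <- function(path) {
  tbl <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(tbl)[names(tbl) %in% c("log2(fold_change)", "log2.fold_change.")] <- "log2_fc"
  required <- c("gene", "value_1", "value_2", "log2_fc", "p_value", "q_value",
                "biotype")
  miss <- setdiff(required, names(tbl))
  if (length(miss) > 0L)
    stop("DE table is missing required column(s): ", paste(miss, collapse = ", "))

  if (!all(c("chrom", "start", "end") %in% names(tbl))) {
    if (!"locus" %in% names(tbl))
      stop("DE table is missing required column(s): locus (or chrom/start/end)")
    m <- regmatches(tbl$locus, regexec("^([^:]+):([0-9]+)-([0-9]+)$", tbl$locus))
    bad <- which(vapply(m, length, integer(1)) != 4L)
    if (length(bad) > 0L)
      stop("malformed locus at data line(s): ", paste(head(bad, 10), collapse = ", "))
    tbl$chrom <- vapply(m, `[`, character(1), 2L)
    tbl$start <- as.integer(vapply(m, `[`, character(1), 3L))
    tbl$end <- as.integer(vapply(m, `[`, character(1), 4L))
  }
  bad <- which(is.na(tbl$start) | is.na(tbl$end) | tbl$end < tbl$start)
  if (length(bad) > 0L)
    stop("end < start (or unparsable coordinates) at data line(s): ",
         paste(head(bad, 10), collapse = ", "))
  num_cols <- c("value_1", "value_2", "log2_fc", "p_value", "q_value")
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(tbl[[col]]))
    bad <- which(is.na(v) & !is.na(tbl[[col]]) & tbl[[col]] != "NA")
    if (length(bad) > 0L)
      stop(sprintf("non-numeric '%s' at data line(s): %s", col,
                   paste(head(bad, 10), collapse = ", ")))
    tbl[[col]] <- v
  }
  tbl$length_kb <- (tbl$end - tbl$start) / 1000
  tbl
}

#' Write a gene table to TSV
#' @param table A gene-record data frame.
#' @param path Output path.
#' @export
write_de_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove significant genes mapped to putative non-coding genes
#'
#' Only records that are both significant (`q < q_threshold`) and non-coding
#' are removed; non-significant non-coding records are retained (the filter
#' applies to the significant, differentially expressed set).
#'
#' @param table Gene table with `q_value` and `biotype` columns.
#' @param q_threshold Significance threshold (default 0.05, strict).
#' @return The filtered table.
#' @export
filter_noncoding <- function(table, q_threshold = 0.05) {
  stopifnot(all(c("q_value", "biotype") %in% names(table)))
  drop <- !is.na(table$q_value) & table$q_value < q_threshold &
    table$biotype != "protein_coding"
  table[!drop, , drop = FALSE]
}

#' Select significantly differentially expressed genes
#'
#' Strict inequality on the false discovery rate (`q < q_threshold`) by
#' default; `relaxed = TRUE` substitutes the unadjusted p-value
#' (`p < p_threshold`).
#'
#' @param table Gene table with `p_value` and `q_value` columns.
#' @param q_threshold FDR threshold (default 0.05).
#' @param relaxed Use the relaxed p-value criterion instead.
#' @param p_threshold p-value threshold for relaxed mode (default 0.05).
#' @return The significant subset.
#' @export
significant_genes <- function(table, q_threshold = 0.05, relaxed = FALSE,
                              p_threshold = 0.05) {
  stopifnot(all(c("p_value", "q_value") %in% names(table)))
  keep <- if (relaxed) {
    !is.na(table$p_value) & table$p_value < p_threshold
  } else {
    !is.na(table$q_value) & table$q_value < q_threshold
  }
  table[keep, , drop = FALSE]
}

#' Classify gene lengths as short or long
#'
#' Genes under 100 kb are short; genes over 100 kb are long; a gene of exactly
#' 100 kb is classed long (documented boundary decision).
#'
#' @param length_kb Numeric vector of gene lengths in kilobases.
#' @param boundary_kb Class boundary (default 100).
#' @return Character vector of `"short"`/`"long"`.
#' @export
gene_length_class <- function(length_kb, boundary_kb = 100) {
  ifelse(length_kb >= boundary_kb, "long", "short")
}

#' Summarize expression direction counts
#'
#' Counts genes with increased (log2 FC > 0) and decreased (log2 FC < 0)
#' expression; exact zeros are counted separately rather than assigned a
#' direction. Percentages are over directional genes and rounded to the
#' nearest integer for reporting.
#'
#' @param table Gene table with a `log2_fc` column.
#' @return List with `n_increased`, `n_decreased`, `n_zero`, `pct_increased`,
#'   `pct_decreased`.
#' @examples
#' direction_summary(data.frame(log2_fc = c(1, -1, -2)))
#' @export
direction_summary <- function(table) {
  stopifnot("log2_fc" %in% names(table))
  fc <- table$log2_fc[!is.na(table$log2_fc)]
  up <- sum(fc > 0); down <- sum(fc < 0); zero <- sum(fc == 0)
  denom <- up + down
  list(n_increased = up, n_decreased = down, n_zero = zero,
       pct_increased = if (denom > 0) round(100 * up / denom) else NA_integer_,
       pct_decreased = if (denom > 0) round(100 * down / denom) else NA_integer_)
}
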