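# CNS cell-type enrichment classification against a reference expression
# matrix (3-fold rule).

#' Reference cell-type column names
#'
#' The seven columns of a conforming reference matrix; the three
#' oligodendrocyte lineage stages collapse to a single oligodendrocyte column
#' in the merged view used for classification.
#' @export
CELL_TYPES_REFERENCE <- c("neuron", "astrocyte", "microglia",
                          "opc", "oligo_newly_formed", "oligo_myelinating",
                          "endothelial")

#' @rdname CELL_TYPES_REFERENCE
#' @export
OLIGO_SUBTYPES <- c("opc", "oligo_newly_formed", "oligo_myelinating")

#' @rdname CELL_TYPES_REFERENCE
#' @export
CELL_TYPES_MERGED <- c("neuron", "astrocyte", "microglia", "oligodendrocyte",
                       "endothelial")

#' Load a cell-type reference expression matrix from TSV
#' @param path TSV with a `gene` column and one column per reference cell type.
#' @return Data frame with `gene` plus the seven reference columns.
#' @export
load_celltype_reference <- function(path) {
  ref <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(c("gene", CELL_TYPES_REFERENCE), names(ref))
  if (length(miss) > 0L)
    stop("reference matrix is missing column(s): ", paste(miss, collapse = ", "))
  if (any(vapply(ref[CELL_TYPES_REFERENCE], function(v) any(v < 0), logical(1))))
    stop("reference expression values must be non-negative")
  ref
}

#' Merge the oligodendrocyte lineage sub-columns
#'
#' Collapses the oligodendrocyte precursor, newly formed and myelinating
#' oligodendrocyte columns into a single oligodendrocyte column. The default
#' merge takes the per-gene maximum, so a gene specific to any lineage stage
#' counts as oligodendrocyte-enriched; a mean merge is available.
#'
#' @param reference Data frame with `gene` and the seven reference columns.
#' @param method `"max"` (default) or `"mean"`.
#' @return Data frame with `gene` and the five merged cell-type columns.
#' @export
merge_oligo_subtypes <- function(reference, method = c("max", "mean")) {
  method <- match.arg(method)
  miss <- setdiff(OLIGO_SUBTYPES, names(reference))
  if (length(miss) > 0L)
    stop("missing oligodendrocyte sub-column(s): ", paste(miss, collapse = ", "))
  sub <- as.matrix(reference[OLIGO_SUBTYPES])
  merged <- if (method == "max") do.call(pmax, reference[OLIGO_SUBTYPES])
            else rowMeans(sub)
  out <- data.frame(gene = reference$gene, stringsAsFactors = FALSE)
  for (cc in c("neuron", "astrocyte", "microglia"))
    out[[cc]] <- reference[[cc]]
  out$oligodendrocyte <- merged
  out$endothelial <- reference$endothelial
  out
}

#' Classify genes into CNS cell types by the 3-fold enrichment rule
#'
#' A gene is called enriched in its top cell type when expression there is at
#' least `threshold`-fold the maximum over the remaining cell types (boundary
#' inclusive: a ratio of exactly 3 is enriched). Genes below the threshold are
#' `not_enriched`; genes missing from the reference are
#' `absent_from_reference`. A zero denominator with positive numerator yields
#' an infinite ratio (enriched); an all-zero row is `not_enriched` with an
#' undefined ratio.
#'
#' @param genes Character vector of query gene identifiers (matching is
#'   case-insensitive).
#' @param reference A merged reference (see [merge_oligo_subtypes()]) with
#'   `gene` plus the five merged cell-type columns.
#' @param threshold Enrichment ratio threshold (default 3.0).
#' @param compare `"max"` (default, strictest reading: top vs the maximum of
#'   the others) or `"mean"` (top vs the mean of the others).
#' @return Data frame with `gene`, `call`, `ratio`.
#' @export
classify_cell_type <- function(genes, reference, threshold = 3.0,
                               compare = c("max", "mean")) {
  compare <- match.arg(compare)
  miss <- setdiff(c("gene", CELL_TYPES_MERGED), names(reference))
  if (length(miss) > 0L)
    stop("merged reference is missing column(s): ", paste(miss, collapse = ", "))
  expr <- as.matrix(reference[CELL_TYPES_MERGED])
  ref_idx <- match(tolower(genes), tolower(reference$gene))

  call <- rep("absent_from_reference", length(genes))
  ratio <- rep(NA_real_, length(genes))
  present <- which(!is.na(ref_idx))
  for (k in present) {
    row <- expr[ref_idx[k], ]
    if (all(row == 0)) { call[k] <- "not_enriched"; next }
    top <- which.max(row)
    rest <- row[-top]
    denom <- if (compare == "max") max(rest) else mean(rest)
    r <- if (denom == 0) Inf else row[top] / denom
    ratio[k] <- r
    call[k] <- if (r >= threshold) CELL_TYPES_MERGED[top] else "not_enriched"
  }
  data.frame(gene = genes, call = call, ratio = ratio, stringsAsFactors = FALSE)
}

#' Summarize enrichment calls
#'
#' Counts calls over the seven categories (five cell types, `not_enriched`,
#' `absent_from_reference`) and fractions over classified genes (those present
#' in the reference).
#'
#' @param calls Data frame from [classify_cell_type()].
#' @return List with `counts` (named integer vector over all categories) and
#'   `fractions` (over classified genes; sums to 1 when any gene classified).
#' @export
distribution_summary <- function(calls) {
  cats <- c(CELL_TYPES_MERGED, "not_enriched", "absent_from_reference")
  counts <- setNames(integer(length(cats)), cats)
  if (nrow(calls) > 0) {
    tab <- table(factor(calls$call, levels = cats))
    counts[] <- as.integer(tab)
  }
  classified <- counts[setdiff(cats, "absent_from_reference")]
  n_classified <- sum(classified)
  fractions <- if (n_classified > 0) classified / n_classified
               else setNames(rep(NA_real_, length(classified)), names(classified))
  list(counts = counts, fractions = fractions)
}
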