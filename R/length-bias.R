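# Gene length x expression direction cross-tabulation, overall and per
# cell-type call.

#' Cross-tabulate gene length class against expression direction
#'
#' Counts short/long x increased/decreased genes overall and within each
#' cell-type call stratum. Fractions carry their integer numerator and
#' denominator; zero-fold-change genes are counted in a separate column
#' rather than assigned a direction. Genes without a call are counted in the
#' `absent_from_reference` stratum.
#'
#' @param genes Gene table with `gene`, `log2_fc` and `length_kb` columns.
#' @param calls Data frame from [classify_cell_type()] (`gene`, `call`).
#' @param boundary_kb Length-class boundary in kb (default 100).
#' @return Data frame with one row per stratum (`overall` plus each call
#'   category): columns `stratum`, `short_increased`, `short_decreased`,
#'   `long_increased`, `long_decreased`, `zero_fc`, `n` and the derived
#'   fractions `frac_long_increased` and `frac_short_decreased`.
#' @export
crosstab_length_direction <- function(genes, calls, boundary_kb = 100) {
  stopifnot(all(c("gene", "log2_fc", "length_kb") %in% names(genes)))
  call <- calls$call[match(genes$gene, calls$gene)]
  missing_call <- is.na(call)
  if (any(missing_call)) {
    warning(sprintf("%d gene(s) without a cell-type call counted as absent",
                    sum(missing_call)))
    call[missing_call] <- "absent_from_reference"
  }
  len <- gene_length_class(genes$length_kb, boundary_kb)
  dir <- ifelse(genes$log2_fc > 0, "increased",
                ifelse(genes$log2_fc < 0, "decreased", "zero"))

  tally <- function(idx) {
    n_li <- sum(len[idx] == "long" & dir[idx] == "increased")
    n_ld <- sum(len[idx] == "long" & dir[idx] == "decreased")
    n_si <- sum(len[idx] == "short" & dir[idx] == "increased")
    n_sd <- sum(len[idx] == "short" & dir[idx] == "decreased")
    n_zero <- sum(dir[idx] == "zero")
    n_long <- n_li + n_ld
    n_short <- n_si + n_sd
    data.frame(short_increased = n_si, short_decreased = n_sd,
               long_increased = n_li, long_decreased = n_ld,
               zero_fc = n_zero, n = length(idx),
               frac_long_increased = if (n_long > 0) n_li / n_long else NA_real_,
               frac_short_decreased = if (n_short > 0) n_sd / n_short else NA_real_)
  }

  strata <- c("overall", CELL_TYPES_MERGED, "not_enriched",
              "absent_from_reference")
  rows <- lapply(strata, function(s) {
    idx <- if (s == "overall") seq_along(call) else which(call == s)
    cbind(data.frame(stratum = s, stringsAsFactors = FALSE), tally(idx))
  })
  do.call(rbind, rows)
}
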