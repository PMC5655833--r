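# DIA quantification engine: fragment deconvolution, quant-fragment selection,
# MS2 AUC integration, retention-time mapping, cross-run extraction,
# normalization, rescaling, and peptide-to-protein roll-up.

#' Deconvolve fragment traces of one peptide in one run
#'
#' Fragment records are grouped across sequential MS/MS scans by m/z (single
#' linkage within `tolerance`), and a group is retained only when its intensity
#' at the peptide's apex scan is at least `retain_fraction` of that group's
#' maximum intensity across the scans. This apex-consistency filter drops
#' interfering fragments whose elution profile disagrees with the peptide's.
#'
#' @param trace Data frame of scan-level fragment records for a single peptide
#'   in a single run; columns `mz`, `scan_index`, `rt_minutes`, `intensity`
#'   (optionally `ion_type`, `charge`, `fragment_id`). Scan indices must be
#'   strictly increasing within a fragment; intensities non-negative.
#' @param tolerance m/z tolerance for grouping fragment records across scans.
#' @param retain_fraction Minimum apex-scan intensity as a fraction of the
#'   fragment's own across-scan maximum.
#' @return A list of class `fragment_set`: `fragments` (one row per retained
#'   group: `group`, `mz`, `ion_type`, `charge`, `apex_intensity`,
#'   `max_intensity`), `traces` (scan-level rows of retained groups with a
#'   `group` column), `apex_scan`, `apex_rt`. An all-zero or empty trace
#'   yields an empty fragment set without error.
#' @export
deconvolve_fragments <- function(trace, tolerance = 0.01, retain_fraction = 0.70) {
  empty <- structure(list(
    fragments = data.frame(group = integer(), mz = numeric(),
                           ion_type = character(), charge = integer(),
                           apex_intensity = numeric(), max_intensity = numeric()),
    traces = data.frame(group = integer(), scan_index = integer(),
                        rt_minutes = numeric(), intensity = numeric()),
    apex_scan = NA_integer_, apex_rt = NA_real_), class = "fragment_set")
  if (is.null(trace) || nrow(trace) == 0L || all(trace$intensity <= 0)) return(empty)
  if (any(trace$intensity < 0)) stop("fragment intensities must be non-negative")

  o <- order(trace$mz)
  mz_sorted <- trace$mz[o]
  grp_sorted <- cumsum(c(1L, as.integer(diff(mz_sorted) > tolerance)))
  group <- integer(nrow(trace)); group[o] <- grp_sorted

  # merged intensity per (group, scan)
  key <- paste(group, trace$scan_index, sep = "\r")
  agg_int <- rowsum(trace$intensity, key, reorder = FALSE)
  first <- !duplicated(key)
  g <- group[first]; scan <- trace$scan_index[first]; rt <- trace$rt_minutes[first]
  inten <- as.numeric(agg_int[match(key[first], rownames(agg_int))])

  # peptide apex: scan with maximal total intensity over all fragment groups
  tot <- rowsum(inten, scan, reorder = FALSE)
  scans <- as.integer(rownames(tot))
  apex_scan <- scans[which.max(tot)]
  apex_rt <- rt[match(apex_scan, scan)]

  max_int <- vapply(split(inten, g), max, numeric(1))
  gids <- as.integer(names(max_int))
  at_apex <- inten[scan == apex_scan]
  g_apex <- g[scan == apex_scan]
  apex_int <- setNames(numeric(length(gids)), gids)
  apex_int[as.character(g_apex)] <- at_apex
  retained <- apex_int >= retain_fraction * max_int & max_int > 0

  meta_col <- function(col, default) {
    if (!col %in% names(trace)) return(rep(default, length(gids)))
    # take metadata from the most intense record of each group
    vapply(split(seq_len(nrow(trace)), group), function(i) {
      trace[[col]][i][which.max(trace$intensity[i])]
    }, trace[[col]][1])[as.character(gids)]
  }
  wmz <- vapply(split(seq_len(nrow(trace)), group), function(i) {
    w <- trace$intensity[i]
    if (sum(w) > 0) sum(trace$mz[i] * w) / sum(w) else mean(trace$mz[i])
  }, numeric(1))[as.character(gids)]

  frags <- data.frame(group = gids, mz = as.numeric(wmz),
                      ion_type = as.character(meta_col("ion_type", NA_character_)),
                      charge = as.integer(meta_col("charge", NA_integer_)),
                      apex_intensity = as.numeric(apex_int),
                      max_intensity = as.numeric(max_int),
                      stringsAsFactors = FALSE)
  frags <- frags[retained, , drop = FALSE]
  keep <- g %in% frags$group
  structure(list(
    fragments = frags,
    traces = data.frame(group = g[keep], scan_index = scan[keep],
                        rt_minutes = rt[keep], intensity = inten[keep]),
    apex_scan = apex_scan, apex_rt = apex_rt), class = "fragment_set")
}

#' Select fragment ions for peptide quantification
#'
#' Only b/y ions in +1 or +2 charge state whose intensity reaches at least
#' `min_rel_intensity` of the strongest assigned fragment are eligible. At most
#' `max_n` (the most intense) are kept; fewer than `min_n` eligible fragments
#' makes the peptide unquantifiable.
#'
#' @param fragments Data frame with columns `ion_type`, `charge` and an
#'   intensity column (`apex_intensity` or `intensity`), e.g. the `fragments`
#'   element of [deconvolve_fragments()].
#' @param min_n,max_n Minimum required / maximum retained number of fragments.
#' @param min_rel_intensity Intensity floor relative to the strongest fragment.
#' @return The selected rows ordered by decreasing intensity, or `NULL` when
#'   the peptide is unquantifiable (a value, not an error).
#' @export
select_quant_fragments <- function(fragments, min_n = 5, max_n = 9,
                                   min_rel_intensity = 0.10) {
  if (is.null(fragments) || nrow(fragments) == 0L) return(NULL)
  int <- fragments$apex_intensity %||% fragments$intensity
  if (is.null(int)) stop("fragments need an 'apex_intensity' or 'intensity' column")
  strongest <- max(int)
  eligible <- fragments$ion_type %in% c("b", "y") &
    fragments$charge %in% c(1L, 2L) &
    int >= min_rel_intensity * strongest
  if (sum(eligible) < min_n) return(NULL)
  sel <- fragments[eligible, , drop = FALSE]
  sel <- sel[order(-int[eligible]), , drop = FALSE]
  head(sel, max_n)
}

#' Integrate MS2 chromatogram area under the curve
#'
#' Per-fragment trapezoidal integral of intensity over retention time, summed
#' over fragments. A fragment observed in a single scan contributes 0.
#'
#' @param traces Data frame with columns `group` (or `fragment_id`),
#'   `rt_minutes`, `intensity` for the selected fragments of one peptide in
#'   one run.
#' @param rt_window Optional `c(lo, hi)` retention-time bounds (minutes);
#'   rows outside are ignored.
#' @return The peptide-level MS2 AUC (a single non-negative number). An empty
#'   window yields 0 with a warning.
#' @export
integrate_ms2_auc <- function(traces, rt_window = NULL) {
  if (!is.null(rt_window) && !is.null(traces) && nrow(traces) > 0L) {
    traces <- traces[traces$rt_minutes >= rt_window[1] &
                     traces$rt_minutes <= rt_window[2], , drop = FALSE]
  }
  if (is.null(traces) || nrow(traces) == 0L) {
    warning("no fragment trace points in the integration window; AUC = 0")
    return(0)
  }
  id <- traces$group %||% traces$fragment_id
  if (is.null(id)) id <- rep(1L, nrow(traces))
  sum(vapply(split(seq_len(nrow(traces)), id), function(i)
    trapz(traces$rt_minutes[i], traces$intensity[i]), numeric(1)))
}

#' Fit a monotone retention-time map between two runs
#'
#' Least-squares linear fit of target apex retention time on reference apex
#' retention time over peptides detected in both runs.
#'
#' @param reference,target Named numeric vectors of apex retention times
#'   (minutes) keyed by peptide identifier.
#' @param min_shared Minimum number of shared peptides (default 5).
#' @return An object of class `rt_map`: list with `slope`, `intercept`,
#'   `sigma` (residual standard deviation) and `n`.
#' @export
fit_rt_map <- function(reference, target, min_shared = 5L) {
  shared <- intersect(names(reference), names(target))
  shared <- shared[!is.na(reference[shared]) & !is.na(target[shared])]
  if (length(shared) < min_shared)
    stop(sprintf(
      "only %d peptides shared between runs (need >= %d); use identity_rt_map() instead",
      length(shared), min_shared))
  x <- reference[shared]; y <- target[shared]
  vx <- sum((x - mean(x))^2)
  if (vx == 0) stop("reference retention times are constant; cannot fit a map")
  slope <- sum((x - mean(x)) * (y - mean(y))) / vx
  intercept <- mean(y) - slope * mean(x)
  res <- y - (intercept + slope * x)
  sigma <- if (length(shared) > 2L) sqrt(sum(res^2) / (length(shared) - 2L)) else 0
  structure(list(slope = slope, intercept = intercept, sigma = sigma,
                 n = length(shared)), class = "rt_map")
}

#' Identity retention-time map
#' @return An `rt_map` with slope 1, intercept 0, and zero residual scale.
#' @export
identity_rt_map <- function() {
  structure(list(slope = 1, intercept = 0, sigma = 0, n = 0L), class = "rt_map")
}

#' Map a reference retention time into a target run's frame
#' @param map An `rt_map`.
#' @param rt Retention time(s) in the reference frame (minutes).
#' @export
predict_rt <- function(map, rt) map$intercept + map$slope * rt

invert_rt <- function(map, rt) (rt - map$intercept) / map$slope

#' Rescale a peptide abundance matrix so the global minimum is 1
#'
#' Every value is divided by the global minimum over finite cells, placing the
#' matrix on a relative scale with 1 as the smallest amount detected. Pairwise
#' ratios are preserved exactly; the operation is idempotent.
#'
#' @param x A numeric matrix or a [peptide_matrix].
#' @return Object of the same type with minimum over finite cells exactly 1.
#' @export
rescale_relative <- function(x) {
  if (inherits(x, "peptide_matrix")) {
    x$abundance <- rescale_relative(x$abundance)
    return(x)
  }
  v <- x[is.finite(x)]
  if (length(v) == 0L) stop("no finite values to rescale")
  if (any(v <= 0)) stop("rescale_relative requires all finite values to be positive")
  x / min(v)
}

#' Resolve peptides shared between proteins to a single top match
#'
#' A peptide assigned to different protein accessions in separate files is
#' mapped to the accession assigned most often; ties break to the
#' lexicographically smallest accession.
#'
#' @param assignments Data frame with columns `peptide_id` and `protein_acc`,
#'   one row per per-file assignment.
#' @return Named character vector: peptide identifier -> protein accession.
#' @export
resolve_shared_peptides <- function(assignments) {
  stopifnot(all(c("peptide_id", "protein_acc") %in% names(assignments)))
  if (nrow(assignments) == 0L) return(setNames(character(), character()))
  vapply(split(assignments$protein_acc, assignments$peptide_id), function(acc) {
    tab <- table(acc)
    top <- names(tab)[tab == max(tab)]
    sort(top)[1L]
  }, character(1))
}

#' Select differentially abundant proteins
#'
#' @param quants A protein quantification table (see [rollup_protein()]).
#' @param alpha Significance threshold; strict inequality `p < alpha`.
#' @return The subset of rows with `p_value < alpha` (NA p-values excluded).
#' @export
significant_proteins <- function(quants, alpha = 0.1) {
  quants[!is.na(quants$p_value) & quants$p_value < alpha, , drop = FALSE]
}
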