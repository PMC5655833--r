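# Peptide-by-run abundance matrix with detection provenance.

#' Construct a peptide abundance matrix
#'
#' Container for peptide x run relative abundances with per-cell detection
#' status (`"measured"`, `"extracted"`, `"absent"`) and per-cell apex
#' retention time.
#'
#' @param abundance Numeric matrix, peptides in rows (rownames = peptide ids),
#'   runs in columns (colnames = run ids). `NA` marks absent cells.
#' @param status Character matrix of the same shape with values
#'   `measured`/`extracted`/`absent`.
#' @param apex_rt Numeric matrix of apex retention times (minutes); `NA` where
#'   unknown.
#' @param peptides Data frame with one row per matrix row: `peptide_id`,
#'   `protein_acc`, `modification`.
#' @param frag_mz Named list, peptide id -> m/z values of the fragments
#'   selected for quantification (used by cross-run extraction).
#' @return An object of class `peptide_matrix`.
#' @export
peptide_matrix <- function(abundance, status, apex_rt, peptides,
                           frag_mz = list()) {
  stopifnot(is.matrix(abundance),
            identical(dim(abundance), dim(status)),
            identical(dim(abundance), dim(apex_rt)),
            nrow(peptides) == nrow(abundance))
  if (!all(status %in% c("measured", "extracted", "absent")))
    stop("status values must be 'measured', 'extracted' or 'absent'")
  structure(list(abundance = abundance, status = status, apex_rt = apex_rt,
                 peptides = peptides, frag_mz = frag_mz),
            class = "peptide_matrix")
}

#' @export
print.peptide_matrix <- function(x, ...) {
  cat(sprintf("peptide_matrix: %d peptides x %d runs (%d measured, %d extracted, %d absent cells)\n",
              nrow(x$abundance), ncol(x$abundance),
              sum(x$status == "measured"), sum(x$status == "extracted"),
              sum(x$status == "absent")))
  invisible(x)
}

#' Extract undetected peptides from their chromatograms in other runs
#'
#' For every (peptide, run) cell with status `absent` where the peptide was
#' measured in at least one other run, the peptide's selected fragment m/z
#' traces are integrated in the target run inside a retention-time window
#' centred on the mapped apex (apex +/- `k_sigma` times the residual scale of
#' the run's retention-time map, with a minimum half-width). The integral is
#' recorded with status `extracted`; measured cells are never touched. A
#' window with no signal records the value 0 (status `extracted`).
#'
#' @param pm A [peptide_matrix].
#' @param traces The scan-level trace table (all runs).
#' @param rt_maps Named list of [fit_rt_map()] objects, one per run, mapping
#'   the reference run's retention times into that run.
#' @param reference_run Run id whose frame anchors the maps.
#' @param k_sigma Window half-width in residual-scale multiples (default 3).
#' @param min_halfwidth Minimum window half-width in minutes.
#' @param tolerance m/z tolerance when matching trace rows to selected
#'   fragment m/z values.
#' @return The updated `peptide_matrix`.
#' @export
extract_missing_peptides <- function(pm, traces, rt_maps, reference_run,
                                     k_sigma = 3, min_halfwidth = 0.5,
                                     tolerance = 0.01) {
  stopifnot(inherits(pm, "peptide_matrix"))
  runs <- colnames(pm$abundance)
  if (!all(runs %in% names(rt_maps)))
    stop("rt_maps must contain a map for every run in the matrix")
  cell_key <- paste(traces$peptide_id, traces$run_id, sep = "\r")
  idx <- split(seq_len(nrow(traces)), cell_key)

  for (p in rownames(pm$abundance)) {
    st <- pm$status[p, ]
    measured <- which(st == "measured")
    absent <- which(st == "absent")
    if (length(absent) == 0L || length(measured) == 0L) next
    mzs <- pm$frag_mz[[p]]
    if (is.null(mzs) || length(mzs) == 0L) next

    # anchor apex RT in the reference frame
    if (st[reference_run] == "measured") {
      anchor <- pm$apex_rt[p, reference_run]
    } else {
      m <- runs[measured[1L]]
      anchor <- invert_rt(rt_maps[[m]], pm$apex_rt[p, m])
    }

    for (j in absent) {
      r <- runs[j]
      map <- rt_maps[[r]]
      centre <- predict_rt(map, anchor)
      hw <- max(k_sigma * map$sigma, min_halfwidth)
      rows <- idx[[paste(p, r, sep = "\r")]]
      value <- 0
      if (!is.null(rows)) {
        sub <- traces[rows, , drop = FALSE]
        near <- vapply(sub$mz, function(m) any(abs(m - mzs) <= tolerance),
                       logical(1))
        sub <- sub[near & sub$rt_minutes >= centre - hw &
                     sub$rt_minutes <= centre + hw, , drop = FALSE]
        if (nrow(sub) > 0L) {
          value <- suppressWarnings(integrate_ms2_auc(data.frame(
            group = sub$fragment_id, rt_minutes = sub$rt_minutes,
            intensity = sub$intensity)))
          pm$apex_rt[p, j] <- sub$rt_minutes[which.max(sub$intensity)]
        }
      }
      pm$abundance[p, j] <- value
      pm$status[p, j] <- "extracted"
    }
  }
  pm
}

#' Normalize a peptide matrix for retention time-dependent matrix effects
#'
#' Normalizer candidates are peptides measured (not extracted) in every run.
#' For each target peptide, the `neighborhood` candidates nearest in mean apex
#' retention time are located and the up to `max_normalizers` of them with the
#' least intensity variation (lowest coefficient of variation across runs)
#' supply a per-run correction factor: the median ratio of each normalizer's
#' value in the run to its across-run mean, which is divided out. A constant
#' multiplicative rescaling of any single run is removed exactly; smooth
#' retention-time-dependent drift is removed to the extent the local
#' normalizers track it.
#'
#' @param pm A [peptide_matrix].
#' @param max_normalizers Maximum normalizer peptides per target (default 25).
#' @param neighborhood Number of nearest-in-retention-time candidates the
#'   low-CV normalizers are drawn from (default 2 x `max_normalizers`).
#' @return The normalized `peptide_matrix`.
#' @export
normalize_matrix <- function(pm, max_normalizers = 25,
                             neighborhood = 2 * max_normalizers) {
  stopifnot(inherits(pm, "peptide_matrix"))
  A <- pm$abundance
  complete <- rowSums(pm$status == "measured") == ncol(A)
  if (!any(complete)) {
    per_run <- colSums(pm$status == "measured")
    stop(sprintf(
      "no peptide measured in every run; run '%s' has the fewest measured peptides (%d)",
      colnames(A)[which.min(per_run)], min(per_run)))
  }
  cand <- which(complete)
  cv <- apply(A[cand, , drop = FALSE], 1L, function(v) sd(v) / mean(v))
  cand_mean <- rowMeans(A[cand, , drop = FALSE])
  ratio <- A[cand, , drop = FALSE] / cand_mean   # candidates x runs
  rt_mean <- rowMeans(pm$apex_rt, na.rm = TRUE)
  rt_cand <- rt_mean[cand]

  out <- A
  for (t in seq_len(nrow(A))) {
    d <- abs(rt_cand - rt_mean[t])
    d[cand == t] <- Inf  # a peptide never normalizes itself
    near <- order(d)[seq_len(min(neighborhood, sum(is.finite(d))))]
    sel <- near[order(cv[near])][seq_len(min(max_normalizers, length(near)))]
    if (length(sel) == 0L) next
    factor <- apply(ratio[sel, , drop = FALSE], 2L, median)
    out[t, ] <- A[t, ] / factor
  }
  pm$abundance <- out
  pm
}

#' Roll peptides up to protein-level quantifications
#'
#' For each protein form (accession x modification label): if any of its
#' peptides was measured in every run, only those complete peptides are used
#' (mode `complete-peptides`); otherwise all peptides with detected or
#' extracted chromatograms are used (mode `all-peptides`). Each peptide's
#' ratio is mean(mutant runs) / mean(control runs); the protein ratio is the
#' median of peptide ratios, reported as a signed fold change (ratio if >= 1,
#' else -1/ratio). Significance comes from a two-sided unpaired t-test on the
#' peptide x run observations of all peptides used for the protein, taken as
#' log2 relative abundances (each peptide divided by its across-run mean); a
#' per-peptide-ratio one-sample variant is available via `test_input`.
#'
#' @param pm A [peptide_matrix] (normalized and rescaled).
#' @param groups Named character vector, run id -> group label.
#' @param control,mutant The two group labels; fold changes are mutant vs
#'   control.
#' @param peptide_map Optional named vector peptide id -> protein accession
#'   (e.g. from [resolve_shared_peptides()]); defaults to the matrix's own
#'   assignments.
#' @param test `"pooled"` (classical unpaired Student t, default) or
#'   `"welch"`.
#' @param test_input `"pooled_obs"` (default: peptide x run log2 relative
#'   abundances as observations) or `"peptide_ratio"` (one-sample t-test on
#'   per-peptide log2 ratios).
#' @return Data frame with one row per protein form: `accession`, `form`,
#'   `n_peptides`, `mode`, `fold_change`, `p_value`.
#' @export
rollup_protein <- function(pm, groups, control = "control", mutant = "mutant",
                           peptide_map = NULL,
                           test = c("pooled", "welch"),
                           test_input = c("pooled_obs", "peptide_ratio")) {
  stopifnot(inherits(pm, "peptide_matrix"))
  test <- match.arg(test)
  test_input <- match.arg(test_input)
  runs <- colnames(pm$abundance)
  if (!all(runs %in% names(groups))) stop("groups must label every run")
  ctl <- runs[groups[runs] == control]
  mut <- runs[groups[runs] == mutant]
  if (length(ctl) == 0L || length(mut) == 0L)
    stop("both groups must contain at least one run")

  prot <- if (is.null(peptide_map)) {
    setNames(pm$peptides$protein_acc, pm$peptides$peptide_id)
  } else peptide_map
  acc <- prot[pm$peptides$peptide_id]
  form_key <- paste(acc, pm$peptides$modification, sep = "\r")

  res <- lapply(split(seq_len(nrow(pm$abundance)), form_key), function(rows) {
    S <- pm$status[rows, , drop = FALSE]
    A <- pm$abundance[rows, , drop = FALSE]
    complete <- rowSums(S == "measured") == ncol(S)
    if (any(complete)) {
      use <- complete
      mode <- "complete-peptides"
    } else {
      ok <- rowSums(is.finite(A[, ctl, drop = FALSE])) > 0 &
        rowSums(is.finite(A[, mut, drop = FALSE])) > 0
      use <- ok
      mode <- "all-peptides"
    }
    if (!any(use)) return(NULL)
    V <- A[use, , drop = FALSE]
    mu_m <- rowMeans(V[, mut, drop = FALSE], na.rm = TRUE)
    mu_c <- rowMeans(V[, ctl, drop = FALSE], na.rm = TRUE)
    ratios <- mu_m / mu_c
    ratios <- ratios[is.finite(ratios) & ratios > 0]
    if (length(ratios) == 0L) return(NULL)
    rmed <- median(ratios)
    fc <- if (rmed >= 1) rmed else -1 / rmed

    p <- NA_real_
    if (test_input == "pooled_obs") {
      rel <- log2(V / rowMeans(V, na.rm = TRUE))
      x <- rel[, ctl, drop = FALSE]; x <- x[is.finite(x)]
      y <- rel[, mut, drop = FALSE]; y <- y[is.finite(y)]
      if (length(x) >= 2L && length(y) >= 2L && (var(x) + var(y)) > 0)
        p <- t.test(y, x, var.equal = (test == "pooled"))$p.value
    } else {
      lr <- log2(ratios)
      if (length(lr) >= 2L && sd(lr) > 0)
        p <- t.test(lr, mu = 0)$p.value
    }
    data.frame(accession = sub("\r.*$", "", form_key[rows[1]]),
               form = pm$peptides$modification[rows[1]],
               n_peptides = sum(use), mode = mode,
               fold_change = fc, p_value = p,
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(res, is.null, logical(1)))
  if (dropped > 0L)
    warning(sprintf("%d protein form(s) had no usable peptides and were omitted",
                    dropped))
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(accession = character(), form = character(),
                      n_peptides = integer(), mode = character(),
                      fold_change = numeric(), p_value = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out[order(out$accession, out$form), , drop = FALSE]
}
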