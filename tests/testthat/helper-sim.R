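# Shared simulation fixtures, built once per test run.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) assign(key, force(expr), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

small_sim <- function() cached("small", simulate_dia_experiment(
  dia_sim_config(n_proteins = 40, frac_changed = 0.25, effect_log2 = c(1, 1),
                 seed = 42)))

noiseless_sim <- function() cached("noiseless", simulate_dia_experiment(
  dia_sim_config(n_proteins = 15, frac_changed = 0, noise_cv = 0,
                 drift_coef_sd = 0, rt_shift_sd = 0, missing_rate = 0,
                 seed = 11)))

# a peptide matrix built directly from a ledger (bypassing the trace path):
# abundance = noisy truth x per-run cubic drift at the peptide's retention time
pm_from_ledger <- function(sim, with_drift = TRUE) {
  led <- sim$ledger
  A <- led$noisy_abundance
  runs <- colnames(A)
  rt <- attr(sim, "apex_rt")
  # recover per-run apex rt from the trace table (max-intensity scan per cell)
  apex <- matrix(NA_real_, nrow(A), ncol(A), dimnames = dimnames(A))
  agg <- tapply(seq_len(nrow(sim$traces)),
                list(sim$traces$peptide_id, sim$traces$run_id),
                function(i) sim$traces$rt_minutes[i][which.max(sim$traces$intensity[i])])
  apex[rownames(agg), colnames(agg)] <- agg
  if (with_drift) {
    cfg_rt <- range(apex, na.rm = TRUE)
    for (j in seq_along(runs)) {
      u <- 2 * (apex[, j] - cfg_rt[1]) / (cfg_rt[2] - cfg_rt[1]) - 1
      d <- exp(led$drift_coef[1, j] * u + led$drift_coef[2, j] * u^2 +
                 led$drift_coef[3, j] * u^3)
      A[, j] <- A[, j] * d
    }
  }
  status <- matrix("measured", nrow(A), ncol(A), dimnames = dimnames(A))
  pep_prot <- sub("pep", "", rownames(A))
  peptide_matrix(A, status, apex,
                 data.frame(peptide_id = rownames(A),
                            protein_acc = sim$traces$protein_acc[
                              match(rownames(A), sim$traces$peptide_id)],
                            modification = "none",
                            stringsAsFactors = FALSE))
}

# textbook pooled-variance two-sample t-test p-value
pooled_t_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(y) - mean(x)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * pt(-abs(t), nx + ny - 2)
}
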