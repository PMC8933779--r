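# shared fixtures and independent oracles

# counts-arithmetic oracle for the domain-impairment rule: affected iff
# >=50% impaired, or >=30% impaired and >=30% low_average
bruteClassify <- function(n_imp, n_low, n_total) {
  (n_imp / n_total >= 0.5) |
    (n_imp / n_total >= 0.3 & n_low / n_total >= 0.3)
}

# build a ScoredCohort whose three-category band counts per score are
# exactly the given (n_impaired, n_low_avg, n_avg_plus, n_total <= n_max);
# patients beyond n_total get NA for that score
bandedCohortFromCounts <- function(counts, n_max = max(counts$n_total)) {
  t_imp <- 30   # Pc ~ 2.3, impaired
  t_low <- 40   # Pc ~ 15.9, low_average
  t_avg <- 55   # Pc ~ 69, average_plus
  m <- matrix(NA_real_, nrow(counts), n_max,
              dimnames = list(counts$score_id,
                              sprintf("P%03d", seq_len(n_max))))
  for (i in seq_len(nrow(counts))) {
    v <- rep(c(t_imp, t_low, t_avg),
             c(counts$n_impaired[i], counts$n_low_avg[i],
               counts$n_avg_plus[i]))
    m[i, seq_along(v)] <- v
  }
  ScoredCohort(m)
}

# toy loading matrix builder for assignment tests
makeLoadingMatrix <- function(L, variance = 0.8) {
  new("LoadingMatrix", loadings = L, Phi = diag(ncol(L)),
      variance_explained = variance, n_factors = ncol(L),
      converged = TRUE, iterations = 1L)
}
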