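# Brute-force oracles, kept deliberately independent of the package's
# grouped-count implementations: everything here enumerates case-control
# pairs explicitly.

# Expand grouped counts to per-subject scores and outcomes.
expand_counts <- function(counts) {
  list(cases = rep(counts$levels, counts$dead),
       controls = rep(counts$levels, counts$alive))
}

# AUC by explicit enumeration of all case-control pairs.
oracle_auc <- function(counts) {
  e <- expand_counts(counts)
  cmp <- outer(e$cases, e$controls, function(x, y) (x > y) + 0.5 * (x == y))
  mean(cmp)
}

# DeLong variance by explicit enumeration: per-case and per-control means
# of the pair kernel, then S10/m + S01/n.
oracle_delong_variance <- function(counts) {
  e <- expand_counts(counts)
  cmp <- outer(e$cases, e$controls, function(x, y) (x > y) + 0.5 * (x == y))
  v10 <- rowMeans(cmp)
  v01 <- colMeans(cmp)
  stats::var(v10) / length(v10) + stats::var(v01) / length(v01)
}

# Paired DeLong z statistic by explicit enumeration for two score vectors.
oracle_delong_z <- function(a, b, dead) {
  ka <- outer(a[dead], a[!dead], function(x, y) (x > y) + 0.5 * (x == y))
  kb <- outer(b[dead], b[!dead], function(x, y) (x > y) + 0.5 * (x == y))
  m <- sum(dead); n <- sum(!dead)
  delta <- mean(ka) - mean(kb)
  var_delta <-
    (stats::var(rowMeans(ka)) + stats::var(rowMeans(kb)) -
       2 * stats::cov(rowMeans(ka), rowMeans(kb))) / m +
    (stats::var(colMeans(ka)) + stats::var(colMeans(kb)) -
       2 * stats::cov(colMeans(ka), colMeans(kb))) / n
  delta / sqrt(var_delta)
}

# Random small score-counts object with at least min_each per class.
random_counts <- function(n_levels = 5, min_each = 2) {
  repeat {
    alive <- rpois(n_levels, 8)
    dead <- rpois(n_levels, 3)
    if (sum(alive) >= min_each && sum(dead) >= min_each) break
  }
  score_counts(seq_len(n_levels) - 1, alive = alive, dead = dead)
}

# Small complete synthetic cohort for pipeline tests.
small_cohort <- function(n = 400, seed = 101) {
  simulate_cohort(sim_config(n = n, seed = seed))
}
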