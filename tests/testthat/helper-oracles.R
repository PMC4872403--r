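# Independent brute-force oracles used to check the exact small-sample
# null distributions, plus small fixture builders. These deliberately share
# no code with the implementations they verify.

# exact left-tail runs-test p-value by enumerating all C(n+m, n) labelings
oracle_runs_p <- function(n, m, r_obs) {
  positions <- utils::combn(n + m, n)
  runs_of <- function(first_idx) {
    lab <- rep(2L, n + m)
    lab[first_idx] <- 1L
    1L + sum(diff(lab) != 0L)
  }
  runs <- apply(positions, 2, runs_of)
  mean(runs <= r_obs)
}

# count runs in the pooled sorted labeling of two tie-free samples
oracle_runs_count <- function(x, y) {
  lab <- rep(1:2, c(length(x), length(y)))[order(c(x, y))]
  1L + sum(diff(lab) != 0L)
}

# exact two-sided Wilcoxon signed-rank p by enumerating all 2^n sign patterns
oracle_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  v_all <- signs %*% r
  p_le <- mean(v_all <= v_obs + 1e-9)
  p_ge <- mean(v_all >= v_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# direct-formula Friedman statistic (tie-corrected), written independently
oracle_friedman_stat <- function(x) {
  n <- nrow(x); k <- ncol(x)
  R <- t(apply(x, 1, rank))
  A <- sum(R^2)
  C <- n * k * (k + 1)^2 / 4
  B <- sum(colSums(R)^2) / n
  n * (k - 1) * (B - C) / (A - C)
}

# exact Friedman p by enumerating within-block permutations of tie-free data
oracle_friedman_p <- function(x) {
  n <- nrow(x); k <- ncol(x)
  perm <- function(v) {
    if (length(v) == 1) return(list(v))
    unlist(lapply(seq_along(v), function(i) {
      lapply(perm(v[-i]), function(p) c(v[i], p))
    }), recursive = FALSE)
  }
  pk <- perm(seq_len(k))
  stat_obs <- oracle_friedman_stat(x)
  grid <- expand.grid(rep(list(seq_along(pk)), n))
  stats_null <- apply(grid, 1, function(g) {
    xm <- do.call(rbind, lapply(seq_len(n), function(i) pk[[g[i]]]))
    oracle_friedman_stat(xm)
  })
  mean(stats_null >= stat_obs - 1e-9)
}

# independent Hedges g via the textbook two-step formula
oracle_hedges_g <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp <- sqrt(((n1 - 1) * stats::sd(a)^2 + (n2 - 1) * stats::sd(b)^2) /
               (n1 + n2 - 2))
  (1 - 3 / (4 * (n1 + n2) - 9)) * (mean(a) - mean(b)) / sp
}

# small full-compliance cohort for engine tests
tiny_cohort <- function(n = 6, seed = 11, ...) {
  cohort <- generate_cohort(
    cohort_config(n_subjects = max(n, 2), dropout_probability = 0,
                  partial_compliance_fraction = 0, ...),
    seed = seed
  )
  if (n < 2) cohort <- head(cohort, n) # keeps attributes
  cohort
}
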