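# Nonparametric and parametric tests of the analysis plan, implemented from
# their defining formulas with exact small-sample null distributions.

adapt_test <- function(method, statistic, p_value, df = NULL,
                       detail = c("exact", "normal_approx", "F_distribution",
                                  "chisq_approx", "t_distribution",
                                  "degenerate"),
                       notes = character(), extra = list()) {
  detail <- match.arg(detail)
  structure(
    c(list(method = method, statistic = statistic, df = df,
           p_value = p_value, detail = detail, notes = notes), extra),
    class = "adapt_test"
  )
}

#' @export
print.adapt_test <- function(x, ...) {
  dfs <- if (is.null(x$df)) "" else paste0(" (df ", paste(x$df, collapse = ", "), ")")
  cat(sprintf("%s\n  statistic = %.6g%s, p = %.4g [%s]\n",
              x$method, x$statistic, dfs, x$p_value, x$detail))
  for (nt in x$notes) cat("  note: ", nt, "\n", sep = "")
  invisible(x)
}

# ---- Wald-Wolfowitz runs test ------------------------------------------------

# deterministic tie-neutral label ordering: sort by value (stable), then
# within every tied value spanning both samples interleave the labels
# alternately, starting from the majority label. A one-sided stacking of
# tied labels would manufacture spurious separation on discrete data.
runs_label_order <- function(pooled, labels) {
  ord <- order(pooled)
  lab <- labels[ord]
  vals <- pooled[ord]
  for (v in unique(vals[duplicated(vals)])) {
    at <- which(vals == v)
    grp <- lab[at]
    if (length(unique(grp)) > 1) {
      n1 <- sum(grp == 1L); n2 <- length(grp) - n1
      first <- if (n1 >= n2) 1L else 2L
      other <- 3L - first
      inter <- integer(length(grp))
      inter[seq(1, by = 2, length.out = max(n1, n2))] <- first
      inter[seq(2, by = 2, length.out = min(n1, n2))] <- other
      lab[at] <- inter
    }
  }
  lab
}

# exact null pmf of the number of runs given group sizes n and m
runs_null_pmf <- function(n, m) {
  rmax <- 2 * min(n, m) + (n != m)
  r <- 2:rmax
  pmf <- vapply(r, function(ri) {
    if (ri %% 2 == 0) {
      k <- ri / 2
      2 * choose(n - 1, k - 1) * choose(m - 1, k - 1)
    } else {
      k <- (ri - 1) / 2
      choose(n - 1, k) * choose(m - 1, k - 1) +
        choose(n - 1, k - 1) * choose(m - 1, k)
    }
  }, numeric(1)) / choose(n + m, n)
  setNames(pmf, r)
}

#' Wald--Wolfowitz runs test for two samples
#'
#' Pools both samples, sorts, labels each value by its sample of origin and
#' counts runs of identical labels; few runs indicate the samples separate.
#' The exact left-tail p-value from the combinatorial null distribution of
#' the run count is used for `n + m <= 12` (or when `exact = TRUE`); larger
#' samples use the normal approximation with mean `2nm/(n+m) + 1`, the
#' standard variance and a continuity correction.
#'
#' The classical test assumes continuous data. Cross-sample ties are
#' resolved deterministically and neutrally: within every tied value the
#' two samples' labels are interleaved alternately (with a warning), so
#' that discreteness neither manufactures nor hides separation.
#'
#' @param x,y Numeric samples.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact null; `NULL`
#'   decides by total sample size.
#' @return An `adapt_test` with the run count as statistic.
#' @examples
#' runs_test(c(1, 3, 5), c(2, 4, 6)) # maximal alternation: 6 runs
#' @export
runs_test <- function(x, y, exact = NULL) {
  if (length(x) == 0 || length(y) == 0) abort("Both samples must be nonempty.")
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  labels <- rep(c(1L, 2L), c(n, m))
  notes <- character()
  tied <- any(duplicated(pooled)) &&
    any(vapply(unique(pooled[duplicated(pooled)]),
               function(v) length(unique(labels[pooled == v])) > 1, logical(1)))
  if (tied) {
    warn("Cross-sample ties present; resolved by alternating tied labels.")
    notes <- "cross-sample ties resolved by alternating tied labels"
  }
  lab_sorted <- runs_label_order(pooled, labels)
  runs <- 1L + sum(diff(lab_sorted) != 0L)
  use_exact <- exact %||% (n + m <= 12)
  if (use_exact) {
    pmf <- runs_null_pmf(n, m)
    p <- sum(pmf[as.integer(names(pmf)) <= runs])
    detail <- "exact"
  } else {
    mu <- 2 * n * m / (n + m) + 1
    sig2 <- 2 * n * m * (2 * n * m - n - m) / ((n + m)^2 * (n + m - 1))
    z <- (runs - mu + 0.5) / sqrt(sig2)
    p <- pnorm(z)
    detail <- "normal_approx"
  }
  adapt_test("Wald-Wolfowitz runs test", statistic = runs,
             p_value = min(p, 1), detail = detail, notes = notes,
             extra = list(n = n, m = m))
}

# ---- Friedman rank ANOVA -----------------------------------------------------

tie_term <- function(v) {
  t <- table(v)
  sum(t^3 - t)
}

#' Friedman rank analysis of variance
#'
#' Ranks the `k` treatments within each of the `n` blocks (mean ranks for
#' ties) and computes
#' \eqn{\chi^2_F = \frac{12}{n k (k+1)} \sum_j R_j^2 - 3 n (k+1)},
#' divided by the tie-correction factor
#' \eqn{1 - \sum (t^3 - t) / (n k (k^2 - 1))}. The p-value comes from the
#' chi-squared distribution with `k - 1` df, or, for untied data with
#' `n * k <= 12` (or `exact = TRUE`), from exhaustive enumeration of all
#' `(k!)^n` within-block rank permutations.
#'
#' @param x An `n x k` matrix or data frame, blocks (subjects) in rows,
#'   treatments (timepoints) in columns. Missing cells are an error.
#' @param exact Force or forbid exact enumeration; `NULL` decides by size.
#' @return An `adapt_test`.
#' @export
friedman_test <- function(x, exact = NULL) {
  x <- as.matrix(x)
  if (anyNA(x)) abort("Missing cells are not allowed (no imputation).")
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) abort("Need at least 2 blocks and 2 treatments.")
  ranks <- t(apply(x, 1, rank))
  has_ties <- any(apply(x, 1, function(r) any(duplicated(r))))
  stat <- friedman_statistic(ranks, n, k)
  if (!is.finite(stat)) {
    return(adapt_test("Friedman rank ANOVA", statistic = 0, p_value = 1,
                      df = k - 1, detail = "degenerate",
                      notes = "all treatments identical within every block"))
  }
  use_exact <- exact %||% (n * k <= 12 && !has_ties)
  if (use_exact && has_ties) {
    warn("Exact Friedman enumeration assumes untied data; using chi-squared.")
    use_exact <- FALSE
  }
  if (use_exact) {
    null_stats <- friedman_null_distribution(n, k)
    p <- mean(null_stats >= stat - 1e-9)
    detail <- "exact"
  } else {
    p <- pchisq(stat, df = k - 1, lower.tail = FALSE)
    detail <- "chisq_approx"
  }
  adapt_test("Friedman rank ANOVA", statistic = stat, p_value = p,
             df = k - 1, detail = detail, extra = list(n = n, k = k))
}

friedman_statistic <- function(ranks, n, k) {
  Rj <- colSums(ranks)
  raw <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  ties <- sum(apply(ranks, 1, tie_term))
  C <- 1 - ties / (n * k * (k^2 - 1))
  if (C <= 0) return(NA_real_) # fully tied within every block
  raw / C
}

# all permutations of 1..k (k <= 6 in practice here)
perms <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- perms(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

friedman_null_distribution <- function(n, k) {
  pk <- perms(k)
  idx <- rep(list(seq_len(nrow(pk))), n)
  grid <- do.call(expand.grid, idx)
  apply(grid, 1, function(g) {
    ranks <- pk[as.integer(g), , drop = FALSE]
    friedman_statistic(ranks, n, k)
  })
}

# ---- Kruskal-Wallis ----------------------------------------------------------

#' Kruskal--Wallis rank sum test
#'
#' Pooled-rank one-way ANOVA:
#' \eqn{H = \frac{12}{N(N+1)} \sum_j R_j^2 / n_j - 3(N+1)}, divided by the
#' tie correction \eqn{1 - \sum(t^3 - t)/(N^3 - N)}; p-value from the
#' chi-squared distribution with `g - 1` df. If every observation is
#' identical, `H = 0` with `p = 1`.
#'
#' @param groups A list of numeric vectors (each nonempty), or a numeric
#'   vector together with `g` giving group labels.
#' @param g Optional grouping factor when `groups` is a vector.
#' @return An `adapt_test`.
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4))) # H = 2.4
#' @export
kruskal_wallis <- function(groups, g = NULL) {
  if (!is.list(groups)) groups <- split(groups, g)
  if (length(groups) < 2 || any(lengths(groups) == 0)) {
    abort("Need at least 2 nonempty groups.")
  }
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  if (length(unique(pooled)) == 1) {
    return(adapt_test("Kruskal-Wallis rank ANOVA", statistic = 0, p_value = 1,
                      df = length(groups) - 1, detail = "degenerate",
                      notes = "all values identical"))
  }
  r <- rank(pooled)
  lab <- rep(seq_along(groups), lengths(groups))
  Rj <- tapply(r, lab, sum)
  nj <- lengths(groups)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
  C <- 1 - tie_term(pooled) / (N^3 - N)
  H <- H / C
  df <- length(groups) - 1
  adapt_test("Kruskal-Wallis rank ANOVA", statistic = H,
             p_value = pchisq(H, df, lower.tail = FALSE), df = df,
             detail = "chisq_approx")
}

# ---- Wilcoxon matched-pairs signed-rank --------------------------------------

# exact conditional null of V = sum of positive signed ranks, given the
# observed (possibly tied, half-integer) ranks; convolution on a 2x integer
# grid, so tied average ranks are handled exactly
signed_rank_null <- function(ranks2) {
  total <- sum(ranks2)
  f <- numeric(total + 1)
  f[1] <- 1
  for (r in ranks2) {
    shifted <- c(rep(0, r), f[seq_len(total + 1 - r)])
    f <- f + shifted
  }
  f / 2^length(ranks2)
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Computes the sum of positive signed ranks of the paired differences
#' `y - x`, dropping zero differences (Wilcoxon's original policy) and
#' assigning mean ranks to tied magnitudes. The two-sided p-value is exact
#' for `n <= 25` nonzero pairs -- computed by convolution of the conditional
#' null given the observed ranks, which handles ties exactly -- and uses the
#' tie-corrected, continuity-corrected normal approximation otherwise.
#'
#' @param x,y Paired samples of equal length (`x` baseline, `y` later).
#' @param exact Force or forbid the exact null; `NULL` decides by size.
#' @return An `adapt_test` with statistic `V` (positive-rank sum). If all
#'   differences are zero, a degenerate result is flagged (no test).
#' @export
wilcoxon_signed_rank <- function(x, y, exact = NULL) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  d <- y - x
  notes <- character()
  if (any(d == 0)) {
    notes <- sprintf("%d zero difference(s) dropped", sum(d == 0))
    d <- d[d != 0]
  }
  if (length(d) == 0) {
    return(adapt_test("Wilcoxon matched-pairs signed-rank test",
                      statistic = NA_real_, p_value = NA_real_,
                      detail = "degenerate",
                      notes = "all differences zero; no test performed"))
  }
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  use_exact <- exact %||% (n <= 25)
  if (use_exact) {
    pmf <- signed_rank_null(as.integer(round(2 * r)))
    v2 <- as.integer(round(2 * V))
    support <- seq_along(pmf) - 1L
    p_le <- sum(pmf[support <= v2])
    p_ge <- sum(pmf[support >= v2])
    p <- min(1, 2 * min(p_le, p_ge))
    detail <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - tie_term(abs(d)) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    detail <- "normal_approx"
  }
  adapt_test("Wilcoxon matched-pairs signed-rank test", statistic = V,
             p_value = p, detail = detail, notes = notes,
             extra = list(n = n))
}

# ---- Levene's test -----------------------------------------------------------

#' Levene's test of variance homogeneity
#'
#' One-way ANOVA on the absolute deviations from the group means (the
#' original mean-centered form): `F` with `(g - 1, N - g)` df.
#'
#' @param groups A list of numeric vectors, each of size >= 2, or a vector
#'   with grouping factor `g`.
#' @param g Optional grouping factor.
#' @param center `"mean"` (default, original form) or `"median"`
#'   (Brown--Forsythe variant).
#' @return An `adapt_test`. If every absolute deviation is zero the result
#'   is flagged degenerate.
#' @export
levene_test <- function(groups, g = NULL, center = c("mean", "median")) {
  center <- match.arg(center)
  if (!is.list(groups)) groups <- split(groups, g)
  if (length(groups) < 2 || any(lengths(groups) < 2)) {
    abort("Need at least 2 groups of size >= 2.")
  }
  cfun <- if (center == "mean") mean else median
  z <- lapply(groups, function(v) abs(v - cfun(v)))
  N <- sum(lengths(z)); k <- length(z)
  zbar <- mean(unlist(z))
  zj <- vapply(z, mean, numeric(1))
  ssb <- sum(lengths(z) * (zj - zbar)^2)
  ssw <- sum(vapply(z, function(v) sum((v - mean(v))^2), numeric(1)))
  if (ssw < .Machine$double.eps && ssb < .Machine$double.eps) {
    return(adapt_test("Levene's test (mean-centered)", statistic = NA_real_,
                      p_value = NA_real_, df = c(k - 1, N - k),
                      detail = "degenerate",
                      notes = "zero within-group deviation everywhere"))
  }
  Fstat <- (ssb / (k - 1)) / (ssw / (N - k))
  adapt_test("Levene's test (mean-centered)", statistic = Fstat,
             p_value = pf(Fstat, k - 1, N - k, lower.tail = FALSE),
             df = c(k - 1, N - k), detail = "F_distribution")
}

# ---- Pearson correlation -----------------------------------------------------

#' Pearson product--moment correlation test
#'
#' `r` by the product-moment formula and a two-sided p-value from
#' \eqn{t = r \sqrt{(n-2)/(1-r^2)}} on `n - 2` df.
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return An `adapt_test` with statistic `r` and element `t`.
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  n <- length(x)
  if (n < 3) abort("Need at least 3 pairs.")
  if (sd(x) == 0 || sd(y) == 0) abort("Zero variance in `x` or `y`.")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  if (abs(r) >= 1) {
    p <- 0
    tstat <- sign(r) * Inf
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tstat), n - 2)
  }
  adapt_test("Pearson product-moment correlation", statistic = r,
             p_value = p, df = n - 2, detail = "t_distribution",
             extra = list(t = tstat, n = n))
}
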