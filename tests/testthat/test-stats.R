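test_that("runs test counts runs correctly in the canonical configurations", {
  # perfect interleaving: maximal number of runs
  r1 <- runs_test(c(1, 3, 5), c(2, 4, 6))
  expect_equal(r1$statistic, 6)
  # complete separation: exactly two runs
  r2 <- runs_test(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r2$statistic, 2)
  expect_lt(r2$p_value, r1$p_value)
})

test_that("exact runs-test p-values equal enumeration over all labelings", {
  set.seed(101)
  for (sizes in list(c(3, 3), c(4, 4), c(5, 3), c(6, 6))) {
    n <- sizes[1]; m <- sizes[2]
    x <- sample(100, n); y <- sample(200, m) + 0.5 # tie-free
    got <- runs_test(x, y, exact = TRUE)
    expect_equal(got$p_value, oracle_runs_p(n, m, oracle_runs_count(x, y)),
                 tolerance = 1e-12)
  }
})

test_that("large-sample runs test uses the stated normal approximation", {
  set.seed(5)
  x <- rnorm(20); y <- rnorm(25)
  got <- runs_test(x, y)
  n <- 20; m <- 25
  r <- oracle_runs_count(x, y)
  mu <- 2 * n * m / (n + m) + 1
  s2 <- 2 * n * m * (2 * n * m - n - m) / ((n + m)^2 * (n + m - 1))
  expect_equal(got$statistic, r)
  expect_equal(got$p_value, pnorm((r - mu + 0.5) / sqrt(s2)))
  expect_equal(got$detail, "normal_approx")
})

test_that("cross-sample ties trigger the documented tie policy warning", {
  expect_warning(runs_test(c(1, 2, 3), c(2, 5, 6)), "ties")
})

test_that("Friedman statistic matches hand evaluation and the formula oracle", {
  # three blocks ranked identically over three treatments: rank sums 3, 6, 9
  x <- rbind(c(1, 2, 3), c(10, 20, 30), c(0.1, 0.2, 0.3))
  got <- friedman_test(x, exact = FALSE)
  expect_equal(got$statistic, 6)
  # all treatments identical within every block: zero after tie handling
  flat <- matrix(5, nrow = 3, ncol = 3)
  gotf <- friedman_test(flat)
  expect_equal(gotf$statistic, 0)
  expect_equal(gotf$p_value, 1)
  # random matrices match the independent direct-formula oracle
  set.seed(7)
  for (k in 1:5) {
    m <- matrix(rnorm(12), nrow = 4)
    expect_equal(friedman_test(m, exact = FALSE)$statistic,
                 oracle_friedman_stat(m), tolerance = 1e-12)
  }
  expect_error(friedman_test(matrix(c(1, NA, 2, 3), 2)), "Missing")
})

test_that("exact Friedman p-values equal exhaustive permutation enumeration", {
  set.seed(13)
  for (dims in list(c(3, 3), c(4, 3), c(2, 4), c(6, 2))) {
    m <- matrix(rnorm(prod(dims)), nrow = dims[1])
    got <- friedman_test(m, exact = TRUE)
    expect_equal(got$p_value, oracle_friedman_p(m), tolerance = 1e-12)
  }
})

test_that("Friedman agrees with the base R implementation", {
  set.seed(19)
  m <- matrix(rnorm(40), nrow = 10)
  got <- friedman_test(m, exact = FALSE)
  ref <- friedman.test(m)
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("Kruskal-Wallis matches hand evaluation, base R, and handles ties", {
  # ranks 1..4 split into {1,2} and {3,4}: H = 2.4
  expect_equal(kruskal_wallis(list(c(1, 2), c(3, 4)))$statistic, 2.4)
  # identical values degenerate to H = 0, p = 1
  flat <- kruskal_wallis(list(c(2, 2), c(2, 2)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  set.seed(23)
  g <- list(rnorm(8), rnorm(6, 1), round(rnorm(7, 2))) # third group has ties
  got <- kruskal_wallis(g)
  ref <- kruskal.test(unlist(g), rep(1:3, lengths(g)))
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("two-group Kruskal-Wallis equals the squared standardized rank statistic", {
  # with two groups H equals z^2 of the (tie-free) Wilcoxon rank-sum
  set.seed(29)
  x <- rnorm(9); y <- rnorm(7, 0.5)
  H <- kruskal_wallis(list(x, y))$statistic
  N <- 16
  R1 <- sum(rank(c(x, y))[1:9])
  z <- (R1 - 9 * (N + 1) / 2) / sqrt(9 * 7 * (N + 1) / 12)
  expect_equal(H, z^2, tolerance = 1e-12)
})

test_that("Wilcoxon signed-rank handles the textbook cases", {
  # uniform positive shift of 6 pairs: extreme statistic, exact p = 2/64
  pre <- c(10, 12, 9, 14, 11, 13)
  got <- wilcoxon_signed_rank(pre, pre + 3)
  expect_equal(got$statistic, 21)
  expect_equal(got$p_value, 2 / 64)
  expect_equal(got$detail, "exact")
  # antisymmetric differences center the statistic at its null mean
  d <- c(-3, -2, -1, 1, 2, 3)
  got2 <- wilcoxon_signed_rank(rep(0, 6), d)
  expect_equal(got2$statistic, 6 * 7 / 4)
  # all-zero differences are flagged, not tested
  deg <- suppressWarnings(wilcoxon_signed_rank(1:4, 1:4))
  expect_equal(deg$detail, "degenerate")
  expect_true(is.na(deg$p_value))
})

test_that("exact Wilcoxon p-values equal sign-pattern enumeration", {
  set.seed(31)
  for (n in c(5, 8, 10, 12)) {
    x <- rnorm(n); y <- x + rnorm(n, 0.4)
    got <- wilcoxon_signed_rank(x, y, exact = TRUE)
    expect_equal(got$p_value, oracle_wilcoxon_p(y - x), tolerance = 1e-12)
  }
  # tied magnitudes: conditional exact null still matches enumeration
  x <- c(0, 0, 0, 0, 0, 0)
  y <- c(1, 1, -1, 2, 2, 3)
  got <- wilcoxon_signed_rank(x, y, exact = TRUE)
  expect_equal(got$p_value, oracle_wilcoxon_p(y - x), tolerance = 1e-12)
})

test_that("Wilcoxon agrees with base R where both are exact", {
  set.seed(37)
  x <- rnorm(12); y <- x + rnorm(12, 0.3)
  got <- wilcoxon_signed_rank(x, y)
  ref <- wilcox.test(y, x, paired = TRUE, exact = TRUE)
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("Levene's test composes deviations with a one-way ANOVA", {
  # identical spread patterns give F = 0
  expect_equal(levene_test(list(c(1, 2, 3), c(11, 12, 13)))$statistic, 0)
  # compositional oracle: absolute deviations fed to aov()
  set.seed(41)
  g <- list(rnorm(8), rnorm(7, 0, 3), rnorm(6, 0, 0.5))
  got <- levene_test(g)
  z <- unlist(lapply(g, function(v) abs(v - mean(v))))
  lab <- factor(rep(seq_along(g), lengths(g)))
  ref <- anova(stats::aov(z ~ lab))
  expect_equal(got$statistic, ref$`F value`[1], tolerance = 1e-12)
  expect_equal(got$p_value, ref$`Pr(>F)`[1], tolerance = 1e-12)
  expect_equal(got$df, c(2, 18))
  # inflating one group's scale strictly increases the statistic
  base <- list(rnorm(10), rnorm(10))
  f_by_scale <- vapply(c(2, 4, 8, 16), function(s) {
    levene_test(list(base[[1]], base[[2]] * s))$statistic
  }, numeric(1))
  expect_true(all(diff(f_by_scale) > 0))
  # constant groups are degenerate
  expect_equal(levene_test(list(c(1, 1), c(2, 2)))$detail, "degenerate")
})

test_that("Levene matches the car implementation with mean centering", {
  skip_if_not_installed("car")
  set.seed(43)
  v <- c(rnorm(9), rnorm(7, 0, 2))
  lab <- factor(rep(1:2, c(9, 7)))
  got <- levene_test(split(v, lab))
  ref <- car::leveneTest(v, lab, center = mean)
  expect_equal(got$statistic, ref$`F value`[1], tolerance = 1e-12)
  expect_equal(got$p_value, ref$`Pr(>F)`[1], tolerance = 1e-12)
})

test_that("mixed ANOVA reproduces the completer/control df structure", {
  set.seed(47)
  change <- matrix(rnorm(18 * 5), nrow = 18)
  arm <- rep(c("training", "control"), c(11, 7))
  got <- mixed_anova(change, arm)
  expect_equal(got$df1[got$effect == "arm"], 1)
  expect_equal(got$df2[got$effect == "arm"], 16)
  expect_equal(got$df1[got$effect == "arm:measure"], 4)
  expect_equal(got$df2[got$effect == "arm:measure"], 64)
  # location invariance: adding a constant changes no F statistic
  shifted <- mixed_anova(change + 7, arm)
  expect_equal(got$statistic, shifted$statistic, tolerance = 1e-12)
  # missing cells are refused
  change_na <- change
  change_na[3, 2] <- NA
  expect_error(mixed_anova(change_na, arm), "Missing")
})

test_that("mixed ANOVA agrees with aov()'s split-plot decomposition", {
  set.seed(53)
  change <- matrix(rnorm(18 * 5, sd = 2), nrow = 18)
  arm <- rep(c("a", "b"), c(11, 7))
  got <- mixed_anova(change, arm)
  long <- data.frame(
    y = as.vector(change),
    subj = factor(rep(seq_len(18), times = 5)),
    measure = factor(rep(seq_len(5), each = 18)),
    arm = factor(rep(arm, times = 5))
  )
  ref <- summary(stats::aov(y ~ arm * measure + Error(subj / measure),
                            data = long))
  ref_arm <- ref[["Error: subj"]][[1]]
  ref_within <- ref[["Error: subj:measure"]][[1]]
  expect_equal(got$statistic[got$effect == "arm"], ref_arm$`F value`[1],
               tolerance = 1e-10)
  expect_equal(got$statistic[got$effect == "arm:measure"],
               ref_within$`F value`[2], tolerance = 1e-10)
  expect_equal(got$p_value[got$effect == "arm:measure"],
               ref_within$`Pr(>F)`[2], tolerance = 1e-10)
})

test_that("mixed ANOVA arm F is calibrated under a true null", {
  set.seed(59)
  fs <- vapply(1:500, function(i) {
    change <- matrix(rnorm(18 * 5), nrow = 18)
    arm <- sample(rep(c("a", "b"), c(11, 7)))
    mixed_anova(change, arm)$statistic[1]
  }, numeric(1))
  # F(1,16) has mean df2/(df2-2) = 16/14
  expect_lt(abs(mean(fs) - 16 / 14), 0.15)
})

test_that("effect sizes carry the small-sample correction", {
  set.seed(61)
  a <- rnorm(11, 1); b <- rnorm(7)
  got <- hedges_g(a, b)
  expect_equal(got$correction_J, 1 - 3 / 63) # n1 = 11, n2 = 7
  expect_equal(got$hedges_g, got$cohen_d * got$correction_J)
  expect_lte(abs(got$hedges_g), abs(got$cohen_d))
  expect_equal(got$hedges_g, oracle_hedges_g(a, b), tolerance = 1e-12)
  # identical groups: zero effect
  both <- c(rnorm(5), 1)
  expect_equal(hedges_g(both, both)$hedges_g, 0)
  # J tends to 1 as samples grow
  big <- hedges_g(rnorm(5000, 0.2), rnorm(5000))
  expect_lt(abs(big$correction_J - 1), 1e-3)
  expect_error(hedges_g(c(1, 1), c(1, 1)), "pooled")
})

test_that("Pearson correlation matches its closed form and cor.test", {
  x <- c(1, 2, 4, 7, 11)
  expect_equal(pearson_test(x, x)$statistic, 1)
  expect_equal(pearson_test(x, -x)$statistic, -1)
  set.seed(67)
  a <- rnorm(11); b <- 0.5 * a + rnorm(11)
  got <- pearson_test(a, b)
  covar <- sum((a - mean(a)) * (b - mean(b)))
  expect_equal(got$statistic,
               covar / sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2)),
               tolerance = 1e-12)
  ref <- cor.test(a, b)
  expect_equal(got$statistic, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  expect_error(pearson_test(rep(1, 5), rnorm(5)), "variance")
  expect_error(pearson_test(1:2, 1:2), "at least 3")
})

test_that("rank-based statistics are invariant under monotone transforms", {
  set.seed(71)
  g <- list(rnorm(6), rnorm(5, 1))
  mono <- function(v) exp(v) + v^3 / 10
  expect_equal(kruskal_wallis(g)$statistic,
               kruskal_wallis(lapply(g, mono))$statistic, tolerance = 1e-12)
  m <- matrix(rnorm(12), 4)
  expect_equal(friedman_test(m, exact = FALSE)$statistic,
               friedman_test(mono(m), exact = FALSE)$statistic,
               tolerance = 1e-12)
  x <- rnorm(6); y <- rnorm(6, 0.5)
  expect_equal(runs_test(x, y)$statistic,
               runs_test(mono(x), mono(y))$statistic)
})

test_that("tidy methods return well-formed one-row summaries", {
  got <- tidy(kruskal_wallis(list(c(1, 2), c(3, 4))))
  expect_s3_class(got, "tbl_df")
  expect_named(got, c("method", "statistic", "df1", "df2", "p_value", "detail"))
  es <- tidy(hedges_g(rnorm(5, 1), rnorm(5)))
  expect_named(es, c("cohen_d", "correction_J", "hedges_g", "n1", "n2"))
})
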