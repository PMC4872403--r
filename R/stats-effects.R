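# Effect sizes and the mixed-design ANOVA on change scores.

#' Bias-corrected standardized mean difference (Hedges' g)
#'
#' Cohen's `d` with the pooled standard deviation over `n1 + n2 - 2` df,
#' multiplied by the small-sample correction
#' \eqn{J = 1 - 3 / (4 (n_1 + n_2) - 9)}.
#'
#' @param a,b Numeric vectors, each of size >= 2.
#' @return A one-row tibble of class `effect_size`: `cohen_d`,
#'   `correction_J`, `hedges_g`, `n1`, `n2`.
#' @examples
#' hedges_g(rnorm(11, 1), rnorm(7)) # J = 1 - 3/63 at these sizes
#' @export
hedges_g <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2) abort("Each group needs at least 2 observations.")
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  if (sp2 <= 0) abort("Zero pooled standard deviation; effect size undefined.")
  d <- (mean(a) - mean(b)) / sqrt(sp2)
  J <- 1 - 3 / (4 * (n1 + n2) - 9)
  out <- tibble(cohen_d = d, correction_J = J, hedges_g = J * d,
                n1 = n1, n2 = n2)
  class(out) <- c("effect_size", class(out))
  out
}

#' Mixed-design ANOVA on change scores
#'
#' Two-way mixed (split-plot) analysis of a complete subjects-by-measures
#' matrix of change scores with a between-subjects arm factor: the
#' between-subjects sum of squares splits into the arm effect (tested
#' against subjects-within-arm, df `(a-1, N-a)`) and the within-subjects sum
#' of squares into the measure effect and the arm-by-measure interaction
#' (tested against the measure-by-subject residual, interaction df
#' `((a-1)(m-1), (N-a)(m-1))`). With two arms, 18 subjects and five
#' measures this is the familiar `(1, 16)` / `(4, 64)` df structure.
#'
#' @param change A complete numeric matrix or data frame, one row per
#'   subject, one column per measure. Missing cells are an error (the
#'   analysis mirrors a completer-only design; no imputation).
#' @param arm A vector of arm labels, one per subject (exactly two levels).
#' @return A tibble of class `mixed_anova` with one row per effect
#'   (`arm`, `measure`, `arm:measure`): `df1`, `df2`, `ss`, `ms`,
#'   `statistic` (F) and `p_value`.
#' @export
mixed_anova <- function(change, arm) {
  change <- as.matrix(change)
  if (anyNA(change)) abort("Missing cells are not allowed (no imputation).")
  if (nrow(change) != length(arm)) {
    abort("`arm` must supply one label per subject row.")
  }
  arm <- as.factor(arm)
  a <- nlevels(arm)
  if (a != 2) abort("Exactly two arms are required.")
  N <- nrow(change); m <- ncol(change)
  if (m < 2) abort("Need at least 2 measures.")
  grand <- mean(change)
  subj_mean <- rowMeans(change)
  meas_mean <- colMeans(change)
  arm_mean <- tapply(subj_mean, arm, mean)
  n_a <- table(arm)
  cell_mean <- apply(change, 2, function(col) tapply(col, arm, mean)) # a x m
  ss_total <- sum((change - grand)^2)
  ss_between_subj <- m * sum((subj_mean - grand)^2)
  ss_arm <- m * sum(n_a * (arm_mean - grand)^2)
  ss_subj_within <- ss_between_subj - ss_arm
  ss_measure <- N * sum((meas_mean - grand)^2)
  ss_int <- sum(vapply(seq_len(m), function(j) {
    sum(n_a * (cell_mean[, j] - arm_mean - meas_mean[j] + grand)^2)
  }, numeric(1)))
  ss_error <- ss_total - ss_between_subj - ss_measure - ss_int
  df_arm <- a - 1
  df_subj <- N - a
  df_meas <- m - 1
  df_int <- (a - 1) * (m - 1)
  df_err <- (N - a) * (m - 1)
  mean_sq <- c(arm = ss_arm / df_arm, subj = ss_subj_within / df_subj,
               measure = ss_measure / df_meas, int = ss_int / df_int,
               err = ss_error / df_err)
  out <- tibble(
    effect = c("arm", "measure", "arm:measure"),
    df1 = c(df_arm, df_meas, df_int),
    df2 = c(df_subj, df_err, df_err),
    ss = c(ss_arm, ss_measure, ss_int),
    ms = unname(mean_sq[c("arm", "measure", "int")]),
    statistic = unname(c(mean_sq[["arm"]] / mean_sq[["subj"]],
                         mean_sq[["measure"]] / mean_sq[["err"]],
                         mean_sq[["int"]] / mean_sq[["err"]]))
  ) |>
    mutate(p_value = pf(.data$statistic, .data$df1, .data$df2,
                        lower.tail = FALSE))
  class(out) <- c("mixed_anova", class(out))
  attr(out, "error_ms") <- c(subjects = unname(mean_sq[["subj"]]),
                             residual = unname(mean_sq[["err"]]))
  out
}
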