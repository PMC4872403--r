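# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @rdname adaptrain-tidiers
#' @title Tidiers for adaptrain result objects
#' @description `tidy()` turns test results, effect sizes, ANOVA tables and
#'   analysis reports into tibbles; `glance()` gives one-row summaries.
#' @param x An `adapt_test`, `effect_size`, `mixed_anova`, `staircase_sim`,
#'   `trial_analysis` or `trial_dataset` object.
#' @param ... Unused, for generic consistency.
#' @return A tibble.
#' @export
tidy.adapt_test <- function(x, ...) {
  tibble(
    method = x$method,
    statistic = unname(x$statistic),
    df1 = if (is.null(x$df)) NA_real_ else x$df[1],
    df2 = if (is.null(x$df) || length(x$df) < 2) NA_real_ else x$df[2],
    p_value = x$p_value,
    detail = x$detail
  )
}

#' @rdname adaptrain-tidiers
#' @export
glance.adapt_test <- function(x, ...) tidy(x, ...)

#' @rdname adaptrain-tidiers
#' @export
tidy.effect_size <- function(x, ...) as_tibble(unclass(x))

#' @rdname adaptrain-tidiers
#' @export
tidy.mixed_anova <- function(x, ...) as_tibble(unclass(x))

#' @rdname adaptrain-tidiers
#' @export
glance.staircase_sim <- function(x, ...) {
  tibble(
    n_trials = x$n_trials,
    burn_in = x$burn_in_used,
    accuracy = x$accuracy,
    converged_challenge = x$converged_challenge,
    n_reversals = x$state$n_reversals,
    final_step = x$state$step,
    band_lower = x$state$target_band[1],
    band_upper = x$state$target_band[2],
    in_band = x$accuracy >= x$state$target_band[1] &
      x$accuracy <= x$state$target_band[2]
  )
}

#' @rdname adaptrain-tidiers
#' @export
tidy.staircase_sim <- function(x, ...) x$trajectory

#' @rdname adaptrain-tidiers
#' @export
tidy.trial_analysis <- function(x, ...) x$report

#' @rdname adaptrain-tidiers
#' @export
glance.trial_analysis <- function(x, ...) {
  rep <- x$report
  pick <- function(test, col = "p_value") {
    v <- rep[[col]][rep$test == test]
    if (length(v) == 0) NA_real_ else v[1]
  }
  tibble(
    n_completers = x$group_sizes[["completers"]],
    n_controls = x$group_sizes[["controls"]],
    n_partials = x$group_sizes[["partials"]],
    arm_F = pick("cognitive_anova_arm", "statistic"),
    arm_p = pick("cognitive_anova_arm"),
    interaction_F = pick("cognitive_anova_arm_x_measure", "statistic"),
    interaction_p = pick("cognitive_anova_arm_x_measure"),
    hedges_g_post = pick("adhd_rs_change_post_effect_size", "statistic"),
    hedges_g_followup = pick("adhd_rs_change_followup_effect_size", "statistic"),
    fig5_r = pick("distractor_fp_change_vs_adhd_rs_change", "statistic"),
    fig5_p = pick("distractor_fp_change_vs_adhd_rs_change")
  )
}

#' @rdname adaptrain-tidiers
#' @export
tidy.trial_dataset <- function(x, ...) x$assessments

#' Plot a staircase trajectory
#'
#' Challenge level over trials, with incorrect trials marked and the
#' steady-state window shaded.
#'
#' @param object A `staircase_sim`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.staircase_sim <- function(object, ...) {
  tr <- object$trajectory
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$trial, y = .data$challenge)) +
    ggplot2::annotate("rect", xmin = object$burn_in_used, xmax = max(tr$trial),
                      ymin = -Inf, ymax = Inf, alpha = 0.08) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_point(data = tr[!tr$correct, ], size = 0.6, colour = "red") +
    ggplot2::geom_hline(yintercept = object$converged_challenge,
                        linetype = "dashed") +
    ggplot2::labs(
      x = "trial", y = "challenge",
      title = sprintf("Staircase trajectory (steady-state accuracy %.1f%%)",
                      100 * object$accuracy)
    ) +
    ggplot2::theme_minimal()
}

#' Plot symptom-rating trajectories of a trial dataset
#'
#' Mean parent-rated symptom severity per arm and compliance status across
#' the four assessment timepoints, with standard-error bars.
#'
#' @param object A `trial_dataset`.
#' @param instrument Instrument to plot (default the primary outcome).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trial_dataset <- function(object, instrument = "adhd_rs", ...) {
  dat <- object$assessments |>
    filter(.data$instrument == !!instrument) |>
    inner_join(select(object$subjects, "subject_id", "arm", "status"),
               by = "subject_id") |>
    mutate(group = ifelse(.data$arm == "control", "control",
                          paste0("training_", .data$status)),
           timepoint = factor(.data$timepoint, tp_levels())) |>
    group_by(.data$group, .data$timepoint) |>
    summarise(mean = mean(.data$value),
              se = sd(.data$value) / sqrt(n()), .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$timepoint, y = .data$mean,
                                    colour = .data$group,
                                    group = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se)) +
    ggplot2::labs(x = NULL, y = paste(instrument, "(mean ± s.e.m.)"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the distractor-improvement vs symptom-improvement relationship
#'
#' Scatter of the change in embedded-probe false positives against the
#' change in symptom ratings for training completers, with the least-squares
#' line; more negative on both axes means larger improvement.
#'
#' @param object A `trial_analysis` whose dataset carried embedded probes.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trial_analysis <- function(object, ...) {
  fig5 <- object$effects$fig5
  if (is.null(fig5)) {
    abort("No distractor-probe correlation available in this analysis.")
  }
  r <- object$report$statistic[
    object$report$test == "distractor_fp_change_vs_adhd_rs_change"][1]
  ggplot2::ggplot(fig5, ggplot2::aes(x = .data$fp_change, y = .data$rs_change)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::labs(
      x = "change in distractor false positives (end - start)",
      y = "change in symptom rating (post - baseline)",
      title = sprintf("Distractor suppression vs symptom change (r = %.2f)", r)
    ) +
    ggplot2::theme_minimal()
}
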