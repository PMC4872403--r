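# The full analysis plan applied to a (simulated or ingested) trial dataset.

tp_levels <- function() c("baseline", "mid", "post", "followup")

#' Pivot one instrument of a long assessment table to subject-by-timepoint
#'
#' Convenience reshaper used throughout the analysis plan: keeps only
#' subjects with a complete set of the requested timepoints (the
#' completer-style, no-imputation convention).
#'
#' @param assessments A long assessment table (`subject_id`, `timepoint`,
#'   `instrument`, `value`).
#' @param instrument The instrument to extract.
#' @param timepoints Timepoints required, in column order.
#' @return A tibble with `subject_id` and one column per timepoint.
#' @export
instrument_wide <- function(assessments, instrument, timepoints = tp_levels()) {
  assessments |>
    filter(.data$instrument == !!instrument,
           .data$timepoint %in% timepoints) |>
    select("subject_id", "timepoint", "value") |>
    tidyr::pivot_wider(names_from = "timepoint", values_from = "value") |>
    filter(if_all(dplyr::all_of(timepoints), ~ !is.na(.x)))
}

collect_notes <- function(expr) {
  notes <- character()
  res <- withCallingHandlers(expr, warning = function(w) {
    notes <<- c(notes, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  list(result = res, notes = notes)
}

test_row <- function(res, name, scope, kind = "test") {
  tibble(
    test = name, scope = scope, kind = kind,
    method = res$method,
    statistic = unname(res$statistic),
    df1 = if (is.null(res$df)) NA_real_ else res$df[1],
    df2 = if (is.null(res$df) || length(res$df) < 2) NA_real_ else res$df[2],
    p_value = res$p_value,
    detail = res$detail
  )
}

#' Run the complete analysis plan on a trial dataset
#'
#' Reproduces the trial's statistical analysis: between-group runs tests on
#' symptom-rating change scores per timepoint; within-group Friedman ANOVAs
#' over the four timepoints for completers, controls and partial trainees
#' (ratings and clinician severity); a Kruskal--Wallis test of medication
#' status against the post-intervention rating change; Wilcoxon
#' matched-pairs tests of baseline against every later timepoint per group;
#' Levene variance checks, the mixed-design ANOVA and per-assessment pooled
#' two-tailed t-tests on the five cognitive change scores (completers vs
#' controls); bias-corrected effect sizes on rating change at post and
#' follow-up; the Pearson correlation of embedded distractor false-positive
#' change against rating change in completers; and a point-biserial
#' diagnostic of training hours vs medication status (flagged as an
#' interpretation of an ambiguous reporting convention). Per-test p-values
#' are reported unadjusted, mirroring the per-test reporting convention;
#' `holm = TRUE` adds a Holm-adjusted column for users who want familywise
#' control.
#'
#' Analyses contrast intervention completers with controls (completer-only,
#' not intent-to-treat); partial trainees contribute only their
#' rating-trajectory analyses.
#'
#' @param dataset A `trial_dataset` from [run_trial()] or [read_dataset()].
#' @param holm Add Holm-adjusted p-values to the report?
#' @return An object of class `trial_analysis`: [tidy()] returns the long
#'   report tibble (`test`, `scope`, `method`, `statistic`, `df1`, `df2`,
#'   `p_value`, `detail`, optional `p_holm`), [glance()] the one-row
#'   headline summary, and [write_report()] serializes both machine- and
#'   human-readable renderings.
#' @export
analyze_trial <- function(dataset, holm = FALSE) {
  if (!inherits(dataset, "trial_dataset")) {
    abort("`dataset` must be a trial_dataset (see run_trial()/read_dataset()).")
  }
  a <- dataset$assessments
  subjects <- dataset$subjects
  problems <- character()
  for (instr in c("adhd_rs", "cgi")) {
    if (!instr %in% a$instrument) {
      problems <- c(problems, paste0("missing instrument: ", instr))
    }
  }
  missing_tp <- setdiff(tp_levels(),
                        unique(a$timepoint[a$instrument == "adhd_rs"]))
  if (length(missing_tp) > 0) {
    problems <- c(problems,
                  paste0("adhd_rs missing timepoint(s): ",
                         paste(missing_tp, collapse = ", ")))
  }
  if (length(problems) > 0) {
    abort(paste0("Dataset not analyzable:\n",
                 paste0("- ", problems, collapse = "\n")))
  }

  completers <- subjects$subject_id[subjects$arm == "training" &
                                      subjects$status == "completer"]
  controls <- subjects$subject_id[subjects$arm == "control" &
                                    subjects$status != "dropout"]
  partials <- subjects$subject_id[subjects$arm == "training" &
                                    subjects$status == "partial"]
  groups <- list(completers = completers, controls = controls,
                 partials = partials)

  rows <- list()
  all_notes <- character()
  add <- function(expr, name, scope, kind = "test") {
    got <- collect_notes(expr)
    all_notes <<- c(all_notes, got$notes)
    rows[[length(rows) + 1]] <<- test_row(got$result, name, scope, kind)
  }

  rs <- instrument_wide(a, "adhd_rs")
  rs_g <- function(ids) rs |> filter(.data$subject_id %in% ids)

  # between-group runs tests on rating change from baseline
  for (tp in c("mid", "post", "followup")) {
    ch_c <- rs_g(completers)[[tp]] - rs_g(completers)$baseline
    ch_k <- rs_g(controls)[[tp]] - rs_g(controls)$baseline
    if (length(ch_c) > 0 && length(ch_k) > 0) {
      add(runs_test(ch_c, ch_k),
          paste0("adhd_rs_change_", tp), "completers_vs_controls")
    }
  }

  # within-group Friedman ANOVAs over the four timepoints
  for (instr in c("adhd_rs", "cgi")) {
    wide <- instrument_wide(a, instr)
    for (gname in names(groups)) {
      gw <- wide |> filter(.data$subject_id %in% groups[[gname]])
      if (nrow(gw) >= 2) {
        add(friedman_test(as.matrix(gw[, tp_levels()])),
            paste0(instr, "_timecourse"), gname)
      }
    }
  }

  # medication interaction with the primary outcome (completers)
  med <- subjects$medication[match(rs$subject_id, subjects$subject_id)]
  comp_idx <- rs$subject_id %in% completers
  if (sum(comp_idx & med) > 0 && sum(comp_idx & !med) > 0) {
    change_post <- rs$post[comp_idx] - rs$baseline[comp_idx]
    add(kruskal_wallis(split(change_post, med[comp_idx])),
        "adhd_rs_change_post_by_medication", "completers")
  }

  # within-group Wilcoxon baseline vs each later timepoint
  for (gname in names(groups)) {
    gw <- rs_g(groups[[gname]])
    if (nrow(gw) >= 2) {
      for (tp in c("mid", "post", "followup")) {
        add(wilcoxon_signed_rank(gw$baseline, gw[[tp]]),
            paste0("adhd_rs_baseline_vs_", tp), gname)
      }
    }
  }

  # cognitive change scores: Levene, mixed ANOVA, per-test pooled t-tests
  cog_instr <- c("cpt_sustained", "cpt_inhibition", "span_spatial",
                 "span_verbal", "stroop")
  have_cog <- all(cog_instr %in% a$instrument)
  effects <- list()
  if (have_cog && length(completers) >= 2 && length(controls) >= 2) {
    change <- purrr::map(cog_instr, function(instr) {
      w <- instrument_wide(a, instr, c("baseline", "post"))
      tibble(subject_id = w$subject_id, !!instr := w$post - w$baseline)
    }) |>
      purrr::reduce(inner_join, by = "subject_id")
    change <- change |>
      filter(.data$subject_id %in% c(completers, controls))
    arm <- ifelse(change$subject_id %in% completers, "training", "control")
    for (instr in cog_instr) {
      add(levene_test(split(change[[instr]], arm)),
          paste0(instr, "_change_variance"), "completers_vs_controls")
    }
    aov_res <- mixed_anova(change[, cog_instr], arm)
    for (k in seq_len(nrow(aov_res))) {
      rows[[length(rows) + 1]] <- tibble(
        test = paste0("cognitive_anova_", gsub(":", "_x_", aov_res$effect[k])),
        scope = "completers_vs_controls", kind = "anova",
        method = "mixed-design ANOVA on change scores",
        statistic = aov_res$statistic[k], df1 = aov_res$df1[k],
        df2 = aov_res$df2[k], p_value = aov_res$p_value[k],
        detail = "F_distribution"
      )
    }
    effects$cognitive_anova <- aov_res
    for (instr in cog_instr) {
      tt <- t.test(change[[instr]][arm == "training"],
                   change[[instr]][arm == "control"], var.equal = TRUE)
      rows[[length(rows) + 1]] <- tibble(
        test = paste0(instr, "_change"), scope = "completers_vs_controls",
        kind = "posthoc_t",
        method = "two-tailed pooled t-test",
        statistic = unname(tt$statistic), df1 = unname(tt$parameter),
        df2 = NA_real_, p_value = tt$p.value, detail = "t_distribution"
      )
    }
  }

  # effect sizes on the primary outcome change at post and follow-up
  for (tp in c("post", "followup")) {
    ch_c <- rs_g(completers)[[tp]] - rs_g(completers)$baseline
    ch_k <- rs_g(controls)[[tp]] - rs_g(controls)$baseline
    if (length(ch_c) >= 2 && length(ch_k) >= 2 &&
        (sd(ch_c) > 0 || sd(ch_k) > 0)) {
      es <- hedges_g(ch_k, ch_c) # positive g = larger improvement in training
      effects[[paste0("hedges_", tp)]] <- es
      rows[[length(rows) + 1]] <- tibble(
        test = paste0("adhd_rs_change_", tp, "_effect_size"),
        scope = "completers_vs_controls", kind = "effect_size",
        method = "Hedges' g (bias-corrected Cohen's d)",
        statistic = es$hedges_g, df1 = NA_real_, df2 = NA_real_,
        p_value = NA_real_, detail = "exact"
      )
    }
  }

  # distractor-suppression improvement vs symptom improvement (completers)
  if ("embedded_distractor" %in% a$instrument) {
    probe <- instrument_wide(a, "embedded_distractor", c("baseline", "post")) |>
      filter(.data$subject_id %in% completers)
    rs_c <- rs_g(completers)
    merged <- inner_join(
      tibble(subject_id = probe$subject_id,
             fp_change = probe$post - probe$baseline),
      tibble(subject_id = rs_c$subject_id,
             rs_change = rs_c$post - rs_c$baseline),
      by = "subject_id"
    )
    if (nrow(merged) >= 3 && sd(merged$fp_change) > 0 &&
        sd(merged$rs_change) > 0) {
      add(pearson_test(merged$fp_change, merged$rs_change),
          "distractor_fp_change_vs_adhd_rs_change", "completers")
      effects$fig5 <- merged
    }
  }

  # compliance diagnostic: training hours vs medication status (training arm)
  tr <- subjects |> filter(.data$arm == "training", .data$status != "dropout")
  if (nrow(tr) >= 3 && sd(tr$logged_hours) > 0 &&
      length(unique(tr$medication)) == 2) {
    add(pearson_test(tr$logged_hours, as.numeric(tr$medication)),
        "training_hours_vs_medication", "training_arm", kind = "interpretation")
  }

  report <- list_rbind(rows)
  if (holm) {
    idx <- report$kind %in% c("test", "anova", "posthoc_t") &
      !is.na(report$p_value)
    report$p_holm <- NA_real_
    report$p_holm[idx] <- stats::p.adjust(report$p_value[idx], "holm")
  }
  structure(
    list(report = report, effects = effects,
         group_sizes = lengths(groups), notes = unique(all_notes)),
    class = "trial_analysis"
  )
}

#' @export
print.trial_analysis <- function(x, ...) {
  gs <- x$group_sizes
  cat(sprintf("<trial_analysis> completers %d, controls %d, partials %d\n",
              gs[["completers"]], gs[["controls"]], gs[["partials"]]))
  rep <- x$report
  for (k in seq_len(nrow(rep))) {
    p <- if (is.na(rep$p_value[k])) "" else sprintf(", p = %.4g", rep$p_value[k])
    dfs <- if (is.na(rep$df1[k])) "" else if (is.na(rep$df2[k])) {
      sprintf("(%g) ", rep$df1[k])
    } else sprintf("(%g, %g) ", rep$df1[k], rep$df2[k])
    cat(sprintf("  %-45s %-24s %s= %.4g%s\n",
                rep$test[k], paste0("[", rep$scope[k], "]"), dfs,
                rep$statistic[k], p))
  }
  invisible(x)
}

#' Write a structured analysis report
#'
#' Serializes a [analyze_trial()] result as machine-readable JSON (one
#' object per test: name, scope, statistic, df, p, detail) next to a plain
#' text rendering.
#'
#' @param analysis A `trial_analysis`.
#' @param path Output path for the JSON report; the text rendering replaces
#'   the extension with `.txt`.
#' @return `path`, invisibly.
#' @export
write_report <- function(analysis, path) {
  stopifnot(inherits(analysis, "trial_analysis"))
  jsonlite::write_json(
    list(
      group_sizes = as.list(analysis$group_sizes),
      tests = analysis$report,
      notes = analysis$notes
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
  )
  txt <- sub("\\.[^.]*$", ".txt", path)
  sink(txt); on.exit(sink(), add = TRUE)
  print(analysis)
  invisible(path)
}
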