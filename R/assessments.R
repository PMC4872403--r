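#' Signal-detection sensitivity (d-prime)
#'
#' Computes \eqn{d' = z(\mathrm{hit\ rate}) - z(\mathrm{false\ alarm\ rate})}
#' with the standard normal quantile. By default the log-linear correction
#' (add 0.5 to each cell count, 1 to each denominator) is applied so that
#' perfect or zero rates yield finite values.
#'
#' @param hits,false_alarms Counts of hits and false alarms.
#' @param n_targets,n_nontargets Total target and non-target trials.
#' @param correction `"loglinear"` (default) or `"none"`.
#' @return The sensitivity index, vectorized over its arguments.
#' @examples
#' compute_dprime(90, 10, 100, 100) # ~ 2.51 after correction
#' compute_dprime(100, 0, 100, 100) # finite under the log-linear correction
#' @export
compute_dprime <- function(hits, false_alarms, n_targets, n_nontargets,
                           correction = c("loglinear", "none")) {
  correction <- match.arg(correction)
  if (any(c(hits, false_alarms, n_targets, n_nontargets) < 0)) {
    abort("Counts must be non-negative.")
  }
  if (any(hits > n_targets) || any(false_alarms > n_nontargets)) {
    abort("Counts cannot exceed their trial totals.")
  }
  if (correction == "loglinear") {
    hr <- (hits + 0.5) / (n_targets + 1)
    fr <- (false_alarms + 0.5) / (n_nontargets + 1)
  } else {
    hr <- hits / n_targets
    fr <- false_alarms / n_nontargets
  }
  qnorm(hr) - qnorm(fr)
}

#' Configuration of the continuous performance test
#'
#' The test has two 10-minute halves of 200 trials at 3 s each: a
#' sustained-attention half with rare targets (22.5% of trials, i.e. exactly
#' 45 of 200) and a response-inhibition half with frequent targets (77.5%,
#' exactly 155 of 200). `challenge` is the fixed assessment difficulty on
#' the unit axis.
#'
#' @param n_trials Trials per half.
#' @param trial_seconds Seconds per trial.
#' @param challenge Fixed assessment challenge.
#' @return A list of class `cpt_config`.
#' @export
cpt_config <- function(n_trials = 200, trial_seconds = 3, challenge = 0.2) {
  structure(list(n_trials = as.integer(n_trials),
                 trial_seconds = trial_seconds,
                 challenge = challenge,
                 target_fraction = c(sustained_attention = 0.225,
                                     response_inhibition = 0.775)),
            class = "cpt_config")
}

#' Run one half of the continuous performance test on a virtual subject
#'
#' Generates a stratified trial sequence with the exact printed target
#' prevalence (22.5% in the sustained-attention half, 77.5% in the
#' response-inhibition half), draws hits from the subject's
#' `signal_sensitivity` trait and false alarms from the `inhibition` trait,
#' and scores d-prime with the log-linear correction.
#'
#' If `n_trials * target_fraction` is not an integer, the trial count is
#' adjusted to the nearest count that makes it integral (with a warning),
#' so the realized prevalence stays exact.
#'
#' @param subject One cohort row.
#' @param phase `"sustained_attention"` or `"response_inhibition"`.
#' @param config A [cpt_config()].
#' @param seed Optional seed.
#' @param p_hit,p_fa Optional probability overrides for the hit and
#'   false-alarm processes (used e.g. for a deterministic ceiling observer).
#' @param cohort_cfg The generating [cohort_config()] (psychometric scale).
#' @return A one-row tibble of class `cpt_result`: `phase`, `n_targets`,
#'   `n_nontargets`, `hits`, `misses`, `false_alarms`, `correct_rejections`,
#'   `d_prime`.
#' @export
run_cpt <- function(subject, phase = c("sustained_attention",
                                       "response_inhibition"),
                    config = cpt_config(), seed = NULL,
                    p_hit = NULL, p_fa = NULL,
                    cohort_cfg = cohort_config()) {
  phase <- match.arg(phase)
  frac <- config$target_fraction[[phase]]
  n <- config$n_trials
  if (abs(n * frac - round(n * frac)) > 1e-9) {
    # smallest adjustment that makes the target count integral (frac = k/40)
    n_adj <- round(n * frac) / frac
    if (abs(n_adj - round(n_adj)) > 1e-9) n_adj <- 40 * round(n / 40)
    warn(sprintf(
      "%d trials cannot realize a %.1f%% target prevalence exactly; using %d.",
      n, 100 * frac, as.integer(round(n_adj))))
    n <- as.integer(round(n_adj))
  }
  n_targets <- as.integer(round(n * frac))
  n_nontargets <- n - n_targets
  if (is.null(p_hit)) {
    p_hit <- 0.5 * subject$lapse_rate +
      (1 - subject$lapse_rate) *
        plogis((subject$signal_sensitivity - config$challenge) / cohort_cfg$sigma)
  }
  if (is.null(p_fa)) {
    p_fa <- 0.5 * subject$lapse_rate +
      (1 - subject$lapse_rate) *
        (1 - plogis((subject$inhibition - config$challenge) / cohort_cfg$sigma))
  }
  counts <- with_seed_(seed, {
    c(hits = rbinom(1, n_targets, p_hit),
      fa = rbinom(1, n_nontargets, p_fa))
  })
  out <- tibble(
    phase = phase,
    n_targets = n_targets,
    n_nontargets = n_nontargets,
    hits = as.integer(counts[["hits"]]),
    misses = n_targets - as.integer(counts[["hits"]]),
    false_alarms = as.integer(counts[["fa"]]),
    correct_rejections = n_nontargets - as.integer(counts[["fa"]]),
    d_prime = compute_dprime(counts[["hits"]], counts[["fa"]],
                             n_targets, n_nontargets)
  )
  class(out) <- c("cpt_result", class(out))
  out
}

#' Configuration of the short-term memory span tasks
#'
#' Spatial spans use loads of 1, 3, 5 and 7 items; verbal spans 3, 5, 7 and
#' 9. Twelve trials per load, half of them match probes (exact 50% match
#' prevalence by construction). The performance metric is the mean response
#' speed over the two highest loads; response times follow
#' `base + load_slope * load / (0.5 + trait) + noise`.
#'
#' @param trials_per_load Trials per span load (even, half match).
#' @param base_seconds Intercept of the response-time model.
#' @param load_slope Seconds added per item at trait 0.5.
#' @param rt_noise_sd Response-time noise sd in seconds.
#' @param p_correct Fixed probe accuracy (held stable across timepoints by
#'   construction; speed is the moving metric).
#' @return A list of class `span_config`.
#' @export
span_config <- function(trials_per_load = 12, base_seconds = 0.4,
                        load_slope = 0.05, rt_noise_sd = 0.15,
                        p_correct = 0.85) {
  structure(list(trials_per_load = as.integer(trials_per_load),
                 base_seconds = base_seconds, load_slope = load_slope,
                 rt_noise_sd = rt_noise_sd, p_correct = p_correct,
                 loads = list(spatial = c(1, 3, 5, 7),
                              verbal = c(3, 5, 7, 9))),
            class = "span_config")
}

#' Run a span task on a virtual subject
#'
#' @param subject One cohort row (speed is driven by `signal_sensitivity`).
#' @param domain `"spatial"` or `"verbal"`.
#' @param config A [span_config()].
#' @param seed Optional seed.
#' @return A list of class `span_result`: `trials` (tibble with `load`,
#'   `match`, `response_seconds`, `correct`), `high_load_speed` (mean
#'   seconds over the two highest loads), `accuracy`, and `match_fraction`.
#' @export
run_span <- function(subject, domain = c("spatial", "verbal"),
                     config = span_config(), seed = NULL) {
  domain <- match.arg(domain)
  loads <- config$loads[[domain]]
  k <- config$trials_per_load
  trait <- subject$signal_sensitivity
  per_load <- rep(loads, each = k)
  match <- rep(c(rep(TRUE, k / 2), rep(FALSE, k - k / 2)), times = length(loads))
  trials <- with_seed_(seed, {
    ord <- sample(length(per_load))
    rt <- config$base_seconds +
      config$load_slope * per_load / (0.5 + trait) +
      rnorm(length(per_load), 0, config$rt_noise_sd)
    tibble(load = per_load[ord], match = match[ord],
           response_seconds = pmax(rt[ord], 0.05),
           correct = runif(length(per_load)) < config$p_correct)
  })
  hi <- sort(loads, decreasing = TRUE)[1:2]
  structure(
    list(trials = trials,
         domain = domain,
         high_load_speed = mean(trials$response_seconds[trials$load %in% hi]),
         accuracy = mean(trials$correct),
         match_fraction = mean(trials$match)),
    class = "span_result"
  )
}

#' Stroop interference score
#'
#' The paper-and-pencil Stroop test presents three 100-stimulus sheets (word,
#' color, color--word), 45 s each. The interference score is the number of
#' correctly reported items on the color--word sheet minus that on the color
#' sheet; it is typically negative and its magnitude measures interference.
#'
#' @param word_correct,color_correct,colorword_correct Correct counts per
#'   sheet, each in `[0, 100]`.
#' @return The interference score `colorword_correct - color_correct`.
#' @examples
#' score_stroop(80, 70, 45) # -25
#' @export
score_stroop <- function(word_correct, color_correct, colorword_correct) {
  counts <- c(word_correct, color_correct, colorword_correct)
  if (any(counts < 0) || any(counts > 100)) {
    abort("Each sheet has 100 stimuli; correct counts must lie in [0, 100].")
  }
  colorword_correct - color_correct
}

#' Simulate Stroop sheet counts for a virtual subject
#'
#' Counts per 45-second sheet are modeled at the sheet level: reading and
#' color naming scale with `signal_sensitivity`, and the color--word deficit
#' shrinks as the `inhibition` trait grows. All counts are capped at the 100
#' stimuli on each sheet.
#'
#' @param subject One cohort row.
#' @param seed Optional seed.
#' @return A one-row tibble: `word_correct`, `color_correct`,
#'   `colorword_correct`, `interference`.
#' @export
simulate_stroop <- function(subject, seed = NULL) {
  with_seed_(seed, {
    word <- round(70 + 20 * subject$signal_sensitivity + rnorm(1, 0, 3))
    color <- round(55 + 20 * subject$signal_sensitivity + rnorm(1, 0, 3))
    deficit <- 25 * (1.2 - subject$inhibition) + rnorm(1, 0, 3)
    colorword <- round(color - pmax(deficit, 0))
    word <- clamp(word, 0, 100); color <- clamp(color, 0, 100)
    colorword <- clamp(colorword, 0, color)
    tibble(word_correct = word, color_correct = color,
           colorword_correct = colorword,
           interference = score_stroop(word, color, colorword))
  })
}

#' SWAN screening classification
#'
#' Classifies per-item mean scores against the screening cutoffs: strictly
#' greater than 2.11 for combined type, 2.48 for inattentive type and 2.00
#' for hyperactive type. A score exactly at a cutoff is screen-negative.
#'
#' @param combined,inattentive,hyperactive Mean item scores per subtype.
#' @return A tibble with `subtype`, `score`, `cutoff`, `positive`; the
#'   attribute `"screen_positive"` is `TRUE` if any subtype exceeds its
#'   cutoff.
#' @examples
#' swan_screen(combined = 2.12)
#' @export
swan_screen <- function(combined = NA_real_, inattentive = NA_real_,
                        hyperactive = NA_real_) {
  cutoffs <- c(combined = 2.11, inattentive = 2.48, hyperactive = 2.00)
  scores <- c(combined = combined, inattentive = inattentive,
              hyperactive = hyperactive)
  out <- tibble(
    subtype = names(cutoffs),
    score = unname(scores),
    cutoff = unname(cutoffs),
    positive = !is.na(scores) & scores > cutoffs
  )
  attr(out, "screen_positive") <- any(out$positive)
  out
}

#' Configuration of the embedded distractor-suppression probe
#'
#' A fixed-challenge (non-adaptive) distractor block embedded in the training
#' program at the beginning and end of the 30-hour dose. Half the trials are
#' distractor trials; the probe's outcome is the count of false-positive
#' responses to distractors. The false-positive probability falls linearly
#' to zero as the distractor-suppression trait reaches ceiling:
#' `lapse + (1 - lapse) * (1 - trait) * challenge`.
#'
#' @param n_trials Probe length (half are distractor trials).
#' @param challenge Fixed probe challenge.
#' @return A list of class `probe_config`.
#' @export
probe_config <- function(n_trials = 200, challenge = 0.5) {
  structure(list(n_trials = as.integer(n_trials), challenge = challenge),
            class = "probe_config")
}

#' Run the embedded distractor probe on a virtual subject
#'
#' @param subject One or more cohort rows (their current
#'   `distractor_suppression` traits).
#' @param when `"start"` or `"end"` of the training period (bookkeeping
#'   label).
#' @param config A [probe_config()].
#' @param seed Optional seed.
#' @return A tibble with one row per subject: `subject_id`, `when`,
#'   `n_distractor_trials`, `false_positives`.
#' @export
distractor_probe <- function(subject, when = c("start", "end"),
                             config = probe_config(), seed = NULL) {
  when <- match.arg(when)
  n_d <- config$n_trials %/% 2
  p_fp <- subject$lapse_rate +
    (1 - subject$lapse_rate) * (1 - subject$distractor_suppression) *
      config$challenge
  fp <- with_seed_(seed, rbinom(nrow(subject), n_d, p_fp))
  tibble(subject_id = subject$subject_id, when = when,
         n_distractor_trials = n_d, false_positives = as.integer(fp))
}

assessment_schedule <- function() {
  list(
    adhd_rs = c("baseline", "mid", "post", "followup"),
    cgi = c("baseline", "mid", "post", "followup"),
    cpt_sustained = c("baseline", "post"),
    cpt_inhibition = c("baseline", "post"),
    span_spatial = c("baseline", "post"),
    span_verbal = c("baseline", "post"),
    stroop = c("baseline", "post"),
    embedded_distractor = c("baseline", "post")
  )
}

#' Validate a long assessment table
#'
#' Checks the schema (`subject_id`, `timepoint`, `instrument`, `value`),
#' the timepoint labels, the instrument names, the per-instrument timepoint
#' schedule (rating scales at all four timepoints; cognitive instruments and
#' the embedded distractor probe only at baseline/post), and instrument
#' ranges (ratings in 0--54, clinician severity in 1--7).
#'
#' @param assessments A data frame in the long assessment format.
#' @return The validated tibble, invisibly; aborts with an itemized message
#'   otherwise.
#' @export
validate_assessments <- function(assessments) {
  problems <- character()
  req <- c("subject_id", "timepoint", "instrument", "value")
  missing_cols <- setdiff(req, names(assessments))
  if (length(missing_cols) > 0) {
    abort(paste0("Assessment table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  sched <- assessment_schedule()
  bad_tp <- setdiff(unique(assessments$timepoint),
                    c("baseline", "mid", "post", "followup"))
  if (length(bad_tp) > 0) {
    problems <- c(problems, paste0("unknown timepoint(s): ",
                                   paste(bad_tp, collapse = ", ")))
  }
  bad_instr <- setdiff(unique(assessments$instrument), names(sched))
  if (length(bad_instr) > 0) {
    problems <- c(problems, paste0("unknown instrument(s): ",
                                   paste(bad_instr, collapse = ", ")))
  }
  for (instr in intersect(unique(assessments$instrument), names(sched))) {
    tps <- unique(assessments$timepoint[assessments$instrument == instr])
    off <- setdiff(tps, sched[[instr]])
    if (length(off) > 0) {
      problems <- c(problems, sprintf("%s measured at disallowed timepoint(s): %s",
                                      instr, paste(off, collapse = ", ")))
    }
  }
  rs <- assessments$value[assessments$instrument == "adhd_rs"]
  if (length(rs) > 0 && (any(rs < 0) || any(rs > 54))) {
    problems <- c(problems, "adhd_rs values outside [0, 54]")
  }
  cgi <- assessments$value[assessments$instrument == "cgi"]
  if (length(cgi) > 0 && (any(cgi < 1) || any(cgi > 7) ||
                          any(cgi != round(cgi)))) {
    problems <- c(problems, "cgi values outside the ordinal 1..7 scale")
  }
  if (length(problems) > 0) {
    abort(paste0("Invalid assessment table:\n",
                 paste0("- ", problems, collapse = "\n")))
  }
  invisible(as_tibble(assessments))
}
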