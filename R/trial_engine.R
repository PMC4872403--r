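#' Design of the in-silico randomized controlled trial
#'
#' Two arms (adaptive training vs active-control games) allocated 2:1 in
#' blocks of eight with medication-stratified balance; a dose of 30 hours as
#' 60 half-hour sessions, 3--5 sessions per week, within 24 weeks; ratings at
#' four timepoints (baseline, mid at 3 months, post at 6 months, follow-up
#' at 12 months with no intervention access after post); cognitive
#' instruments at baseline and post only.
#'
#' @param allocation_ratio `c(training, control)` allocation weights.
#' @param block_size Randomization block size.
#' @param dose_hours Assigned intervention dose in hours.
#' @param n_sessions Number of sessions realizing the dose.
#' @param session_minutes Session window in minutes.
#' @param max_weeks Maximum intervention calendar length.
#' @param sessions_per_week Range `c(min, max)` of sessions per week.
#' @return A list of class `trial_design`.
#' @export
trial_design <- function(allocation_ratio = c(2, 1), block_size = 8,
                         dose_hours = 30, n_sessions = 60,
                         session_minutes = 30, max_weeks = 24,
                         sessions_per_week = c(3, 5)) {
  if (length(allocation_ratio) != 2 || any(allocation_ratio <= 0)) {
    abort("`allocation_ratio` must be two positive weights.")
  }
  if (block_size < 2) abort("`block_size` must be >= 2.")
  structure(
    list(allocation_ratio = as.numeric(allocation_ratio),
         block_size = as.integer(block_size),
         dose_hours = dose_hours, n_sessions = as.integer(n_sessions),
         session_minutes = session_minutes, max_weeks = max_weeks,
         sessions_per_week = as.integer(sessions_per_week),
         timepoints = c(baseline = 0, mid = 3, post = 6, followup = 12)),
    class = "trial_design"
  )
}

#' Blocked, medication-stratified 2:1 randomization
#'
#' Assigns arms within sequential blocks of `block_size` subjects. The
#' per-block training-arm count is chosen greedily so the cumulative
#' allocation tracks the 2:1 target (for blocks of eight this alternates
#' 5:3 and 6:2 splits); a final short block is split proportionally. Within
#' each block, medicated and unmedicated subjects are allocated to arms in
#' proportion (pseudo-randomization of medication status); if a block's
#' stratification is infeasible the block falls back to unstratified
#' assignment with a warning.
#'
#' @param cohort A cohort tibble ([generate_cohort()]).
#' @param design A [trial_design()].
#' @param seed Integer seed; the assignment is reproducible.
#' @return A tibble `subject_id`, `block`, `arm` (`"training"` /
#'   `"control"`).
#' @export
randomize_arms <- function(cohort, design = trial_design(), seed = 1) {
  if (nrow(cohort) == 0) abort("Cohort must be nonempty.")
  n <- nrow(cohort)
  bs <- design$block_size
  w <- design$allocation_ratio / sum(design$allocation_ratio)
  blocks <- split(seq_len(n), ceiling(seq_len(n) / bs))
  with_seed_(seed, {
    arm <- character(n)
    cum_n <- 0; cum_t <- 0
    cum_med <- 0; cum_med_t <- 0
    for (b in seq_along(blocks)) {
      idx <- blocks[[b]]
      nb <- length(idx)
      # training count keeping the cumulative allocation nearest the target
      k <- round(w[1] * (cum_n + nb) - cum_t)
      k <- max(0, min(nb, k))
      med <- cohort$medication[idx]
      # medicated share tracked greedily across blocks so the training arm's
      # medicated proportion follows the cohort's
      target_med_t <- (cum_t + k) * (cum_med + sum(med)) / (cum_n + nb)
      k_med <- round(target_med_t - cum_med_t)
      k_med <- max(max(0, k - sum(!med)), min(c(sum(med), k), k_med))
      k_unmed <- k - k_med
      if (k_unmed < 0 || k_unmed > sum(!med)) {
        warn(sprintf("Block %d: medication stratification infeasible; %s",
                     b, "assigning unstratified."))
        chosen <- idx[sample.int(nb, k)]
        k_med <- sum(cohort$medication[chosen])
      } else {
        chosen <- c(idx[med][sample.int(sum(med), k_med)],
                    idx[!med][sample.int(sum(!med), k_unmed)])
      }
      arm[idx] <- "control"
      arm[chosen] <- "training"
      cum_n <- cum_n + nb; cum_t <- cum_t + k
      cum_med <- cum_med + sum(med); cum_med_t <- cum_med_t + k_med
    }
    tibble(subject_id = cohort$subject_id,
           block = ceiling(seq_len(n) / bs),
           arm = arm)
  })
}

# minutes per trait in one session when scheduling is bypassed: the session
# window split across the registry's category proportions (8+8+8+1 of 25)
aggregate_trait_minutes <- function(session_minutes = 30) {
  per_cat <- session_minutes * c(attended_signal = 8, explicit_distractor = 8,
                                 implicit_distractor = 8,
                                 response_inhibition = 1) / 25
  c(signal_sensitivity = unname(per_cat["attended_signal"]),
    distractor_suppression = unname(per_cat["explicit_distractor"] +
                                      per_cat["implicit_distractor"]),
    inhibition = unname(per_cat["response_inhibition"]))
}

# simulate one adaptive exercise block for a subject, returning the response
# log and the updated staircase state; plain loops kept lean on purpose
run_exercise_block <- function(subject, spec, state, config) {
  n <- spec$trials_per_block
  trait <- subject[[category_trait(spec$category)]]
  go_no_go <- spec$category == "response_inhibition"
  guess <- if (go_no_go) 0 else config$guess
  challenge <- numeric(n); correct <- logical(n)
  for (i in seq_len(n)) {
    challenge[i] <- state$challenge
    p <- respond_probability(trait, state$challenge, subject$lapse_rate,
                             guess = guess, sigma = config$sigma)
    correct[i] <- runif(1) < p
    state <- update_staircase(state, correct[i], record = FALSE)
  }
  trials <- generate_trials(spec, challenge = challenge, n = n)
  trials$correct <- correct
  if (go_no_go) {
    trials$response <- ifelse(trials$target_present,
                              ifelse(correct, "withhold", "go"),
                              ifelse(correct, "go", "withhold"))
    trials$is_false_positive <- trials$target_present & !correct
  } else {
    trials$response <- ifelse(trials$target_present,
                              ifelse(correct, "yes", "no"),
                              ifelse(correct, "no", "yes"))
    trials$is_false_positive <- !trials$target_present & !correct
  }
  list(trials = trials, state = state)
}

#' Run the full in-silico trial
#'
#' Orchestrates one complete randomized controlled trial on a virtual
#' cohort: blocked stratified randomization, post-baseline dropout draws,
#' partial-compliance draws for the training arm (target hours from the
#' 1--13 h partial range), week-by-week training through the exercise
#' scheduler with saturating trait learning, embedded distractor probes at
#' the start and end of training, and the scheduled assessment battery.
#' Arm labels never enter any assessment computation; assessments depend on
#' the subject's traits alone.
#'
#' @param cohort A cohort from [generate_cohort()] (its `cohort_config` is
#'   carried as an attribute).
#' @param design A [trial_design()].
#' @param seed Integer master seed; every stage derives its own substream.
#' @param granularity `"session"` (default) logs training at the session
#'   level and drives learning through the exercise scheduler; `"trial"`
#'   additionally simulates every adaptive trial and returns the trial log;
#'   `"aggregate"` bypasses the scheduler, splitting each session across
#'   categories in registry proportion (fast path for replicate studies).
#' @param registry The exercise registry.
#' @param include Character subset of `c("ratings", "cognitive", "probes")`
#'   selecting which assessment families to simulate.
#' @param probe_cfg,cpt_cfg,span_cfg Assessment configurations.
#' @return An object of class `trial_dataset`: a list with tibbles
#'   `subjects` (cohort plus `arm`, `status`, `target_hours`,
#'   `logged_hours`), `training` (session log), `trials` (trial log or
#'   `NULL`), `assessments` (long table), plus the `design`, `config`,
#'   `seed` and a reproducibility `manifest`.
#' @examples
#' ds <- run_trial(generate_cohort(cohort_config(), seed = 1), seed = 1)
#' dplyr::count(ds$subjects, arm, status)
#' @export
run_trial <- function(cohort, design = trial_design(), seed = 1,
                      granularity = c("session", "trial", "aggregate"),
                      registry = build_registry(),
                      include = c("ratings", "cognitive", "probes"),
                      probe_cfg = probe_config(), cpt_cfg = cpt_config(),
                      span_cfg = span_config()) {
  granularity <- match.arg(granularity)
  include <- match.arg(include, several.ok = TRUE)
  config <- attr(cohort, "config") %||% cohort_config()
  n <- nrow(cohort)

  assignments <- randomize_arms(cohort, design, seed = derive_seed(seed, "randomize"))
  subjects <- left_join(cohort, assignments, by = "subject_id")

  # dropout after baseline, before any intervention exposure
  dropped <- with_seed_(derive_seed(seed, "dropout"),
                        runif(n) < config$dropout_probability)

  # compliance: training-arm subjects may train only partially
  subjects$target_hours <- design$dose_hours
  partial <- with_seed_(derive_seed(seed, "compliance"), {
    is_partial <- subjects$arm == "training" & !dropped &
      subjects$compliance_propensity < config$partial_compliance_fraction
    hrs <- clamp(rnorm(n, 4.5, 3.6), 1, 13)
    list(flag = is_partial, hours = hrs)
  })
  subjects$target_hours[partial$flag] <- round(partial$hours[partial$flag] * 2) / 2
  subjects$target_hours[dropped] <- 0

  spw <- with_seed_(derive_seed(seed, "calendar"),
                    sample(seq(design$sessions_per_week[1],
                               design$sessions_per_week[2]), n, replace = TRUE))

  # per-subject training execution
  traits_mid <- traits_post <- cohort[, trait_names()]
  training_log <- vector("list", n)
  trial_log <- if (granularity == "trial") vector("list", n) else NULL
  logged_hours <- numeric(n)
  train_seed <- derive_seed(seed, "training")
  mid_week <- design$max_weeks / 2

  for (i in seq_len(n)) {
    subj <- subjects[i, ]
    n_sess <- min(design$n_sessions,
                  floor(subj$target_hours * 60 / design$session_minutes))
    if (n_sess == 0) next
    weeks <- ceiling(seq_len(n_sess) / spw[i])
    slot <- (seq_len(n_sess) - 1) %% spw[i]
    start_hour <- (weeks - 1) * 168 + slot * 48 + 17
    is_training_arm <- subj$arm == "training"
    sessions <- tibble(
      subject_id = subj$subject_id, session_index = seq_len(n_sess),
      week = weeks, start_hour = start_hour,
      minutes = design$session_minutes
    )
    if (is_training_arm && granularity != "aggregate") {
      progress <- tibble(exercise_id = registry$exercise_id,
                         minutes_trained = 0)
      stair <- setNames(vector("list", nrow(registry)), registry$exercise_id)
      sess_trials <- if (granularity == "trial") vector("list", n_sess) else NULL
      mid_snapshot <- FALSE
      with_seed_(derive_seed(train_seed, subj$subject_id), {
        for (s in seq_len(n_sess)) {
          sched <- schedule_session(progress, registry,
                                    session_minutes = design$session_minutes)
          if (granularity == "trial") {
            blocks <- vector("list", nrow(sched))
            for (j in seq_len(nrow(sched))) {
              spec <- as.list(sched[j, ])
              st <- stair[[spec$exercise_id]] %||% staircase_state()
              st$step <- staircase_state()$step # step resets per session
              res <- run_exercise_block(subj, spec, st, config)
              stair[[spec$exercise_id]] <- res$state
              blocks[[j]] <- res$trials |>
                mutate(subject_id = subj$subject_id, session_index = s,
                       .before = 1)
            }
            sess_trials[[s]] <- list_rbind(blocks)
          }
          subj <- apply_learning(subj, sched)
          progress$minutes_trained <-
            progress$minutes_trained +
            vapply(progress$exercise_id, function(id) {
              sum(sched$duration_minutes[sched$exercise_id == id])
            }, numeric(1))
          if (!mid_snapshot && weeks[s] > mid_week) {
            traits_mid[i, ] <- subj[, trait_names()]
            mid_snapshot <- TRUE
          }
        }
      })
      if (!mid_snapshot) traits_mid[i, ] <- subj[, trait_names()]
      traits_post[i, ] <- subj[, trait_names()]
      if (granularity == "trial") trial_log[[i]] <- list_rbind(sess_trials)
    } else {
      # aggregate learning path (training arm fast path, or control drift)
      mbt <- aggregate_trait_minutes(design$session_minutes)
      rates <- vapply(trait_names(),
                      function(tr) subj[[paste0("lr_", tr)]], numeric(1))
      if (!is_training_arm) {
        # control game play does not target the trained traits; any placebo
        # drift enters through control_learning_rate
        rates <- rep(config$control_learning_rate, length(rates))
      }
      k_mid <- sum(weeks <= mid_week)
      for (tr in trait_names()) {
        t0 <- cohort[[tr]][i]
        r <- rates[[match(tr, trait_names())]]
        traits_mid[i, tr] <- learning_trajectory(t0, r, mbt[[tr]], k_mid)
        traits_post[i, tr] <- learning_trajectory(t0, r, mbt[[tr]], n_sess)
      }
    }
    training_log[[i]] <- sessions
    logged_hours[i] <- n_sess * design$session_minutes / 60
  }

  subjects$logged_hours <- logged_hours
  subjects$status <- case_when(
    dropped ~ "dropout",
    logged_hours >= design$dose_hours ~ "completer",
    logged_hours > 0 ~ "partial",
    .default = "dropout"
  )

  # assessment battery; note: arm labels are never consulted here, only the
  # subject's traits at each timepoint
  snapshots <- list(baseline = cohort[, trait_names()],
                    mid = traits_mid, post = traits_post,
                    followup = traits_post)
  assess <- list()
  as_seed <- derive_seed(seed, "assessments")
  if ("ratings" %in% include) {
    rows <- list()
    for (tp in names(snapshots)) {
      live <- if (tp == "baseline") rep(TRUE, n) else subjects$status != "dropout"
      sub_tp <- subjects
      sub_tp[, trait_names()] <- snapshots[[tp]]
      rs <- emit_symptom_rating(sub_tp, config,
                                seed = derive_seed(as_seed, paste0("rs_", tp)))
      cg <- emit_cgi(sub_tp, config,
                     seed = derive_seed(as_seed, paste0("cgi_", tp)))
      rows[[tp]] <- bind_rows(
        tibble(subject_id = subjects$subject_id[live], timepoint = tp,
               instrument = "adhd_rs", value = as.numeric(rs[live])),
        tibble(subject_id = subjects$subject_id[live], timepoint = tp,
               instrument = "cgi", value = as.numeric(cg[live]))
      )
    }
    assess$ratings <- list_rbind(rows)
  }
  if ("cognitive" %in% include) {
    rows <- list()
    for (tp in c("baseline", "post")) {
      live <- if (tp == "baseline") rep(TRUE, n) else subjects$status != "dropout"
      sub_tp <- subjects
      sub_tp[, trait_names()] <- snapshots[[tp]]
      for (i in which(live)) {
        sj <- sub_tp[i, ]
        sd_seed <- derive_seed(as_seed, paste0("cog_", tp, "_", sj$subject_id))
        cpt_s <- run_cpt(sj, "sustained_attention", cpt_cfg,
                         seed = derive_seed(sd_seed, "cpt_s"),
                         cohort_cfg = config)
        cpt_i <- run_cpt(sj, "response_inhibition", cpt_cfg,
                         seed = derive_seed(sd_seed, "cpt_i"),
                         cohort_cfg = config)
        sp_s <- run_span(sj, "spatial", span_cfg,
                         seed = derive_seed(sd_seed, "span_s"))
        sp_v <- run_span(sj, "verbal", span_cfg,
                         seed = derive_seed(sd_seed, "span_v"))
        str <- simulate_stroop(sj, seed = derive_seed(sd_seed, "stroop"))
        rows[[length(rows) + 1]] <- tibble(
          subject_id = sj$subject_id, timepoint = tp,
          instrument = c("cpt_sustained", "cpt_inhibition", "span_spatial",
                         "span_verbal", "stroop"),
          value = c(cpt_s$d_prime, cpt_i$d_prime, sp_s$high_load_speed,
                    sp_v$high_load_speed, str$interference)
        )
      }
    }
    assess$cognitive <- list_rbind(rows)
  }
  if ("probes" %in% include) {
    trained <- subjects$arm == "training" & subjects$status != "dropout"
    if (any(trained)) {
      sub_start <- subjects[trained, ]
      sub_start[, trait_names()] <- snapshots$baseline[trained, ]
      sub_end <- subjects[trained, ]
      sub_end[, trait_names()] <- snapshots$post[trained, ]
      pr_start <- distractor_probe(sub_start, "start", probe_cfg,
                                   seed = derive_seed(as_seed, "probe_start"))
      pr_end <- distractor_probe(sub_end, "end", probe_cfg,
                                 seed = derive_seed(as_seed, "probe_end"))
      assess$probes <- bind_rows(
        tibble(subject_id = pr_start$subject_id, timepoint = "baseline",
               instrument = "embedded_distractor",
               value = as.numeric(pr_start$false_positives)),
        tibble(subject_id = pr_end$subject_id, timepoint = "post",
               instrument = "embedded_distractor",
               value = as.numeric(pr_end$false_positives))
      )
    }
  }
  assessments <- list_rbind(assess)
  validate_assessments(assessments)

  structure(
    list(
      subjects = subjects,
      training = list_rbind(training_log) %||%
        tibble(subject_id = character(), session_index = integer(),
               week = integer(), start_hour = numeric(), minutes = numeric()),
      trials = if (granularity == "trial") list_rbind(trial_log) else NULL,
      assessments = assessments,
      design = design,
      config = config,
      seed = seed,
      granularity = granularity,
      manifest = build_manifest(config, design, seed, granularity)
    ),
    class = "trial_dataset"
  )
}

#' @export
print.trial_dataset <- function(x, ...) {
  tab <- table(x$subjects$arm, x$subjects$status)
  cat(sprintf("<trial_dataset> %d subjects, seed %s, granularity '%s'\n",
              nrow(x$subjects), format(x$seed), x$granularity))
  print(tab)
  cat(sprintf("  training sessions: %d; assessment rows: %d\n",
              nrow(x$training), nrow(x$assessments)))
  invisible(x)
}
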