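#' Build the 25-exercise training registry
#'
#' The program comprises 25 exercises: eight attended-signal, eight
#' explicit-distractor and eight implicit-distractor modules (four visual and
#' four auditory each, climbing a four-tier stimulus-complexity ladder), plus
#' one visual go/no-go response-inhibition exercise with complex face/scene
#' images. Visual ladders run Gabor patches, colored shapes/textures, motion,
#' scenes; auditory ladders run tones, frequency sweeps, phonemes, words.
#' The single response-inhibition exercise forms its own one-exercise chain
#' and carries tier 1 so it is available from the start.
#'
#' @param trials_per_block Trials presented per 3--5 minute exercise block.
#' @return A tibble of 25 rows: `exercise_id`, `category`, `modality`,
#'   `tier`, `stimulus_family`, `response_format`, `duration_min`,
#'   `duration_max`, `trials_per_block`. Construction is deterministic.
#' @examples
#' dplyr::count(build_registry(), category)
#' @export
build_registry <- function(trials_per_block = 40) {
  assert_scalar_num(trials_per_block, "trials_per_block", lo = 1)
  fam <- list(
    visual = c("gabor", "shapes_textures", "motion", "scenes"),
    auditory = c("tones", "sweeps", "phonemes", "words")
  )
  abbr <- c(attended_signal = "as", explicit_distractor = "ed",
            implicit_distractor = "id")
  core <- tidyr::expand_grid(
    category = names(abbr),
    modality = c("visual", "auditory"),
    tier = 1:4
  ) |>
    mutate(
      exercise_id = sprintf("%s_%s_%d", abbr[.data$category],
                            substr(.data$modality, 1, 3), .data$tier),
      stimulus_family = purrr::map2_chr(.data$modality, .data$tier,
                                        function(m, t) fam[[m]][t]),
      response_format = "two_afc_yes_no"
    )
  ri <- tibble(
    category = "response_inhibition", modality = "visual", tier = 1L,
    exercise_id = "ri_vis_1", stimulus_family = "faces_scenes",
    response_format = "go_no_go"
  )
  bind_rows(core, ri) |>
    mutate(duration_min = 3, duration_max = 5,
           trials_per_block = as.integer(trials_per_block)) |>
    select("exercise_id", "category", "modality", "tier", "stimulus_family",
           "response_format", "duration_min", "duration_max",
           "trials_per_block") |>
    arrange(.data$category, .data$modality, .data$tier)
}

#' Generate training trials for one exercise block
#'
#' Emits the stimulus side of a block of trials at a given challenge level:
#' target presence is stratified so that exactly half the trials contain a
#' target (the two-alternative forced-choice default), stimulus parameters
#' come from [challenge_to_stimulus()], and the distractor kind follows the
#' exercise category (explicit-distractor exercises flag a pre-specified
#' distractor window; implicit-distractor exercises interleave distractors
#' the subject must classify; the go/no-go exercise presents withhold-targets
#' among go-distractors).
#'
#' @param spec One registry row (see [build_registry()]), as a one-row data
#'   frame or list.
#' @param challenge Challenge level(s): a scalar applied to all trials or a
#'   vector of length `n`.
#' @param n Number of trials.
#' @param p_target Target prevalence (0.5 by default); with `stratified =
#'   TRUE` the realized fraction is exact (`round(n * p_target)` targets).
#' @param stratified Use exact stratified target counts rather than i.i.d.
#'   Bernoulli presence.
#' @param seed Optional seed for the presence permutation.
#' @return A tibble with one row per trial: `exercise_id`, `trial`,
#'   `challenge`, `target_present`, `distractor_kind`, `stimulus_axis`,
#'   `stimulus_value`, and empty `response`/`correct`/`is_false_positive`
#'   columns to be filled by an observer.
#' @export
generate_trials <- function(spec, challenge, n = spec$trials_per_block,
                            p_target = 0.5, stratified = TRUE, seed = NULL) {
  spec <- as.list(spec)
  assert_prob(p_target, "p_target")
  n <- as.integer(n)
  if (length(challenge) == 1) challenge <- rep(challenge, n)
  if (length(challenge) != n) abort("`challenge` must have length 1 or `n`.")
  present <- with_seed_(seed, {
    if (stratified) {
      k <- round(n * p_target)
      sample(c(rep(TRUE, k), rep(FALSE, n - k)))
    } else {
      runif(n) < p_target
    }
  })
  stim <- challenge_to_stimulus(spec$category, challenge)
  kind <- switch(spec$category,
    explicit_distractor = "explicit",
    implicit_distractor = "implicit",
    "none"
  )
  tibble(
    exercise_id = spec$exercise_id,
    trial = seq_len(n),
    challenge = challenge,
    target_present = present,
    distractor_kind = kind,
    stimulus_axis = stim$axis,
    stimulus_value = stim$value,
    response = NA_character_,
    correct = NA,
    is_false_positive = NA
  )
}

#' Schedule one 30-minute training session
#'
#' Picks up to seven exercises for a session, honoring the unveiling rule:
#' within each (category, modality) chain, a tier-k exercise becomes
#' schedulable only once the tier-(k-1) exercise is completed (tier-1
#' exercises, and the stand-alone response-inhibition exercise, are available
#' from the start). Among schedulable exercises the least-trained come first,
#' ties broken by exercise id. Per-exercise durations are drawn uniformly
#' from 3--5 minutes and truncated so the session total never exceeds the
#' session length.
#'
#' @param progress A data frame with `exercise_id` and `minutes_trained`
#'   covering (a subset of) the registry; missing exercises count as
#'   untrained.
#' @param registry The exercise registry ([build_registry()]).
#' @param session_minutes Session length in minutes.
#' @param max_exercises Maximum exercises per session.
#' @param completion_minutes Cumulative training minutes after which an
#'   exercise counts as completed for unveiling purposes.
#' @param seed Optional seed for the duration draws.
#' @return A tibble of scheduled registry rows with an extra
#'   `duration_minutes` column (possibly empty, with a `diagnostic`
#'   attribute, if nothing is schedulable).
#' @export
schedule_session <- function(progress, registry = build_registry(),
                             session_minutes = 30, max_exercises = 7,
                             completion_minutes = 60, seed = NULL) {
  if (nrow(registry) == 0) {
    out <- registry
    out$duration_minutes <- numeric(0)
    attr(out, "diagnostic") <- "empty registry: nothing schedulable"
    warn("No schedulable exercises; returning an empty session.")
    return(out)
  }
  mins <- setNames(rep(0, nrow(registry)), registry$exercise_id)
  if (nrow(progress) > 0) {
    unknown <- setdiff(progress$exercise_id, registry$exercise_id)
    if (length(unknown) > 0) {
      abort(paste0("`progress` references unknown exercises: ",
                   paste(unknown, collapse = ", ")))
    }
    mins[progress$exercise_id] <- progress$minutes_trained
  }
  completed <- mins >= completion_minutes
  chain_key <- paste(registry$category, registry$modality)
  prev_key <- paste0(chain_key, "_", registry$tier - 1L)
  this_key <- paste0(chain_key, "_", registry$tier)
  names(completed) <- NULL
  done_by_key <- setNames(completed, this_key[match(registry$exercise_id,
                                                    registry$exercise_id)])
  unlocked <- registry$tier == 1L |
    unname(done_by_key[prev_key]) %in% TRUE
  avail <- registry[unlocked, , drop = FALSE]
  avail_mins <- mins[avail$exercise_id]
  ord <- order(avail_mins, avail$exercise_id)
  avail <- avail[ord, , drop = FALSE]
  take <- head(seq_len(nrow(avail)), max_exercises)
  avail <- avail[take, , drop = FALSE]
  durations <- with_seed_(seed, sample(3:5, nrow(avail), replace = TRUE))
  cum <- cumsum(durations)
  over <- cum > session_minutes
  if (any(over)) {
    first_over <- which(over)[1]
    room <- session_minutes - if (first_over > 1) cum[first_over - 1] else 0
    if (room >= avail$duration_min[first_over]) {
      durations[first_over] <- room
      keep <- seq_len(first_over)
    } else {
      keep <- seq_len(first_over - 1)
    }
    avail <- avail[keep, , drop = FALSE]
    durations <- durations[keep]
  }
  avail$duration_minutes <- durations
  avail
}

#' Summarise a training log into curriculum compliance
#'
#' Totals the logged session time per subject and classifies compliance
#' against the 30-hour dose (60 half-hour sessions over at most 24 weeks).
#'
#' @param sessions A data frame of session logs with columns `session_index`,
#'   `minutes`, and optionally `subject_id`, `week`, `start_hour` (hours
#'   since study start; used to detect overlapping sessions).
#' @return A tibble per subject: `n_sessions`, `total_hours`,
#'   `weeks_spanned`, `completer` (`TRUE` once at least 30 hours are logged).
#' @examples
#' accumulate_curriculum(data.frame(session_index = 1:60, minutes = 30))
#' @export
accumulate_curriculum <- function(sessions) {
  sessions <- as_tibble(sessions)
  if (!"subject_id" %in% names(sessions)) sessions$subject_id <- "subject"
  if (nrow(sessions) > 0 && "start_hour" %in% names(sessions)) {
    bad <- sessions |>
      group_by(.data$subject_id) |>
      arrange(.data$start_hour, .by_group = TRUE) |>
      filter(row_number() > 1 &
               .data$start_hour < lag(.data$start_hour) + lag(.data$minutes) / 60) |>
      ungroup()
    if (nrow(bad) > 0) {
      abort(paste0("Overlapping sessions for subject(s): ",
                   paste(unique(bad$subject_id), collapse = ", ")))
    }
  }
  template <- tibble(subject_id = character(), n_sessions = integer(),
                     total_hours = numeric(), weeks_spanned = integer(),
                     completer = logical())
  if (nrow(sessions) == 0) return(template)
  sessions |>
    group_by(.data$subject_id) |>
    summarise(
      n_sessions = n(),
      total_hours = sum(.data$minutes) / 60,
      weeks_spanned = if ("week" %in% names(sessions)) {
        as.integer(max(.data$week) - min(.data$week) + 1L)
      } else {
        NA_integer_
      },
      .groups = "drop"
    ) |>
    mutate(completer = .data$total_hours >= 30)
}
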