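#' Configuration for a simulated ADHD cohort
#'
#' Collects the generative parameters of the virtual-subject model. The
#' defaults reproduce the structure of the study population this package
#' emulates: 31 children, mean age 12 (sd 1.9) truncated to 8--16 years,
#' roughly half on stimulant medication (15/31), a 2:1 allocation toward the
#' training arm in blocks of eight, about one in ten subjects dropping out
#' after baseline, and roughly half of the retained training-arm subjects
#' adhering only partially (1--13 logged hours).
#'
#' Each subject carries three latent traits on the unit challenge axis
#' (`signal_sensitivity`, `distractor_suppression`, `inhibition`), a lapse
#' rate, per-trait learning-rate multipliers (log-normal heterogeneity in
#' training responsiveness), and a symptom model: the parent-rated symptom
#' total is `intercept - coupling_strength * distractor_suppression` plus
#' noise, clamped to the 0--54 scale of an 18-item, 0--3 rating instrument.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param arm_ratio Allocation ratio `c(training, control)`.
#' @param fraction_medicated Fraction of subjects on stimulant medication.
#' @param coupling_strength Rating points of symptom relief per unit of
#'   distractor-suppression trait. Set to 0 for a null generator.
#' @param dropout_probability Probability a subject leaves after baseline,
#'   before any intervention exposure.
#' @param partial_compliance_fraction Fraction of retained training-arm
#'   subjects who train only partially (target hours drawn from 1--13 h,
#'   centered at 4.5 h).
#' @param age_mean,age_sd Age distribution (years), truncated to `[8, 16]`.
#' @param trait_shape1,trait_shape2 Beta parameters for the baseline traits.
#' @param lapse_max Lapse rates are uniform on `[0, lapse_max]`.
#' @param learning_rate Base trait gain per trained minute (saturating
#'   update; see [apply_learning()]). Set to 0 for a null generator.
#' @param learning_sdlog Log-sd of the per-subject, per-trait responsiveness
#'   multipliers.
#' @param control_learning_rate Trait gain per minute of control game play
#'   (0 by default: the active control is not expected to move the traits; a
#'   positive value models placebo drift).
#' @param symptom_intercept_mean,symptom_intercept_sd Untrained symptom
#'   severity intercept distribution (rating points).
#' @param symptom_noise_sd Rating noise sd (points) per assessment.
#' @param sigma Psychometric scale on the challenge axis (logistic link).
#' @param guess Guess floor for two-alternative forced-choice responses.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 31,
                          arm_ratio = c(2, 1),
                          fraction_medicated = 15 / 31,
                          coupling_strength = 30,
                          dropout_probability = 3 / 31,
                          partial_compliance_fraction = 10 / 21,
                          age_mean = 12, age_sd = 1.9,
                          trait_shape1 = 2.5, trait_shape2 = 4.5,
                          lapse_max = 0.06,
                          learning_rate = 4e-4,
                          learning_sdlog = 0.6,
                          control_learning_rate = 0,
                          symptom_intercept_mean = 43,
                          symptom_intercept_sd = 4,
                          symptom_noise_sd = 1.5,
                          sigma = 0.125,
                          guess = 0.5) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), arm_ratio = as.numeric(arm_ratio),
    fraction_medicated = fraction_medicated,
    coupling_strength = coupling_strength,
    dropout_probability = dropout_probability,
    partial_compliance_fraction = partial_compliance_fraction,
    age_mean = age_mean, age_sd = age_sd,
    trait_shape1 = trait_shape1, trait_shape2 = trait_shape2,
    lapse_max = lapse_max, learning_rate = learning_rate,
    learning_sdlog = learning_sdlog,
    control_learning_rate = control_learning_rate,
    symptom_intercept_mean = symptom_intercept_mean,
    symptom_intercept_sd = symptom_intercept_sd,
    symptom_noise_sd = symptom_noise_sd,
    sigma = sigma, guess = guess
  )
  problems <- character()
  if (is.na(cfg$n_subjects) || cfg$n_subjects < 2) {
    problems <- c(problems, "n_subjects must be >= 2")
  }
  if (length(cfg$arm_ratio) != 2 || any(cfg$arm_ratio <= 0)) {
    problems <- c(problems, "arm_ratio must be two positive numbers")
  }
  for (p in c("fraction_medicated", "dropout_probability",
              "partial_compliance_fraction")) {
    if (!is.numeric(cfg[[p]]) || is.na(cfg[[p]]) || cfg[[p]] < 0 || cfg[[p]] > 1) {
      problems <- c(problems, paste(p, "must be a probability in [0, 1]"))
    }
  }
  if (cfg$lapse_max < 0 || cfg$lapse_max > 0.1) {
    problems <- c(problems, "lapse_max must lie in [0, 0.1]")
  }
  if (cfg$learning_rate < 0 || cfg$control_learning_rate < 0) {
    problems <- c(problems, "learning rates must be >= 0")
  }
  if (cfg$symptom_noise_sd < 0) {
    problems <- c(problems, "symptom_noise_sd must be >= 0")
  }
  if (cfg$sigma <= 0) problems <- c(problems, "sigma must be > 0")
  if (length(problems) > 0) {
    abort(paste0("Invalid cohort configuration:\n",
                 paste0("- ", problems, collapse = "\n")))
  }
  structure(cfg, class = "cohort_config")
}

trait_names <- function() {
  c("signal_sensitivity", "distractor_suppression", "inhibition")
}

#' Generate a reproducible virtual cohort
#'
#' Draws subjects from a [cohort_config()]: ages from a truncated normal,
#' an exact `round(n * fraction_medicated)` subjects flagged as medicated,
#' baseline traits from independent Beta distributions, lapse rates, symptom
#' intercepts, per-trait learning multipliers and compliance propensities.
#' The same `(config, seed)` pair always yields the identical cohort.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return A tibble with one row per subject and the configuration attached
#'   as attribute `"config"`. Trait columns are named
#'   `signal_sensitivity`, `distractor_suppression`, `inhibition`; learning
#'   multipliers are `lr_<trait>`.
#' @examples
#' cohort <- generate_cohort(cohort_config(), seed = 1)
#' mean(cohort$age_years)
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  n <- config$n_subjects
  cohort <- with_seed_(seed, {
    age <- rnorm(4 * n, config$age_mean, config$age_sd)
    age <- age[age >= 8 & age <= 16][seq_len(n)]
    if (anyNA(age)) { # extremely narrow truncation window fallback
      age[is.na(age)] <- clamp(rnorm(sum(is.na(age)), config$age_mean,
                                     config$age_sd), 8, 16)
    }
    n_med <- round(n * config$fraction_medicated)
    medicated <- rep(FALSE, n)
    medicated[sample.int(n, n_med)] <- TRUE
    traits <- matrix(rbeta(3 * n, config$trait_shape1, config$trait_shape2),
                     ncol = 3, dimnames = list(NULL, trait_names()))
    lr <- matrix(config$learning_rate *
                   rlnorm(3 * n, 0, config$learning_sdlog),
                 ncol = 3, dimnames = list(NULL, paste0("lr_", trait_names())))
    tibble(
      subject_id = sprintf("S%03d", seq_len(n)),
      age_years = age,
      medication = medicated,
      as_tibble(traits),
      lapse_rate = runif(n, 0, config$lapse_max),
      as_tibble(lr),
      symptom_intercept = clamp(rnorm(n, config$symptom_intercept_mean,
                                      config$symptom_intercept_sd), 10, 54),
      symptom_noise_sd = config$symptom_noise_sd,
      compliance_propensity = runif(n)
    )
  })
  attr(cohort, "config") <- config
  attr(cohort, "seed") <- seed
  cohort
}

#' Map an exercise category to the latent trait it trains
#'
#' @param category Exercise category string(s).
#' @return The trait name(s); errors on an unmapped category.
#' @export
category_trait <- function(category) {
  map <- c(attended_signal = "signal_sensitivity",
           explicit_distractor = "distractor_suppression",
           implicit_distractor = "distractor_suppression",
           response_inhibition = "inhibition")
  out <- unname(map[category])
  if (anyNA(out)) {
    abort(paste0("No trait mapped for category: ",
                 paste(unique(category[is.na(out)]), collapse = ", ")))
  }
  out
}

#' Probability a subject answers a trial correctly
#'
#' The closed-form lapse-corrected logistic observer:
#' \eqn{P = \gamma + (1 - \gamma - \lambda) F((trait - challenge)/\sigma)}
#' with logistic `F`, guess floor `gamma` and lapse `lambda`. Vectorized over
#' all arguments.
#'
#' @param trait Latent ability on the challenge axis.
#' @param challenge Challenge level in `[0, 1]`.
#' @param lapse Lapse rate.
#' @param guess Guess floor (0.5 for 2AFC).
#' @param sigma Logistic scale.
#' @return Probability of a correct response, in `[guess, 1 - lapse]`.
#' @export
respond_probability <- function(trait, challenge, lapse = 0, guess = 0.5,
                                sigma = 0.125) {
  guess + (1 - guess - lapse) * plogis((trait - challenge) / sigma)
}

#' Draw a subject's responses to training trials
#'
#' Fills the response side of trials from [generate_trials()]: the response
#' is correct with [respond_probability()] given the trait mapped to the
#' exercise category. For yes/no trials an incorrect response on a
#' target-absent trial is an affirmative response to a distractor and is
#' flagged as a false positive; for the go/no-go exercise a failure to
#' withhold on a withhold-target is the false positive.
#'
#' @param subject One cohort row ([generate_cohort()]).
#' @param trials A trials tibble from [generate_trials()].
#' @param category Exercise category (defaults to the registry category
#'   implied by `trials$distractor_kind` is not unique, so pass it).
#' @param config The generating [cohort_config()] (for `sigma` and `guess`).
#' @param seed Optional seed.
#' @return `trials` with `response`, `correct` and `is_false_positive`
#'   filled in.
#' @export
respond <- function(subject, trials, category, config = cohort_config(),
                    seed = NULL) {
  trait <- subject[[category_trait(category)]]
  go_no_go <- category == "response_inhibition"
  p <- respond_probability(trait, trials$challenge, subject$lapse_rate,
                           guess = if (go_no_go) 0 else config$guess,
                           sigma = config$sigma)
  correct <- with_seed_(seed, runif(nrow(trials)) < p)
  if (go_no_go) {
    # targets demand withholding; distractors demand a go response
    response <- ifelse(trials$target_present,
                       ifelse(correct, "withhold", "go"),
                       ifelse(correct, "go", "withhold"))
    fp <- trials$target_present & response == "go"
  } else {
    response <- ifelse(trials$target_present,
                       ifelse(correct, "yes", "no"),
                       ifelse(correct, "no", "yes"))
    fp <- !trials$target_present & response == "yes"
  }
  trials$response <- response
  trials$correct <- correct
  trials$is_false_positive <- fp
  trials
}

#' Apply saturating learning from a training session
#'
#' Each trained trait grows by `rate * minutes * (1 - trait)` per session,
#' where `rate` is the subject's per-trait learning multiplier; the trait is
#' bounded in `[0, 1]` and gains saturate as ability approaches ceiling.
#' Iterating k equal sessions has the closed form
#' `1 - (1 - trait) * (1 - rate * minutes)^k`.
#'
#' @param subject One or more cohort rows.
#' @param minutes_by_trait Named numeric vector or one-row data frame of
#'   trained minutes per trait (names among the trait columns), or a session
#'   log with `category` and `duration_minutes` columns which is aggregated
#'   via [category_trait()].
#' @return The subject rows with updated trait columns.
#' @export
apply_learning <- function(subject, minutes_by_trait) {
  if (is.data.frame(minutes_by_trait) &&
      all(c("category", "duration_minutes") %in% names(minutes_by_trait))) {
    agg <- minutes_by_trait |>
      mutate(trait = category_trait(.data$category)) |>
      group_by(.data$trait) |>
      summarise(minutes = sum(.data$duration_minutes), .groups = "drop")
    minutes_by_trait <- setNames(agg$minutes, agg$trait)
  }
  for (tr in names(minutes_by_trait)) {
    if (!tr %in% trait_names()) abort(paste0("Unknown trait: ", tr))
    rate <- subject[[paste0("lr_", tr)]]
    gain <- rate * minutes_by_trait[[tr]] * (1 - subject[[tr]])
    subject[[tr]] <- clamp(subject[[tr]] + gain, 0, 1)
  }
  subject
}

# closed form for k equal sessions of m minutes at per-minute rate r
learning_trajectory <- function(trait0, rate, minutes, k) {
  1 - (1 - trait0) * (1 - rate * minutes)^pmax(k, 0)
}

#' Emit a parent-rated symptom severity total
#'
#' The symptom model couples distractor suppression to the 0--54 rating
#' total: `clamp(round(intercept - coupling * distractor_suppression +
#' noise), 0, 54)`, higher = more severe. With `coupling_strength = 0` the
#' ratings are independent of training (null-generator mode).
#'
#' @param subject One or more cohort rows (current traits).
#' @param config The generating [cohort_config()].
#' @param seed Optional seed for the rating noise.
#' @return Integer rating totals, one per subject row.
#' @export
emit_symptom_rating <- function(subject, config = cohort_config(), seed = NULL) {
  noise <- with_seed_(seed,
                      rnorm(nrow(subject), 0, subject$symptom_noise_sd))
  score <- subject$symptom_intercept -
    config$coupling_strength * subject$distractor_suppression + noise
  as.integer(clamp(round(score), 0, 54))
}

# clinician global-impression severity derived from the same latent severity,
# coarsened onto the ordinal 1-7 scale
emit_cgi <- function(subject, config, seed = NULL) {
  latent <- subject$symptom_intercept -
    config$coupling_strength * subject$distractor_suppression
  noise <- with_seed_(seed, rnorm(nrow(subject), 0, 0.5))
  as.integer(clamp(round(1 + 6 * latent / 54 + noise), 1, 7))
}
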