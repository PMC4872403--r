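#' Create a fresh adaptive staircase state
#'
#' The training program holds every exercise in a 75--85% percent-correct band
#' using a transformed up-down (3-down-1-up) staircase on a normalized
#' challenge axis: after `n_up` consecutive correct responses the challenge is
#' raised by one step, after any error it is lowered by one step, and each
#' reversal of direction halves the step down to a floor. The 3-down-1-up rule
#' converges on the stimulus level where the probability of a correct response
#' is \eqn{0.5^{1/3} \approx 0.794}, inside the designed band.
#'
#' @param challenge Starting challenge in `[0, 1]` (0 = easiest). Training
#'   starts easy by design, hence the low default.
#' @param step Initial step size on the challenge axis.
#' @param step_floor Smallest step size; halving stops here.
#' @param n_up Number of consecutive correct responses required before the
#'   challenge is raised (3 gives the classic 79.4% convergence point).
#' @param target_band Performance band the rule is designed to hold, as
#'   `c(lower, upper)` proportions correct.
#' @return An object of class `staircase_state`.
#' @seealso [update_staircase()], [simulate_staircase()]
#' @examples
#' st <- staircase_state()
#' st <- update_staircase(st, correct = TRUE)
#' @export
staircase_state <- function(challenge = 0.1, step = 0.08, step_floor = 0.01,
                            n_up = 3, target_band = c(0.75, 0.85)) {
  assert_scalar_num(challenge, "challenge", 0, 1)
  assert_scalar_num(step, "step", lo = .Machine$double.eps)
  assert_scalar_num(step_floor, "step_floor", lo = .Machine$double.eps)
  if (length(target_band) != 2 || target_band[1] >= target_band[2]) {
    abort("`target_band` must be c(lower, upper) with lower < upper.")
  }
  structure(
    list(
      challenge = challenge,
      step = max(step, step_floor),
      step_floor = step_floor,
      n_up = as.integer(n_up),
      n_consecutive_correct = 0L,
      n_reversals = 0L,
      last_direction = "none",
      target_band = as.numeric(target_band),
      history = list(challenge = numeric(), correct = logical())
    ),
    class = "staircase_state"
  )
}

#' @export
print.staircase_state <- function(x, ...) {
  cat(sprintf(
    "<staircase_state> challenge %.3f, step %.3f, %d reversal(s), %d trial(s)\n",
    x$challenge, x$step, x$n_reversals, length(x$history$challenge)
  ))
  invisible(x)
}

#' Apply one correctness outcome to a staircase
#'
#' Implements the 3-down-1-up update: the third consecutive correct response
#' raises the challenge by the current step and resets the counter; any
#' incorrect response immediately lowers it. A change of movement direction
#' counts as a reversal and halves the step (not below the floor) before the
#' move is applied. The challenge is always clamped to `[0, 1]`.
#'
#' @param state A [staircase_state()].
#' @param correct Logical scalar, whether the response was correct.
#' @param record Keep the `(challenge, correct)` pair in the state's history?
#'   Disable inside long simulations where the trajectory is tracked outside.
#' @return The updated `staircase_state`.
#' @export
update_staircase <- function(state, correct, record = TRUE) {
  if (!inherits(state, "staircase_state")) abort("`state` must be a staircase_state.")
  if (!is.logical(correct) || length(correct) != 1 || is.na(correct)) {
    abort("`correct` must be TRUE or FALSE.")
  }
  move <- "none"
  if (correct) {
    state$n_consecutive_correct <- state$n_consecutive_correct + 1L
    if (state$n_consecutive_correct >= state$n_up) {
      move <- "up"
      state$n_consecutive_correct <- 0L
    }
  } else {
    move <- "down"
    state$n_consecutive_correct <- 0L
  }
  if (move != "none") {
    if (state$last_direction != "none" && move != state$last_direction) {
      state$n_reversals <- state$n_reversals + 1L
      state$step <- max(state$step / 2, state$step_floor)
    }
    delta <- if (move == "up") state$step else -state$step
    state$challenge <- clamp(state$challenge + delta, 0, 1)
    state$last_direction <- move
  }
  if (record) {
    state$history$challenge <- c(state$history$challenge, state$challenge)
    state$history$correct <- c(state$history$correct, correct)
  }
  state
}

#' Replay a correctness sequence through the staircase rule
#'
#' Used to check that the reversal count stored in a state is recoverable from
#' its history alone.
#'
#' @param correct Logical vector of outcomes.
#' @param state Starting state (fresh by default).
#' @return The final `staircase_state` after applying every outcome.
#' @export
replay_staircase <- function(correct, state = staircase_state()) {
  for (ok in correct) state <- update_staircase(state, ok)
  state
}

#' Logistic psychometric observer
#'
#' Builds a function `P(correct | challenge)` of the standard lapse-corrected
#' logistic form
#' \eqn{\gamma + (1 - \gamma - \lambda) / (1 + e^{s (c - \theta)})},
#' decreasing in challenge: performance is at the guess floor for very hard
#' stimuli and near `1 - lapse` for very easy ones.
#'
#' @param threshold Challenge at which performance is halfway between floor
#'   and ceiling.
#' @param slope Logistic slope on the challenge axis.
#' @param lapse Lapse rate (ceiling is `1 - lapse`).
#' @param guess Guess floor (0.5 for two-alternative forced choice).
#' @return A function of `challenge` with class `psychometric_observer`; its
#'   parameters are retrievable via `attr(, "params")`.
#' @examples
#' obs <- logistic_observer()
#' obs(0.5) # == guess + (1 - guess - lapse) / 2
#' @export
logistic_observer <- function(threshold = 0.5, slope = 8, lapse = 0.02,
                              guess = 0.5) {
  assert_prob(lapse, "lapse")
  assert_prob(guess, "guess")
  f <- function(challenge) {
    guess + (1 - guess - lapse) * plogis(slope * (threshold - challenge))
  }
  structure(f, class = c("psychometric_observer", "function"),
            params = list(threshold = threshold, slope = slope,
                          lapse = lapse, guess = guess))
}

#' Challenge level at which an observer attains a given percent correct
#'
#' Inverts a [logistic_observer()] analytically; any other monotone observer
#' is inverted numerically on `[0, 1]`.
#'
#' @param observer An observer function `P(correct | challenge)`.
#' @param p Target probability correct.
#' @return The challenge value, or `NA` if `p` is outside the observer's range.
#' @export
observer_quantile <- function(observer, p) {
  prm <- attr(observer, "params")
  if (!is.null(prm)) {
    f <- (p - prm$guess) / (1 - prm$guess - prm$lapse)
    if (f <= 0 || f >= 1) return(NA_real_)
    return(prm$threshold - qlogis(f) / prm$slope)
  }
  lo <- observer(1); hi <- observer(0)
  if (p < lo || p > hi) return(NA_real_)
  stats::uniroot(function(c) observer(c) - p, c(0, 1))$root
}

#' Theoretical convergence point of an n-up transformed up-down rule
#'
#' The rule equilibrates where the probability of stepping up equals the
#' probability of stepping down, i.e. where \eqn{p^{n_{up}} = 1/2}.
#'
#' @param n_up Consecutive-correct requirement (3 by default).
#' @return The asymptotic proportion correct (`0.794` for 3-down-1-up).
#' @export
staircase_convergence_p <- function(n_up = 3) 0.5^(1 / n_up)

#' Simulate a staircase against a simulated observer
#'
#' Runs the adaptive rule for `n_trials` trials, drawing each trial's
#' correctness from `observer(challenge)`, and summarises the steady state
#' after a burn-in of the first `burn_in` trials or the first `min_reversals`
#' reversals, whichever ends later.
#'
#' @param observer A function `P(correct | challenge)`, non-increasing in
#'   challenge (e.g. [logistic_observer()]). An observer whose success
#'   probability increases with challenge is rejected.
#' @param n_trials Number of trials (>= 1).
#' @param seed Optional integer seed; the simulation is fully reproducible
#'   given `(observer, n_trials, seed, state)`.
#' @param state Starting [staircase_state()].
#' @param burn_in Minimum number of initial trials excluded from the
#'   steady-state summary.
#' @param min_reversals Burn-in also waits for this many reversals.
#' @return An object of class `staircase_sim` with elements `trajectory`
#'   (a tibble: `trial`, `challenge` presented, `p_correct`, `correct`,
#'   `step`, `n_reversals`), `accuracy` (steady-state proportion correct),
#'   `converged_challenge`, `burn_in_used`, and the final `state`.
#'   [glance()] returns the summary as a one-row tibble and [autoplot()]
#'   draws the trajectory.
#' @examples
#' sim <- simulate_staircase(logistic_observer(), n_trials = 500, seed = 1)
#' glance(sim)
#' @export
simulate_staircase <- function(observer, n_trials, seed = NULL,
                               state = staircase_state(), burn_in = 200,
                               min_reversals = 6) {
  if (!is.function(observer)) abort("`observer` must be a function of challenge.")
  assert_scalar_num(n_trials, "n_trials", lo = 1)
  grid <- seq(0, 1, by = 0.05)
  pg <- vapply(grid, observer, numeric(1))
  if (any(pg < -1e-9 | pg > 1 + 1e-9)) {
    abort("`observer` must return probabilities in [0, 1].")
  }
  if (any(diff(pg) > 1e-8)) {
    abort(paste0(
      "`observer` is non-monotone: P(correct) increases with challenge ",
      "between ", grid[which(diff(pg) > 1e-8)[1]], " and ",
      grid[which(diff(pg) > 1e-8)[1] + 1], ". The staircase assumes harder ",
      "stimuli are answered correctly less often."
    ))
  }
  n_trials <- as.integer(n_trials)
  challenge <- p_corr <- step <- numeric(n_trials)
  correct <- logical(n_trials)
  revs <- integer(n_trials)
  with_seed_(seed, {
    for (i in seq_len(n_trials)) {
      challenge[i] <- state$challenge
      p <- observer(state$challenge)
      p_corr[i] <- p
      ok <- runif(1) < p
      correct[i] <- ok
      state <- update_staircase(state, ok, record = FALSE)
      step[i] <- state$step
      revs[i] <- state$n_reversals
    }
  })
  rev_trial <- if (any(revs >= min_reversals)) which(revs >= min_reversals)[1] else burn_in
  burn_used <- min(max(burn_in, rev_trial), n_trials - 1L)
  keep <- seq.int(burn_used + 1L, n_trials)
  structure(
    list(
      trajectory = tibble(
        trial = seq_len(n_trials), challenge = challenge, p_correct = p_corr,
        correct = correct, step = step, n_reversals = revs
      ),
      accuracy = mean(correct[keep]),
      converged_challenge = mean(challenge[keep]),
      burn_in_used = burn_used,
      n_trials = n_trials,
      state = state
    ),
    class = "staircase_sim"
  )
}

#' @export
print.staircase_sim <- function(x, ...) {
  cat(sprintf(
    paste0("<staircase_sim> %d trials (burn-in %d)\n",
           "  steady-state accuracy   %.3f\n",
           "  converged challenge     %.3f\n",
           "  reversals               %d\n"),
    x$n_trials, x$burn_in_used, x$accuracy, x$converged_challenge,
    x$state$n_reversals
  ))
  invisible(x)
}

#' Map a challenge level onto a concrete stimulus axis
#'
#' Each exercise category adapts a different physical stimulus dimension:
#' attended-signal exercises make the target less salient as challenge rises,
#' distractor exercises make distractors more similar to the target, and the
#' response-inhibition exercise shortens the interstimulus interval.
#'
#' @param category One of `"attended_signal"`, `"explicit_distractor"`,
#'   `"implicit_distractor"`, `"response_inhibition"`.
#' @param challenge Numeric vector in `[0, 1]`.
#' @param isi_range Interstimulus-time range in seconds `c(min, max)` used by
#'   the response-inhibition mapping (challenge 0 maps to `max`).
#' @return A tibble with `category`, `challenge`, `axis`
#'   (`target_salience`, `distractor_similarity` or `interstimulus_time`) and
#'   `value` (unit scale for salience/similarity, seconds for time).
#' @examples
#' challenge_to_stimulus("attended_signal", c(0, 1))
#' @export
challenge_to_stimulus <- function(category, challenge, isi_range = c(0.5, 3)) {
  category <- match.arg(category, c("attended_signal", "explicit_distractor",
                                    "implicit_distractor", "response_inhibition"))
  if (any(!is.finite(challenge)) || any(challenge < 0 | challenge > 1)) {
    abort("`challenge` must lie in [0, 1].")
  }
  if (length(isi_range) != 2 || isi_range[1] <= 0 || isi_range[1] >= isi_range[2]) {
    abort("`isi_range` must be c(min, max) seconds with 0 < min < max.")
  }
  axis <- switch(category,
    attended_signal = "target_salience",
    explicit_distractor = ,
    implicit_distractor = "distractor_similarity",
    response_inhibition = "interstimulus_time"
  )
  value <- switch(axis,
    target_salience = 1 - challenge,
    distractor_similarity = challenge,
    interstimulus_time = isi_range[2] - challenge * (isi_range[2] - isi_range[1])
  )
  tibble(category = category, challenge = challenge, axis = axis, value = value)
}
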