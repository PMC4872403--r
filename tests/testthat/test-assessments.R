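test_that("d-prime matches the quantile oracle and handles extreme rates", {
  # matched hit and false-alarm counts give zero sensitivity
  expect_equal(compute_dprime(50, 50, 100, 100), 0)
  # uncorrected 0.9/0.1 rates: z(0.9) - z(0.1)
  expect_equal(compute_dprime(90, 10, 100, 100, correction = "none"),
               qnorm(0.9) - qnorm(0.1))
  # perfect performance stays finite under the log-linear correction,
  # equal to the corrected-rate closed form
  expect_equal(compute_dprime(100, 0, 100, 100),
               qnorm(100.5 / 101) - qnorm(0.5 / 101))
  expect_true(is.finite(compute_dprime(100, 0, 100, 100)))
  expect_error(compute_dprime(-1, 0, 10, 10), "non-negative")
  expect_error(compute_dprime(11, 0, 10, 10), "exceed")
})

test_that("d-prime is antisymmetric and monotone in its rates", {
  expect_equal(compute_dprime(80, 20, 100, 100),
               -compute_dprime(20, 80, 100, 100))
  hits <- seq(10, 90, by = 10)
  d_by_hits <- compute_dprime(hits, 20, 100, 100)
  expect_true(all(diff(d_by_hits) > 0))
  d_by_fa <- compute_dprime(80, hits, 100, 100)
  expect_true(all(diff(d_by_fa) < 0))
})

test_that("CPT halves realize the printed target prevalences exactly", {
  subj <- tiny_cohort(1, seed = 21)[1, ]
  sus <- run_cpt(subj, "sustained_attention", seed = 1)
  expect_equal(sus$n_targets, 45L) # 22.5% of 200
  expect_equal(sus$n_nontargets, 155L)
  expect_equal(sus$hits + sus$misses, sus$n_targets)
  expect_equal(sus$false_alarms + sus$correct_rejections, sus$n_nontargets)
  inh <- run_cpt(subj, "response_inhibition", seed = 1)
  expect_equal(inh$n_targets, 155L) # 77.5% of 200
  expect_equal(inh$n_nontargets, 45L)
  # indivisible trial counts are adjusted with a warning, keeping exactness
  expect_warning(
    odd <- run_cpt(subj, "sustained_attention", cpt_config(n_trials = 190),
                   seed = 1),
    "exactly"
  )
  expect_equal(odd$n_targets / (odd$n_targets + odd$n_nontargets), 0.225)
})

test_that("an omniscient observer attains the corrected-ceiling d-prime", {
  subj <- tiny_cohort(1, seed = 22)[1, ]
  res <- run_cpt(subj, "sustained_attention", seed = 1, p_hit = 1, p_fa = 0)
  ceiling_d <- qnorm(45.5 / 46) - qnorm(0.5 / 156)
  expect_equal(res$d_prime, ceiling_d)
})

test_that("span tasks use the printed loads, exact 50% probes, and monotone speed", {
  subj <- tiny_cohort(1, seed = 23)[1, ]
  sp <- run_span(subj, "spatial", seed = 2)
  expect_setequal(unique(sp$trials$load), c(1, 3, 5, 7))
  expect_equal(sp$match_fraction, 0.5)
  vb <- run_span(subj, "verbal", seed = 2)
  expect_setequal(unique(vb$trials$load), c(3, 5, 7, 9))
  expect_equal(vb$match_fraction, 0.5)
  # high-load metric covers the two highest loads only
  expect_equal(sp$high_load_speed,
               mean(sp$trials$response_seconds[sp$trials$load %in% c(5, 7)]))
  # zero noise: higher trait means strictly faster high-load speed
  cfg0 <- span_config(rt_noise_sd = 0)
  slow <- subj; slow$signal_sensitivity <- 0.3
  fast <- subj; fast$signal_sensitivity <- 0.8
  expect_gt(run_span(slow, "verbal", cfg0, seed = 1)$high_load_speed,
            run_span(fast, "verbal", cfg0, seed = 1)$high_load_speed)
})

test_that("span speed matches its analytic mean over repeated runs", {
  subj <- tiny_cohort(1, seed = 24)[1, ]
  cfg <- span_config()
  sims <- vapply(1:1000, function(s) {
    run_span(subj, "spatial", cfg, seed = s)$high_load_speed
  }, numeric(1))
  analytic <- cfg$base_seconds +
    cfg$load_slope * 6 / (0.5 + subj$signal_sensitivity) # mean(c(5,7)) = 6
  expect_lt(abs(mean(sims) - analytic) / analytic, 0.01)
})

test_that("Stroop interference is the printed sheet difference with 100-cap", {
  expect_equal(score_stroop(80, 70, 45), -25)
  expect_equal(score_stroop(90, 60, 60), 0) # no interference
  expect_error(score_stroop(80, 101, 45), "100")
  expect_error(score_stroop(80, 70, -2), "100")
  subj <- tiny_cohort(1, seed = 25)[1, ]
  sheets <- purrr::map(1:50, ~ simulate_stroop(subj, seed = .x)) |>
    purrr::list_rbind()
  expect_true(all(sheets$word_correct <= 100))
  expect_true(all(sheets$color_correct <= 100))
  expect_true(all(sheets$colorword_correct <= 100))
  expect_true(all(sheets$interference <= 0))
})

test_that("screening cutoffs are strict inequalities per subtype", {
  expect_true(swan_screen(combined = 2.12)$positive[1])
  # exactly at every cutoff: screen-negative
  at_cut <- swan_screen(combined = 2.11, inattentive = 2.48,
                        hyperactive = 2.00)
  expect_false(any(at_cut$positive))
  expect_false(attr(at_cut, "screen_positive"))
  one <- swan_screen(combined = 0, inattentive = 2.49, hyperactive = 0)
  expect_identical(one$subtype[one$positive], "inattentive")
})

test_that("distractor probe counts fall with the suppression trait", {
  subj <- tiny_cohort(1, seed = 26)[1, ]
  # perfect suppressor commits zero false positives
  perfect <- subj
  perfect$distractor_suppression <- 1
  perfect$lapse_rate <- 0
  expect_equal(distractor_probe(perfect, "start", seed = 1)$false_positives, 0L)
  # identical traits at start and end: expected change is zero
  fp <- vapply(1:500, function(s) {
    pr <- distractor_probe(subj, "start", seed = s)$false_positives -
      distractor_probe(subj, "end", seed = 1000 + s)$false_positives
    as.numeric(pr)
  }, numeric(1))
  expect_lt(abs(mean(fp)), 2)
  # improved trait: mean false-positive change over seeded probe pairs < 0
  improved <- subj
  improved$distractor_suppression <-
    min(1, subj$distractor_suppression + 0.25)
  delta <- vapply(1:500, function(s) {
    end <- distractor_probe(improved, "end", seed = s)$false_positives
    start <- distractor_probe(subj, "start", seed = 2000 + s)$false_positives
    as.numeric(end - start)
  }, numeric(1))
  expect_lt(mean(delta), 0)
})

test_that("assessment tables are validated against the timepoint schedule", {
  good <- tibble::tibble(
    subject_id = "S1",
    timepoint = c("baseline", "mid", "post", "followup", "baseline", "post"),
    instrument = c(rep("adhd_rs", 4), "cpt_sustained", "cpt_sustained"),
    value = c(30, 28, 25, 24, 1.5, 2.5)
  )
  expect_silent(validate_assessments(good))
  # cognitive instrument at a mid timepoint violates the schedule
  bad_tp <- good
  bad_tp$timepoint[5] <- "mid"
  expect_error(validate_assessments(bad_tp), "disallowed")
  bad_range <- good
  bad_range$value[1] <- 60
  expect_error(validate_assessments(bad_range), "\\[0, 54\\]")
  bad_instr <- good
  bad_instr$instrument[1] <- "mystery"
  expect_error(validate_assessments(bad_instr), "unknown instrument")
})
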