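test_that("trial inclusion needs three licks inside the half-open window", {
  f <- matrix(rnorm(600, 100), 1)
  tr <- make_trials(1, first = 5)
  rw <- tr$reward_time
  s3 <- make_session(f, tr, licks = rw + c(0.1, 0.4, 0.9))
  expect_true(included_trials(s3))
  s2 <- make_session(f, tr, licks = rw + c(0.1, 0.4))
  expect_false(included_trials(s2))
  sb <- make_session(f, tr, licks = rw + c(0.1, 0.4, 2.5)) # boundary lick
  expect_false(included_trials(sb))
  s_tone <- make_session(f, tibble::tibble(cs_onset = 5), licks = numeric(),
                         paradigm = "tone_only")
  expect_true(included_trials(s_tone))
})

test_that("response windows follow the paradigm", {
  f <- matrix(rnorm(40 * 30, 100), 1)
  tr <- make_trials(1, first = 5)
  s <- make_session(f, tr)
  expect_equal(response_window_start(s, "cs"), tr$cs_onset)
  expect_equal(response_window_start(s, "reward"), tr$reward_time)
  # nonpaired: reward window opens at the first post-delivery lick
  np <- ca_session(f, tibble::tibble(cs_onset = 5, reward_time = 10),
                   licks = c(13.2, 13.4, 13.6), mouse_id = "m", day = 1,
                   paradigm = "nonpaired")
  expect_equal(response_window_start(np, "reward"), 13.2)
  np2 <- ca_session(f, tibble::tibble(cs_onset = 5, reward_time = 10),
                    licks = numeric(), mouse_id = "m", day = 1,
                    paradigm = "nonpaired")
  expect_true(is.na(response_window_start(np2, "reward")))
})

test_that("trial responsiveness needs a 5-frame strict exceedance run", {
  z <- rep(0, 300)
  z[61:66] <- 1.5
  expect_true(is_trial_responsive(z, 2, 30))
  z2 <- rep(0, 300); z2[61:64] <- 2
  expect_false(is_trial_responsive(z2, 2, 30))
  z3 <- rep(0, 300); z3[61:65] <- 1 # exactly at threshold
  expect_false(is_trial_responsive(z3, 2, 30))
  expect_error(is_trial_responsive(z, 9.5, 30), "window")
})

test_that("window profiles agree with direct per-window evaluation", {
  set.seed(61)
  for (rep in 1:3) {
    z <- rnorm(400) + ifelse(runif(400) < 0.05, 2, 0)
    prof <- catrace:::cpp_window_profile(z, 1, 5L, 75L)
    direct <- vapply(seq_len(400 - 74), function(k) {
      r <- rle(z[k:(k + 74)] > 1)
      any(r$values & r$lengths >= 5)
    }, logical(1))
    expect_identical(as.logical(prof), direct)
  }
})

test_that("percent-responsive pooling: per-trial, mouse median, cohort mean", {
  resp <- tibble::tibble(
    mouse_id = rep(c("a", "b"), each = 6),
    day = 1L, stimulus = "cs",
    trial = rep(rep(1:3, each = 2), 2),
    neuron = rep(1:2, 6),
    included = TRUE,
    responsive = c(
      T, F,  T, T,  F, F,   # mouse a: 50, 100, 0 -> median 50
      F, F,  T, F,  F, F)   # mouse b: 0, 50, 0  -> median 0
  )
  out <- percent_responsive_summary(resp)
  expect_equal(sort(out$per_mouse$median_percent), c(0, 50))
  expect_equal(out$summary$mean_percent, 25)
})

test_that("percent-responsive is invariant to trial duplication", {
  resp <- tibble::tibble(
    mouse_id = "a", day = 1L, stimulus = "cs",
    trial = rep(1:3, each = 2), neuron = rep(1:2, 3), included = TRUE,
    responsive = c(T, F, T, T, F, F)
  )
  base <- percent_responsive_summary(resp)$summary$mean_percent
  dup <- resp
  dup$trial <- dup$trial + 10
  doubled <- percent_responsive_summary(dplyr::bind_rows(resp, dup))
  expect_equal(doubled$summary$mean_percent, base)
})

test_that("reliability is the percent of included responsive trials", {
  resp <- tibble::tibble(
    mouse_id = "a", day = 1L, neuron = 1L, stimulus = "cs",
    trial = 1:10, included = rep(TRUE, 10),
    responsive = c(rep(TRUE, 3), rep(FALSE, 7))
  )
  expect_equal(reliability_table(resp)$reliability, 30)
})

test_that("the High/Low split uses the nonzero 50th percentile", {
  sp <- split_by_reliability(c(10, 20, 30, 40))
  expect_equal(attr(sp, "threshold"), 25)
  expect_equal(sp$group, c("Low", "Low", "High", "High"))

  one <- split_by_reliability(c(0, 15))
  expect_equal(one$group, c("Low", "Low")) # zeros join Low; single value <= itself
  expect_true(!one$responder[1] && one$responder[2])

  ties <- split_by_reliability(rep(20, 5))
  expect_true(all(ties$group == "Low"))

  expect_warning(none <- split_by_reliability(c(0, 0)), "zero")
  expect_true(all(is.na(none$group)))
})

test_that("delta reliability is the day difference in points", {
  expect_equal(delta_reliability(20, 50), 30)
  expect_equal(delta_reliability(c(10, 40), c(10, 40)), c(0, 0))
})

test_that("random reliability reflects the day-7 window profile", {
  f <- matrix(rnorm(600, 100), 1)
  s <- make_session(f, day = 7L)
  silent <- fake_analysis(matrix(0, 1, 600), s)
  out <- delta_reliability_random(silent, 1, day1_index = 40, n_draws = 12)
  expect_equal(out$random_reliability, 0)
  expect_equal(out$delta_random, -40)
  loud <- fake_analysis(matrix(2, 1, 600), s)
  out2 <- delta_reliability_random(loud, 1, day1_index = 10, n_draws = 12)
  expect_equal(out2$random_reliability, 100)
})

test_that("onset latency counts to the fifth frame of the first run", {
  tr <- make_trials(2, first = 5, spacing = 15)
  f <- matrix(rnorm(2 * 35 * 30, 100), 2)
  s <- make_session(f, tr)
  z <- matrix(0, 2, ncol(f))
  cs_frames <- floor(tr$cs_onset * 30) + 1
  # trial 1: run starts exactly at the window start; trial 2: 0.5 s later
  z[1, cs_frames[1] + 0:7] <- 2
  z[1, cs_frames[2] + 15 + 0:7] <- 2
  a <- fake_analysis(z, s)
  lat <- onset_latency(a, "cs")
  expect_equal(lat$latency_s[lat$neuron == 1],
               mean(c(4 / 30, 19 / 30)))
  expect_false(2 %in% lat$neuron) # silent neuron skipped
})

test_that("cross-day fates partition the day-1 responders", {
  rel <- tibble::tibble(
    mouse_id = "a",
    day = rep(c(1L, 7L), each = 20),
    neuron = rep(1:10, 4),
    stimulus = rep(rep(c("cs", "reward"), each = 10), 2),
    reliability = c(
      rep(30, 10), rep(0, 10),               # day 1: all CS responders
      c(rep(30, 8), 0, 0), c(rep(0, 9), 25)) # day 7: 8 keep CS, 1 switches
  )
  fate <- cross_day_fate(rel, "cs")
  expect_equal(fate$maintained, 0.8)
  expect_equal(fate$switched, 0.1)
  expect_equal(fate$lost, 0.1)
  expect_equal(fate$maintained + fate$switched + fate$lost, 1)
})

test_that("the Monte-Carlo null enforces its iteration floor", {
  f <- matrix(rnorm(600, 100), 1)
  a <- fake_analysis(matrix(rnorm(600), 1), make_session(f))
  expect_error(null_percent_responsive(list(a), n_iter = 50), "100")
})

test_that("a saturated cohort is never called significant", {
  # every window everywhere responsive -> observed == null everywhere
  f <- matrix(rnorm(1200, 100), 2)
  s <- make_session(f)
  a <- fake_analysis(matrix(3, 2, 1200), s)
  mc <- null_percent_responsive(list(a), "cs", n_iter = 200,
                                bonferroni_m = 1)
  expect_equal(mc$observed, 100)
  expect_true(all(mc$null_values == 100))
  expect_false(mc$significant)
  expect_equal(mc$stars, "n.s.")
})
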