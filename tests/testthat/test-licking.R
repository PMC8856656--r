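test_that("binned lick rates convert counts to licks per second", {
  f <- matrix(rnorm(35 * 30, 100), 1)
  tr <- make_trials(1, first = 5)
  s0 <- make_session(f, tr, licks = tr$reward_time + c(0.2, 0.5, 0.9))
  empty <- make_session(f, tr, licks = tr$reward_time + c(10, 10.2, 10.4))
  # licks far from the trial grid -> aligned rate is zero near the CS
  b0 <- binned_lick_rate(empty, from = -2, to = 5)
  expect_true(all(b0$rate == 0))
  # two licks in one 0.5-s bin over one trial -> 4 licks/s
  s2 <- make_session(f, tr, licks = c(tr$cs_onset + c(0.1, 0.3),
                                      tr$reward_time + c(0.2, 0.5, 0.9)))
  b2 <- binned_lick_rate(s2)
  expect_equal(b2$rate[b2$t == 0], 4)
})

test_that("Poisson lick trains recover their rate on the binned grid", {
  set.seed(81)
  tr <- make_trials(40, first = 5, spacing = 20)
  lam <- 3
  licks <- sort(unlist(lapply(tr$cs_onset, function(cs) {
    k <- rpois(1, lam * 7)
    cs - 2 + sort(runif(k, 0, 7))
  })))
  f <- matrix(rnorm((max(tr$cs_onset) + 15) * 30, 100), 1)
  s <- make_session(f, tr, licks = licks)
  b <- binned_lick_rate(s, from = -2, to = 5)
  se <- sqrt(lam / (0.5 * 40))
  expect_true(all(abs(b$rate - lam) < 4 * se))
})

test_that("anticipatory rate covers [cs, cs + 2.5) only", {
  f <- matrix(rnorm(35 * 30, 100), 1)
  tr <- make_trials(1, first = 5)
  s0 <- make_session(f, tr, licks = tr$reward_time + c(0.3, 0.6, 0.9))
  expect_equal(anticipatory_lick_rate(s0)$rate, 0)
  s5 <- make_session(f, tr, licks = c(tr$cs_onset + seq(0.1, 2.1, 0.5),
                                      tr$reward_time + c(0.3, 0.6, 0.9)))
  expect_equal(anticipatory_lick_rate(s5)$rate, 5 / 2.5)
  # a lick exactly at reward delivery is outside the half-open window
  sb <- make_session(f, tr, licks = c(tr$reward_time,
                                      tr$reward_time + c(0.3, 0.6, 0.9)))
  expect_equal(anticipatory_lick_rate(sb)$rate, 0)
})

test_that("bout segmentation follows the 20-s and 3-s gap rules", {
  f <- matrix(rnorm(80 * 30, 100), 1)
  tr <- make_trials(1, first = 5) # reward at 7.5, session to 80 s
  rw <- tr$reward_time
  one <- make_session(f, tr, licks = sort(c(rw + c(0.2, 0.5, 0.9),
                                            rw + c(25, 25.4, 25.9))))
  b1 <- detect_iti_lick_bouts(one)
  expect_equal(nrow(b1), 1)
  expect_equal(b1$n_licks, 3)
  expect_equal(b1$start, rw + 25)
  expect_true(b1$first_in_iti)

  two <- make_session(f, tr, licks = sort(c(rw + c(0.2, 0.5, 0.9),
                                            rw + 25, rw + 29)))
  b2 <- detect_iti_lick_bouts(two)
  expect_equal(nrow(b2), 2) # separated by >= 3 s
  expect_equal(b2$first_in_iti, c(TRUE, FALSE))

  early <- make_session(f, tr, licks = sort(c(rw + c(0.2, 0.5, 0.9),
                                              rw + 19.9)))
  expect_equal(nrow(detect_iti_lick_bouts(early)), 0) # before the 20-s mark
})

test_that("bouts too close to the next CS are dropped, by bout start", {
  tr <- make_trials(2, first = 5, spacing = 40)
  f <- matrix(rnorm((max(tr$cs_onset) + 15) * 30, 100), 1)
  rw <- tr$reward_time[1]
  next_cs <- tr$cs_onset[2]
  s <- make_session(f, tr, licks = sort(c(tr$reward_time + 0.2,
                                          tr$reward_time + 0.5,
                                          tr$reward_time + 0.9,
                                          next_cs - 2.0)))
  expect_equal(nrow(detect_iti_lick_bouts(s)), 0)
  s2 <- make_session(f, tr, licks = sort(c(tr$reward_time + 0.2,
                                           tr$reward_time + 0.5,
                                           tr$reward_time + 0.9,
                                           next_cs - 2.6)))
  expect_equal(nrow(detect_iti_lick_bouts(s2)), 1)
})

test_that("bout segmentation partitions the eligible licks", {
  set.seed(82)
  tr <- make_trials(3, first = 5, spacing = 60)
  f <- matrix(rnorm((max(tr$cs_onset) + 15) * 30, 100), 1)
  licks <- sort(c(tr$reward_time + 0.2, tr$reward_time + 0.5,
                  tr$reward_time + 0.9, runif(40, 0, max(tr$cs_onset) + 10)))
  s <- make_session(f, tr, licks = licks)
  bouts <- detect_iti_lick_bouts(s)
  if (nrow(bouts) > 1) {
    expect_true(all(bouts$start[-1] >= bouts$end[-nrow(bouts)] + 3 |
                      diff(bouts$iti) > 0))
  }
  # each kept bout's licks are within [start, end] and bouts do not overlap
  expect_true(all(bouts$end >= bouts$start))
})

test_that("bout reliability applies the verbatim criterion to bout windows", {
  tr <- make_trials(1, first = 5)
  f <- matrix(rnorm(80 * 30, 100), 1)
  rw <- tr$reward_time
  licks <- sort(c(rw + c(0.2, 0.5, 0.9), rw + 25, rw + 35, rw + 45, rw + 55))
  s <- make_session(f, tr, licks = licks)
  bouts <- detect_iti_lick_bouts(s)
  expect_equal(nrow(bouts), 4)
  z <- matrix(0, 2, ncol(f))
  # neuron 1 responds in bouts 1 and 3 only
  for (b in c(1, 3)) {
    i0 <- floor(bouts$start[b] * 30) + 1
    z[1, i0 + 2:10] <- 2
  }
  a <- fake_analysis(z, s)
  br <- bout_reliability(a, bouts)
  expect_equal(br$bout_reliability[br$neuron == 1], 50)
  expect_equal(br$bout_reliability[br$neuron == 2], 0)
})

test_that("lick cells are recovered and null neurons stay unlabelled", {
  set.seed(83)
  cfg <- generator_config(
    n_mice = 1, n_neurons_per_mouse = 12, n_trials = 10,
    iti_range = c(30, 40), t_session = "auto", days = 1,
    class_fractions = c(lick = 0.5, untuned = 0.5),
    response_prob_day1 = 1, amplitude = 4, bout_rate = 1 / 10,
    spont_rate = 0, seed = 84)
  sim <- simulate_cohort(cfg)
  s <- cohort_session(sim$cohort, "m01", 1)
  bouts <- detect_iti_lick_bouts(s)
  expect_gte(sum(bouts$first_in_iti), 2)
  a <- analyze_session(s, detect = FALSE)
  lc <- classify_lick_cells(a, bouts)
  classes <- sim$truth$specs$tuned_class
  expect_gte(mean(lc$lick_cell[classes == "lick"]), 0.5)
  expect_lte(mean(lc$lick_cell[classes == "untuned"]), 0.25)
})

test_that("mixed selectivity recovers a CS-driven cell", {
  set.seed(85)
  cfg <- generator_config(
    n_mice = 1, n_neurons_per_mouse = 6, n_trials = 12,
    iti_range = c(30, 40), t_session = "auto", days = 1,
    class_fractions = c(cs = 1), response_prob_day1 = 1, amplitude = 4,
    spont_rate = 0, seed = 86)
  sim <- simulate_cohort(cfg)
  s <- cohort_session(sim$cohort, "m01", 1)
  a <- analyze_session(s, detect = FALSE)
  ms <- classify_mixed_selectivity(a, a$active)
  expect_gte(mean(ms$category %in% c("cs", "cs_and_reward")), 0.8)
})
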