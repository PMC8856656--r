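test_that("a fixed seed reproduces the cohort exactly", {
  cfg <- generator_config(n_mice = 2, n_neurons_per_mouse = 4, n_trials = 5,
                          iti_range = c(15, 25), t_session = "auto", seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$cohort$sessions[["m02.7"]]$fluorescence,
                   b$cohort$sessions[["m02.7"]]$fluorescence)
  expect_identical(a$cohort$sessions[["m01.1"]]$licks,
                   b$cohort$sessions[["m01.1"]]$licks)
  expect_identical(a$truth$responses, b$truth$responses)
})

test_that("an all-untuned noiseless cohort contains no evoked transients", {
  cfg <- generator_config(n_mice = 1, n_neurons_per_mouse = 3, n_trials = 4,
                          iti_range = c(15, 25), t_session = "auto",
                          class_fractions = c(untuned = 1), noise_sd = 0,
                          spont_rate = 0, drift = c(0, 600), days = 1,
                          seed = 3)
  sim <- simulate_cohort(cfg)
  expect_true(is.null(sim$truth$responses) ||
                !any(sim$truth$responses$responded))
  f <- cohort_session(sim$cohort, "m01", 1)$fluorescence
  # flat baseline only: each neuron's trace is constant
  expect_lt(max(apply(f, 1, function(r) diff(range(r)))), 1e-9)
})

test_that("paired inter-CS gaps equal the trial span plus the drawn ITI", {
  cfg <- generator_config(n_mice = 1, n_neurons_per_mouse = 1, n_trials = 32,
                          days = 1, seed = 5)
  sim <- simulate_cohort(cfg)
  gaps <- diff(cohort_session(sim$cohort, "m01", 1)$trials$cs_onset)
  expect_true(all(gaps >= 62.5 & gaps <= 122.5))
})

test_that("the generator errors when the trial block cannot fit", {
  cfg <- generator_config(n_mice = 1, n_neurons_per_mouse = 1, n_trials = 32,
                          t_session = 100, seed = 1)
  expect_error(simulate_cohort(cfg), "too short")
})

test_that("lick simulation matches its configured rates", {
  w <- analysis_windows()
  trials <- make_trials(32, first = 20, spacing = 40)
  rates <- c(iti_bout = 1.5, anticipatory = 3.5, reward_burst = 7.2)
  t_sess <- max(trials$reward_time) + 30

  set.seed(21)
  lk <- simulate_licks(trials, "paired", learned = TRUE, rates,
                       bout_rate = 1 / 60, t_sess, w)
  n_ant <- sum(vapply(trials$cs_onset, function(cs) {
    sum(lk$licks >= cs & lk$licks < cs + 2.5)
  }, numeric(1)))
  lambda <- 3.5 * 2.5 * 32
  expect_lt(abs(n_ant - lambda), 3 * sqrt(lambda)) # Poisson 3-sigma

  set.seed(22)
  lk0 <- simulate_licks(trials, "paired", learned = FALSE, rates,
                        bout_rate = 1 / 60, t_sess, w)
  n0 <- sum(vapply(trials$cs_onset, function(cs) {
    sum(lk0$licks >= cs & lk0$licks < cs + 2.5)
  }, numeric(1)))
  lambda0 <- 1.5 * 2.5 * 32 # unlearned CS-window licking at the bout rate
  expect_lt(abs(n0 - lambda0), 3 * sqrt(lambda0))

  lk_none <- simulate_licks(trials, "paired", learned = TRUE,
                            c(iti_bout = 0, anticipatory = 0,
                              reward_burst = 0), 1 / 60, t_sess, w)
  expect_length(lk_none$licks, 0)
})

test_that("transient kernel peaks at its closed-form maximum", {
  cfg <- generator_config(n_mice = 1, n_neurons_per_mouse = 1, n_trials = 1,
                          noise_sd = 0, drift = c(0, 600), spont_rate = 0,
                          latency = 0, latency_jitter = 0, amplitude = 5,
                          iti_range = c(15, 25), t_session = "auto")
  trials <- tibble::tibble(cs_onset = 10, reward_time = 12.5)
  lk <- list(licks = numeric(), bout_starts = numeric(),
             burst_starts = NA_real_)
  set.seed(2)
  sim <- simulate_trace("cs", 1, 5, trials, lk, cfg, t_session = 30,
                        baseline_f = 100)
  tau_r <- 0.05; tau_d <- 0.6
  t_peak <- tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)
  peak_frame <- which.max(sim$f)
  expected_frame <- floor((10 + t_peak) * 30) + 1
  expect_lte(abs(peak_frame - expected_frame), 1)
  expect_equal(max(sim$f) - 100, 5, tolerance = 0.02)
})

test_that("zero amplitude leaves baseline plus noise only", {
  cfg <- generator_config(noise_sd = 1, drift = c(0, 600), spont_rate = 0)
  trials <- tibble::tibble(cs_onset = 10, reward_time = 12.5)
  lk <- list(licks = numeric(), bout_starts = numeric(),
             burst_starts = NA_real_)
  set.seed(4)
  sim <- simulate_trace("cs", 1, 0, trials, lk, cfg, t_session = 30,
                        baseline_f = 100)
  expect_equal(mean(sim$f), 100, tolerance = 0.2)
  expect_equal(sd(sim$f), 1, tolerance = 0.15)
})

test_that("recorded response booleans match the injected transients", {
  cfg <- generator_config(n_mice = 1, n_neurons_per_mouse = 20, n_trials = 32,
                          iti_range = c(15, 25), t_session = "auto",
                          class_fractions = c(cs = 1), days = 1,
                          spont_rate = 0, response_prob_day1 = 0.5, seed = 31)
  sim <- simulate_cohort(cfg)
  n_true <- sum(sim$truth$responses$responded)
  n_events <- sum(sim$truth$events$kind == "stimulus")
  expect_equal(n_true, n_events) # conservation
  # per-neuron counts lie inside exact Binomial(32, 0.5) 99.9% bounds
  per_neuron <- tapply(sim$truth$responses$responded,
                       sim$truth$responses$neuron, sum)
  bounds <- qbinom(c(5e-4, 1 - 5e-4), 32, 0.5)
  expect_true(all(per_neuron >= bounds[1] & per_neuron <= bounds[2]))
})

test_that("class fractions must sum to one", {
  expect_error(generator_config(class_fractions = c(cs = 0.5, untuned = 0.4)),
               "sum to 1")
})
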