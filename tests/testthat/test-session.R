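test_that("session containers round-trip losslessly", {
  set.seed(11)
  f <- matrix(rnorm(2 * 900, mean = 100, sd = 5), nrow = 2)
  trials <- tibble::tibble(cs_onset = c(5, 5 + runif(1, 8, 9)))
  trials$reward_time <- trials$cs_onset + 2.5
  s <- make_session(f, trials, licks = sort(runif(20, 0, 19)))
  path <- file.path(tempdir(), "sess_rt")
  write_session(s, path)
  s2 <- read_session(path)
  expect_identical(s2$fluorescence, s$fluorescence)
  expect_identical(s2$trials$cs_onset, s$trials$cs_onset)
  expect_identical(s2$trials$reward_time, s$trials$reward_time)
  expect_identical(s2$licks, s$licks)
  expect_equal(s2$mouse_id, s$mouse_id)
  expect_equal(s2$frame_rate, s$frame_rate)
  expect_equal(s2$t_session, s$t_session)
  unlink(path, recursive = TRUE)
})

test_that("zero-ROI sessions write and re-read with zero ROIs", {
  s <- make_session(matrix(numeric(), 0, 500))
  path <- file.path(tempdir(), "sess_empty")
  write_session(s, path)
  s2 <- read_session(path)
  expect_equal(nrow(s2$fluorescence), 0)
  expect_equal(ncol(s2$fluorescence), 500)
  unlink(path, recursive = TRUE)
})

test_that("a container missing its lick table fails naming the field", {
  s <- make_session(matrix(rnorm(500, 100), 1))
  path <- file.path(tempdir(), "sess_nolick")
  write_session(s, path)
  unlink(file.path(path, "licks.csv"))
  expect_error(read_session(path), "licks")
  unlink(path, recursive = TRUE)
})

test_that("constructor rejects malformed sessions", {
  f <- matrix(rnorm(600, 100), 1)
  expect_error(make_session(f, licks = c(3, 1, 2)), "sorted")
  tr <- tibble::tibble(cs_onset = 5, reward_time = 4)
  expect_error(make_session(f, tr), "reward_time")
  # trial window extending past the end of the trace
  tr2 <- tibble::tibble(cs_onset = 15, reward_time = 17.5)
  expect_error(make_session(f, tr2, licks = 17.7), "session|trace")
})

test_that("validate_cohort reports violations as data and is side-effect free", {
  set.seed(12)
  mk <- function(m, d) make_session(matrix(rnorm(2 * 600, 100), 2),
                                    mouse = m, day = d)
  cohort <- ca_cohort(list(mk("a", 1), mk("a", 7), mk("b", 1), mk("b", 7)))
  expect_equal(nrow(validate_cohort(cohort)), 0)

  bad <- cohort
  bad$tracked_cells$neuron_day7[1] <- 99L
  v <- validate_cohort(bad)
  expect_equal(nrow(v), 1)
  expect_equal(v$field, "tracked_cells")

  # trial whose post-window exceeds t_session (mutated past the constructor)
  bad2 <- cohort
  bad2$sessions[["a.1"]]$trials$cs_onset <- bad2$sessions[["a.1"]]$t_session - 1
  v2 <- validate_cohort(bad2)
  expect_true(any(v2$mouse_id == "a" & v2$day == 1 & v2$field == "trials"))
  # idempotent
  expect_identical(validate_cohort(bad2), v2)
})

test_that("generator sessions survive a write/read cycle exactly", {
  cfg <- generator_config(n_mice = 1, n_neurons_per_mouse = 3, n_trials = 4,
                          iti_range = c(15, 25), t_session = "auto",
                          days = 1, seed = 99)
  sim <- simulate_cohort(cfg)
  s <- cohort_session(sim$cohort, "m01", 1)
  path <- file.path(tempdir(), "sess_gen")
  write_session(s, path)
  s2 <- read_session(path)
  expect_equal(nrow(s2$trials), 4)
  expect_identical(s2$fluorescence, s$fluorescence)
  expect_identical(s2$licks, s$licks)
  unlink(path, recursive = TRUE)
})
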