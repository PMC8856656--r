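test_that("stimulus indicators tile the aligned grid as specified", {
  ind_cs <- stimulus_indicator("cs")
  ind_rw <- stimulus_indicator("reward")
  expect_length(ind_cs, 390) # 13 s at 30 Hz
  expect_equal(which(ind_cs), 61:135)  # [2, 4.5) s on the grid
  expect_equal(which(ind_rw), 136:210) # [4.5, 7) s
  expect_false(any(ind_cs & ind_rw))
})

test_that("trial averaging is the frame-wise mean of aligned snippets", {
  set.seed(71)
  grid <- 390
  snippet <- rnorm(grid)
  z <- c(rep(0, 60), rep(snippet, 3), rep(0, 60))
  starts <- 2 + (0:2) * 13 + 2 # cs onsets: snippet k starts at 60+k*390 frames
  avg <- trial_averaged_trace(z, starts, frame_rate = 30)
  expect_equal(avg, snippet, tolerance = 1e-12)
  # antisymmetric snippets cancel
  z2 <- c(rep(0, 60), snippet, -snippet, rep(0, 60))
  avg2 <- trial_averaged_trace(z2, starts[1:2], frame_rate = 30)
  expect_equal(avg2, rep(0, grid), tolerance = 1e-12)
  expect_error(trial_averaged_trace(z, 0.5, frame_rate = 30), "outside")
})

test_that("averaging over trials grows SNR like sqrt(n)", {
  set.seed(72)
  grid <- 390
  n_tr <- 32
  z <- rnorm(60 + n_tr * grid + 60)
  starts <- 2 + (0:(n_tr - 1)) * 13
  avg <- trial_averaged_trace(z, starts, frame_rate = 30)
  expect_equal(sd(avg), 1 / sqrt(n_tr), tolerance = 0.25)
})

test_that("Spearman tuning matches the brute-force rank oracle", {
  toy <- c(0.1, 0.4, 0.2, 0.9, 0.8)
  ind <- c(FALSE, FALSE, FALSE, TRUE, TRUE)
  expect_equal(spearman_tuning(toy, ind), spearman_oracle(toy, ind),
               tolerance = 1e-12)
  set.seed(73)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    x <- round(rnorm(n), 1) # rounding forces ties
    y <- runif(n) < 0.3
    if (all(y) || !any(y) || sd(x) == 0) next
    expect_equal(spearman_tuning(x, y), spearman_oracle(x, y),
                 tolerance = 1e-12)
    expect_equal(spearman_tuning(x, y),
                 suppressWarnings(cor(x, as.numeric(y), method = "spearman")),
                 tolerance = 1e-12)
  }
})

test_that("perfectly (anti)concordant traces hit the bounds", {
  ind <- stimulus_indicator("cs")
  expect_equal(spearman_tuning(2 + 3 * ind, ind), 1)
  expect_equal(spearman_tuning(-as.numeric(ind), ind), -1)
  expect_true(is.na(spearman_tuning(rep(1, 390), ind)))
})

test_that("rho is invariant under strictly increasing transforms", {
  set.seed(74)
  x <- rnorm(390)
  ind <- stimulus_indicator("cs")
  expect_equal(spearman_tuning(x, ind), spearman_tuning(exp(x), ind),
               tolerance = 1e-12)
})

test_that("delta-rho-bar balances mice regardless of cell counts", {
  tun <- tibble::tibble(
    mouse_id = c(rep("a", 2), rep("b", 4)),
    day = 1L, neuron = c(1:2, 1:4), stimulus = "cs",
    rho = 0.1
  )
  tun7 <- tun
  tun7$day <- 7L
  tun7$rho <- 0.1 + c(0.2, 0.2, -0.1, -0.1, -0.1, -0.1)
  out <- mean_delta_rho(dplyr::bind_rows(tun, tun7), "cs")
  expect_equal(out$delta_rho_bar, (0.2 - 0.1) / 2) # equal mouse weights
  # duplicating mouse b's cells leaves its weight unchanged
  dup <- dplyr::bind_rows(tun, tun7)
  extra <- dup[dup$mouse_id == "b", ]
  extra$neuron <- extra$neuron + 10L
  out2 <- mean_delta_rho(dplyr::bind_rows(dup, extra), "cs")
  expect_equal(out2$delta_rho_bar, out$delta_rho_bar)
  # all cells unchanged -> zero
  out0 <- mean_delta_rho(dplyr::bind_rows(tun, dplyr::mutate(tun, day = 7L)),
                         "cs")
  expect_equal(out0$delta_rho_bar, 0)
})

test_that("the delta-rho null enforces its iteration floor", {
  f <- matrix(rnorm(600, 100), 1)
  s1 <- make_session(f)
  a1 <- fake_analysis(matrix(rnorm(600), 1), s1)
  expect_error(null_mean_delta_rho(list(a1), list(a1), n_iter = 50), "100")
})
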