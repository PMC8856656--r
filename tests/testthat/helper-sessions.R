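# small programmatic fixtures shared across the suite

# paired trial table with regular spacing
make_trials <- function(n = 3, first = 10, spacing = 20) {
  cs <- first + (seq_len(n) - 1) * spacing
  tibble::tibble(cs_onset = cs, reward_time = cs + 2.5)
}

# minimal valid paired session around a given fluorescence matrix
make_session <- function(f, trials = NULL, licks = NULL, mouse = "m01",
                         day = 1L, paradigm = "paired", frame_rate = 30) {
  if (!is.matrix(f)) f <- matrix(f, nrow = 1)
  if (is.null(trials)) trials <- make_trials(1, first = 5)
  if (is.null(licks)) {
    # three prompt licks per reward so every trial passes the inclusion filter
    rw <- trials$reward_time[!is.na(trials$reward_time)]
    licks <- sort(c(rw + 0.2, rw + 0.5, rw + 0.9))
  }
  ca_session(f, trials, licks, mouse_id = mouse, day = day,
             paradigm = paradigm, frame_rate = frame_rate)
}

# fabricated analysis bundle for operations that only consume z/profiles
fake_analysis <- function(z, session, z_thresh = 1, min_run = 5) {
  if (!is.matrix(z)) z <- matrix(z, nrow = 1)
  w <- analysis_windows()
  win <- as.integer(round(w$response_window * session$frame_rate))
  profiles <- vapply(seq_len(nrow(z)), function(i) {
    as.integer(catrace:::cpp_window_profile(z[i, ], z_thresh, min_run, win))
  }, integer(ncol(z) - win + 1L))
  structure(
    list(session = session, windows = w, z = z, zparams = NULL,
         events = NULL, neurons = seq_len(nrow(z)),
         active = seq_len(nrow(z)), profiles = profiles,
         pct_active = 100, z_thresh = z_thresh, min_run = min_run),
    class = "ca_session_analysis"
  )
}

# exhaustive circular-shift exceedance oracle, independent R implementation
exhaustive_exceedance_oracle <- function(x) {
  L <- length(x)
  counts <- integer(L)
  for (s in seq_len(L - 1)) {
    shifted <- x[((seq_len(L) - 1 - s) %% L) + 1]
    counts <- counts + (x > shifted)
  }
  counts
}

# brute-force Spearman oracle: average ranks then Pearson on ranks
spearman_oracle <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
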