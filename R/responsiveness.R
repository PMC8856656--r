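# ---- session analysis bundle -------------------------------------------

#' Preprocess one session and identify its active neurons
#'
#' Convenience bundle used by the higher-level analyses: runs
#' [preprocess_session()], optionally [detect_events()] on dF, intersects
#' the event-active set with the non-degenerate set, and precomputes each
#' active neuron's 2.5-s window-responsiveness profile (for every possible
#' window start frame, does a run of `min_run` frames above `z_thresh` z lie
#' entirely inside the window?). The profile makes trial responsiveness,
#' the Monte-Carlo nulls, and the random-reliability controls O(1) per
#' window.
#'
#' @param session A [ca_session()].
#' @param windows [analysis_windows()].
#' @param neurons ROIs to analyse (default all; pass the tracked subset to
#'   honour the cross-day tracking rule).
#' @param detect Run the circular-shift event filter (set `FALSE` to treat
#'   every non-degenerate neuron as active, e.g. in calibration studies
#'   that target the downstream statistics).
#' @param n_shifts,min_count Event-detection parameters.
#' @param z_thresh,min_run Trial-responsiveness criterion (z > 1 for >= 5
#'   consecutive frames).
#' @return An object of class `ca_session_analysis`.
#' @export
analyze_session <- function(session, windows = analysis_windows(),
                            neurons = NULL, detect = TRUE,
                            n_shifts = 1000, min_count = 950,
                            z_thresh = 1, min_run = 5) {
  neurons <- neurons %||% seq_len(nrow(session$fluorescence))
  pp <- preprocess_session(session, windows)
  ok <- neurons[!pp$zparams$degenerate[neurons]]
  if (detect) {
    ev <- detect_events(pp$delta_f[neurons, , drop = FALSE],
                        n_shifts = n_shifts, min_count = min_count,
                        min_run = min_run, frame_rate = session$frame_rate)
    active <- intersect(neurons[filter_active_neurons(ev)], ok)
    pct_active <- percent_active(ev)
  } else {
    ev <- NULL
    active <- ok
    pct_active <- 100 * length(ok) / length(neurons)
  }
  win_frames <- window_n_frames(windows$response_window, session$frame_rate)
  profiles <- matrix(
    0L, nrow = ncol(session$fluorescence) - win_frames + 1L,
    ncol = length(active)
  )
  for (j in seq_along(active)) {
    profiles[, j] <- as.integer(cpp_window_profile(
      pp$z[active[j], ], z_thresh, as.integer(min_run), win_frames))
  }
  structure(
    list(session = session, windows = windows, z = pp$z,
         zparams = pp$zparams, events = ev, neurons = neurons,
         active = active, profiles = profiles, pct_active = pct_active,
         z_thresh = z_thresh, min_run = min_run),
    class = "ca_session_analysis"
  )
}

#' @export
print.ca_session_analysis <- function(x, ...) {
  cat(sprintf("<ca_session_analysis> mouse %s day %d: %d/%d neurons active\n",
              x$session$mouse_id, x$session$day, length(x$active),
              length(x$neurons)))
  invisible(x)
}

# ---- trial inclusion and response windows ------------------------------

#' Which trials meet the behavioural inclusion criterion?
#'
#' A trial enters the neural analyses only when the mouse licked at least
#' three times within 2.5 s of reward delivery; tone-only sessions have no
#' reward criterion and include every trial.
#'
#' @param session A [ca_session()].
#' @param windows [analysis_windows()].
#' @return Logical vector, one element per trial.
#' @export
included_trials <- function(session, windows = analysis_windows()) {
  if (session$paradigm == "tone_only") {
    return(rep(TRUE, nrow(session$trials)))
  }
  vapply(session$trials$reward_time, function(rw) {
    if (is.na(rw)) return(FALSE)
    sum(session$licks >= rw & session$licks < rw + windows$response_window) >= 3
  }, logical(1))
}

#' Start of the stimulus response window for each trial
#'
#' CS windows open at the CS onset. Reward windows open at reward delivery
#' in the paired task; in the nonpaired task (where mice take a variable
#' time to notice the unsignalled water) they open at the first lick after
#' delivery, and trials with no lick before the next tone are excluded
#' (`NA`).
#'
#' @param session A [ca_session()].
#' @param stimulus `"cs"` or `"reward"`.
#' @return Numeric vector of window starts (s), `NA` where undefined.
#' @export
response_window_start <- function(session, stimulus = c("cs", "reward")) {
  stimulus <- match.arg(stimulus)
  tr <- session$trials
  if (stimulus == "cs") return(tr$cs_onset)
  if (session$paradigm == "tone_only") return(rep(NA_real_, nrow(tr)))
  if (session$paradigm == "paired") return(tr$reward_time)
  next_cs <- c(tr$cs_onset[-1], Inf)
  vapply(seq_len(nrow(tr)), function(i) {
    rw <- tr$reward_time[i]
    if (is.na(rw)) return(NA_real_)
    lk <- session$licks[session$licks >= rw & session$licks < next_cs[i]]
    if (length(lk) == 0) NA_real_ else lk[1]
  }, numeric(1))
}

#' Trial-by-trial responsiveness of one z-scored trace
#'
#' A trial counts as responsive when some run of at least `min_run`
#' consecutive frames with `z > z_thresh` (strict) lies entirely inside the
#' half-open window `[window_start, window_start + window_len)`.
#'
#' @param z One neuron's z-scored dF trace.
#' @param window_start Window start (s).
#' @param frame_rate Hz.
#' @param z_thresh,min_run Criterion parameters.
#' @param window_len Window length (s).
#' @return Logical scalar.
#' @export
is_trial_responsive <- function(z, window_start, frame_rate, z_thresh = 1,
                                min_run = 5, window_len = 2.5) {
  idx <- window_frames(window_start, window_len, frame_rate)
  if (min(idx) < 1 || max(idx) > length(z)) abort("window outside the trace")
  has_run_above(z[idx], z_thresh, min_run)
}

# ---- responsiveness and reliability tables -----------------------------

#' Per-neuron, per-trial CS/reward responsiveness
#'
#' @param analysis An [analyze_session()] result.
#' @param stimuli Which stimuli to evaluate.
#' @return Tibble: `mouse_id`, `day`, `neuron`, `trial`, `stimulus`,
#'   `included`, `window_start`, `responsive`. `included` combines the
#'   behavioural lick criterion with window availability.
#' @export
responsiveness_table <- function(analysis, stimuli = c("cs", "reward")) {
  s <- analysis$session
  if (s$paradigm == "tone_only") stimuli <- intersect(stimuli, "cs")
  inc <- included_trials(s, analysis$windows)
  purrr::map_dfr(stimuli, function(stim) {
    starts <- response_window_start(s, stim)
    rows <- frame_of_time(starts, s$frame_rate)
    purrr::map_dfr(seq_along(analysis$active), function(j) {
      resp <- rep(NA, length(starts))
      okw <- !is.na(starts)
      resp[okw] <- analysis$profiles[rows[okw], j] == 1L
      tibble(
        mouse_id = s$mouse_id, day = s$day, neuron = analysis$active[j],
        trial = seq_along(starts), stimulus = stim,
        included = inc & okw, window_start = starts, responsive = resp
      )
    })
  })
}

#' Reliability index per neuron
#'
#' Percent of included trials on which the neuron met the responsiveness
#' criterion for the stimulus.
#'
#' @param resp A [responsiveness_table()] (rows from one or more sessions).
#' @return Tibble: `mouse_id`, `day`, `neuron`, `stimulus`, `reliability`,
#'   `n_included`. Neurons with zero included trials are dropped.
#' @export
reliability_table <- function(resp) {
  resp %>%
    filter(.data$included) %>%
    group_by(.data$mouse_id, .data$day, .data$neuron, .data$stimulus) %>%
    summarise(reliability = 100 * mean(.data$responsive),
              n_included = n(), .groups = "drop")
}

#' Percent-responsive summary with the task's pooling convention
#'
#' Per included trial, the percent of active neurons responsive; per mouse,
#' the median over its trials; at the cohort level, the mean over mice.
#'
#' @param resp A [responsiveness_table()] over the cohort (one day).
#' @return List of tibbles `per_trial`, `per_mouse`, `summary` (one row per
#'   day x stimulus with `mean_percent`, `sem`, `n_mice`).
#' @export
percent_responsive_summary <- function(resp) {
  per_trial <- resp %>%
    filter(.data$included) %>%
    group_by(.data$mouse_id, .data$day, .data$stimulus, .data$trial) %>%
    summarise(percent = 100 * mean(.data$responsive), .groups = "drop")
  per_mouse <- per_trial %>%
    group_by(.data$mouse_id, .data$day, .data$stimulus) %>%
    summarise(median_percent = median(.data$percent),
              n_trials = n(), .groups = "drop")
  summary <- per_mouse %>%
    group_by(.data$day, .data$stimulus) %>%
    summarise(mean_percent = mean(.data$median_percent),
              sem = sd(.data$median_percent) / sqrt(n()),
              n_mice = n(), .groups = "drop")
  list(per_trial = per_trial, per_mouse = per_mouse, summary = summary)
}

# ---- Monte-Carlo null objects ------------------------------------------

new_mc_test <- function(observed, null_values, bonferroni_m = 1,
                        label = "", n = NA_integer_) {
  null_values <- null_values[is.finite(null_values)]
  k <- length(null_values)
  p_lower <- (1 + sum(null_values <= observed)) / (k + 1)
  p_upper <- (1 + sum(null_values >= observed)) / (k + 1)
  p_two <- min(1, 2 * min(p_lower, p_upper))
  outside <- observed > max(null_values) || observed < min(null_values)
  stars <- if (outside) "***" else if (p_two <= 0.01) "**"
  else if (p_two <= 0.05) "*" else "n.s."
  structure(
    list(observed = observed, null_values = null_values, n_iter = k,
         p_lower = p_lower, p_upper = p_upper, p_two = p_two,
         p_adjusted = min(1, p_two * bonferroni_m),
         bonferroni_m = bonferroni_m, stars = stars,
         significant = p_two <= 0.05,
         significant_adjusted = min(1, p_two * bonferroni_m) <= 0.05,
         direction = if (observed >= median(null_values)) "upper" else "lower",
         label = label, n = n),
    class = "ca_mc_test"
  )
}

#' @export
print.ca_mc_test <- function(x, ...) {
  cat(sprintf(
    "<ca_mc_test> %s\n  observed %.3f vs null [%.3f, %.3f] (%d iterations)\n  p = %.4g (%s tail), Bonferroni m = %d -> p = %.4g %s\n",
    x$label, x$observed, min(x$null_values), max(x$null_values), x$n_iter,
    x$p_two, x$direction, x$bonferroni_m, x$p_adjusted, x$stars
  ))
  invisible(x)
}

#' Monte-Carlo null for the percent of responsive neurons
#'
#' Resamples the cohort under the null that responses are unrelated to the
#' task: each iteration bootstraps mice with replacement; for every sampled
#' mouse it draws as many uniformly placed 2.5-s windows as that mouse has
#' included trials, scores each active neuron with the same z/run
#' criterion, takes the per-draw percent responsive, the median over draws
#' and the mean over mice. The observed cohort mean percent is then
#' compared with the two tails of the resulting distribution.
#'
#' @param analyses List of [analyze_session()] results, one mouse each
#'   (same day and cell type).
#' @param stimulus `"cs"` or `"reward"`.
#' @param n_iter Null iterations (>= 100).
#' @param bonferroni_m Number of simultaneous comparisons the verdict is
#'   corrected for (2 stimuli x 2 days = 4 in the standard report).
#' @return A `ca_mc_test` with the observed value, the null sample, exact
#'   resampling p-values, and the star verdict (`***` when the observed
#'   value lies outside the whole null sample).
#' @export
null_percent_responsive <- function(analyses, stimulus = "cs", n_iter = 1000,
                                    bonferroni_m = 4) {
  if (n_iter < 100) abort("n_iter must be >= 100")
  resp <- purrr::map_dfr(analyses, responsiveness_table, stimuli = stimulus)
  obs_tbl <- percent_responsive_summary(resp)
  observed <- obs_tbl$summary$mean_percent[1]
  n_draws <- vapply(analyses, function(a) {
    s <- a$session
    sum(included_trials(s, a$windows) &
          !is.na(response_window_start(s, stimulus)))
  }, integer(1))
  keep <- n_draws > 0 & vapply(analyses, function(a) length(a$active) > 0, logical(1))
  if (!all(keep)) {
    warn(sprintf("%d mouse/mice without included trials or active neurons excluded",
                 sum(!keep)))
  }
  profiles <- lapply(analyses[keep], `[[`, "profiles")
  null_values <- cpp_null_percent_responsive(profiles, n_draws[keep],
                                             as.integer(n_iter))
  day <- analyses[[1]]$session$day
  out <- new_mc_test(
    observed, null_values, bonferroni_m,
    label = sprintf("percent %s-responsive, day %d", stimulus, day),
    n = sum(vapply(analyses, function(a) length(a$active), integer(1)))
  )
  out$per_mouse <- obs_tbl$per_mouse
  out$stimulus <- stimulus
  out$day <- day
  out
}

# ---- reliability groups and learning-related changes -------------------

#' Split neurons into High/Low reliability groups
#'
#' The threshold is the 50th percentile (linear interpolation) of the
#' nonzero day-1 reliability indices pooled across mice for one cell type
#' and stimulus. Neurons at or below the threshold fall into the Low group;
#' above it, High. Day-1 nonresponders (index 0) are excluded from the
#' threshold computation but assigned to the Low group so their day-7 fate
#' can be followed; the `responder` column keeps them identifiable.
#'
#' @param day1_index Numeric vector of day-1 reliability indices (percent).
#' @return Tibble with `day1_index`, `group` (`"High"`/`"Low"`), and
#'   `responder`; the threshold is attached as attribute `threshold`.
#' @export
split_by_reliability <- function(day1_index) {
  nz <- day1_index[day1_index > 0]
  if (length(nz) == 0) {
    warn("all reliability indices are zero; no High/Low split possible")
    out <- tibble(day1_index = day1_index, group = NA_character_,
                  responder = FALSE)
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  thr <- unname(quantile(nz, 0.5, type = 7))
  out <- tibble(
    day1_index = day1_index,
    group = ifelse(day1_index > thr, "High", "Low"),
    responder = day1_index > 0
  )
  attr(out, "threshold") <- thr
  out
}

#' Change in reliability between days
#' @param day1,day7 Reliability indices (percent), matched per neuron.
#' @return `day7 - day1` in percentage points.
#' @export
delta_reliability <- function(day1, day7) day7 - day1

#' Random-sampling control for the change in reliability
#'
#' For each neuron, the day-7 session is sampled irrespective of the task:
#' as many uniformly placed 2.5-s windows as there are day-7 included
#' trials, scored with the verbatim responsiveness criterion, give a
#' "random reliability"; the control is `random - day1`.
#'
#' @param analysis_day7 The day-7 [analyze_session()] for the mouse.
#' @param neurons Neuron indices (must be active in `analysis_day7`).
#' @param day1_index Matched day-1 reliability indices (percent).
#' @param n_draws Number of windows (default: day-7 included trial count).
#' @return Tibble: `neuron`, `random_reliability`, `delta_random`.
#' @export
delta_reliability_random <- function(analysis_day7, neurons, day1_index,
                                     n_draws = NULL) {
  s <- analysis_day7$session
  n_draws <- n_draws %||% sum(included_trials(s, analysis_day7$windows))
  W <- nrow(analysis_day7$profiles)
  cols <- match(neurons, analysis_day7$active)
  if (anyNA(cols)) abort("all neurons must be active in the day-7 analysis")
  rand_rel <- vapply(cols, function(j) {
    starts <- sample.int(W, n_draws, replace = TRUE)
    100 * mean(analysis_day7$profiles[starts, j])
  }, numeric(1))
  tibble(neuron = neurons, random_reliability = rand_rel,
         delta_random = rand_rel - day1_index)
}

#' Onset latency of stimulus-evoked activity
#'
#' Latency on each responsive trial is the time from the window start to
#' the fifth frame of the first qualifying run (>= `min_run` frames above
#' threshold inside the response window); per neuron, the mean over its
#' responsive trials.
#'
#' @param analysis An [analyze_session()] result.
#' @param stimulus `"cs"` or `"reward"`; reward latencies in the nonpaired
#'   task are measured from the first post-reward lick.
#' @return Tibble: `mouse_id`, `day`, `neuron`, `latency_s`, `n_trials`.
#'   Neurons with no responsive trial are omitted.
#' @export
onset_latency <- function(analysis, stimulus = "cs") {
  s <- analysis$session
  rate <- s$frame_rate
  w <- analysis$windows
  starts <- response_window_start(s, stimulus)
  inc <- included_trials(s, w) & !is.na(starts)
  min_run <- analysis$min_run
  purrr::map_dfr(analysis$active, function(nr) {
    z <- analysis$z[nr, ]
    lat <- c()
    for (tr in which(inc)) {
      idx <- window_frames(starts[tr], w$response_window, rate)
      rs <- which(cpp_run_starts(z[idx], analysis$z_thresh, as.integer(min_run)))
      rs <- rs[rs + min_run - 1 <= length(idx)]
      if (length(rs) > 0) lat <- c(lat, (rs[1] - 1 + min_run - 1) / rate)
    }
    if (length(lat) == 0) return(NULL)
    tibble(mouse_id = s$mouse_id, day = s$day, neuron = nr,
           latency_s = mean(lat), n_trials = length(lat))
  })
}

#' Median onset latency per mouse
#' @param latencies An [onset_latency()] table (possibly several mice).
#' @return Tibble with one row per mouse: `median_latency_s`, `n_neurons`.
#' @export
onset_latency_by_mouse <- function(latencies) {
  latencies %>%
    group_by(.data$mouse_id, .data$day) %>%
    summarise(median_latency_s = median(.data$latency_s),
              n_neurons = n(), .groups = "drop")
}

#' Cross-day fate of day-1 responders
#'
#' Among neurons responsive to `stimulus` on day 1 (reliability > 0), the
#' fractions that maintained the response on day 7, switched (lost it but
#' responded to the other stimulus), or lost responsiveness to both.
#'
#' @param rel Reliability table over both days and stimuli (pooled across
#'   mice), as from [reliability_table()] on tracked neurons.
#' @param stimulus Stimulus whose day-1 responders are followed.
#' @return One-row tibble: `maintained`, `switched`, `lost`, `n_day1`.
#' @export
cross_day_fate <- function(rel, stimulus = "cs") {
  other <- setdiff(c("cs", "reward"), stimulus)
  wide <- rel %>%
    select("mouse_id", "day", "neuron", "stimulus", "reliability") %>%
    tidyr::pivot_wider(names_from = c("stimulus", "day"),
                       values_from = "reliability",
                       names_glue = "{stimulus}_d{day}")
  need <- c(paste0(stimulus, "_d1"), paste0(stimulus, "_d7"),
            paste0(other, "_d7"))
  for (col in need) if (!col %in% names(wide)) wide[[col]] <- NA_real_
  d1 <- wide[[need[1]]]
  responders <- !is.na(d1) & d1 > 0
  if (!any(responders)) {
    warn("no day-1 responders for this stimulus")
    return(tibble(stimulus = stimulus, maintained = NA_real_,
                  switched = NA_real_, lost = NA_real_, n_day1 = 0L))
  }
  s7 <- wide[[need[2]]][responders]
  o7 <- wide[[need[3]]][responders]
  s7[is.na(s7)] <- 0
  o7[is.na(o7)] <- 0
  maintained <- s7 > 0
  switched <- !maintained & o7 > 0
  lost <- !maintained & !switched
  tibble(stimulus = stimulus, maintained = mean(maintained),
         switched = mean(switched), lost = mean(lost),
         n_day1 = sum(responders))
}
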