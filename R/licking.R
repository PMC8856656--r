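# eligible ITI spans: >= 20 s after the previous trial end, ending 2.5 s
# before the next CS (the last span runs to the end of the session)
eligible_iti_spans <- function(session, windows = analysis_windows()) {
  tr <- session$trials
  trial_end <- ifelse(is.na(tr$reward_time),
                      tr$cs_onset + windows$t_cs, tr$reward_time)
  tibble(
    iti = seq_len(nrow(tr)),
    lo = trial_end + 20,
    hi = c(tr$cs_onset[-1], session$t_session) - windows$response_window
  ) %>% filter(.data$hi > .data$lo)
}

#' Trial-aligned lick rate in 500-ms bins
#'
#' Lick counts per bin relative to the CS onset, converted to licks/s and
#' averaged across all trials of the session (every trial enters the
#' behavioural analysis, regardless of the neural inclusion filter).
#'
#' @param session A [ca_session()].
#' @param bin Bin width (s).
#' @param from,to Grid limits relative to CS onset (s).
#' @return Tibble: `t` (bin left edge), `rate` (licks/s).
#' @export
binned_lick_rate <- function(session, bin = 0.5, from = -2, to = 11) {
  edges <- seq(from, to, by = bin)
  counts <- numeric(length(edges) - 1)
  for (cs in session$trials$cs_onset) {
    rel <- session$licks - cs
    rel <- rel[rel >= from & rel < to]
    counts <- counts + tabulate(findInterval(rel, edges), length(edges) - 1)
  }
  tibble(t = edges[-length(edges)],
         rate = counts / nrow(session$trials) / bin)
}

#' Anticipatory lick rate per trial
#'
#' Licks per second over the CS-plus-delay window
#' `[cs_onset, cs_onset + 2.5)` — the conditioned-response readout; the
#' half-open window excludes licks at the moment of reward delivery.
#'
#' @param session A [ca_session()].
#' @param windows [analysis_windows()].
#' @return Tibble: `trial`, `rate` (licks/s).
#' @export
anticipatory_lick_rate <- function(session, windows = analysis_windows()) {
  len <- windows$t_cs + windows$t_delay
  rate <- vapply(session$trials$cs_onset, function(cs) {
    sum(session$licks >= cs & session$licks < cs + len) / len
  }, numeric(1))
  tibble(trial = seq_len(nrow(session$trials)), rate = rate)
}

#' Segment self-initiated ITI lick bouts
#'
#' Licks at least 20 s after the previous trial end are grouped into bouts
#' by the 3-s gap rule (a gap of 3 s or more starts a new bout); a bout is
#' kept only when it starts more than 2.5 s before the next CS onset, so
#' the analysed 2.5-s span never touches the CS. The first bout of each
#' ITI is flagged.
#'
#' @param session A [ca_session()].
#' @param windows [analysis_windows()].
#' @return Tibble: `iti`, `start`, `end`, `n_licks`, `duration`,
#'   `first_in_iti`.
#' @export
detect_iti_lick_bouts <- function(session, windows = analysis_windows()) {
  spans <- eligible_iti_spans(session, windows)
  out <- list()
  for (i in seq_len(nrow(spans))) {
    nxt_cs_minus <- spans$hi[i] # next CS - 2.5 s
    lk <- session$licks[session$licks >= spans$lo[i] &
                          session$licks < nxt_cs_minus + windows$response_window]
    if (length(lk) == 0) next
    grp <- cumsum(c(1, diff(lk) >= 3))
    first <- TRUE
    for (g in unique(grp)) {
      bl <- lk[grp == g]
      if (bl[1] >= nxt_cs_minus) next # starts too close to the next CS
      out[[length(out) + 1L]] <- tibble(
        iti = spans$iti[i], start = bl[1], end = bl[length(bl)],
        n_licks = length(bl), duration = bl[length(bl)] - bl[1],
        first_in_iti = first
      )
      first <- FALSE
    }
  }
  if (length(out) == 0) {
    return(tibble(iti = integer(), start = numeric(), end = numeric(),
                  n_licks = integer(), duration = numeric(),
                  first_in_iti = logical()))
  }
  bind_rows(out)
}

#' Mean lick rate during ITI bouts, the CS window, and the reward window
#'
#' The behavioural specificity comparison: within-bout rate over the first
#' 2.5 s of each ITI bout vs. the CS window vs. the 2.5 s after reward.
#'
#' @param session A [ca_session()].
#' @param windows [analysis_windows()].
#' @return One-row tibble: `iti_rate`, `cs_rate`, `reward_rate` (licks/s;
#'   `NaN` when the session has no bouts, `NA` reward rate for tone-only).
#' @export
lick_rate_comparison <- function(session, windows = analysis_windows()) {
  len <- windows$response_window
  bouts <- detect_iti_lick_bouts(session, windows)
  rate_in <- function(starts) {
    if (length(starts) == 0) return(NaN)
    mean(vapply(starts, function(s0) {
      sum(session$licks >= s0 & session$licks < s0 + len) / len
    }, numeric(1)))
  }
  rw <- session$trials$reward_time
  tibble(
    mouse_id = session$mouse_id, day = session$day,
    iti_rate = rate_in(bouts$start),
    cs_rate = rate_in(session$trials$cs_onset),
    reward_rate = if (all(is.na(rw))) NA_real_ else rate_in(rw[!is.na(rw)]),
    n_bouts = nrow(bouts)
  )
}

#' Reliability of neural responses during ITI lick bouts
#'
#' The verbatim trial-responsiveness criterion (z > 1 for >= 5 consecutive
#' frames) applied to the first 2.5 s of every ITI lick bout.
#'
#' @param analysis An [analyze_session()] result.
#' @param bouts Bout table from [detect_iti_lick_bouts()] (recomputed when
#'   omitted).
#' @return Tibble: `mouse_id`, `day`, `neuron`, `bout_reliability`
#'   (percent of bouts responsive), `n_bouts`; zero rows when the session
#'   has no bouts (the mouse is skipped for this comparison).
#' @export
bout_reliability <- function(analysis, bouts = NULL) {
  s <- analysis$session
  bouts <- bouts %||% detect_iti_lick_bouts(s, analysis$windows)
  rows <- frame_of_time(bouts$start, s$frame_rate)
  rows <- rows[rows >= 1 & rows <= nrow(analysis$profiles)]
  if (length(rows) == 0) return(tibble(
    mouse_id = character(), day = integer(), neuron = integer(),
    bout_reliability = numeric(), n_bouts = integer()))
  purrr::map_dfr(seq_along(analysis$active), function(j) {
    tibble(mouse_id = s$mouse_id, day = s$day, neuron = analysis$active[j],
           bout_reliability = 100 * mean(analysis$profiles[rows, j]),
           n_bouts = length(rows))
  })
}

# mean z over a 2.5-s window per start, for one neuron
mean_z_windows <- function(z, starts, frame_rate, len) {
  vapply(starts, function(s0) {
    mean(z[window_frames(s0, len, frame_rate)])
  }, numeric(1))
}

# draw n random 2.5-s window starts from the eligible ITI spans,
# duration-weighted, without replacement on the frame grid
random_iti_starts <- function(session, windows, n) {
  spans <- eligible_iti_spans(session, windows)
  starts <- unlist(lapply(seq_len(nrow(spans)), function(i) {
    seq(spans$lo[i], spans$hi[i], by = 1 / session$frame_rate)
  }))
  if (length(starts) < n) return(NULL)
  sample(starts, n, replace = FALSE)
}

#' Classify lick cells from first-of-ITI lick bouts
#'
#' For each active neuron the mean z-scored dF over the first 2.5 s of each
#' ITI's first lick bout is compared (paired t-test, two-sided, alpha 0.05)
#' with the mean over an equal number of random, duration-matched windows
#' drawn from the eligible ITI spans. Cells with significantly *higher*
#' activity during bouts are labelled lick cells.
#'
#' @param analysis An [analyze_session()] result.
#' @param bouts Optional precomputed bout table.
#' @return Tibble: `mouse_id`, `day`, `neuron`, `mean_bout`, `mean_random`,
#'   `p_value`, `lick_cell`; neurons are `NA`-flagged when fewer than two
#'   ITIs have a first bout.
#' @export
classify_lick_cells <- function(analysis, bouts = NULL) {
  s <- analysis$session
  w <- analysis$windows
  bouts <- bouts %||% detect_iti_lick_bouts(s, w)
  firsts <- bouts$start[bouts$first_in_iti]
  firsts <- firsts[firsts + w$response_window <= s$t_session]
  out_na <- function() purrr::map_dfr(analysis$active, function(nr) tibble(
    mouse_id = s$mouse_id, day = s$day, neuron = nr,
    mean_bout = NA_real_, mean_random = NA_real_, p_value = NA_real_,
    lick_cell = NA))
  if (length(firsts) < 2) {
    warn("fewer than two first-of-ITI bouts; lick cells unclassifiable")
    return(out_na())
  }
  purrr::map_dfr(analysis$active, function(nr) {
    z <- analysis$z[nr, ]
    stat_bout <- mean_z_windows(z, firsts, s$frame_rate, w$response_window)
    rnd <- random_iti_starts(s, w, length(firsts))
    if (is.null(rnd)) return(tibble(
      mouse_id = s$mouse_id, day = s$day, neuron = nr, mean_bout = NA_real_,
      mean_random = NA_real_, p_value = NA_real_, lick_cell = NA))
    stat_rnd <- mean_z_windows(z, rnd, s$frame_rate, w$response_window)
    p <- if (sd(stat_bout - stat_rnd) == 0) 1 else
      t.test(stat_bout, stat_rnd, paired = TRUE)$p.value
    tibble(mouse_id = s$mouse_id, day = s$day, neuron = nr,
           mean_bout = mean(stat_bout), mean_random = mean(stat_rnd),
           p_value = p,
           lick_cell = p <= 0.05 && mean(stat_bout) > mean(stat_rnd))
  })
}

#' Mixed selectivity of lick cells for CS and reward
#'
#' The lick-cell contrast repeated with the CS and reward response windows
#' of the included trials against equal numbers of random ITI windows;
#' the pair of verdicts yields the category.
#'
#' @param analysis An [analyze_session()] result.
#' @param neurons Neurons to classify (typically the lick cells).
#' @return Tibble: `neuron`, `cs_selective`, `reward_selective`,
#'   `category` (`"cs"`, `"reward"`, `"cs_and_reward"`, `"none"`).
#' @export
classify_mixed_selectivity <- function(analysis, neurons) {
  s <- analysis$session
  w <- analysis$windows
  inc <- included_trials(s, w)
  sel <- function(nr, stim) {
    starts <- response_window_start(s, stim)
    starts <- starts[inc & !is.na(starts)]
    if (length(starts) < 2) return(NA)
    rnd <- random_iti_starts(s, w, length(starts))
    if (is.null(rnd)) return(NA)
    z <- analysis$z[nr, ]
    a <- mean_z_windows(z, starts, s$frame_rate, w$response_window)
    b <- mean_z_windows(z, rnd, s$frame_rate, w$response_window)
    if (sd(a - b) == 0) return(FALSE)
    t.test(a, b, paired = TRUE)$p.value <= 0.05 && mean(a) > mean(b)
  }
  purrr::map_dfr(neurons, function(nr) {
    cs <- sel(nr, "cs")
    rw <- if (s$paradigm == "tone_only") NA else sel(nr, "reward")
    category <- dplyr::case_when(
      isTRUE(cs) & isTRUE(rw) ~ "cs_and_reward",
      isTRUE(cs) ~ "cs",
      isTRUE(rw) ~ "reward",
      TRUE ~ "none"
    )
    tibble(mouse_id = s$mouse_id, day = s$day, neuron = nr,
           cs_selective = cs, reward_selective = rw, category = category)
  })
}
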