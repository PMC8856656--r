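#' Binary stimulus indicator on the trial-aligned grid
#'
#' The grid spans `[-t_baseline, t_cs + t_delay + t_reward + t_post)`
#' around the CS onset (13 s, 390 frames at 30 Hz). The CS indicator is 1
#' from the CS onset to the start of reward delivery (CS + delay, 2.5 s);
#' the reward indicator is 1 over the first 2.5 s of reward delivery.
#'
#' @param stimulus `"cs"` or `"reward"`.
#' @param windows [analysis_windows()].
#' @param frame_rate Hz.
#' @return Logical vector of grid length.
#' @export
stimulus_indicator <- function(stimulus = c("cs", "reward"),
                               windows = analysis_windows(),
                               frame_rate = 30) {
  stimulus <- match.arg(stimulus)
  n <- grid_n_frames(windows, frame_rate)
  ind <- rep(FALSE, n)
  anticipatory <- windows$t_cs + windows$t_delay
  from <- if (stimulus == "cs") windows$t_baseline else
    windows$t_baseline + anticipatory
  len <- if (stimulus == "cs") anticipatory else windows$t_reward
  idx <- window_frames(from, len, frame_rate)
  ind[idx[idx <= n]] <- TRUE
  ind
}

#' Trial-averaged trace on the aligned grid
#'
#' Frame-wise mean of the per-trial snippets
#' `[cs_onset - t_baseline, cs_onset + t_cs + t_delay + t_reward + t_post)`.
#'
#' @param z One neuron's trace (z-scored dF by default in this pipeline).
#' @param cs_onsets Trial start times (s).
#' @param windows [analysis_windows()].
#' @param frame_rate Hz.
#' @return Numeric vector of grid length.
#' @export
trial_averaged_trace <- function(z, cs_onsets, windows = analysis_windows(),
                                 frame_rate = 30) {
  if (length(cs_onsets) < 1) abort("need at least one trial")
  n <- grid_n_frames(windows, frame_rate)
  first <- frame_of_time(cs_onsets - windows$t_baseline, frame_rate)
  if (min(first) < 1 || max(first) + n - 1 > length(z)) {
    abort("trial window outside the trace")
  }
  acc <- numeric(n)
  for (f in first) acc <- acc + z[f:(f + n - 1)]
  acc / length(first)
}

#' Spearman tuning coefficient of a trial-averaged trace
#'
#' Spearman rank correlation (average ranks for ties) between the
#' trial-averaged trace and the binary stimulus-period indicator.
#'
#' @param mean_trace Trial-averaged trace on the aligned grid.
#' @param indicator Logical indicator from [stimulus_indicator()].
#' @return The coefficient in `[-1, 1]`, or `NA` for a constant trace
#'   (such cells are excluded with a flag upstream).
#' @export
spearman_tuning <- function(mean_trace, indicator) {
  if (length(mean_trace) != length(indicator)) {
    abort("trace and indicator grids differ in length")
  }
  cpp_spearman_binary(mean_trace, as.logical(indicator))
}

#' Tuning coefficients for every active neuron of a session
#'
#' @param analysis An [analyze_session()] result.
#' @param stimuli Stimuli to correlate against.
#' @param included_only Restrict the trial average to included trials
#'   (the behavioural lick filter), the default.
#' @return Tibble: `mouse_id`, `day`, `neuron`, `stimulus`, `rho`.
#' @export
tuning_table <- function(analysis, stimuli = c("cs", "reward"),
                         included_only = TRUE) {
  s <- analysis$session
  if (s$paradigm == "tone_only") stimuli <- intersect(stimuli, "cs")
  keep <- if (included_only) included_trials(s, analysis$windows) else
    rep(TRUE, nrow(s$trials))
  onsets <- s$trials$cs_onset[keep]
  inds <- lapply(stimuli, stimulus_indicator, windows = analysis$windows,
                 frame_rate = s$frame_rate)
  purrr::map_dfr(analysis$active, function(nr) {
    avg <- trial_averaged_trace(analysis$z[nr, ], onsets, analysis$windows,
                                s$frame_rate)
    tibble(mouse_id = s$mouse_id, day = s$day, neuron = nr,
           stimulus = stimuli,
           rho = vapply(inds, function(ind) spearman_tuning(avg, ind),
                        numeric(1)))
  })
}

#' Cohort mean change in tuning, mouse-balanced
#'
#' Per tracked cell, `delta_rho = rho(day 7) - rho(day 1)`; per mouse, the
#' mean over its cells; at the cohort level, the mean over mice (so every
#' mouse carries equal weight regardless of cell count).
#'
#' @param tuning Tuning table over both days (tracked cells only; cells
#'   with an `NA` coefficient on either day are dropped).
#' @param stimulus Which stimulus.
#' @return List: `per_cell` (tibble with `delta_rho`), `per_mouse`,
#'   `delta_rho_bar` (scalar).
#' @export
mean_delta_rho <- function(tuning, stimulus = "cs") {
  wide <- tuning %>%
    filter(.data$stimulus == !!stimulus) %>%
    tidyr::pivot_wider(id_cols = c("mouse_id", "neuron"),
                       names_from = "day", values_from = "rho",
                       names_prefix = "d") %>%
    filter(!is.na(.data$d1) & !is.na(.data$d7)) %>%
    mutate(delta_rho = .data$d7 - .data$d1)
  per_mouse <- wide %>%
    group_by(.data$mouse_id) %>%
    summarise(mean_delta = mean(.data$delta_rho), n_cells = n(),
              .groups = "drop")
  list(per_cell = wide, per_mouse = per_mouse,
       delta_rho_bar = mean(per_mouse$mean_delta))
}

#' Bootstrap/trial-scramble null for the mean change in tuning
#'
#' Each iteration bootstraps mice with replacement; for every sampled mouse
#' and day it draws as many fake trial start times, uniform over the
#' session (with the full aligned grid kept in bounds), as that mouse has
#' analysed trials, recomputes every cell's Spearman coefficient on the
#' scrambled alignment, and forms the mouse-balanced mean change. The
#' observed change is compared with the two tails.
#'
#' @param analyses_day1,analyses_day7 Lists of [analyze_session()] results
#'   in matching mouse order.
#' @param tracked Tracked-cell table (`mouse_id`, `neuron_day1`,
#'   `neuron_day7`); defaults to cells active on both days under the
#'   identity mapping.
#' @param stimulus `"cs"` or `"reward"`.
#' @param n_iter Null iterations (>= 100).
#' @param included_only Apply the behavioural trial filter to the observed
#'   alignment (the scramble always matches the analysed trial counts).
#' @return A `ca_mc_test` whose `observed` is the cohort `delta_rho_bar`;
#'   the per-cell table is attached as `$per_cell`.
#' @export
null_mean_delta_rho <- function(analyses_day1, analyses_day7, tracked = NULL,
                                stimulus = "cs", n_iter = 1000,
                                included_only = TRUE) {
  if (n_iter < 100) abort("n_iter must be >= 100")
  mice <- vapply(analyses_day1, function(a) a$session$mouse_id, character(1))
  if (is.null(tracked)) {
    tracked <- purrr::map_dfr(seq_along(mice), function(i) {
      common <- intersect(analyses_day1[[i]]$active, analyses_day7[[i]]$active)
      tibble(mouse_id = mice[i], neuron_day1 = common, neuron_day7 = common)
    })
  }
  w <- analyses_day1[[1]]$windows
  rate <- analyses_day1[[1]]$session$frame_rate
  grid_len <- grid_n_frames(w, rate)
  ind <- stimulus_indicator(stimulus, w, rate)
  tune_one <- function(analysis, neurons) {
    s <- analysis$session
    keep <- if (included_only) included_trials(s, w) else
      rep(TRUE, nrow(s$trials))
    onsets <- s$trials$cs_onset[keep]
    vapply(neurons, function(nr) {
      spearman_tuning(
        trial_averaged_trace(analysis$z[nr, ], onsets, w, rate), ind)
    }, numeric(1))
  }
  z1 <- list(); z7 <- list(); nt1 <- integer(); nt7 <- integer()
  deltas <- numeric(0); mouse_of <- character(0)
  for (i in seq_along(mice)) {
    tc <- tracked %>% filter(.data$mouse_id == mice[i])
    if (nrow(tc) == 0) next
    r1 <- tune_one(analyses_day1[[i]], tc$neuron_day1)
    r7 <- tune_one(analyses_day7[[i]], tc$neuron_day7)
    ok <- !is.na(r1) & !is.na(r7)
    deltas <- c(deltas, (r7 - r1)[ok])
    mouse_of <- c(mouse_of, rep(mice[i], sum(ok)))
    # frames x neurons so each cell's trace is contiguous for the scramble
    z1[[length(z1) + 1L]] <- t(analyses_day1[[i]]$z[tc$neuron_day1[ok], ,
                                                    drop = FALSE])
    z7[[length(z7) + 1L]] <- t(analyses_day7[[i]]$z[tc$neuron_day7[ok], ,
                                                    drop = FALSE])
    nt1 <- c(nt1, sum(if (included_only)
      included_trials(analyses_day1[[i]]$session, w) else
        rep(TRUE, nrow(analyses_day1[[i]]$session$trials))))
    nt7 <- c(nt7, sum(if (included_only)
      included_trials(analyses_day7[[i]]$session, w) else
        rep(TRUE, nrow(analyses_day7[[i]]$session$trials))))
  }
  per_mouse <- tibble(mouse_id = mouse_of, delta_rho = deltas) %>%
    group_by(.data$mouse_id) %>%
    summarise(mean_delta = mean(.data$delta_rho), .groups = "drop")
  observed <- mean(per_mouse$mean_delta)
  null_values <- cpp_null_delta_rho(
    z1, z7, nt1, nt7, as.integer(grid_len),
    as.integer(which(ind) - 1L), as.integer(n_iter)
  )
  out <- new_mc_test(
    observed, null_values, bonferroni_m = 1,
    label = sprintf("mean delta-rho (%s tuning)", stimulus),
    n = length(deltas)
  )
  out$per_cell <- tibble(mouse_id = mouse_of, delta_rho = deltas)
  out$per_mouse <- per_mouse
  out$stimulus <- stimulus
  out
}
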