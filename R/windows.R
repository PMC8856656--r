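#' Analysis window lengths for the conditioning task
#'
#' Bundles the fixed time windows used throughout the pipeline, all in
#' seconds. The trial-aligned analysis grid runs from `t_baseline` before the
#' CS onset to `t_cs + t_delay + t_reward + t_post` after it; the z-score
#' baseline is the `t_baseline_z` stretch immediately preceding each CS
#' onset; `response_window` is the stimulus response period used for
#' trial-by-trial responsiveness.
#'
#' Defaults encode the task timing: a 1-s auditory CS, a 1.5-s trace delay,
#' reward delivery 2.5 s after CS onset, and a 2.5-s response window.
#'
#' @param t_baseline_z Pre-CS stretch pooled for the z-score baseline (s).
#' @param t_baseline Pre-CS extent of the trial-aligned grid (s).
#' @param t_cs CS (tone) duration (s).
#' @param t_delay Delay between CS offset and reward (s).
#' @param t_reward Reward period on the aligned grid (s).
#' @param t_post Post-reward extent of the aligned grid (s).
#' @param response_window Stimulus response window (s).
#'
#' @return An object of class `ca_windows` (a named list).
#' @examples
#' w <- analysis_windows()
#' w$t_cs + w$t_delay # anticipatory window length
#' @export
analysis_windows <- function(t_baseline_z = 2.5, t_baseline = 2, t_cs = 1,
                             t_delay = 1.5, t_reward = 2.5, t_post = 6,
                             response_window = 2.5) {
  w <- list(
    t_baseline_z = t_baseline_z, t_baseline = t_baseline, t_cs = t_cs,
    t_delay = t_delay, t_reward = t_reward, t_post = t_post,
    response_window = response_window
  )
  vals <- unlist(w)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all analysis windows must be strictly positive")
  }
  structure(w, class = "ca_windows")
}

# total span of the trial-aligned grid after the CS onset (s)
grid_post_span <- function(w) w$t_cs + w$t_delay + w$t_reward + w$t_post

# number of frames on the trial-aligned grid
grid_n_frames <- function(w, rate) {
  window_n_frames(w$t_baseline + grid_post_span(w), rate)
}
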