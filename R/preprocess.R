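#' Iterative percentile estimate of the slow baseline F0
#'
#' Estimates a time-varying baseline from the inactive parts of a raw
#' fluorescence trace: a running 8th-percentile over a 60-s sliding window
#' (evaluated every `step_s` and linearly interpolated) is fitted, frames
#' rising more than two robust SDs above it are flagged as active, and the
#' percentile is recomputed on the remaining inactive frames; the flag/refit
#' cycle repeats until the active set stabilises or `max_iter` passes.
#'
#' @param trace Raw fluorescence vector.
#' @param frame_rate Hz.
#' @param window_s Sliding-window width (s).
#' @param p Percentile used within each window (0-1).
#' @param step_s Spacing of window centres (s).
#' @param max_iter Iteration cap.
#' @return Numeric vector, same length as `trace`.
#' @export
estimate_baseline_f0 <- function(trace, frame_rate, window_s = 60, p = 0.08,
                                 step_s = 15, max_iter = 10) {
  if (all(is.na(trace))) abort("trace is all NA")
  L <- length(trace)
  if (L < 2) return(trace)
  width <- max(3L, window_n_frames(window_s, frame_rate))
  step <- max(1L, window_n_frames(step_s, frame_rate))
  # stabilisation tolerance: the active set is deemed stable once fewer
  # than 0.5% of frames change flag between passes (pure-noise traces
  # otherwise jitter a handful of threshold frames forever)
  cpp_percentile_f0(trace, width, step, p, min_keep = 5L,
                    max_iter = as.integer(max_iter), tol_frac = 5e-3)
}

#' Baseline-subtracted fluorescence
#'
#' @param trace Raw fluorescence (vector or neurons x frames matrix).
#' @param f0 Baseline of identical shape, e.g. from
#'   [estimate_baseline_f0()].
#' @return `trace - f0`, elementwise.
#' @export
compute_delta_f <- function(trace, f0) {
  if (length(trace) != length(f0)) abort("trace and f0 lengths differ")
  trace - f0
}

#' Z-score dF traces against the pooled pre-CS baseline
#'
#' For each neuron, the z-score baseline is the concatenation of the
#' `t_baseline_z` (2.5 s) stretches immediately preceding every CS onset in
#' the session; `Z = (dF - mu) / sigma` with the sample (n-1) SD. Neurons
#' whose baseline SD is zero are flagged degenerate (their Z rows are `NA`)
#' and should be excluded downstream.
#'
#' @param delta_f Neurons x frames dF matrix (a vector is treated as one
#'   neuron).
#' @param trials Trial tibble with `cs_onset`.
#' @param windows [analysis_windows()].
#' @param frame_rate Hz.
#' @return List with `z` (matrix like `delta_f`) and `params`, a tibble
#'   with one row per neuron: `mu`, `sigma`, `degenerate`.
#' @export
zscore_session <- function(delta_f, trials, windows = analysis_windows(),
                           frame_rate = 30) {
  if (!is.matrix(delta_f)) delta_f <- matrix(delta_f, nrow = 1)
  if (nrow(trials) < 1) abort("need at least one trial")
  idx <- unlist(lapply(trials$cs_onset, function(cs) {
    window_frames(cs - windows$t_baseline_z, windows$t_baseline_z, frame_rate)
  }))
  if (min(idx) < 1 || max(idx) > ncol(delta_f)) {
    abort("pre-CS baseline window outside the trace")
  }
  base <- delta_f[, idx, drop = FALSE]
  mu <- rowMeans(base)
  nb <- ncol(base)
  sigma <- sqrt(pmax(rowSums((base - mu)^2), 0) / (nb - 1))
  degenerate <- !is.finite(sigma) | sigma == 0
  if (any(degenerate)) {
    warn(sprintf("%d neuron(s) with flat pre-CS baseline flagged degenerate",
                 sum(degenerate)))
  }
  z <- (delta_f - mu) / ifelse(degenerate, NA_real_, sigma)
  list(
    z = z,
    params = tibble(neuron = seq_len(nrow(delta_f)), mu = mu, sigma = sigma,
                    degenerate = degenerate, n_baseline_frames = length(idx))
  )
}

#' Run the full preprocessing chain on one session
#'
#' F0 estimation per neuron, dF subtraction, and pre-CS z-scoring.
#'
#' @param session A [ca_session()].
#' @param windows [analysis_windows()].
#' @param ... Passed to [estimate_baseline_f0()].
#' @return List with `delta_f`, `z` (matrices), `zparams` (tibble), and
#'   `f0_summary` (per-neuron mean F0, for QC export).
#' @export
preprocess_session <- function(session, windows = analysis_windows(), ...) {
  f <- session$fluorescence
  delta_f <- f
  f0_mean <- numeric(nrow(f))
  for (i in seq_len(nrow(f))) {
    f0 <- estimate_baseline_f0(f[i, ], session$frame_rate, ...)
    delta_f[i, ] <- f[i, ] - f0
    f0_mean[i] <- mean(f0)
  }
  zs <- zscore_session(delta_f, session$trials, windows, session$frame_rate)
  list(delta_f = delta_f, z = zs$z,
       zparams = zs$params %>% mutate(f0_mean = f0_mean))
}
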