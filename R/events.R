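#' Detect significant activity events by circular-shift permutation
#'
#' For each neuron the dF trace is circularly shifted by a random integer
#' (uniform on 1..L-1, never 0) `n_shifts` times and compared frame-by-frame
#' to the original. A frame is event-eligible when the original strictly
#' exceeds the shifted trace in at least `min_count` of the shifts; events
#' are maximal runs of eligible frames of length at least `min_run`.
#' Detection runs on dF, before z-scoring.
#'
#' @param delta_f dF matrix (neurons x frames) or a single trace.
#' @param n_shifts Number of random circular shifts.
#' @param min_run Minimum event length in frames.
#' @param min_count Minimum number of shifts the original must exceed.
#' @param frame_rate Hz, used only to report event times in seconds.
#' @return An object of class `ca_events`: list with `mask` (logical
#'   neurons x frames), `events` (tibble: neuron, start_frame, end_frame,
#'   start_s, end_s) and the detection parameters.
#' @export
detect_events <- function(delta_f, n_shifts = 1000, min_run = 5,
                          min_count = 950, frame_rate = 30) {
  if (!is.matrix(delta_f)) delta_f <- matrix(delta_f, nrow = 1)
  L <- ncol(delta_f)
  if (L <= min_run) abort("trace no longer than min_run frames")
  if (n_shifts < 1) abort("n_shifts must be >= 1")
  mask <- matrix(FALSE, nrow(delta_f), L)
  evts <- list()
  for (i in seq_len(nrow(delta_f))) {
    counts <- cpp_shift_exceedance(delta_f[i, ], n_shifts)
    eligible <- counts >= min_count
    runs <- true_runs(eligible)
    runs <- runs[runs[, "end"] - runs[, "start"] + 1L >= min_run, , drop = FALSE]
    if (nrow(runs) > 0) {
      for (r in seq_len(nrow(runs))) {
        mask[i, runs[r, "start"]:runs[r, "end"]] <- TRUE
      }
      evts[[length(evts) + 1L]] <- tibble(
        neuron = i, start_frame = runs[, "start"], end_frame = runs[, "end"]
      )
    }
  }
  events <- if (length(evts)) bind_rows(evts) else
    tibble(neuron = integer(), start_frame = integer(), end_frame = integer())
  events <- events %>% mutate(
    start_s = (.data$start_frame - 1) / frame_rate,
    end_s = .data$end_frame / frame_rate
  )
  structure(
    list(mask = mask, events = events,
         params = list(n_shifts = n_shifts, min_run = min_run,
                       min_count = min_count, frame_rate = frame_rate)),
    class = "ca_events"
  )
}

#' @export
print.ca_events <- function(x, ...) {
  cat(sprintf("<ca_events> %d neurons, %d events (%d/%d criterion, run >= %d)\n",
              nrow(x$mask), nrow(x$events), x$params$min_count,
              x$params$n_shifts, x$params$min_run))
  invisible(x)
}

#' Indices of neurons with at least one significant event
#'
#' Neurons without a single significant activity event anywhere in the
#' session, irrespective of the behaviour, are dropped from all analyses.
#'
#' @param events A [detect_events()] result.
#' @return Integer vector of active neuron indices (original order).
#' @export
filter_active_neurons <- function(events) {
  stopifnot(inherits(events, "ca_events"))
  which(rowSums(events$mask) > 0)
}

#' Percentage of ROIs retained as active
#' @param events A [detect_events()] result.
#' @return `100 * active / total` ROIs.
#' @export
percent_active <- function(events) {
  stopifnot(inherits(events, "ca_events"))
  n <- nrow(events$mask)
  if (n == 0) abort("no ROIs")
  100 * length(filter_active_neurons(events)) / n
}
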