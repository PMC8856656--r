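#' Construct a single-session recording
#'
#' A `ca_session` holds one mouse-day of data: the raw ROI fluorescence
#' matrix (neurons x frames, arbitrary units), the ordered trial table, the
#' lick timestamps, and session metadata. All times are seconds from session
#' start; frame `k` covers `[(k-1)/frame_rate, k/frame_rate)`.
#'
#' @param fluorescence Numeric matrix, neurons x frames, raw F.
#' @param trials Data frame with columns `cs_onset` (s) and `reward_time`
#'   (s, `NA` for tone-only trials); an optional logical `included` column is
#'   carried along verbatim.
#' @param licks Sorted numeric vector of lick timestamps (s).
#' @param mouse_id Identifier for the animal.
#' @param day Session day (the task images days 1 and 7).
#' @param cell_type One of `"PN"`, `"PV"`, `"SOM"`, `"VIP"`.
#' @param paradigm One of `"paired"`, `"tone_only"`, `"nonpaired"`.
#' @param frame_rate Imaging frame rate in Hz.
#' @param t_session Session duration (s); defaults to the trace length.
#' @param windows [analysis_windows()] used to validate trial placement.
#'
#' @return A validated object of class `ca_session`.
#' @export
ca_session <- function(fluorescence, trials, licks, mouse_id, day,
                       cell_type = "PN", paradigm = "paired",
                       frame_rate = 30, t_session = NULL,
                       windows = analysis_windows()) {
  if (!is.matrix(fluorescence)) fluorescence <- matrix(fluorescence, nrow = 1)
  trials <- as_tibble(trials)
  if (!"reward_time" %in% names(trials)) trials$reward_time <- NA_real_
  if (!"included" %in% names(trials)) trials$included <- NA
  t_session <- t_session %||% (ncol(fluorescence) / frame_rate)
  s <- structure(
    list(
      mouse_id = as.character(mouse_id), day = as.integer(day),
      cell_type = cell_type, paradigm = paradigm,
      frame_rate = frame_rate, t_session = t_session,
      fluorescence = fluorescence,
      trials = trials[c("cs_onset", "reward_time", "included")],
      licks = as.numeric(licks)
    ),
    class = "ca_session"
  )
  validate_session(s, windows)
  s
}

validate_session <- function(s, windows = analysis_windows()) {
  v <- session_violations(s, windows)
  if (nrow(v) > 0) {
    abort(paste0("invalid session: ",
                 paste(v$field, v$message, sep = ": ", collapse = "; ")))
  }
  invisible(s)
}

# violations as data, shared by validate_session and validate_cohort
session_violations <- function(s, windows = analysis_windows()) {
  out <- list()
  bad <- function(field, message) {
    out[[length(out) + 1L]] <<- tibble(field = field, message = message)
  }
  if (!is.numeric(s$fluorescence) || ncol(s$fluorescence) < 1) {
    bad("fluorescence", "needs at least one frame per neuron")
  }
  if (is.unsorted(s$trials$cs_onset)) bad("trials", "not sorted by cs_onset")
  if (is.unsorted(s$licks)) bad("licks", "not sorted ascending")
  rw <- s$trials$reward_time
  if (any(!is.na(rw) & rw <= s$trials$cs_onset)) {
    bad("trials", "reward_time must follow cs_onset")
  }
  if (s$paradigm == "paired" && any(is.na(rw))) {
    bad("trials", "paired paradigm requires reward_time on every trial")
  }
  pre <- s$trials$cs_onset - max(windows$t_baseline, windows$t_baseline_z)
  post <- s$trials$cs_onset + grid_post_span(windows)
  if (any(pre < 0) || any(post > s$t_session)) {
    bad("trials", "trial window extends beyond the session")
  }
  if (nrow(s$trials) > 0 && ncol(s$fluorescence) < ceiling(max(post) * s$frame_rate)) {
    bad("fluorescence", "trace shorter than the last trial window")
  }
  if (length(out) == 0) return(tibble(field = character(), message = character()))
  bind_rows(out)
}

#' @export
print.ca_session <- function(x, ...) {
  cat(sprintf(
    "<ca_session> mouse %s day %d (%s, %s): %d neurons x %d frames @ %g Hz, %d trials, %d licks\n",
    x$mouse_id, x$day, x$cell_type, x$paradigm, nrow(x$fluorescence),
    ncol(x$fluorescence), x$frame_rate, nrow(x$trials), length(x$licks)
  ))
  invisible(x)
}

#' Construct a cohort of sessions with cross-day cell correspondences
#'
#' @param sessions List of [ca_session()] objects (any order).
#' @param tracked_cells Data frame with columns `mouse_id`, `neuron_day1`,
#'   `neuron_day7` giving the cell correspondence between the day-1 and
#'   day-7 sessions of each mouse. Only tracked ROIs enter the analyses.
#'   Defaults to the identity mapping over the ROIs present on both days.
#'
#' @return An object of class `ca_cohort`.
#' @export
ca_cohort <- function(sessions, tracked_cells = NULL) {
  stopifnot(length(sessions) > 0)
  key <- vapply(sessions, function(s) paste(s$mouse_id, s$day, sep = "."),
                character(1))
  if (anyDuplicated(key)) abort("duplicate (mouse, day) sessions")
  names(sessions) <- key
  mice <- sort(unique(vapply(sessions, `[[`, character(1), "mouse_id")))
  if (is.null(tracked_cells)) {
    tracked_cells <- purrr::map_dfr(mice, function(m) {
      d1 <- sessions[[paste(m, 1, sep = ".")]]
      d7 <- sessions[[paste(m, 7, sep = ".")]]
      n <- if (!is.null(d1) && !is.null(d7)) {
        min(nrow(d1$fluorescence), nrow(d7$fluorescence))
      } else if (!is.null(d1)) nrow(d1$fluorescence)
      else if (!is.null(d7)) nrow(d7$fluorescence) else 0L
      tibble(mouse_id = m, neuron_day1 = seq_len(n), neuron_day7 = seq_len(n))
    })
  }
  structure(
    list(mice = mice, sessions = sessions,
         tracked_cells = as_tibble(tracked_cells)),
    class = "ca_cohort"
  )
}

#' @export
print.ca_cohort <- function(x, ...) {
  cat(sprintf("<ca_cohort> %d mice, %d sessions, %d tracked cell pairs\n",
              length(x$mice), length(x$sessions), nrow(x$tracked_cells)))
  invisible(x)
}

#' Fetch one session from a cohort
#' @param cohort A [ca_cohort()].
#' @param mouse_id,day Which session.
#' @return The `ca_session`, or `NULL` if absent.
#' @export
cohort_session <- function(cohort, mouse_id, day) {
  cohort$sessions[[paste(mouse_id, day, sep = ".")]]
}

#' Check every cohort invariant and report violations as data
#'
#' Runs all session- and cohort-level invariants (sorted trials and licks,
#' trial windows inside the session, tracked-cell indices referencing real
#' ROIs on both days) and returns one row per violation. It never throws:
#' violations are data, and an empty result means the cohort is valid.
#'
#' @param cohort A [ca_cohort()].
#' @param windows [analysis_windows()].
#' @return A tibble with columns `mouse_id`, `day`, `field`, `message`
#'   (zero rows when everything holds).
#' @export
validate_cohort <- function(cohort, windows = analysis_windows()) {
  per_session <- purrr::map_dfr(cohort$sessions, function(s) {
    v <- session_violations(s, windows)
    if (nrow(v) == 0) return(v %>% mutate(mouse_id = character(), day = integer()))
    v %>% mutate(mouse_id = s$mouse_id, day = s$day)
  })
  tracked <- purrr::map_dfr(unique(cohort$tracked_cells$mouse_id), function(m) {
    tc <- cohort$tracked_cells %>% filter(.data$mouse_id == m)
    out <- list()
    for (d in c(1L, 7L)) {
      s <- cohort_session(cohort, m, d)
      col <- if (d == 1L) tc$neuron_day1 else tc$neuron_day7
      if (is.null(s)) {
        out[[length(out) + 1L]] <- tibble(
          mouse_id = m, day = d, field = "sessions",
          message = "tracked cells reference a missing session"
        )
      } else if (any(col < 1 | col > nrow(s$fluorescence))) {
        out[[length(out) + 1L]] <- tibble(
          mouse_id = m, day = d, field = "tracked_cells",
          message = "neuron index outside the fluorescence matrix"
        )
      }
    }
    bind_rows(out)
  })
  out <- bind_rows(per_session, tracked)
  if (nrow(out) == 0) {
    return(tibble(mouse_id = character(), day = integer(),
                  field = character(), message = character()))
  }
  out[c("mouse_id", "day", "field", "message")]
}
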