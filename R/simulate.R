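#' Configuration for the synthetic-session generator
#'
#' The generator emulates the head-fixed auditory cued reward conditioning
#' task: a 1-s tone (CS), a 1.5-s delay, a water reward, and intertrial
#' intervals drawn uniformly from `iti_range`; GCaMP6f-like transients on
#' tuned and untuned neurons with a controllable per-trial response
#' probability; slow multiplicative baseline drift; additive Gaussian noise;
#' and lick trains (spontaneous ITI bouts, CS-window licking whose rate
#' jumps from the baseline within-bout rate to the anticipatory rate once
#' the association is learned, and post-reward bursts).
#'
#' @param n_mice,n_neurons_per_mouse Cohort size.
#' @param class_fractions Named fractions over tuned classes
#'   (`cs`, `reward`, `cs_and_reward`, `lick`, `untuned`); must sum to 1.
#' @param n_trials Trials per session.
#' @param paradigm `"paired"` (CS -> delay -> reward, ITI 60-120 s),
#'   `"tone_only"` (no reward, ITI 15-25 s) or `"nonpaired"` (reward at a
#'   random 40-80 s delay, ITI 15-25 s).
#' @param iti_range ITI bounds (s); defaults per paradigm as above.
#' @param t_session Session length (s): `NULL` for the paradigm default
#'   (3600 s paired, 2700 s controls), `"auto"` to fit the trial block.
#' @param learned_day7 Does the day-7 paired session express the learned
#'   association (anticipatory licking)?
#' @param response_prob_day1,response_prob_day7 Per-trial response
#'   probability of tuned neurons: a scalar, a `c(lo, hi)` range sampled
#'   uniformly per neuron, or one value per neuron. Day 7 defaults to
#'   day 1 plus `day7_boost` (clamped to 1).
#' @param day7_boost Additive day-7 change in response probability.
#' @param amplitude Evoked transient peak in dF units; with the default
#'   `noise_sd = 1` this is the peak in z-score units. Scalar or `c(lo, hi)`.
#' @param latency,latency_jitter Mean and SD (s) of transient onset delay
#'   after the driving event.
#' @param kinetics `c(tau_rise, tau_decay)` (s) of the
#'   difference-of-exponentials transient kernel.
#' @param noise_sd Additive white-noise SD (arbitrary F units).
#' @param drift `c(amplitude, period)`: fractional sinusoidal baseline
#'   drift (unitless fraction, s).
#' @param baseline_range Per-neuron baseline F drawn uniformly (a.u.).
#' @param lick_rates `c(iti_bout, anticipatory, reward_burst)` in licks/s.
#' @param bout_rate ITI bout initiation rate (bouts/s of eligible ITI).
#' @param spont_rate Spontaneous transient rate for every neuron (events/s).
#' @param frame_rate Imaging rate (Hz).
#' @param days Which days to simulate.
#' @param seed Optional integer; when given, `simulate_cohort()` seeds R's
#'   RNG so the whole cohort is reproducible.
#'
#' @return A list of class `ca_generator_config`.
#' @export
generator_config <- function(n_mice = 6, n_neurons_per_mouse = 100,
                             class_fractions = c(cs = 0.15, reward = 0.15,
                                                 cs_and_reward = 0.10,
                                                 lick = 0.10, untuned = 0.50),
                             n_trials = 32, paradigm = "paired",
                             iti_range = NULL, t_session = NULL,
                             learned_day7 = TRUE,
                             response_prob_day1 = 0.5,
                             response_prob_day7 = NULL, day7_boost = 0.1,
                             amplitude = 3, latency = 0.1,
                             latency_jitter = 0.05,
                             kinetics = c(tau_rise = 0.05, tau_decay = 0.6),
                             noise_sd = 1, drift = c(amplitude = 0.05, period = 600),
                             baseline_range = c(50, 200),
                             lick_rates = c(iti_bout = 1.5, anticipatory = 3.4,
                                            reward_burst = 7.2),
                             bout_rate = 1 / 60, spont_rate = 1 / 150,
                             frame_rate = 30, days = c(1L, 7L), seed = NULL) {
  paradigm <- match.arg(paradigm, c("paired", "tone_only", "nonpaired"))
  if (abs(sum(class_fractions) - 1) > 1e-9) {
    abort("class_fractions must sum to 1")
  }
  if (n_trials < 1) abort("n_trials must be >= 1")
  iti_range <- iti_range %||% if (paradigm == "paired") c(60, 120) else c(15, 25)
  t_session <- t_session %||% if (paradigm == "paired") 3600 else 2700
  structure(
    list(n_mice = n_mice, n_neurons_per_mouse = n_neurons_per_mouse,
         class_fractions = class_fractions, n_trials = n_trials,
         paradigm = paradigm, iti_range = iti_range, t_session = t_session,
         learned_day7 = learned_day7,
         response_prob_day1 = response_prob_day1,
         response_prob_day7 = response_prob_day7, day7_boost = day7_boost,
         amplitude = amplitude, latency = latency,
         latency_jitter = latency_jitter, kinetics = kinetics,
         noise_sd = noise_sd, drift = drift, baseline_range = baseline_range,
         lick_rates = lick_rates, bout_rate = bout_rate,
         spont_rate = spont_rate, frame_rate = frame_rate,
         days = as.integer(days), nonpaired_delay = c(40, 80), seed = seed),
    class = "ca_generator_config"
  )
}

# resolve a scalar / range / per-neuron vector into one value per neuron
resolve_per_neuron <- function(x, n) {
  if (length(x) == n) return(as.numeric(x))
  if (length(x) == 1) return(rep(as.numeric(x), n))
  if (length(x) == 2) return(runif(n, x[1], x[2]))
  abort("expected a scalar, a c(lo, hi) range, or one value per neuron")
}

# deterministic class counts that always sum to n
class_counts <- function(fractions, n) {
  cum <- round(cumsum(fractions) * n)
  counts <- diff(c(0L, cum))
  setNames(as.integer(counts), names(fractions))
}

# trial times for one session; errors when the trial block cannot fit
simulate_trials <- function(config, windows = analysis_windows()) {
  n <- config$n_trials
  first_cs <- 20
  cs <- numeric(n)
  reward <- rep(NA_real_, n)
  cs[1] <- first_cs
  for (i in seq_len(n)) {
    if (config$paradigm == "paired") {
      reward[i] <- cs[i] + windows$t_cs + windows$t_delay
      nxt <- reward[i] + runif(1, config$iti_range[1], config$iti_range[2])
    } else if (config$paradigm == "nonpaired") {
      reward[i] <- cs[i] + runif(1, config$nonpaired_delay[1],
                                 config$nonpaired_delay[2])
      nxt <- reward[i] + runif(1, config$iti_range[1], config$iti_range[2])
    } else {
      nxt <- cs[i] + windows$t_cs +
        runif(1, config$iti_range[1], config$iti_range[2])
    }
    if (i < n) cs[i + 1] <- nxt
  }
  trial_end <- if (config$paradigm == "tone_only") cs + windows$t_cs else reward
  required <- max(cs) + grid_post_span(windows) +
    max(0, max(trial_end) - max(cs) - grid_post_span(windows)) + 10
  t_session <- config$t_session
  if (identical(t_session, "auto")) t_session <- ceiling(required + 10)
  if (required > t_session) {
    abort(sprintf(
      "session too short for %d trials with the configured intervals (need %.0f s, have %.0f s)",
      n, required, t_session))
  }
  list(trials = tibble(cs_onset = cs, reward_time = reward, included = NA),
       t_session = t_session, trial_end = trial_end)
}

#' Simulate the lick train of one session
#'
#' Homogeneous-Poisson lick generation: a burst at the configured
#' `reward_burst` rate after every reward, CS+delay-window licking at the
#' anticipatory rate when `learned` (and at the baseline within-bout rate
#' otherwise, matching naive mice that lick indiscriminately), and
#' spontaneous ITI bouts (intra-bout gaps < 3 s) initiated at `bout_rate`
#' inside the eligible ITI span (>= 20 s after the previous reward, ending
#' > 2.5 s before the next CS).
#'
#' @param trials Trial tibble (`cs_onset`, `reward_time`).
#' @param paradigm Task paradigm (see [generator_config()]).
#' @param learned Is the CS-reward association expressed?
#' @param rates `c(iti_bout, anticipatory, reward_burst)` licks/s.
#' @param bout_rate Bout initiations per second of eligible ITI.
#' @param t_session Session length (s).
#' @param windows [analysis_windows()].
#' @return List with `licks` (sorted timestamps), `bout_starts`, and
#'   `burst_starts` (first post-reward lick per rewarded trial, `NA` when
#'   absent).
#' @export
simulate_licks <- function(trials, paradigm, learned, rates,
                           bout_rate = 1 / 60, t_session,
                           windows = analysis_windows()) {
  licks <- numeric()
  n <- nrow(trials)
  anticipatory_rate <- if (learned) rates[["anticipatory"]] else rates[["iti_bout"]]
  anticipatory_len <- windows$t_cs + windows$t_delay
  for (i in seq_len(n)) {
    k <- rpois(1, anticipatory_rate * anticipatory_len)
    if (k > 0) {
      licks <- c(licks, trials$cs_onset[i] + sort(runif(k, 0, anticipatory_len)))
    }
  }
  burst_starts <- rep(NA_real_, n)
  burst_len <- 2.5
  for (i in seq_len(n)) {
    rw <- trials$reward_time[i]
    if (is.na(rw) || rates[["reward_burst"]] <= 0) next
    lag <- if (paradigm == "nonpaired") 0.2 + min(rexp(1, 1 / 0.8), 5) else runif(1, 0.05, 0.3)
    start <- rw + lag
    k <- rpois(1, rates[["reward_burst"]] * burst_len)
    burst <- c(start, start + sort(runif(k, 0, burst_len)))
    burst_starts[i] <- start
    licks <- c(licks, burst)
  }
  bout_starts <- numeric()
  if (rates[["iti_bout"]] > 0 && bout_rate > 0) {
    trial_end <- ifelse(is.na(trials$reward_time),
                        trials$cs_onset + windows$t_cs, trials$reward_time)
    span_lo <- trial_end + 20
    span_hi <- c(trials$cs_onset[-1] - 2.6, t_session - 3)
    for (i in seq_len(n)) {
      if (span_hi[i] <= span_lo[i]) next
      t <- span_lo[i] + rexp(1, bout_rate)
      while (t < span_hi[i]) {
        dur <- runif(1, 1.5, 4)
        gaps <- pmin(rexp(50, rates[["iti_bout"]]), 2.9)
        bl <- t + c(0, cumsum(gaps))
        bl <- bl[bl <= min(t + dur, span_hi[i] + 2.4)]
        bout_starts <- c(bout_starts, t)
        licks <- c(licks, bl)
        t <- max(bl) + 3.05 + rexp(1, bout_rate)
      }
    }
  }
  list(licks = sort(licks), bout_starts = bout_starts,
       burst_starts = burst_starts)
}

# vectorised whole-session trace builder (same model as simulate_trace,
# applied to every neuron at once; draw order: responses/onsets per neuron,
# spontaneous events, drift phases, then one noise matrix)
build_session_traces <- function(classes, p_day, amp, base_f, trials,
                                 lick_info, config, t_session) {
  rate <- config$frame_rate
  L <- as.integer(round(t_session * rate))
  n <- length(classes)
  onset_list <- vector("list", n)
  kind_list <- vector("list", n)
  resp <- list()
  draw_stim <- function(stim, times) {
    drives <- switch(stim, cs = c("cs", "cs_and_reward"),
                     reward = c("reward", "cs_and_reward"), lick_bout = "lick")
    for (ni in which(classes %in% drives)) {
      responded <- runif(length(times)) < p_day[ni] & !is.na(times)
      onset <- rep(NA_real_, length(times))
      if (any(responded)) {
        jit <- config$latency + rnorm(sum(responded), 0, config$latency_jitter)
        onset[responded] <- pmin(pmax(times[responded] + pmax(jit, 0),
                                      times[responded]), t_session - 1)
        onset_list[[ni]] <<- c(onset_list[[ni]], onset[responded])
        kind_list[[ni]] <<- c(kind_list[[ni]],
                              rep("stimulus", sum(responded)))
      }
      resp[[length(resp) + 1L]] <<- tibble(
        neuron = ni, trial = seq_along(times), stimulus = stim,
        responded = responded, onset = onset
      )
    }
  }
  draw_stim("cs", trials$cs_onset)
  rw_times <- if (config$paradigm == "nonpaired") lick_info$burst_starts else
    trials$reward_time
  draw_stim("reward", rw_times)
  if (length(lick_info$bout_starts) > 0) {
    draw_stim("lick_bout", lick_info$bout_starts)
  }
  for (ni in seq_len(n)) {
    k <- rpois(1, config$spont_rate * t_session)
    if (k > 0) {
      sp <- runif(k, 1, t_session - 2)
      onset_list[[ni]] <- c(onset_list[[ni]], sp)
      kind_list[[ni]] <- c(kind_list[[ni]], rep("spontaneous", k))
    }
  }
  tau_r <- config$kinetics[[1]]
  tau_d <- config$kinetics[[2]]
  ker_n <- as.integer(ceiling(5 * tau_d * rate))
  f <- matrix(0, n, L)
  for (ni in seq_len(n)) {
    ons <- onset_list[[ni]]
    if (is.null(ons) || length(ons) == 0) next
    row <- numeric(L)
    for (on in ons) {
      i0 <- frame_of_time(on, rate)
      idx <- i0:min(L, i0 + ker_n)
      row[idx] <- row[idx] + amp[ni] * ca_kernel((idx - 1) / rate - on,
                                                 tau_r, tau_d)
    }
    f[ni, ] <- row
  }
  phase <- runif(n, 0, 2 * pi)
  ang <- 2 * pi * ((seq_len(L) - 1) / rate) / config$drift[[2]]
  # sin(ang + phase) expanded so the transcendental grid is computed once
  drift <- config$drift[[1]] *
    (outer(cos(phase), sin(ang)) + outer(sin(phase), cos(ang)))
  f <- base_f * (1 + drift) + f
  f <- f + matrix(rnorm(n * L, 0, config$noise_sd), n, L)
  responses <- if (length(resp) > 0) bind_rows(resp) else
    tibble(neuron = integer(), trial = integer(), stimulus = character(),
           responded = logical(), onset = numeric())
  events <- tibble(
    neuron = rep(seq_len(n), lengths(onset_list)),
    onset = unlist(onset_list) %||% numeric(),
    kind = unlist(kind_list) %||% character()
  )
  list(f = f, responses = responses, events = events)
}

# difference-of-exponentials transient kernel, peak-normalised to 1
ca_kernel <- function(t, tau_rise, tau_decay) {
  tpk <- tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
  norm <- exp(-tpk / tau_decay) - exp(-tpk / tau_rise)
  out <- (exp(-t / tau_decay) - exp(-t / tau_rise)) / norm
  out[t < 0] <- 0
  out
}

#' Simulate one neuron's raw fluorescence trace
#'
#' The trace is `baseline * (1 + drift) + transients + noise`: a sinusoidal
#' fractional drift, difference-of-exponentials transients (peak scaled to
#' `amplitude` noise-SD units) at stimulus-driven and spontaneous onsets,
#' and white Gaussian noise. Stimulus-driven onsets occur per trial with the
#' neuron's response probability; each realized response is recorded so the
#' ground truth matches the injected transients exactly.
#'
#' @param tuned_class One of `"cs"`, `"reward"`, `"cs_and_reward"`,
#'   `"lick"`, `"untuned"`.
#' @param response_prob Per-trial (or per-bout) response probability.
#' @param amplitude Transient peak, noise-SD units.
#' @param trials Trial tibble.
#' @param lick_info Result of [simulate_licks()].
#' @param config A [generator_config()] (kinetics, noise, drift, rates).
#' @param t_session Session length (s).
#' @param baseline_f Baseline fluorescence (a.u.).
#' @return List with `f` (raw trace), `responses` (tibble: trial, stimulus,
#'   responded, onset), `events` (tibble: onset, kind).
#' @export
simulate_trace <- function(tuned_class, response_prob, amplitude, trials,
                           lick_info, config, t_session,
                           baseline_f = NULL) {
  rate <- config$frame_rate
  L <- as.integer(round(t_session * rate))
  baseline_f <- baseline_f %||% runif(1, config$baseline_range[1],
                                      config$baseline_range[2])
  onsets <- numeric()
  resp <- list()
  add_stimulus <- function(stim, times) {
    responded <- runif(length(times)) < response_prob & !is.na(times)
    onset <- rep(NA_real_, length(times))
    if (any(responded)) {
      jit <- config$latency + rnorm(sum(responded), 0, config$latency_jitter)
      onset[responded] <- pmin(pmax(times[responded] + pmax(jit, 0),
                                    times[responded]), t_session - 1)
      onsets <<- c(onsets, onset[responded])
    }
    resp[[length(resp) + 1L]] <<- tibble(
      trial = seq_along(times), stimulus = stim,
      responded = responded, onset = onset
    )
  }
  if (tuned_class %in% c("cs", "cs_and_reward")) {
    add_stimulus("cs", trials$cs_onset)
  }
  if (tuned_class %in% c("reward", "cs_and_reward")) {
    rw <- if (config$paradigm == "nonpaired") lick_info$burst_starts else trials$reward_time
    add_stimulus("reward", rw)
  }
  if (tuned_class == "lick" && length(lick_info$bout_starts) > 0) {
    add_stimulus("lick_bout", lick_info$bout_starts)
  }
  kinds <- rep("stimulus", length(onsets))
  n_spont <- rpois(1, config$spont_rate * t_session)
  if (n_spont > 0) {
    sp <- runif(n_spont, 1, t_session - 2)
    onsets <- c(onsets, sp)
    kinds <- c(kinds, rep("spontaneous", n_spont))
  }
  signal <- numeric(L)
  if (length(onsets) > 0) {
    tau_r <- config$kinetics[[1]]
    tau_d <- config$kinetics[[2]]
    ker_n <- as.integer(ceiling(5 * tau_d * rate))
    for (on in onsets) {
      i0 <- frame_of_time(on, rate)
      idx <- i0:min(L, i0 + ker_n)
      tt <- (idx - 1) / rate - on
      signal[idx] <- signal[idx] + amplitude * ca_kernel(tt, tau_r, tau_d)
    }
  }
  phase <- runif(1, 0, 2 * pi)
  tgrid <- (seq_len(L) - 1) / rate
  drift <- config$drift[[1]] * sin(2 * pi * tgrid / config$drift[[2]] + phase)
  f <- baseline_f * (1 + drift) + signal + rnorm(L, 0, config$noise_sd)
  responses <- if (length(resp) > 0) bind_rows(resp) else
    tibble(trial = integer(), stimulus = character(),
           responded = logical(), onset = numeric())
  list(f = f, responses = responses,
       events = tibble(onset = onsets, kind = kinds))
}

#' Simulate a full cohort with ground truth
#'
#' Generates `n_mice` mice, each with the configured days, under a fixed
#' draw order (trials, then licks, then per-neuron transients and noise) so
#' a fixed seed reproduces the cohort exactly. All neurons are tracked
#' across days (identity correspondence).
#'
#' @param config A [generator_config()].
#' @param windows [analysis_windows()].
#' @param cell_type Cell-type label stamped on the sessions.
#' @return List with `cohort` (a [ca_cohort()]) and `truth` (class
#'   `ca_ground_truth`: neuron specs, per-trial response booleans, event
#'   onsets, bout/burst times).
#' @export
simulate_cohort <- function(config, windows = analysis_windows(),
                            cell_type = "PN") {
  stopifnot(inherits(config, "ca_generator_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n_nrn <- config$n_neurons_per_mouse
  counts <- class_counts(config$class_fractions, n_nrn)
  sessions <- list()
  specs_all <- list()
  resp_all <- list()
  events_all <- list()
  bouts_all <- list()
  for (mi in seq_len(config$n_mice)) {
    mouse <- sprintf("m%02d", mi)
    classes <- rep(names(counts), times = counts)
    p1 <- resolve_per_neuron(config$response_prob_day1, n_nrn)
    p7 <- if (is.null(config$response_prob_day7)) {
      pmin(1, p1 + config$day7_boost)
    } else resolve_per_neuron(config$response_prob_day7, n_nrn)
    amp <- resolve_per_neuron(config$amplitude, n_nrn)
    base_f <- runif(n_nrn, config$baseline_range[1], config$baseline_range[2])
    specs_all[[mi]] <- tibble(
      mouse_id = mouse, neuron = seq_len(n_nrn), tuned_class = classes,
      response_prob_day1 = p1, response_prob_day7 = p7, amplitude = amp
    )
    for (day in config$days) {
      tr <- simulate_trials(config, windows)
      learned <- config$paradigm == "paired" && day == 7 && config$learned_day7
      lk <- simulate_licks(tr$trials, config$paradigm, learned,
                           config$lick_rates, config$bout_rate,
                           tr$t_session, windows)
      p_day <- if (day == 7) p7 else p1
      built <- build_session_traces(classes, p_day, amp, base_f, tr$trials,
                                    lk, config, tr$t_session)
      f <- built$f
      if (nrow(built$responses) > 0) {
        resp_all[[length(resp_all) + 1L]] <- built$responses %>%
          mutate(mouse_id = mouse, day = day)
      }
      if (nrow(built$events) > 0) {
        events_all[[length(events_all) + 1L]] <- built$events %>%
          mutate(mouse_id = mouse, day = day)
      }
      bouts_all[[length(bouts_all) + 1L]] <- tibble(
        mouse_id = mouse, day = day,
        bout_start = lk$bout_starts
      )
      sessions[[length(sessions) + 1L]] <- ca_session(
        fluorescence = f, trials = tr$trials, licks = lk$licks,
        mouse_id = mouse, day = day, cell_type = cell_type,
        paradigm = config$paradigm, frame_rate = config$frame_rate,
        t_session = tr$t_session, windows = windows
      )
    }
  }
  truth <- structure(
    list(
      specs = bind_rows(specs_all),
      responses = if (length(resp_all)) bind_rows(resp_all) else NULL,
      events = if (length(events_all)) bind_rows(events_all) else NULL,
      bouts = bind_rows(bouts_all),
      config = config
    ),
    class = "ca_ground_truth"
  )
  list(cohort = ca_cohort(sessions), truth = truth)
}
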