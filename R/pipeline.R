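#' Assemble (or load) a pipeline run configuration
#'
#' Either reads a JSON/YAML config file or builds one from arguments.
#' Recognised fields: `generator` (arguments for [generator_config()]) or
#' `input_dir` (a [write_cohort()] directory), `cell_type`, `n_iter`,
#' `n_shifts`, `seed`, `gating`, `bonferroni_m`, `detect_events`,
#' `out_dir`.
#'
#' @param path Optional path to a `.json` or `.yaml`/`.yml` file.
#' @param ... Fields overriding (or replacing) the file contents.
#' @return A list of class `ca_run_config`.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- list()
  if (!is.null(path)) {
    cfg <- if (grepl("\\.ya?ml$", path)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        abort("the yaml package is needed to read YAML configs")
      }
      yaml::read_yaml(path)
    } else {
      jsonlite::read_json(path, simplifyVector = TRUE)
    }
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  defaults <- list(cell_type = "PN", n_iter = 1000, n_shifts = 1000,
                   seed = 1L, gating = TRUE, bonferroni_m = 4,
                   detect_events = TRUE, out_dir = NULL)
  for (nm in names(defaults)) cfg[[nm]] <- cfg[[nm]] %||% defaults[[nm]]
  if (cfg$n_iter < 100) abort("n_iter must be >= 100")
  structure(cfg, class = "ca_run_config")
}

#' Run the full analysis pipeline on a cohort
#'
#' Stages, in order: preprocessing and event detection per session; the
#' Monte-Carlo percent-responsive test per day and stimulus; significance
#' gating (only day/stimulus combinations whose responsive fraction is
#' significantly *above* chance on both days are analysed further —
#' significantly lower combinations are reported but not followed up);
#' reliability indices, High/Low split, Low-group delta-reliability with
#' the random-sampling control and its KS comparison; tuning delta-rho-bar
#' with its bootstrap/scramble null; onset latencies and cross-day fates;
#' behavioural lick metrics and the licking-confound analyses. All
#' resampler draws derive from `config$seed`, and the full null samples are
#' kept in the report so significance can be re-assessed without
#' recomputation.
#'
#' @param config A [run_config()].
#' @param cohort Optionally, a prebuilt [ca_cohort()] (otherwise simulated
#'   from `config$generator` or read from `config$input_dir`).
#' @return A list of class `ca_report`; when `config$out_dir` is set the
#'   tables are also written there as CSV plus a `summary.json`.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "ca_run_config"))
  set.seed(config$seed)
  truth <- NULL
  if (is.null(cohort)) {
    if (!is.null(config$generator)) {
      gen <- do.call(generator_config, config$generator)
      sim <- simulate_cohort(gen, cell_type = config$cell_type)
      cohort <- sim$cohort
      truth <- sim$truth
    } else if (!is.null(config$input_dir)) {
      cohort <- read_cohort(config$input_dir)
    } else {
      abort("config needs either `generator` or `input_dir`")
    }
  }
  days <- sort(unique(vapply(cohort$sessions, `[[`, integer(1), "day")))
  paradigm <- cohort$sessions[[1]]$paradigm
  stimuli <- if (paradigm == "tone_only") "cs" else c("cs", "reward")

  analyses <- list()
  for (d in days) {
    analyses[[as.character(d)]] <- lapply(cohort$mice, function(m) {
      s <- cohort_session(cohort, m, d)
      tc <- cohort$tracked_cells %>% filter(.data$mouse_id == m)
      nrns <- if (d == 1) tc$neuron_day1 else tc$neuron_day7
      analyze_session(s, neurons = nrns, detect = config$detect_events,
                      n_shifts = config$n_shifts)
    })
  }

  active_tbl <- purrr::map_dfr(days, function(d) {
    purrr::map_dfr(analyses[[as.character(d)]], function(a) tibble(
      mouse_id = a$session$mouse_id, day = d,
      percent_active = a$pct_active, n_active = length(a$active)))
  })

  mc_tests <- list()
  for (d in days) for (stim in stimuli) {
    mc_tests[[paste(stim, d, sep = "_day")]] <- null_percent_responsive(
      analyses[[as.character(d)]], stim, n_iter = config$n_iter,
      bonferroni_m = config$bonferroni_m)
  }
  gate <- function(stim) {
    if (!config$gating) return(TRUE)
    all(vapply(days, function(d) {
      t <- mc_tests[[paste(stim, d, sep = "_day")]]
      t$significant_adjusted && t$direction == "upper"
    }, logical(1)))
  }
  gated <- stimuli[vapply(stimuli, gate, logical(1))]

  resp <- purrr::map_dfr(unlist(analyses, recursive = FALSE),
                         responsiveness_table, stimuli = stimuli)
  rel <- reliability_table(resp)
  pct <- percent_responsive_summary(resp)

  both_days <- all(c(1, 7) %in% days)
  reliability_analysis <- list()
  tuning_tests <- list()
  fates <- list()
  latencies <- list()
  for (stim in gated) {
    if (!both_days) break
    wide <- rel %>%
      filter(.data$stimulus == stim) %>%
      tidyr::pivot_wider(id_cols = c("mouse_id", "neuron"),
                         names_from = "day", values_from = "reliability",
                         names_prefix = "d", values_fill = NA) %>%
      filter(!is.na(.data$d1) & !is.na(.data$d7))
    split <- split_by_reliability(wide$d1)
    wide$group <- split$group
    low <- wide %>% filter(.data$group == "Low")
    drand <- purrr::map_dfr(seq_along(cohort$mice), function(i) {
      a7 <- analyses[["7"]][[i]]
      lw <- low %>% filter(.data$mouse_id == cohort$mice[i],
                           .data$neuron %in% a7$active)
      if (nrow(lw) == 0) return(NULL)
      delta_reliability_random(a7, lw$neuron, lw$d1) %>%
        mutate(mouse_id = cohort$mice[i])
    })
    low <- low %>% mutate(delta = delta_reliability(.data$d1, .data$d7))
    ks <- if (nrow(low) >= 2 && nrow(drand) >= 2) {
      compare_reliability_distributions(low$delta, drand$delta_random)
    } else NULL
    reliability_analysis[[stim]] <- list(
      threshold = attr(split, "threshold"), table = wide, low = low,
      delta_random = drand, ks_delta = ks,
      group_means = wide %>% group_by(.data$group) %>%
        summarise(day1 = mean(.data$d1), day7 = mean(.data$d7),
                  n = n(), .groups = "drop")
    )
    tuning_tests[[stim]] <- null_mean_delta_rho(
      analyses[["1"]], analyses[["7"]], stimulus = stim,
      n_iter = config$n_iter)
    fates[[stim]] <- cross_day_fate(rel, stim)
    latencies[[stim]] <- purrr::map_dfr(unlist(analyses, recursive = FALSE),
                                        onset_latency, stimulus = stim)
  }

  behavior <- list(
    binned = purrr::map_dfr(cohort$sessions, function(s) {
      binned_lick_rate(s) %>% mutate(mouse_id = s$mouse_id, day = s$day)
    }),
    anticipatory = purrr::map_dfr(cohort$sessions, function(s) {
      tibble(mouse_id = s$mouse_id, day = s$day,
             rate = mean(anticipatory_lick_rate(s)$rate))
    }),
    comparison = purrr::map_dfr(cohort$sessions, lick_rate_comparison)
  )

  licking <- list()
  if (length(gated) > 0) {
    licking$bout_reliability <- purrr::map_dfr(
      unlist(analyses, recursive = FALSE), bout_reliability)
    licking$lick_cells <- purrr::map_dfr(
      unlist(analyses, recursive = FALSE), classify_lick_cells)
  }

  report <- structure(
    list(config = config, days = days, stimuli = stimuli, gated = gated,
         active = active_tbl, mc_tests = mc_tests,
         percent_responsive = pct, reliability = rel,
         reliability_analysis = reliability_analysis,
         tuning = tuning_tests, fates = fates, latencies = latencies,
         behavior = behavior, licking = licking, truth = truth,
         seed = config$seed),
    class = "ca_report"
  )
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.ca_report <- function(x, ...) {
  cat(sprintf("<ca_report> days %s; gated stimuli: %s\n",
              paste(x$days, collapse = ","),
              if (length(x$gated)) paste(x$gated, collapse = ",") else
                "none (no significant task responses)"))
  for (t in x$mc_tests) print(t)
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) utils::write.csv(
    df, file.path(out_dir, paste0(name, ".csv")), row.names = FALSE)
  wr(report$active, "percent_active")
  wr(report$percent_responsive$per_mouse, "percent_responsive_per_mouse")
  wr(report$percent_responsive$summary, "percent_responsive_summary")
  wr(report$reliability, "reliability")
  wr(report$behavior$comparison, "lick_rate_comparison")
  wr(report$behavior$anticipatory, "anticipatory_lick_rate")
  wr(purrr::map_dfr(report$mc_tests, tidy, .id = "test"), "mc_tests")
  nulls <- purrr::map_dfr(report$mc_tests, function(t) tibble(
    label = t$label, value = t$null_values))
  wr(nulls, "null_samples")
  summary <- list(
    seed = report$seed, gated = report$gated,
    verdicts = lapply(report$mc_tests, function(t) list(
      observed = t$observed, p = t$p_two, stars = t$stars))
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Two-sample KS comparison of reliability (or delta-reliability) values
#'
#' Thin wrapper over the standard two-sample Kolmogorov-Smirnov test with
#' the task's pooling convention (per-neuron indices pooled across mice).
#'
#' @param a,b Numeric vectors of indices.
#' @return One-row tibble: `statistic`, `p_value`, `n_a`, `n_b`.
#' @export
compare_reliability_distributions <- function(a, b) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) {
    warn("fewer than two values per group; KS comparison not computed")
    return(tibble(statistic = NA_real_, p_value = NA_real_,
                  n_a = length(a), n_b = length(b)))
  }
  ks <- suppressWarnings(ks.test(a, b))
  tibble(statistic = unname(ks$statistic), p_value = ks$p.value,
         n_a = length(a), n_b = length(b))
}
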