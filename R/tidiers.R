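#' Tidy a Monte-Carlo resampling test
#'
#' @param x A `ca_mc_test` (from [null_percent_responsive()] or
#'   [null_mean_delta_rho()]).
#' @param ... Unused.
#' @return One-row tibble: `label`, `observed`, `null_mean`, `null_lo`,
#'   `null_hi` (central 95% of the null), `p_value`, `p_adjusted`,
#'   `stars`, `significant`.
#' @export
tidy.ca_mc_test <- function(x, ...) {
  q <- quantile(x$null_values, c(0.025, 0.975), names = FALSE)
  tibble(
    label = x$label, observed = x$observed,
    null_mean = mean(x$null_values), null_lo = q[1], null_hi = q[2],
    p_value = x$p_two, p_adjusted = x$p_adjusted, stars = x$stars,
    significant = x$significant_adjusted
  )
}

#' @rdname tidy.ca_mc_test
#' @export
glance.ca_mc_test <- function(x, ...) {
  tibble(n_iter = x$n_iter, n = x$n, bonferroni_m = x$bonferroni_m,
         direction = x$direction)
}

#' Tidy a pipeline report into one row per resampling verdict
#'
#' @param x A `ca_report` from [run_pipeline()].
#' @param ... Unused.
#' @return Tibble of all Monte-Carlo verdicts in the report.
#' @export
tidy.ca_report <- function(x, ...) {
  bind_rows(
    purrr::map_dfr(x$mc_tests, tidy),
    purrr::map_dfr(x$tuning, tidy)
  )
}

#' @rdname tidy.ca_report
#' @export
glance.ca_report <- function(x, ...) {
  tibble(
    n_mice = length(unique(x$active$mouse_id)),
    n_days = length(x$days),
    gated = paste(x$gated, collapse = ","),
    seed = x$seed
  )
}
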