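# On-disk session container: a directory of plain-text files
#   meta.json   session metadata (mouse, day, cell type, paradigm, rate, T)
#   F.csv       neurons x frames raw fluorescence, one neuron per row
#   trials.csv  cs_onset, reward_time, included
#   licks.csv   one timestamp per row
# Numbers are written with 17 significant digits so a write/read round trip
# is bit-identical for doubles.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write a session to a plain-text container
#'
#' @param session A [ca_session()].
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @seealso [read_session()]
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "ca_session"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) abort(sprintf("cannot create '%s'", path))
  meta <- session[c("mouse_id", "day", "cell_type", "paradigm",
                    "frame_rate", "t_session")]
  meta$n_neurons <- nrow(session$fluorescence)
  meta$n_frames <- ncol(session$fluorescence)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  f <- file.path(path, "F.csv")
  if (meta$n_neurons == 0) {
    writeLines(character(), f)
  } else {
    rows <- apply(session$fluorescence, 1, function(r) paste(fmt_num(r), collapse = ","))
    writeLines(rows, f)
  }
  tr <- session$trials
  writeLines(
    c("cs_onset,reward_time,included",
      paste(fmt_num(tr$cs_onset), fmt_num(tr$reward_time),
            ifelse(is.na(tr$included), "NA", tr$included), sep = ",")),
    file.path(path, "trials.csv")
  )
  writeLines(c("lick_time", fmt_num(session$licks)), file.path(path, "licks.csv"))
  invisible(path)
}

#' Read a session from its plain-text container
#'
#' Inverse of [write_session()]; validates the result, so malformed
#' containers fail with an error naming the offending file or field.
#'
#' @param path Session directory.
#' @param windows [analysis_windows()] used for validation.
#' @return A [ca_session()].
#' @export
read_session <- function(path, windows = analysis_windows()) {
  if (!dir.exists(path)) abort(sprintf("no session directory at '%s'", path))
  need <- c("meta.json", "F.csv", "trials.csv", "licks.csv")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing) > 0) {
    abort(sprintf("session container missing: %s",
                  paste(sub("\\..*$", "", missing), collapse = ", ")))
  }
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  for (field in c("mouse_id", "day", "frame_rate", "t_session", "n_neurons", "n_frames")) {
    if (is.null(meta[[field]])) abort(sprintf("meta.json missing field '%s'", field))
  }
  flines <- readLines(file.path(path, "F.csv"))
  flines <- flines[nzchar(flines)]
  if (length(flines) != meta$n_neurons) {
    abort("F.csv row count does not match meta.json n_neurons")
  }
  f <- if (meta$n_neurons == 0) {
    matrix(numeric(), nrow = 0, ncol = meta$n_frames)
  } else {
    do.call(rbind, lapply(flines, function(l) {
      as.numeric(strsplit(l, ",", fixed = TRUE)[[1]])
    }))
  }
  if (meta$n_neurons > 0 && ncol(f) != meta$n_frames) {
    abort("F.csv column count does not match meta.json n_frames")
  }
  tr <- utils::read.csv(file.path(path, "trials.csv"),
                        colClasses = c("numeric", "numeric", "logical"))
  lk <- utils::read.csv(file.path(path, "licks.csv"), colClasses = "numeric")
  if (!"lick_time" %in% names(lk)) abort("licks.csv missing field 'lick_time'")
  ca_session(
    fluorescence = f, trials = tr, licks = lk$lick_time,
    mouse_id = meta$mouse_id, day = meta$day,
    cell_type = meta$cell_type %||% "PN", paradigm = meta$paradigm %||% "paired",
    frame_rate = meta$frame_rate, t_session = meta$t_session, windows = windows
  )
}

#' Write a whole cohort (sessions plus tracked-cell table)
#' @param cohort A [ca_cohort()].
#' @param path Directory; one subdirectory per session is created.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (s in cohort$sessions) {
    write_session(s, file.path(path, paste(s$mouse_id, s$day, sep = "_day")))
  }
  utils::write.csv(cohort$tracked_cells, file.path(path, "tracked_cells.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#' @param path Cohort directory.
#' @return A [ca_cohort()].
#' @export
read_cohort <- function(path) {
  dirs <- list.dirs(path, recursive = FALSE)
  sessions <- lapply(dirs, read_session)
  tc_path <- file.path(path, "tracked_cells.csv")
  tracked <- if (file.exists(tc_path)) utils::read.csv(tc_path) else NULL
  ca_cohort(sessions, tracked)
}
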