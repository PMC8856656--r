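# internal time/frame conventions, used by every module:
# frame k (1-based) covers [(k-1)/rate, k/rate); the frame containing time t
# is floor(t * rate) + 1; an analysis window [start, start + len) maps to a
# fixed-length run of round(len * rate) frames beginning at the frame
# containing `start`.

frame_of_time <- function(t, rate) as.integer(floor(t * rate)) + 1L

window_frames <- function(start, len, rate) {
  first <- frame_of_time(start, rate)
  seq.int(first, first + as.integer(round(len * rate)) - 1L)
}

window_n_frames <- function(len, rate) as.integer(round(len * rate))

# maximal runs of TRUE in a logical vector, as a two-column matrix
true_runs <- function(x) {
  r <- rle(as.logical(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & !is.na(r$values)
  cbind(start = starts[keep], end = ends[keep])
}

# TRUE iff x contains >= min_run consecutive values strictly above thresh
has_run_above <- function(x, thresh = 1, min_run = 5L) {
  if (length(x) < min_run) return(FALSE)
  r <- rle(x > thresh)
  any(r$values & r$lengths >= min_run)
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
}
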