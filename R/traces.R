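#' Construct a raw signal trace
#'
#' A `raw_trace` holds a uniformly sampled pupil-area or locomotion signal.
#' Pupil area is in arbitrary camera units (later normalized per epoch);
#' locomotion is in cm/s.
#'
#' @param values numeric vector of samples (length >= 2, all finite unless
#'   explicitly allowed).
#' @param sampling_rate samples per second (> 0); recordings in this paradigm
#'   are acquired at 20 Hz.
#' @param channel `"pupil"` or `"locomotion"`.
#' @return an object of class `raw_trace`.
#' @export
raw_trace <- function(values, sampling_rate = 20, channel = c("pupil", "locomotion")) {
  channel <- match.arg(channel)
  values <- as.numeric(values)
  if (length(values) < 2) stop("a trace needs at least 2 samples", call. = FALSE)
  if (!is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("`sampling_rate` must be > 0", call. = FALSE)
  }
  structure(
    list(values = values, sampling_rate = sampling_rate, channel = channel),
    class = "raw_trace"
  )
}

#' @export
print.raw_trace <- function(x, ...) {
  cat(sprintf(
    "<raw_trace> %s, %d samples at %g Hz (%.1f s)\n",
    x$channel, length(x$values), x$sampling_rate,
    length(x$values) / x$sampling_rate
  ))
  invisible(x)
}

#' @export
length.raw_trace <- function(x) length(x$values)

#' Construct a stimulus-event log
#'
#' @param onset numeric vector of stimulus onsets in seconds from trace start.
#' @param intensity numeric vector of stimulus intensities in uA (>= 0).
#' @return data.frame with columns `onset`, `intensity`.
#' @export
stimulus_events <- function(onset, intensity) {
  if (length(onset) != length(intensity)) {
    stop("`onset` and `intensity` must have the same length", call. = FALSE)
  }
  if (any(intensity < 0)) stop("intensities must be >= 0", call. = FALSE)
  if (is.unsorted(onset)) stop("onsets must be non-decreasing", call. = FALSE)
  data.frame(onset = as.numeric(onset), intensity = as.numeric(intensity))
}

#' Read / write traces and event logs as plain tabular text
#'
#' Traces are stored one sample per row with a `value` column; the sampling
#' rate and channel are kept in `#`-prefixed header lines. Event logs use
#' columns `onset_s`, `intensity_uA`.
#'
#' @param trace a [raw_trace()].
#' @param path file path.
#' @return `read_trace()` returns a `raw_trace`; writers return `path`
#'   invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "raw_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# sampling_rate: %.10g", trace$sampling_rate),
    sprintf("# channel: %s", trace$channel),
    "value"
  ), con)
  writeLines(format(trace$values, digits = 15, trim = TRUE, scientific = FALSE), con)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  hdr <- readLines(path, n = 2)
  rate <- as.numeric(sub("# sampling_rate: *", "", hdr[1]))
  channel <- sub("# channel: *", "", hdr[2])
  vals <- read.csv(path, comment.char = "#")$value
  raw_trace(vals, sampling_rate = rate, channel = channel)
}

#' @rdname write_trace
#' @param events a data.frame from [stimulus_events()].
#' @export
write_events <- function(events, path) {
  write.csv(
    data.frame(onset_s = events$onset, intensity_uA = events$intensity),
    path, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_trace
#' @export
read_events <- function(path) {
  d <- read.csv(path)
  stimulus_events(d$onset_s, d$intensity_uA)
}
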