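#' Remove blink artifacts from a pupil trace
#'
#' Implements the derivative rule used for pupil tracks: take the absolute
#' first difference of the signal, median-filter it, min-max normalize the
#' filtered track to `[0, 1]`, and flag every difference exceeding
#' `derivative_threshold`. Both endpoint samples of a flagged difference are
#' replaced by `NA` and then linearly interpolated between the nearest valid
#' neighbors (edges are extended with the nearest valid value).
#'
#' Conventions for unstated corner cases: the median-filter kernel defaults
#' to 5 samples (0.25 s at 20 Hz) and is truncated to the largest odd length
#' that fits short traces; when the filtered derivative is constant the
#' min-max normalization is degenerate and the trace is returned unchanged
#' (a constant-slope trace contains no blinks).
#'
#' @param trace a [raw_trace()] (length >= 3).
#' @param derivative_threshold flagging threshold on the normalized filtered
#'   derivative (default 0.2).
#' @param median_window median-filter kernel length in samples (odd).
#' @return a cleaned `raw_trace`; flagged sample indices are attached as
#'   attribute `"flagged_samples"`.
#' @export
remove_blinks <- function(trace, derivative_threshold = 0.2, median_window = 5L) {
  stopifnot(inherits(trace, "raw_trace"))
  x <- trace$values
  n <- length(x)
  if (n < 3) stop("trace too short for blink removal", call. = FALSE)
  ad <- abs(diff(x))
  k <- min(as.integer(median_window), if (length(ad) %% 2 == 1) length(ad) else length(ad) - 1L)
  if (k %% 2 == 0) k <- k - 1L
  filt <- if (k >= 3) as.numeric(stats::runmed(ad, k, endrule = "keep")) else ad
  rng <- range(filt)
  if (rng[2] == rng[1]) {
    attr(trace, "flagged_samples") <- integer(0)
    return(trace)
  }
  norm <- (filt - rng[1]) / (rng[2] - rng[1])
  bad_diff <- which(norm > derivative_threshold)
  flagged <- sort(unique(c(bad_diff, bad_diff + 1L)))  # both endpoints
  if (length(flagged) == 0) {
    attr(trace, "flagged_samples") <- integer(0)
    return(trace)
  }
  if (length(flagged) >= n) {
    stop("every sample flagged as blink artifact; trace unusable", call. = FALSE)
  }
  y <- x
  y[flagged] <- NA_real_
  good <- which(!is.na(y))
  y <- approx(good, y[good], xout = seq_len(n), rule = 2)$y
  out <- raw_trace(y, sampling_rate = trace$sampling_rate, channel = trace$channel)
  attr(out, "flagged_samples") <- flagged
  out
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing with the parameters used for
#' pupil and locomotion tracks: polynomial order 6 and a 1.5 s window. The
#' window length in samples is `round(window_s * sampling_rate)` forced odd
#' by incrementing (31 samples at 20 Hz).
#'
#' @param trace a [raw_trace()].
#' @param poly_order polynomial order (default 6).
#' @param window_s window length in seconds (default 1.5).
#' @return a smoothed `raw_trace` of identical length.
#' @export
smooth_savgol <- function(trace, poly_order = 6L, window_s = 1.5) {
  stopifnot(inherits(trace, "raw_trace"))
  w <- round(window_s * trace$sampling_rate)
  if (w %% 2 == 0) w <- w + 1L
  if (w <= poly_order) {
    stop(sprintf(
      "window of %d samples must exceed polynomial order %d", w, poly_order
    ), call. = FALSE)
  }
  if (length(trace$values) <= w) {
    stop("trace shorter than the smoothing window", call. = FALSE)
  }
  sm <- signal::sgolayfilt(trace$values, p = poly_order, n = w)
  raw_trace(sm, sampling_rate = trace$sampling_rate, channel = trace$channel)
}

#' Epoch a trace around stimulus events
#'
#' Cuts one epoch per stimulus from `pre` s before to `post` s after onset.
#' The sample at the exact onset time belongs to the post-stimulus segment,
#' so at 20 Hz with `pre = 1, post = 4` each epoch has 100 samples (20 pre,
#' 80 post) and the time axis runs from -1 s to 3.95 s.
#'
#' @param trace a [raw_trace()].
#' @param events a [stimulus_events()] data.frame.
#' @param pre,post window extents in seconds.
#' @return object of class `trial_matrix`: list with `epochs`
#'   (trial x time matrix), `time` (s relative to onset), `intensity`
#'   (uA per trial), `normalization` (`"raw"`), and an `exclusions`
#'   data.frame logging dropped trials.
#' @export
epoch_trials <- function(trace, events, pre = 1, post = 4) {
  stopifnot(inherits(trace, "raw_trace"))
  rate <- trace$sampling_rate
  n_pre <- round(pre * rate)
  n_post <- round(post * rate)
  n <- length(trace$values)
  if (nrow(events) == 0) {
    return(structure(
      list(
        epochs = matrix(numeric(0), 0, n_pre + n_post),
        time = (seq_len(n_pre + n_post) - n_pre - 1) / rate,
        intensity = numeric(0), sampling_rate = rate,
        normalization = "raw",
        exclusions = data.frame(trial = integer(0), reason = character(0))
      ),
      class = "trial_matrix"
    ))
  }
  onset_idx <- round(events$onset * rate) + 1L
  first <- onset_idx - n_pre
  last <- onset_idx + n_post - 1L
  bad <- which(first < 1 | last > n)
  if (length(bad) > 0) {
    stop(sprintf(
      "epoch window outside trace bounds for event(s): %s",
      paste(bad, collapse = ", ")
    ), call. = FALSE)
  }
  epochs <- t(vapply(
    seq_along(onset_idx),
    function(i) trace$values[first[i]:last[i]],
    numeric(n_pre + n_post)
  ))
  structure(
    list(
      epochs = epochs,
      time = (seq_len(n_pre + n_post) - n_pre - 1) / rate,
      intensity = events$intensity, sampling_rate = rate,
      normalization = "raw",
      exclusions = data.frame(trial = integer(0), reason = character(0))
    ),
    class = "trial_matrix"
  )
}

#' @export
print.trial_matrix <- function(x, ...) {
  cat(sprintf(
    "<trial_matrix> %d trials x %d samples (%.2f..%.2f s), normalization: %s\n",
    nrow(x$epochs), ncol(x$epochs), min(x$time), max(x$time), x$normalization
  ))
  if (nrow(x$exclusions) > 0) {
    cat(sprintf("  %d excluded trial(s)\n", nrow(x$exclusions)))
  }
  invisible(x)
}

#' Normalize epochs to their prestimulus baseline
#'
#' `"zscore"` standardizes each epoch by the mean and sd of its 1 s
#' prestimulus window (the pupil convention); `"subtract_mean"` removes the
#' prestimulus mean but preserves scale (the locomotion convention). Epochs
#' whose prestimulus sd is zero cannot be z-scored; they are excluded and
#' logged with a reason rather than silently zeroed.
#'
#' @param trials a `trial_matrix` from [epoch_trials()].
#' @param mode `"zscore"` or `"subtract_mean"`.
#' @param baseline_s length of the prestimulus baseline window in seconds.
#' @return a normalized `trial_matrix`; exclusions are appended to
#'   `$exclusions`.
#' @export
normalize_epochs <- function(trials, mode = c("zscore", "subtract_mean"),
                             baseline_s = 1) {
  stopifnot(inherits(trials, "trial_matrix"))
  mode <- match.arg(mode)
  pre_idx <- which(trials$time < 0 & trials$time >= -baseline_s)
  if (length(pre_idx) < round(baseline_s * trials$sampling_rate)) {
    stop("epochs do not contain the full prestimulus baseline", call. = FALSE)
  }
  ep <- trials$epochs
  if (nrow(ep) == 0) {
    trials$normalization <- if (mode == "zscore") "zscored" else "baseline_subtracted"
    return(trials)
  }
  mu <- rowMeans(ep[, pre_idx, drop = FALSE])
  out <- ep - mu
  excl <- integer(0)
  if (mode == "zscore") {
    s <- apply(ep[, pre_idx, drop = FALSE], 1, sd)
    excl <- which(s == 0)
    if (length(excl) == nrow(ep)) {
      stop("all epochs have zero prestimulus variance; cannot z-score", call. = FALSE)
    }
    keep <- setdiff(seq_len(nrow(ep)), excl)
    out <- out[keep, , drop = FALSE] / s[keep]
    trials$intensity <- trials$intensity[keep]
  } else if (length(excl) > 0) {
    excl <- integer(0)
  }
  trials$epochs <- out
  trials$normalization <- if (mode == "zscore") "zscored" else "baseline_subtracted"
  if (length(excl) > 0) {
    trials$exclusions <- rbind(
      trials$exclusions,
      data.frame(trial = excl, reason = "zero prestimulus variance")
    )
  }
  trials
}

#' Extract one response value per trial
#'
#' The response is the mean of the normalized signal in the half-open window
#' `[window[1], window[2])` seconds after stimulus onset (default 1-2 s; 20
#' samples at 20 Hz).
#'
#' @param trials a normalized `trial_matrix`.
#' @param window two-element numeric, seconds after onset.
#' @return data.frame with columns `intensity` and `response`, one row per
#'   (retained) trial.
#' @export
extract_responses <- function(trials, window = c(1, 2)) {
  stopifnot(inherits(trials, "trial_matrix"))
  if (window[1] < min(trials$time) || window[2] > max(trials$time) + 1 / trials$sampling_rate) {
    stop("response window outside epoch extent", call. = FALSE)
  }
  idx <- which(trials$time >= window[1] & trials$time < window[2])
  if (length(idx) == 0) stop("response window contains no samples", call. = FALSE)
  data.frame(
    intensity = trials$intensity,
    response = rowMeans(trials$epochs[, idx, drop = FALSE])
  )
}

#' Subtract the 0 uA (sham) condition
#'
#' Averages responses per (animal, intensity) and subtracts each animal's
#' own mean response to the 0 uA condition, so the 0 uA row becomes exactly
#' zero and every other intensity is expressed relative to sham stimulation.
#'
#' @param responses data.frame with columns `animal`, `intensity`,
#'   `response` (per trial or already averaged).
#' @return data.frame with columns `animal`, `intensity`, `response`
#'   (zero-corrected per-animal means).
#' @export
subtract_zero_condition <- function(responses) {
  req <- c("animal", "intensity", "response")
  if (!all(req %in% names(responses))) {
    stop("`responses` needs columns animal, intensity, response", call. = FALSE)
  }
  agg <- aggregate(response ~ animal + intensity, data = responses, FUN = mean)
  out <- do.call(rbind, lapply(split(agg, agg$animal), function(d) {
    zero <- d$response[d$intensity == 0]
    if (length(zero) != 1) {
      stop(sprintf("animal %s has no 0 uA condition", d$animal[1]), call. = FALSE)
    }
    d$response <- d$response - zero
    d
  }))
  rownames(out) <- NULL
  out[order(out$animal, out$intensity), ]
}

#' Full preprocessing chain for one session
#'
#' Convenience wrapper running blink removal (pupil only), Savitzky-Golay
#' smoothing, epoching, baseline normalization (z-score for pupil,
#' baseline subtraction for locomotion), and response extraction.
#'
#' @param trace a [raw_trace()].
#' @param events a [stimulus_events()] data.frame.
#' @param normalization override the channel's default normalization mode.
#' @inheritParams epoch_trials
#' @return per-trial response data.frame as from [extract_responses()].
#' @export
session_responses <- function(trace, events, pre = 1, post = 4,
                              normalization = NULL) {
  if (trace$channel == "pupil") {
    trace <- remove_blinks(trace)
  }
  trace <- smooth_savgol(trace)
  trials <- epoch_trials(trace, events, pre = pre, post = post)
  mode <- if (!is.null(normalization)) normalization
          else if (trace$channel == "pupil") "zscore" else "subtract_mean"
  trials <- normalize_epochs(trials, mode = mode)
  extract_responses(trials)
}
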