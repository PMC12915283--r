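#' Configuration for a simulated pupillometry/locomotion session
#'
#' Holds the generating model for one head-fixed stimulation session. The
#' defaults reproduce the experimental design: an ascending-then-descending
#' ladder of tail-shock intensities (0, 50, 150, 300, 500 uA) repeated for 3
#' cycles (6 trials per level), 60 s between stimuli, sampled at 20 Hz, with
#' the evoked response amplitude following a sigmoid of intensity.
#'
#' @param sampling_rate samples per second (> 0).
#' @param ladder ordered stimulus intensities in uA (all >= 0). One
#'   ascending-descending cycle presents each intensity exactly twice, in the
#'   order `ladder[1], ..., ladder[n], ladder[1], ladder[n], ..., ladder[2]`.
#' @param repeats_per_level number of ascending-descending cycles; each level
#'   is presented `2 * repeats_per_level` times in total.
#' @param inter_stimulus_interval seconds between stimulus onsets.
#' @param true_params named numeric vector `c(b, L, k, x0)` of the generating
#'   sigmoid: baseline `b`, span `L`, slope `k` (per uA), threshold `x0` (uA).
#' @param noise_sd standard deviation (z-units) of the per-trial amplitude
#'   jitter, of the baseline pupillary unrest oscillation, and of the white
#'   sensor noise on the trace.
#' @param blink_rate blink artifacts per minute (>= 0). Real pupil tracks
#'   always contain blinks, and the blink-removal rule normalizes the
#'   derivative by its maximum — which presumes blink flanks dominate — so
#'   the default is a realistic 3 per minute.
#' @param seed integer seed; identical configs with identical seeds produce
#'   byte-identical sessions.
#' @return object of class `session_sim_config`.
#' @export
session_sim_config <- function(sampling_rate = 20,
                               ladder = c(0, 50, 150, 300, 500),
                               repeats_per_level = 3,
                               inter_stimulus_interval = 60,
                               true_params = c(b = 0.05, L = 0.9, k = 0.02, x0 = 250),
                               noise_sd = 0.05,
                               blink_rate = 3,
                               seed = 1L) {
  if (!is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("`sampling_rate` must be > 0", call. = FALSE)
  }
  if (length(ladder) < 1 || any(ladder < 0)) {
    stop("`ladder` intensities must all be >= 0", call. = FALSE)
  }
  repeats_per_level <- .check_count(repeats_per_level, "repeats_per_level")
  if (!is.finite(inter_stimulus_interval) || inter_stimulus_interval <= 0) {
    stop("`inter_stimulus_interval` must be > 0", call. = FALSE)
  }
  if (!all(c("b", "L", "k", "x0") %in% names(true_params))) {
    stop("`true_params` must be named c(b, L, k, x0)", call. = FALSE)
  }
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be >= 0", call. = FALSE)
  }
  if (!is.finite(blink_rate) || blink_rate < 0) {
    stop("`blink_rate` must be >= 0", call. = FALSE)
  }
  structure(
    list(
      sampling_rate = sampling_rate, ladder = as.numeric(ladder),
      repeats_per_level = repeats_per_level,
      inter_stimulus_interval = inter_stimulus_interval,
      true_params = true_params[c("b", "L", "k", "x0")],
      noise_sd = noise_sd, blink_rate = blink_rate, seed = as.integer(seed)
    ),
    class = "session_sim_config"
  )
}

# Evoked pupil transient: raised-cosine rise over `rise` s, unit plateau
# until `plateau_end` s, raised-cosine decay over `decay` s. The plateau
# spans the 1-2 s scoring window so the window mean of a unit transient is
# the trial amplitude itself.
.evoked_kernel <- function(t, rise = 0.5, plateau_end = 2, decay = 2.5) {
  k <- numeric(length(t))
  up <- t > 0 & t < rise
  k[up] <- 0.5 * (1 - cos(pi * t[up] / rise))
  k[t >= rise & t <= plateau_end] <- 1
  dn <- t > plateau_end & t < plateau_end + decay
  k[dn] <- 0.5 * (1 + cos(pi * (t[dn] - plateau_end) / decay))
  k
}

#' Simulate a stimulation session
#'
#' Generates a pupil trace plus its stimulus-event log. Each stimulus evokes
#' a transient whose amplitude is `sigmoid(intensity; true_params)` plus
#' Gaussian jitter (sd `noise_sd`). The baseline is ongoing pupillary
#' unrest, modeled as a phase-wandering oscillation around 2 Hz with sd
#' `noise_sd` — a band-limited process whose sd inside any 1 s prestimulus
#' window is well defined, as baseline z-scoring presumes — plus white
#' sensor noise of the same sd. Blink artifacts are injected at
#' `blink_rate` per minute via [inject_blinks()].
#'
#' @param config a [session_sim_config()].
#' @return list with elements `trace` (a [raw_trace()]) and `events`
#'   (a [stimulus_events()] data.frame).
#' @seealso [sigmoid_response()] for the generating amplitude model.
#' @export
simulate_pupil_session <- function(config) {
  if (!inherits(config, "session_sim_config")) {
    stop("`config` must be a session_sim_config", call. = FALSE)
  }
  set.seed(config$seed)
  rate <- config$sampling_rate
  isi <- config$inter_stimulus_interval
  lad <- config$ladder
  cycle <- if (length(lad) > 1) c(lad, lad[1], rev(lad[-1])) else rep(lad, 2)
  intensities <- rep(cycle, config$repeats_per_level)
  n_trials <- length(intensities)
  onsets <- isi * seq_len(n_trials)
  duration <- isi * (n_trials + 1)
  n <- round(duration * rate)

  p <- config$true_params
  values <- rnorm(n, sd = config$noise_sd)
  if (config$noise_sd > 0) {
    # baseline pupillary unrest: ~1 Hz oscillation with slowly wandering
    # phase; one full cycle per 1 s baseline window keeps the prestimulus
    # sd well defined regardless of stimulus timing
    phase <- cumsum(rnorm(n, sd = 0.05))
    values <- values + config$noise_sd * sqrt(2) *
      sin(2 * pi * seq_len(n) / rate + phase)
  }
  kt <- seq(0, 5.5, by = 1 / rate)
  kernel <- .evoked_kernel(kt)
  amp <- sigmoid_response(intensities, p["b"], p["L"], p["k"], p["x0"]) +
    rnorm(n_trials, sd = config$noise_sd)
  for (i in seq_len(n_trials)) {
    i0 <- round(onsets[i] * rate) + 1L
    idx <- i0:(i0 + length(kernel) - 1L)
    keep <- idx <= n
    values[idx[keep]] <- values[idx[keep]] + amp[i] * kernel[keep]
  }
  trace <- raw_trace(values, sampling_rate = rate, channel = "pupil")
  if (config$blink_rate > 0) {
    trace <- inject_blinks(trace, rate_per_min = config$blink_rate,
                           seed = config$seed + 1L)
  }
  list(trace = trace, events = stimulus_events(onsets, intensities))
}

#' Inject blink artifacts into a trace
#'
#' Inserts short V-shaped drops (2-5 samples wide) at Poisson-distributed
#' times. The steep flanks reproduce the high-first-derivative signature that
#' blink removal targets; `rate_per_min = 0` returns the input unchanged.
#'
#' @param trace a [raw_trace()].
#' @param rate_per_min expected artifacts per minute (>= 0).
#' @param amplitude drop depth in trace units.
#' @param seed integer seed.
#' @return a `raw_trace` with artifacts added; the insertion sample indices
#'   are attached as attribute `"blink_samples"`.
#' @export
inject_blinks <- function(trace, rate_per_min, amplitude = 5, seed = 1L) {
  stopifnot(inherits(trace, "raw_trace"))
  if (!is.finite(rate_per_min) || rate_per_min < 0) {
    stop("`rate_per_min` must be >= 0", call. = FALSE)
  }
  if (rate_per_min == 0) return(trace)
  set.seed(seed)
  n <- length(trace$values)
  minutes <- n / trace$sampling_rate / 60
  n_blinks <- rpois(1, rate_per_min * minutes)
  out <- trace
  touched <- integer(0)
  if (n_blinks > 0) {
    starts <- sort(sample.int(n - 8L, n_blinks, replace = TRUE) + 1L)
    widths <- sample(2:5, n_blinks, replace = TRUE)
    for (b in seq_len(n_blinks)) {
      w <- widths[b]
      k1 <- ceiling(w / 2)
      depths <- amplitude * c(seq_len(k1) / k1,
                              rev(seq_len(w - k1)) / (w - k1 + 1))
      idx <- starts[b]:(starts[b] + w - 1L)
      out$values[idx] <- out$values[idx] - depths
      touched <- c(touched, idx)
    }
  }
  attr(out, "blink_samples") <- sort(unique(touched))
  attr(out, "n_blinks") <- n_blinks
  out
}
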