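test_that("blink removal interpolates flagged samples per the derivative rule", {
  # hand-computed: |diff| = 0,4,4,0 -> filtered -> normalized 0,1,1,0;
  # both endpoints of each flagged difference removed and interpolated
  tr <- raw_trace(c(1, 1, 5, 1, 1), sampling_rate = 20)
  out <- remove_blinks(tr)
  expect_equal(out$values, rep(1, 5))
  expect_equal(attr(out, "flagged_samples"), 2:4)
})

test_that("constant and constant-slope traces pass through blink removal", {
  cst <- raw_trace(rep(5, 10), sampling_rate = 20)
  expect_equal(remove_blinks(cst)$values, rep(5, 10))
  # linear ramp: all |diff| equal, min-max normalization degenerate -> no flags
  ramp <- raw_trace(0:9, sampling_rate = 20)
  expect_equal(remove_blinks(ramp)$values, as.numeric(0:9))
  expect_length(attr(remove_blinks(ramp), "flagged_samples"), 0)
})

test_that("blink removal is idempotent on its target artifact class", {
  # blinks on a stationary baseline: the cleaned trace is artifact-free and
  # a second pass flags nothing
  tr <- raw_trace(rep(2, 2400), sampling_rate = 20)
  bl <- inject_blinks(tr, rate_per_min = 4, amplitude = 5, seed = 6)
  once <- remove_blinks(bl)
  twice <- remove_blinks(once)
  expect_identical(twice$values, once$values)
  expect_length(attr(twice, "flagged_samples"), 0)
})

test_that("repeated cleaning leaves extracted responses stable on full sessions", {
  # with evoked transients present the min-max rule renormalizes on a second
  # pass and touches transient flanks; the scientific readout (the 1-2 s
  # window mean) must not move
  s <- simulate_pupil_session(session_sim_config(
    noise_sd = 0, blink_rate = 4, seed = 6,
    ladder = c(0, 150, 500), repeats_per_level = 1,
    inter_stimulus_interval = 20
  ))
  resp_of <- function(tr) {
    tm <- epoch_trials(smooth_savgol(tr), s$events)
    extract_responses(normalize_epochs(tm, "subtract_mean"))$response
  }
  r1 <- resp_of(remove_blinks(s$trace))
  r2 <- resp_of(remove_blinks(remove_blinks(s$trace)))
  expect_equal(r2, r1, tolerance = 0.01)
})

test_that("Savitzky-Golay smoothing is exact on low-order polynomials", {
  t <- seq(0, 10, by = 0.05)
  x <- 2 + 0.5 * t - 0.1 * t^3 + 0.002 * t^6
  tr <- raw_trace(x, sampling_rate = 20)
  sm <- smooth_savgol(tr)  # 1.5 s window -> 31 samples at 20 Hz
  interior <- 16:(length(x) - 16)
  expect_equal(sm$values[interior], x[interior], tolerance = 1e-8)
  expect_equal(smooth_savgol(raw_trace(rep(2, 100), 20))$values, rep(2, 100))
  expect_error(smooth_savgol(raw_trace(rnorm(100), 2), poly_order = 6),
               "exceed")
})

test_that("epoching yields 100-sample epochs with the onset in the post segment", {
  tr <- raw_trace(seq_len(400) / 10, sampling_rate = 20)
  ev <- stimulus_events(onset = c(5, 10), intensity = c(0, 300))
  tm <- epoch_trials(tr, ev, pre = 1, post = 4)
  expect_equal(dim(tm$epochs), c(2, 100))
  expect_equal(sum(tm$time < 0), 20)
  expect_equal(sum(tm$time >= 0), 80)
  # onset exactly on a tick: epoch starts 20 samples before the onset sample
  expect_equal(tm$epochs[1, 1], tr$values[5 * 20 + 1 - 20])
  expect_equal(tm$epochs[1, 21], tr$values[5 * 20 + 1])
  expect_equal(tm$intensity, c(0, 300))
  # zero events: a valid empty object
  empty <- epoch_trials(tr, stimulus_events(numeric(0), numeric(0)))
  expect_s3_class(empty, "trial_matrix")
  expect_equal(nrow(empty$epochs), 0)
  # out-of-bounds windows name the offending events
  expect_error(epoch_trials(tr, stimulus_events(0.5, 100)), "event")
})

test_that("baseline normalization fixes the prestimulus moments", {
  ep <- rbind(c(rep(2, 20), rep(4, 80)),
              c(rnorm(20, 5, 2), rnorm(80)))
  tm <- structure(list(
    epochs = ep, time = ((1:100) - 21) / 20, intensity = c(0, 500),
    sampling_rate = 20, normalization = "raw",
    exclusions = data.frame(trial = integer(0), reason = character(0))
  ), class = "trial_matrix")
  sub <- normalize_epochs(tm, "subtract_mean")
  expect_equal(sub$epochs[1, 21:100], rep(2, 80))
  expect_equal(mean(sub$epochs[2, 1:20]), 0, tolerance = 1e-12)
  z <- normalize_epochs(tm, "zscore")
  pre <- z$time < 0
  for (i in seq_len(nrow(z$epochs))) {
    expect_lt(abs(mean(z$epochs[i, pre])), 1e-10)
    expect_lt(abs(sd(z$epochs[i, pre]) - 1), 1e-10)
  }
})

test_that("constant epochs cannot be z-scored and are excluded with a logged reason", {
  ep <- rbind(rep(3, 100), c(rnorm(20), rnorm(80, 2)))
  tm <- structure(list(
    epochs = ep, time = ((1:100) - 21) / 20, intensity = c(0, 500),
    sampling_rate = 20, normalization = "raw",
    exclusions = data.frame(trial = integer(0), reason = character(0))
  ), class = "trial_matrix")
  z <- normalize_epochs(tm, "zscore")
  expect_equal(nrow(z$epochs), 1)
  expect_equal(z$exclusions$trial, 1L)
  expect_match(z$exclusions$reason, "variance")
  # all epochs degenerate -> error, not a silently zeroed matrix
  tm$epochs <- rbind(rep(3, 100), rep(1, 100))
  expect_error(normalize_epochs(tm, "zscore"), "z-score")
})

test_that("the response is the mean over the half-open 1-2 s window", {
  time <- ((1:100) - 21) / 20
  tm <- structure(list(
    epochs = rbind(rep(3, 100), matrix(time, 1)), time = time,
    intensity = c(100, 200), sampling_rate = 20, normalization = "zscored",
    exclusions = data.frame(trial = integer(0), reason = character(0))
  ), class = "trial_matrix")
  r <- extract_responses(tm)
  expect_equal(r$response[1], 3)
  expect_equal(r$response[2], 1.475)  # mean of t over [1, 2) at 20 Hz
  expect_equal(sum(time >= 1 & time < 2), 20)
  expect_error(extract_responses(tm, window = c(3, 6)), "window")
})

test_that("zero-condition subtraction is per animal and exact at 0 uA", {
  d <- data.frame(
    animal = rep(c("a", "b"), each = 2),
    intensity = c(0, 500, 0, 500),
    response = c(0.2, 1.2, -0.5, 0.5)
  )
  z <- subtract_zero_condition(d)
  expect_equal(z$response[z$intensity == 0], c(0, 0))
  expect_equal(z$response[z$animal == "a" & z$intensity == 500], 1.0)
  expect_equal(z$response[z$animal == "b" & z$intensity == 500], 1.0)
  expect_error(subtract_zero_condition(d[d$intensity != 0, ]), "0 uA")
})

test_that("the noiseless chain recovers the generating sigmoid within 2%", {
  cfg <- session_sim_config(noise_sd = 0, blink_rate = 0, seed = 10)
  s <- simulate_pupil_session(cfg)
  r <- session_responses(s$trace, s$events, normalization = "subtract_mean")
  r$animal <- "m1"
  z <- subtract_zero_condition(r)
  p <- cfg$true_params
  truth <- sigmoid_response(z$intensity, p["b"], p["L"], p["k"], p["x0"]) -
    sigmoid_response(0, p["b"], p["L"], p["k"], p["x0"])
  nz <- z$intensity > 0
  expect_lt(max(abs(z$response[nz] / truth[nz] - 1)), 0.02)
})
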