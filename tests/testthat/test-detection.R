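# Seizure detection: smoothing, prominence-based offsets, changepoint
# onsets, ISI extraction, and invariance properties, on constructed
# fixtures with planted features.

# Fixture: baseline with smooth troughs of given depth at known times.
planted_troughs <- function(t_end, rate, trough_times, depth = 10,
                            width = 3) {
  t <- seq(0, t_end, by = 1 / rate)
  sig <- rep(0, length(t))
  for (tt in trough_times)
    sig <- sig - depth * exp(-((t - tt) / width)^2)
  list(time = t, signal = sig, rate = rate)
}

test_that("moving-average smoothing has the stated kernel behavior", {
  expect_equal(smooth_signal(rep(3.7, 100), rate = 10, window = 1),
               rep(3.7, 100))
  # single impulse of height h spreads to a plateau of height h / w
  x <- rep(0, 200); x[100] <- 5
  s <- smooth_signal(x, rate = 10, window = 1.1)  # 11-sample window
  expect_equal(max(s), 5 / 11)
  expect_equal(sum(s > 0), 11)
  expect_error(smooth_signal(1:100, rate = 1, window = 1), "3 samples")
  # white-noise variance is reduced about w-fold
  set.seed(42)
  z <- rnorm(2e4)
  s <- smooth_signal(z, rate = 1000, window = 0.021)  # w = 21
  expect_equal(var(s[500:19500]) * 21, 1, tolerance = 0.1)
})

test_that("offsets recover planted troughs and respect separation", {
  fx <- planted_troughs(300, 10, c(60, 120, 180, 240))
  offs <- detect_offsets(fx$signal, fx$rate)
  expect_equal(offs, c(60, 120, 180, 240), tolerance = 0.11)
  expect_identical(detect_offsets(rep(1, 100), 10), numeric(0))
  # two troughs 10 s apart: separation keeps the more prominent one
  fx2 <- planted_troughs(120, 10, c(60, 70), depth = 10)
  fx2$signal <- fx2$signal - 2 * exp(-((fx2$time - 70) / 3)^2) # 70 deeper
  offs2 <- detect_offsets(fx2$signal, fx2$rate)
  expect_equal(offs2, 70, tolerance = 0.11)
  # exact tie -> earlier trough kept
  t <- seq(0, 120, by = 0.1)
  sig <- -10 * exp(-((t - 60) / 3)^2) - 10 * exp(-((t - 70) / 3)^2)
  offs3 <- detect_offsets(sig, 10)
  expect_equal(offs3, 60, tolerance = 0.11)
})

test_that("changepoint onset finds a planted slope break", {
  rate <- 100
  t <- seq(0, 30, by = 1 / rate)
  y <- ifelse(t < 18, 0.1 * t, 0.1 * 18 + 5 * (t - 18))
  on <- detect_onset_before(y, rate, offset_time = 30, lookback = 30)
  expect_equal(as.numeric(on), 18, tolerance = 2 / rate)
  expect_false(attr(on, "low_confidence"))
  # a pure line is flagged low-confidence
  on2 <- detect_onset_before(0.3 * t, rate, offset_time = 30)
  expect_true(attr(on2, "low_confidence"))
  expect_error(detect_onset_before(y, rate, offset_time = 0.01), "4 samples")
})

test_that("detection is invariant to offset and positive rescaling", {
  tr <- simulate_epileptor(p_ref(), 200)
  ev <- detect_events(tr)
  rate <- 1 / tr$record_dt
  ev_raw <- detect_events(tr$V, rate = rate)
  ev_shift <- detect_events(5.3 + tr$V, rate = rate)
  ev_scale <- detect_events(0.02 * tr$V, rate = rate)
  expect_equal(ev_shift$offset, ev_raw$offset)
  expect_equal(ev_scale$offset, ev_raw$offset)
  expect_equal(ev_shift$onset, ev_raw$onset)
  expect_equal(ev_scale$onset, ev_raw$onset)
  expect_equal(ev$offset, ev_raw$offset)
})

test_that("steady-state cycles give near-identical ISIs and durations", {
  tr <- simulate_epileptor(p_ref(), 400)
  ev <- detect_events(tr)
  expect_gte(nrow(ev), 2)                 # recurrent events by 400 s
  isis <- extract_isis(ev)
  expect_true(all(isis > 0))
  # drop the first (transient) cycle; the rest repeat to < 1%
  if (length(isis) > 2) {
    ss <- isis[-1]
    expect_lt(max(abs(ss - mean(ss))) / mean(ss), 0.01)
    dur <- ev$duration[-(1:2)]
    expect_lt(max(abs(dur - mean(dur))) / mean(dur), 0.01)
  }
  expect_identical(attr(ev, "regime"), "periodic")
})

test_that("ISI extraction is the offset-to-next-onset difference", {
  ev <- data.frame(onset = c(5, 74, 140), offset = c(10, 80, 150))
  expect_equal(extract_isis(ev), c(64, 60))
  expect_identical(extract_isis(ev[1, ]), numeric(0))
  path <- tempfile(fileext = ".csv")
  write_events_csv(structure(ev, class = c("epi_events", "data.frame"),
                             regime = "periodic"), path)
  back <- read.csv(path)
  expect_equal(back$next_isi, c(64, 60, NA))
})
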