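# LFES trial machinery: control consistency, labels, monotonicity, and
# protocol errors. The heavier parameter sweeps live in the acceptance
# suite.

test_that("zero-amplitude trials reproduce the control ISI exactly", {
  cyc <- cached_cycle("slice0")
  tr <- run_lfes_trial(cyc, onset = 0, duration = 30, amplitude = 0)
  expect_equal(tr$delay_pct, 0, tolerance = 1e-9)
  expect_identical(tr$label, "no-effect")
  expect_false(tr$premature)
})

test_that("burn-in fails loudly outside the periodic regime", {
  expect_error(steady_state_cycle(slice_preset("slice0", K_bath = 4),
                                  t_max = 150),
               "no steady-state")
})

test_that("a supra-critical early train delays, a late one fires a seizure", {
  cyc <- cached_cycle("slice0")
  early <- run_lfes_trial(cyc, onset = 0, duration = 30, amplitude = 20)
  expect_identical(early$label, "delayed")
  expect_gt(early$delay_pct, 10)
  late <- run_lfes_trial(cyc, onset = 22, duration = 30, amplitude = 20)
  expect_identical(late$label, "immediate-seizure")
  expect_lt(late$isi_stim, cyc$isi_ctrl)
})

test_that("relative delay is non-decreasing in duration past the capture
           window, and the sweep slope tracks 100 / ISI_ctrl", {
  cyc <- cached_cycle("slice0")
  sw <- duration_sweep(cyc, durations = seq(20, 50, by = 10), amplitude = 20)
  expect_true(all(diff(sw$trials$delay_pct) > 0))
  expect_equal(sw$slope, 100 / cyc$isi_ctrl, tolerance = 0.3)
  # too few effective durations -> no slope
  sw0 <- duration_sweep(cyc, durations = c(12, 20), amplitude = 20)
  expect_true(is.na(sw0$slope))
})

test_that("above the critical amplitude the outcome is insensitive to it", {
  cyc <- cached_cycle("slice0")
  a <- run_lfes_trial(cyc, onset = 5, duration = 30, amplitude = 16)
  b <- run_lfes_trial(cyc, onset = 5, duration = 30, amplitude = 30)
  expect_identical(a$label, "delayed")
  expect_identical(b$label, "delayed")
  expect_equal(a$delay_pct, b$delay_pct, tolerance = 0.05)
})

test_that("the forced attractor rejects premature trials and reports
           elevated pump activity", {
  cyc <- cached_cycle("slice0")
  fa <- characterize_forced_attractor(cyc, amplitude = 20, duration = 60,
                                      onset = 5, settle_fraction = 2 / 3)
  expect_lt(diff(fa$Na_range), 1)          # sub-mM band
  expect_lt(diff(fa$K_range), 1)
  # pump on the attractor beats the unstimulated state at equal elapsed time
  ctrl <- run_lfes_trial(cyc, onset = 5, duration = 60, amplitude = 0,
                         keep_trajectory = TRUE)
  # compare against the unstimulated interictal portion of the window
  # (the control run seizes spontaneously at ISI_ctrl)
  sel <- ctrl$trajectory$time >= fa$window[1] &
    ctrl$trajectory$time <= min(fa$window[2], cyc$isi_ctrl - 5)
  pump_ctrl <- pump_current(ctrl$trajectory$K_o[sel],
                            ctrl$trajectory$Na_i[sel], cyc$params)
  expect_gt(min(fa$pump_range), max(pump_ctrl))
  expect_error(characterize_forced_attractor(cyc, amplitude = 20,
                                             duration = 60, onset = 25),
               "premature")
})

test_that("single-spike probes on a potassium ramp are artifacts at low
           K and seizure triggers at elevated K", {
  p <- p_ref()
  # pick probe times from an unprobed run, inside the established seizure
  # cycle: one just after an offset (low K, pump-active: artifact) and
  # one late in the interictal interval (K near threshold: trigger)
  base <- run_kbath_ramp_with_probing(p, ramp_rate = 0.02,
                                      probe_times = numeric(0), t_end = 340)
  ev <- base$events
  expect_gte(nrow(ev), 2)
  t_low <- ev$offset[1] + 4
  t_high <- ev$offset[1] + 0.85 * (ev$onset[2] - ev$offset[1])
  rp <- run_kbath_ramp_with_probing(p, ramp_rate = 0.02,
                                    probe_times = c(t_low, t_high),
                                    probe_amplitude = 15, t_end = 340)
  expect_false(rp$probes$triggered_seizure[1])  # low K: artifact only
  expect_true(rp$probes$triggered_seizure[2])   # elevated K: seizure
  # zero-amplitude probes leave the trajectory untouched
  r0 <- run_kbath_ramp_with_probing(p, ramp_rate = 0.02,
                                    probe_times = c(t_low, t_high),
                                    probe_amplitude = 0, t_end = 340)
  expect_identical(r0$trajectory$V, base$trajectory$V)
})
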