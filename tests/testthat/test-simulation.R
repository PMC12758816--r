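# Integrator contracts: impulse realization, determinism, convergence,
# admissible-set checks, bath-potassium scheduling.

test_that("a pulse displaces the membrane potential by exactly R_stim * A", {
  p <- p_ref()
  a <- simulate_epileptor(p, 2, stim = stim_train(1, 0, 15), record_dt = 1e-4)
  b <- simulate_epileptor(p, 2, record_dt = 1e-4)
  i <- which(a$time == 1)
  expect_equal(a$V[i] - b$V[i], p$R_stim * 15)
  # pre-pulse samples are bit-identical
  expect_identical(a$V[seq_len(i - 1L)], b$V[seq_len(i - 1L)])
})

test_that("the impulse map is linear: two half pulses equal one pulse", {
  p <- p_ref()
  one <- simulate_epileptor(p, 2, stim = stim_train(1, 0, 15))
  half <- simulate_epileptor(p, 2, stim = list(stim_train(1, 0, 7.5),
                                               stim_train(1, 0, 7.5)))
  expect_identical(one$V, half$V)
  zero <- simulate_epileptor(p, 2, stim = stim_train(1, 0, 0))
  none <- simulate_epileptor(p, 2)
  expect_identical(zero$V, none$V)
})

test_that("repeated runs are bit-identical", {
  p <- slice_preset("slice2")
  a <- simulate_epileptor(p, 30, stim = stim_train(0, 10, 15))
  b <- simulate_epileptor(p, 30, stim = stim_train(0, 10, 15))
  expect_identical(a$V, b$V)
  expect_identical(a$final_state, b$final_state)
})

test_that("step halving changes the solution by less than 1e-6 relative", {
  p <- slice_preset("slice0", K_bath = 4)  # quiescent: no seizures in 50 s
  a <- simulate_epileptor(p, 50, dt = 1e-4)
  b <- simulate_epileptor(p, 50, dt = 5e-5)
  rel <- max(abs(a$final_state - b$final_state) /
               pmax(abs(b$final_state), 1e-8))
  expect_lt(rel, 1e-6)
})

test_that("dt guard and admissible-set abort are enforced", {
  p <- p_ref()
  expect_error(simulate_epileptor(p, 1, dt = 1e-3), "tau_m")
  expect_error(simulate_epileptor(p, 1, init = c(0, 1, -1, 10)))
})

test_that("stimulus trains derive their pulse times correctly", {
  s <- stim_train(onset = 3, duration = 4.5, amplitude = 10, frequency = 2)
  expect_equal(s$pulse_times, 3 + (0:9) / 2)
  expect_true(all(diff(s$pulse_times) > 0))
  expect_error(stim_train(duration = -1))
})

test_that("state invariants hold along long trajectories for all presets", {
  for (nm in paste0("slice", 0:4)) {
    tr <- simulate_epileptor(slice_preset(nm), 300)
    expect_true(all(tr$x_D >= 0 & tr$x_D <= 1), label = nm)
    expect_true(all(tr$K_o > 0), label = nm)
    expect_true(all(tr$Na_i > 0), label = nm)
    expect_true(all(is.finite(tr$V)), label = nm)
  }
})

test_that("bath-potassium schedules drive the leak target", {
  p <- slice_preset("slice0", K_bath = 4)
  # a step up mid-run raises the late-time K compared to the constant run
  kb <- kbath_schedule("step", times = c(0, 25), values = c(4, 8))
  a <- simulate_epileptor(p, 50, kbath = kb)
  b <- simulate_epileptor(p, 50)
  expect_identical(a$K_o[a$time < 25], b$K_o[b$time < 25])
  expect_gt(a$final_state[3], b$final_state[3] + 1)
  # ramps interpolate: a symmetric up ramp ends higher than it starts
  kr <- kbath_schedule("ramp", times = c(0, 50), values = c(4, 6))
  r <- simulate_epileptor(p, 50, kbath = kr)
  expect_gt(r$final_state[3], b$final_state[3])
})

test_that("trajectory containers export consistent tables", {
  p <- p_ref()
  tr <- simulate_epileptor(p, 5, stim = stim_train(2, 1, 15))
  df <- as.data.frame(tr)
  expect_equal(nrow(df), length(tr$time))
  expect_true(any(df$stim))
  expect_named(df, c("time", "V", "x_D", "K_o", "Na_i", "stim"))
  path <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  back <- read.csv(path)
  expect_equal(back$V, df$V, tolerance = 1e-8)
  der <- trajectory_derived(tr)
  expect_equal(der$rate, firing_rate(tr$V, p))
})
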