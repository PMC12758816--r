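# Model equations as pure functions: values frozen from direct arithmetic
# evaluation of the rate, pump and drive expressions.

test_that("firing rate is a bounded increasing sigmoid with the right scale", {
  p <- p_ref()
  expect_equal(firing_rate(p$V_th, p), p$nu_max / 2)
  expect_equal(firing_rate(1e4, p), p$nu_max)
  expect_equal(firing_rate(-1e4, p), 0)
  # slice-0 resting potential: 75/(1 + e^10)
  expect_equal(firing_rate(0, p), 3.40484e-3, tolerance = 1e-5)
  V <- seq(-40, 40, by = 0.5)
  nu <- firing_rate(V, p)
  expect_true(all(diff(nu) > 0))
  expect_true(all(nu > 0 & nu < p$nu_max))
})

test_that("pump flux saturates at rho and increases in both ions", {
  p <- p_ref()
  expect_equal(pump_current(3.5, 25.0, p), p$rho / 4)
  expect_equal(pump_current(3.5, 25.0, p), 0.02855)
  expect_equal(pump_current(1e3, 1e3, p), p$rho)
  expect_equal(pump_current(3.0, 10.0, p), 2.8856e-4, tolerance = 1e-4)
  K <- seq(0.5, 12, by = 0.25); Na <- seq(5, 40, by = 0.5)
  expect_true(all(diff(pump_current(K, 20, p)) > 0))
  expect_true(all(diff(pump_current(5, Na, p)) > 0))
  grid <- expand.grid(K = K, Na = Na)
  Ip <- pump_current(grid$K, grid$Na, p)
  expect_true(all(Ip > 0 & Ip < p$rho))
})

test_that("membrane drive terms vanish at their reference points", {
  p <- p_ref()
  # potassium term zero at resting K; inhibitory term zero at reversal;
  # excitatory term zero at depleted resource
  expect_equal(membrane_drive(p$V_inh, 0, p$K_o0, p),
               0 + 0 + 0)
  d_noexc <- membrane_drive(5, 0, p$K_o0, p)
  expect_equal(d_noexc, p$g_inh_rel * (p$V_inh - 5))
  d_K <- membrane_drive(p$V_inh, 0, 6, p)
  expect_equal(d_K, p$g_K_rel * p$nernst_scale * log(6 / p$K_o0))
  expect_error(membrane_drive(0, 1, -1, p), "positive")
})

test_that("state derivatives match direct arithmetic and keep x_D in [0,1]", {
  p <- p_ref()
  d <- model_derivatives(c(V = 0, x_D = 1, K_o = 3, Na_i = 10), p)
  expect_equal(unname(d["dK_o"]), 0.308583, tolerance = 1e-4)
  expect_equal(unname(d["dNa_i"]), -7.635e-4, tolerance = 1e-3)
  expect_equal(unname(d["dx_D"]), -3.40484e-5, tolerance = 1e-5)
  expect_equal(unname(d["dV"]), -1263.99, tolerance = 1e-4)
  # forward invariance of the resource interval at its boundaries
  d0 <- model_derivatives(c(0, 0, 3, 10), p)
  expect_equal(unname(d0["dx_D"]), 1 / p$tau_x)
  d1 <- model_derivatives(c(30, 1, 6, 20), p)
  expect_lte(unname(d1["dx_D"]), 0)
  # leak term vanishes at K_o = K_bath, pump then pulls K down
  dk <- model_derivatives(c(-20, 1, p$K_bath, 25), p)
  expect_lt(unname(dk["dK_o"]), 0)
})

test_that("parameter validation rejects inadmissible values", {
  expect_error(epi_params(tau_m = 0), "positive")
  expect_error(epi_params(K_bath = -1), "positive")
  expect_error(epi_params(g_inh_rel = -0.1), "non-negative")
  expect_error(update(p_ref(), not_a_param = 1), "unknown")
  p2 <- update(p_ref(), g_inh_rel = 0)
  expect_equal(p2$g_inh_rel, 0)
})

test_that("slice presets carry the slice-specific excitability values", {
  s1 <- slice_preset("slice1")
  expect_equal(s1$K_bath, 9.5)
  expect_equal(s1$V_th, 14)
  expect_equal(s1$nu_max, 80)
  expect_equal(s1$g_inh_rel, 0.05)
  s4 <- slice_preset("slice4")
  expect_equal(s4$V_th, 2.4)
  expect_equal(s4$nu_max, 35)
  expect_equal(s4$K_bath, 5.3)
  expect_equal(s4$g_inh_rel, 0.1686)
  # shared fixed set is untouched by the preset switch
  expect_equal(s4$rho, 0.1142)
  expect_equal(s4$tau_K, 17.5)
  expect_error(slice_preset("slice9"))
  # override mechanism reproduces the no-inhibition variant
  s0n <- slice_preset("slice0", g_inh_rel = 0)
  expect_equal(s0n$g_inh_rel, 0)
})

test_that("config files merge a preset with overrides", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("preset: slice1", "V_th: 15", "nu_max: 90"), path)
  p <- read_params_config(path)
  expect_equal(p$K_bath, 9.5)   # from the preset
  expect_equal(p$V_th, 15)      # overridden
  expect_equal(p$nu_max, 90)
})
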