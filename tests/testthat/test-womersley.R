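test_that("steady wall shear equals the Poiseuille closed form", {
  ws <- womersley_wall_shear(2.5, waveform_preset("steady", 600))
  q_si <- 600 * 1e-6 / 60
  expect_equal(ws$steady_tau, 4 * 3.5e-3 * q_si / (pi * 0.0025^3),
               tolerance = 1e-12)
  expect_equal(unique(ws$tau), ws$steady_tau)
  # approx 2.85 Pa at these conditions
  expect_lt(abs(ws$steady_tau - 2.85), 0.01)
})

test_that("slow pulsation reduces to the quasi-steady limit", {
  wf <- waveform_preset("pulsatile", 300, period = 100)
  ws <- womersley_wall_shear(1.5, wf)
  qs <- 4 * 3.5e-3 * (waveform_flow(wf) * 1e-6 / 60) / (pi * 0.0015^3)
  expect_lt(max(abs(ws$tau / qs - 1)), 0.01)
})

test_that("harmonic wall shear matches a time-stepping finite-difference solve", {
  wf <- waveform_preset("pulsatile", 600)
  ws <- womersley_wall_shear(2.5, wf)
  for (k in seq_along(wf$harmonic_index)) {
    n <- wf$harmonic_index[k]
    oracle <- oracle_fd_harmonic(0.0025, n * 2 * pi,
                                 wf$harmonic_amplitude[k] * 1e-6 / 60,
                                 3.5e-3, 1050)
    expect_lt(Mod(ws$tau_hat[k] - oracle) / Mod(oracle), 0.005)
  }
})

test_that("cycle mean of the signed shear equals the steady component (linearity)", {
  set.seed(5)
  for (rep in 1:5) {
    harm <- lapply(sample(1:6, 3), function(n)
      list(n = n, amplitude = complex(real = rnorm(1, 0, 100),
                                      imaginary = rnorm(1, 0, 100))))
    wf <- flow_waveform(400, harm, n_samples = 48)
    ws <- womersley_wall_shear(2, wf)
    w <- diff(c(wf$sample_times, wf$period))
    expect_lt(abs(sum(ws$tau * w) / wf$period / ws$steady_tau - 1), 0.005)
  }
})

test_that("very high Womersley numbers fall back to finite differences with a warning", {
  wf <- waveform_preset("pulsatile", 600)
  w <- capture_warnings(ws_fd <- womersley_wall_shear(2.5, wf, alpha_max = 1))
  expect_length(w, 2)  # one per harmonic
  expect_true(all(grepl("finite differences", w)))
  ws <- womersley_wall_shear(2.5, wf)
  expect_lt(max(Mod(ws_fd$tau_hat - ws$tau_hat) / Mod(ws$tau_hat)), 0.005)
})

test_that("waveform validation rejects ill-formed sampling", {
  expect_error(flow_waveform(100, period = -1), "period")
  expect_error(flow_waveform(100, sample_times = c(0.1, 0.2)), "start at 0")
  expect_error(flow_waveform(100, sample_times = c(0, 0.5, 0.4)), "increasing")
  expect_error(flow_waveform(100, sample_times = c(0, 1)), "below the period")
})

test_that("peak systole is the earliest flow maximum", {
  # steady flow: tie across all samples resolves to the first
  expect_identical(peak_systole_index(waveform_preset("steady", 500)), 1L)
  # Q = 10 + 3 sin(Omega t): maximum nearest t = T/4
  wf <- flow_waveform(10, list(list(n = 1, amplitude = -3i)), n_samples = 64)
  expect_equal(wf$sample_times[peak_systole_index(wf)], 0.25,
               tolerance = 1 / 64)
  # two equal maxima: earlier index wins
  wf2 <- flow_waveform(10, list(list(n = 2, amplitude = 1 + 0i)),
                       n_samples = 8)
  q <- waveform_flow(wf2)
  expect_gte(sum(abs(q - max(q)) < 1e-9), 2)
  expect_identical(peak_systole_index(wf2), which(abs(q - max(q)) < 1e-9)[1])
})
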