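test_that("spike detection uses upward threshold crossings", {
  dt <- 0.1
  flat <- rep(-40, 1000)
  expect_length(detect_spikes(flat, dt)$spike_times, 0)

  # three separated 2 ms triangular pulses peaking at +20 mV
  v <- rep(-60, 3000)
  onsets <- c(500, 1500, 2500)
  for (o in onsets) {
    up <- seq(-60, 20, length.out = 11)
    v[o:(o + 20)] <- c(up, rev(up)[-1])
  }
  train <- detect_spikes(v, dt)
  expect_length(train$spike_times, 3)
  # crossing happens where the ramp passes 0: 7.5 samples into the rise
  expect_equal(train$spike_times, (onsets - 1 + 8) * dt, tolerance = 1e-12)

  # constant suprathreshold trace: one spike at t = 0, not one per sample
  expect_equal(detect_spikes(rep(10, 500), dt)$spike_times, 0)

  # equivalence with a brute-force scan on random traces
  set.seed(21)
  for (i in 1:10) {
    vr <- cumsum(rnorm(2000, sd = 3)) - 30
    got <- detect_spikes(vr, dt, refractory = 0)$spike_times
    above <- vr >= 0
    brute <- (which(above & !c(FALSE, above[-length(above)])) - 1) * dt
    if (above[1]) brute <- union(0, brute)
    expect_equal(got, brute)
  }
})

test_that("firing rate is spikes per window", {
  train <- structure(list(spike_times = seq(10, 460, by = 50)),
                     class = "rgc_spike_train")
  expect_equal(firing_rate(train, c(0, 500)), 20)
  empty <- structure(list(spike_times = numeric(0)), class = "rgc_spike_train")
  expect_equal(firing_rate(empty, c(0, 500)), 0)
  expect_equal(firing_rate(train, c(460.5, 660.5)), 0)
  expect_error(firing_rate(train, c(100, 100)), "window")
})

test_that("spike removal excises 2 ms after each 10 mV/ms threshold hit", {
  dt <- 0.1
  expect_equal(mean_vm_spike_removed(rep(-60, 20000), dt), -60)

  v <- rep(-60, 20000)
  for (o in seq(1000, 19000, by = 1000)) {
    v[o:(o + 5)] <- seq(-60, 30, length.out = 6)   # 150 mV/ms rise
    v[(o + 6):(o + 10)] <- seq(12, -60, length.out = 5)
  }
  got <- mean_vm_spike_removed(v, dt)
  # brute-force mask written independently
  dv <- c(diff(v) / dt, 0)
  bad <- rep(FALSE, length(v))
  for (i in which(dv > 10)) bad[i:min(length(v), i + 20)] <- TRUE
  expect_equal(as.numeric(got), mean(v[!bad]))
  expect_equal(as.numeric(got), -60, tolerance = 0.01)

  ramp <- seq(0, 20 * 1999 * dt, length.out = 2000)  # 20 mV/ms everywhere
  out <- mean_vm_spike_removed(ramp, dt, min_retained = 100)
  expect_true(isTRUE(attr(out, "warning")))
})

test_that("CV of the ISI uses the sample standard deviation", {
  periodic <- structure(list(spike_times = seq(0, 1000, by = 25)),
                        class = "rgc_spike_train")
  expect_equal(cv_isi(periodic), 0)
  train <- structure(list(spike_times = c(0, 10, 30, 60)),
                     class = "rgc_spike_train")
  expect_equal(cv_isi(train), 0.5)  # ISIs 10, 20, 30: sd 10, mean 20
  two <- structure(list(spike_times = c(0, 10)), class = "rgc_spike_train")
  expect_error(cv_isi(two), "intervals")
  # scale invariance
  scaled <- structure(list(spike_times = c(0, 10, 30, 60) * 7.3),
                      class = "rgc_spike_train")
  expect_equal(cv_isi(scaled), cv_isi(train))
})

test_that("oscillation analysis finds synthetic rhythms and rejects noise", {
  dt <- 0.5
  t <- seq(0, 5000, by = dt)
  set.seed(5)
  flat <- -60 + rnorm(length(t), sd = 0.01)
  expect_false(oscillation_report(flat, dt)$present)

  sine <- -60 + 1 * sin(2 * pi * 4 * t / 1000)
  rep4 <- oscillation_report(sine, dt)
  expect_true(rep4$present)
  expect_true(rep4$sustained)
  expect_equal(rep4$frequency, 4, tolerance = 0.25 / 4)
  expect_equal(rep4$peak_to_peak, 2, tolerance = 0.1)

  damped <- -60 + exp(-t / 1000) * sin(2 * pi * 4 * t / 1000)
  repd <- oscillation_report(damped, dt)
  expect_true(repd$present)
  expect_false(repd$sustained)

  expect_error(oscillation_report(sine[1:1000], dt), "2 s")

  # frequency recovered within one spectral bin at SNR >= 10 across the band
  for (f in c(2, 3.5, 6, 8)) {
    x <- -60 + sin(2 * pi * f * t / 1000) + rnorm(length(t), sd = 0.1)
    r <- oscillation_report(x, dt)
    expect_true(r$present)
    expect_lt(abs(r$frequency - f), 0.45)
  }
})

test_that("step metrics recover constructed waveform features", {
  dt <- 0.5
  n <- 5001                                     # 2.5 s
  v <- rep(-60, n)
  step <- data.frame(t_start = 1500, duration = 500, amplitude = -0.2)
  on <- (3001):(4000)
  v[on] <- -90
  v[3001:3040] <- seq(-60, -95, length.out = 40) # early dip below steady state
  v[3041:3080] <- seq(-95, -90, length.out = 40) # relaxes back: 5 mV sag
  # rebound spike 50 ms after offset
  sp <- 4001 + 100
  v[sp:(sp + 4)] <- c(-20, 20, 10, -30, -60)
  rec <- fake_recording(v, dt, steps = step)
  sm <- step_response_metrics(rec)
  expect_equal(sm$v_rest, -60, tolerance = 0.01)
  expect_equal(sm$v_hyp, -90, tolerance = 0.01)
  expect_equal(sm$hyp_depth, 30, tolerance = 0.01)
  expect_equal(sm$sag, 5, tolerance = 0.1)
  expect_equal(sm$latent_period, 50.5, tolerance = 0.02)
  expect_equal(sm$rebound_burst_rate, 5)        # one spike in 200 ms
  expect_error(step_response_metrics(
    fake_recording(v, dt, steps = data.frame(t_start = 2400, duration = 500,
                                             amplitude = -0.1))),
    "not contained")
})

test_that("passive step responses follow the closed form with no sag", {
  d <- sqrt(5.23e-5 * 1e8 / pi)
  cell <- build_cell(soma_only_morph(d), c(0, 0, 0), passive_table())
  cfg <- simulation_config(settle_time = 300, initial_v = -60)
  rec <- simulate(cell, make_protocol("hyp_step_200pA"), cfg)
  sm <- step_response_metrics(rec)
  expect_equal(sm$hyp_depth, 0.2 / (1.2e-4 * 5.23e-5 * 1e6), tolerance = 0.01)
  expect_lt(sm$sag, 0.05)
  expect_equal(sm$spikes_during_step, 0)
  expect_equal(sm$rebound_burst_rate, 0)
})

test_that("input resistance scales inversely with membrane area", {
  d <- sqrt(5.23e-5 * 1e8 / pi)
  cell1 <- build_cell(soma_only_morph(d), c(0, 0, 0), passive_table())
  cell2 <- build_cell(soma_only_morph(d * sqrt(2)), c(0, 0, 0), passive_table())
  r1 <- input_resistance(cell1)
  r2 <- input_resistance(cell2)
  expect_equal(r1 / r2, 2, tolerance = 0.01)
})
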