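# Spike detection, AP morphology, rate statistics and the sensitivity index.

synthetic_train <- function(times, dt = 0.05, dur = 2000, width = 1.2,
                            amp = 80, base = -60) {
  tt <- seq(0, dur, by = dt)
  V <- rep(base, length(tt))
  for (tc in times) V <- V + amp * exp(-((tt - tc) / width)^2)
  list(time = tt, V = V)
}

test_that("spike detection finds constructed spikes and rejects subthreshold", {
  expect_length(detect_spikes(rep(-60, 1000), seq(0, 99.9, by = 0.1)), 0)
  tr <- synthetic_train(c(200, 650, 1300, 1900))
  got <- detect_spikes(tr$V, tr$time)
  expect_length(got, 4)
  expect_true(all(abs(got - c(200, 650, 1300, 1900)) <= 0.05 + 1e-9))
  # subthreshold oscillation peaking at -30 mV never crosses the criterion
  sub <- synthetic_train(c(500, 1000), amp = 30)
  expect_length(detect_spikes(sub$V, sub$time), 0)
  # refractory enforcement: a doublet 1 ms apart yields one event
  dbl <- synthetic_train(c(500, 501), width = 0.4)
  expect_length(detect_spikes(dbl$V, dbl$time), 1)
  expect_error(detect_spikes(c(-60, -10, -60), c(0, 1, 5)), "uniform")
})

test_that("morphology recovers an idealized triangular action potential", {
  dt <- 0.01
  tt <- seq(0, 400, by = dt)
  ap <- function(tc) {
    v <- rep(0, length(tt))
    ramp <- tt >= tc - 20 & tt < tc - 2          # slow approach: 0.5 mV/ms
    v[ramp] <- 0.5 * (tt[ramp] - (tc - 20))
    up <- tt >= tc - 2 & tt < tc                 # upstroke: 30 mV/ms
    v[up] <- 9 + 30 * (tt[up] - (tc - 2))
    down <- tt >= tc & tt < tc + 3               # repolarization to baseline
    v[down] <- 69 - 23 * (tt[down] - tc)
    v
  }
  V <- -55 + ap(100) + ap(300)
  spk <- detect_spikes(V, tt)
  expect_length(spk, 2)
  m <- ap_morphology(V, tt, spk)
  # the slope first exceeds 10 mV/ms exactly where the 30 mV/ms leg starts
  expect_equal(m$threshold, -55 + 9, tolerance = 0.05)
  expect_equal(m$amplitude, 60, tolerance = 0.1)
  # AHP: threshold minus the floor between the spikes
  expect_equal(m$ahp_depth, (-55 + 9) - (-55), tolerance = 0.1)
  # invariance under a uniform voltage offset
  m2 <- ap_morphology(V + 5, tt, detect_spikes(V + 5, tt))
  expect_equal(m2$amplitude, m$amplitude, tolerance = 1e-9)
  expect_equal(m2$ahp_depth, m$ahp_depth, tolerance = 1e-9)
  expect_equal(m2$threshold, m$threshold + 5, tolerance = 1e-9)
  expect_error(ap_morphology(V, tt, spk[1]), "two spikes")
})

test_that("rate statistics handle periodic trains and empty windows", {
  spk <- seq(0, 10000, by = 1000)     # 1 Hz
  r <- rate_statistics(spk, c(0, 3000), c(5000, 10000))
  expect_equal(r$peak_rate, 1)
  expect_equal(r$steady_rate, 1.2)    # 6 spikes in 5 s
  expect_equal(r$sfa_ratio, 1 / 1.2)
  r0 <- rate_statistics(numeric(0), c(0, 1000), c(1000, 2000))
  expect_equal(r0$peak_rate, 0)
  expect_equal(r0$steady_rate, 0)
  expect_true(is.na(r0$sfa_ratio))
})

test_that("the sensitivity index reproduces every printed rate/index pair", {
  expect_equal(sensitivity_index(1.43, 1.43), 0)
  expect_error(sensitivity_index(2, 0), "> 0")
  # printed columns are internally consistent with the index definition
  t2 <- data.frame(fr = c(2.87, 1.46, 1.78, 2.02),
                   si = c(100.7, 2.09, 24.47, 41.26))
  expect_equal(sensitivity_index(t2$fr, 1.43), t2$si, tolerance = 5e-3)
  t3 <- data.frame(fr = c(1.43, 1.26, 3.03, 2.85, 2.68),
                   si = c(0, 11.9, 111.9, 99.3, 87.4))
  expect_equal(sensitivity_index(t3$fr, 1.43), t3$si, tolerance = 5e-3)
})

test_that("onset scans report an absent boundary rather than guessing", {
  ov <- list(channels = list(
    Na = list(gbar = 0), Kdr = list(gbar = 0), KM = list(gbar = 0),
    KA = list(gbar = 0), CaT = list(gbar = 0), CaL = list(gbar = 0),
    CaN = list(gbar = 0), H = list(gbar = 0), Kir = list(gbar = 0),
    BK = list(gbar = 0), SK = list(gbar = 0)))
  p0 <- lc_default_params(ov)
  sc <- spiking_onset_scan(p0, "I_app", c(-0.01, 0.01), sim_ms = 3000,
                           resolution = 5e-3)
  expect_true(is.na(sc$boundary))
  expect_false(any(sc$spiking_at))
})

test_that("rebound/recovery flags are absent for a constant protocol", {
  p <- default_params()
  prot <- protocol_constant("N", 0, 6000, record_dt = 0.1)
  sim <- cached("const6", function() run_protocol(prot, p))
  out <- detect_rebound_and_recovery(sim, prot)
  expect_false(out$pir)
  expect_false(out$recovery)
})
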