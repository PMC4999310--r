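test_that("baseline noise SD is recovered from the pre-stimulus window", {
  flat <- renderTrace(0, durationMs = 20, stimulusTimeMs = 5)
  expect_equal(estimateNoiseSd(flat), 0)

  tr <- renderTrace(0, durationMs = 220, stimulusTimeMs = 210,
                    samplingKhz = 50, noiseSdPa = 2, seed = 4)
  # >10,000 baseline samples; generator SD is the oracle
  expect_equal(estimateNoiseSd(tr, c(0, 205)), 2, tolerance = 0.05)

  expect_error(estimateNoiseSd(flat, c(0, 0.1)), "50 samples")
  expect_error(estimateNoiseSd(flat, c(0, 10)), "precede")
})

test_that("detection finds rendered EPSCs and reports failures", {
  flat <- renderTrace(0)
  evFlat <- detectEPSC(flat, kThreshold = 3)
  expect_true(isFailure(evFlat))

  # A = 100 pA alpha EPSC in 2 pA noise at k = 3
  tr <- renderTrace(100 * 0.5 * exp(1), tauMs = 0.5, noiseSdPa = 2,
                    seed = 8)
  ev <- detectEPSC(tr, kThreshold = 3)
  expect_false(isFailure(ev))
  expect_equal(ev@amplitudePa, 100, tolerance = 0.05)

  # onset limit: event starting 2.5 ms after the search window opens
  late <- renderTrace(200, onsetLatencyMs = 2.5, noiseSdPa = 1, seed = 9)
  evLate <- detectEPSC(late, kThreshold = 3, onsetLimitMs = 2)
  expect_true(isFailure(evLate))
  expect_true("onset_limit" %in% evLate@flags)
  # and accepted once the limit is relaxed
  expect_false(isFailure(detectEPSC(late, kThreshold = 3, onsetLimitMs = 4)))

  expect_error(detectEPSC(tr, kThreshold = 5), "\\[2, 4\\]")
})

test_that("detection is monotone in the threshold multiplier", {
  for (s in 1:10) {
    tr <- renderTrace(runif(1, 20, 400), tauMs = runif(1, 0.3, 1),
                      noiseSdPa = 2, seed = 200 + s)
    at4 <- !isFailure(detectEPSC(tr, kThreshold = 4))
    at2 <- !isFailure(detectEPSC(tr, kThreshold = 2))
    if (at4) expect_true(at2)
  }
})

test_that("kinetics match a dense-grid evaluation of the alpha waveform", {
  tau <- 0.5
  tr <- renderTrace(135.914, tauMs = tau, noiseSdPa = 0, samplingKhz = 100)
  ev <- measureKinetics(tr, detectEPSC(tr, kThreshold = 3))
  oracle <- alphaKineticsOracle(tau)
  expect_equal(ev@rise1090Ms, oracle$rise1090, tolerance = 0.02)
  expect_equal(ev@decay37Ms, oracle$decay37, tolerance = 0.02)
  expect_equal(ev@latencyMs, 1, tolerance = 0.1)
  expect_lte(ev@onsetMs, ev@peakMs)
})

test_that("triangular pulse rise time is 80% of its rising edge", {
  kHz <- 100
  tm <- seq(0, 20, by = 1 / kHz)
  cur <- numeric(length(tm))
  up <- tm >= 6 & tm <= 7    # 1 ms rising edge to peak at t = 7
  dn <- tm > 7 & tm <= 9
  cur[up] <- -100 * (tm[up] - 6)
  cur[dn] <- -100 * (1 - (tm[dn] - 7) / 2)
  tr <- EPSCTrace(tm, cur, stimulusTime = 5, samplingKhz = kHz)
  ev <- measureKinetics(tr, detectEPSC(tr, kThreshold = 3,
                                       onsetLimitMs = 2))
  expect_equal(ev@rise1090Ms, 0.8, tolerance = 0.01)
  expect_equal(ev@onsetMs, 6, tolerance = 0.02)  # back-projection to base

  failEv <- measureKinetics(tr, detectEPSC(renderTrace(0), 3))
  expect_true(isFailure(failEv))
  expect_true("kinetics_on_failure" %in% failEv@flags)
})

test_that("kinetics are scale-invariant; amplitude and charge equivariant", {
  tr <- renderTrace(200, tauMs = 0.6, noiseSdPa = 0, samplingKhz = 100)
  ev1 <- analyzeTrace(tr)
  tr3 <- EPSCTrace(tr@time, tr@current * 3, tr@stimulusTime,
                   tr@samplingKhz)
  ev3 <- analyzeTrace(tr3)
  expect_equal(ev3@rise1090Ms, ev1@rise1090Ms, tolerance = 1e-8)
  expect_equal(ev3@decay37Ms, ev1@decay37Ms, tolerance = 1e-8)
  expect_equal(ev3@latencyMs, ev1@latencyMs, tolerance = 1e-8)
  expect_equal(ev3@amplitudePa, 3 * ev1@amplitudePa)
  expect_equal(ev3@chargeFc, 3 * ev1@chargeFc, tolerance = 1e-8)
})

test_that("charge integration matches closed forms and is additive", {
  # rectangular 100 pA x 1 ms pulse -> 100 fC (unit identity)
  kHz <- 200
  tm <- seq(0, 20, by = 1 / kHz)
  cur <- ifelse(tm >= 6 & tm <= 7, -100, 0)
  tr <- EPSCTrace(tm, cur, stimulusTime = 5, samplingKhz = kHz)
  ev <- detectEPSC(tr, kThreshold = 3)
  expect_equal(integrateCharge(tr, ev), 100, tolerance = 0.01)

  # rendered alpha EPSC, A = 100 pA, tau = 0.5 -> A*tau*e = 135.914 fC
  tra <- renderTrace(100 * 0.5 * exp(1), tauMs = 0.5, noiseSdPa = 0,
                     samplingKhz = 100, durationMs = 60)
  eva <- detectEPSC(tra, kThreshold = 3)
  expect_equal(integrateCharge(tra, eva), 100 * 0.5 * exp(1),
               tolerance = 0.005)

  # superposition of two non-overlapping events adds their charges
  tr1 <- renderTrace(80, tauMs = 0.5, stimulusTimeMs = 5, durationMs = 60,
                     samplingKhz = 100)
  tp <- tr1@time - 26  # second event at 25 ms latency, far from the first
  cur2 <- numeric(length(tp))
  A2 <- 50 / (0.5 * exp(1))
  cur2[tp > 0] <- -A2 * (tp[tp > 0] / 0.5) * exp(1 - tp[tp > 0] / 0.5)
  both <- EPSCTrace(tr1@time, tr1@current + cur2, 5, tr1@samplingKhz)
  evb <- detectEPSC(both, kThreshold = 3)
  expect_equal(integrateCharge(both, evb, maxWindowMs = 50), 80 + 50,
               tolerance = 0.005 * 130)

  # zero trace integrates to zero
  expect_equal(integrateCharge(renderTrace(0), ev), 0)
})

test_that("noise-free rendered charge round-trips within 0.5%", {
  for (q in c(30, 120, 550)) {
    tr <- renderTrace(q, tauMs = 0.7, noiseSdPa = 0, samplingKhz = 100,
                      durationMs = 60)
    ev <- analyzeTrace(tr)
    expect_lt(abs(ev@chargeFc - q) / q, 0.005)
  }
})

test_that("epoch stability slope flags drifting epochs", {
  tt <- seq(0, 95, by = 5)
  st <- epochStability(rep(100, 20), tt)
  expect_equal(st$slope, 0)
  expect_true(st$pass)

  # linear rise 100 -> 200 fC: normalized slope = range/mean = 100/150
  rising <- seq(100, 200, length.out = 20)
  st2 <- epochStability(rising, tt)
  expect_equal(st2$slope, 100 / 150, tolerance = 1e-9)
  expect_false(st2$pass)

  # a normalized slope of exactly 0.05 sits on the boundary and fails
  # (strict inequality): y/mean(y) = 0.975 + 0.05 x has mean 1, slope 0.05
  x <- seq(0, 1, length.out = 20)
  st3 <- epochStability((0.975 + 0.05 * x) * 100, tt)
  expect_equal(st3$slope, 0.05, tolerance = 1e-12)
  expect_false(st3$pass)

  expect_error(epochStability(rep(100, 5), tt[1:5]), "10 trials")
  expect_error(epochStability(rep(0, 20), tt), "zero mean")
})
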