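test_that("pairwise variance matches hand-computed and iid cases", {
  expect_equal(pairwiseVariance(c(5, 5, 5, 5)), 0)
  expect_equal(pairwiseVariance(c(1, 3, 1, 3)), 2)
  expect_error(pairwiseVariance(5), "2 trials")

  set.seed(7)
  x <- rnorm(10000, 0, 3)
  expect_equal(pairwiseVariance(x), 9, tolerance = 0.05)
  expect_equal(pairwiseVariance(x) / var(x), 1, tolerance = 0.03)
})

test_that("pairwise variance removes linear drift exactly", {
  # pure ramp x_i = a + b*i: pairwise variance is b^2/2 for any n,
  # ordinary variance grows as b^2 n^2 / 12
  for (n in c(10, 75, 500)) {
    b <- 1.7
    x <- 2 + b * seq_len(n)
    expect_equal(pairwiseVariance(x), b^2 / 2)
    expect_equal(var(x), b^2 * n * (n + 1) / 12)
  }
})

test_that("variance-of-variance formula and its Monte-Carlo behaviour", {
  expect_equal(varianceOfVariance(10, 101), 2)
  expect_equal(varianceOfVariance(7, 2), 2 * 49)
  expect_error(varianceOfVariance(1, 1), ">= 2")

  # sampling variance of the *pairwise* estimator on iid Gaussian epochs:
  # exact closed form sigma^4 (8(n-1) + 4(n-2)) / (4(n-1)^2), which exceeds
  # the Gaussian s^2 formula 2 sigma^4/(n-1) by ~3/2 (efficiency 2/3 of the
  # consecutive-difference estimator); the 2 sigma^4/(n-1) approximation is
  # used for fit weights, where constant factors cancel
  set.seed(42)
  n <- 75; sigma <- 3
  pv <- replicate(10000, pairwiseVariance(rnorm(n, 0, sigma)))
  exact <- sigma^4 * (8 * (n - 1) + 4 * (n - 2)) / (4 * (n - 1)^2)
  expect_equal(var(pv), exact, tolerance = 0.1)
  expect_equal(exact / varianceOfVariance(sigma^2, n), 1.493,
               tolerance = 0.001)
})

test_that("variance-mean points reflect the generative moments", {
  p <- QuantalParameters(20, 40)
  e <- makeExperiment(p, fourConditions(), 75, seed = 3)
  pts <- suppressWarnings(varianceMeanPoints(e, requireStability = FALSE))
  expect_equal(nrow(pts), 4)
  for (i in 1:4) {
    mo <- theoreticalMoments(p, fourConditions()$p_r[i])
    se <- sqrt(mo$variance / 75)
    expect_lt(abs(pts$mean_fC[i] - mo$mean), 3 * se)
  }
  expect_true(all(pts$weight > 0))
  expect_true(all(pts$n == 75))

  two <- Experiment(epochs(e)[1:2])
  expect_error(suppressWarnings(varianceMeanPoints(two)), ">= 3 conditions")

  # constant-charge epochs give degenerate zero-variance points, flagged
  eps <- lapply(1:4, function(i) Epoch(paste0("c", i), i,
                                       charges = rep(100 * i, 20)))
  degPts <- varianceMeanPoints(Experiment(eps))
  expect_true(all(degPts$var_fC2 == 0))
  expect_true(all(degPts$degenerate))
})

test_that("exact noiseless parabola is inverted to machine precision", {
  p <- QuantalParameters(20, 40)
  prs <- c(0.1, 0.33, 0.5, 0.8)
  pts <- theoreticalPoints(p, prs)
  expect_equal(pts$mean_fC, c(80, 264, 400, 640))
  expect_equal(pts$var_fC2, c(2880, 7075.2, 8000, 5120))
  fit <- suppressWarnings(fitParabola(pts))
  expect_lt(abs(quantalSize(fit) - 40) / 40, 1e-9)
  expect_lt(abs(releaseSites(fit) - 20) / 20, 1e-9)
  expect_equal(unname(releaseProb(fit)), prs, tolerance = 1e-9)
})

test_that("parameter recovery at the experimental design scale", {
  # 30 simulated experiments (75 trials/epoch, no quantal noise): medians
  # recover the generative q and N; the full-scale study runs in the
  # acceptance suite
  p <- QuantalParameters(20, 40)
  res <- sapply(1:30, function(s) {
    e <- makeExperiment(p, fourConditions(), 75, seed = s)
    f <- suppressWarnings(mpfa(e, requireStability = FALSE))
    c(q = quantalSize(f), N = releaseSites(f))
  })
  expect_lt(abs(median(res["q", ]) - 40) / 40, 0.10)
  expect_lt(abs(median(res["N", ], na.rm = TRUE) - 20) / 20, 0.20)
})

test_that("collinear variance-mean points take the no-curvature path", {
  pts <- data.frame(label = c("a", "b", "c"), mean_fC = c(10, 20, 30),
                    var_fC2 = c(50, 100, 150), n = 50)
  pts$weight <- 1 / varianceOfVariance(pts$var_fC2, pts$n)
  w <- capture_warnings(fit <- fitParabola(pts))
  expect_true(any(grepl("no curvature", w)))
  expect_true(is.na(releaseSites(fit)))
  expect_equal(quantalSize(fit), 5, tolerance = 1e-6)  # initial slope
  expect_false(fit@converged)

  dup <- pts; dup$mean_fC <- c(10, 10, 30)
  expect_error(fitParabola(dup), "duplicate")
})

test_that("fit is scale-equivariant and P_r monotone in epoch mean", {
  p <- QuantalParameters(15, 30, cvIntra = 0.2)
  e <- makeExperiment(p, fourConditions(), 80, seed = 21)
  f1 <- suppressWarnings(mpfa(e, requireStability = FALSE))
  cc <- 2.5
  eps <- lapply(epochs(e), function(ep)
    Epoch(ep@label, ep@caMM, ep@pR, cc * charges(ep), trialTimes(ep)))
  f2 <- suppressWarnings(mpfa(Experiment(eps), requireStability = FALSE))
  expect_equal(quantalSize(f2), cc * quantalSize(f1), tolerance = 1e-8)
  expect_equal(releaseSites(f2), releaseSites(f1), tolerance = 1e-8)
  expect_equal(unname(releaseProb(f2)), unname(releaseProb(f1)),
               tolerance = 1e-8)
  # P_r ordering follows the epoch-mean ordering for a fixed fit
  ord <- order(f1@points$mean_fC)
  expect_true(all(diff(releaseProb(f1)[ord]) > 0))
})

test_that("quantal noise inflates fitted q by (1 + cv^2)", {
  # with cv_intra = 0.3 the variance-mean slope at the origin is
  # q (1 + cv^2), so fitted q is inflated ~1.09; subset of the full
  # acceptance-scale study
  p <- QuantalParameters(20, 40, cvIntra = 0.3)
  infl <- sapply(1:40, function(s) {
    e <- makeExperiment(p, fourConditions(), 300, seed = 500 + s)
    suppressWarnings(mpfa(e, requireStability = FALSE))@qFc / 40
  })
  expect_gt(median(infl), 1.02)
  expect_lt(median(infl), 1.16)
})

test_that("predicted failure rate matches the binomial closed form", {
  expect_equal(predictedFailureRate(5, 0), 1)
  expect_equal(predictedFailureRate(1, 0.3), 0.7)
  expect_equal(predictedFailureRate(5, 0.2), 0.32768)
  # simulation oracle at 1e5 trials
  p <- QuantalParameters(5, 10)
  x <- simulateTrialCharges(p, 0.2, 1e5, seed = 77)
  obs <- mean(x == 0)
  se <- sqrt(0.32768 * (1 - 0.32768) / 1e5)
  expect_lt(abs(obs - 0.32768), 3 * se)
  # non-integer N permitted
  expect_equal(predictedFailureRate(4.7, 0.17), (1 - 0.17)^4.7)
})

test_that("failure consistency compares prediction with observation", {
  pts <- theoreticalPoints(QuantalParameters(20, 40), c(0.1, 0.33, 0.5, 0.8))
  fit <- suppressWarnings(fitParabola(pts))
  # rat-like check: N = 4.7, P = 0.17 predicts 41.7% failures; an observed
  # 39.1% at 75 trials is consistent within 1 binomial SE
  pred <- predictedFailureRate(4.7, 0.17)
  expect_equal(pred, 0.417, tolerance = 0.005)
  se <- sqrt(pred * (1 - pred) / 75)
  expect_lt(abs(0.391 - pred), se)

  obs <- predictedFailureRate(fit@nFrs, fit@pR)  # perfectly consistent
  rep1 <- failureConsistency(fit, obs, nTrials = 75)
  expect_false(any(rep1$flagged))

  # P_r = 1 condition with any observed failures must be flagged
  pts2 <- theoreticalPoints(QuantalParameters(5, 10), c(0.3, 0.6, 1.0))
  fit2 <- suppressWarnings(fitParabola(pts2))
  obs2 <- c(c1 = 0.35, c2 = 0.07, c3 = 0.02)
  rep2 <- failureConsistency(fit2, obs2, nTrials = 75)
  expect_true(rep2$flagged[rep2$label == "c3"])
})
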