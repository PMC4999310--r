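# Generative twin of the binomial release model MPFA assumes: N independent
# sites, each releasing one quantum q with probability Pr per stimulus.

#' Simulate per-trial EPSC charges from the binomial release-site model
#'
#' Each trial charge is the sum over release sites of a Bernoulli(\code{pR})
#' release indicator times the site's quantal charge. Site quanta are drawn
#' once (with CV \code{cvInter} around \code{q}) and reused across trials;
#' `makeExperiment()` draws them once per experiment and shares them across
#' epochs. Each released quantum additionally carries independent
#' multiplicative intra-site noise (Normal with mean 1, SD \code{cvIntra}).
#' Additive Gaussian baseline noise (\code{noiseSd}) and an optional linear
#' multiplicative drift of the quantal content across the epoch complete the
#' trial charge.
#'
#' @param params a [QuantalParameters-class] object.
#' @param pR per-site release probability in [0, 1].
#' @param nTrials number of trials; 0 returns an empty vector.
#' @param seed optional integer seed; fixed seed gives identical output.
#' @param siteQuanta optional numeric vector of length \code{nSites} of
#'   per-site quantal charges, overriding the inter-site draw.
#' @return numeric vector of trial charges (fC, positive magnitudes).
#' @examples
#' p <- QuantalParameters(nSites = 5, q = 10)
#' simulateTrialCharges(p, pR = 1, nTrials = 4, seed = 1)  # 50 50 50 50
#' @seealso [theoreticalMoments()] for the closed-form moments.
#' @export
simulateTrialCharges <- function(params, pR, nTrials, seed = NULL,
                                 siteQuanta = NULL) {
  stopifnot(is(params, "QuantalParameters"))
  validObject(params)
  if (!is.numeric(pR) || length(pR) != 1L || is.na(pR) || pR < 0 || pR > 1)
    stop("pR must be a single probability in [0, 1]")
  nTrials <- as.integer(nTrials)
  if (is.na(nTrials) || nTrials < 0L)
    stop("nTrials must be a non-negative integer")
  if (nTrials == 0L) return(numeric(0))
  if (!is.null(seed)) set.seed(seed)

  n <- nTrials
  N <- params@nSites
  if (is.null(siteQuanta)) {
    siteQuanta <- if (params@cvInter > 0)
      params@q * (1 + params@cvInter * stats::rnorm(N))
    else rep(params@q, N)
  }
  stopifnot(length(siteQuanta) == N)

  released <- matrix(stats::rbinom(n * N, 1L, pR), nrow = n, ncol = N)
  quanta <- released * rep(siteQuanta, each = n)
  if (params@cvIntra > 0) {
    intra <- matrix(1 + params@cvIntra * stats::rnorm(n * N), nrow = n)
    quanta <- quanta * intra
  }
  total <- rowSums(quanta)

  if (params@driftPerEpoch != 0 && n > 1L) {
    drift <- 1 + params@driftPerEpoch * (seq_len(n) - 1) / (n - 1)
    total <- total * drift
  }
  if (params@noiseSd > 0)
    total <- total + stats::rnorm(n, 0, params@noiseSd)
  total
}

#' Closed-form moments of the binomial quantal model
#'
#' Mean, variance and failure probability of the per-trial charge implied by
#' \code{params} at release probability \code{pR}, for the \code{cvInter = 0}
#' case:
#' \deqn{\mu = N p q, \quad
#'   \sigma^2 = N p (1-p) q^2 + N p q^2 cv_{intra}^2 + \sigma_{noise}^2, \quad
#'   P(fail) = (1-p)^N.}
#' Inter-site quantal dispersion is a simulator-only feature: it makes site
#' quanta unequal, which the single-q binomial moments above (and MPFA itself)
#' do not model, so it is deliberately excluded here.
#'
#' @inheritParams simulateTrialCharges
#' @return list with components `mean` (fC), `variance` (fC^2), `failure`.
#' @examples
#' p <- QuantalParameters(nSites = 5, q = 10)
#' theoreticalMoments(p, 0.2)  # mean 10, variance 80, failure 0.32768
#' @export
theoreticalMoments <- function(params, pR) {
  stopifnot(is(params, "QuantalParameters"))
  if (!is.numeric(pR) || length(pR) != 1L || pR < 0 || pR > 1)
    stop("pR must be a single probability in [0, 1]")
  N <- as.numeric(params@nSites)
  q <- params@q
  list(
    mean = N * pR * q,
    variance = N * pR * (1 - pR) * q^2 +
      N * pR * q^2 * params@cvIntra^2 + params@noiseSd^2,
    failure = (1 - pR)^N
  )
}

# fixed arithmetic so every epoch is independently reproducible from the
# master seed; kept below .Machine$integer.max
.epochSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + 7 * i) %% 2147483647)
}

#' Assemble a multi-condition synthetic experiment
#'
#' Builds one [Epoch-class] per condition via [simulateTrialCharges()], with
#' per-site quanta drawn once from the master seed and shared across epochs,
#' and per-epoch seeds derived by fixed arithmetic so each epoch is
#' independently reproducible. Trials are placed at 5 s intervals. MPFA needs
#' at least three release-probability conditions, so fewer than three is an
#' error; more than five is rejected to mirror the experimental design.
#'
#' @param params a [QuantalParameters-class] object (the ground truth,
#'   recorded in the result).
#' @param conditions data.frame with columns `label`, `ca_mM`, `p_r`;
#'   `p_r` must be non-decreasing in `ca_mM`.
#' @param nTrialsPerEpoch trials per epoch (default 75, the typical epoch
#'   length in paired recordings).
#' @param seed master integer seed.
#' @return an [Experiment-class] with `paramsTrue` set.
#' @examples
#' conds <- data.frame(label = c("0.5Ca", "1.5Ca", "2Ca", "4Ca"),
#'                     ca_mM = c(0.5, 1.5, 2, 4),
#'                     p_r = c(0.1, 0.33, 0.5, 0.8))
#' exp <- makeExperiment(QuantalParameters(20, 40), conds, 75, seed = 1)
#' @export
makeExperiment <- function(params, conditions, nTrialsPerEpoch = 75,
                           seed = 1) {
  stopifnot(is(params, "QuantalParameters"))
  validObject(params)
  if (!is.data.frame(conditions) ||
      !all(c("label", "ca_mM", "p_r") %in% names(conditions)))
    stop("conditions must be a data.frame with columns label, ca_mM, p_r")
  nc <- nrow(conditions)
  if (nc < 3L || nc > 5L)
    stop("MPFA requires 3 to 5 release-probability conditions, got ", nc)
  if (anyDuplicated(conditions$label))
    stop("condition labels must be unique")
  ord <- order(conditions$ca_mM)
  if (any(diff(conditions$p_r[ord]) < 0))
    stop("p_r must be non-decreasing in ca_mM")

  set.seed(seed)
  siteQuanta <- if (params@cvInter > 0)
    params@q * (1 + params@cvInter * stats::rnorm(params@nSites))
  else rep(params@q, params@nSites)

  eps <- lapply(seq_len(nc), function(i) {
    ch <- simulateTrialCharges(params, conditions$p_r[i], nTrialsPerEpoch,
                               seed = .epochSeed(seed, i),
                               siteQuanta = siteQuanta)
    Epoch(label = conditions$label[i], caMM = conditions$ca_mM[i],
          pR = conditions$p_r[i], charges = ch)
  })
  Experiment(epochs = eps, paramsTrue = params, seed = seed)
}

#' Render a synthetic EPSC current trace
#'
#' Produces a negative-going alpha-function current
#' \eqn{I(t) = -A (t'/\tau) e^{1 - t'/\tau}} for \eqn{t' = t - t_{onset}}
#' after the stimulus, with the peak amplitude \eqn{A = charge / (\tau e)}
#' chosen so the integral of \eqn{|I|} equals the requested charge
#' (\eqn{\int_0^\infty A (t'/\tau) e^{1-t'/\tau} dt' = A \tau e}).
#' The waveform is a rendering surrogate: only its kinetic summaries
#' (latency, rise, decay, charge) are meaningful downstream.
#'
#' @param charge requested EPSC charge, fC (0 gives a flat trace).
#' @param onsetLatencyMs onset latency after the stimulus, ms.
#' @param tauMs alpha-function time constant, ms, > 0.
#' @param samplingKhz sampling rate, kHz, >= 10.
#' @param noiseSdPa additive Gaussian sample noise SD, pA.
#' @param durationMs total trace duration, ms.
#' @param stimulusTimeMs presynaptic stimulus time, ms.
#' @param seed optional integer seed for the noise.
#' @return an [EPSCTrace-class].
#' @examples
#' tr <- renderTrace(135.914, tauMs = 0.5)  # peak amplitude 100 pA
#' min(tr@current)
#' @export
renderTrace <- function(charge, onsetLatencyMs = 1, tauMs = 0.5,
                        samplingKhz = 50, noiseSdPa = 0, durationMs = 20,
                        stimulusTimeMs = 5, seed = NULL) {
  if (!is.numeric(tauMs) || tauMs <= 0) stop("tauMs must be > 0")
  if (samplingKhz < 10) stop("samplingKhz must be >= 10")
  if (charge < 0) stop("charge must be a non-negative magnitude")
  if (!is.null(seed)) set.seed(seed)

  tm <- seq(0, durationMs, by = 1 / samplingKhz)
  tp <- tm - (stimulusTimeMs + onsetLatencyMs)
  A <- charge / (tauMs * exp(1))
  cur <- numeric(length(tm))
  on <- tp > 0
  cur[on] <- -A * (tp[on] / tauMs) * exp(1 - tp[on] / tauMs)
  if (noiseSdPa > 0)
    cur <- cur + stats::rnorm(length(tm), 0, noiseSdPa)
  EPSCTrace(time = tm, current = cur, stimulusTime = stimulusTimeMs,
            samplingKhz = samplingKhz)
}

#' Generate a synthetic active zone with vesicles in requested classes
#'
#' Draws scalar vesicle membrane distances uniformly from the class-defining
#' ranges (docked: [0, contact tolerance]; pre-docked: (tolerance, 5] nm;
#' pool: (5, 100] nm; outside/far: (100, 300] nm) so that downstream
#' classification recovers the requested counts exactly.
#'
#' @param areaUm2 AZ area, um^2, > 0.
#' @param nDocked,nPredocked,nPool,nFar non-negative class counts.
#' @param seed optional integer seed.
#' @param azId identifier for the resulting [ActiveZone-class].
#' @param contactToleranceNm docked/pre-docked boundary, nm.
#' @return an [ActiveZone-class] with classified vesicles.
#' @examples
#' az <- generateActiveZone(0.09, nDocked = 4, nPool = 10, seed = 1)
#' dockedCount(az)  # 4
#' @export
generateActiveZone <- function(areaUm2, nDocked = 0, nPredocked = 0,
                               nPool = 0, nFar = 0, seed = NULL,
                               azId = "az1", contactToleranceNm = 0.5) {
  if (areaUm2 <= 0) stop("areaUm2 must be > 0")
  counts <- c(nDocked, nPredocked, nPool, nFar)
  if (any(counts < 0)) stop("vesicle counts must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  d <- c(
    stats::runif(nDocked, 0, contactToleranceNm),
    stats::runif(nPredocked, contactToleranceNm + 1e-9, 5),
    stats::runif(nPool, 5 + 1e-9, 100),
    stats::runif(nFar, 100 + 1e-9, 300)
  )
  ActiveZone(azId = azId, areaUm2 = areaUm2, distanceNm = d,
             contactToleranceNm = contactToleranceNm)
}
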