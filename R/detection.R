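# Stimulus-locked EPSC detection and kinetic measurement.
#
# Conventions: EPSCs are inward (negative) currents; internally everything
# works on the "deflection" = baseline - current, a positive magnitude for an
# inward event. Baseline is the mean of the pre-stimulus window (the paper
# does not define baseline estimation; this is the package's convention).

.baselineWindow <- function(trace, baselineWindowMs) {
  if (is.null(baselineWindowMs))
    baselineWindowMs <- c(trace@time[1], trace@stimulusTime)
  baselineWindowMs
}

.windowIdx <- function(trace, windowMs) {
  which(trace@time >= windowMs[1] & trace@time <= windowMs[2])
}

#' Estimate baseline noise SD from a pre-stimulus window
#'
#' Standard deviation of the current in a baseline window preceding the
#' stimulus, after subtracting the window mean. This feeds the k-times-SD
#' detection threshold.
#'
#' @param trace an [EPSCTrace-class].
#' @param baselineWindowMs numeric length-2 interval (ms); defaults to the
#'   whole pre-stimulus stretch. Must precede the stimulus and contain at
#'   least 50 samples.
#' @return noise SD in pA.
#' @export
estimateNoiseSd <- function(trace, baselineWindowMs = NULL) {
  stopifnot(is(trace, "EPSCTrace"))
  w <- .baselineWindow(trace, baselineWindowMs)
  if (w[2] > trace@stimulusTime + 1e-9)
    stop("baseline window must precede the stimulus time")
  idx <- .windowIdx(trace, w)
  if (!length(idx) || w[1] < trace@time[1] - 1e-9)
    stop("baseline window outside the trace")
  if (length(idx) < 50L)
    stop("baseline window must contain at least 50 samples, has ",
         length(idx))
  stats::sd(trace@current[idx])
}

.failureEvent <- function(flags = character(0)) {
  new("EPSCEvent", isFailure = TRUE, flags = flags)
}

# linear interpolation of the time at which y (ordered along idx) first
# crosses the level, scanning forward
.crossTime <- function(tm, y, level, from, to, rising = TRUE) {
  ii <- from:to
  if (rising) hit <- which(y[ii] >= level) else hit <- which(y[ii] <= level)
  if (!length(hit)) return(NA_real_)
  j <- ii[hit[1]]
  if (j == from || y[j] == level) return(tm[j])
  j0 <- j - 1L
  frac <- (level - y[j0]) / (y[j] - y[j0])
  tm[j0] + frac * (tm[j] - tm[j0])
}

# 10% and 90% crossing times on the rising phase, scanning backward from the
# peak so late re-crossings of noisy baselines are ignored
.riseCrossings <- function(tm, defl, iStart, iPeak, amp) {
  t90 <- t10 <- NA_real_
  for (lev in c(0.9, 0.1)) {
    j <- iPeak
    while (j > iStart && defl[j] >= lev * amp) j <- j - 1L
    if (defl[j] >= lev * amp) {       # never dropped below: degenerate rise
      tt <- tm[j]
    } else {
      frac <- (lev * amp - defl[j]) / (defl[j + 1L] - defl[j])
      tt <- tm[j] + frac * (tm[j + 1L] - tm[j])
    }
    if (lev == 0.9) t90 <- tt else t10 <- tt
  }
  c(t10 = t10, t90 = t90)
}

#' Detect a stimulus-evoked EPSC in a current trace
#'
#' Searches after the stimulus time for the first excursion of the current
#' beyond \code{kThreshold} times the baseline noise SD below baseline.
#' The event is accepted only if the threshold is reached within
#' \code{onsetLimitMs} of the stimulus (onset time limit) and the peak is
#' reached within \code{peakLimitMs} of the threshold crossing (peak time
#' limit); otherwise a failure event is returned. Onset is defined by
#' back-projecting the 10-90\% rise slope line to baseline.
#'
#' @param trace an [EPSCTrace-class].
#' @param kThreshold detection threshold in baseline-noise SDs, in [2, 4].
#' @param onsetLimitMs maximum interval from the stimulus until the
#'   deflection reaches threshold (default 2 ms).
#' @param peakLimitMs maximum interval from threshold crossing to peak
#'   (default 3 ms).
#' @param baselineWindowMs baseline window passed to [estimateNoiseSd()].
#' @return an [EPSCEvent-class]; a failure event when no acceptable
#'   deflection is found, with `flags` saying which limit rejected it.
#' @examples
#' tr <- renderTrace(500, noiseSdPa = 2, seed = 1)
#' detectEPSC(tr, kThreshold = 3)
#' @export
detectEPSC <- function(trace, kThreshold = 3, onsetLimitMs = 2,
                       peakLimitMs = 3, baselineWindowMs = NULL) {
  stopifnot(is(trace, "EPSCTrace"))
  if (kThreshold < 2 || kThreshold > 4)
    stop("kThreshold must be in [2, 4]")
  if (is.na(trace@stimulusTime)) stop("trace has no stimulus time")

  w <- .baselineWindow(trace, baselineWindowMs)
  bidx <- .windowIdx(trace, w)
  baseline <- mean(trace@current[bidx])
  noiseSd <- estimateNoiseSd(trace, w)

  tm <- trace@time
  defl <- baseline - trace@current
  n <- length(tm)
  iStim <- which(tm >= trace@stimulusTime)[1]

  thr <- kThreshold * noiseSd
  cand <- which(defl > thr & seq_len(n) >= iStim)
  if (!length(cand)) return(.failureEvent("no_threshold_crossing"))
  iCross <- cand[1]
  tCross <- .crossTime(tm, defl, thr, max(iStim, iCross - 1L), iCross)
  if (is.na(tCross)) tCross <- tm[iCross]
  if (tCross - trace@stimulusTime > onsetLimitMs)
    return(.failureEvent("onset_limit"))

  # peak: maximum deflection within the peak time limit of the crossing
  iLim <- max(which(tm <= tCross + peakLimitMs))
  seg <- iCross:iLim
  iPeak <- seg[which.max(defl[seg])]
  # still rising at the edge of the peak window -> peak limit exceeded
  if (iPeak == iLim && iLim < n && defl[iLim + 1L] > defl[iLim])
    return(.failureEvent("peak_limit"))
  amp <- defl[iPeak]

  rc <- .riseCrossings(tm, defl, iStim, iPeak, amp)
  slope <- unname(0.8 * amp / (rc[["t90"]] - rc[["t10"]]))
  onset <- if (is.finite(slope) && slope > 0)
    rc[["t10"]] - 0.1 * amp / slope
  else tm[iPeak]

  new("EPSCEvent", onsetMs = onset, peakMs = tm[iPeak], amplitudePa = amp,
      isFailure = FALSE)
}

#' Measure EPSC kinetics (latency, rise, decay)
#'
#' Completes a detected event with latency (onset minus stimulus time),
#' 10-90\% rise time and the time from peak until the current magnitude first
#' falls to 37\% of peak, all level crossings linearly interpolated between
#' samples. A failure event is returned unchanged with a flag. If the trace
#' ends before the 37\% decay level is reached the decay is reported missing
#' and the event flagged right-censored.
#'
#' @param trace an [EPSCTrace-class].
#' @param event an [EPSCEvent-class] from [detectEPSC()].
#' @param baselineWindowMs baseline window, as in [detectEPSC()].
#' @return the completed [EPSCEvent-class].
#' @export
measureKinetics <- function(trace, event, baselineWindowMs = NULL) {
  stopifnot(is(trace, "EPSCTrace"), is(event, "EPSCEvent"))
  if (event@isFailure) {
    event@flags <- union(event@flags, "kinetics_on_failure")
    return(event)
  }
  w <- .baselineWindow(trace, baselineWindowMs)
  baseline <- mean(trace@current[.windowIdx(trace, w)])
  tm <- trace@time
  defl <- baseline - trace@current
  n <- length(tm)
  iStim <- which(tm >= trace@stimulusTime)[1]
  iPeak <- which.min(abs(tm - event@peakMs))
  amp <- event@amplitudePa

  rc <- .riseCrossings(tm, defl, iStim, iPeak, amp)
  event@rise1090Ms <- rc[["t90"]] - rc[["t10"]]
  event@latencyMs <- event@onsetMs - trace@stimulusTime

  tDecay <- .crossTime(tm, defl, 0.37 * amp, iPeak, n, rising = FALSE)
  if (is.na(tDecay)) {
    event@decay37Ms <- NA_real_
    event@flags <- union(event@flags, "right_censored")
  } else {
    event@decay37Ms <- tDecay - tm[iPeak]
  }
  validObject(event)
  event
}

#' Integrate the charge of a detected EPSC
#'
#' Trapezoidal integral of the baseline-subtracted current magnitude from the
#' event onset until the current first returns within one baseline-noise SD
#' of baseline after the peak, or until \code{maxWindowMs} past onset,
#' whichever comes first. 1 pA x 1 ms = 1 fC, so the pA-ms integral is
#' reported directly as fC.
#'
#' @param trace an [EPSCTrace-class].
#' @param event a detected [EPSCEvent-class].
#' @param maxWindowMs maximum integration window after onset, ms.
#' @param baselineWindowMs baseline window, as in [detectEPSC()].
#' @return charge in fC (also stored in the returned event by
#'   `analyzeTrace()`).
#' @export
integrateCharge <- function(trace, event, maxWindowMs = 50,
                            baselineWindowMs = NULL) {
  stopifnot(is(trace, "EPSCTrace"), is(event, "EPSCEvent"))
  if (event@isFailure) return(NA_real_)
  w <- .baselineWindow(trace, baselineWindowMs)
  baseline <- mean(trace@current[.windowIdx(trace, w)])
  noiseSd <- estimateNoiseSd(trace, w)
  tm <- trace@time
  defl <- baseline - trace@current
  n <- length(tm)

  iOn <- which(tm >= event@onsetMs)[1]
  if (is.na(iOn)) return(0)
  iPeak <- which.min(abs(tm - event@peakMs))
  post <- which(defl <= noiseSd & seq_len(n) > iPeak)
  iEnd <- if (length(post)) post[1] else n
  iMax <- max(which(tm <= event@onsetMs + maxWindowMs))
  iEnd <- min(iEnd, iMax)
  if (iEnd <= iOn) return(0)
  seg <- iOn:iEnd
  sum(diff(tm[seg]) * (defl[seg][-1] + defl[seg][-length(seg)]) / 2)
}

#' Detect, measure and integrate in one call
#'
#' Convenience wrapper running [detectEPSC()], [measureKinetics()] and
#' [integrateCharge()] and returning the completed event.
#'
#' @inheritParams detectEPSC
#' @param maxWindowMs integration window, see [integrateCharge()].
#' @return a completed [EPSCEvent-class].
#' @export
analyzeTrace <- function(trace, kThreshold = 3, onsetLimitMs = 2,
                         peakLimitMs = 3, maxWindowMs = 50,
                         baselineWindowMs = NULL) {
  ev <- detectEPSC(trace, kThreshold, onsetLimitMs, peakLimitMs,
                   baselineWindowMs)
  if (ev@isFailure) return(ev)
  ev <- measureKinetics(trace, ev, baselineWindowMs)
  ev@chargeFc <- integrateCharge(trace, ev, maxWindowMs, baselineWindowMs)
  ev
}

#' Epoch stability check (normalized charge-vs-time slope)
#'
#' Ordinary least-squares regression of charge normalized to the epoch mean
#' against time normalized to the epoch duration; the epoch is stable iff the
#' absolute slope is strictly below 0.05 (i.e. less than 5\% drift across the
#' epoch). The normalization makes the criterion scale-free.
#'
#' @param charges numeric vector of per-trial charges (fC), >= 10 trials.
#' @param trialTimes numeric vector of trial times (s), strictly increasing.
#' @param slopeLimit pass threshold on the absolute normalized slope.
#' @return list with `slope` (normalized) and `pass` (logical).
#' @examples
#' epochStability(rep(100, 20), seq(0, 95, by = 5))  # slope 0, pass
#' @export
epochStability <- function(charges, trialTimes, slopeLimit = 0.05) {
  if (length(charges) < 10L)
    stop("epoch stability needs at least 10 trials")
  if (length(charges) != length(trialTimes))
    stop("charges and trialTimes must have equal length")
  m <- mean(charges)
  if (!is.finite(m) || m == 0)
    stop("zero mean charge: stability slope undefined")
  dur <- trialTimes[length(trialTimes)] - trialTimes[1]
  if (dur <= 0) stop("trialTimes must span a positive duration")
  y <- charges / m
  x <- (trialTimes - trialTimes[1]) / dur
  slope <- unname(stats::coef(stats::lm(y ~ x))[2])
  # strict inequality at the limit, robust to floating-point slack so a
  # drift of exactly the limit never passes
  pass <- abs(slope) < slopeLimit &&
    abs(abs(slope) - slopeLimit) > 1e-9 * max(1, slopeLimit)
  list(slope = slope, pass = pass)
}
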