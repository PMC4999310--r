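#' @import methods
NULL

#' Ground-truth generative parameters of a synaptic connection
#'
#' Container for the parameters of the binomial release-site model: a
#' connection is made of \code{nSites} independent functional release sites,
#' each releasing at most one vesicle per presynaptic action potential with
#' probability \eqn{P_r}, each released vesicle contributing a quantal charge
#' \eqn{q} (fC) to the postsynaptic response.
#'
#' Quantal variability is decomposed into an intra-site component
#' (\code{cvIntra}, independent multiplicative noise per released vesicle per
#' trial) and an inter-site component (\code{cvInter}, fixed per-site quanta
#' drawn once per experiment). \code{noiseSd} is additive Gaussian baseline
#' charge noise and \code{driftPerEpoch} a fractional linear multiplicative
#' drift of the quantal content across one recording epoch.
#'
#' @slot nSites integer, number of release sites (N), \eqn{\ge 1}.
#' @slot q numeric, quantal charge in fC, \eqn{> 0}.
#' @slot cvIntra numeric, intra-site quantal coefficient of variation.
#' @slot cvInter numeric, inter-site quantal coefficient of variation.
#' @slot noiseSd numeric, additive baseline charge noise SD in fC.
#' @slot driftPerEpoch numeric, fractional drift of q over one epoch.
#' @seealso [simulateTrialCharges()], [theoreticalMoments()], [makeExperiment()]
#' @export
setClass("QuantalParameters",
  slots = c(
    nSites = "integer",
    q = "numeric",
    cvIntra = "numeric",
    cvInter = "numeric",
    noiseSd = "numeric",
    driftPerEpoch = "numeric"
  )
)

setValidity("QuantalParameters", function(object) {
  msg <- character(0)
  if (length(object@nSites) != 1L || is.na(object@nSites) || object@nSites < 1L)
    msg <- c(msg, "nSites must be a single integer >= 1")
  if (length(object@q) != 1L || !is.finite(object@q) || object@q <= 0)
    msg <- c(msg, "q must be a single positive number (fC)")
  for (nm in c("cvIntra", "cvInter", "noiseSd")) {
    v <- slot(object, nm)
    if (length(v) != 1L || !is.finite(v) || v < 0)
      msg <- c(msg, paste(nm, "must be a single number >= 0"))
  }
  if (length(object@driftPerEpoch) != 1L || !is.finite(object@driftPerEpoch))
    msg <- c(msg, "driftPerEpoch must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' @param nSites,q,cvIntra,cvInter,noiseSd,driftPerEpoch see slot descriptions.
#' @return `QuantalParameters()` returns a validated object.
#' @examples
#' QuantalParameters(nSites = 20, q = 40)
#' @rdname QuantalParameters-class
#' @export
QuantalParameters <- function(nSites, q, cvIntra = 0, cvInter = 0,
                              noiseSd = 0, driftPerEpoch = 0) {
  new("QuantalParameters",
      nSites = as.integer(nSites), q = as.numeric(q),
      cvIntra = as.numeric(cvIntra), cvInter = as.numeric(cvInter),
      noiseSd = as.numeric(noiseSd), driftPerEpoch = as.numeric(driftPerEpoch))
}

#' One recording epoch under a single release-probability condition
#'
#' An ordered series of per-trial EPSC charges recorded under one extracellular
#' calcium condition. Charges are stored as positive magnitudes (EPSCs are
#' inward at -70 mV; the sign lives at the trace level only). \code{pR} is the
#' per-site vesicular release probability when known (synthetic data); for
#' recorded data it is \code{NA}.
#'
#' @slot label character, unique condition label.
#' @slot caMM numeric, extracellular calcium concentration in mM.
#' @slot pR numeric, per-site release probability in [0, 1] or NA.
#' @slot charges numeric, per-trial EPSC charges in fC, acquisition order.
#' @slot trialTimes numeric, trial times in seconds from epoch start,
#'   strictly increasing.
#' @export
setClass("Epoch",
  slots = c(
    label = "character",
    caMM = "numeric",
    pR = "numeric",
    charges = "numeric",
    trialTimes = "numeric"
  )
)

setValidity("Epoch", function(object) {
  msg <- character(0)
  if (length(object@label) != 1L || is.na(object@label))
    msg <- c(msg, "label must be a single string")
  if (length(object@caMM) != 1L || (!is.na(object@caMM) && object@caMM <= 0))
    msg <- c(msg, "caMM must be a single positive number (mM)")
  if (length(object@pR) != 1L ||
      (!is.na(object@pR) && (object@pR < 0 || object@pR > 1)))
    msg <- c(msg, "pR must be NA or in [0, 1]")
  if (length(object@charges) != length(object@trialTimes))
    msg <- c(msg, "charges and trialTimes must have equal length")
  if (length(object@trialTimes) > 1L && any(diff(object@trialTimes) <= 0))
    msg <- c(msg, "trialTimes must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' @param label,caMM,pR,charges,trialTimes see slot descriptions. If
#'   `trialTimes` is missing, trials are placed at 5 s intervals (the
#'   stimulation interval used in paired recordings).
#' @rdname Epoch-class
#' @export
Epoch <- function(label, caMM = NA_real_, pR = NA_real_, charges,
                  trialTimes = NULL) {
  if (is.null(trialTimes))
    trialTimes <- (seq_along(charges) - 1) * 5
  new("Epoch", label = as.character(label), caMM = as.numeric(caMM),
      pR = as.numeric(pR), charges = as.numeric(charges),
      trialTimes = as.numeric(trialTimes))
}

setClassUnion("QuantalParametersOrNULL", c("QuantalParameters", "NULL"))

#' A multi-condition quantal-analysis experiment
#'
#' Epochs recorded (or simulated) from one connection under several
#' release-probability conditions, the unit of input to MPFA fitting.
#' MPFA needs at least three conditions; `varianceMeanPoints()` enforces this
#' at fit time so partially assembled experiments remain representable.
#'
#' @slot epochs list of [Epoch-class] objects with unique labels.
#' @slot paramsTrue the generative [QuantalParameters-class] for synthetic
#'   experiments, or NULL for recorded data.
#' @slot seed integer master seed used for simulation (NA for recorded data).
#' @export
setClass("Experiment",
  slots = c(
    epochs = "list",
    paramsTrue = "QuantalParametersOrNULL",
    seed = "integer"
  )
)

setValidity("Experiment", function(object) {
  msg <- character(0)
  if (!length(object@epochs))
    msg <- c(msg, "at least one epoch required")
  if (!all(vapply(object@epochs, is, logical(1), class2 = "Epoch")))
    msg <- c(msg, "epochs must all be Epoch objects")
  else {
    labs <- vapply(object@epochs, function(e) e@label, character(1))
    if (anyDuplicated(labs))
      msg <- c(msg, "condition labels must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' @param epochs,paramsTrue,seed see slot descriptions.
#' @rdname Experiment-class
#' @export
Experiment <- function(epochs, paramsTrue = NULL, seed = NA_integer_) {
  new("Experiment", epochs = epochs, paramsTrue = paramsTrue,
      seed = as.integer(seed))
}

#' A sampled postsynaptic current trace around one presynaptic stimulus
#'
#' Uniformly sampled current (pA, negative = inward) with the presynaptic
#' stimulus time as the latency reference.
#'
#' @slot time numeric, ms, uniform grid.
#' @slot current numeric, pA.
#' @slot stimulusTime numeric, ms, within the time range.
#' @slot samplingKhz numeric, sampling rate in kHz.
#' @export
setClass("EPSCTrace",
  slots = c(
    time = "numeric",
    current = "numeric",
    stimulusTime = "numeric",
    samplingKhz = "numeric"
  )
)

setValidity("EPSCTrace", function(object) {
  msg <- character(0)
  n <- length(object@time)
  if (n < 2L)
    msg <- c(msg, "trace needs at least two samples")
  if (length(object@current) != n)
    msg <- c(msg, "time and current must have equal length")
  if (n >= 2L) {
    dt <- diff(object@time)
    if (any(abs(dt - dt[1]) > 1e-6 * dt[1]))
      msg <- c(msg, "time grid must be uniform")
  }
  st <- object@stimulusTime
  if (length(st) != 1L || st < object@time[1] || st > object@time[n])
    msg <- c(msg, "stimulusTime must lie within the time range")
  if (length(msg)) msg else TRUE
})

#' @param time,current,stimulusTime,samplingKhz see slot descriptions;
#'   `samplingKhz` defaults to the reciprocal of the grid step.
#' @rdname EPSCTrace-class
#' @export
EPSCTrace <- function(time, current, stimulusTime,
                      samplingKhz = 1 / diff(time[1:2])) {
  new("EPSCTrace", time = as.numeric(time), current = as.numeric(current),
      stimulusTime = as.numeric(stimulusTime),
      samplingKhz = as.numeric(samplingKhz))
}

#' A detected (or failed) evoked EPSC with kinetic measurements
#'
#' Amplitude is stored as a positive magnitude. Failure events (no deflection
#' beyond threshold within the detection limits) carry no kinetics; all
#' measurement slots are NA and `flags` records why.
#'
#' @slot onsetMs numeric, onset time (back-projection of the 10-90\% rise
#'   slope line to baseline), ms.
#' @slot peakMs numeric, peak time, ms.
#' @slot amplitudePa numeric, peak amplitude magnitude, pA.
#' @slot latencyMs numeric, onset minus stimulus time, ms.
#' @slot rise1090Ms numeric, 10-90\% rise time, ms.
#' @slot decay37Ms numeric, time from peak to 37\% of peak, ms.
#' @slot chargeFc numeric, integrated charge, fC.
#' @slot isFailure logical.
#' @slot flags character, diagnostic flags (e.g. "onset_limit",
#'   "right_censored").
#' @export
setClass("EPSCEvent",
  slots = c(
    onsetMs = "numeric",
    peakMs = "numeric",
    amplitudePa = "numeric",
    latencyMs = "numeric",
    rise1090Ms = "numeric",
    decay37Ms = "numeric",
    chargeFc = "numeric",
    isFailure = "logical",
    flags = "character"
  ),
  prototype = prototype(
    onsetMs = NA_real_, peakMs = NA_real_, amplitudePa = NA_real_,
    latencyMs = NA_real_, rise1090Ms = NA_real_, decay37Ms = NA_real_,
    chargeFc = NA_real_, isFailure = FALSE, flags = character(0)
  )
)

setValidity("EPSCEvent", function(object) {
  msg <- character(0)
  if (!object@isFailure) {
    if (!is.na(object@onsetMs) && !is.na(object@peakMs) &&
        object@onsetMs > object@peakMs)
      msg <- c(msg, "onset must not follow the peak")
    kin <- c(object@amplitudePa, object@rise1090Ms, object@decay37Ms)
    if (any(!is.na(kin) & kin < 0))
      msg <- c(msg, "kinetic measurements must be >= 0")
  } else {
    if (!all(is.na(c(object@amplitudePa, object@rise1090Ms,
                     object@decay37Ms, object@latencyMs))))
      msg <- c(msg, "failure events must carry no kinetics")
  }
  if (length(msg)) msg else TRUE
})

#' Result of a variance-mean parabola fit (MPFA)
#'
#' Estimates from the weighted fit of \eqn{\sigma^2 = A \bar{I} - B \bar{I}^2}
#' to per-epoch (mean, pairwise variance) points: quantal size \eqn{q = A},
#' number of functional release sites \eqn{N_{frs} = 1/B}, and per-condition
#' release probability \eqn{P_r = \bar{I} / (N_{frs} q)}.
#'
#' @slot qFc numeric, estimated quantal size, fC.
#' @slot nFrs numeric, estimated number of functional release sites
#'   (positive real, never rounded; NA when the fit shows no curvature).
#' @slot pR named numeric, per-condition release probability estimates.
#' @slot A,B numeric, parabola coefficients.
#' @slot se named numeric, standard errors for A, B, q and nFrs.
#' @slot points data.frame of variance-mean points used in the fit.
#' @slot nIterations integer, reweighting iterations performed.
#' @slot converged logical.
#' @slot warnings character, diagnostic messages (clipping, no curvature...).
#' @seealso [fitParabola()]
#' @export
setClass("MPFAFit",
  slots = c(
    qFc = "numeric",
    nFrs = "numeric",
    pR = "numeric",
    A = "numeric",
    B = "numeric",
    se = "numeric",
    points = "data.frame",
    nIterations = "integer",
    converged = "logical",
    warnings = "character"
  )
)

#' A presynaptic active zone with classified vesicles
#'
#' An active-zone (AZ) membrane area plus the scalar membrane-gap distances of
#' its synaptic vesicles (outer vesicle leaflet to inner plasma-membrane
#' leaflet, nm), with class labels assigned by [classifyVesicle()].
#'
#' @slot azId character identifier.
#' @slot areaUm2 numeric, AZ area in square micrometres, > 0.
#' @slot distances numeric, vesicle membrane distances in nm, >= 0.
#' @slot labels character, one of "docked", "pre_docked", "pool", "outside"
#'   per vesicle.
#' @export
setClass("ActiveZone",
  slots = c(
    azId = "character",
    areaUm2 = "numeric",
    distances = "numeric",
    labels = "character"
  )
)

setValidity("ActiveZone", function(object) {
  msg <- character(0)
  if (length(object@areaUm2) != 1L || !is.finite(object@areaUm2) ||
      object@areaUm2 <= 0)
    msg <- c(msg, "areaUm2 must be a single positive number")
  if (any(object@distances < 0))
    msg <- c(msg, "vesicle distances must be >= 0")
  if (length(object@labels) != length(object@distances))
    msg <- c(msg, "labels and distances must have equal length")
  if (!all(object@labels %in% c("docked", "pre_docked", "pool", "outside")))
    msg <- c(msg, "unknown vesicle label")
  if (length(msg)) msg else TRUE
})

#' @param azId,areaUm2 see slot descriptions.
#' @param distanceNm numeric vector of vesicle membrane distances, nm.
#' @param contactToleranceNm,predockedMaxNm,poolRadiusNm classification bounds
#'   passed to [classifyVesicle()].
#' @rdname ActiveZone-class
#' @export
ActiveZone <- function(azId, areaUm2, distanceNm = numeric(0),
                       contactToleranceNm = 0.5, predockedMaxNm = 5,
                       poolRadiusNm = 100) {
  new("ActiveZone", azId = as.character(azId), areaUm2 = as.numeric(areaUm2),
      distances = as.numeric(distanceNm),
      labels = classifyVesicle(distanceNm, contactToleranceNm,
                               predockedMaxNm, poolRadiusNm))
}

#' Published or computed cohort-level summary for one species
#'
#' Cohort means used by the derived cross-species metrics: mean number of
#' functional release sites per connection (N_frs, from MPFA), mean number of
#' light-microscopically detected synaptic contacts per connection (N_lm),
#' mean AZ area, and mean docked-vesicle count per AZ.
#'
#' @slot species character, e.g. "human" or "rat".
#' @slot meanNfrs,meanNlm,meanAzAreaUm2,meanDockedPerAz numeric, all > 0.
#' @export
setClass("CohortSummary",
  slots = c(
    species = "character",
    meanNfrs = "numeric",
    meanNlm = "numeric",
    meanAzAreaUm2 = "numeric",
    meanDockedPerAz = "numeric"
  )
)

setValidity("CohortSummary", function(object) {
  vals <- c(object@meanNfrs, object@meanNlm, object@meanAzAreaUm2,
            object@meanDockedPerAz)
  if (any(!is.finite(vals)) || any(vals <= 0))
    "all cohort means must be positive" else TRUE
})

#' @param species,meanNfrs,meanNlm,meanAzAreaUm2,meanDockedPerAz see slots.
#' @rdname CohortSummary-class
#' @export
CohortSummary <- function(species, meanNfrs, meanNlm, meanAzAreaUm2,
                          meanDockedPerAz) {
  new("CohortSummary", species = as.character(species),
      meanNfrs = as.numeric(meanNfrs), meanNlm = as.numeric(meanNlm),
      meanAzAreaUm2 = as.numeric(meanAzAreaUm2),
      meanDockedPerAz = as.numeric(meanDockedPerAz))
}

#' Derived cross-species release-site metrics for one cohort
#'
#' Headline quantities computed from cohort means: functional release sites
#' per AZ (mean N_frs / mean N_lm), AZ membrane area per release site, and
#' docking-site occupancy (mean docked vesicles per AZ / release sites per
#' AZ). All slots keep full precision; presentation rounding happens only in
#' the show method. Occupancy above 1 is reported with a note, never clamped.
#'
#' @slot species character.
#' @slot sitesPerAz numeric.
#' @slot areaPerSiteUm2 numeric.
#' @slot occupancy numeric.
#' @slot nFrsFold numeric, fold change of mean N_frs vs a reference cohort
#'   (NA if no reference supplied).
#' @slot notes character.
#' @seealso [derivedReport()]
#' @export
setClass("DerivedReport",
  slots = c(
    species = "character",
    sitesPerAz = "numeric",
    areaPerSiteUm2 = "numeric",
    occupancy = "numeric",
    nFrsFold = "numeric",
    notes = "character"
  )
)
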