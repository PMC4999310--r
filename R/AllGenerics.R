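#' Accessor generics
#'
#' Small accessor family so downstream code never touches slots directly.
#'
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("quantalSize", function(x) standardGeneric("quantalSize"))

#' @rdname accessors
#' @export
setGeneric("releaseSites", function(x) standardGeneric("releaseSites"))

#' @rdname accessors
#' @export
setGeneric("releaseProb", function(x) standardGeneric("releaseProb"))

#' @rdname accessors
#' @export
setGeneric("epochs", function(x) standardGeneric("epochs"))

#' @rdname accessors
#' @export
setGeneric("epochLabels", function(x) standardGeneric("epochLabels"))

#' @rdname accessors
#' @export
setGeneric("charges", function(x) standardGeneric("charges"))

#' @rdname accessors
#' @export
setGeneric("trialTimes", function(x) standardGeneric("trialTimes"))

#' @rdname accessors
#' @export
setGeneric("trueParams", function(x) standardGeneric("trueParams"))

#' @rdname accessors
#' @export
setGeneric("azArea", function(x) standardGeneric("azArea"))

#' @rdname accessors
#' @export
setGeneric("vesicleDistances", function(x) standardGeneric("vesicleDistances"))

#' @rdname accessors
#' @export
setGeneric("vesicleLabels", function(x) standardGeneric("vesicleLabels"))

#' @rdname accessors
#' @export
setGeneric("dockedCount", function(x) standardGeneric("dockedCount"))

#' @rdname accessors
#' @export
setGeneric("isFailure", function(x) standardGeneric("isFailure"))

#' @rdname accessors
setMethod("quantalSize", "QuantalParameters", function(x) x@q)

#' @rdname accessors
setMethod("quantalSize", "MPFAFit", function(x) x@qFc)

#' @rdname accessors
setMethod("releaseSites", "QuantalParameters", function(x) x@nSites)

#' @rdname accessors
setMethod("releaseSites", "MPFAFit", function(x) x@nFrs)

#' @rdname accessors
setMethod("releaseProb", "Epoch", function(x) x@pR)

#' @rdname accessors
setMethod("releaseProb", "MPFAFit", function(x) x@pR)

#' @rdname accessors
setMethod("epochs", "Experiment", function(x) x@epochs)

#' @rdname accessors
setMethod("epochLabels", "Experiment",
          function(x) vapply(x@epochs, function(e) e@label, character(1)))

#' @rdname accessors
setMethod("charges", "Epoch", function(x) x@charges)

#' @rdname accessors
setMethod("trialTimes", "Epoch", function(x) x@trialTimes)

#' @rdname accessors
setMethod("trueParams", "Experiment", function(x) x@paramsTrue)

#' @rdname accessors
setMethod("azArea", "ActiveZone", function(x) x@areaUm2)

#' @rdname accessors
setMethod("vesicleDistances", "ActiveZone", function(x) x@distances)

#' @rdname accessors
setMethod("vesicleLabels", "ActiveZone", function(x) x@labels)

#' @rdname accessors
setMethod("dockedCount", "ActiveZone",
          function(x) sum(x@labels == "docked"))

#' @rdname accessors
setMethod("isFailure", "EPSCEvent", function(x) x@isFailure)

setMethod("show", "QuantalParameters", function(object) {
  cat("QuantalParameters: N =", object@nSites,
      "| q =", format(object@q), "fC\n")
  cat("  cvIntra =", object@cvIntra, "| cvInter =", object@cvInter,
      "| noiseSd =", object@noiseSd, "fC | drift/epoch =",
      object@driftPerEpoch, "\n")
})

setMethod("show", "Epoch", function(object) {
  cat(sprintf("Epoch '%s': %d trials", object@label, length(object@charges)))
  if (!is.na(object@caMM)) cat(sprintf(", %.3g mM [Ca2+]o", object@caMM))
  if (!is.na(object@pR)) cat(sprintf(", Pr = %.3g", object@pR))
  if (length(object@charges))
    cat(sprintf(" | mean charge %.4g fC", mean(object@charges)))
  cat("\n")
})

setMethod("show", "Experiment", function(object) {
  cat("Experiment with", length(object@epochs), "epochs:\n")
  for (e in object@epochs) show(e)
  if (!is.null(object@paramsTrue)) {
    cat("True generative parameters:\n")
    show(object@paramsTrue)
  }
})

setMethod("show", "EPSCTrace", function(object) {
  cat(sprintf(
    "EPSCTrace: %d samples @ %.4g kHz, %.4g-%.4g ms, stimulus at %.4g ms\n",
    length(object@time), object@samplingKhz, object@time[1],
    object@time[length(object@time)], object@stimulusTime))
})

setMethod("show", "EPSCEvent", function(object) {
  if (object@isFailure) {
    cat("EPSCEvent: failure",
        if (length(object@flags)) paste0("(", paste(object@flags,
                                                    collapse = ", "), ")"),
        "\n")
  } else {
    cat(sprintf("EPSCEvent: amplitude %.4g pA, onset %.4g ms\n",
                object@amplitudePa, object@onsetMs))
    cat(sprintf("  latency %.4g ms | rise(10-90%%) %.4g ms | decay(37%%) %.4g ms | charge %.4g fC\n",
                object@latencyMs, object@rise1090Ms, object@decay37Ms,
                object@chargeFc))
  }
})

setMethod("show", "MPFAFit", function(object) {
  cat("MPFA variance-mean parabola fit\n")
  if (is.na(object@nFrs)) {
    cat("  no curvature: N_frs undetermined; q (initial slope) =",
        format(object@qFc), "fC\n")
  } else {
    cat(sprintf("  q = %.4g fC (SE %.3g) | N_frs = %.4g (SE %.3g)\n",
                object@qFc, object@se[["q"]], object@nFrs,
                object@se[["nFrs"]]))
    cat("  P_r by condition:",
        paste(sprintf("%s=%.3g", names(object@pR), object@pR),
              collapse = ", "), "\n")
  }
  cat("  ", nrow(object@points), "variance-mean points, ",
      object@nIterations, "reweighting iterations\n")
  if (length(object@warnings))
    cat("  warnings:", paste(object@warnings, collapse = "; "), "\n")
})

setMethod("show", "ActiveZone", function(object) {
  tab <- table(factor(object@labels,
                      levels = c("docked", "pre_docked", "pool", "outside")))
  cat(sprintf("ActiveZone '%s': area %.4g um^2, %d vesicles\n",
              object@azId, object@areaUm2, length(object@distances)))
  cat("  ", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                  collapse = ", "), "\n")
})

setMethod("show", "CohortSummary", function(object) {
  cat(sprintf("CohortSummary (%s): N_frs %.4g | N_lm %.4g | AZ area %.4g um^2 | docked/AZ %.4g\n",
              object@species, object@meanNfrs, object@meanNlm,
              object@meanAzAreaUm2, object@meanDockedPerAz))
})

setMethod("show", "DerivedReport", function(object) {
  cat(sprintf("DerivedReport (%s)\n", object@species))
  cat(sprintf("  release sites per AZ: %.1f   (%.6g)\n",
              object@sitesPerAz, object@sitesPerAz))
  cat(sprintf("  AZ area per release site: %.3f um^2   (%.6g)\n",
              object@areaPerSiteUm2, object@areaPerSiteUm2))
  cat(sprintf("  docking-site occupancy: %.1f   (%.6g)\n",
              object@occupancy, object@occupancy))
  if (!is.na(object@nFrsFold))
    cat(sprintf("  N_frs fold vs reference: %.1f   (%.6g)\n",
                object@nFrsFold, object@nFrsFold))
  for (nt in object@notes) cat("  note:", nt, "\n")
})
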