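# Cross-species derived metrics computed from cohort means. Ratios are
# computed at full precision; presentation rounding (one decimal / two
# significant figures) happens only when a report is printed.

#' Functional release sites per active zone
#'
#' Mean number of functional release sites per connection (MPFA) divided by
#' the mean number of light-microscopically detected synaptic contacts per
#' connection. Since each bouton contains a single AZ, this is the average
#' number of release sites per AZ.
#'
#' @param meanNfrs mean N_frs, > 0.
#' @param meanNlm mean N_lm, > 0.
#' @return the ratio at full precision.
#' @examples
#' sitesPerAZ(20.5, 3.3)  # 6.21 -> presented as 6.2
#' @export
sitesPerAZ <- function(meanNfrs, meanNlm) {
  if (any(meanNlm <= 0)) stop("meanNlm must be > 0")
  if (any(meanNfrs <= 0)) stop("meanNfrs must be > 0")
  meanNfrs / meanNlm
}

#' Active-zone membrane area per functional release site
#'
#' @param meanAzAreaUm2 mean AZ area, um^2, >= 0.
#' @param sitesPerAz release sites per AZ, > 0.
#' @return um^2 per release site.
#' @examples
#' areaPerSite(0.077, sitesPerAZ(20.5, 3.3))  # ~0.012 um^2
#' @export
areaPerSite <- function(meanAzAreaUm2, sitesPerAz) {
  if (any(sitesPerAz <= 0)) stop("sitesPerAz must be > 0")
  if (any(meanAzAreaUm2 < 0)) stop("meanAzAreaUm2 must be >= 0")
  meanAzAreaUm2 / sitesPerAz
}

#' Docking-site occupancy
#'
#' Mean number of docked vesicles per AZ divided by the number of functional
#' release sites per AZ. An estimate ratio, not a probability: values above
#' 1 are reported as-is (the caller may attach a note), never clamped.
#'
#' @param meanDockedPerAz mean docked vesicles per AZ, > 0.
#' @param sitesPerAz release sites per AZ, > 0.
#' @return the occupancy ratio.
#' @examples
#' dockingOccupancy(1.3, sitesPerAZ(4.7, 2.9))  # ~0.8
#' @export
dockingOccupancy <- function(meanDockedPerAz, sitesPerAz) {
  if (any(sitesPerAz <= 0)) stop("sitesPerAz must be > 0")
  if (any(meanDockedPerAz <= 0)) stop("meanDockedPerAz must be > 0")
  meanDockedPerAz / sitesPerAz
}

#' Fold change of two cohort means
#'
#' @param numeratorMean,denominatorMean cohort means; denominator > 0.
#' @return the quotient.
#' @examples
#' foldChange(20.5, 4.7)  # 4.4-fold larger N_frs
#' @export
foldChange <- function(numeratorMean, denominatorMean) {
  if (any(denominatorMean <= 0)) stop("denominator mean must be > 0")
  numeratorMean / denominatorMean
}

#' Convert rat postnatal age to equivalent human years
#'
#' Linear map anchored at sexual maturity (rat P38 corresponds to 12 human
#' years) with 3.3 rat days per human year:
#' \deqn{years = 12 + (day - 38) / 3.3.}
#'
#' @param postnatalDay rat postnatal day, > 0 (vectorized).
#' @return equivalent human age in years.
#' @examples
#' ratToHumanAge(c(18, 38, 65))  # ~6, 12, ~20 years
#' @export
ratToHumanAge <- function(postnatalDay) {
  if (any(postnatalDay <= 0)) stop("postnatal day must be > 0")
  12 + (postnatalDay - 38) / 3.3
}

#' Inverse of [ratToHumanAge()]
#'
#' @param humanYears human age in years.
#' @return rat postnatal day.
#' @export
humanAgeToRatDay <- function(humanYears) {
  38 + 3.3 * (humanYears - 12)
}

#' Compute the derived cross-species metrics for a cohort
#'
#' Combines [sitesPerAZ()], [areaPerSite()] and [dockingOccupancy()] on a
#' [CohortSummary-class]; if a reference cohort is supplied, the N_frs fold
#' change versus that reference is included.
#'
#' @param cohort a [CohortSummary-class].
#' @param reference optional [CohortSummary-class] used as the fold-change
#'   denominator.
#' @return a [DerivedReport-class].
#' @examples
#' hu <- CohortSummary("human", 20.5, 3.3, 0.077, 4.2)
#' rt <- CohortSummary("rat", 4.7, 2.9, 0.041, 1.3)
#' derivedReport(hu, reference = rt)
#' @export
derivedReport <- function(cohort, reference = NULL) {
  stopifnot(is(cohort, "CohortSummary"))
  spa <- sitesPerAZ(cohort@meanNfrs, cohort@meanNlm)
  occ <- dockingOccupancy(cohort@meanDockedPerAz, spa)
  notes <- character(0)
  if (occ > 1)
    notes <- c(notes, "occupancy exceeds 1 (estimate ratio, not clamped)")
  fold <- NA_real_
  if (!is.null(reference)) {
    stopifnot(is(reference, "CohortSummary"))
    fold <- foldChange(cohort@meanNfrs, reference@meanNfrs)
  }
  new("DerivedReport", species = cohort@species, sitesPerAz = spa,
      areaPerSiteUm2 = areaPerSite(cohort@meanAzAreaUm2, spa),
      occupancy = occ, nFrsFold = fold, notes = notes)
}
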