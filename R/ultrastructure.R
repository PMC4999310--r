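# Electron-tomographic vesicle classification and active-zone geometry.

#' Classify vesicles by membrane distance
#'
#' Assigns each vesicle to exactly one class from its scalar membrane-gap
#' distance (outer vesicle leaflet to inner presynaptic membrane leaflet):
#' \itemize{
#'   \item docked: direct membrane contact, operationalized as distance
#'     \eqn{\le} \code{contactToleranceNm} (0.5 nm absorbs measurement
#'     quantization);
#'   \item pre_docked: within \code{predockedMaxNm} (5 nm) of the membrane
#'     without contact;
#'   \item pool: within \code{poolRadiusNm} (100 nm) of the AZ;
#'   \item outside: farther than the pool radius.
#' }
#' Membrane-proximal vesicles are docked plus pre-docked. All class bounds
#' are closed on the upper end ("did not exceed 5 nm"), so boundary values
#' fall into the inner class deterministically.
#'
#' @param distanceNm numeric vector of distances, nm, >= 0.
#' @param contactToleranceNm,predockedMaxNm,poolRadiusNm class bounds, nm.
#' @return character vector of labels.
#' @examples
#' classifyVesicle(c(0, 4, 50, 150))
#' @export
classifyVesicle <- function(distanceNm, contactToleranceNm = 0.5,
                            predockedMaxNm = 5, poolRadiusNm = 100) {
  distanceNm <- as.numeric(distanceNm)
  if (any(distanceNm < 0, na.rm = TRUE))
    stop("vesicle distances must be >= 0")
  as.character(ifelse(distanceNm <= contactToleranceNm, "docked",
    ifelse(distanceNm <= predockedMaxNm, "pre_docked",
      ifelse(distanceNm <= poolRadiusNm, "pool", "outside"))))
}

#' Docked-vesicle density of an active zone
#'
#' Number of docked vesicles divided by the AZ area.
#'
#' @param az an [ActiveZone-class] with classified vesicles.
#' @return density per um^2.
#' @examples
#' az <- generateActiveZone(0.09, nDocked = 4, seed = 1)
#' dockedDensity(az)  # 44.4 per um^2
#' @export
dockedDensity <- function(az) {
  stopifnot(is(az, "ActiveZone"))
  if (az@areaUm2 <= 0) stop("AZ area must be > 0")
  sum(az@labels == "docked") / az@areaUm2
}

#' Proximal vesicle pool normalized to AZ area
#'
#' Count of vesicles within the pool radius (default 100 nm, i.e. docked,
#' pre-docked and pool classes) divided by the AZ area.
#'
#' @param az an [ActiveZone-class].
#' @param poolRadiusNm pool radius, nm.
#' @return vesicles per um^2.
#' @export
proximalPoolNormalized <- function(az, poolRadiusNm = 100) {
  stopifnot(is(az, "ActiveZone"))
  if (az@areaUm2 <= 0) stop("AZ area must be > 0")
  sum(az@distances <= poolRadiusNm) / az@areaUm2
}

#' Bouton volume from its largest cross-section, assuming a sphere
#'
#' The largest cross-section of a sphere is its equatorial disc, so
#' \eqn{r = \sqrt{area/\pi}} and
#' \eqn{V = (4/3)\pi r^3 = \frac{4}{3\sqrt{\pi}} \, area^{3/2}}.
#'
#' @param largestCrossSectionUm2 numeric, um^2, >= 0 (vectorized).
#' @return volume(s) in um^3.
#' @examples
#' boutonVolumeSphere(pi * 0.2^2)  # sphere of radius 0.2 um: 0.03351 um^3
#' @export
boutonVolumeSphere <- function(largestCrossSectionUm2) {
  if (any(largestCrossSectionUm2 < 0))
    stop("cross-section area must be >= 0")
  4 / (3 * sqrt(pi)) * largestCrossSectionUm2^1.5
}

#' Per-AZ and cohort summary of active-zone ultrastructure
#'
#' Builds a per-AZ table (area, class counts, docked density, proximal pool
#' density) and cohort statistics (means, SDs, and the Spearman rank
#' correlation of docked count with AZ area). With a single AZ the SDs and
#' the correlation are undefined and flagged NA.
#'
#' @param azs list of [ActiveZone-class] objects.
#' @return list with `perAZ` (data.frame) and `cohort` (list of means, SDs
#'   and `spearman_docked_area`).
#' @export
azSummary <- function(azs) {
  if (is(azs, "ActiveZone")) azs <- list(azs)
  if (!length(azs)) stop("at least one active zone required")
  stopifnot(all(vapply(azs, is, logical(1), class2 = "ActiveZone")))
  perAZ <- do.call(rbind, lapply(azs, function(az) {
    data.frame(
      az_id = az@azId,
      area_um2 = az@areaUm2,
      n_docked = sum(az@labels == "docked"),
      n_predocked = sum(az@labels == "pre_docked"),
      n_pool = sum(az@labels == "pool"),
      n_outside = sum(az@labels == "outside"),
      docked_density = dockedDensity(az),
      proximal_pool_density = proximalPoolNormalized(az),
      stringsAsFactors = FALSE)
  }))
  rownames(perAZ) <- NULL
  one <- nrow(perAZ) < 2L
  rho <- if (one) NA_real_ else
    suppressWarnings(stats::cor(perAZ$n_docked, perAZ$area_um2,
                                method = "spearman"))
  cohort <- list(
    n_az = nrow(perAZ),
    mean_area_um2 = mean(perAZ$area_um2),
    sd_area_um2 = if (one) NA_real_ else stats::sd(perAZ$area_um2),
    mean_docked = mean(perAZ$n_docked),
    sd_docked = if (one) NA_real_ else stats::sd(perAZ$n_docked),
    mean_docked_density = mean(perAZ$docked_density),
    mean_proximal_pool_density = mean(perAZ$proximal_pool_density),
    spearman_docked_area = rho
  )
  list(perAZ = perAZ, cohort = cohort)
}
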