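# Plain-text interchange: trial tables, vesicle tables, traces with a JSON
# sidecar, cohort summaries and fit reports.

#' Convert an experiment to the trial-table layout
#'
#' Columns: experiment_id, epoch_label, ca_mM, trial_index, time_s,
#' charge_fC.
#'
#' @param experiment an [Experiment-class].
#' @param experimentId identifier written into the table.
#' @return data.frame in trial-table layout.
#' @export
experimentToTable <- function(experiment, experimentId = "exp1") {
  stopifnot(is(experiment, "Experiment"))
  do.call(rbind, lapply(experiment@epochs, function(e) {
    data.frame(experiment_id = experimentId, epoch_label = e@label,
               ca_mM = e@caMM, trial_index = seq_along(e@charges),
               time_s = e@trialTimes, charge_fC = e@charges,
               stringsAsFactors = FALSE)
  }))
}

#' @rdname experimentToTable
#' @param path CSV file path.
#' @export
writeTrialTable <- function(experiment, path, experimentId = "exp1") {
  df <- if (is.data.frame(experiment)) experiment
        else experimentToTable(experiment, experimentId)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a trial-table CSV into experiments
#'
#' @param path CSV with columns experiment_id, epoch_label, ca_mM,
#'   trial_index, time_s, charge_fC.
#' @return named list of [Experiment-class], one per experiment_id. Release
#'   probabilities are unknown for recorded data and set NA.
#' @export
readTrialTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("experiment_id", "epoch_label", "ca_mM", "trial_index",
           "time_s", "charge_fC")
  if (!all(req %in% names(df)))
    stop("trial table must have columns ", paste(req, collapse = ", "))
  out <- lapply(split(df, df$experiment_id), function(d) {
    eps <- lapply(split(d, d$epoch_label), function(e) {
      e <- e[order(e$trial_index), ]
      Epoch(label = e$epoch_label[1], caMM = e$ca_mM[1],
            charges = e$charge_fC, trialTimes = e$time_s)
    })
    # keep epochs ordered by calcium (acquisition order low -> high)
    eps <- eps[order(vapply(eps, function(e) e@caMM, numeric(1)))]
    Experiment(epochs = unname(eps))
  })
  out
}

#' Write / read a vesicle table
#'
#' CSV columns: az_id, area_um2, vesicle_id, distance_nm. Vesicle-free AZs
#' are written with a single row with an empty vesicle_id and NA distance.
#'
#' @param azs list of [ActiveZone-class] objects.
#' @param path CSV file path.
#' @return `writeVesicleTable()` the path, invisibly; `readVesicleTable()`
#'   a list of [ActiveZone-class].
#' @export
writeVesicleTable <- function(azs, path) {
  if (is(azs, "ActiveZone")) azs <- list(azs)
  df <- do.call(rbind, lapply(azs, function(az) {
    nv <- length(az@distances)
    if (nv == 0L)
      data.frame(az_id = az@azId, area_um2 = az@areaUm2,
                 vesicle_id = NA_character_, distance_nm = NA_real_,
                 stringsAsFactors = FALSE)
    else
      data.frame(az_id = az@azId, area_um2 = az@areaUm2,
                 vesicle_id = paste0(az@azId, "_v", seq_len(nv)),
                 distance_nm = az@distances, stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeVesicleTable
#' @export
readVesicleTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("az_id", "area_um2", "distance_nm")
  if (!all(req %in% names(df)))
    stop("vesicle table must have columns ", paste(req, collapse = ", "))
  lapply(split(df, df$az_id), function(d) {
    ActiveZone(azId = d$az_id[1], areaUm2 = d$area_um2[1],
               distanceNm = d$distance_nm[!is.na(d$distance_nm)])
  })
}

#' Write / read a current trace as CSV plus JSON sidecar
#'
#' The CSV holds time_ms and current_pA; the sidecar holds
#' \{stimulus_time_ms, sampling_khz\}.
#'
#' @param trace an [EPSCTrace-class].
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `writeTraceCSV()` the path, invisibly; `readTraceCSV()` an
#'   [EPSCTrace-class].
#' @export
writeTraceCSV <- function(trace, path) {
  stopifnot(is(trace, "EPSCTrace"))
  utils::write.csv(data.frame(time_ms = trace@time,
                              current_pA = trace@current),
                   path, row.names = FALSE)
  jsonlite::write_json(list(stimulus_time_ms = trace@stimulusTime,
                            sampling_khz = trace@samplingKhz),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeTraceCSV
#' @export
readTraceCSV <- function(path) {
  df <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  EPSCTrace(time = df$time_ms, current = df$current_pA,
            stimulusTime = side$stimulus_time_ms,
            samplingKhz = side$sampling_khz)
}

#' Write an MPFA fit report as JSON
#'
#' @param fit an [MPFAFit-class].
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
writeFitReport <- function(fit, path) {
  stopifnot(is(fit, "MPFAFit"))
  jsonlite::write_json(list(
    q_fC = fit@qFc, n_frs = fit@nFrs, A = fit@A, B = fit@B,
    p_r_by_condition = as.list(fit@pR), se = as.list(fit@se),
    n_iterations = fit@nIterations, converged = fit@converged,
    warnings = fit@warnings), path, auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(path)
}

#' Read a cohort summary from JSON
#'
#' Expects keys species, mean_n_frs, mean_n_lm, mean_az_area_um2,
#' mean_docked_per_az (the layout of the files under
#' `system.file("extdata", package = "synquant")`).
#'
#' @param path JSON path.
#' @return a [CohortSummary-class].
#' @export
readCohortSummary <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  CohortSummary(species = x$species, meanNfrs = x$mean_n_frs,
                meanNlm = x$mean_n_lm, meanAzAreaUm2 = x$mean_az_area_um2,
                meanDockedPerAz = x$mean_docked_per_az)
}
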