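# Multiple-probability fluctuation analysis: weighted parabola fit of
# per-condition pairwise variance against mean EPSC charge.

#' Pairwise (consecutive-difference) variance
#'
#' Drift-robust variance estimator built from squared differences of
#' consecutive trials in acquisition order:
#' \deqn{s^2_{pw} = \sum_{i=1}^{n-1} (x_{i+1} - x_i)^2 / (2(n-1)).}
#' For iid data it is unbiased for the ordinary variance; for a pure linear
#' ramp \eqn{x_i = a + b i} it equals \eqn{b^2/2} independent of n, which is
#' what removes slow temporal drift from MPFA variance estimates.
#'
#' @param x numeric vector in acquisition order, length >= 2.
#' @return the pairwise variance.
#' @examples
#' pairwiseVariance(c(1, 3, 1, 3))  # 2
#' @export
pairwiseVariance <- function(x) {
  n <- length(x)
  if (n < 2L) stop("pairwise variance needs at least 2 trials")
  sum(diff(x)^2) / (2 * (n - 1))
}

#' Theoretical variance of a sample variance
#'
#' Gaussian-approximation weighting formula
#' \eqn{Var(s^2) = 2 \sigma^4 / (n - 1)}, used as the reciprocal weight of
#' each variance-mean point.
#'
#' @param variance the (estimated or predicted) variance, fC^2.
#' @param n number of trials, >= 2.
#' @return variance of the variance estimate, fC^4.
#' @export
varianceOfVariance <- function(variance, n) {
  if (any(n < 2L)) stop("n must be >= 2")
  2 * variance^2 / (n - 1)
}

#' Build variance-mean points from an experiment
#'
#' One point per epoch: mean charge, pairwise variance, trial count and
#' weight (reciprocal of the theoretical variance of variance). Epochs are
#' checked for stability ([epochStability()]); unstable epochs are excluded
#' with a warning unless \code{requireStability = FALSE}, in which case they
#' are kept with a logged warning. Fewer than three eligible epochs is an
#' error (MPFA requires at least three conditions). Zero-variance epochs give
#' infinite weight and are flagged degenerate; [fitParabola()] falls back to
#' equal weights when any point is degenerate.
#'
#' @param experiment an [Experiment-class].
#' @param requireStability drop unstable epochs (TRUE) or keep them with a
#'   warning (FALSE).
#' @return data.frame with columns `label`, `mean_fC`, `var_fC2`, `n`,
#'   `weight`, `degenerate`.
#' @export
varianceMeanPoints <- function(experiment, requireStability = TRUE) {
  stopifnot(is(experiment, "Experiment"))
  rows <- lapply(experiment@epochs, function(e) {
    n <- length(e@charges)
    if (n < 10L) {
      warning("epoch '", e@label, "' has fewer than 10 trials; excluded")
      return(NULL)
    }
    st <- epochStability(e@charges, e@trialTimes)
    if (!st$pass) {
      if (requireStability) {
        warning("epoch '", e@label, "' fails stability (slope ",
                signif(st$slope, 3), "); excluded")
        return(NULL)
      }
      warning("epoch '", e@label, "' fails stability (slope ",
              signif(st$slope, 3), "); kept on caller override")
    }
    v <- pairwiseVariance(e@charges)
    vv <- varianceOfVariance(v, n)
    data.frame(label = e@label, mean_fC = mean(e@charges), var_fC2 = v,
               n = n, weight = if (vv > 0) 1 / vv else Inf,
               degenerate = vv == 0, stringsAsFactors = FALSE)
  })
  pts <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(pts) || nrow(pts) < 3L)
    stop("MPFA requires >= 3 conditions (eligible epochs), got ",
         if (is.null(pts)) 0L else nrow(pts))
  rownames(pts) <- NULL
  pts
}

#' Fit the variance-mean parabola (MPFA)
#'
#' Weighted least-squares fit of \eqn{\sigma^2 = A \bar{I} - B \bar{I}^2}
#' (no intercept by default) to variance-mean points, with optional iterative
#' reweighting: after each fit the weights are recomputed from the parabola's
#' predicted variances via [varianceOfVariance()] until the relative change
#' in (A, B) drops below \code{tol} or \code{maxIter} iterations. Quantal
#' parameters follow as \eqn{q = A}, \eqn{N_{frs} = 1/B} and per-condition
#' \eqn{P_r = \bar{I}/(N_{frs} q)}, clipped to [0, 1] with a warning if
#' clipping occurs. \eqn{N_{frs}} is reported as a positive real, never
#' rounded.
#'
#' If the fitted curvature is not positive (B <= 0, or negligible relative to
#' the linear term) the release probabilities are too low to constrain N: a
#' "no curvature" warning is raised, \code{q} is taken from the initial
#' weighted slope and \code{nFrs} is NA.
#'
#' @param points data.frame from [varianceMeanPoints()] (columns `mean_fC`,
#'   `var_fC2`, `n`, `weight`; optional `label`, `degenerate`).
#' @param reweight iterate weights from the fitted parabola (default TRUE).
#' @param intercept add a fitted intercept (baseline-noise variance) instead
#'   of forcing the parabola through the origin.
#' @param tol relative parameter-change convergence tolerance.
#' @param maxIter maximum reweighting iterations.
#' @return an [MPFAFit-class].
#' @examples
#' p <- QuantalParameters(nSites = 20, q = 40)
#' pts <- data.frame(
#'   label = paste0("c", 1:4),
#'   mean_fC = sapply(c(.1, .33, .5, .8), function(pr) theoreticalMoments(p, pr)$mean),
#'   var_fC2 = sapply(c(.1, .33, .5, .8), function(pr) theoreticalMoments(p, pr)$variance),
#'   n = 75)
#' pts$weight <- 1 / varianceOfVariance(pts$var_fC2, pts$n)
#' fit <- fitParabola(pts)
#' quantalSize(fit); releaseSites(fit)
#' @export
fitParabola <- function(points, reweight = TRUE, intercept = FALSE,
                        tol = 1e-6, maxIter = 20L) {
  req <- c("mean_fC", "var_fC2", "n", "weight")
  if (!is.data.frame(points) || !all(req %in% names(points)))
    stop("points must have columns ", paste(req, collapse = ", "))
  if (nrow(points) < 3L)
    stop("MPFA requires >= 3 variance-mean points")
  if (anyDuplicated(points$mean_fC))
    stop("duplicate condition means: point weights would be ill-defined")
  warns <- character(0)

  m <- points$mean_fC
  v <- points$var_fC2
  nn <- points$n
  w <- points$weight
  if (any(!is.finite(w)) || any(w <= 0)) {
    warns <- c(warns, "degenerate weights; equal weighting used")
    w <- rep(1, length(m))
  }
  labs <- if ("label" %in% names(points)) points$label
          else as.character(seq_along(m))

  form <- if (intercept) v ~ m + I(m^2) else v ~ 0 + m + I(m^2)
  coefName <- c("m", "I(m^2)")
  fit <- stats::lm(form, weights = w)
  A <- unname(stats::coef(fit)[coefName[1]])
  B <- -unname(stats::coef(fit)[coefName[2]])
  iter <- 0L
  if (reweight) {
    repeat {
      # floor predicted variances so a degenerate (zero-variance) point
      # cannot produce an infinite weight and a singular reweighted fit
      pred <- pmax(stats::fitted(fit), 1e-6 * max(abs(v), 1))
      w <- 1 / varianceOfVariance(pred, nn)
      fitNew <- stats::lm(form, weights = w)
      A1 <- unname(stats::coef(fitNew)[coefName[1]])
      B1 <- -unname(stats::coef(fitNew)[coefName[2]])
      if (!is.finite(A1) || !is.finite(B1)) break  # keep last stable fit
      fit <- fitNew
      iter <- iter + 1L
      delta <- max(abs(c(A1 - A, B1 - B)) /
                     pmax(abs(c(A, B)), .Machine$double.eps))
      A <- A1; B <- B1
      if (delta < tol || iter >= maxIter) break
    }
  }

  sm <- summary(fit)$coefficients
  seA <- sm[coefName[1], "Std. Error"]
  seB <- sm[coefName[2], "Std. Error"]

  noCurvature <- !is.finite(B) || B <= 0 || B * max(m) <= 1e-8 * abs(A)
  if (noCurvature) {
    warns <- c(warns,
               "no curvature: release probabilities too low to constrain N")
    warning(warns[length(warns)])
    slopeFit <- stats::lm(v ~ 0 + m, weights = w)
    A <- unname(stats::coef(slopeFit)[1])
    seA <- summary(slopeFit)$coefficients[1, "Std. Error"]
    nFrs <- NA_real_
    pR <- stats::setNames(rep(NA_real_, length(m)), labs)
    seOut <- c(A = seA, B = NA_real_, q = seA, nFrs = NA_real_)
    B <- NA_real_
  } else {
    nFrs <- 1 / B
    pR <- m / (nFrs * A)
    if (any(pR < 0 | pR > 1)) {
      warns <- c(warns, "release probability estimates clipped to [0, 1]")
      warning(warns[length(warns)])
      pR <- pmin(pmax(pR, 0), 1)
    }
    pR <- stats::setNames(pR, labs)
    seOut <- c(A = seA, B = seB, q = seA, nFrs = seB / B^2)
  }

  pts <- points
  pts$weight <- w
  new("MPFAFit", qFc = A, nFrs = nFrs, pR = pR, A = A, B = B,
      se = seOut, points = pts, nIterations = iter,
      converged = !noCurvature, warnings = warns)
}

#' Run MPFA on an experiment
#'
#' Convenience wrapper: [varianceMeanPoints()] followed by [fitParabola()].
#'
#' @inheritParams varianceMeanPoints
#' @inheritParams fitParabola
#' @return an [MPFAFit-class].
#' @export
mpfa <- function(experiment, requireStability = TRUE, reweight = TRUE,
                 intercept = FALSE) {
  fitParabola(varianceMeanPoints(experiment, requireStability),
              reweight = reweight, intercept = intercept)
}

#' Predicted failure rate under the binomial release model
#'
#' \eqn{(1 - P_r)^{N_{frs}}}; a real (non-integer) exponent is permitted
#' because fitted \eqn{N_{frs}} is an estimator, not a count.
#'
#' @param nFrs number of functional release sites, > 0 (real).
#' @param pR release probability in [0, 1].
#' @return predicted fraction of trials with no release.
#' @examples
#' predictedFailureRate(5, 0.2)  # 0.32768
#' @export
predictedFailureRate <- function(nFrs, pR) {
  if (any(nFrs <= 0)) stop("nFrs must be > 0")
  if (any(pR < 0 | pR > 1)) stop("pR must be in [0, 1]")
  (1 - pR)^nFrs
}

#' Compare observed failure fractions with the fitted binomial prediction
#'
#' For each condition, the failure rate predicted from the fit,
#' \eqn{(1 - \hat{P}_r)^{\hat{N}}}, is compared to the observed failure
#' fraction using the binomial standard error
#' \eqn{\sqrt{p(1-p)/n}} at the predicted rate; conditions deviating by more
#' than 3 SE are flagged.
#'
#' @param fit a converged [MPFAFit-class].
#' @param observed named numeric vector of observed failure fractions, names
#'   matching the fit's conditions.
#' @param nTrials integer vector (recycled) of trials per condition.
#' @return data.frame with columns `label`, `predicted`, `observed`, `se`,
#'   `z`, `flagged`.
#' @export
failureConsistency <- function(fit, observed, nTrials) {
  stopifnot(is(fit, "MPFAFit"))
  if (!fit@converged) stop("failure consistency needs a converged fit")
  labs <- names(fit@pR)
  if (is.null(names(observed))) names(observed) <- labs
  if (!all(labs %in% names(observed)))
    stop("observed fractions missing for some conditions")
  obs <- observed[labs]
  nTrials <- rep_len(nTrials, length(labs))
  pred <- predictedFailureRate(fit@nFrs, fit@pR)
  se <- sqrt(pred * (1 - pred) / nTrials)
  z <- ifelse(se > 0, (obs - pred) / se,
              ifelse(obs == pred, 0, Inf * sign(obs - pred)))
  data.frame(label = labs, predicted = unname(pred), observed = unname(obs),
             se = unname(se), z = unname(z), flagged = abs(z) > 3,
             stringsAsFactors = FALSE)
}

#' Plot the variance-mean relationship and fitted parabola
#'
#' @param fit an [MPFAFit-class].
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the fit.
#' @export
plotVarianceMean <- function(fit, ...) {
  stopifnot(is(fit, "MPFAFit"))
  m <- fit@points$mean_fC
  v <- fit@points$var_fC2
  graphics::plot(m, v, xlab = "mean EPSC charge (fC)",
                 ylab = expression(paste("pairwise variance (", fC^2, ")")),
                 pch = 19, xlim = c(0, max(m) * 1.1),
                 ylim = c(0, max(v) * 1.3), ...)
  xx <- seq(0, max(m) * 1.1, length.out = 200)
  if (!is.na(fit@B))
    graphics::lines(xx, fit@A * xx - fit@B * xx^2, col = "steelblue")
  else
    graphics::lines(xx, fit@A * xx, col = "grey50", lty = 2)
  invisible(fit)
}
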