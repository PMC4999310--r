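# Shared fixtures, built in code.

# the four-condition calcium grid used throughout (human-like P_r values)
fourConditions <- function(p_r = c(0.1, 0.33, 0.5, 0.8)) {
  data.frame(label = c("0.5Ca", "1.5Ca", "2Ca", "4Ca"),
             ca_mM = c(0.5, 1.5, 2, 4), p_r = p_r)
}

# exact variance-mean points from the closed-form binomial moments
theoreticalPoints <- function(params, prs, n = 75) {
  mo <- lapply(prs, function(p) theoreticalMoments(params, p))
  pts <- data.frame(label = paste0("c", seq_along(prs)),
                    mean_fC = vapply(mo, `[[`, numeric(1), "mean"),
                    var_fC2 = vapply(mo, `[[`, numeric(1), "variance"),
                    n = n)
  pts$weight <- 1 / varianceOfVariance(pts$var_fC2, pts$n)
  pts
}

# independent dense-grid oracle for alpha-function kinetics: evaluates
# f(t) = (t/tau) exp(1 - t/tau) on a 1 MHz grid and reads level crossings
# off the grid with linear interpolation
alphaKineticsOracle <- function(tauMs) {
  tt <- seq(0, 25 * tauMs, by = 1e-3)
  f <- (tt / tauMs) * exp(1 - tt / tauMs)
  ipk <- which.max(f)
  crossUp <- function(lev) {
    i <- which(f[seq_len(ipk)] >= lev)[1]
    tt[i - 1] + (lev - f[i - 1]) / (f[i] - f[i - 1]) * 1e-3
  }
  crossDown <- function(lev) {
    i <- ipk - 1L + which(f[ipk:length(f)] <= lev)[1]
    tt[i - 1] + (lev - f[i - 1]) / (f[i] - f[i - 1]) * 1e-3
  }
  list(rise1090 = crossUp(0.9) - crossUp(0.1),
       decay37 = crossDown(0.37) - tt[ipk],
       peakT = tt[ipk])
}
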