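#' Whiten a perturbation series
#'
#' Applies the exact inverse of the zero-order-hold discretized
#' perturbation prefilter, recovering the white driving sequence. The
#' prefilter induces autocorrelation in the perturbation; whitening removes
#' it so the cross-correlation with the control input has a flat (delta)
#' reference rather than a smeared one.
#'
#' @param d perturbation samples at `sample_rate`.
#' @param constants a `"task_constants"`.
#' @return Whitened series of the same length (the first sample, which has
#'   no predecessor, carries the stationary initial condition).
#' @export
whiten <- function(d, constants) {
  dt <- 1 / constants$sample_rate
  phi <- exp(-2 * pi * constants$pert_cutoff * dt)
  n <- length(d)
  dw <- numeric(n)
  dw[1] <- d[1]
  dw[2:n] <- (d[2:n] - phi * d[1:(n - 1)]) / (1 - phi)
  dw
}

# exact inverse of whiten() for round-trip checks
unwhiten <- function(dw, constants) {
  dt <- 1 / constants$sample_rate
  phi <- exp(-2 * pi * constants$pert_cutoff * dt)
  n <- length(dw)
  d <- numeric(n)
  d[1] <- dw[1]
  for (k in 2:n) d[k] <- phi * d[k - 1] + (1 - phi) * dw[k]
  d
}

#' Cross-correlation of whitened perturbation and control input
#'
#' Covariance-form cross-correlation \eqn{r_j = n^{-1} \sum_k (d_{w,k} -
#' \bar d_w)(u_{k+j} - \bar u)} over lags `-max_lag..max_lag` samples. The
#' estimate is de-biased by subtracting the mean of `r` over the strictly
#' negative (acausal) lags, where no true correlation can exist.
#'
#' @param d_w whitened perturbation (see [whiten()]).
#' @param u control-input series, same length.
#' @param max_lag maximum lag in samples.
#' @return An object of class `"crosscorr"`: list with `lags` (samples),
#'   `r`, `n_effective`, `noise_floor_sd` (SD of the de-biased negative-lag
#'   values) and `smoothed = FALSE`.
#' @export
cross_correlate <- function(d_w, u, max_lag) {
  n <- length(d_w)
  if (length(u) != n) stop("d_w and u must have equal length")
  max_lag <- as.integer(max_lag)
  if (n < 10 * max_lag)
    stop("series too short for max_lag = ", max_lag, " (need >= ", 10 * max_lag, ")")
  if (stats::sd(d_w) == 0 || stats::sd(u) == 0)
    stop("degenerate (zero-variance) input series")
  dc <- d_w - mean(d_w)
  uc <- u - mean(u)
  lags <- seq.int(-max_lag, max_lag)
  r <- vapply(lags, function(j) {
    if (j >= 0) sum(dc[1:(n - j)] * uc[(1 + j):n]) / n
    else sum(dc[(1 - j):n] * uc[1:(n + j)]) / n
  }, numeric(1))
  neg <- lags < 0
  r <- r - mean(r[neg])
  structure(list(lags = lags, r = r, n_effective = n,
                 noise_floor_sd = stats::sd(r[neg]), smoothed = FALSE),
            class = "crosscorr")
}

#' @export
print.crosscorr <- function(x, ...) {
  cat("Cross-correlation over lags [", min(x$lags), ",", max(x$lags),
      "] samples", if (x$smoothed) " (smoothed)", "\n", sep = "")
  invisible(x)
}

#' Zero-phase smoothing of a cross-correlation
#'
#' Forward-backward (zero-phase) second-order Butterworth filtering of the
#' correlation sequence, treating the lag axis like a 100 Hz time axis with
#' a 20 Hz cutoff. Derivatives amplify estimation noise; this smoothing
#' precedes the second-derivative latency read-out without moving broad
#' features.
#'
#' @param cc a `"crosscorr"` from [cross_correlate()].
#' @param sample_rate sample rate (Hz) that the lag axis refers to.
#' @param cutoff_hz filter cutoff in Hz.
#' @return A smoothed `"crosscorr"` (`smoothed = TRUE`); the noise floor of
#'   the unsmoothed estimate is retained.
#' @export
smooth_cc <- function(cc, sample_rate = 100, cutoff_hz = 20) {
  if (cc$smoothed) stop("cross-correlation is already smoothed")
  bf <- signal::butter(2, cutoff_hz / (sample_rate / 2))
  # odd-reflection padding suppresses the forward-backward filter's edge
  # transients (the plain call assumes zero initial conditions)
  x <- cc$r
  n <- length(x)
  p <- min(50L, n - 1L)
  xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  r_s <- signal::filtfilt(bf, xp)[(p + 1):(p + n)]
  out <- cc
  out$r <- r_s
  out$smoothed <- TRUE
  out
}

#' Latency from the curvature of the smoothed cross-correlation
#'
#' The whitened-perturbation cross-correlation wanders near zero until the
#' subject's correction appears, then bends into a negative (corrective)
#' trend. The latency is read off as the lag of peak curvature at the onset
#' of that trend: the second central difference of the negated (corrective)
#' smoothed correlation is scanned over the search window and the first
#' local maximum reaching at least `peak_frac` of the window's largest
#' curvature is taken (the curvature of the corrective bend typically has a
#' flat shoulder after its onset peak; taking the global maximum would let
#' estimation noise drift the read-out onto that shoulder). A response is
#' only accepted if the corrective dip falls below three times the
#' negative-lag noise floor.
#'
#' @param cc a smoothed `"crosscorr"` (see [smooth_cc()]).
#' @param sample_rate sample rate in Hz mapping lags to seconds.
#' @param search_window two-element numeric, seconds (default 0.05-0.60).
#' @param peak_frac fraction of the window's maximum curvature a local
#'   maximum must reach to count as the onset peak.
#' @return Latency in seconds, with attributes `peak_curvature` and
#'   `noise_floor`.
#' @export
estimate_latency <- function(cc, sample_rate = 100,
                             search_window = c(0.05, 0.60),
                             peak_frac = 0.7) {
  if (!cc$smoothed) stop("estimate_latency expects a smoothed cross-correlation")
  lag_s <- cc$lags / sample_rate
  win <- which(lag_s >= search_window[1] & lag_s <= search_window[2])
  if (length(win) < 5) stop("search window too narrow for the available lags")
  floor3 <- 3 * cc$noise_floor_sd
  if (min(cc$r[win]) > -floor3)
    stop("no response detected: no corrective trend below the noise floor")
  # second central difference of the corrective (negated) correlation
  r_corr <- -cc$r                          # corrective trend is positive here
  d2 <- c(NA, diff(r_corr, differences = 2), NA)
  dw <- d2[win]
  peaks <- which(diff(sign(diff(dw))) == -2) + 1   # interior local maxima
  peaks <- peaks[dw[peaks] >= peak_frac * max(dw, na.rm = TRUE)]
  i <- if (length(peaks) > 0) peaks[1] else which.max(dw)
  idx <- win[i]
  structure(lag_s[idx],
            peak_curvature = d2[idx],
            noise_floor = floor3)
}

#' Cross-correlation latency of one trial
#'
#' Convenience wrapper chaining [whiten()], [cross_correlate()],
#' [smooth_cc()] and [estimate_latency()] for a trial record.
#'
#' @param trial a `"trial_record"`.
#' @param constants a `"task_constants"`.
#' @param max_lag_s maximum lag in seconds.
#' @param search_window latency search window in seconds.
#' @return Latency in seconds (see [estimate_latency()]), or `NA` with a
#'   warning if no response is detected.
#' @export
latency_crosscorr <- function(trial, constants, max_lag_s = 1,
                              search_window = c(0.05, 0.60)) {
  dw <- whiten(trial$d, constants)
  cc <- cross_correlate(dw, trial$u,
                        max_lag = round(max_lag_s * trial$sample_rate))
  ccs <- smooth_cc(cc, sample_rate = trial$sample_rate)
  tryCatch(as.numeric(estimate_latency(ccs, sample_rate = trial$sample_rate,
                                       search_window = search_window)),
           error = function(e) {
             warning("subject ", trial$subject_id, " trial ", trial$trial_index,
                     ": ", conditionMessage(e))
             NA_real_
           })
}
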