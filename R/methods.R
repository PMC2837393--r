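#' @export
print.lqg_fit <- function(x, ...) {
  cat("LQG tracking-model fit (subject ", x$subject_id, ", trial ",
      x$trial_index, ")\n", sep = "")
  print(x$params)
  cat(sprintf("  fit cost %.4g (%s, %d restart%s)\n", x$cost,
              if (x$converged) "converged" else "not converged",
              x$n_restarts_used, if (x$n_restarts_used == 1) "" else "s"))
  invisible(x)
}

#' Parameter estimates of a fitted tracking model
#'
#' @param object an `"lqg_fit"`.
#' @param log10 return base-10 logarithms (the fitting scale) instead of
#'   linear values.
#' @param ... unused.
#' @return Named numeric vector of the four parameters.
#' @export
coef.lqg_fit <- function(object, log10 = FALSE, ...) {
  if (log10) object$log10
  else c(latency = object$params$latency_tau,
         intensity = object$params$noise_intensity,
         bandwidth = object$params$noise_bandwidth,
         rho = object$params$rho)
}

#' @export
summary.lqg_fit <- function(object, ...) {
  out <- list(log10 = object$log10,
              linear = coef(object),
              cost = object$cost,
              converged = object$converged,
              latency_crosscorr = object$latency_crosscorr,
              implied_rms_e = object$implied_rms_e,
              observed_rms_e = object$observed_rms_e,
              rms_ratio = object$implied_rms_e / object$observed_rms_e,
              hsv = tryCatch(controller_hsvs(object$controller)$normalized,
                             error = function(e) NULL),
              subject_id = object$subject_id,
              trial_index = object$trial_index)
  class(out) <- "summary.lqg_fit"
  out
}

#' @export
print.summary.lqg_fit <- function(x, ...) {
  cat("Fitted optimal-control tracking model — subject ", x$subject_id,
      ", trial ", x$trial_index, "\n\n", sep = "")
  m <- rbind(linear = x$linear, log10 = x$log10)
  print(signif(m, 4))
  cat(sprintf("\nfit cost: %.4g (%s)\n", x$cost,
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("cross-correlation latency: %.3f s\n", x$latency_crosscorr))
  cat(sprintf("implied / observed RMS error: %.3f / %.3f (ratio %.3f)\n",
              x$implied_rms_e, x$observed_rms_e, x$rms_ratio))
  if (!is.null(x$hsv))
    cat("normalized controller HSVs:",
        paste(signif(x$hsv[1:5], 3), collapse = " "), "...\n")
  invisible(x)
}

#' Model-implied spectral quantities of a fitted model
#'
#' Evaluates the fitted model's closed-loop transfer function from
#' perturbation to control input and the implied control-input power
#' spectrum, either on the trial's own Fourier grid or a supplied one.
#'
#' @param object an `"lqg_fit"`.
#' @param omega optional angular frequency grid (rad/s); defaults to the
#'   grid of the fitted spectra.
#' @param ... unused.
#' @return List with `omega`, `H_ud`, `S_uu` (as [predicted_response()]).
#' @export
predict.lqg_fit <- function(object, omega = NULL, ...) {
  if (is.null(omega)) omega <- object$spectra$omega
  plant <- assemble_plant(object$constants, object$params)
  predicted_response(plant, object$controller, omega)
}

#' Residuals of the spectral fit
#'
#' @param object an `"lqg_fit"`.
#' @param type `"transfer"` for the complex transfer-function residuals
#'   `H_hat - H(theta)`, `"spectrum"` for the power-spectrum residuals.
#' @param ... unused.
#' @return Complex (transfer) or numeric (spectrum) vector on the fit grid.
#' @export
residuals.lqg_fit <- function(object, type = c("transfer", "spectrum"), ...) {
  type <- match.arg(type)
  pr <- predict(object)
  if (type == "transfer") object$spectra$H_hat - pr$H_ud
  else object$spectra$S_uu_hat - pr$S_uu
}

#' Re-simulate trials from a fitted model
#'
#' Runs the closed-loop trial simulator with the fitted parameters,
#' reproducing the generative protocol (true integer-sample delay,
#' filtered endogenous noise).
#'
#' @param object an `"lqg_fit"`.
#' @param nsim number of trials.
#' @param seed integer seed for perturbation and noise draws.
#' @param ... unused.
#' @return List of `"trial_record"`.
#' @export
simulate.lqg_fit <- function(object, nsim = 1, seed = 1L, ...) {
  d_list <- generate_perturbations(object$constants, n_trials = nsim,
                                   seed = seed)
  simulate_subject(object$constants, object$params, d_list,
                   seed = seed + 1L,
                   subject_id = paste0(object$subject_id, "_sim"))
}

#' Plot a fitted tracking model against the trial spectra
#'
#' Three panels in the layout conventional for this analysis: magnitude and
#' phase of the empirical versus fitted transfer function from perturbation
#' to control input, and the control-input power spectral density.
#'
#' @param x an `"lqg_fit"`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.lqg_fit <- function(x, ...) {
  pr <- predict(x)
  sp <- x$spectra
  op <- graphics::par(mfrow = c(3, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::plot(sp$omega, Mod(sp$H_hat), log = "xy", pch = 1, cex = 0.5,
                 xlab = "", ylab = "|H_ud|",
                 main = paste0("subject ", x$subject_id, ", trial ",
                               x$trial_index), ...)
  graphics::lines(pr$omega, Mod(pr$H_ud), lwd = 2)
  graphics::plot(sp$omega, Arg(sp$H_hat) * 180 / pi, log = "x", pch = 1,
                 cex = 0.5, xlab = "", ylab = "phase (deg)")
  graphics::lines(pr$omega, Arg(pr$H_ud) * 180 / pi, lwd = 2)
  graphics::plot(sp$omega, sp$S_uu_hat, log = "xy", pch = 1, cex = 0.5,
                 xlab = "angular frequency (rad/s)", ylab = "S_uu")
  graphics::lines(pr$omega, pr$S_uu, lwd = 2)
  invisible(x)
}
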