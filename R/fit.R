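#' Empirical transfer function and control-input spectrum of a trial
#'
#' Computes the empirical closed-loop transfer estimate from perturbation
#' to control input as the ratio of the Daniell-smoothed cross-spectrum to
#' the Daniell-smoothed perturbation auto-spectrum, together with the raw
#' (unsmoothed) periodogram of the control input. The transfer estimate is
#' smoothed because it is a ratio of noisy spectra; the control-input power
#' spectrum is deliberately left unsmoothed, since its low- and
#' mid-frequency shape is dominated by the response to a perturbation that
#' is known exactly during analysis. Spectra use the two-sided
#' per-(rad/s) convention, so `mean(u^2)` equals the integral of the
#' periodogram over frequency divided by `2 pi`.
#'
#' @param trial a `"trial_record"` (warm-up already discarded).
#' @param constants a `"task_constants"`.
#' @param daniell_m half-width M of the Daniell (moving-average) smoother,
#'   applied over `2M + 1` Fourier bins.
#' @param omega_max highest angular frequency retained, rad/s.
#' @return An object of class `"spectral_estimate"`: list with `omega`
#'   (rad/s grid), `H_hat` (complex), `S_uu_hat` (raw periodogram of `u`),
#'   `S_dd_hat` (smoothed), and smoothing metadata.
#' @export
estimate_spectra <- function(trial, constants, daniell_m = 5L,
                             omega_max = 30) {
  n <- length(trial$u)
  dt <- 1 / trial$sample_rate
  if (n < 20 * (2 * daniell_m + 1))
    stop("trial too short for the requested smoothing span")
  D <- stats::fft(trial$d - mean(trial$d))
  U <- stats::fft(trial$u - mean(trial$u))
  # two-sided spectral densities per rad/s
  I_dd <- Mod(D)^2 * dt / n
  I_uu <- Mod(U)^2 * dt / n
  I_du <- Conj(D) * U * dt / n
  sm_re <- function(x) {
    # circular moving average over 2M+1 bins
    k <- 2 * daniell_m + 1
    xx <- c(x[(n - daniell_m + 1):n], x, x[1:daniell_m])
    as.numeric(stats::filter(xx, rep(1 / k, k),
                             sides = 2)[(daniell_m + 1):(daniell_m + n)])
  }
  sm <- function(x) complex(real = sm_re(Re(x)), imaginary = sm_re(Im(x)))
  S_dd_s <- sm_re(I_dd)
  S_du_s <- sm(I_du)
  omega_all <- 2 * pi * (seq_len(n) - 1) / (n * dt)
  keep <- which(omega_all > 0 & omega_all <= omega_max)
  K_bin <- max(keep) - 1L                          # highest kept Fourier bin
  ext <- seq_len(min(K_bin + daniell_m, n - 1)) + 1L   # bins 1..K+M
  structure(list(omega = omega_all[keep],
                 H_hat = as.complex(S_du_s[keep] / S_dd_s[keep]),
                 S_uu_hat = I_uu[keep],
                 S_dd_hat = S_dd_s[keep],
                 S_uu_smoothed = sm_re(I_uu)[keep],
                 omega_ext = omega_all[ext],
                 I_dd_raw = I_dd[ext],
                 daniell_m = daniell_m,
                 n_samples = n, dt = dt),
            class = "spectral_estimate")
}

# Linear operator reproducing, on a model transfer function, exactly the
# smearing the Daniell-smoothed cross/auto-spectrum ratio applies to the
# data: conditional on the realized perturbation, the empirical estimate at
# bin k has expectation sum_j |D_j|^2 H_j / sum_j |D_j|^2 over the span
# (negative-frequency bins enter with conjugated H; the DC bin has zero
# weight because the series are mean-removed).
make_smearer <- function(spectra) {
  M <- spectra$daniell_m
  K <- length(spectra$omega)
  Jmat <- outer(seq_len(K), -M:M, "+")
  Wmat <- matrix(0, K, 2 * M + 1)
  pos <- abs(Jmat) >= 1
  Wmat[pos] <- spectra$I_dd_raw[abs(Jmat[pos])]
  Wn <- Wmat / rowSums(Wmat)
  neg <- Jmat < 0
  function(H_ext) {
    Hv <- H_ext[pmax(abs(Jmat), 1)]
    dim(Hv) <- dim(Jmat)
    Hv[neg] <- Conj(Hv[neg])
    Hv[Jmat == 0] <- 0
    rowSums(Wn * Hv)
  }
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat("Spectral estimate on", length(x$omega), "frequencies up to",
      format(max(x$omega), digits = 3), "rad/s (Daniell M =", x$daniell_m, ")\n")
  invisible(x)
}

#' Frequency weighting for the fit cost
#'
#' `fit_weight()` is the band-emphasis factor `W(omega) = omega^2 / (1 +
#' (omega/omega_w)^4)`, zero above `omega_cut`: it rises through the low
#' frequencies whose shape is insensitive to latency, peaks near the
#' closed-loop bandwidth, and excludes the noise-dominated band where
#' coherence is lost. `fit_weights()` builds the full per-term weight
#' vectors used by [fit_lqg()]: the band emphasis divided by an estimate of
#' each quantity's sampling variance — for the transfer estimate, the
#' residual (incoherent) control-input power over the perturbation power
#' and the smoothing span; for the raw power spectrum, its own squared
#' level (periodogram values have standard deviation equal to their mean).
#' The spectrum-term weight is zeroed above `s_cut`, where the coherent
#' response is gone and small systematic model error would otherwise
#' dominate many bins.
#'
#' @param omega angular frequencies, rad/s.
#' @param omega_w peak location parameter, rad/s.
#' @param omega_cut hard cutoff, rad/s.
#' @return `fit_weight()`: numeric weights. `fit_weights()`: list with
#'   components `H` and `S`.
#' @export
fit_weight <- function(omega, omega_w = 6, omega_cut = 30) {
  w <- omega^2 / (1 + (omega / omega_w)^4)
  w[omega > omega_cut] <- 0
  w
}

#' @rdname fit_weight
#' @param spectra a `"spectral_estimate"`.
#' @param lambda relative weight of the power-spectrum term.
#' @param s_cut hard cutoff of the spectrum term, rad/s.
#' @export
fit_weights <- function(spectra, lambda = 1, omega_w = 6, omega_cut = 30,
                        s_cut = 15) {
  band <- fit_weight(spectra$omega, omega_w = omega_w, omega_cut = omega_cut)
  resid_pow <- pmax(spectra$S_uu_smoothed -
                      Mod(spectra$H_hat)^2 * spectra$S_dd_hat,
                    0.05 * spectra$S_uu_smoothed)
  # sampling variance of H_hat plus a relative model-error floor: when the
  # statistical error vanishes (clean trials), a few percent of |H| is the
  # irreducible structural discrepancy and the weight must not blow up
  varH <- resid_pow / (spectra$S_dd_hat * (2 * spectra$daniell_m + 1)) +
    (0.03 * Mod(spectra$H_hat))^2
  wS <- lambda * band / spectra$S_uu_smoothed^2
  wS[spectra$omega > s_cut] <- 0
  list(H = band / varH, S = wS)
}

#' Weighted frequency-domain fit cost
#'
#' Discrepancy between the empirical and model-implied spectral quantities:
#' \deqn{J(\theta) = \sum_k W_k |\hat H_k - H(\omega_k;\theta)|^2 +
#'   \lambda \sum_k W_k (\hat S_k - S(\omega_k;\theta))^2.}
#' Parameter sets for which LQG synthesis fails (or that fall outside the
#' box bounds) return a large finite penalty rather than an error, so a
#' simplex search can retreat from them.
#'
#' @param theta_log10 named log10 parameter vector (latency, intensity,
#'   bandwidth, rho).
#' @param spectra a `"spectral_estimate"`.
#' @param constants a `"task_constants"`.
#' @param lambda weight of the power-spectrum term (used when `weights` is
#'   not supplied, or with a plain-vector `weights`).
#' @param weights either a plain weight vector applied to both terms (the
#'   spectrum term additionally scaled by `lambda`), or a list with
#'   components `H` and `S` as returned by [fit_weights()].
#' @param bounds box bounds in log10 space (see [fit_bounds()]).
#' @param smearer optional operator from [make_smearer()]; when supplied,
#'   the model transfer function is evaluated on the extended bin grid and
#'   passed through the same realized-perturbation-weighted smoothing the
#'   empirical estimate received (removing the smoothing bias from the
#'   comparison), and the predicted control-input spectrum is conditioned
#'   on the realized perturbation periodogram.
#' @return Nonnegative scalar cost.
#' @export
fit_cost <- function(theta_log10, spectra, constants, lambda = 1,
                     weights = NULL, bounds = fit_bounds(), smearer = NULL) {
  if (is.null(weights)) weights <- fit_weight(spectra$omega)
  if (!is.list(weights)) weights <- list(H = weights, S = lambda * weights)
  penalty <- 1e6 * (1 + sum(weights$H * Mod(spectra$H_hat)^2) +
                      sum(weights$S * spectra$S_uu_hat^2))
  if (any(theta_log10 < bounds$lower | theta_log10 > bounds$upper))
    return(penalty)
  omega_eval <- if (is.null(smearer)) spectra$omega else spectra$omega_ext
  pr <- tryCatch({
    params <- params_from_log10(theta_log10)
    plant <- assemble_plant(constants, params)
    ctrl <- design_lqg(plant)
    predicted_response(plant, ctrl, omega_eval)
  }, error = function(e) NULL)
  if (is.null(pr)) return(penalty)
  nk <- length(spectra$omega)
  H_model <- if (is.null(smearer)) pr$H_ud else smearer(pr$H_ud)
  S_model <- if (is.null(smearer)) pr$S_uu[seq_len(nk)] else {
    # condition the predicted control-input spectrum on the realized
    # perturbation: its periodogram is known exactly during analysis, so
    # only the endogenous-noise contribution is taken in expectation
    k <- seq_len(nk)
    Mod(pr$H_ud[k])^2 * spectra$I_dd_raw[k] +
      Mod(pr$H_nu[k])^2 * 10^theta_log10[["intensity"]]
  }
  j <- sum(weights$H * Mod(spectra$H_hat - H_model)^2) +
    sum(weights$S * (spectra$S_uu_hat - S_model)^2)
  if (!is.finite(j)) penalty else j
}

#' Box bounds for fitting, in log10 units
#'
#' @param latency latency bounds in seconds.
#' @param bandwidth noise-bandwidth bounds in rad/s.
#' @param intensity,rho bounds for the remaining parameters.
#' @return List with named `lower` and `upper` log10 vectors.
#' @export
fit_bounds <- function(latency = c(0.1, 1), bandwidth = c(1, 100),
                       intensity = c(1e-5, 1e2), rho = c(1e-5, 1e2)) {
  list(lower = c(latency = log10(latency[1]), intensity = log10(intensity[1]),
                 bandwidth = log10(bandwidth[1]), rho = log10(rho[1])),
       upper = c(latency = log10(latency[2]), intensity = log10(intensity[2]),
                 bandwidth = log10(bandwidth[2]), rho = log10(rho[2])))
}

#' Fit the four-parameter optimal-control model to one trial
#'
#' The central model fit: Nelder-Mead minimization of the weighted
#' frequency-domain cost ([fit_cost()]) over the base-10 logarithms of the
#' four subject parameters, with multiple restarts. The first simplex is
#' centered on the cross-correlation latency estimate and the best point of
#' a coarse grid over noise intensity and control cost; further restarts
#' perturb the center. Trials 1 and 2 of a session are normally excluded
#' from analysis (learning effects) — the fitter warns but proceeds if
#' given one.
#'
#' @param trial a `"trial_record"`.
#' @param constants a `"task_constants"`.
#' @param restarts number of Nelder-Mead restarts.
#' @param lambda power-spectrum term weight in the cost.
#' @param maxit maximum cost evaluations per restart (convergence is
#'   declared earlier when the simplex's relative improvement falls below
#'   `1e-6`, which corresponds to a simplex much smaller than `1e-4` log10
#'   units on this surface).
#' @param bounds box bounds from [fit_bounds()].
#' @param daniell_m,omega_max spectral-estimation settings
#'   (see [estimate_spectra()]).
#' @param seed integer seed for the restart perturbations.
#' @param enforce_trial_filter error if `trial_index < 3` (default warns).
#' @return An object of class `"lqg_fit"` with components `params`
#'   (`"subject_params"`), `log10` (named vector), `cost`, `converged`,
#'   `n_restarts_used`, `latency_crosscorr`, `implied_rms_e`,
#'   `observed_rms_e`, `spectra`, `trial` metadata, and the fitted
#'   controller.
#' @seealso [coef.lqg_fit()], [predict.lqg_fit()], [plot.lqg_fit()],
#'   [simulate.lqg_fit()], [residuals.lqg_fit()]
#' @export
fit_lqg <- function(trial, constants = task_constants(), restarts = 5L,
                    lambda = 1, maxit = 250L, bounds = fit_bounds(),
                    daniell_m = 5L, omega_max = 30, seed = 1L,
                    enforce_trial_filter = FALSE) {
  stopifnot(inherits(trial, "trial_record"))
  if (trial$trial_index < 3) {
    msg <- paste0("trial ", trial$trial_index,
                  " is within the learning period (trials 1-2 are normally excluded)")
    if (enforce_trial_filter) stop(msg) else warning(msg)
  }
  spectra <- estimate_spectra(trial, constants, daniell_m = daniell_m,
                              omega_max = omega_max)
  weights <- fit_weights(spectra, lambda = lambda, omega_cut = omega_max)
  smearer <- make_smearer(spectra)
  obj <- function(th) {
    names(th) <- c("latency", "intensity", "bandwidth", "rho")
    fit_cost(th, spectra, constants, lambda = lambda, weights = weights,
             bounds = bounds, smearer = smearer)
  }
  # starting center: cross-correlation latency + coarse grid over
  # (intensity, rho) at a mid-range noise bandwidth
  tau0 <- latency_crosscorr(trial, constants)
  if (is.na(tau0)) tau0 <- 0.25
  tau0 <- min(max(tau0, 10^bounds$lower[["latency"]] * 1.2),
              10^bounds$upper[["latency"]] / 1.2)
  bw0 <- 0.95                     # log10 rad/s, mid-range start
  grid <- expand.grid(intensity = c(-3.5, -2.5, -1.5),
                      rho = c(-1.5, -0.7, 0.1))
  gcost <- apply(grid, 1, function(g) {
    obj(c(log10(tau0), g[["intensity"]], bw0, g[["rho"]]))
  })
  g0 <- grid[which.min(gcost), ]
  center <- c(latency = log10(tau0), intensity = g0$intensity,
              bandwidth = bw0, rho = g0$rho)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  best <- NULL
  used <- 0L
  for (r in seq_len(restarts)) {
    start <- if (r == 1) center else
      center + stats::rnorm(4, sd = c(0.05, 0.4, 0.2, 0.4))
    start <- pmin(pmax(start, bounds$lower + 1e-3), bounds$upper - 1e-3)
    opt <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-6))
    used <- used + 1L
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  th <- best$par
  names(th) <- c("latency", "intensity", "bandwidth", "rho")
  params <- params_from_log10(th)
  plant <- assemble_plant(constants, params)
  ctrl <- design_lqg(plant)
  obs_rms <- sqrt(mean(trial$e^2))
  imp_rms <- implied_rms_error(ctrl, constants, params,
                               d_full_from_trial(trial, constants))
  structure(list(params = params, log10 = th, cost = best$value,
                 converged = best$convergence == 0,
                 n_restarts_used = used,
                 latency_crosscorr = tau0,
                 implied_rms_e = imp_rms, observed_rms_e = obs_rms,
                 spectra = spectra, controller = ctrl,
                 constants = constants, lambda = lambda,
                 subject_id = trial$subject_id,
                 trial_index = trial$trial_index,
                 trial = trial),
            class = "lqg_fit")
}

# implied_rms_error expects the perturbation over the full trial including
# warm-up; for stored (post-discard) records, re-prefix with zeros so the
# transient is re-created over the warm-up window and the RMS is taken over
# the retained part.
d_full_from_trial <- function(trial, constants) {
  n_warm <- round(constants$warmup_discard * trial$sample_rate)
  c(rep(0, n_warm), trial$d)
}

#' Effort/performance tradeoff traced by the control-cost parameter
#'
#' Constructs the model-implied Pareto front between corrective effort (RMS
#' control-input velocity) and tracking performance (RMS error) by sweeping
#' the control-cost parameter while the endogenous-noise intensity follows
#' the multiplicative (signal-dependent) noise rule: at each `rho` the
#' design is iterated until the noise intensity is consistent with
#' `mult_noise_coeff` times the stationary mean-square control-input
#' velocity it produces.
#'
#' @param constants a `"task_constants"`.
#' @param mult_noise_coeff multiplicative-noise coefficient (intensity per
#'   unit mean-square control velocity; >= 0).
#' @param rho_grid ascending positive control-cost values to sweep.
#' @param latency_tau,noise_bandwidth fixed remaining parameters.
#' @param tol relative convergence tolerance of the fixed point.
#' @param max_iter iteration cap per grid point.
#' @return A data frame with columns `rho`, `rms_udot`, `rms_e`,
#'   `intensity`, `iterations`.
#' @export
pareto_front <- function(constants, mult_noise_coeff, rho_grid,
                         latency_tau = 0.26, noise_bandwidth = 8.9,
                         tol = 1e-4, max_iter = 50L) {
  if (mult_noise_coeff < 0) stop("mult_noise_coeff must be >= 0")
  if (is.unsorted(rho_grid, strictly = TRUE) || any(rho_grid <= 0))
    stop("rho_grid must be positive ascending")
  rows <- lapply(rho_grid, function(rho) {
    q <- mult_noise_coeff * 1     # initial guess; refined by iteration
    if (mult_noise_coeff == 0) q <- 0
    it <- 0L
    repeat {
      it <- it + 1L
      params <- subject_params(latency_tau, max(q, 0), noise_bandwidth, rho)
      ms <- closed_loop_moments(constants, params)
      q_new <- mult_noise_coeff * ms[["ms_udot"]]
      if (mult_noise_coeff == 0 ||
          abs(q_new - q) <= tol * max(q_new, 1e-12)) {
        q <- q_new
        break
      }
      q <- q_new
      if (it >= max_iter)
        stop("multiplicative-noise fixed point did not converge for rho = ", rho)
    }
    params <- subject_params(latency_tau, max(q, 0), noise_bandwidth, rho)
    ms <- closed_loop_moments(constants, params)
    data.frame(rho = rho, rms_udot = sqrt(ms[["ms_udot"]]),
               rms_e = sqrt(ms[["ms_e"]]), intensity = q, iterations = it)
  })
  do.call(rbind, rows)
}

# Stationary second moments of the design closed loop: mean-square error
# and mean-square (band-limited) control-input velocity under both white
# sources.
closed_loop_moments <- function(constants, params) {
  plant <- assemble_plant(constants, params)
  ctrl <- design_lqg(plant)
  cl <- closed_loop(plant, ctrl)
  # cascade a band-limited differentiator on the u output
  df <- build_diff_filter(constants$diff_corner)
  nss <- nstates(cl)
  A <- rbind(cbind(cl$A, matrix(0, nss, 1)),
             cbind(df$B %*% cl$C[1, , drop = FALSE], df$A))
  G <- rbind(cl$B[, 2:3, drop = FALSE], matrix(0, 1, 2))
  Cm <- rbind(cbind(cl$C[2, , drop = FALSE], 0),            # e
              cbind(df$D %*% cl$C[1, , drop = FALSE], df$C)) # band-limited udot
  Qn <- G %*% diag(c(constants$pert_white_intensity,
                     params$noise_intensity), 2) %*% t(G)
  X <- solve_lyapunov(A, Qn)
  v <- diag(Cm %*% X %*% t(Cm))
  c(ms_e = v[1], ms_udot = v[2])
}
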