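#' Task constants for the compensatory tracking protocol
#'
#' Bundles the fixed properties of the tracking task: the sampling and trial
#' protocol, the perturbation prefilter, the screen scale, the corner of the
#' differentiation filter used in the quadratic cost, and the (negligible)
#' measurement noise level that keeps the Kalman design well posed.
#'
#' @param sample_rate sampling rate in Hz.
#' @param trial_length trial duration in seconds.
#' @param warmup_discard initial seconds discarded from every trial.
#' @param pert_cutoff corner frequency of the first-order perturbation
#'   prefilter, in Hz. The published protocol does not fix this value; the
#'   package default is 0.3 Hz.
#' @param pert_white_intensity intensity (variance per unit bandwidth,
#'   units^2 s) of the white noise driving the perturbation prefilter. The
#'   default is calibrated (see [calibrate_pert_intensity()]) so that an
#'   uncorrected cursor first crosses the screen half-width in a median of
#'   about 10 seconds.
#' @param screen_halfwidth half-width of the display in error units.
#' @param diff_corner corner (rad/s) of the band-limited differentiator in
#'   the cost function; must sit well above the closed-loop bandwidth.
#' @param meas_noise_variance intensity of the white measurement noise; kept
#'   small but positive for a well-posed Kalman Riccati equation.
#' @return An object of class `"task_constants"`.
#' @export
task_constants <- function(sample_rate = 100,
                           trial_length = 60,
                           warmup_discard = 9,
                           pert_cutoff = 0.3,
                           pert_white_intensity = 0.1334,
                           screen_halfwidth = 1,
                           diff_corner = 100,
                           meas_noise_variance = 1e-6) {
  vals <- c(sample_rate = sample_rate, trial_length = trial_length,
            warmup_discard = warmup_discard, pert_cutoff = pert_cutoff,
            pert_white_intensity = pert_white_intensity,
            screen_halfwidth = screen_halfwidth, diff_corner = diff_corner,
            meas_noise_variance = meas_noise_variance)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all task constants must be positive and finite")
  if (warmup_discard >= trial_length)
    stop("warmup_discard must be smaller than trial_length")
  if (diff_corner < 50)
    warning("diff_corner below 50 rad/s may interfere with the closed-loop band")
  structure(as.list(vals), class = "task_constants")
}

#' @export
print.task_constants <- function(x, ...) {
  cat("Tracking task constants:\n")
  for (nm in names(x)) cat(sprintf("  %-22s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Subject parameters of the optimal-control model
#'
#' The four quantities that define a modeled subject: response latency,
#' intensity and bandwidth of the endogenous noise (filtered Gaussian noise
#' added to the ideal control input), and the combined control-cost /
#' multiplicative-noise weight `rho`. The two components of `rho` have a
#' summed joint effect on the time-invariant optimal design and are not
#' separately identifiable, so a single scalar is carried.
#'
#' @param latency_tau response latency in seconds (> 0).
#' @param noise_intensity endogenous-noise intensity, variance per unit
#'   bandwidth of the white source before the noise prefilter (>= 0).
#' @param noise_bandwidth corner of the critically damped second-order noise
#'   prefilter, rad/s (> 0).
#' @param rho control-cost/multiplicative-noise weight (> 0).
#' @return An object of class `"subject_params"`.
#' @seealso [params_log10()], [params_from_log10()]
#' @export
subject_params <- function(latency_tau, noise_intensity, noise_bandwidth, rho) {
  if (!is.finite(latency_tau) || latency_tau <= 0) stop("latency_tau must be > 0")
  if (!is.finite(noise_intensity) || noise_intensity < 0)
    stop("noise_intensity must be >= 0")
  if (!is.finite(noise_bandwidth) || noise_bandwidth <= 0)
    stop("noise_bandwidth must be > 0")
  if (!is.finite(rho) || rho <= 0) stop("rho must be > 0")
  structure(list(latency_tau = latency_tau,
                 noise_intensity = noise_intensity,
                 noise_bandwidth = noise_bandwidth,
                 rho = rho,
                 log10 = c(latency = log10(latency_tau),
                           intensity = log10(noise_intensity),
                           bandwidth = log10(noise_bandwidth),
                           rho = log10(rho))),
            class = "subject_params")
}

#' @export
print.subject_params <- function(x, ...) {
  cat(sprintf(paste0("Subject parameters: latency %.3f s, noise intensity %.3g,",
                     " noise bandwidth %.2f rad/s, rho %.3g\n"),
              x$latency_tau, x$noise_intensity, x$noise_bandwidth, x$rho))
  invisible(x)
}

#' Base-10 log representation of subject parameters
#'
#' Parameters are reported and fitted on the log10 scale (the scale on which
#' their cohort statistics are approximately normal). The log10 vector is
#' stored canonically in the object, so
#' `params_log10(params_from_log10(x))` returns `x` exactly.
#'
#' @param params a `"subject_params"` object.
#' @return Named numeric vector `c(latency, intensity, bandwidth, rho)` of
#'   log10 values.
#' @export
params_log10 <- function(params) params$log10

#' @rdname params_log10
#' @param x named numeric vector as returned by [params_log10()].
#' @export
params_from_log10 <- function(x) {
  p <- subject_params(latency_tau = 10^x[["latency"]],
                      noise_intensity = 10^x[["intensity"]],
                      noise_bandwidth = 10^x[["bandwidth"]],
                      rho = 10^x[["rho"]])
  p$log10 <- c(latency = x[["latency"]], intensity = x[["intensity"]],
               bandwidth = x[["bandwidth"]], rho = x[["rho"]])
  p
}

#' Perturbation prefilter
#'
#' First-order low-pass with unit DC gain and corner `2 pi pert_cutoff`
#' rad/s. Driven by white noise it produces the band-limited Gaussian
#' perturbation that moves the cursor.
#'
#' @param constants a `"task_constants"` object.
#' @return A 1-state `"ss"`.
#' @export
build_perturbation_filter <- function(constants) {
  a <- 2 * pi * constants$pert_cutoff
  if (a <= 0) stop("pert_cutoff must be positive")
  ss(-a, a, 1, state_labels = "pert_filter")
}

#' Endogenous-noise prefilter
#'
#' Critically damped second-order low-pass, unit DC gain, double real pole
#' at `-noise_bandwidth`. Shapes the white endogenous-noise source before it
#' is added to the control input.
#'
#' @param noise_bandwidth double-pole location in rad/s (> 0).
#' @return A 2-state `"ss"`.
#' @export
build_noise_filter <- function(noise_bandwidth) {
  if (!is.finite(noise_bandwidth) || noise_bandwidth <= 0)
    stop("noise_bandwidth must be positive")
  wn <- noise_bandwidth
  ss(matrix(c(0, -wn^2, 1, -2 * wn), 2), c(0, wn^2), matrix(c(1, 0), 1),
     state_labels = c("noise_f1", "noise_f2"))
}

#' Band-limited differentiator
#'
#' Realizes `s a / (s + a)`: gain approximately `omega` well below the
#' corner `a`, bounded gain `a` at high frequency. Used to penalize control
#' input velocity in the quadratic cost without an improper system.
#'
#' @param diff_corner corner frequency `a` in rad/s (> 0).
#' @return A 1-state `"ss"` with feedthrough.
#' @export
build_diff_filter <- function(diff_corner) {
  if (!is.finite(diff_corner) || diff_corner <= 0)
    stop("diff_corner must be positive")
  a <- diff_corner
  ss(-a, a, -a, a, state_labels = "diff")
}

#' Assemble the nine-state augmented tracking plant
#'
#' Builds the design plant for LQG synthesis. The cursor is a pure
#' integrator driven by the sum of the subject's control input and the
#' filtered perturbation; the subject's measurement is the cursor error
#' passed through a fourth-order Pade approximation of the response latency;
#' the quadratic cost penalizes tracking error and (scaled by `sqrt(rho)`)
#' the band-limited derivative of the ideal control input.
#'
#' State ordering (fixed convention): cursor, perturbation filter, noise
#' filter (2), Pade delay (4), differentiator — nine states. Inputs:
#' `u_ideal`, white perturbation source `w`, white endogenous-noise source
#' `n_w`, and the realized perturbation `d` injected directly at the cursor
#' (used when the perturbation series is known). Outputs: delayed
#' measurement `y`, error `e`, total control `u`, and the two cost channels.
#'
#' @param constants a `"task_constants"` object.
#' @param params a `"subject_params"` object.
#' @return An object of class `"aug_plant"`: list with the `"ss"` in `sys`,
#'   port index maps `inputs` and `outputs`, and the arguments.
#' @export
assemble_plant <- function(constants, params) {
  stopifnot(inherits(constants, "task_constants"),
            inherits(params, "subject_params"))
  pf <- build_perturbation_filter(constants)
  nf <- build_noise_filter(params$noise_bandwidth)
  dl <- pade_delay(params$latency_tau, 4L)
  df <- build_diff_filter(constants$diff_corner)
  a_d <- constants$diff_corner
  n <- 9L
  A <- matrix(0, n, n)
  B <- matrix(0, n, 4)
  ix <- list(cursor = 1L, pert = 2L, noise = 3:4, delay = 5:8, diff = 9L)
  iu <- c(u = 1L, w = 2L, n = 3L, d = 4L)
  # cursor integrator: e_dot = u_ideal + noise-filter output + pert-filter output (+ d)
  A[1, 2] <- 1                         # pert filter output (C = 1 on its state)
  A[1, 3:4] <- nf$C                    # noise filter output
  B[1, 1] <- 1
  B[1, 4] <- 1
  # perturbation filter
  A[2, 2] <- pf$A
  B[2, 2] <- pf$B
  # noise filter
  A[3:4, 3:4] <- nf$A
  B[3:4, 3] <- nf$B
  # delay driven by the cursor error
  A[5:8, 5:8] <- dl$A
  A[5:8, 1] <- dl$B
  # differentiator driven by u_ideal
  A[9, 9] <- -a_d
  B[9, 1] <- a_d
  # outputs: y (delayed e), e, u, z1 = sqrt(rho)*udot_hat, z2 = e
  C <- matrix(0, 5, n)
  D <- matrix(0, 5, 4)
  C[1, 5:8] <- dl$C
  C[1, 1] <- dl$D
  C[2, 1] <- 1
  C[3, 3:4] <- nf$C                    # u = u_ideal + filtered noise
  D[3, 1] <- 1
  C[4, 9] <- -sqrt(params$rho) * a_d
  D[4, 1] <- sqrt(params$rho) * a_d
  C[5, 1] <- 1
  sys <- ss(A, B, C, D,
            state_labels = c("cursor", "pert_filter", "noise_f1", "noise_f2",
                             paste0("delay", 1:4), "diff"))
  structure(list(sys = sys, states = ix, inputs = iu,
                 outputs = c(y = 1L, e = 2L, u = 3L, z1 = 4L, z2 = 5L),
                 constants = constants, params = params),
            class = "aug_plant")
}

#' @export
print.aug_plant <- function(x, ...) {
  cat("Augmented tracking plant:", nstates(x$sys), "states\n")
  print(x$params)
  invisible(x)
}

#' Synthesize the LQG controller for an assembled plant
#'
#' Computes the optimal state-feedback (LQR) gain from the Riccati equation
#' with the cost channels (tracking error and `sqrt(rho)`-weighted control
#' velocity, including the feedthrough-induced cross term), and the Kalman
#' gain from the dual Riccati equation with process noise entering through
#' the perturbation and endogenous-noise channels and white measurement
#' noise on the delayed error. The controller is the standard
#' estimator-plus-static-gain realization
#' \deqn{\dot{\hat x} = (A - B K - L C_y)\hat x + L y, \qquad u = -K \hat x.}
#'
#' @param plant an `"aug_plant"` from [assemble_plant()].
#' @param constants,params optional overrides; default to those stored in
#'   `plant`.
#' @return An object of class `"lqg_controller"`: list with `sys` (the
#'   9-state controller, input `y`, output `u_ideal`), gains `K` and `L`,
#'   and the design parameters.
#' @export
design_lqg <- function(plant, constants = plant$constants,
                       params = plant$params) {
  sys <- plant$sys
  n <- nstates(sys)
  A <- sys$A
  B1 <- sys$B[, plant$inputs[["u"]], drop = FALSE]
  Cz <- sys$C[c(plant$outputs[["z1"]], plant$outputs[["z2"]]), , drop = FALSE]
  Dz <- sys$D[c(plant$outputs[["z1"]], plant$outputs[["z2"]]),
              plant$inputs[["u"]], drop = FALSE]
  Cy <- sys$C[plant$outputs[["y"]], , drop = FALSE]
  Qx <- crossprod(Cz)
  Rx <- crossprod(Dz)
  Nx <- crossprod(Cz, Dz)
  lqr <- tryCatch(solve_care(A, B1, Qx, Rx, Nx),
                  error = function(e) stop("LQR synthesis failed: ",
                                           conditionMessage(e)))
  G <- sys$B[, c(plant$inputs[["w"]], plant$inputs[["n"]]), drop = FALSE]
  Wn <- diag(c(constants$pert_white_intensity, params$noise_intensity), 2)
  kal <- tryCatch(
    solve_care(t(A), t(Cy), G %*% Wn %*% t(G),
               matrix(constants$meas_noise_variance)),
    error = function(e) stop("Kalman synthesis failed: ", conditionMessage(e)))
  K <- lqr$K                            # 1 x n
  L <- t(kal$K)                         # n x 1
  Ac <- A - B1 %*% K - L %*% Cy
  ctrl_sys <- ss(Ac, L, -K, state_labels = paste0("xhat_", sys$state_labels))
  # the defining LQG property: the design closed loop must be stable
  Acl <- rbind(cbind(A, -B1 %*% K), cbind(L %*% Cy, Ac))
  if (max(Re(eigen(Acl, only.values = TRUE)$values)) >= 0)
    stop("LQG synthesis produced an unstable design closed loop")
  structure(list(sys = ctrl_sys, K = K, L = L,
                 design_params = params, constants = constants,
                 residuals = c(lqr = lqr$residual, kalman = kal$residual)),
            class = "lqg_controller")
}

#' @export
print.lqg_controller <- function(x, ...) {
  cat("LQG controller:", nstates(x$sys), "states; |K| =",
      format(sqrt(sum(x$K^2)), digits = 4),
      "; |L| =", format(sqrt(sum(x$L^2)), digits = 4), "\n")
  invisible(x)
}

# Closed loop of a design plant and its controller.
# States: 9 plant + 9 estimator. Inputs: (d, w, n_w). Outputs: (u, e).
closed_loop <- function(plant, controller) {
  sys <- plant$sys
  A <- sys$A
  B1 <- sys$B[, plant$inputs[["u"]], drop = FALSE]
  Cy <- sys$C[plant$outputs[["y"]], , drop = FALSE]
  K <- controller$K; L <- controller$L
  n <- nstates(sys)
  Acl <- rbind(cbind(A, -B1 %*% K),
               cbind(L %*% Cy, controller$sys$A))
  Bd <- sys$B[, plant$inputs[["d"]], drop = FALSE]
  Bw <- sys$B[, plant$inputs[["w"]], drop = FALSE]
  Bn <- sys$B[, plant$inputs[["n"]], drop = FALSE]
  Bcl <- cbind(rbind(Bd, matrix(0, n, 1)),
               rbind(Bw, matrix(0, n, 1)),
               rbind(Bn, matrix(0, n, 1)))
  # u = -K xhat + noise-filter output; e = cursor state
  Cu <- cbind(sys$C[plant$outputs[["u"]], , drop = FALSE], -K)
  Ce <- cbind(sys$C[plant$outputs[["e"]], , drop = FALSE], matrix(0, 1, n))
  ss(Acl, Bcl, rbind(Cu, Ce),
     state_labels = c(sys$state_labels, controller$sys$state_labels))
}

#' Predicted closed-loop response and control-input spectrum
#'
#' Evaluates the model-implied transfer function from the perturbation to
#' the subject's control input, and the model-implied power spectral density
#' of the control input (two-sided, per rad/s), on a grid of angular
#' frequencies. These are the quantities compared against the empirical
#' spectral estimates during fitting.
#'
#' @param plant an `"aug_plant"`.
#' @param controller an `"lqg_controller"` designed for it.
#' @param omega angular frequency grid, rad/s.
#' @return List with `omega`, `H_ud` (complex vector), `S_uu` (numeric
#'   vector).
#' @export
predicted_response <- function(plant, controller, omega) {
  cl <- closed_loop(plant, controller)
  ed <- eigen(cl$A)
  if (max(Re(ed$values)) >= 0) stop("closed loop is unstable")
  Cu <- cl$C[1, , drop = FALSE]
  H <- fast_freqresp_row(ed, cl$A, cl$B, Cu, omega)   # 3 x n_omega
  H_ud <- H[1, ]
  S_uu <- Mod(H[2, ])^2 * plant$constants$pert_white_intensity +
    Mod(H[3, ])^2 * plant$params$noise_intensity
  list(omega = omega, H_ud = H_ud, S_uu = S_uu,
       H_wu = H[2, ], H_nu = H[3, ])
}

# Single-output frequency response C (iwI - A)^-1 B for all inputs at once,
# via one eigendecomposition and one matrix product; falls back to direct
# per-frequency solves if a spot check against the direct solve fails
# (near-defective eigenvector bases).
fast_freqresp_row <- function(ed, A, B, Crow, omega) {
  n <- nrow(A); m <- ncol(B)
  direct <- function(w) as.vector(Crow %*% solve(1i * w * diag(n) - A, B))
  out <- tryCatch({
    ViB <- solve(ed$vectors, B)                   # n x m
    cv <- as.vector(Crow %*% ed$vectors)          # length n
    M <- ViB * cv                                 # rows scaled
    G <- 1 / (outer(ed$values, omega, function(l, w) 1i * w - l))  # n x nw
    H <- t(M) %*% G                               # m x nw
    chk <- direct(omega[length(omega)])
    if (max(Mod(chk - H[, ncol(H)])) > 1e-7 * (1 + max(Mod(chk))))
      stop("fallback")
    H
  }, error = function(e) NULL)
  if (!is.null(out)) return(out)
  vapply(omega, direct, complex(m))
}

# Stationary output covariance of the closed loop under the white sources
# (w at the perturbation intensity, n_w at the endogenous intensity).
# outputs: named vector of stationary variances for u and e.
stationary_output_variance <- function(plant, controller,
                                       include_pert = TRUE,
                                       include_noise = TRUE) {
  cl <- closed_loop(plant, controller)
  qw <- if (include_pert) plant$constants$pert_white_intensity else 0
  qn <- if (include_noise) plant$params$noise_intensity else 0
  G <- cl$B[, 2:3, drop = FALSE]
  Qn <- G %*% diag(c(qw, qn), 2) %*% t(G)
  X <- solve_lyapunov(cl$A, Qn)
  v <- diag(cl$C %*% X %*% t(cl$C))
  c(u = v[1], e = v[2])
}

#' Model-implied RMS tracking error for a known perturbation
#'
#' Combines the deterministic closed-loop response to the realized
#' perturbation series (zero initial conditions) with the stationary
#' stochastic contribution of the endogenous noise, as a root sum of
#' squares. This is the quantity compared with the observed RMS error as a
#' test of the fitted model.
#'
#' @param controller an `"lqg_controller"`.
#' @param constants a `"task_constants"`.
#' @param params a `"subject_params"`.
#' @param d_series realized perturbation samples at `sample_rate`, covering
#'   the full trial (warm-up included).
#' @return Predicted RMS error (positive scalar) over the post-warm-up
#'   window.
#' @export
implied_rms_error <- function(controller, constants, params, d_series) {
  plant <- assemble_plant(constants, params)
  cl <- closed_loop(plant, controller)
  if (max(Re(eigen(cl$A, only.values = TRUE)$values)) >= 0)
    stop("closed loop is unstable")
  dt <- 1 / constants$sample_rate
  dsys <- discretize_zoh(ss(cl$A, cl$B[, 1, drop = FALSE],
                            cl$C[2, , drop = FALSE]), dt)
  e_det <- simulate_ss(dsys, d_series)[, 1]
  keep <- seq.int(round(constants$warmup_discard / dt) + 1L, length(d_series))
  rms_det <- sqrt(mean(e_det[keep]^2))
  var_stoch <- if (params$noise_intensity > 0)
    stationary_output_variance(plant, controller,
                               include_pert = FALSE)[["e"]] else 0
  sqrt(rms_det^2 + var_stoch)
}
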