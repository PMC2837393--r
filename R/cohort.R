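#' Generate perturbation time histories
#'
#' Produces the band-limited Gaussian perturbation series used in the
#' tracking protocol: discrete-time white Gaussian noise passed through the
#' zero-order-hold discretization of the first-order perturbation prefilter.
#' Every subject in a cohort receives the same list of sequences (as in the
#' protocol, where all subjects saw the same perturbations in the same
#' order), so the list depends only on the constants, trial count and seed.
#'
#' @param constants a `"task_constants"` object.
#' @param n_trials number of trials (default 10).
#' @param seed integer seed; the same seed reproduces identical sequences.
#' @return A list of `n_trials` numeric vectors of length
#'   `trial_length * sample_rate`, in screen units.
#' @export
generate_perturbations <- function(constants, n_trials = 10L, seed = 1L) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  dt <- 1 / constants$sample_rate
  a <- 2 * pi * constants$pert_cutoff
  phi <- exp(-a * dt)
  q <- constants$pert_white_intensity
  sigma_w <- sqrt(q * constants$sample_rate)
  N <- round(constants$trial_length * constants$sample_rate)
  # stationary variance of the ZOH-discretized filter output
  var_stat <- sigma_w^2 * (1 - phi)^2 / (1 - phi^2)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  lapply(seq_len(n_trials), function(i) {
    w <- rnorm(N, sd = sigma_w)
    d <- numeric(N)
    d[1] <- rnorm(1, sd = sqrt(var_stat))
    gain <- 1 - phi
    for (k in 2:N) d[k] <- phi * d[k - 1] + gain * w[k - 1]
    d
  })
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Calibrate the perturbation white-noise intensity
#'
#' Finds, by bisection, the intensity of the white source driving the
#' perturbation prefilter such that an uncorrected cursor (control input
#' identically zero) first crosses the screen half-width after a median of
#' `target_time` seconds across simulated trials. This pins the open-loop
#' difficulty of the task: left alone, the cursor wanders off the screen in
#' about ten seconds.
#'
#' @param constants a `"task_constants"` (its `pert_white_intensity` is
#'   ignored).
#' @param target_time target median first-passage time in seconds.
#' @param n_sims number of simulated trials per evaluation.
#' @param seed integer seed for the simulation draws.
#' @param tol acceptable deviation of the achieved median from
#'   `target_time`, in seconds.
#' @return The calibrated intensity (positive scalar).
#' @export
calibrate_pert_intensity <- function(constants, target_time = 10,
                                     n_sims = 200L, seed = 99L, tol = 1) {
  dt <- 1 / constants$sample_rate
  h <- constants$screen_halfwidth
  base <- constants
  base$pert_white_intensity <- 1   # unit-intensity reference paths
  d_unit <- generate_perturbations(base, n_trials = n_sims, seed = seed)
  e_unit <- lapply(d_unit, function(d) cumsum(d) * dt)
  med_fpt <- function(q) {
    scale <- sqrt(q)
    fpt <- vapply(e_unit, function(e) {
      idx <- which(abs(e) * scale >= h)
      if (length(idx) == 0) Inf else idx[1] * dt
    }, numeric(1))
    median(fpt)
  }
  lo <- 1e-6; hi <- 1e2
  if (!(med_fpt(lo) > target_time && med_fpt(hi) < target_time))
    stop("calibration bracket does not contain the target first-passage time")
  for (it in 1:200) {
    mid <- sqrt(lo * hi)
    m <- med_fpt(mid)
    if (is.finite(m) && abs(m - target_time) <= tol * 0.5) return(mid)
    if (m > target_time) lo <- mid else hi <- mid
    if (hi / lo < 1 + 1e-6) break
  }
  m <- med_fpt(sqrt(lo * hi))
  if (abs(m - target_time) <= tol) return(sqrt(lo * hi))
  stop("bisection on perturbation intensity did not converge")
}

#' Cohort specification from group-level log10 statistics
#'
#' Describes a synthetic cohort: subjects are drawn independently with each
#' of the four model parameters lognormal, using group means and SDs of the
#' base-10 logarithms. The defaults are the inferred group statistics for
#' the young and elderly cohorts (per-parameter aggregate SDs shared across
#' groups).
#'
#' @param group `"young"` or `"elderly"`.
#' @param n_subjects number of subjects (default 12).
#' @param log10_means named numeric vector (latency, intensity, bandwidth,
#'   rho) of log10 means; defaults depend on `group`.
#' @param log10_sds named numeric vector of log10 SDs (positive).
#' @param seed integer seed used when sampling the cohort.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(group = c("young", "elderly"), n_subjects = 12L,
                        log10_means = NULL, log10_sds = NULL, seed = 1L) {
  group <- match.arg(group)
  defaults <- cohort_table_defaults()
  if (is.null(log10_means)) log10_means <- defaults$means[[group]]
  if (is.null(log10_sds)) log10_sds <- defaults$sds
  nm <- c("latency", "intensity", "bandwidth", "rho")
  if (!all(nm %in% names(log10_means)) || !all(nm %in% names(log10_sds)))
    stop("log10_means and log10_sds must be named with ",
         paste(nm, collapse = ", "))
  if (any(log10_sds[nm] < 0)) stop("log10 SDs must be nonnegative")
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  structure(list(group = group, n_subjects = as.integer(n_subjects),
                 log10_means = log10_means[nm], log10_sds = log10_sds[nm],
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Group statistics of the base-10 log parameters (means per group, shared
# aggregate SDs) used as the generative cohort model.
cohort_table_defaults <- function() {
  list(means = list(
    young = c(latency = -0.5879, intensity = -2.7556,
              bandwidth = 0.9495, rho = -0.7257),
    elderly = c(latency = -0.6252, intensity = -2.6408,
                bandwidth = 0.9039, rho = -0.3010)),
    sds = c(latency = 0.1109, intensity = 0.5756,
            bandwidth = 0.2713, rho = 0.4552))
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Cohort spec:", x$group, "-", x$n_subjects, "subjects, seed", x$seed, "\n")
  m <- rbind(`log10 mean` = x$log10_means, `log10 sd` = x$log10_sds)
  print(round(m, 4))
  invisible(x)
}

#' Draw subject parameters for a cohort
#'
#' Independent lognormal draws of the four model parameters per subject,
#' reproducible from the seed stored in the spec.
#'
#' @param spec a `"cohort_spec"`.
#' @return A list of `"subject_params"`, one per subject.
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  lapply(seq_len(spec$n_subjects), function(i) {
    lg <- rnorm(4, mean = spec$log10_means, sd = spec$log10_sds)
    names(lg) <- names(spec$log10_means)
    params_from_log10(lg)
  })
}

#' Simulate one subject's trials in closed loop
#'
#' Runs the full trial protocol for a modeled subject: the subject's
#' internal LQG controller (designed with the Pade delay model) acts on the
#' displayed error delayed by a true integer-sample latency, endogenous
#' noise filtered by the critically damped prefilter is added to the ideal
#' control input, and the cursor integrates control plus perturbation at
#' the sample rate. The world uses a true delay while the subject's
#' internal model uses the Pade approximation, so fitting is exercised
#' under realistic model mismatch. The warm-up seconds are discarded from
#' the returned records.
#'
#' @param constants a `"task_constants"`.
#' @param params a `"subject_params"`.
#' @param d_list list of perturbation series from
#'   [generate_perturbations()].
#' @param seed integer seed for the endogenous-noise draws.
#' @param subject_id identifier stored in the records.
#' @return A list of `"trial_record"` objects (one per element of
#'   `d_list`), each with fields `subject_id`, `trial_index`, `t`, `d`,
#'   `u`, `e`, `sample_rate`, `warmup_discarded`.
#' @export
simulate_subject <- function(constants, params, d_list, seed = 1L,
                             subject_id = "s1") {
  plant <- assemble_plant(constants, params)
  ctrl <- design_lqg(plant)
  dt <- 1 / constants$sample_rate
  cd <- discretize_zoh(ctrl$sys, dt)
  nf <- build_noise_filter(params$noise_bandwidth)
  nfd <- discretize_zoh(nf, dt)
  # integer measurement shift chosen so that the total discrete-loop dead
  # time from perturbation to control response -- the one-sample cursor
  # integration plus the shift itself -- equals round(tau * fs) samples
  # (the controller state is updated with the current measurement before
  # its output is read, emulating a continuous controller at the samples)
  delay_n <- max(0L, as.integer(round(params$latency_tau * constants$sample_rate)) - 1L)
  N <- length(d_list[[1]])
  keep <- seq.int(round(constants$warmup_discard / dt) + 1L, N)
  sigma_n <- sqrt(params$noise_intensity * constants$sample_rate)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  out <- vector("list", length(d_list))
  for (tr in seq_along(d_list)) {
    d <- d_list[[tr]]
    if (length(d) != N) stop("perturbation series have unequal lengths")
    n_filt <- if (sigma_n > 0)
      simulate_ss(nfd, rnorm(N, sd = sigma_n))[, 1] else numeric(N)
    e <- numeric(N); u <- numeric(N)
    xc <- rep(0, nstates(ctrl$sys))
    Ad <- cd$Ad; Bd <- as.numeric(cd$Bd); Cc <- as.numeric(cd$C)
    for (k in seq_len(N)) {
      y <- if (k > delay_n) e[k - delay_n] else 0
      xc <- Ad %*% xc + Bd * y
      u[k] <- sum(Cc * xc) + n_filt[k]
      if (k < N) e[k + 1] <- e[k] + dt * (u[k] + d[k])
    }
    if (max(abs(e)) > 50 * constants$screen_halfwidth)
      stop("closed-loop simulation diverged for subject ", subject_id,
           " trial ", tr)
    out[[tr]] <- trial_record(subject_id = subject_id, trial_index = tr,
                              t = (keep - 1) * dt, d = d[keep], u = u[keep],
                              e = e[keep],
                              sample_rate = constants$sample_rate,
                              warmup_discarded = TRUE)
  }
  out
}

#' Construct a trial record
#'
#' @param subject_id subject identifier.
#' @param trial_index trial number within the session.
#' @param t time stamps in seconds.
#' @param d,u,e perturbation, control-input and error series (equal length).
#' @param sample_rate sampling rate in Hz.
#' @param warmup_discarded logical flag.
#' @return An object of class `"trial_record"`.
#' @export
trial_record <- function(subject_id, trial_index, t, d, u, e, sample_rate,
                         warmup_discarded = TRUE) {
  n <- length(t)
  if (length(d) != n || length(u) != n || length(e) != n)
    stop("t, d, u, e must have equal length")
  structure(list(subject_id = subject_id,
                 trial_index = as.integer(trial_index),
                 t = t, d = d, u = u, e = e,
                 sample_rate = sample_rate,
                 warmup_discarded = isTRUE(warmup_discarded)),
            class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("Trial %d of subject %s: %.1f s at %g Hz%s\n",
              x$trial_index, x$subject_id,
              length(x$t) / x$sample_rate, x$sample_rate,
              if (x$warmup_discarded) " (warm-up discarded)" else ""))
  invisible(x)
}

#' Verify a trial's stored error series against the cursor dynamics
#'
#' The cursor dynamics require the stored error to equal the cumulative
#' integral of control plus perturbation; this checks that self-consistency
#' of a record.
#'
#' @param trial a `"trial_record"`.
#' @return Maximum absolute deviation from the integral identity.
#' @export
trial_integral_residual <- function(trial) {
  dt <- 1 / trial$sample_rate
  n <- length(trial$e)
  e_rec <- trial$e[1] + c(0, cumsum(trial$u[-n] + trial$d[-n])) * dt
  max(abs(e_rec - trial$e))
}

#' RMS performance metrics of a trial
#'
#' RMS cursor error (performance) and RMS control-input velocity (effort),
#' the two axes of the effort/performance tradeoff. The input velocity is
#' computed from first differences scaled by the sample rate.
#'
#' @param trial a `"trial_record"`.
#' @return Named numeric vector `c(rms_e, rms_udot)`.
#' @export
rms_metrics <- function(trial) {
  rms_e <- sqrt(mean(trial$e^2))
  du <- diff(trial$u) * trial$sample_rate
  c(rms_e = rms_e, rms_udot = sqrt(mean(du^2)))
}

#' Write or read a trial record as CSV
#'
#' The CSV carries columns `t`, `d`, `u`, `e` and a comment header with the
#' subject id, trial index and sample rate.
#'
#' @param trial a `"trial_record"`.
#' @param path file path.
#' @return `write_trial_csv` returns `path` invisibly; `read_trial_csv`
#'   returns a `"trial_record"`.
#' @export
write_trial_csv <- function(trial, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# subject_id=%s trial_index=%d sample_rate=%g warmup_discarded=%d",
                     trial$subject_id, trial$trial_index, trial$sample_rate,
                     as.integer(trial$warmup_discarded)), con)
  utils::write.csv(data.frame(t = trial$t, d = trial$d, u = trial$u,
                              e = trial$e),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  kv <- regmatches(hdr, gregexpr("[a-z_]+=[^ ]+", hdr))[[1]]
  meta <- stats::setNames(sub("^[a-z_]+=", "", kv), sub("=.*$", "", kv))
  df <- utils::read.csv(path, comment.char = "#")
  trial_record(subject_id = meta[["subject_id"]],
               trial_index = as.integer(meta[["trial_index"]]),
               t = df$t, d = df$d, u = df$u, e = df$e,
               sample_rate = as.numeric(meta[["sample_rate"]]),
               warmup_discarded = meta[["warmup_discarded"]] == "1")
}
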