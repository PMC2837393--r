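#' Hankel singular values of an LQG controller
#'
#' Computes the controller's Hankel singular values from its Gramians (the
#' controllability Gramian driven by the Kalman gain input, the
#' observability Gramian seen through the feedback-gain output) and
#' normalizes them by the first. The number of non-negligible values is the
#' effective dynamical order of the control strategy — the package's
#' complexity measure.
#'
#' @param controller an `"lqg_controller"` (or any stable `"ss"` given as
#'   `controller$sys`).
#' @param subject_id,trial_index optional identifiers carried through.
#' @return An object of class `"hsv_profile"`: list with `hsvs`
#'   (descending), `normalized` (divided by the first), `subject_id`,
#'   `trial_index`.
#' @export
controller_hsvs <- function(controller, subject_id = NA, trial_index = NA) {
  sys <- if (inherits(controller, "lqg_controller")) controller$sys
  else controller
  if (max(Re(eigen(sys$A, only.values = TRUE)$values)) >= -1e-12)
    stop("controller is not asymptotically stable as a standalone system")
  h <- balanced_hsv(sys)
  structure(list(hsvs = h, normalized = h / h[1],
                 subject_id = subject_id, trial_index = trial_index),
            class = "hsv_profile")
}

#' @export
print.hsv_profile <- function(x, ...) {
  cat("Controller HSVs (normalized):",
      paste(signif(x$normalized, 3), collapse = " "), "\n")
  invisible(x)
}

#' Relative endogenous-noise power implied by fitted parameters
#'
#' The derived noise measure: noise bandwidth times noise intensity divided
#' by the mean-square control-input velocity — the power of the endogenous
#' noise relative to the power of the exciting signal. Reported in log10.
#'
#' @param params a `"subject_params"`.
#' @param ms_udot mean-square control-input velocity of the trial(s)
#'   (e.g. `rms_metrics(trial)[["rms_udot"]]^2`); must be positive.
#' @return log10 of the measure (`-Inf` when the intensity is zero).
#' @export
derived_noise_measure <- function(params, ms_udot) {
  if (!is.finite(ms_udot) || ms_udot <= 0) stop("ms_udot must be positive")
  val <- params$noise_bandwidth * params$noise_intensity / ms_udot
  if (val == 0) -Inf else log10(val)
}

#' Welch comparisons of two cohorts' per-subject summaries
#'
#' Two-tailed Welch t-tests between groups for each supplied per-subject
#' quantity. Tests are computed on one value per subject (subject means),
#' never on pooled trials, to avoid repeated-measures bias.
#'
#' @param young,elderly data frames (or named lists of numeric vectors)
#'   with one row/element per subject and identical column names; columns
#'   are the per-subject summary quantities (typically log10 scale).
#' @return An object of class `"cohort_tests"`: data frame with columns
#'   `quantity`, `mean_young`, `mean_elderly`, `t`, `df`, `p`.
#' @export
cohort_tests <- function(young, elderly) {
  young <- as.data.frame(young); elderly <- as.data.frame(elderly)
  common <- intersect(names(young), names(elderly))
  if (length(common) == 0) stop("no common quantities to compare")
  if (nrow(young) < 2 || nrow(elderly) < 2)
    stop("need at least 2 subjects per group")
  rows <- lapply(common, function(nm) {
    a <- young[[nm]]; b <- elderly[[nm]]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 2 || length(b) < 2 ||
        (stats::sd(a) == 0 && stats::sd(b) == 0))
      stop("degenerate variance for quantity ", nm)
    tt <- stats::t.test(a, b, var.equal = FALSE)
    data.frame(quantity = nm, mean_young = mean(a), mean_elderly = mean(b),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_tests", "data.frame")
  out
}

#' @export
print.cohort_tests <- function(x, ...) {
  cat("Welch two-tailed comparisons (one value per subject):\n")
  df <- as.data.frame(x)
  df[, -1] <- signif(df[, -1], 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Response slowing induced by increased noise
#'
#' The computational experiment at the heart of the slowing hypothesis:
#' take fitted (young) models, scale the noise bandwidth, the noise
#' intensity, or the control-cost/multiplicative-noise parameter, redesign
#' the optimal controller, and report how the closed-loop response
#' magnitude and the cross-correlation latency of re-simulated trials
#' change. The optimal adaptation to more noise is a slower response —
#' smaller high-frequency |H_ud| — with the latency until response onset
#' unchanged.
#'
#' @param params_list list of `"subject_params"` (e.g. fitted young
#'   models).
#' @param constants a `"task_constants"`.
#' @param scale_factors numeric vector of multiplicative factors (> 0)
#'   applied to one parameter at a time.
#' @param which_params parameters to scale.
#' @param omega_probe frequencies (rad/s) at which |H_ud| is reported.
#' @param n_trials trials re-simulated per condition for the latency
#'   read-out (0 skips re-simulation).
#' @param seed integer seed for the re-simulations.
#' @return Data frame with one row per (model, parameter, factor):
#'   magnitudes at the probe frequencies, gain norm over the physical
#'   states `K_phys_norm`, and mean cross-correlation latency (`NA` when
#'   not simulated or not detected).
#' @export
slowing_experiment <- function(params_list, constants,
                               scale_factors = c(1, 4),
                               which_params = c("intensity", "bandwidth", "rho"),
                               omega_probe = c(5, 10, 20),
                               n_trials = 4L, seed = 21L) {
  if (any(scale_factors <= 0)) stop("scale_factors must be positive")
  d_list <- if (n_trials > 0)
    generate_perturbations(constants, n_trials, seed = seed) else NULL
  rows <- list()
  for (mi in seq_along(params_list)) {
    base <- params_list[[mi]]
    for (wp in which_params) {
      for (sf in scale_factors) {
        p <- base
        field <- switch(wp, intensity = "noise_intensity",
                        bandwidth = "noise_bandwidth", rho = "rho")
        p[[field]] <- p[[field]] * sf
        p <- subject_params(p$latency_tau, p$noise_intensity,
                            p$noise_bandwidth, p$rho)
        row <- tryCatch({
          plant <- assemble_plant(constants, p)
          ctrl <- design_lqg(plant)
          pr <- predicted_response(plant, ctrl, omega_probe)
          lat <- NA_real_
          if (n_trials > 0) {
            trs <- simulate_subject(constants, p, d_list,
                                    seed = seed + mi,
                                    subject_id = paste0("m", mi))
            lats <- vapply(trs, function(tr)
              suppressWarnings(latency_crosscorr(tr, constants)), numeric(1))
            lat <- mean(lats, na.rm = TRUE)
          }
          mags <- stats::setNames(as.list(Mod(pr$H_ud)),
                                  paste0("H_", omega_probe))
          c(list(model = mi, param = wp, factor = sf,
                 K_phys_norm = sqrt(sum(ctrl$K[-9]^2)),
                 latency = lat, failed = FALSE), mags)
        }, error = function(e) {
          c(list(model = mi, param = wp, factor = sf,
                 K_phys_norm = NA_real_, latency = NA_real_, failed = TRUE),
            stats::setNames(as.list(rep(NA_real_, length(omega_probe))),
                            paste0("H_", omega_probe)))
        })
        rows[[length(rows) + 1]] <- as.data.frame(row)
      }
    }
  }
  do.call(rbind, rows)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Generates perturbations, samples and simulates young and elderly
#' cohorts, estimates latencies (cross-correlation), fits the
#' optimal-control model per analyzed trial, computes controller HSVs and
#' cohort statistics, and writes the results to an output directory
#' (`cohort.json`, `latencies.csv`, `fits.csv`, `hsvs.csv`, `stats.csv`,
#' `report.txt`). Fully seeded: the same configuration and seed reproduce
#' identical outputs.
#'
#' @param out_dir output directory (created if missing); `NULL` skips
#'   writing.
#' @param constants a `"task_constants"`.
#' @param n_subjects subjects per group.
#' @param n_trials trials per subject (analysis uses trials 3 onward).
#' @param restarts,maxit fitting effort per trial (see [fit_lqg()]).
#' @param seed master integer seed; all stage seeds derive from it.
#' @param verbose print per-stage progress to stderr.
#' @return A list with `cohort` (subject truth and group labels), `trials`,
#'   `latencies`, `fits`, `hsvs`, `subject_summary`, `tests`.
#' @export
run_pipeline <- function(out_dir = NULL, constants = task_constants(),
                         n_subjects = 12L, n_trials = 10L, restarts = 2L,
                         maxit = 250L, seed = 1L, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t_start <- proc.time()[3]
  d_list <- generate_perturbations(constants, n_trials, seed = seed)
  specs <- list(young = cohort_spec("young", n_subjects, seed = seed + 1L),
                elderly = cohort_spec("elderly", n_subjects, seed = seed + 2L))
  cohort <- list()
  trials <- list()
  say("simulating %d + %d subjects (%d trials each)...",
      n_subjects, n_subjects, n_trials)
  for (grp in names(specs)) {
    pars <- sample_cohort(specs[[grp]])
    for (i in seq_along(pars)) {
      sid <- sprintf("%s%02d", substr(grp, 1, 1), i)
      cohort[[sid]] <- list(group = grp, params = pars[[i]])
      trials[[sid]] <- simulate_subject(constants, pars[[i]], d_list,
                                        seed = seed + 100L + length(cohort),
                                        subject_id = sid)
    }
  }
  analyzed <- 3:n_trials
  say("estimating cross-correlation latencies...")
  lat_rows <- list()
  for (sid in names(trials)) for (ti in analyzed) {
    lat <- suppressWarnings(latency_crosscorr(trials[[sid]][[ti]], constants))
    lat_rows[[length(lat_rows) + 1]] <-
      data.frame(subject = sid, group = cohort[[sid]]$group, trial = ti,
                 latency_s = lat)
  }
  latencies <- do.call(rbind, lat_rows)
  say("fitting the optimal-control model per trial...")
  fit_rows <- list(); hsv_rows <- list()
  for (sid in names(trials)) {
    t_subj <- proc.time()[3]
    for (ti in analyzed) {
      f <- fit_lqg(trials[[sid]][[ti]], constants, restarts = restarts,
                   maxit = maxit, seed = seed + 17L)
      hs <- tryCatch(controller_hsvs(f$controller, sid, ti),
                     error = function(e) NULL)
      met <- rms_metrics(trials[[sid]][[ti]])
      fit_rows[[length(fit_rows) + 1]] <- data.frame(
        subject = sid, group = cohort[[sid]]$group, trial = ti,
        t(f$log10), cost = f$cost, converged = f$converged,
        latency_cc = f$latency_crosscorr,
        implied_rms_e = f$implied_rms_e, observed_rms_e = f$observed_rms_e,
        rms_e = met[["rms_e"]], rms_udot = met[["rms_udot"]],
        ctrl_stable = !is.null(hs))
      if (!is.null(hs))
        hsv_rows[[length(hsv_rows) + 1]] <- data.frame(
          subject = sid, group = cohort[[sid]]$group, trial = ti,
          t(stats::setNames(hs$hsvs, paste0("hsv", seq_along(hs$hsvs)))))
    }
    say("  %s: %d trials fitted (%.1f s)", sid, length(analyzed),
        proc.time()[3] - t_subj)
  }
  fits <- do.call(rbind, fit_rows)
  hsvs <- do.call(rbind, hsv_rows)
  say("aggregating per-subject summaries and group tests...")
  subject_summary <- subject_level_summary(cohort, fits, latencies, hsvs)
  test_cols <- c("latency", "intensity", "bandwidth", "rho",
                 "latency_cc_log10", "latency_fit_log10", "log_rms_udot",
                 "noise_measure", "log_nhsv3", "log_nhsv4")
  tests <- cohort_tests(
    subject_summary[subject_summary$group == "young", test_cols],
    subject_summary[subject_summary$group == "elderly", test_cols])
  out <- list(cohort = cohort, trials = trials, latencies = latencies,
              fits = fits, hsvs = hsvs, subject_summary = subject_summary,
              tests = tests, constants = constants, seed = seed)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  say("pipeline finished in %.1f s", proc.time()[3] - t_start)
  invisible(out)
}

# One row per subject: mean log10 fitted parameters, both latency measures,
# effort/performance metrics, derived noise measure, normalized HSV means.
subject_level_summary <- function(cohort, fits, latencies, hsvs) {
  rows <- lapply(names(cohort), function(sid) {
    fsub <- fits[fits$subject == sid, ]
    lsub <- latencies[latencies$subject == sid, ]
    truth <- params_log10(cohort[[sid]]$params)
    ms_udot <- mean(fsub$rms_udot^2)
    mean_params <- subject_params(10^mean(fsub$latency),
                                  10^mean(fsub$intensity),
                                  10^mean(fsub$bandwidth),
                                  10^mean(fsub$rho))
    hsub <- hsvs[hsvs$subject == sid, grep("^hsv", names(hsvs)), drop = FALSE]
    nh3 <- nh4 <- NA_real_
    if (nrow(hsub) > 0) {
      norm1 <- mean(hsub$hsv1)
      nh3 <- mean(hsub$hsv3) / norm1
      nh4 <- mean(hsub$hsv4) / norm1
    }
    data.frame(subject = sid, group = cohort[[sid]]$group,
               latency = mean(fsub$latency),
               intensity = mean(fsub$intensity),
               bandwidth = mean(fsub$bandwidth),
               rho = mean(fsub$rho),
               true_latency = truth[["latency"]],
               true_intensity = truth[["intensity"]],
               true_bandwidth = truth[["bandwidth"]],
               true_rho = truth[["rho"]],
               latency_cc_s = mean(lsub$latency_s, na.rm = TRUE),
               latency_cc_sd = stats::sd(lsub$latency_s, na.rm = TRUE),
               latency_fit_s = mean(10^fsub$latency),
               latency_fit_sd = stats::sd(10^fsub$latency),
               latency_cc_log10 = log10(mean(lsub$latency_s, na.rm = TRUE)),
               latency_fit_log10 = mean(fsub$latency),
               rms_e = mean(fsub$rms_e),
               rms_udot = mean(fsub$rms_udot),
               log_rms_udot = log10(mean(fsub$rms_udot)),
               rms_ratio = mean(fsub$implied_rms_e / fsub$observed_rms_e),
               noise_measure = derived_noise_measure(mean_params, ms_udot),
               log_nhsv3 = log10(nh3), log_nhsv4 = log10(nh4))
  })
  do.call(rbind, rows)
}

write_pipeline_outputs <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cj <- lapply(out$cohort, function(s)
    list(group = s$group, log10_params = as.list(params_log10(s$params))))
  jsonlite::write_json(cj, file.path(out_dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(out$latencies, file.path(out_dir, "latencies.csv"),
                   row.names = FALSE)
  utils::write.csv(out$fits, file.path(out_dir, "fits.csv"),
                   row.names = FALSE)
  utils::write.csv(out$hsvs, file.path(out_dir, "hsvs.csv"),
                   row.names = FALSE)
  utils::write.csv(out$subject_summary,
                   file.path(out_dir, "subject_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(out$tests), file.path(out_dir, "stats.csv"),
                   row.names = FALSE)
  writeLines(pipeline_report_text(out), file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

pipeline_report_text <- function(out) {
  ss <- out$subject_summary
  y <- ss[ss$group == "young", ]; e <- ss[ss$group == "elderly", ]
  tst <- as.data.frame(out$tests)
  fmt <- function(x, d = 3) formatC(x, digits = d, format = "f")
  lines <- c(
    "Synthetic visuomotor tracking cohort analysis",
    sprintf("seed %d; %d young, %d elderly subjects", out$seed, nrow(y), nrow(e)),
    "",
    "Latency (cross-correlation method):",
    sprintf("  young %s ms, elderly %s ms (means of subject means)",
            fmt(1000 * mean(y$latency_cc_s), 0), fmt(1000 * mean(e$latency_cc_s), 0)),
    sprintf("  median intra-subject SD: young %s ms, elderly %s ms",
            fmt(1000 * stats::median(y$latency_cc_sd), 0),
            fmt(1000 * stats::median(e$latency_cc_sd), 0)),
    "Latency (model-based):",
    sprintf("  young %s ms, elderly %s ms",
            fmt(1000 * mean(y$latency_fit_s), 0), fmt(1000 * mean(e$latency_fit_s), 0)),
    sprintf("  median intra-subject SD: young %s ms, elderly %s ms",
            fmt(1000 * stats::median(y$latency_fit_sd), 0),
            fmt(1000 * stats::median(e$latency_fit_sd), 0)),
    "",
    "Implied vs observed RMS error (per-subject mean ratio):",
    sprintf("  young %s, elderly %s", fmt(mean(y$rms_ratio)), fmt(mean(e$rms_ratio))),
    "",
    "Effort/performance (per-subject means):",
    sprintf("  young:   RMS e %s, RMS udot %s", fmt(mean(y$rms_e)), fmt(mean(y$rms_udot))),
    sprintf("  elderly: RMS e %s, RMS udot %s", fmt(mean(e$rms_e)), fmt(mean(e$rms_udot))),
    "",
    "Group comparisons (Welch two-tailed t on subject means):")
  for (i in seq_len(nrow(tst)))
    lines <- c(lines, sprintf("  %-18s t = %s, p = %s", tst$quantity[i],
                              fmt(tst$t[i], 2), fmt(tst$p[i], 4)))
  lines
}
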