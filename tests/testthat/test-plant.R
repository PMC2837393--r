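tc <- task_constants()

test_that("subsystem filters have the prescribed frequency-domain shapes", {
  pf <- build_perturbation_filter(tc)
  a <- 2 * pi * tc$pert_cutoff
  expect_equal(Mod(fr1(pf, 1e-3)), 1, tolerance = 1e-5)       # unit DC gain
  expect_equal(Mod(fr1(pf, a)), 1 / sqrt(2), tolerance = 1e-9) # corner
  # white noise of intensity q through the filter: stationary variance q*a/2
  q <- 0.4
  P <- solve_lyapunov(pf$A, pf$B %*% t(pf$B) * q)
  expect_equal(P[1, 1], q * a / 2, tolerance = 1e-9)

  nf <- build_noise_filter(4)
  expect_equal(nstates(nf), 2L)
  ev <- eigen(nf$A, only.values = TRUE)$values
  expect_equal(sort(Re(ev)), c(-4, -4), tolerance = 1e-9)     # critical damping
  expect_equal(max(abs(Im(ev))), 0, tolerance = 1e-9)
  expect_equal(Mod(fr1(nf, 1e-3)), 1, tolerance = 1e-5)
  expect_equal(Mod(fr1(nf, 4)), 1 / 2, tolerance = 1e-9)      # double pole at corner
  # no overshoot in the step response
  dn <- discretize_zoh(nf, 0.001)
  ystep <- simulate_ss(dn, rep(1, 5000))[, 1]
  expect_lte(max(ystep), 1 + 1e-9)

  df <- build_diff_filter(100)
  expect_equal(Mod(fr1(df, 1)), 1, tolerance = 0.01)          # gain ~ omega below corner
  expect_equal(Mod(fr1(df, 3)), 3, tolerance = 0.01)
  expect_equal(Mod(fr1(df, 100)), 100 / sqrt(2), tolerance = 1e-6)
  # DC input killed
  dd <- discretize_zoh(df, 0.01)
  ydc <- simulate_ss(dd, rep(1, 2000))[, 1]
  expect_lt(abs(ydc[2000]), 1e-8)

  expect_error(build_noise_filter(-1), "positive")
  expect_error(build_diff_filter(0), "positive")
})

test_that("assembled plant has nine labeled states and integrator error dynamics", {
  sp <- young_params()
  pl <- assemble_plant(tc, sp)
  expect_equal(nstates(pl$sys), 9L)
  expect_equal(length(pl$states$delay), 4L)
  expect_equal(pl$sys$state_labels[1], "cursor")

  # with u_ideal = 0 and noise off, e integrates the filtered perturbation:
  # oracle = fine-step simulation of the prefilter plus trapezoidal
  # quadrature of its output, sampled back onto the coarse grid
  dt <- 1 / tc$sample_rate
  sysd <- discretize_zoh(pl$sys, dt)
  set.seed(4)
  n_c <- 2000; refine <- 20
  w <- rnorm(n_c, sd = sqrt(tc$pert_white_intensity * tc$sample_rate))
  U <- cbind(0, w, 0, 0)
  e_sim <- simulate_ss(sysd, U)[, 2]
  pf_fine <- discretize_zoh(build_perturbation_filter(tc), dt / refine)
  d_fine <- simulate_ss(pf_fine, rep(w, each = refine))[, 1]
  e_fine <- c(0, cumsum((d_fine[-1] + d_fine[-length(d_fine)]) / 2)) *
    dt / refine
  e_quad <- e_fine[seq(1, by = refine, length.out = n_c)]
  expect_equal(e_sim, e_quad, tolerance = 1e-5)

  # vanishing delay: y tracks e with negligible lag on a ramp input
  sp_fast <- subject_params(1e-4, sp$noise_intensity, sp$noise_bandwidth, sp$rho)
  pl_fast <- assemble_plant(tc, sp_fast)
  sysf <- discretize_zoh(pl_fast$sys, dt)
  Ur <- cbind(seq(0, 1, length.out = 300), 0, 0, 0)  # ramp in u_ideal
  out <- simulate_ss(sysf, Ur)
  lag_err <- max(abs(out[100:300, 1] - out[100:300, 2]))
  ramp_rate <- max(abs(diff(out[, 2]))) / dt
  expect_lt(lag_err / ramp_rate, 1e-3)               # <= 1 ms effective lag
})

test_that("LQG design satisfies the separation principle and responds to parameters", {
  sp <- young_params()
  pl <- assemble_plant(tc, sp)
  ct <- design_lqg(pl)
  expect_equal(nstates(ct$sys), 9L)
  expect_lt(max(ct$residuals), 1e-8)

  # closed-loop eigenvalues = LQR eigenvalues + estimator eigenvalues
  A <- pl$sys$A; B1 <- pl$sys$B[, 1, drop = FALSE]
  Cy <- pl$sys$C[1, , drop = FALSE]
  cl <- predicted_response(pl, ct, c(1))  # also asserts stability
  Acl <- rbind(cbind(A, -B1 %*% ct$K),
               cbind(ct$L %*% Cy, ct$sys$A))
  ecl <- eigen(Acl, only.values = TRUE)$values
  esep <- c(eigen(A - B1 %*% ct$K, only.values = TRUE)$values,
            eigen(A - ct$L %*% Cy, only.values = TRUE)$values)
  mismatch <- vapply(ecl, function(z) min(abs(z - esep)), numeric(1))
  expect_lt(max(mismatch / (1 + Mod(ecl))), 1e-6)

  # doubling rho shrinks the physical-state feedback gains
  sp2 <- subject_params(sp$latency_tau, sp$noise_intensity,
                        sp$noise_bandwidth, sp$rho * 2)
  ct2 <- design_lqg(assemble_plant(tc, sp2))
  expect_lt(sqrt(sum(ct2$K[-9]^2)), sqrt(sum(ct$K[-9]^2)))

  # 10x noise intensity slows the estimator's slowest eigenvalue
  sp3 <- subject_params(sp$latency_tau, sp$noise_intensity * 10,
                        sp$noise_bandwidth, sp$rho)
  ct3 <- design_lqg(assemble_plant(tc, sp3))
  slowest <- function(ctrl) max(Re(eigen(A - ctrl$L %*% Cy,
                                         only.values = TRUE)$values))
  expect_gt(slowest(ct3), slowest(ct))

  # very large rho: control gain collapses toward zero
  sp4 <- subject_params(sp$latency_tau, sp$noise_intensity,
                        sp$noise_bandwidth, 1e6)
  ct4 <- design_lqg(assemble_plant(tc, sp4))
  expect_lt(sqrt(sum(ct4$K[-9]^2)), 1e-2 * sqrt(sum(ct$K[-9]^2)))
})

test_that("predicted closed-loop response rejects DC and rolls off", {
  sp <- young_params()
  pl <- assemble_plant(tc, sp)
  ct <- design_lqg(pl)
  w <- c(0.01, 1, 30)
  pr <- predicted_response(pl, ct, w)
  expect_equal(Mod(pr$H_ud[1]), 1, tolerance = 0.02)
  expect_equal(abs(Arg(pr$H_ud[1])) * 180 / pi, 180, tolerance = 2)
  expect_lt(Mod(pr$H_ud[3]), Mod(pr$H_ud[2]))
  # zero endogenous noise: spectrum is the perturbation channel alone
  sp0 <- subject_params(sp$latency_tau, 0, sp$noise_bandwidth, sp$rho)
  pl0 <- assemble_plant(tc, sp0)
  ct0 <- design_lqg(pl0)
  pr0 <- predicted_response(pl0, ct0, w)
  expect_equal(pr0$S_uu, Mod(pr0$H_wu)^2 * tc$pert_white_intensity,
               tolerance = 1e-12)
})

test_that("response magnitude weakly decreases with each noise parameter", {
  # monotone slowing holds through the response band; near 30 rad/s the
  # response is orders of magnitude below the perturbation band and the
  # ordering saturates, so the probe grid stops at 20 rad/s
  sp <- young_params()
  grid <- c(5, 8, 12, 16, 20)
  base <- predicted_response(assemble_plant(tc, sp),
                             design_lqg(assemble_plant(tc, sp)), grid)
  bump <- list(
    intensity = subject_params(sp$latency_tau, sp$noise_intensity * 4,
                               sp$noise_bandwidth, sp$rho),
    bandwidth = subject_params(sp$latency_tau, sp$noise_intensity,
                               sp$noise_bandwidth * 2, sp$rho),
    rho = subject_params(sp$latency_tau, sp$noise_intensity,
                         sp$noise_bandwidth, sp$rho * 4))
  for (nm in names(bump)) {
    pl2 <- assemble_plant(tc, bump[[nm]])
    pr2 <- predicted_response(pl2, design_lqg(pl2), grid)
    expect_true(all(Mod(pr2$H_ud) <= Mod(base$H_ud) * (1 + 1e-9)),
                info = paste("parameter:", nm))
  }
})

test_that("implied RMS error matches Monte-Carlo simulation for a noise-driven loop", {
  sp <- young_params()
  pl <- assemble_plant(tc, sp)
  ct <- design_lqg(pl)
  # no perturbation: implied value reduces to the stationary noise term
  n_zero <- round(tc$trial_length * tc$sample_rate)
  imp <- implied_rms_error(ct, tc, sp, rep(0, n_zero))
  # 600 s closed-loop noise-driven simulation (model world)
  cl <- visuotrack:::closed_loop(pl, ct)
  dsys <- discretize_zoh(ss(cl$A, cl$B[, 3, drop = FALSE],
                            cl$C[2, , drop = FALSE]), 0.01)
  set.seed(8)
  nw <- rnorm(60000, sd = sqrt(sp$noise_intensity * tc$sample_rate))
  e_sim <- simulate_ss(dsys, nw)[, 1]
  rms_mc <- sqrt(mean(e_sim[-(1:2000)]^2))
  expect_equal(imp, rms_mc, tolerance = 0.1)
  # zero noise and zero perturbation: implied error is exactly zero
  sp0 <- subject_params(sp$latency_tau, 0, sp$noise_bandwidth, sp$rho)
  ct0 <- design_lqg(assemble_plant(tc, sp0))
  expect_equal(implied_rms_error(ct0, tc, sp0, rep(0, n_zero)), 0)
})

test_that("parameter log10 representation round-trips exactly", {
  sp <- subject_params(0.2468, 0.00137, 9.31, 0.188)
  expect_identical(params_log10(params_from_log10(params_log10(sp))),
                   params_log10(sp))
  x <- c(latency = -0.59, intensity = -2.71, bandwidth = 0.93, rho = -0.7)
  expect_identical(params_log10(params_from_log10(x)), x)
  expect_error(subject_params(-0.1, 1, 1, 1), "latency")
  expect_error(subject_params(0.2, -1, 1, 1), "intensity")
})
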