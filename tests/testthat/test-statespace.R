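test_that("series connection multiplies transfer functions and stacks states", {
  s1 <- first_order(1)            # 1/(s+1)
  s2 <- first_order(2)            # 1/(s+2)
  cas <- ss_series(s1, s2)
  expect_equal(nstates(cas), 2L)

  w <- c(0.3, 1, 5)
  expect_equal(fr1(cas, w), fo_tf(1, 1, 1, w) * fo_tf(2, 1, 1, w),
               tolerance = 1e-10)

  # identity leaves a system unchanged; a 1-state + 2-state cascade has 3 states
  noisef <- build_noise_filter(4)
  expect_equal(nstates(ss_series(ss_identity(1), noisef)), 2L)
  expect_equal(fr1(ss_series(ss_identity(1), s1), w), fo_tf(1, 1, 1, w),
               tolerance = 1e-12)
  expect_equal(nstates(ss_series(s1, noisef)), 3L)

  expect_error(ss_series(ss(-1, 1, diag(1)), ss_identity(2)), "port mismatch")
})

test_that("negative feedback of gain k around an integrator gives 1/(s+k)", {
  integ <- ss(0, 1, 1)
  k <- 2.5
  cl <- ss_feedback(integ, static_gain(k), sign = -1)
  expect_equal(as.numeric(eigen(cl$A, only.values = TRUE)$values[1]), -k,
               tolerance = 1e-12)
  w <- c(0.5, 2, 10)
  expect_equal(fr1(cl, w), 1 / (1i * w + k), tolerance = 1e-10)

  # zero controller: closed loop equals open loop
  cl0 <- ss_feedback(first_order(1), static_gain(0))
  expect_equal(fr1(cl0, w), fo_tf(1, 1, 1, w), tolerance = 1e-12)
})

test_that("interconnection frequency response equals algebraic composition", {
  set.seed(11)
  wgrid <- 10^seq(-1, 1.5, length.out = 50)
  for (rep in 1:5) {
    g1 <- rand_stable(3); g2 <- rand_stable(2)
    cas <- ss_series(g1, g2)
    expect_equal(fr1(cas, wgrid), fr1(g1, wgrid) * fr1(g2, wgrid),
                 tolerance = 1e-8)
    cl <- ss_feedback(g1, g2, sign = -1)
    expect_equal(fr1(cl, wgrid),
                 fr1(g1, wgrid) / (1 + fr1(g1, wgrid) * fr1(g2, wgrid)),
                 tolerance = 1e-7)
  }
})

test_that("Pade delay is all-pass with the correct low-frequency phase", {
  d <- pade_delay(0.25, 4)
  expect_equal(nstates(d), 4L)
  expect_equal(abs(fr1(d, c(0.1, 1, 10))), rep(1, 3), tolerance = 1e-9)
  # phase at omega = 4 rad/s should match exp(-i w tau): -1.0 rad
  expect_equal(Arg(fr1(d, 4)), -1.0, tolerance = 1e-3)
  # broader phase agreement below the approximation's breakdown frequency
  w <- seq(0.5, 12, by = 0.5)
  expect_equal(Arg(fr1(d, w)), -w * 0.25, tolerance = 1e-3)

  # tau = 0 gives a unit static gain
  expect_equal(nstates(pade_delay(0)), 0L)
  expect_error(pade_delay(-0.1), "tau")
})

test_that("CARE solver matches closed forms and passes residual checks", {
  # scalar A=0, B=1, Q=1, R=1: -P^2 + 1 = 0 -> P = 1, K = 1
  out <- solve_care(0, 1, 1, 1)
  expect_equal(out$P[1, 1], 1, tolerance = 1e-10)
  expect_equal(out$K[1, 1], 1, tolerance = 1e-10)

  # Q = 0 with A Hurwitz -> P = 0
  out0 <- solve_care(-2, 1, 0, 1)
  expect_equal(out0$P[1, 1], 0, tolerance = 1e-12)

  # independent oracle: stable eigenvector basis of the Hamiltonian matrix
  care_oracle <- function(A, B, Q, R) {
    n <- nrow(A)
    G <- B %*% solve(R) %*% t(B)
    H <- rbind(cbind(A, -G), cbind(-Q, -t(A)))
    eh <- eigen(H)
    idx <- which(Re(eh$values) < 0)
    V <- eh$vectors[, idx, drop = FALSE]
    Re(V[(n + 1):(2 * n), , drop = FALSE] %*% solve(V[1:n, , drop = FALSE]))
  }
  set.seed(21)
  for (rep in 1:20) {
    n <- 3
    sys <- rand_stable(n)
    Q <- crossprod(matrix(rnorm(n * n), n))
    out <- solve_care(sys$A, sys$B, Q, matrix(1))
    expect_equal(out$P, care_oracle(sys$A, sys$B, Q, matrix(1)),
                 tolerance = 1e-7)
    res <- t(sys$A) %*% out$P + out$P %*% sys$A -
      out$P %*% sys$B %*% t(sys$B) %*% out$P + Q
    expect_lt(norm(res, "F"), 1e-8 * (1 + norm(out$P, "F")))
    expect_true(isSymmetric(out$P, tol = 1e-9))
    expect_gte(min(eigen(out$P, symmetric = TRUE, only.values = TRUE)$values), -1e-9)
    Acl <- sys$A - sys$B %*% out$K
    expect_lt(max(Re(eigen(Acl, only.values = TRUE)$values)), 0)
  }
  expect_error(solve_care(1, 0, diag(1), 1), "Riccati")
  expect_error(solve_care(0, 1, 1, -1), "positive definite")
})

test_that("Lyapunov solver matches closed form and Kronecker oracle", {
  expect_equal(solve_lyapunov(-1, 2)[1, 1], 1, tolerance = 1e-12)
  expect_equal(solve_lyapunov(-3, 0)[1, 1], 0, tolerance = 1e-14)
  set.seed(31)
  for (rep in 1:20) {
    sys <- rand_stable(4)
    Q <- crossprod(matrix(rnorm(16), 4))
    P <- solve_lyapunov(sys$A, Q)
    expect_equal(P, lyap_oracle(sys$A, Q), tolerance = 1e-9)
    expect_lt(norm(sys$A %*% P + P %*% t(sys$A) + Q, "F"),
              1e-9 * (1 + norm(P, "F")))
  }
  expect_error(solve_lyapunov(1, 1), "Hurwitz")
})

test_that("Hankel singular values match closed forms and are similarity invariant", {
  # first order A=-a, B=b, C=c: Wc = b^2/2a, Wo = c^2/2a, HSV = |bc|/2a
  expect_equal(balanced_hsv(ss(-1, 2, 3)), 3, tolerance = 1e-10)
  expect_equal(balanced_hsv(ss(-4, 1, 1)), 1 / 8, tolerance = 1e-10)

  # exact invariance under the diagonal rescaling T = diag(10, 0.1)
  two <- ss(matrix(c(-1, 0.3, -0.2, -2), 2), c(1, 0.5), matrix(c(1, 2), 1))
  Td <- diag(c(10, 0.1))
  two2 <- ss(solve(Td, two$A %*% Td), solve(Td, two$B), two$C %*% Td)
  h_two <- balanced_hsv(two)
  expect_lt(max(abs(balanced_hsv(two2) - h_two)) / h_two[1], 1e-8)

  # invariance under random badly scaled transformations (relative to the
  # dominant value, since trailing HSVs lose accuracy with the conditioning
  # of the transformation)
  set.seed(41)
  for (rep in 1:10) {
    sys <- rand_stable(3)
    h1 <- balanced_hsv(sys)
    T <- diag(c(10, 0.1, 3)) %*% matrix(rnorm(9), 3)
    while (abs(det(T)) < 1e-3) T <- diag(c(10, 0.1, 3)) %*% matrix(rnorm(9), 3)
    sys2 <- ss(solve(T, sys$A %*% T), solve(T, sys$B), sys$C %*% T)
    expect_lt(max(abs(balanced_hsv(sys2) - h1)) / h1[1], 1e-6)
    expect_false(is.unsorted(rev(h1)))
  }

  # two well-separated modes: HSVs near the per-mode closed forms
  sep <- ss(diag(c(-1, -100)), c(2, 40), matrix(c(3, 5), 1))
  expect_equal(sort(balanced_hsv(sep), decreasing = TRUE),
               sort(c(2 * 3 / 2, 40 * 5 / 200), decreasing = TRUE),
               tolerance = 0.05)
  expect_error(balanced_hsv(ss(0.1, 1, 1)), "stable")
})

test_that("frequency response matches closed forms and flags marginal poles", {
  expect_equal(fr1(first_order(1), 1), (1 - 1i) / 2, tolerance = 1e-12)
  integ <- ss(0, 1, 1)
  r <- fr1(integ, 0.1)
  expect_equal(Mod(r), 10, tolerance = 1e-12)
  expect_equal(Arg(r), -pi / 2, tolerance = 1e-12)
  # static gain
  rD <- freqresp(ss_identity(1), c(1, 2))
  expect_equal(Mod(rD$values[1, 1, ]), c(1, 1))
  # marginal pole on the grid
  osc <- ss(matrix(c(0, -1, 1, 0), 2), c(1, 0), matrix(c(1, 0), 1))
  expect_error(freqresp(osc, 1), "marginal pole")
  expect_error(freqresp(first_order(1), c(2, 1)), "ascending")
})

test_that("ZOH discretization matches continuous-time responses at samples", {
  # A=-1, step input: y(t) = 1 - exp(-t)
  d <- discretize_zoh(first_order(1), 0.01)
  y <- simulate_ss(d, rep(1, 101))
  expect_equal(y[101, 1], 1 - exp(-1), tolerance = 1e-6)

  # integrator ramp: constant input 1 for 10 s -> 10
  di <- discretize_zoh(ss(0, 1, 1), 0.01)
  yi <- simulate_ss(di, rep(1, 1001))
  expect_equal(yi[1001, 1], 10, tolerance = 1e-8)

  # zero input -> identically zero
  expect_equal(max(abs(simulate_ss(d, rep(0, 50)))), 0)

  # random stable systems vs matrix-exponential step-response oracle
  set.seed(51)
  for (rep in 1:5) {
    sys <- rand_stable(3)
    dt <- 0.02
    dd <- discretize_zoh(sys, dt)
    N <- 200
    y <- simulate_ss(dd, rep(1, N + 1))
    # oracle: x(t) = A^{-1} (expm(A t) - I) B for step input
    t_end <- N * dt
    xT <- solve(sys$A, (as.matrix(Matrix::expm(sys$A * t_end)) - diag(3)) %*% sys$B)
    expect_equal(y[N + 1, 1], (sys$C %*% xT)[1, 1], tolerance = 1e-8)
  }
})

test_that("state-space JSON round trip preserves matrices", {
  sys <- rand_stable(3, m = 2, p = 1)
  js <- ss_to_json(sys)
  back <- jsonlite::fromJSON(js)
  expect_equal(matrix(back$A, 3, 3), sys$A, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$state_labels, sys$state_labels)
})
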