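#' Construct a continuous-time linear state-space model
#'
#' Builds the `"ss"` object used throughout the package: a continuous-time
#' linear time-invariant system
#' \deqn{\dot x = A x + B u, \qquad y = C x + D u.}
#' All subsystems (perturbation prefilter, endogenous-noise prefilter, Pade
#' delay, differentiator), the assembled tracking plant, the LQG controller
#' and every closed loop are represented this way.
#'
#' @param A square state matrix (n x n), units 1/s on the states.
#' @param B input matrix (n x m).
#' @param C output matrix (p x n).
#' @param D feedthrough matrix (p x m); defaults to zeros.
#' @param state_labels optional character vector of state names, length n.
#' @return An object of class `"ss"`: a list with elements `A`, `B`, `C`,
#'   `D` (numeric matrices) and `state_labels`.
#' @examples
#' sys <- ss(-1, 1, 1)      # first-order lag 1/(s+1)
#' nstates(sys)
#' @export
ss <- function(A, B, C, D = NULL, state_labels = NULL) {
  A <- as_matrix(A); B <- as_matrix(B); C <- as_matrix(C)
  n <- nrow(A)
  if (ncol(A) != n) stop("A must be square")
  if (n > 0 && nrow(B) != n) stop("B must have as many rows as A (", n, "), got ", nrow(B))
  if (n > 0 && ncol(C) != n) stop("C must have as many columns as A (", n, "), got ", ncol(C))
  if (is.null(D)) D <- matrix(0, nrow(C), ncol(B)) else D <- as_matrix(D)
  if (nrow(D) != nrow(C) || ncol(D) != ncol(B))
    stop("D must be ", nrow(C), " x ", ncol(B))
  if (!all(is.finite(A)) || !all(is.finite(B)) || !all(is.finite(C)) || !all(is.finite(D)))
    stop("state-space matrices must have finite entries")
  if (is.null(state_labels)) state_labels <- if (n > 0) paste0("x", seq_len(n)) else character(0)
  if (length(state_labels) != n) stop("state_labels must have length ", n)
  structure(list(A = A, B = B, C = C, D = D,
                 state_labels = as.character(state_labels)),
            class = "ss")
}

as_matrix <- function(x) {
  if (is.matrix(x)) return(matrix(as.numeric(x), nrow(x), ncol(x)))
  x <- as.numeric(x)
  if (length(x) == 0) matrix(0, 0, 0) else matrix(x, length(x), 1)
}

#' @rdname ss
#' @param sys an `"ss"` object.
#' @export
nstates <- function(sys) nrow(sys$A)

#' @export
print.ss <- function(x, ...) {
  cat("Continuous-time state-space model: ",
      nstates(x), " states, ", ncol(x$B), " input(s), ", nrow(x$C),
      " output(s)\n", sep = "")
  cat("states:", paste(x$state_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Identity (static unity-gain) system
#'
#' @param m number of inputs/outputs.
#' @return A zero-state `"ss"` with `D = I`.
#' @export
ss_identity <- function(m = 1L) {
  ss(matrix(0, 0, 0), matrix(0, 0, m), matrix(0, m, 0), diag(m),
     state_labels = character(0))
}

#' Series interconnection of two systems
#'
#' Returns the cascade `sys2 o sys1` (the output of `sys1` feeds the input
#' of `sys2`), so the transfer function is `G2(s) G1(s)`.
#'
#' @param sys1,sys2 `"ss"` objects; the output dimension of `sys1` must
#'   equal the input dimension of `sys2`.
#' @return An `"ss"` object with `nstates(sys1) + nstates(sys2)` states.
#' @export
ss_series <- function(sys1, sys2) {
  p1 <- nrow(sys1$C); m2 <- ncol(sys2$B)
  if (p1 != m2)
    stop("port mismatch in series connection: sys1 has ", p1,
         " output(s) but sys2 has ", m2, " input(s)")
  n1 <- nstates(sys1); n2 <- nstates(sys2)
  A <- rbind(cbind(sys1$A, matrix(0, n1, n2)),
             cbind(sys2$B %*% sys1$C, sys2$A))
  B <- rbind(sys1$B, sys2$B %*% sys1$D)
  C <- cbind(sys2$D %*% sys1$C, sys2$C)
  D <- sys2$D %*% sys1$D
  ss(A, B, C, D, state_labels = c(sys1$state_labels, sys2$state_labels))
}

#' Close a feedback loop around a plant and controller
#'
#' Connects `controller` from the plant output back to the plant input:
#' `u = r + sign * C(y)`, where `r` is the new exogenous input. The default
#' `sign = -1` is the negative feedback used in the tracking loop.
#'
#' @param plant,controller `"ss"` objects with compatible ports.
#' @param sign `+1` or `-1` feedback sign.
#' @return The closed-loop `"ss"` from `r` to the plant output, with
#'   `nstates(plant) + nstates(controller)` states.
#' @export
ss_feedback <- function(plant, controller, sign = -1) {
  if (!sign %in% c(-1, 1)) stop("sign must be +1 or -1")
  if (nrow(plant$C) != ncol(controller$B))
    stop("plant output dimension ", nrow(plant$C),
         " does not match controller input dimension ", ncol(controller$B))
  if (nrow(controller$C) != ncol(plant$B))
    stop("controller output dimension ", nrow(controller$C),
         " does not match plant input dimension ", ncol(plant$B))
  n1 <- nstates(plant); n2 <- nstates(controller)
  m <- ncol(plant$B); p <- nrow(plant$C)
  # well-posedness: I - sign * D1 D2 must be invertible
  M <- diag(m) - sign * controller$D %*% plant$D
  if (rcond_safe(M) < 1e-12)
    stop("algebraic loop: feedthrough coupling is singular")
  Mi <- solve(M)
  D1 <- plant$D; D2 <- controller$D
  # u = r + sign*C2 x2 + sign*D2 (C1 x1 + D1 u)  =>  u = Mi (r + sign*C2 x2 + sign*D2 C1 x1)
  A <- rbind(
    cbind(plant$A + sign * plant$B %*% Mi %*% D2 %*% plant$C,
          sign * plant$B %*% Mi %*% controller$C),
    cbind(controller$B %*% (plant$C + sign * D1 %*% Mi %*% D2 %*% plant$C),
          controller$A + sign * controller$B %*% D1 %*% Mi %*% controller$C))
  B <- rbind(plant$B %*% Mi, controller$B %*% D1 %*% Mi)
  C <- cbind(plant$C + sign * D1 %*% Mi %*% D2 %*% plant$C,
             sign * D1 %*% Mi %*% controller$C)
  D <- D1 %*% Mi
  ss(A, B, C, D, state_labels = c(plant$state_labels, controller$state_labels))
}

rcond_safe <- function(M) {
  if (length(M) == 1) return(abs(M[1]))
  tryCatch(rcond(M), error = function(e) 0)
}

#' Pade approximation of a pure time delay
#'
#' Diagonal (n, n) Pade rational approximation of `exp(-s * tau)`, realized
#' in controllable canonical form. The approximation is all-pass (unit
#' magnitude at every frequency) with phase approximating `-omega * tau` at
#' low frequency; it is what makes a finite-dimensional LQG design possible
#' with a response latency in the loop.
#'
#' @param tau delay in seconds (`tau >= 0`).
#' @param order approximation order (default 4).
#' @return An `"ss"` with `order` states (`tau = 0` gives the identity).
#' @examples
#' d <- pade_delay(0.25, 4)
#' abs(freqresp(d, 1)$values)   # == 1: all-pass
#' @export
pade_delay <- function(tau, order = 4L) {
  if (length(tau) != 1 || !is.finite(tau) || tau < 0) stop("tau must be >= 0")
  order <- as.integer(order)
  if (order < 1) stop("order must be >= 1")
  if (tau == 0) return(ss_identity(1))
  n <- order
  k <- 0:n
  # coefficients of P(x) = sum c_k x^k with den = P(tau*s), num = P(-tau*s);
  # realized in the normalized variable sigma = s*tau and then time-scaled,
  # with a diagonal grading of the companion states so the matrices stay
  # well conditioned.
  cks <- exp(lfactorial(2 * n - k) + lfactorial(n) -
               lfactorial(2 * n) - lfactorial(k) - lfactorial(n - k))
  den <- cks / cks[n + 1]                 # monic in sigma, low-to-high
  num <- cks * (-1)^k / cks[n + 1]
  b0 <- num[n + 1]                        # = (-1)^n
  a <- den[1:n]
  A <- rbind(-rev(a), cbind(diag(1, n - 1, n - 1), 0))
  if (n == 1) A <- matrix(-a, 1, 1)
  B <- matrix(c(1, rep(0, n - 1)), n, 1)
  Cc <- matrix(rev(num[1:n] - b0 * a), 1, n)
  r <- a[1]^(1 / n)                       # grading radius ~ |a0|^(1/n)
  d <- r^(-(0:(n - 1)))
  A <- A * outer(1 / d, d)                # T^-1 A T with T = diag(d)
  B <- B / d
  Cc <- Cc * rep(d, each = 1)
  sys <- ss(A / tau, B / tau, Cc, matrix(b0, 1, 1),
            state_labels = paste0("delay", seq_len(n)))
  sys
}

# Osborne-style diagonal balancing: returns d such that diag(1/d) M diag(d)
# has roughly equal row and column norms.
balance_diag <- function(M) {
  n <- nrow(M)
  d <- rep(1, n)
  Mb <- M
  for (sweep in 1:4) {
    for (i in seq_len(n)) {
      ci <- sum(abs(Mb[, i])) - abs(Mb[i, i])
      ri <- sum(abs(Mb[i, ])) - abs(Mb[i, i])
      if (ci > 0 && ri > 0) {
        f <- sqrt(ri / ci)
        f <- min(max(f, 1e-8), 1e8)
        Mb[, i] <- Mb[, i] * f
        Mb[i, ] <- Mb[i, ] / f
        d[i] <- d[i] * f
      }
    }
  }
  list(Mb = Mb, d = d)
}

#' Solve the continuous algebraic Riccati equation
#'
#' Finds the stabilizing symmetric solution `P` of
#' \deqn{A'P + PA - (PB + N) R^{-1} (B'P + N') + Q = 0}
#' via the stable invariant subspace of the associated Hamiltonian matrix.
#' With the optional cross-weight `N` this covers quadratic costs with a
#' control feedthrough (as arises from the differentiator channel in the
#' tracking cost). Both the LQR gain and the Kalman gain used for controller
#' synthesis come from this routine.
#'
#' @param A,B system matrices.
#' @param Q symmetric positive semidefinite state weight.
#' @param R symmetric positive definite control weight.
#' @param N optional cross-weight matrix (n x m), default zero.
#' @details The stable invariant subspace of the Hamiltonian is extracted
#'   with the matrix sign function (scaled Newton iteration), which remains
#'   well behaved for defective eigenvalues such as the double pole of the
#'   critically damped noise prefilter; the solution is accepted only if the
#'   relative equation residual is below `1e-8`.
#' @return A list with `P` (stabilizing solution), `K` (= `R^{-1}(B'P + N')`)
#'   and `residual` (relative equation residual).
#' @export
solve_care <- function(A, B, Q, R, N = NULL) {
  A <- as_matrix(A); B <- as_matrix(B); Q <- as_matrix(Q); R <- as_matrix(R)
  n <- nrow(A); m <- ncol(B)
  if (is.null(N)) N <- matrix(0, n, m) else N <- as_matrix(N)
  Q <- (Q + t(Q)) / 2; R <- (R + t(R)) / 2
  er <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(er) <= 0) stop("R must be positive definite")
  Ri <- solve(R)
  # reduce cross-term problem to standard form
  At <- A - B %*% Ri %*% t(N)
  Qt <- Q - N %*% Ri %*% t(N)
  Qt <- (Qt + t(Qt)) / 2
  G <- B %*% Ri %*% t(B)
  H <- rbind(cbind(At, -G), cbind(-Qt, -t(At)))
  # similarity balancing, then matrix sign of H by scaled Newton iteration
  bal <- balance_diag(H)
  S <- bal$Mb
  ok <- FALSE
  for (it in 1:100) {
    Si <- tryCatch(solve(S), error = function(e) NULL)
    if (is.null(Si))
      stop("Riccati failure: Hamiltonian is (numerically) singular; ",
           "pair may not be stabilizable/detectable")
    dS <- abs(det(S))
    cs <- if (is.finite(dS) && dS > 0) dS^(-1 / (2 * n)) else 1
    Snew <- 0.5 * (cs * S + Si / cs)
    if (norm(Snew - S, "F") <= 1e-12 * norm(Snew, "F")) { S <- Snew; ok <- TRUE; break }
    S <- Snew
  }
  if (!ok) stop("Riccati failure: sign iteration did not converge ",
                "(imaginary-axis Hamiltonian eigenvalues?)")
  W <- 0.5 * (diag(2 * n) - S)       # projector onto the stable subspace
  sv <- svd(W)
  rk <- sum(sv$d > 0.5)              # projector singular values are >= 1 or ~ 0
  if (rk != n)
    stop("Riccati failure: stable subspace has dimension ", rk,
         ", expected ", n, " (pair may not be stabilizable/detectable)")
  V <- bal$d * sv$u[, 1:n, drop = FALSE]   # undo balancing row-wise
  X1 <- V[1:n, , drop = FALSE]
  X2 <- V[(n + 1):(2 * n), , drop = FALSE]
  if (rcond_safe(X1) < 1e-13) stop("Riccati failure: singular subspace basis")
  P <- X2 %*% solve(X1)
  P <- (P + t(P)) / 2
  K <- Ri %*% (t(B) %*% P + t(N))
  res <- t(A) %*% P + P %*% A - (P %*% B + N) %*% K + Q
  rel <- norm(res, "F") / (1 + norm(P, "F"))
  if (!is.finite(rel) || rel > 1e-8)
    stop("Riccati solution failed residual check (", format(rel), ")")
  list(P = P, K = K, residual = rel)
}

#' Solve the continuous Lyapunov equation
#'
#' Stabilized solution of `A P + P A' + Q = 0` by the Kronecker-product
#' linear solve; used for Gramians and stationary covariances. `A` must be
#' Hurwitz (all eigenvalues in the open left half-plane), otherwise the
#' Gramian does not exist.
#'
#' @param A Hurwitz matrix.
#' @param Q symmetric positive semidefinite matrix.
#' @return The symmetric solution matrix `P`.
#' @export
solve_lyapunov <- function(A, Q) {
  A <- as_matrix(A); Q <- as_matrix(Q)
  n <- nrow(A)
  if (max(Re(eigen(A, only.values = TRUE)$values)) >= -1e-12)
    stop("A must be Hurwitz: Lyapunov/Gramian solution undefined")
  M <- diag(n) %x% A + A %x% diag(n)
  P <- matrix(solve(M, -as.vector(Q)), n, n)
  (P + t(P)) / 2
}

#' Hankel singular values via balanced Gramians
#'
#' Computes the Hankel singular values of an asymptotically stable system:
#' the singular values shared by the controllability and observability
#' Gramians in the balanced realization. They count the dynamically
#' significant states of the system and are the complexity measure applied
#' to fitted controllers. Values below `1e-12` times the largest are
#' reported as exact zeros (numerical floor for near-unobservable states).
#'
#' @param sys a stable `"ss"` object.
#' @return Numeric vector of length `nstates(sys)`, nonnegative, descending.
#' @examples
#' balanced_hsv(ss(-1, 2, 3))   # |b c| / (2 a) = 3
#' @export
balanced_hsv <- function(sys) {
  n <- nstates(sys)
  if (max(Re(eigen(sys$A, only.values = TRUE)$values)) >= -1e-12)
    stop("balanced_hsv requires an asymptotically stable system")
  Wc <- solve_lyapunov(sys$A, sys$B %*% t(sys$B))
  Wo <- solve_lyapunov(t(sys$A), t(sys$C) %*% sys$C)
  Lc <- sym_sqrt(Wc)
  Lo <- sym_sqrt(Wo)
  sv <- svd(Lo %*% Lc, nu = 0, nv = 0)$d
  sv <- sort(sv, decreasing = TRUE)
  if (sv[1] > 0) sv[sv < 1e-12 * sv[1]] <- 0
  sv
}

sym_sqrt <- function(W) {
  e <- eigen((W + t(W)) / 2, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

#' Frequency response of a state-space model
#'
#' Evaluates `G(i omega) = C (i omega I - A)^{-1} B + D` on a grid of
#' angular frequencies. An eigen-decomposition of `A` is used when well
#' conditioned (one O(n^3) factorization, then O(n^2) per frequency), with a
#' direct linear solve per frequency as fallback.
#'
#' @param sys an `"ss"` object.
#' @param omega vector of angular frequencies in rad/s, positive ascending.
#' @return An object of class `"freqresp"`: list with `omega` and `values`,
#'   a complex array of dimension `c(p, m, length(omega))`.
#' @export
freqresp <- function(sys, omega) {
  omega <- as.numeric(omega)
  if (any(!is.finite(omega)) || any(omega <= 0)) stop("omega must be positive")
  if (is.unsorted(omega, strictly = TRUE)) stop("omega must be strictly ascending")
  n <- nstates(sys); m <- ncol(sys$B); p <- nrow(sys$C)
  ev <- if (n > 0) eigen(sys$A, only.values = TRUE)$values else complex(0)
  for (w in omega) {
    if (n > 0 && any(Mod(1i * w - ev) < 1e-10 * max(1, w)))
      stop("marginal pole at omega = ", w, " rad/s lies on the evaluation grid")
  }
  vals <- array(0i, dim = c(p, m, length(omega)))
  if (n == 0) {
    for (k in seq_along(omega)) vals[, , k] <- sys$D
  } else {
    ed <- eigen(sys$A)
    use_eig <- rcond_safe_c(ed$vectors) > 1e-9
    if (use_eig) {
      ViB <- solve(ed$vectors, sys$B)        # n x m
      CV <- sys$C %*% ed$vectors             # p x n
      for (k in seq_along(omega)) {
        g <- 1 / (1i * omega[k] - ed$values)
        vals[, , k] <- CV %*% (g * ViB) + sys$D
      }
    } else {
      for (k in seq_along(omega)) {
        vals[, , k] <- sys$C %*% solve(1i * omega[k] * diag(n) - sys$A, sys$B) + sys$D
      }
    }
  }
  structure(list(omega = omega, values = vals), class = "freqresp")
}

rcond_safe_c <- function(M) {
  fn <- function(X) sqrt(sum(Mod(X)^2))
  tryCatch(1 / (fn(M) * fn(solve(M))), error = function(e) 0)
}

#' Zero-order-hold discretization
#'
#' Discretizes a continuous-time model at sample interval `dt` under a
#' zero-order hold on the inputs, via the block matrix exponential. The
#' discrete model reproduces the continuous response exactly at the sample
#' instants for piecewise-constant inputs.
#'
#' @param sys an `"ss"` object.
#' @param dt sample interval in seconds.
#' @return An object of class `"ssd"`: list with `Ad`, `Bd`, `C`, `D`, `dt`.
#' @export
discretize_zoh <- function(sys, dt) {
  if (length(dt) != 1 || !is.finite(dt) || dt <= 0) stop("dt must be > 0")
  n <- nstates(sys); m <- ncol(sys$B)
  if (n == 0) {
    return(structure(list(Ad = matrix(0, 0, 0), Bd = matrix(0, 0, m),
                          C = sys$C, D = sys$D, dt = dt), class = "ssd"))
  }
  M <- rbind(cbind(sys$A, sys$B), matrix(0, m, n + m)) * dt
  E <- as.matrix(Matrix::expm(M))
  structure(list(Ad = E[1:n, 1:n, drop = FALSE],
                 Bd = E[1:n, (n + 1):(n + m), drop = FALSE],
                 C = sys$C, D = sys$D, dt = dt),
            class = "ssd")
}

#' Simulate a discretized model
#'
#' Propagates `x[k+1] = Ad x[k] + Bd u[k]`, `y[k] = C x[k] + D u[k]` from a
#' given initial state over an input sequence.
#'
#' @param dsys an `"ssd"` object from [discretize_zoh()].
#' @param inputs numeric matrix (samples x inputs) or vector for one input.
#' @param x0 initial state (default zero).
#' @return Numeric matrix of outputs, samples x outputs.
#' @export
simulate_ss <- function(dsys, inputs, x0 = NULL) {
  if (is.vector(inputs)) inputs <- matrix(inputs, ncol = 1)
  m <- ncol(dsys$Bd)
  if (ncol(inputs) != m) stop("inputs must have ", m, " column(s)")
  n <- nrow(dsys$Ad); N <- nrow(inputs); p <- nrow(dsys$C)
  if (is.null(x0)) x0 <- rep(0, n)
  y <- matrix(0, N, p)
  x <- as.numeric(x0)
  for (k in seq_len(N)) {
    u <- inputs[k, ]
    y[k, ] <- dsys$C %*% x + dsys$D %*% u
    x <- dsys$Ad %*% x + dsys$Bd %*% u
  }
  y
}

#' Serialize a state-space model to JSON
#'
#' @param sys an `"ss"` object.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
ss_to_json <- function(sys, path = NULL) {
  obj <- list(A = unclass(sys$A), B = unclass(sys$B), C = unclass(sys$C),
              D = unclass(sys$D), state_labels = sys$state_labels)
  js <- jsonlite::toJSON(obj, digits = NA, matrix = "rowmajor")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
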