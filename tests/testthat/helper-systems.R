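# Small systems and oracles shared across test files.

first_order <- function(a, b = 1, c = 1) ss(-a, b, c)

static_gain <- function(k) ss(matrix(0, 0, 0), matrix(0, 0, 1),
                              matrix(0, 1, 0), k)

# exact transfer of a first-order lag b*c/(s+a)
fo_tf <- function(a, b, c, w) b * c / (1i * w + a)

# random stable system with eigenvalues in [-re_max, -re_min]
rand_stable <- function(n, m = 1, p = 1, re_min = 0.2, re_max = 3) {
  d <- -runif(n, re_min, re_max)
  T <- matrix(rnorm(n * n), n)
  while (abs(det(T)) < 1e-3) T <- matrix(rnorm(n * n), n)
  A <- T %*% diag(d, n) %*% solve(T)
  ss(A, matrix(rnorm(n * m), n), matrix(rnorm(p * n), p))
}

# independent Lyapunov oracle: direct Kronecker solve written out inline
lyap_oracle <- function(A, Q) {
  n <- nrow(A)
  matrix(solve(diag(n) %x% A + A %x% diag(n), -as.vector(Q)), n, n)
}

# scalar frequency response helper
fr1 <- function(sys, w) {
  r <- freqresp(sys, w)
  as.complex(r$values[1, 1, seq_along(w)])
}

young_params <- function() {
  subject_params(latency_tau = 10^-0.5879, noise_intensity = 10^-2.7556,
                 noise_bandwidth = 10^0.9495, rho = 10^-0.7257)
}

elderly_params <- function() {
  subject_params(latency_tau = 10^-0.6252, noise_intensity = 10^-2.6408,
                 noise_bandwidth = 10^0.9039, rho = 10^-0.3010)
}
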