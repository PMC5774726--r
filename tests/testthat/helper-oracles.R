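# Independent oracles used across the test files. Everything here is
# deliberately brute-force and slow: quadrature, literal contour
# integration, null-space solves. None of it shares code with the package
# paths it checks (the matrix exponential used below comes from Matrix's
# Pade implementation via expm_propagator, which serves as the arbiter).

random_profile <- function(d, lambda = 0, lo = 1, hi = 10) {
  rate_profile(stats::runif(d, lo, hi), reinit_prob = lambda)
}

# Lifetime-weighted occupancy integral int_0^inf c e^{-ct} Q(t) dt by
# adaptive quadrature, entry by entry.
quadrature_laplace <- function(profile, cc) {
  d <- profile$d
  out <- matrix(0, d, d)
  for (i in seq_len(d)) for (j in seq_len(d)) {
    out[i, j] <- stats::integrate(
      function(tt) vapply(tt, function(u) {
        cc * exp(-cc * u) * expm_propagator(profile, u)[i, j]
      }, numeric(1)),
      0, Inf, rel.tol = 1e-11)$value
  }
  out
}

# Literal numerical contour integration of the circular-chain propagator
# entries: (1/2*pi*i) * closed integral of e^{ts} N_ij(s) / P(s) ds over a
# circle enclosing every root of P. Periodic trapezoid rule (exponentially
# convergent for analytic integrands).
contour_propagator <- function(profile, t, n_nodes = 4096) {
  eps <- profile$epsilons
  lam <- profile$reinit_prob
  d <- profile$d
  center <- -mean(eps)
  radius <- max(eps) + abs(center) + 1
  theta <- 2 * pi * (seq_len(n_nodes) - 1) / n_nodes
  s <- center + radius * exp(1i * theta)
  P <- vapply(s, function(ss) prod(ss + eps), complex(1)) - lam * prod(eps)
  Q <- matrix(0, d, d)
  for (i in seq_len(d)) for (j in seq_len(d)) {
    N <- if (i < j) {
      lam * prod(eps[c(seq_len(i - 1), j:d)]) *
        vapply(s, function(ss) prod(ss + eps[seq(i + 1, j - 1,
                                                 length.out = max(0, j - 1 - i))]),
               complex(1))
    } else {
      prod(eps[seq(j, i - 1, length.out = max(0, i - j))]) *
        vapply(s, function(ss) {
          ks <- c(seq_len(j - 1), seq(i + 1, d, length.out = max(0, d - i)))
          prod(ss + eps[ks])
        }, complex(1))
    }
    integrand <- exp(t * s) * N / P * (s - center)   # ds = i(s - c) dtheta
    Q[i, j] <- Re(mean(integrand))
  }
  Q
}

# Null vector of the lambda = 1 generator by linear solve (replace the last
# balance equation with the normalization constraint).
nullspace_steady_state <- function(profile) {
  Tm <- build_generator(profile)
  d <- nrow(Tm)
  A <- rbind(Tm[-d, , drop = FALSE], rep(1, d))
  as.numeric(solve(A, c(rep(0, d - 1), 1)))
}

expect_matrix_close <- function(a, b, tol) {
  expect_lt(max(abs(a - b)), tol)
}
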