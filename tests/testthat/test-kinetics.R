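test_that("transition matrix has the step/recycle structure and conserves mass", {
  pr0 <- rate_profile(c(2, 3), reinit_prob = 0, alpha = 10)
  expect_equal(build_transition_matrix(pr0),
               matrix(c(0.8, 0.2, 0, 0.7), 2, 2))
  pr1 <- rate_profile(c(2, 3), reinit_prob = 1, alpha = 10)
  U1 <- build_transition_matrix(pr1)
  expect_equal(U1[1, 2], 0.3)
  expect_equal(U1[2, 2], 0.7)

  set.seed(1)
  for (lam in c(0, 0.3, 1)) {
    pr <- random_profile(5, lam)
    U <- build_transition_matrix(pr)
    expect_true(all(U >= 0 & U <= 1))
    if (lam == 1) {
      expect_equal(colSums(U), rep(1, 5))
    } else {
      expect_true(all(colSums(U) <= 1 + 1e-12))
      # only the termination column leaks, by (1 - lambda) p_d
      expect_equal(colSums(U)[5],
                   1 - (1 - lam) * pr$epsilons[5] / pr$alpha)
    }
  }
  expect_error(rate_profile(c(2, 30), alpha = 10), "p_2")
})

test_that("generator is alpha * (U - I) with zero column sums iff lambda = 1", {
  expect_equal(build_generator(rate_profile(c(2, 3), 0)),
               matrix(c(-2, 2, 0, -3), 2, 2))
  expect_equal(build_generator(rate_profile(c(2, 3), 1)),
               matrix(c(-2, 2, 3, -3), 2, 2))
  set.seed(2)
  for (rep in 1:5) {
    pr <- random_profile(6, 1)
    Tm <- build_generator(pr)
    expect_equal(colSums(Tm), rep(0, 6), tolerance = 1e-12)
    expect_equal(Tm, pr$alpha * (build_transition_matrix(pr) - diag(6)))
    # Gershgorin: all eigenvalues in the closed left half-plane
    expect_true(all(Re(eigen(Tm, only.values = TRUE)$values) <= 1e-10))
  }
})

test_that("stationary occupancy is inverse-rate weighted and matches the null space", {
  pi1 <- steady_state_distribution(rate_profile(c(1, 2, 4), 1))
  expect_equal(pi1$probs, c(4, 2, 1) / 7)
  expect_equal(steady_state_distribution(rate_profile(rep(3, 7), 1))$probs,
               rep(1 / 7, 7))
  set.seed(3)
  for (rep in 1:5) {
    pr <- random_profile(6, 1)
    expect_equal(steady_state_distribution(pr)$probs,
                 nullspace_steady_state(pr), tolerance = 1e-10)
  }
  expect_error(steady_state_distribution(rate_profile(c(1, 2), 0.5)),
               "absorbing")
})

test_that("polypeptides per template follows the decay-weighted product formula", {
  expect_equal(
    polypeptides_per_template(rate_profile(c(1, 1), 0), decay_model(1)), 0.25)
  pr <- rate_profile(c(2, 3), 1)
  expect_equal(polypeptides_per_template(pr, decay_model(1)), 1.0)
  # independent check: N = c * eps_d * int e^{-ct} Q(t)_{d,1} dt
  num <- stats::integrate(function(tt) vapply(tt, function(u) {
    1 * 3 * exp(-u) * expm_propagator(pr, u)[2, 1]
  }, numeric(1)), 0, Inf, rel.tol = 1e-12)$value
  expect_equal(polypeptides_per_template(pr, decay_model(1)), num,
               tolerance = 1e-9)
  # c -> 0 on the circular chain approaches the steady circulation flux
  pr30 <- rate_profile(rep(10, 30), 1)
  for (cc in c(1e-3, 1e-5)) {
    expect_equal(
      polypeptides_per_template(pr30, decay_model(cc)) / steady_flux(pr30),
      1, tolerance = 50 * cc)
  }
  # completions per initiation are monotone decreasing in c for any lambda;
  # the lifetime-weighted count shares this on the fully recycling chain
  set.seed(4)
  cgrid <- c(0.01, 0.1, 0.5, 1, 5, 20)
  for (lam in c(0, 0.5, 1)) {
    pr <- random_profile(8, lam)
    per_init <- vapply(cgrid, function(cc)
      polypeptides_per_template(pr, decay_model(cc), lifetime_weighted = FALSE),
      numeric(1))
    expect_true(all(diff(per_init) < 0))
  }
  pr1 <- random_profile(8, 1)
  weighted <- vapply(cgrid, function(cc)
    polypeptides_per_template(pr1, decay_model(cc)), numeric(1))
  expect_true(all(diff(weighted) < 0))
  expect_error(polypeptides_per_template(rate_profile(c(1, 2), 1),
                                         decay_model(0)), "c > 0")
  # log-space evaluation survives long chains with large rates
  big <- rate_profile(rep(50, 300), 0)
  expect_true(is.finite(polypeptides_per_template(big, decay_model(0.01))))
})

test_that("mean ribosome load matches the equal-rate closed form and quadrature", {
  d <- 30; R <- 10; epsv <- 10
  middle_form <- function(cc) {
    kappa <- (epsv / (cc + epsv))^d
    ((cc + epsv) * (1 - kappa) - cc * d * kappa) / (R * cc)
  }
  pr <- rate_profile(rep(epsv, d), 0)
  # identity with the closed form, checked where the closed form itself is
  # evaluable without catastrophic cancellation (c of order eps/10)
  got1 <- mean_ribosomes_per_template(pr, decay_model(1, ribosome_spacing = R))
  expect_equal(got1, middle_form(1), tolerance = 1e-12)
  # c << eps regime: closed form agrees to its own double-precision limit
  # and the c d (d+1) / (2 R eps) approximation holds within 5%
  cc <- 0.01
  got <- mean_ribosomes_per_template(pr, decay_model(cc, ribosome_spacing = R))
  expect_equal(got, middle_form(cc), tolerance = 1e-10)
  approx <- cc * d * (d + 1) / (2 * R * epsv)
  expect_equal(approx, 0.0465)
  expect_lt(abs(got - approx) / approx, 0.05)
  # random rates vs brute-force quadrature of the decay-weighted progress
  set.seed(5)
  pr3 <- random_profile(3, 0)
  cc <- 0.7
  oracle <- sum(vapply(1:3, function(i) {
    (i / 2) * stats::integrate(function(tt) vapply(tt, function(u) {
      cc * exp(-cc * u) * expm_propagator(pr3, u)[i, 1]
    }, numeric(1)), 0, Inf, rel.tol = 1e-11)$value
  }, numeric(1)))
  expect_equal(
    mean_ribosomes_per_template(pr3, decay_model(cc, ribosome_spacing = 2)),
    oracle, tolerance = 1e-8)
})

test_that("expected chain length is the occupancy-weighted site index", {
  expect_equal(mean_chain_length(rep(1 / 3, 3)), 2)
  expect_equal(mean_chain_length(occupancy_vector(c(1, 0, 0, 0))), 1)
  expect_equal(mean_chain_length(steady_state_distribution(
    rate_profile(c(1, 2, 4), 1))), 11 / 7)
})

test_that("greedy codon optimization raises the limiting rate and the flux", {
  pr <- rate_profile(c(1, 5, 5), 1)
  steps <- optimize_limiting_codons(pr, c(5, 5, 5))
  expect_equal(nrow(steps), 1L)
  expect_equal(steps$site, 1L)
  expect_equal(steady_flux(pr), 1 / 1.4)
  expect_equal(steps$flux, 5 / 3)
  # already optimal: nothing to do
  pr2 <- rate_profile(c(5, 5, 5), 1)
  expect_equal(nrow(optimize_limiting_codons(pr2, c(5, 5, 5))), 0L)
  # monotone non-decreasing flux sequence
  set.seed(6)
  pr10 <- random_profile(10, 1)
  seq10 <- optimize_limiting_codons(pr10, 2 * pr10$epsilons)
  expect_true(all(diff(seq10$flux) >= 0))
  expect_true(all(diff(c(steady_flux(pr10), seq10$flux)) >= 0))
  expect_error(optimize_limiting_codons(pr10, pr10$epsilons * 0.5), "below")
})
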