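test_that("rate sampling hits the requested family parameters and is reproducible", {
  spec <- rate_ensemble_spec("gamma", list(shape = 10, scale = 5), d = 30,
                             n_templates = 5000, seed = 21)
  ens <- sample_rate_profiles(spec)
  se <- sqrt(10) * 5 / sqrt(5000)
  expect_true(all(abs(colMeans(ens$epsilons) - 50) < 3 * se + 0.3))

  specn <- rate_ensemble_spec("normal", list(mean = 50, sd = 15), d = 10,
                              n_templates = 5000, seed = 22)
  ensn <- sample_rate_profiles(specn)
  expect_true(all(ensn$epsilons > 0))
  expect_lt(abs(stats::sd(ensn$epsilons) - 15) / 15, 0.05)

  specf <- rate_ensemble_spec("fixed", list(), d = 4, n_templates = 7,
                              seed = 1, per_site_means = c(1, 2, 3, 4))
  ensf <- sample_rate_profiles(specf)
  expect_equal(ensf$epsilons, matrix(rep(c(1, 2, 3, 4), each = 7), 7, 4))

  # bit-identical resampling under the same spec, and the spec seed does not
  # disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99)
  ens2 <- sample_rate_profiles(spec)
  expect_identical(runif(1), before)
  expect_identical(ens$epsilons, ens2$epsilons)

  expect_error(rate_ensemble_spec("normal", list(mean = 1, sd = 100), d = 5,
                                  n_templates = 10, seed = 1),
               "resemble")
  expect_error(rate_ensemble_spec("gamma", list(shape = 10, scale = 5),
                                  d = 5, n_templates = 10),
               "seed")
})

test_that("copula correlation preserves marginals and delivers the requested dependence", {
  base <- rate_ensemble_spec("gamma", list(shape = 10, scale = 5), d = 30,
                             n_templates = 5000, seed = 23,
                             correlation = list(mode = "along_sites",
                                                strength = 0))
  ens0 <- sample_rate_profiles(base)
  ks <- suppressWarnings(stats::ks.test(as.vector(ens0$epsilons), stats::pgamma,
                                        shape = 10, scale = 5))
  expect_gt(ks$p.value, 0.01)

  strong <- rate_ensemble_spec("gamma", list(shape = 10, scale = 5), d = 30,
                               n_templates = 500, seed = 24,
                               correlation = list(mode = "along_sites",
                                                  strength = 0.9))
  enss <- sample_rate_profiles(strong)
  expect_gt(enss$lag1, 0.6)
  # marginal family parameters preserved within 5% despite the dependence
  # (a KS test would be invalid here: the draws are serially correlated)
  expect_lt(abs(mean(enss$epsilons) - 50) / 50, 0.05)
  expect_lt(abs(stats::sd(enss$epsilons) - sqrt(10) * 5) / (sqrt(10) * 5), 0.05)

  across <- rate_ensemble_spec("gamma", list(shape = 10, scale = 5), d = 5,
                               n_templates = 2000, seed = 25,
                               correlation = list(mode = "across_templates",
                                                  strength = 0.9))
  ensa <- sample_rate_profiles(across)
  expect_gt(ensa$lag1, 0.6)
  ma <- site_moving_average(ensa, site = 3, window = 100)
  expect_equal(nrow(ma), 2000 - 100 + 1)
  expect_true(all(is.finite(ma$rate_moving_average)))

  expect_error(rate_ensemble_spec("gamma", list(shape = 10, scale = 5), d = 5,
                                  n_templates = 10, seed = 1,
                                  correlation = list(mode = "along_sites",
                                                     strength = 1)),
               "strength")
})

test_that("occupancy simulation starts at v0, relaxes to each template's stationary law, and stabilizes", {
  spec <- rate_ensemble_spec("gamma", list(shape = 10, scale = 5), d = 6,
                             n_templates = 50, seed = 26)
  ens <- sample_rate_profiles(spec)
  traj <- simulate_occupancy(ens, c(0, 0.1, 5))
  expect_equal(dim(traj$V), c(50, 6, 3))
  for (j in 1:50) expect_equal(traj$V[j, , 1], c(1, 0, 0, 0, 0, 0))
  # late times: within 1e-6 of the per-template stationary distribution
  for (j in 1:50) {
    pi_j <- steady_state_distribution(ensemble_profile(ens, j))$probs
    expect_lt(max(abs(traj$V[j, , 3] - pi_j)), 1e-6)
  }
  expect_equal(traj$n_dropped + dim(traj$V)[1], 50)

  # distribution of the terminal readout stabilizes at late times
  spec30 <- rate_ensemble_spec("gamma", list(shape = 10, scale = 5), d = 30,
                               n_templates = 1000, seed = 27)
  ens30 <- sample_rate_profiles(spec30)
  T1 <- time_unit(ens30)
  tr30 <- simulate_occupancy(ens30, T1 * c(8, 10, 12))
  v10 <- protein_output_distribution(tr30, "terminal_occupancy", T1 * 10)
  v12 <- protein_output_distribution(tr30, "terminal_occupancy", T1 * 12)
  ksd <- suppressWarnings(stats::ks.test(v10, v12))$statistic
  expect_lt(unname(ksd), 0.01)
})

test_that("protein output metrics: point mass, stationary flux identity, log-normality screen", {
  one <- rate_ensemble_spec("gamma", list(shape = 10, scale = 5), d = 6,
                            n_templates = 1, seed = 28)
  ens1 <- sample_rate_profiles(one)
  tr1 <- simulate_occupancy(ens1, c(1, 2))
  x1 <- protein_output_distribution(tr1, "terminal_occupancy", 2)
  expect_length(x1, 1L)

  spec <- rate_ensemble_spec("gamma", list(shape = 10, scale = 5), d = 6,
                             n_templates = 40, seed = 29)
  ens <- sample_rate_profiles(spec)
  tr <- simulate_occupancy(ens, c(0.5, 8))
  flux <- protein_output_distribution(tr, "completion_flux", 8)
  expect_equal(as.vector(flux),
               apply(ens$epsilons, 1, function(e) 1 / sum(1 / e)),
               tolerance = 1e-5, ignore_attr = TRUE)
  # cumulative protein is non-decreasing without decay
  expect_true(all(tr$protein[, 2] >= tr$protein[, 1]))

  # central log-normality of the population sample (tails may deviate)
  big <- rate_ensemble_spec("gamma", list(shape = 10, scale = 5), d = 30,
                            n_templates = 5000, seed = 30)
  y <- log(steady_state_protein_sample(sample_rate_profiles(big)))
  p <- (seq_along(y) - 0.5) / length(y)
  inner <- p > 0.05 & p < 0.95
  qq_cor <- stats::cor(sort(y)[inner], stats::qnorm(p[inner]))
  expect_gt(qq_cor, 0.99)

  expect_error(protein_output_distribution(tr, "terminal_occupancy", 3.3),
               "grid")
})

test_that("slow codons stall ribosomes at the slow site", {
  set.seed(31)
  means <- stats::runif(30, 50, 150)
  mk <- function(site) {
    m <- means; m[site] <- 1
    spec <- rate_ensemble_spec("gamma", list(shape = 10, scale = 5), d = 30,
                               n_templates = 200, seed = 32,
                               per_site_means = m,
                               slow_sites = list(list(site = site, mean = 1)))
    slow_codon_profile(sample_rate_profiles(spec))
  }
  expect_equal(mk(20)$argmax_site, 20L)
  expect_equal(mk(7)$argmax_site, 7L)

  # no slow site: late-time mean occupancy tracks the mean inverse rate
  flat <- rate_ensemble_spec("gamma", list(shape = 10, scale = 5), d = 10,
                             n_templates = 300, seed = 33)
  ensf <- sample_rate_profiles(flat)
  trf <- simulate_occupancy(ensf, c(30 / min(ensf$epsilons)))
  mean_occ <- colMeans(trf$V[, , 1])
  oracle <- colMeans(t(apply(ensf$epsilons, 1,
                             function(e) (1 / e) / sum(1 / e))))
  expect_equal(mean_occ, oracle, tolerance = 1e-6)
})

test_that("transient statistics: linear growth, decay-induced bending, shrinking site spread", {
  spec <- rate_ensemble_spec("exponential", list(mean = 10), d = 30,
                             n_templates = 200, seed = 34, reinit_prob = 0)
  ens <- sample_rate_profiles(spec)
  early <- seq(0.1, 1.2, by = 0.1)
  tr <- simulate_occupancy(ens, early)
  ts <- transient_statistics(tr)
  fit <- stats::lm(L ~ time, data = ts$L)
  expect_gt(summary(fit)$r.squared, 0.99)

  # protein decay bends L below the early-time linear extrapolation
  grid <- seq(0.2, 6, by = 0.4)
  trd <- simulate_occupancy(ens, grid, protein_decay_rate = 0.2)
  tsd <- transient_statistics(trd)
  fe <- stats::lm(L ~ time, data = tsd$L[tsd$L$time <= 1.2, ])
  extrap <- stats::predict(fe, newdata = data.frame(time = 6))
  expect_lt(tsd$L$L[length(grid)], extrap)

  # per-site log-variance spread across sites shrinks at successive late times
  spec1 <- rate_ensemble_spec("exponential", list(mean = 10), d = 30,
                              n_templates = 200, seed = 35)
  ens1 <- sample_rate_profiles(spec1)
  T1 <- time_unit(ens1)
  trl <- simulate_occupancy(ens1, T1 * c(1, 2, 3, 4, 6))
  tsl <- transient_statistics(trl)
  spread <- apply(tsl$log_variance, 1, stats::sd, na.rm = TRUE)
  expect_true(all(diff(spread) < 0))
  expect_error(transient_statistics(simulate_occupancy(
    sample_rate_profiles(rate_ensemble_spec("fixed", list(value = 5), d = 3,
                                            n_templates = 1, seed = 1)),
    c(1))), "2 templates")
})

test_that("template dropping is accounted for and bounded", {
  spec <- rate_ensemble_spec("gamma", list(shape = 10, scale = 5), d = 4,
                             n_templates = 10, seed = 36)
  ens <- sample_rate_profiles(spec)
  # poison one template with a rate far beyond double-precision dynamics
  ens$epsilons[3, ] <- 1e308
  expect_error(simulate_occupancy(ens, c(1, 2)), "dropped")
  tr <- simulate_occupancy(ens, c(1, 2), max_drop_frac = 0.5)
  expect_equal(tr$n_dropped, 1L)
  expect_equal(dim(tr$V)[1] + tr$n_dropped, 10L)
  expect_false(3L %in% tr$kept)
})
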